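# Core data containers: count tables (taxa rows x sample columns), rooted
# phylogenies, and two-group designs. Everything downstream consumes these.

#' Construct a count table
#'
#' A count table is an integer matrix of taxa (rows) by samples (columns) with
#' unique identifiers on both margins, optionally carrying a per-sample group
#' label. Library sizes are always recomputed from the matrix, never cached.
#'
#' @param counts Non-negative integer matrix with unique rownames (taxon IDs)
#'   and colnames (sample IDs).
#' @param sample_group Optional named character vector mapping sample IDs to
#'   group labels. Names must be a subset of `colnames(counts)`.
#' @param provenance Free-text tag recording where the table came from.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, sample_group = NULL, provenance = "") {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.numeric(counts)) stop("counts must be numeric")
  if (anyNA(counts) || any(!is.finite(counts))) stop("counts contain NA/NaN/Inf")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be integral (found non-integer cells)")
  }
  counts <- round(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must have taxon rownames and sample colnames")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon IDs")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs")
  if (!is.null(sample_group)) {
    if (is.null(names(sample_group))) {
      stop("sample_group must be named by sample ID")
    }
    # a superset labeling (e.g. carried over from a pre-filtering table) is
    # fine: keep the labels for this table's samples
    sample_group <- sample_group[names(sample_group) %in% colnames(counts)]
    if (!length(sample_group)) {
      stop("sample_group names must be sample IDs of the table")
    }
    sample_group <- vapply(sample_group, as.character, character(1))
  }
  structure(
    list(counts = counts, sample_group = sample_group, provenance = provenance),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf(
    "count_table: %d taxa x %d samples (library sizes %s-%s)%s\n",
    nrow(x$counts), ncol(x$counts),
    if (ncol(x$counts)) min(library_sizes(x)) else NA,
    if (ncol(x$counts)) max(library_sizes(x)) else NA,
    if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""
  ))
  invisible(x)
}

#' Per-sample library sizes (column sums)
#' @param table A `count_table` or `normalized_table`.
#' @return Named numeric vector of column sums.
#' @export
library_sizes <- function(table) {
  colSums(values_of(table))
}

#' Extract the numeric matrix from a table-like object
#'
#' @param x A `count_table`, `normalized_table`, or plain matrix.
#' @return The taxa x samples numeric matrix.
#' @export
values_of <- function(x) {
  if (inherits(x, "count_table")) return(x$counts)
  if (inherits(x, "normalized_table")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected a count_table, normalized_table, or matrix")
}

#' Read a count table from TSV or BIOM
#'
#' The TSV dialect is: header row of sample IDs, first column of taxon IDs,
#' tab-separated integer cells. BIOM is the JSON (v1) dialect; matrices stored
#' sample-major are transposed to the taxa-rows convention.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"biom"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 1) stop("malformed TSV count table")
    ids <- as.character(df[[1]])
    if (ncol(df) == 1) {
      m <- matrix(0, nrow = nrow(df), ncol = 0,
                  dimnames = list(ids, character(0)))
    } else {
      m <- as.matrix(df[, -1, drop = FALSE])
      if (!is.numeric(m)) stop("non-numeric cells in count table")
      rownames(m) <- ids
    }
    count_table(m, provenance = path)
  } else {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # observations x samples
    count_table(m, provenance = path)
  }
}

#' Write a count table to TSV or BIOM
#'
#' @param table A [count_table()].
#' @param path Output path.
#' @param format `"tsv"` or `"biom"`.
#' @return Invisibly, `path`. `read_count_table(write_count_table(x))`
#'   round-trips the matrix and its IDs exactly.
#' @export
write_count_table <- function(table, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  stopifnot(inherits(table, "count_table"))
  if (format == "tsv") {
    ids <- c(rownames(table$counts), colnames(table$counts))
    if (any(grepl("[\t\n]", ids))) {
      stop("taxon/sample IDs may not contain tabs or newlines in TSV output")
    }
    df <- data.frame(`#OTU_ID` = rownames(table$counts), table$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("#OTU_ID", colnames(table$counts))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(table$counts)
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Edges lacking a branch length get length 0 with a warning; negative branch
#' lengths are rejected.
#'
#' @param path Path to a Newick tree file.
#' @return An [ape::read.tree()] `phylo` object with non-negative edge lengths.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Drop samples below a library-size percentile
#'
#' Samples whose library size falls strictly below the requested percentile of
#' the library-size distribution (type-7 quantile) are dropped; ties at the
#' threshold are kept. The dropped IDs are preserved so clustering accuracy can
#' optionally count them as incorrectly clustered.
#'
#' @param table A [count_table()].
#' @param percentile Fraction in `[0, 1]`.
#' @return List with elements `kept` (a `count_table`) and `dropped`
#'   (character vector of removed sample IDs).
#' @export
filter_low_depth <- function(table, percentile) {
  stopifnot(inherits(table, "count_table"))
  if (!is.numeric(percentile) || percentile < 0 || percentile > 1) {
    stop("percentile must lie in [0, 1]")
  }
  if (ncol(table$counts) == 0) stop("table has no samples")
  ls <- library_sizes(table)
  thr <- stats::quantile(ls, percentile, type = 7, names = FALSE)
  keep <- ls >= thr
  kept <- count_table(table$counts[, keep, drop = FALSE],
                      sample_group = table$sample_group[
                        names(table$sample_group) %in% colnames(table$counts)[keep]],
                      provenance = table$provenance)
  list(kept = kept, dropped = colnames(table$counts)[!keep])
}

#' Add a pseudocount to every cell
#'
#' @param table A [count_table()] (left unmodified).
#' @param c Positive real added to every entry.
#' @return A real-valued matrix of the same shape.
#' @export
add_pseudocount <- function(table, c) {
  stopifnot(inherits(table, "count_table"))
  if (!is.numeric(c) || length(c) != 1 || c <= 0) stop("pseudocount must be > 0")
  table$counts + c
}

#' Construct a two-group / covariate design
#'
#' @param sample_ids Character vector of sample IDs.
#' @param group Character vector of group labels, parallel to `sample_ids`.
#' @param covariates Optional data.frame of additional (e.g. numeric)
#'   covariates for PERMANOVA, one row per sample.
#' @return An object of class `group_design` (a data.frame with rownames the
#'   sample IDs and a `group` column first).
#' @export
group_design <- function(sample_ids, group, covariates = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in design")
  if (length(group) != length(sample_ids)) stop("group/sample length mismatch")
  if (anyNA(group)) stop("missing group labels")
  df <- data.frame(group = as.character(group), row.names = sample_ids,
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(sample_ids)) stop("covariate rows mismatch")
    rownames(covariates) <- sample_ids
    df <- cbind(df, covariates)
  }
  class(df) <- c("group_design", "data.frame")
  df
}

# Index the two groups of a design against a sample ordering; errors unless
# exactly two labels are present and both are represented.
.two_groups <- function(design, sample_ids) {
  if (!all(sample_ids %in% rownames(design))) {
    stop("design does not label every analyzed sample")
  }
  g <- design[sample_ids, "group"]
  lev <- sort(unique(g))
  if (length(lev) != 2) {
    stop("two-group operations require exactly 2 group labels, got ",
         length(lev))
  }
  list(i1 = which(g == lev[1]), i2 = which(g == lev[2]), levels = lev, labels = g)
}
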