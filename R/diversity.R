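# Beta-diversity machinery: distance matrices, principal coordinates,
# sequential-SS PERMANOVA, and PAM clustering with the dropped-sample penalty
# convention used when scoring rarefied data.

.new_dist <- function(m, metric) {
  structure(list(matrix = m, metric = metric, sample_ids = rownames(m)),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix [%s]: %d samples\n", x$metric, nrow(x$matrix)))
  invisible(x)
}

#' Compute a between-sample distance matrix
#'
#' Supported metrics: `"euclidean"`, `"bray"` (Bray-Curtis), `"jaccard"`
#' (binary, presence/absence with presence defined as value > 0),
#' `"unweighted_unifrac"` and `"weighted_unifrac"` (normalized to `[0, 1]`).
#' UniFrac metrics need a rooted tree whose tips cover every taxon with a
#' nonzero total. Negative values (possible for unclamped variance-stabilized
#' data) are rejected for all non-Euclidean metrics.
#'
#' @param x A `count_table`, `normalized_table`, or taxa x samples matrix.
#' @param metric Metric tag (see Details).
#' @param tree A rooted `phylo` tree; required for the UniFrac metrics.
#' @return A `dist_matrix` (full symmetric matrix plus metric tag).
#' @export
compute_distance <- function(x, metric = c("euclidean", "bray", "jaccard",
                                           "unweighted_unifrac",
                                           "weighted_unifrac"),
                             tree = NULL) {
  metric <- match.arg(metric)
  v <- values_of(x)
  if (metric != "euclidean" && any(v < 0)) {
    stop("negative values are not admissible for metric '", metric,
         "'; clamp the variance-stabilized values or use Euclidean")
  }
  if (metric %in% c("euclidean", "bray", "jaccard")) {
    d <- switch(metric,
      euclidean = vegan::vegdist(t(v), method = "euclidean"),
      bray = vegan::vegdist(t(v), method = "bray"),
      jaccard = vegan::vegdist(t(v > 0) * 1, method = "jaccard", binary = TRUE)
    )
    m <- as.matrix(d)
  } else {
    if (is.null(tree)) stop("UniFrac metrics require a tree")
    nz <- rowSums(v) > 0
    v2 <- v[nz, , drop = FALSE]
    missing <- setdiff(rownames(v2), tree$tip.label)
    if (length(missing)) {
      stop("tree is missing tips for taxa: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    if (!ape::is.rooted(tree)) stop("UniFrac requires a rooted tree")
    tr <- ape::keep.tip(tree, rownames(v2))
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(v2, taxa_are_rows = TRUE),
      phyloseq::phy_tree(tr)
    )
    d <- phyloseq::UniFrac(ps, weighted = metric == "weighted_unifrac",
                           normalized = TRUE)
    m <- as.matrix(d)
  }
  m[m < 0] <- 0
  dimnames(m) <- list(colnames(v), colnames(v))
  .new_dist(m, metric)
}

#' Principal coordinate analysis
#'
#' Gower-centered eigendecomposition of the squared distances. Negative
#' eigenvalues are reported, not corrected; coordinates are returned for the
#' positive axes only and reproduce the input distances exactly when the input
#' is Euclidean.
#'
#' @param dm A `dist_matrix`.
#' @return An object of class `ordination` with `coordinates` (samples x
#'   axes), `eigenvalues` (all, descending) and `proportion_explained`
#'   (positive axes, over the positive-eigenvalue total).
#' @export
pcoa <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  m <- dm$matrix
  if (any(!is.finite(m))) stop("non-finite distances")
  n <- nrow(m)
  # cmdscale warns when fewer than k eigenvalues are positive; the full
  # eigenvalue vector (including negatives) is reported below regardless
  cm <- suppressWarnings(
    stats::cmdscale(stats::as.dist(m), k = max(n - 1, 1), eig = TRUE))
  eig <- sort(cm$eig, decreasing = TRUE)
  pos <- eig[eig > 1e-12]
  pts <- cm$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  rownames(pts) <- rownames(m)
  prop <- if (length(pos)) pos / sum(pos) else numeric(0)
  structure(list(coordinates = pts, eigenvalues = eig,
                 proportion_explained = prop),
            class = "ordination")
}

#' Sequential (type-I) PERMANOVA
#'
#' Partitions the Gower-centered total sum of squares of a distance matrix
#' over an ordered list of model terms, first term unadjusted and later terms
#' adjusted for earlier ones, with permutation p-values. Putting a library-size
#' term before the biological term controls for depth differences before
#' assessing biology.
#'
#' @param dm A `dist_matrix`.
#' @param design A [group_design()] covering the samples of `dm`.
#' @param terms Character vector of design column names, in model order
#'   (default: all covariates then `group` last if present, otherwise the
#'   design's column order).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return A `permanova_result`: data.frame of per-term df, SS, R2, pseudo-F
#'   and p, plus `residual_r2` and `n_perm`.
#' @export
permanova_sequential <- function(dm, design, terms = NULL, n_perm = 999,
                                 seed = NULL) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  ids <- dm$sample_ids
  if (!all(ids %in% rownames(design))) stop("design does not cover all samples")
  df <- as.data.frame(design)[ids, , drop = FALSE]
  if (is.null(terms)) terms <- colnames(df)
  if (!all(terms %in% colnames(df))) stop("unknown design terms")
  const <- vapply(terms, function(t) length(unique(df[[t]])) < 2, logical(1))
  if (any(const)) {
    warning("constant term(s): ", paste(terms[const], collapse = ", "),
            " (their R2 will be ~0)")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- stats::as.dist(dm$matrix)
  fml <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")),
                           env = environment())
  fit <- vegan::adonis2(fml, data = df, permutations = n_perm, by = "terms")
  tab <- as.data.frame(fit)
  k <- length(terms)
  res <- data.frame(
    term = rownames(tab)[seq_len(k)],
    df = tab$Df[seq_len(k)],
    ss = tab$SumOfSqs[seq_len(k)],
    r2 = tab$R2[seq_len(k)],
    f = tab$F[seq_len(k)],
    p = tab$`Pr(>F)`[seq_len(k)],
    stringsAsFactors = FALSE
  )
  structure(list(terms = res,
                 residual_r2 = tab$R2[rownames(tab) == "Residual"],
                 total_ss = tab$SumOfSqs[rownames(tab) == "Total"],
                 n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("Sequential PERMANOVA (", x$n_perm, " permutations)\n", sep = "")
  print(x$terms, row.names = FALSE)
  cat(sprintf("Residual R2: %.4f\n", x$residual_r2))
  invisible(x)
}

.pam_cost <- function(m, medoids, labels) {
  sum(m[cbind(seq_len(nrow(m)), medoids[labels])])
}

#' Partitioning around medoids on a distance matrix
#'
#' Deterministic BUILD + SWAP k-medoids, plus `restarts` seeded random-start
#' runs; the clustering with the lowest total within-cluster distance wins.
#'
#' @param dm A `dist_matrix`.
#' @param k Number of clusters (default 2).
#' @param seed Optional integer seed for the random restarts.
#' @param restarts Number of random-initialization runs added to the
#'   deterministic BUILD start (default 10).
#' @return A `clustering_result`: named cluster `labels`, `medoids` (sample
#'   IDs), and total within-cluster `cost`.
#' @export
pam_cluster <- function(dm, k = 2, seed = NULL, restarts = 10) {
  stopifnot(inherits(dm, "dist_matrix"))
  m <- dm$matrix
  n <- nrow(m)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of samples")
  if (k == n) {
    labels <- stats::setNames(seq_len(n), rownames(m))
    return(structure(list(labels = labels, medoids = rownames(m),
                          cost = 0, k = k),
                     class = "clustering_result"))
  }
  d <- stats::as.dist(m)
  fits <- list(cluster::pam(d, k, do.swap = TRUE))
  if (restarts > 0 && n > k) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(restarts)) {
      init <- sample(n, k)
      fits[[r + 1]] <- cluster::pam(d, k, medoids = init, do.swap = TRUE)
    }
  }
  costs <- vapply(fits, function(f) {
    .pam_cost(m, f$id.med, f$clustering)
  }, numeric(1))
  best <- fits[[which.min(costs)]]
  labels <- best$clustering
  names(labels) <- rownames(m)
  structure(list(labels = labels,
                 medoids = rownames(m)[best$id.med],
                 cost = min(costs), k = k),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: k=%d, cost=%.4f, sizes: %s\n", x$k, x$cost,
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Clustering accuracy against known groups
#'
#' The fraction of samples assigned to the right cluster, maximized over the
#' matching of cluster labels to group labels. With `penalize_dropped = TRUE`
#' the samples in `dropped` (e.g. removed by rarefying) enter the denominator
#' as incorrectly clustered; with the default they are ignored, scoring
#' accuracy only among the samples that were actually clustered.
#'
#' @param result A `clustering_result` (or named vector of cluster labels).
#' @param truth A [group_design()] (or named vector of true group labels)
#'   covering the clustered samples.
#' @param dropped Character vector of sample IDs excluded before clustering.
#' @param penalize_dropped Count dropped samples as incorrectly clustered.
#' @return Accuracy in `[0, 1]`.
#' @export
clustering_accuracy <- function(result, truth, dropped = character(0),
                                penalize_dropped = FALSE) {
  labels <- if (inherits(result, "clustering_result")) result$labels else result
  if (!length(labels)) stop("empty clustering")
  tr <- if (inherits(truth, "group_design")) {
    stats::setNames(truth$group, rownames(truth))
  } else truth
  if (!all(names(labels) %in% names(tr))) {
    stop("truth does not cover all clustered samples")
  }
  tr <- tr[names(labels)]
  cl_lev <- unique(labels)
  g_lev <- unique(tr)
  if (length(cl_lev) > length(g_lev)) {
    stop("more clusters than group labels; cannot match labels")
  }
  perms <- .permutations(g_lev)
  best <- 0
  for (p in perms) {
    mapping <- stats::setNames(p[seq_along(cl_lev)], cl_lev)
    best <- max(best, sum(mapping[as.character(labels)] == tr))
  }
  denom <- length(labels) + if (penalize_dropped) length(dropped) else 0
  best / denom
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
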