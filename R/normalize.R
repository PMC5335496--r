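# The seven library-size normalization strategies, each a pure transform of a
# count table into a real-valued matrix with recorded per-sample scale factors.
# All scaling methods rescale onto a comparable "counts" scale through the
# global constant C = median library size of the input table.

.new_normalized <- function(values, method, scale_factors = NULL,
                            params = list(), dropped = character(0)) {
  structure(
    list(values = values, method = method, scale_factors = scale_factors,
         params = params, dropped = dropped),
    class = "normalized_table"
  )
}

#' @export
print.normalized_table <- function(x, ...) {
  cat(sprintf("normalized_table [%s]: %d taxa x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  if (length(x$dropped)) {
    cat("  dropped samples:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

.median_depth <- function(counts) {
  stats::median(colSums(counts))
}

#' Total-sum scaling (proportions)
#'
#' Each column is divided by its sum, so non-empty columns sum to 1.
#'
#' @param table A [count_table()].
#' @return A `normalized_table` with `method = "proportion"`.
#' @export
proportion_normalize <- function(table) {
  counts <- values_of(table)
  ls <- colSums(counts)
  if (any(ls == 0)) stop("all-zero sample(s): ",
                         paste(colnames(counts)[ls == 0], collapse = ", "))
  .new_normalized(sweep(counts, 2, ls, "/"), "proportion", scale_factors = ls)
}

# One multivariate hypergeometric draw: subsample `depth` reads without
# replacement from a count vector.
.rarefy_column <- function(x, depth) {
  reads <- rep.int(seq_along(x), x)
  tabulate(sample(reads, depth), nbins = length(x))
}

#' Rarefy to even depth
#'
#' Subsamples every column to exactly `depth` reads, by default without
#' replacement (multivariate hypergeometric model); with replacement uses a
#' multinomial draw. Samples shallower than `depth` are excluded and reported.
#'
#' @param table A [count_table()].
#' @param depth Positive integer target depth.
#' @param with_replacement Draw multinomially instead of hypergeometrically.
#' @param seed Optional integer; draws are reproducible given the seed.
#' @return A `normalized_table` with integer columns summing to `depth` and
#'   the excluded sample IDs in `$dropped`.
#' @export
rarefy <- function(table, depth, with_replacement = FALSE, seed = NULL) {
  counts <- values_of(table)
  if (!is.numeric(depth) || depth < 1) stop("depth must be >= 1")
  depth <- as.integer(round(depth))
  ls <- colSums(counts)
  keep <- ls >= depth
  if (!any(keep)) stop("rarefaction depth exceeds every library size")
  if (!is.null(seed)) set.seed(seed)
  kept <- counts[, keep, drop = FALSE]
  out <- kept
  for (j in seq_len(ncol(kept))) {
    if (with_replacement) {
      out[, j] <- stats::rmultinom(1, depth, kept[, j])[, 1]
    } else if (sum(kept[, j]) == depth) {
      out[, j] <- kept[, j]
    } else {
      out[, j] <- .rarefy_column(kept[, j], depth)
    }
  }
  .new_normalized(out, "rarefy",
                  params = list(depth = depth, seed = seed,
                                with_replacement = with_replacement),
                  dropped = colnames(counts)[!keep])
}

#' Log upper-quartile normalization
#'
#' Each sample is scaled by the 75th percentile of its nonzero counts, brought
#' back onto a common scale by the median library size, then log2-transformed
#' after adding a pseudocount. The quantile is taken over nonzero counts:
#' with ~90% zeros the raw 75th percentile is 0, which would be degenerate.
#'
#' @param table A [count_table()].
#' @param pseudocount Added inside the log (default 1).
#' @return A `normalized_table` with `method = "logUQ"`.
#' @export
loguq_normalize <- function(table, pseudocount = 1) {
  counts <- values_of(table)
  s <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop("sample with all-zero counts")
    stats::quantile(nz, 0.75, type = 7, names = FALSE)
  })
  C <- .median_depth(counts)
  vals <- log2(sweep(counts, 2, s, "/") * C + pseudocount)
  .new_normalized(vals, "logUQ", scale_factors = s,
                  params = list(pseudocount = pseudocount, C = C,
                                quantile_over = "nonzero"))
}

# Adaptive CSS quantile: per-sample quantile curves of the nonzero count
# distribution on a grid; the chosen quantile is the first grid point where the
# median relative deviation of the sample curves from their across-sample
# median curve destabilizes (exceeds its running minimum by more than 10%).
.css_pick_quantile <- function(counts, grid = seq(0.01, 0.99, by = 0.01)) {
  qmat <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop("sample with all-zero counts")
    stats::quantile(nz, grid, type = 7, names = FALSE)
  })
  ref <- apply(qmat, 1, stats::median)
  reldev <- vapply(seq_along(grid), function(l) {
    if (ref[l] <= 0) return(NA_real_)
    stats::median(abs(qmat[l, ] - ref[l]) / ref[l])
  }, numeric(1))
  runmin <- cummin(ifelse(is.na(reldev), Inf, reldev))
  # destabilized: deviation exceeds its running minimum by >10%, and is large
  # enough (2% floor) that integer-quantization noise does not trigger it
  unstable <- which(is.finite(reldev) &
                      reldev > pmax(1.1 * runmin, 0.02))
  if (length(unstable)) grid[unstable[1]] else NA_real_
}

#' Cumulative sum scaling (CSS)
#'
#' Each sample is scaled by the cumulative sum of its counts up to a quantile
#' of its own count distribution, so only the segment of the distribution that
#' is relatively invariant across samples drives the scaling. The quantile is
#' chosen adaptively unless fixed by the caller; if no destabilization point is
#' found the method falls back to the median (0.5) with a warning.
#'
#' @param table A [count_table()].
#' @param quantile `"auto"` (adaptive) or a fixed value in `(0, 1]`.
#' @return A `normalized_table` with `method = "CSS"`; `scale_factors` holds
#'   the per-sample cumulative sums.
#' @export
css_normalize <- function(table, quantile = "auto") {
  counts <- values_of(table)
  if (ncol(counts) < 2) stop("CSS requires at least 2 samples")
  if (identical(quantile, "auto")) {
    lhat <- .css_pick_quantile(counts)
    if (is.na(lhat)) {
      warning("no stabilizing quantile found; falling back to 0.5")
      lhat <- 0.5
    }
  } else {
    if (!is.numeric(quantile) || quantile <= 0 || quantile > 1) {
      stop("quantile must lie in (0, 1]")
    }
    lhat <- quantile
  }
  s <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    nz <- x[x > 0]
    if (!length(nz)) stop("sample with all-zero counts")
    qj <- stats::quantile(nz, lhat, type = 7, names = FALSE)
    sum(x[x <= qj])
  }, numeric(1))
  names(s) <- colnames(counts)
  if (any(s == 0)) stop("zero CSS scale factor")
  C <- .median_depth(counts)
  .new_normalized(sweep(counts, 2, s, "/") * C, "CSS", scale_factors = s,
                  params = list(quantile = lhat, C = C))
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over taxa of the ratio of that taxon's count to
#' its geometric mean across samples. By default only taxa with strictly
#' positive counts in every sample enter; if none exist, a pseudocount of 1 is
#' added to all cells (recorded) so every taxon can be used. Factors are
#' rescaled to geometric mean 1.
#'
#' @param table A [count_table()].
#' @param pseudocount `NULL` (all-positive taxa only) or a positive constant
#'   added to every cell before taking geometric means.
#' @return Named positive numeric vector of per-sample size factors, with the
#'   pseudocount actually used in `attr(, "pseudocount")`.
#' @export
deseq_size_factors <- function(table, pseudocount = NULL) {
  counts <- values_of(table)
  if (ncol(counts) == 1) {
    s <- 1
    names(s) <- colnames(counts)
    return(s)
  }
  m <- counts
  if (is.null(pseudocount)) {
    usable <- rowSums(m > 0) == ncol(m)
    if (!any(usable)) {
      warning("no taxon positive in all samples; adding pseudocount 1")
      pseudocount <- 1
      m <- m + pseudocount
      usable <- rep(TRUE, nrow(m))
    }
  } else {
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    m <- m + pseudocount
    usable <- rep(TRUE, nrow(m))
  }
  logm <- log(m[usable, , drop = FALSE])
  loggeo <- rowMeans(logm)
  s <- apply(logm, 2, function(lx) exp(stats::median(lx - loggeo)))
  s <- s / exp(mean(log(s)))
  attr(s, "pseudocount") <- pseudocount
  s
}

# Closed-form variance-stabilizing transform for a common NB dispersion alpha:
# 2*asinh(sqrt(alpha*x)) rewritten so that f(x) - log2(x) -> 0 as x -> Inf.
.nb_vst <- function(x, alpha) {
  log2(1 + 2 * alpha * x + 2 * sqrt(alpha * x * (1 + alpha * x))) -
    log2(4 * alpha)
}

#' Size-factor + variance-stabilizing normalization
#'
#' Counts are divided by median-of-ratios size factors, a common negative
#' binomial dispersion is estimated by moments, and a glog-type transform is
#' applied under which the across-sample variance of a taxon is approximately
#' independent of its mean. The transform is calibrated to the log2 asymptote
#' at large counts. Negative transformed values (which arise for counts near 0
#' when the dispersion is large) are clamped to zero by default.
#'
#' @param table A [count_table()].
#' @param clamp_negatives Set negative transformed values to 0.
#' @param size_factors Optional precomputed size factors.
#' @return A `normalized_table` with `method = "DESeqVS"`; the fitted
#'   dispersion is in `$params$alpha`.
#' @export
deseq_vs_normalize <- function(table, clamp_negatives = TRUE,
                               size_factors = NULL) {
  counts <- values_of(table)
  if (ncol(counts) < 2) stop("variance stabilization requires >= 2 samples")
  sf <- if (is.null(size_factors)) deseq_size_factors(table) else size_factors
  y <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(y)
  v <- .row_vars(y)
  ok <- mu > 0 & is.finite(v)
  alpha <- stats::median((v[ok] - mu[ok]) / mu[ok]^2)
  if (!is.finite(alpha) || alpha <= 0) {
    warning("non-positive dispersion estimate; using Poisson-limit log transform")
    vals <- log2(y + 1)
    alpha <- NA_real_
  } else {
    vals <- .nb_vst(y, alpha)
  }
  clamped <- FALSE
  if (clamp_negatives) {
    clamped <- any(vals < 0)
    vals[vals < 0] <- 0
  }
  .new_normalized(vals, "DESeqVS", scale_factors = sf,
                  params = list(alpha = alpha, clamp = clamp_negatives,
                                clamped_any = clamped))
}

.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# TMM factors against a reference sample: precision-weighted mean of doubly
# trimmed log-ratios (M trimmed 30% total, A trimmed 5% total).
.tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  ls <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j], 0.75, type = 7, names = FALSE) / ls[j]
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  r <- counts[, ref]
  Nr <- ls[ref]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    x <- counts[, j]
    Nj <- ls[j]
    ok <- x > 0 & r > 0
    if (!any(ok)) {
      warning("sample shares no nonzero taxon with TMM reference; factor 1")
      return(1)
    }
    px <- x[ok] / Nj
    pr <- r[ok] / Nr
    M <- log2(px / pr)
    A <- 0.5 * log2(px * pr)
    w <- 1 / ((Nj - x[ok]) / (Nj * x[ok]) + (Nr - r[ok]) / (Nr * r[ok]))
    keep <- .double_trim(M, A, trim_M, trim_A)
    if (!any(keep)) return(1)
    2^(sum(M[keep] * w[keep]) / sum(w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "ref") <- colnames(counts)[ref]
  f
}

.double_trim <- function(M, A, trim_M, trim_A) {
  n <- length(M)
  loM <- stats::quantile(M, trim_M / 2, type = 7, names = FALSE)
  hiM <- stats::quantile(M, 1 - trim_M / 2, type = 7, names = FALSE)
  loA <- stats::quantile(A, trim_A / 2, type = 7, names = FALSE)
  hiA <- stats::quantile(A, 1 - trim_A / 2, type = 7, names = FALSE)
  M >= loM & M <= hiM & A >= loA & A <= hiA
}

#' Trimmed mean of M-values (TMM) normalization
#'
#' The scaling factor of each sample is 2 to the precision-weighted mean of its
#' per-taxon log-fold changes against a reference sample, after trimming the
#' most extreme log-fold changes and the most extreme average abundances.
#' Effective library sizes are the product of the raw library size and the TMM
#' factor; factors are rescaled to geometric mean 1.
#'
#' @param table A [count_table()].
#' @param trim_M Total fraction of M-values trimmed (default 0.30).
#' @param trim_A Total fraction of A-values trimmed (default 0.05).
#' @return A `normalized_table` with `method = "TMM"`.
#' @export
tmm_normalize <- function(table, trim_M = 0.30, trim_A = 0.05) {
  counts <- values_of(table)
  if (ncol(counts) < 2) stop("TMM requires >= 2 samples")
  if (any(colSums(counts) == 0)) stop("all-zero sample")
  f <- .tmm_factors(counts, trim_M, trim_A)
  ls <- colSums(counts)
  C <- .median_depth(counts)
  vals <- sweep(counts, 2, ls * f, "/") * C
  .new_normalized(vals, "TMM", scale_factors = f,
                  params = list(trim_M = trim_M, trim_A = trim_A, C = C,
                                ref = attr(f, "ref")))
}

#' Normalize a count table by method tag
#'
#' Dispatcher over the implemented normalizations. `"none"` returns the counts
#' unchanged (no correction for unequal library sizes).
#'
#' @param table A [count_table()].
#' @param method One of `"none"`, `"proportion"`, `"rarefy"`, `"logUQ"`,
#'   `"CSS"`, `"DESeqVS"`, `"TMM"`.
#' @param ... Passed through to the specific normalization.
#' @return A `normalized_table` stamped with `method`.
#' @export
normalize <- function(table, method, ...) {
  switch(method,
    none = .new_normalized(values_of(table), "none"),
    proportion = proportion_normalize(table),
    rarefy = rarefy(table, ...),
    logUQ = loguq_normalize(table, ...),
    CSS = css_normalize(table, ...),
    DESeqVS = deseq_vs_normalize(table, ...),
    TMM = tmm_normalize(table, ...),
    stop("unknown normalization method: ", method)
  )
}
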