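# Two-group differential abundance procedures: rank and t tests on normalized
# values, the compositional ANCOM W procedure, negative-binomial GLM tests
# (Wald with log-fold-change shrinkage, and a conditional exact mode), a
# voom-style precision-weighted moderated t, and a zero-inflated Gaussian EM.
# Every test returns a `da_result` with per-taxon statistics, raw p, BH q, and
# the called set at the chosen alpha.

.new_da_result <- function(stats_df, method, alpha, params = list()) {
  stopifnot(all(c("taxon", "stat", "lfc", "p", "q", "called") %in%
                  colnames(stats_df)))
  rownames(stats_df) <- stats_df$taxon
  structure(list(table = stats_df, method = method, alpha = alpha,
                 params = params,
                 called = stats_df$taxon[which(stats_df$called)]),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf("da_result [%s]: %d taxa, %d called at alpha=%g\n",
              x$method, nrow(x$table), length(x$called), x$alpha))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. Non-finite p-values are excluded from the ranking
#' (the effective number of tests shrinks accordingly) and propagate as NA.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return Vector of BH-adjusted q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(pvals) {
  ok <- is.finite(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pvals))
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  q
}

# log2 ratio of group means, defined for non-negative value matrices.
.lfc_of_means <- function(m1, m2, eps = 1e-8) {
  log2((m1 + eps) / (m2 + eps))
}

#' Per-taxon two-sided Welch t test
#'
#' @param values A `count_table`, `normalized_table`, or matrix.
#' @param design A [group_design()] with exactly two groups.
#' @param alpha BH threshold for the called set (default 0.05).
#' @return A `da_result`. Taxa with zero variance in both groups get p = 1.
#' @export
welch_t_test <- function(values, design, alpha = 0.05) {
  v <- values_of(values)
  g <- .two_groups(design, colnames(v))
  n1 <- length(g$i1); n2 <- length(g$i2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  x1 <- v[, g$i1, drop = FALSE]; x2 <- v[, g$i2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- .row_vars(x1); v2 <- .row_vars(x2)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  dfree <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), dfree)
  degen <- se2 == 0
  tstat[degen] <- 0
  p[degen] <- 1
  lfc <- if (all(v >= 0)) .lfc_of_means(m1, m2) else rep(NA_real_, nrow(v))
  q <- bh_adjust(p)
  .new_da_result(
    data.frame(taxon = rownames(v), stat = tstat, lfc = lfc, p = p, q = q,
               called = !is.na(q) & q <= alpha, stringsAsFactors = FALSE),
    method = "welch_t", alpha = alpha,
    params = list(groups = g$levels)
  )
}

#' Per-taxon two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-values for small groups (both sizes at most 8, no ties), otherwise
#' the normal approximation with mid-rank tie correction. Constant taxa (all
#' values tied) get p = 1.
#'
#' @inheritParams welch_t_test
#' @return A `da_result`; `stat` holds the U statistic of the first group.
#' @export
mann_whitney_test <- function(values, design, alpha = 0.05) {
  v <- values_of(values)
  g <- .two_groups(design, colnames(v))
  n1 <- length(g$i1); n2 <- length(g$i2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  exact <- n1 <= 8 && n2 <= 8
  res <- t(vapply(seq_len(nrow(v)), function(i) {
    x1 <- v[i, g$i1]; x2 <- v[i, g$i2]
    if (length(unique(c(x1, x2))) == 1) return(c(n1 * n2 / 2, 1))
    wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = exact,
                                              correct = TRUE))
    c(unname(wt$statistic), wt$p.value)
  }, numeric(2)))
  m1 <- rowMeans(v[, g$i1, drop = FALSE]); m2 <- rowMeans(v[, g$i2, drop = FALSE])
  lfc <- if (all(v >= 0)) .lfc_of_means(m1, m2) else rep(NA_real_, nrow(v))
  q <- bh_adjust(res[, 2])
  .new_da_result(
    data.frame(taxon = rownames(v), stat = res[, 1], lfc = lfc, p = res[, 2],
               q = q, called = !is.na(q) & q <= alpha, stringsAsFactors = FALSE),
    method = "mann_whitney", alpha = alpha,
    params = list(groups = g$levels, exact = exact)
  )
}

# Row-wise two-sided Mann-Whitney, normal approximation with mid-rank tie
# correction. Used inside ANCOM where hundreds of thousands of tests run.
.mw_rows <- function(M, i1, i2) {
  n1 <- length(i1); n2 <- length(i2); n <- n1 + n2
  apply(M, 1, function(r) {
    rk <- rank(r)
    U <- sum(rk[i1]) - n1 * (n1 + 1) / 2
    tt <- table(r)
    tiecor <- sum(tt^3 - tt)
    s2 <- n1 * n2 / 12 * ((n + 1) - tiecor / (n * (n - 1)))
    if (s2 <= 0) return(1)
    z <- (U - n1 * n2 / 2)
    z <- (abs(z) - 0.5) / sqrt(s2)  # continuity correction
    2 * stats::pnorm(-abs(z))
  })
}

#' ANCOM: analysis of composition of microbiomes
#'
#' For each ordered pair of taxa (i, j) the per-sample additive log-ratio
#' `log((k_i + c)/(k_j + c))` is compared between the two groups with a
#' Mann-Whitney test. For each taxon the m-1 p-values of its ratios are
#' BH-adjusted at `alpha`, and W_i counts the rejections. The final call is
#' either a fixed fraction of m-1 (`w_mode = "threshold"`) or a cutoff at the
#' largest gap in the upper 30% of the sorted W distribution
#' (`w_mode = "empirical"`).
#'
#' @param table A [count_table()].
#' @param design A [group_design()] with exactly two groups.
#' @param pseudocount Positive constant added to all counts before logs
#'   (default 0.001).
#' @param alpha BH level for the per-ratio tests (default 0.05).
#' @param w_mode `"threshold"` or `"empirical"`.
#' @param w_threshold_frac Fraction of m-1 that W must reach in threshold
#'   mode (default 0.7).
#' @param min_prevalence Minimum fraction of samples in which a taxon must be
#'   observed to enter the log-ratio universe (default 0: all taxa, the
#'   literal procedure). A taxon that is zero in most samples is a censored
#'   reference — its pseudocounted ratio to taxon i just mirrors taxon i's
#'   own relative abundance, defeating the compositional correction — so
#'   filtering low-prevalence taxa is the procedure's standard preprocessing
#'   on sparse tables. Filtered taxa get W = NA and are never called.
#' @return A `da_result`; `stat` holds W (integers in `[0, m-1]`), `p` is NA
#'   (ANCOM has no single per-taxon p-value).
#' @export
ancom_test <- function(table, design, pseudocount = 0.001, alpha = 0.05,
                       w_mode = c("threshold", "empirical"),
                       w_threshold_frac = 0.7, min_prevalence = 0) {
  w_mode <- match.arg(w_mode)
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  counts_all <- values_of(table)
  if (nrow(counts_all) < 2) stop("ANCOM needs at least 2 taxa")
  g <- .two_groups(design, colnames(counts_all))
  keep <- rowMeans(counts_all > 0) >= min_prevalence
  if (sum(keep) < 2) stop("fewer than 2 taxa pass the prevalence filter")
  counts <- counts_all[keep, , drop = FALSE]
  m <- nrow(counts)
  logc <- log(counts + pseudocount)
  # all unordered pairs, processed in chunks to bound memory
  ii <- rep(seq_len(m - 1), times = (m - 1):1)
  jj <- unlist(lapply(seq_len(m - 1), function(i) (i + 1):m))
  P <- matrix(NA_real_, m, m)
  chunk <- 50000L
  for (s in seq(1, length(ii), by = chunk)) {
    e <- min(s + chunk - 1L, length(ii))
    D <- logc[ii[s:e], , drop = FALSE] - logc[jj[s:e], , drop = FALSE]
    pv <- .mw_rows(D, g$i1, g$i2)
    P[cbind(ii[s:e], jj[s:e])] <- pv
    P[cbind(jj[s:e], ii[s:e])] <- pv
  }
  W <- vapply(seq_len(m), function(i) {
    q <- bh_adjust(P[i, -i])
    sum(q <= alpha, na.rm = TRUE)
  }, numeric(1))
  called <- switch(w_mode,
    threshold = W >= w_threshold_frac * (m - 1),
    empirical = .ancom_empirical_cut(W)
  )
  m1 <- rowMeans(counts_all[, g$i1, drop = FALSE])
  m2 <- rowMeans(counts_all[, g$i2, drop = FALSE])
  W_all <- rep(NA_real_, nrow(counts_all))
  W_all[keep] <- W
  called_all <- rep(FALSE, nrow(counts_all))
  called_all[keep] <- called
  .new_da_result(
    data.frame(taxon = rownames(counts_all), stat = W_all,
               lfc = .lfc_of_means(m1, m2), p = NA_real_, q = NA_real_,
               called = called_all, stringsAsFactors = FALSE),
    method = "ancom", alpha = alpha,
    params = list(pseudocount = pseudocount, w_mode = w_mode,
                  w_threshold_frac = w_threshold_frac,
                  min_prevalence = min_prevalence, m_used = m,
                  groups = g$levels)
  )
}

# Empirical cutoff: the largest drop between consecutive sorted W values,
# searched within the upper 30% of taxa; taxa above the gap are called.
.ancom_empirical_cut <- function(W) {
  m <- length(W)
  ord <- order(W, decreasing = TRUE)
  ws <- W[ord]
  kmax <- max(1L, ceiling(0.3 * m) - 1L)
  gaps <- ws[seq_len(kmax)] - ws[seq_len(kmax) + 1L]
  if (all(gaps <= 0)) return(rep(FALSE, m))
  k <- which.max(gaps)
  cut <- ws[k]
  W >= cut & W > 0
}

# --- negative binomial machinery -------------------------------------------

# Per-taxon method-of-moments NB dispersions on size-factor-normalized counts,
# shrunk on the log scale toward a lowess mean-dispersion trend.
.nb_dispersions <- function(counts, sf, shrink_weight = 0.5, floor = 1e-8) {
  y <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(y)
  v <- .row_vars(y)
  raw <- (v - mu) / mu^2
  ok <- is.finite(raw) & raw > 0 & mu > 0
  if (sum(ok) >= 5) {
    lo <- stats::lowess(log(mu[ok]), log(raw[ok]), f = 0.5)
    trend_at <- function(lm0) {
      stats::approx(lo$x, lo$y, xout = lm0, rule = 2, ties = "ordered")$y
    }
    ltrend <- trend_at(log(pmax(mu, min(mu[mu > 0]))))
  } else {
    ltrend <- rep(log(pmax(stats::median(raw[ok]), floor)), length(mu))
    if (!any(ok)) ltrend <- rep(log(floor), length(mu))
  }
  disp <- exp(ltrend)
  disp[ok] <- exp(shrink_weight * log(raw[ok]) +
                    (1 - shrink_weight) * ltrend[ok])
  pmax(disp, floor)
}

# Conditional exact two-sided test on the split of the (size-factor adjusted)
# group sums given their total, under NB with the fitted dispersion.
.nb_exact_p <- function(s1, s2, n1, n2, alpha_i) {
  t <- s1 + s2
  if (t == 0) return(1)
  size1 <- n1 / alpha_i; size2 <- n2 / alpha_i
  mu <- t / (n1 + n2)
  mu1 <- n1 * mu; mu2 <- n2 * mu
  lo <- max(0, min(stats::qnbinom(1e-12, size = size1, mu = mu1),
                   t - stats::qnbinom(1 - 1e-12, size = size2, mu = mu2)))
  hi <- min(t, max(stats::qnbinom(1 - 1e-12, size = size1, mu = mu1),
                   t - stats::qnbinom(1e-12, size = size2, mu = mu2)))
  k <- lo:hi
  if (!(s1 %in% k)) k <- sort(unique(c(k, s1)))
  pr <- stats::dnbinom(k, size = size1, mu = mu1) *
    stats::dnbinom(t - k, size = size2, mu = mu2)
  tot <- sum(pr)
  if (tot <= 0) return(1)
  pobs <- pr[k == s1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-10)]) / tot)
}

#' Negative binomial GLM differential abundance test
#'
#' Per-taxon NB dispersions are estimated by moments and moderated toward a
#' lowess mean-dispersion trend. `mode = "wald"` fits a log-link NB GLM with a
#' group covariate and size-factor offsets, optionally shrinks the log-fold
#' change with a zero-centered normal prior whose variance is estimated from
#' the unshrunk estimates, and tests with a Wald statistic referred to a t
#' distribution with residual df. `mode = "exact"` conditions the split of the
#' group sums on their total under the fitted NB. Non-convergent taxa are
#' flagged with p = NA and excluded from the BH ranking.
#'
#' @param table A [count_table()].
#' @param design A [group_design()] with exactly two groups.
#' @param mode `"wald"` or `"exact"`.
#' @param shrink_lfc Shrink the Wald log-fold change toward zero.
#' @param size_factors Optional precomputed size factors (default:
#'   median-of-ratios from the table).
#' @param dispersion_shrink Weight of the taxon-wise dispersion relative to
#'   the trend, in `[0, 1]` (default 0.5; 0 = pure trend, more conservative).
#' @param alpha BH threshold for the called set.
#' @return A `da_result`; `lfc` is the (possibly shrunk) log2 fold change.
#' @export
nb_glm_test <- function(table, design, mode = c("wald", "exact"),
                        shrink_lfc = TRUE, size_factors = NULL,
                        dispersion_shrink = 0.5, alpha = 0.05) {
  mode <- match.arg(mode)
  counts <- values_of(table)
  g <- .two_groups(design, colnames(counts))
  n1 <- length(g$i1); n2 <- length(g$i2); n <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  sf <- if (is.null(size_factors)) deseq_size_factors(table) else size_factors
  disp <- .nb_dispersions(counts, sf, shrink_weight = dispersion_shrink)
  m <- nrow(counts)
  if (mode == "wald") {
    grp <- as.numeric(seq_len(ncol(counts)) %in% g$i2)
    offs <- log(sf)
    est <- matrix(NA_real_, m, 2)
    for (i in seq_len(m)) {
      y <- counts[i, ]
      if (all(y == 0)) next
      fit <- tryCatch(
        suppressWarnings(stats::glm(
          y ~ grp, offset = offs,
          family = MASS::negative.binomial(theta = 1 / disp[i])
        )),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) next
      sm <- summary(fit)$coefficients
      if (nrow(sm) < 2 || !is.finite(sm[2, 2]) || sm[2, 2] > 1e3) next
      est[i, ] <- sm[2, 1:2]
    }
    b <- -est[, 1]  # sign convention: effect of group 1 relative to group 2
    se <- est[, 2]
    # Wald test on the maximum-likelihood LFC; the zero-centered normal prior
    # shrinks the *reported* fold change (posterior mean) without deflating
    # the test statistic, which keeps the null calibration intact.
    z <- b / se
    if (shrink_lfc) {
      okb <- is.finite(b) & is.finite(se)
      sigma2 <- max(mean(b[okb]^2) - mean(se[okb]^2), 1e-6)
      lfc <- (b * sigma2 / (sigma2 + se^2)) / log(2)
    } else {
      lfc <- b / log(2)
    }
    p <- 2 * stats::pt(-abs(z), df = n - 2)
    stat <- z
    params <- list(mode = mode, shrink_lfc = shrink_lfc,
                   dispersion_shrink = dispersion_shrink,
                   prior_var = if (shrink_lfc) sigma2 else NA_real_)
  } else {
    yadj <- sweep(counts, 2, sf, "/")
    s1 <- round(rowSums(yadj[, g$i1, drop = FALSE]))
    s2 <- round(rowSums(yadj[, g$i2, drop = FALSE]))
    p <- vapply(seq_len(m), function(i) {
      .nb_exact_p(s1[i], s2[i], n1, n2, disp[i])
    }, numeric(1))
    lfc <- log2((s1 / n1 + 0.5) / (s2 / n2 + 0.5))
    stat <- s1
    params <- list(mode = mode, dispersion_shrink = dispersion_shrink)
  }
  q <- bh_adjust(p)
  .new_da_result(
    data.frame(taxon = rownames(counts), stat = stat, lfc = lfc, p = p, q = q,
               called = !is.na(q) & q <= alpha, stringsAsFactors = FALSE),
    method = paste0("nb_glm_", mode), alpha = alpha, params = params
  )
}

# --- empirical Bayes variance moderation ------------------------------------

.trigamma_inverse <- function(x) {
  if (!is.finite(x) || x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (it in 1:50) {
    delta <- (trigamma(y) - x) / psigamma(y, 2)
    y <- y - delta
    if (y <= 0) y <- 1e-8
    if (abs(delta) < 1e-8 * y) break
  }
  y
}

# Moments-matching estimate of the prior df d0 and prior variance s0^2 for
# scaled-chisq sample variances s2 on df degrees of freedom.
.squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) {
    return(list(df_prior = 0, var_prior = stats::median(s2[ok]),
                var_post = s2))
  }
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  ve <- stats::var(e) - trigamma(df / 2)
  if (is.na(ve) || ve <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
    post <- rep(s02, length(s2))
    post[!ok] <- s02
  } else {
    d0 <- 2 * .trigamma_inverse(ve)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    post <- (d0 * s02 + df * s2) / (d0 + df)
    post[!ok] <- s02
  }
  list(df_prior = d0, var_prior = s02, var_post = post)
}

#' Voom-style precision-weighted moderated t test
#'
#' Counts are converted to log2 counts per million with TMM effective library
#' sizes and an offset of 0.5; a locally weighted regression of the
#' square-root residual standard deviation on the mean log count supplies
#' per-observation precision weights (predicted sd to the power -4); each
#' taxon is then fit by weighted least squares and tested with an empirical
#' Bayes moderated t whose prior df and scale come from moments matching on
#' the log sample variances.
#'
#' @inheritParams nb_glm_test
#' @return A `da_result`. All-zero taxa get p = NA and are excluded from BH.
#' @export
voom_test <- function(table, design, alpha = 0.05) {
  counts <- values_of(table)
  g <- .two_groups(design, colnames(counts))
  n1 <- length(g$i1); n2 <- length(g$i2); n <- n1 + n2
  if (n1 < 3 || n2 < 3) stop("voom needs >= 3 samples per group")
  f <- .tmm_factors(counts)
  lib <- colSums(counts) * f
  y <- log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)
  m <- nrow(counts)
  allzero <- rowSums(counts) == 0
  # first pass: unweighted group-mean fit
  m1 <- rowMeans(y[, g$i1, drop = FALSE]); m2 <- rowMeans(y[, g$i2, drop = FALSE])
  fitted <- matrix(0, m, n)
  fitted[, g$i1] <- m1; fitted[, g$i2] <- m2
  resid <- y - fitted
  s <- sqrt(rowSums(resid^2) / (n - 2))
  ybar <- rowMeans(y)
  ok <- !allzero & s > 0
  lo <- stats::lowess(ybar[ok], sqrt(s[ok]), f = 0.5)
  pred_sqrt_sd <- function(x) {
    out <- stats::approx(lo$x, lo$y, xout = x, rule = 2,
                         ties = "ordered")$y
    pmax(out, 1e-3)
  }
  w <- matrix(pred_sqrt_sd(as.vector(fitted)), m, n)^(-4)
  # weighted two-group fit, closed form
  sw1 <- rowSums(w[, g$i1, drop = FALSE]); sw2 <- rowSums(w[, g$i2, drop = FALSE])
  mw1 <- rowSums(w[, g$i1, drop = FALSE] * y[, g$i1, drop = FALSE]) / sw1
  mw2 <- rowSums(w[, g$i2, drop = FALSE] * y[, g$i2, drop = FALSE]) / sw2
  b <- mw1 - mw2
  fittedw <- matrix(0, m, n)
  fittedw[, g$i1] <- mw1; fittedw[, g$i2] <- mw2
  rss <- rowSums(w * (y - fittedw)^2)
  s2 <- rss / (n - 2)
  sq <- .squeeze_var(ifelse(ok, s2, NA), df = n - 2)
  se2 <- sq$var_post * (1 / sw1 + 1 / sw2)
  tstat <- b / sqrt(se2)
  dft <- (n - 2) + ifelse(is.finite(sq$df_prior), sq$df_prior, 1e6)
  p <- 2 * stats::pt(-abs(tstat), df = dft)
  p[!ok] <- NA_real_
  tstat[!ok] <- NA_real_
  q <- bh_adjust(p)
  .new_da_result(
    data.frame(taxon = rownames(counts), stat = tstat, lfc = b, p = p, q = q,
               called = !is.na(q) & q <= alpha, stringsAsFactors = FALSE),
    method = "voom", alpha = alpha,
    params = list(df_prior = sq$df_prior, var_prior = sq$var_prior)
  )
}

# --- zero-inflated Gaussian -------------------------------------------------

#' Zero-inflated Gaussian / lognormal differential abundance test
#'
#' Models each log-scale value as a mixture of a point mass at zero and a
#' Gaussian whose mean has an intercept and a group effect, fit by EM. In
#' `mode = "zig"` the zero-mass probability is a logistic function of the log
#' library size, shared across taxa (which is why this model is misled when
#' the counts have been rarefied and the original library sizes erased); in
#' `mode = "zi_lognormal"` the zero-mass probability is taxon-specific. Only
#' observations with a zero count can carry posterior zero responsibility.
#' The group effect is tested with a moderated t (zig) or a Wald statistic
#' with empirical-Bayes-shrunk variance (zi_lognormal), with responsibilities
#' down-weighting structural zeros.
#'
#' @param table A [count_table()] (the CSS-normalized log values are computed
#'   internally unless `values` is supplied).
#' @param design A [group_design()] with exactly two groups.
#' @param mode `"zig"` or `"zi_lognormal"`.
#' @param max_iter,tol EM stopping rule.
#' @param values Optional precomputed log-scale value matrix.
#' @param alpha BH threshold for the called set.
#' @return A `da_result`; `params$loglik_trace` holds the (non-decreasing)
#'   observed-data log-likelihood per EM iteration and `params$converged` the
#'   convergence flag.
#' @export
zig_test <- function(table, design, mode = c("zig", "zi_lognormal"),
                     max_iter = 100, tol = 1e-6, values = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  counts <- values_of(table)
  g <- .two_groups(design, colnames(counts))
  n1 <- length(g$i1); n2 <- length(g$i2); n <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  if (is.null(values)) {
    norm <- css_normalize(if (inherits(table, "count_table")) table else
      count_table(counts))
    y <- log2(norm$values + 1)
  } else {
    y <- values
  }
  m <- nrow(y)
  iszero <- counts == 0
  eta <- log(colSums(counts) + 1)
  eta <- eta - mean(eta)
  # initialization
  zf <- colMeans(iszero)
  pifit <- suppressWarnings(stats::glm(zf ~ eta, family = stats::quasibinomial()))
  pij <- matrix(stats::fitted(pifit), m, n, byrow = TRUE)
  if (mode == "zi_lognormal") {
    pij <- matrix(rowMeans(iszero), m, n)
  }
  pij <- pmin(pmax(pij, 1e-6), 1 - 1e-6)
  z <- matrix(0, m, n)
  sigma <- pmax(apply(y, 1, stats::sd), 0.05)
  mu <- matrix(0, m, n)
  mu[, g$i1] <- rowMeans(y[, g$i1, drop = FALSE])
  mu[, g$i2] <- rowMeans(y[, g$i2, drop = FALSE])
  loglik <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step
    dens <- stats::dnorm(y, mean = mu, sd = sigma)
    z[] <- 0
    num <- pij[iszero]
    den <- num + (1 - pij[iszero]) * dens[iszero]
    z[iszero] <- num / pmax(den, 1e-300)
    # M-step: zero-mass model
    if (mode == "zig") {
      zbar <- colMeans(z)
      pifit <- suppressWarnings(stats::glm(zbar ~ eta,
                                           family = stats::quasibinomial()))
      pij <- matrix(stats::fitted(pifit), m, n, byrow = TRUE)
    } else {
      pij <- matrix(pmin(pmax(rowMeans(z), 1e-6), 1 - 1e-6), m, n)
    }
    pij <- pmin(pmax(pij, 1e-6), 1 - 1e-6)
    # M-step: Gaussian component, weights 1 - z
    wts <- 1 - z
    sw1 <- rowSums(wts[, g$i1, drop = FALSE]); sw2 <- rowSums(wts[, g$i2, drop = FALSE])
    mw1 <- rowSums(wts[, g$i1, drop = FALSE] * y[, g$i1, drop = FALSE]) / pmax(sw1, 1e-8)
    mw2 <- rowSums(wts[, g$i2, drop = FALSE] * y[, g$i2, drop = FALSE]) / pmax(sw2, 1e-8)
    mu[, g$i1] <- mw1; mu[, g$i2] <- mw2
    sigma <- sqrt(rowSums(wts * (y - mu)^2) / pmax(rowSums(wts), 1e-8))
    sigma <- pmax(sigma, 0.05)
    # observed-data log-likelihood
    dens <- stats::dnorm(y, mean = mu, sd = sigma)
    ll_cells <- log((1 - pij) * dens + ifelse(iszero, pij, 0))
    ll <- sum(ll_cells)
    trace <- c(trace, ll)
    if (it > 1 && ll < loglik - 1e-6 * abs(loglik) - 1e-8) {
      stop(sprintf(
        "EM log-likelihood decreased at iteration %d (%.6g -> %.6g)",
        it, loglik, ll))
    }
    if (it > 1 && abs(ll - loglik) < tol * (abs(loglik) + 1)) {
      converged <- TRUE
      loglik <- ll
      break
    }
    loglik <- ll
  }
  # test on the Gaussian component
  wts <- 1 - z
  sw1 <- rowSums(wts[, g$i1, drop = FALSE]); sw2 <- rowSums(wts[, g$i2, drop = FALSE])
  mw1 <- rowSums(wts[, g$i1, drop = FALSE] * y[, g$i1, drop = FALSE]) / pmax(sw1, 1e-8)
  mw2 <- rowSums(wts[, g$i2, drop = FALSE] * y[, g$i2, drop = FALSE]) / pmax(sw2, 1e-8)
  b <- mw1 - mw2
  dfres <- pmax(sw1 + sw2 - 2, 1)
  s2 <- rowSums(wts * (y - mu)^2) / dfres
  sq <- .squeeze_var(ifelse(s2 > 0, s2, NA), df = stats::median(dfres))
  se2 <- sq$var_post * (1 / pmax(sw1, 1e-8) + 1 / pmax(sw2, 1e-8))
  tstat <- b / sqrt(se2)
  dft <- dfres + ifelse(is.finite(sq$df_prior), sq$df_prior, 1e6)
  p <- 2 * stats::pt(-abs(tstat), df = dft)
  bad <- sw1 < 2 | sw2 < 2
  p[bad] <- NA_real_
  q <- bh_adjust(p)
  .new_da_result(
    data.frame(taxon = rownames(y), stat = tstat, lfc = b, p = p, q = q,
               called = !is.na(q) & q <= alpha, stringsAsFactors = FALSE),
    method = paste0("zig_", mode), alpha = alpha,
    params = list(loglik_trace = trace, converged = converged,
                  df_prior = sq$df_prior, mode = mode)
  )
}

#' Run a (normalization, test) pipeline
#'
#' Applies the stated normalization, then the stated test. Count-model tests
#' (`ancom`, `nb_wald`, `nb_exact`, `voom`, `zig`, `zi_lognormal`) accept only
#' `"none"` or `"rarefy"` (they need integer counts and do their own internal
#' scaling); value tests (`mw`, `t`) run on any normalization. Running `zig`
#' on rarefied counts is permitted but flagged with a warning, since its
#' library-size covariate is then misleading.
#'
#' @param table A [count_table()].
#' @param design A [group_design()].
#' @param method One of `"mw"`, `"t"`, `"ancom"`, `"nb_wald"`, `"nb_exact"`,
#'   `"voom"`, `"zig"`, `"zi_lognormal"`.
#' @param normalization A [normalize()] method tag (default `"none"`).
#' @param alpha BH threshold.
#' @param ... Extra arguments for the normalization (e.g. `depth`, `seed` for
#'   rarefying) or the test.
#' @return A `da_result`.
#' @export
run_da <- function(table, design, method, normalization = "none",
                   alpha = 0.05, ...) {
  dots <- list(...)
  norm_names <- c("depth", "seed", "with_replacement", "pseudocount_norm",
                  "quantile", "clamp_negatives")
  norm_args <- dots[names(dots) %in% norm_names]
  names(norm_args)[names(norm_args) == "pseudocount_norm"] <- "pseudocount"
  test_args <- dots[!names(dots) %in% norm_names]
  count_methods <- c("ancom", "nb_wald", "nb_exact", "voom", "zig",
                     "zi_lognormal")
  if (method %in% count_methods &&
      !normalization %in% c("none", "rarefy")) {
    stop("method '", method, "' needs integer counts; normalization '",
         normalization, "' is not meaningful here")
  }
  nt <- do.call(normalize, c(list(table = table, method = normalization),
                             norm_args))
  if (method %in% count_methods) {
    tab2 <- count_table(nt$values, provenance = table$provenance)
    if (method %in% c("zig", "zi_lognormal") && normalization == "rarefy") {
      warning("zero-inflated model on rarefied counts: the library-size ",
              "covariate no longer reflects the original depths")
    }
    res <- switch(method,
      ancom = do.call(ancom_test, c(list(tab2, design, alpha = alpha), test_args)),
      nb_wald = do.call(nb_glm_test, c(list(tab2, design, mode = "wald",
                                            alpha = alpha), test_args)),
      nb_exact = do.call(nb_glm_test, c(list(tab2, design, mode = "exact",
                                             alpha = alpha), test_args)),
      voom = do.call(voom_test, c(list(tab2, design, alpha = alpha), test_args)),
      zig = do.call(zig_test, c(list(tab2, design, mode = "zig",
                                     alpha = alpha), test_args)),
      zi_lognormal = do.call(zig_test, c(list(tab2, design,
                                              mode = "zi_lognormal",
                                              alpha = alpha), test_args))
    )
  } else {
    res <- switch(method,
      mw = do.call(mann_whitney_test, c(list(nt, design, alpha = alpha),
                                        test_args)),
      t = do.call(welch_t_test, c(list(nt, design, alpha = alpha), test_args)),
      stop("unknown method tag: ", method)
    )
  }
  res$params$normalization <- normalization
  res
}
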