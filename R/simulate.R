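# Community templates and the simulation designs: template fitting
# (multinomial, Dirichlet-multinomial by moments, gamma-Poisson by moments),
# a synthetic heavy-tailed template generator, the two-class clustering
# simulation, the balanced and legacy ("original") differential-abundance
# simulations under three count families, the compositional simulation where
# ecosystem truth and relative-abundance truth deliberately disagree, and
# real-null splitters.

.new_template <- function(taxon_ids, pi, family, theta = NULL, shape = NULL,
                          rate = NULL, source = "") {
  pi <- as.numeric(pi)
  if (any(pi < 0)) stop("negative proportions")
  if (abs(sum(pi) - 1) > 1e-8) stop("proportions must sum to 1")
  if (family == "dirichlet_multinomial" && (is.null(theta) || theta <= 0)) {
    stop("DM template needs theta > 0")
  }
  if (family == "gamma_poisson" &&
      (is.null(shape) || is.null(rate) || any(shape <= 0) || any(rate <= 0))) {
    stop("GP template needs positive shapes and rates")
  }
  structure(list(taxon_ids = taxon_ids, pi = stats::setNames(pi, taxon_ids),
                 family = family, theta = theta, shape = shape, rate = rate,
                 source = source),
            class = "template_community")
}

#' @export
print.template_community <- function(x, ...) {
  cat(sprintf("template_community [%s]: %d taxa%s\n", x$family,
              length(x$pi),
              if (!is.null(x$theta)) sprintf(", theta=%.3g", x$theta) else ""))
  invisible(x)
}

#' Fit a multinomial template
#'
#' The taxon proportion vector is the row-sum vector over the grand total.
#'
#' @param table A [count_table()].
#' @return A `template_community` with `family = "multinomial"`.
#' @export
fit_multinomial <- function(table) {
  counts <- values_of(table)
  if (ncol(counts) < 1 || sum(counts) == 0) stop("empty table")
  rs <- rowSums(counts)
  .new_template(rownames(counts), rs / sum(rs), "multinomial",
                source = table$provenance)
}

#' Fit a Dirichlet-multinomial template by the method of moments
#'
#' The proportion vector is the mean of the per-sample proportions; the
#' overdispersion theta (0 = multinomial limit, 1 = maximal) comes from the
#' across-sample variance of the proportions:
#' `E[var(p_i)] = pi_i (1 - pi_i) (1/N + theta (1 - 1/N))`, pooled over taxa
#' with the harmonic mean library size for N. Theta is clipped to
#' `(1e-8, 1)`.
#'
#' @param table A [count_table()] with at least 2 samples.
#' @return A `template_community` with `family = "dirichlet_multinomial"`.
#' @export
fit_dirichlet_multinomial <- function(table) {
  counts <- values_of(table)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  ls <- colSums(counts)
  if (any(ls == 0)) stop("all-zero sample")
  props <- sweep(counts, 2, ls, "/")
  pi_hat <- rowMeans(props)
  v <- .row_vars(props)
  nh <- 1 / mean(1 / ls)  # harmonic mean depth
  denom <- sum(pi_hat * (1 - pi_hat))
  theta <- (sum(v) / denom - 1 / nh) / (1 - 1 / nh)
  theta <- min(max(theta, 1e-8), 1 - 1e-8)
  .new_template(rownames(counts), pi_hat, "dirichlet_multinomial",
                theta = theta, source = table$provenance)
}

#' Fit a gamma-Poisson template by the method of moments
#'
#' Counts are first scaled to a common depth (the median library size); the
#' per-taxon mean m and variance v then give shape `m^2/(v-m)` and rate
#' `m/(v-m)` where v > m, and a Poisson-limit large shape (flagged) where
#' v <= m. The fitted gamma mean `shape/rate` equals the observed mean.
#'
#' @param table A [count_table()] with at least 2 samples.
#' @return A `template_community` with `family = "gamma_poisson"`; the fitting
#'   depth is in `$source_depth` and Poisson-limit taxa in `$poisson_limit`.
#' @export
fit_gamma_poisson <- function(table) {
  counts <- values_of(table)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  ls <- colSums(counts)
  if (any(ls == 0)) stop("all-zero sample")
  C <- stats::median(ls)
  y <- sweep(counts, 2, ls, "/") * C
  m <- rowMeans(y)
  v <- .row_vars(y)
  over <- v > m & m > 0
  shape <- ifelse(over, m^2 / (v - m), 1e8)
  rate <- ifelse(over, m / (v - m), ifelse(m > 0, 1e8 / m, 1e8))
  shape[m == 0] <- 1e-8
  rate[m == 0] <- 1
  tpl <- .new_template(rownames(counts), m / sum(m), "gamma_poisson",
                       shape = shape, rate = rate, source = table$provenance)
  tpl$source_depth <- C
  tpl$poisson_limit <- rownames(counts)[!over]
  tpl
}

#' Generate a synthetic heavy-tailed community template
#'
#' Taxon proportions are drawn from a log-normal law whose log-scale sd is
#' calibrated (deterministically, given the seed) so that multinomial sampling
#' at a 2000-read depth yields approximately the requested zero fraction —
#' emulating the ~90% sparsity and heavy-tailed rank-abundance shape of real
#' survey tables. If the target is unattainable the nearest attainable
#' sparsity is used with a warning.
#'
#' @param n_taxa Number of taxa (>= 10).
#' @param sparsity_target Desired expected zero fraction at depth 2000.
#' @param seed Integer seed; the same seed yields the same template.
#' @param depth Calibration depth (default 2000).
#' @return A `template_community` with `family = "multinomial"`.
#' @export
make_synthetic_template <- function(n_taxa, sparsity_target = 0.9, seed = 1,
                                    depth = 2000) {
  if (n_taxa < 10) stop("n_taxa must be >= 10")
  if (sparsity_target < 0 || sparsity_target >= 1) {
    stop("sparsity_target must lie in [0, 1)")
  }
  set.seed(seed)
  zraw <- stats::rnorm(n_taxa)
  expected_zero <- function(sigma) {
    pi <- exp(sigma * zraw)
    pi <- pi / sum(pi)
    mean((1 - pi)^depth)
  }
  lo <- 0.01; hi <- 12
  zlo <- expected_zero(lo); zhi <- expected_zero(hi)
  if (sparsity_target <= zlo) {
    if (abs(sparsity_target - zlo) > 0.02) {
      warning(sprintf("sparsity target %.2f unattainable; using %.2f",
                      sparsity_target, zlo))
    }
    sigma <- lo
  } else if (sparsity_target >= zhi) {
    warning(sprintf("sparsity target %.2f unattainable; using %.2f",
                    sparsity_target, zhi))
    sigma <- hi
  } else {
    sigma <- stats::uniroot(function(s) expected_zero(s) - sparsity_target,
                            c(lo, hi), tol = 1e-4)$root
  }
  pi <- exp(sigma * zraw)
  pi <- pi / sum(pi)
  .new_template(sprintf("OTU_%04d", seq_len(n_taxa)), pi, "multinomial",
                source = sprintf("synthetic(seed=%d,sigma=%.3f)", seed, sigma))
}

# Library sizes: lognormal around the median N_L. spread is the log-scale sd;
# the default 0.5 puts ~95% of samples within a ~7x range.
.draw_library_sizes <- function(n, N_L, spread = 0.5) {
  pmax(1L, as.integer(round(N_L * exp(stats::rnorm(n, 0, spread)))))
}

.draw_counts <- function(pi, N, family, theta = NULL, gp_shape = NULL,
                         gp_rate = NULL, fit_depth = NULL) {
  m <- length(pi)
  switch(family,
    multinomial = stats::rmultinom(1, N, pi)[, 1],
    dirichlet_multinomial = {
      a <- pi * (1 - theta) / theta
      p <- stats::rgamma(m, shape = a, rate = 1)
      if (sum(p) == 0) p <- pi
      stats::rmultinom(1, N, p)[, 1]
    },
    gamma_poisson = {
      # scale the gamma mean by drawn depth / fitting depth
      lam <- stats::rgamma(length(gp_shape), shape = gp_shape,
                           rate = gp_rate * fit_depth / N)
      stats::rpois(length(gp_shape), lam)
    },
    stop("unknown family: ", family)
  )
}

.new_simdata <- function(counts, group, truth, design) {
  ct <- count_table(counts, sample_group = group,
                    provenance = design$kind)
  structure(list(table = ct, truth = truth, design = design),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated_dataset [%s]: %d taxa x %d samples, %d true positives\n",
              x$design$kind, nrow(x$table$counts), ncol(x$table$counts),
              length(x$truth$taxa)))
  invisible(x)
}

#' Two-class clustering simulation
#'
#' Mixes two template communities in defined proportions to generate two
#' sample classes of tunable separability: class 1 samples come from
#' `normalize(ES * pi_A + pi_B)` and class 2 from `normalize(ES * pi_B +
#' pi_A)`, where ES >= 1 is the effect size (ES = 1 makes the classes
#' identical; large ES recovers the pure templates). Counts are multinomial
#' with lognormal library sizes around `N_L`.
#'
#' @param template_A,template_B Two `template_community` objects; their taxon
#'   universes are merged (zero-padded union).
#' @param effect_size Mixing effect size, >= 1.
#' @param n_samples Total samples, split evenly between classes (default 40).
#' @param N_L Median library size.
#' @param spread Log-scale sd of the library-size law (default 0.5).
#' @param seed Integer seed.
#' @return A `simulated_dataset` whose `truth` records the class ecosystems.
#' @export
simulate_clustering_dataset <- function(template_A, template_B, effect_size,
                                        n_samples = 40, N_L = 2000,
                                        spread = 0.5, seed = 1) {
  if (effect_size < 1) stop("effect_size must be >= 1")
  taxa <- union(template_A$taxon_ids, template_B$taxon_ids)
  pa <- stats::setNames(rep(0, length(taxa)), taxa)
  pb <- pa
  pa[template_A$taxon_ids] <- template_A$pi
  pb[template_B$taxon_ids] <- template_B$pi
  mix1 <- effect_size * pa + pb; mix1 <- mix1 / sum(mix1)
  mix2 <- effect_size * pb + pa; mix2 <- mix2 / sum(mix2)
  n1 <- floor(n_samples / 2); n2 <- n_samples - n1
  set.seed(seed)
  Ns <- .draw_library_sizes(n_samples, N_L, spread)
  counts <- matrix(0L, length(taxa), n_samples,
                   dimnames = list(taxa, sprintf("S%03d", seq_len(n_samples))))
  grp <- c(rep("classA", n1), rep("classB", n2))
  for (j in seq_len(n_samples)) {
    pij <- if (grp[j] == "classA") mix1 else mix2
    counts[, j] <- .draw_counts(pij, Ns[j], "multinomial")
  }
  .new_simdata(counts, stats::setNames(grp, colnames(counts)),
               truth = list(taxa = character(0),
                            class_pi = list(classA = mix1, classB = mix2)),
               design = list(kind = "clustering", effect_size = effect_size,
                             n_samples = n_samples, N_L = N_L,
                             spread = spread, seed = seed))
}

# Stratified true-positive selection: sample within abundance quartiles so
# rare and common taxa are both represented.
.pick_tp <- function(pi, n_tp) {
  qs <- stats::quantile(pi, c(0.25, 0.5, 0.75), type = 7)
  strata <- findInterval(pi, qs) + 1L
  picked <- integer(0)
  per <- ceiling(n_tp / 4)
  for (s in 1:4) {
    pool <- setdiff(which(strata == s), picked)
    picked <- c(picked, sample(pool, min(per, length(pool))))
  }
  if (length(picked) > n_tp) picked <- sample(picked, n_tp)
  if (length(picked) < n_tp) {
    pool <- setdiff(seq_along(pi), picked)
    picked <- c(picked, sample(pool, n_tp - length(picked)))
  }
  sort(picked)
}

#' Balanced (or legacy) differential-abundance simulation
#'
#' In the `"balanced"` design, the true-positive set is split into two equal
#' halves; one half is multiplied by the fold change in group 1's ecosystem
#' vector and the other half in group 2's, each vector renormalized — so the
#' taxa that differ in ecosystem abundance are exactly the taxa that differ in
#' relative abundance. The `"original"` design reproduces the older scheme:
#' both groups sample the same ecosystem and the true positives are inflated
#' after sampling, one-sidedly, which silently shifts every other taxon's
#' relative abundance. Counts are drawn from the requested family.
#'
#' @param template A `template_community` supplying the base proportions (and
#'   theta / gamma parameters when it carries them).
#' @param family `"multinomial"`, `"dirichlet_multinomial"`, or
#'   `"gamma_poisson"`.
#' @param n_per_group Samples per group.
#' @param fold_change Fold change of the true positives, >= 1.
#' @param tp_fraction Fraction of taxa made truly differential (in
#'   `[0, 0.5)` for balanced).
#' @param design `"balanced"` or `"original"`.
#' @param N_L,spread Library-size law (median, log-sd).
#' @param seed Integer seed.
#' @param theta DM overdispersion override (default: template's).
#' @param gp_shape Gamma-Poisson shape override (scalar) used when the
#'   template has no fitted per-taxon gamma parameters.
#' @return A `simulated_dataset`; `truth$taxa` is empty when
#'   `fold_change = 1` or `tp_fraction = 0`.
#' @export
simulate_da_dataset <- function(template, family = template$family,
                                n_per_group = 25, fold_change = 5,
                                tp_fraction = 0.1,
                                design = c("balanced", "original"),
                                N_L = 2000, spread = 0.5, seed = 1,
                                theta = template$theta, gp_shape = 10) {
  design <- match.arg(design)
  if (fold_change < 1) stop("fold_change must be >= 1")
  if (tp_fraction < 0 || tp_fraction >= 1) stop("tp_fraction must be in [0, 1)")
  if (design == "balanced" && tp_fraction >= 0.5) {
    stop("balanced design needs tp_fraction < 0.5 (the halves would overlap)")
  }
  family <- match.arg(family, c("multinomial", "dirichlet_multinomial",
                                "gamma_poisson"))
  if (family == "dirichlet_multinomial" && is.null(theta)) theta <- 0.01
  pi <- template$pi
  m <- length(pi)
  taxa <- template$taxon_ids
  set.seed(seed)
  n_tp <- round(tp_fraction * m)
  null_case <- fold_change == 1 || n_tp == 0
  if (design == "balanced" && !null_case && n_tp < 2) {
    stop("balanced design needs at least 2 true positives (pairs)")
  }
  tp <- if (null_case) integer(0) else .pick_tp(pi, n_tp)
  if (design == "balanced") {
    # Split the TP set into two halves of (nearly) equal abundance mass by
    # greedy assignment in descending abundance order, then solve for the
    # second half's multiplier so both group vectors share the same
    # normalizer. Non-TP taxa then have *identical* relative abundance in the
    # two groups: differential abundance and differential relative abundance
    # coincide exactly, which is the point of the balanced design.
    ord <- tp[order(pi[tp], decreasing = TRUE)]
    h1 <- integer(0); h2 <- integer(0)
    mass1 <- 0; mass2 <- 0
    for (i in ord) {
      if (mass1 <= mass2) {
        h1 <- c(h1, i); mass1 <- mass1 + pi[i]
      } else {
        h2 <- c(h2, i); mass2 <- mass2 + pi[i]
      }
    }
    if (!null_case && (!length(h1) || !length(h2))) {
      stop("balanced design could not form two non-empty halves")
    }
    fc2 <- if (null_case) 1 else 1 + (fold_change - 1) * mass1 / mass2
    a1 <- pi; a1[h1] <- a1[h1] * fold_change
    a2 <- pi; a2[h2] <- a2[h2] * fc2
    pi1 <- a1 / sum(a1); pi2 <- a2 / sum(a2)
    mult <- stats::setNames(rep(1, length(tp)), taxa[tp])
    mult[taxa[h1]] <- fold_change  # inflated in group 1
    mult[taxa[h2]] <- 1 / fc2      # inflated in group 2
  } else {
    pi1 <- pi; pi2 <- pi
    h1 <- tp; h2 <- integer(0)
    mult <- stats::setNames(rep(fold_change, length(tp)), taxa[tp])
  }
  n <- 2 * n_per_group
  Ns <- .draw_library_sizes(n, N_L, spread)
  grp <- rep(c("group1", "group2"), each = n_per_group)
  counts <- matrix(0L, m, n, dimnames = list(taxa, sprintf("S%03d", 1:n)))
  fit_depth <- if (!is.null(template$source_depth)) template$source_depth else N_L
  for (j in seq_len(n)) {
    pij <- if (grp[j] == "group1") pi1 else pi2
    if (family == "gamma_poisson") {
      if (!is.null(template$shape)) {
        sh <- template$shape
        ra <- template$rate
        # group effect enters through the gamma mean
        scalefac <- pij / pi
        scalefac[!is.finite(scalefac)] <- 1
        ra <- ra / scalefac
      } else {
        sh <- rep(gp_shape, m)
        ra <- gp_shape / (pij * fit_depth)
        ra[pij == 0] <- 1e12
      }
      counts[, j] <- .draw_counts(NULL, Ns[j], "gamma_poisson",
                                  gp_shape = sh, gp_rate = ra,
                                  fit_depth = fit_depth)
    } else {
      counts[, j] <- .draw_counts(pij, Ns[j], family, theta = theta)
    }
  }
  if (design == "original" && !null_case) {
    ing1 <- grp == "group1"
    counts[tp, ing1] <- counts[tp, ing1, drop = FALSE] * fold_change
  }
  .new_simdata(counts, stats::setNames(grp, colnames(counts)),
               truth = list(taxa = taxa[tp], multipliers = mult,
                            pi_group1 = pi1, pi_group2 = pi2),
               design = list(kind = paste0(design, "_da"), family = family,
                             n_per_group = n_per_group,
                             fold_change = fold_change,
                             tp_fraction = tp_fraction, N_L = N_L,
                             spread = spread, seed = seed, theta = theta,
                             gp_shape = gp_shape))
}

#' Compositional differential-abundance simulation
#'
#' The ecosystem abundances of a fraction of taxa are multiplied by the fold
#' change in group 1 only; both groups' sampling proportions are then obtained
#' by renormalization and counts drawn multinomially. The recorded truth is
#' the ecosystem-level set — NOT the relative-abundance truth, which after
#' renormalization includes every taxon (each non-inflated taxon's relative
#' abundance strictly decreases in group 1). FDR computed against this truth
#' is exactly the quantity that blows up for methods testing relative
#' abundance.
#'
#' @param template A `template_community` (multinomial sampling is used).
#' @param tp_fraction Fraction of taxa inflated (default 0.10), in
#'   `(0, 0.5]`.
#' @param fold_change Ecosystem fold change of the inflated taxa, > 1.
#' @param n_per_group Samples per group.
#' @param N_L,spread Library-size law.
#' @param seed Integer seed.
#' @return A `simulated_dataset`.
#' @export
simulate_compositional_dataset <- function(template, tp_fraction = 0.10,
                                           fold_change = 5, n_per_group = 25,
                                           N_L = 2000, spread = 0.5,
                                           seed = 1) {
  if (fold_change <= 1) stop("fold_change must be > 1")
  if (tp_fraction <= 0 || tp_fraction > 0.5) {
    stop("tp_fraction must lie in (0, 0.5]")
  }
  pi <- template$pi
  m <- length(pi)
  taxa <- template$taxon_ids
  set.seed(seed)
  tp <- .pick_tp(pi, round(tp_fraction * m))
  a1 <- pi
  a1[tp] <- a1[tp] * fold_change
  pi1 <- a1 / sum(a1)
  pi2 <- pi
  n <- 2 * n_per_group
  Ns <- .draw_library_sizes(n, N_L, spread)
  grp <- rep(c("group1", "group2"), each = n_per_group)
  counts <- matrix(0L, m, n, dimnames = list(taxa, sprintf("S%03d", 1:n)))
  for (j in seq_len(n)) {
    counts[, j] <- .draw_counts(if (grp[j] == "group1") pi1 else pi2,
                                Ns[j], "multinomial")
  }
  .new_simdata(counts, stats::setNames(grp, colnames(counts)),
               truth = list(taxa = taxa[tp],
                            multipliers = stats::setNames(
                              rep(fold_change, length(tp)), taxa[tp]),
                            pi_group1 = pi1, pi_group2 = pi2),
               design = list(kind = "compositional_da",
                             tp_fraction = tp_fraction,
                             fold_change = fold_change,
                             n_per_group = n_per_group, N_L = N_L,
                             spread = spread, seed = seed))
}

#' Split a one-group table into two null groups
#'
#' Samples from a single biological group are divided into two groups of
#' `n_per_group`, either uniformly at random or from the depth-sorted extremes
#' so the two group mean library sizes differ by approximately
#' `target_ratio`. The recorded truth is empty: every subsequent call is a
#' false positive.
#'
#' @param table A [count_table()].
#' @param n_per_group Samples per group.
#' @param mode `"random"` or `"uneven"`.
#' @param target_ratio Desired mean library-size ratio for `"uneven"`
#'   (default 10).
#' @param seed Integer seed.
#' @return A `simulated_dataset` whose table is the selected sub-table with
#'   groups `group1`/`group2`.
#' @export
split_null <- function(table, n_per_group, mode = c("random", "uneven"),
                       target_ratio = 10, seed = 1) {
  mode <- match.arg(mode)
  counts <- values_of(table)
  n_avail <- ncol(counts)
  if (n_avail < 2 * n_per_group) stop("not enough samples to split")
  set.seed(seed)
  ls <- colSums(counts)
  if (mode == "random") {
    pick <- sample(n_avail, 2 * n_per_group)
    g1 <- pick[seq_len(n_per_group)]
    g2 <- pick[n_per_group + seq_len(n_per_group)]
  } else {
    ord <- order(ls)
    g2 <- ord[seq_len(n_per_group)]                 # shallowest
    # deepest window whose mean best matches target_ratio * mean(shallow)
    target <- target_ratio * mean(ls[g2])
    starts <- (n_per_group + 1):(n_avail - n_per_group + 1)
    wmeans <- vapply(starts, function(s) {
      mean(ls[ord[s:(s + n_per_group - 1)]])
    }, numeric(1))
    best <- starts[which.min(abs(log(wmeans / target)))]
    g1 <- ord[best:(best + n_per_group - 1)]
    achieved <- mean(ls[g1]) / mean(ls[g2])
    if (abs(log(achieved / target_ratio)) > log(1.5)) {
      warning(sprintf(
        "closest attainable library-size ratio %.2f differs from target %.2f",
        achieved, target_ratio))
    }
  }
  sel <- c(g1, g2)
  grp <- stats::setNames(rep(c("group1", "group2"), each = n_per_group),
                         colnames(counts)[sel])
  .new_simdata(counts[, sel, drop = FALSE], grp,
               truth = list(taxa = character(0)),
               design = list(kind = "null_split", mode = mode,
                             n_per_group = n_per_group,
                             target_ratio = target_ratio, seed = seed))
}

#' Design object of a simulated dataset, as a group design
#'
#' @param simdata A `simulated_dataset`.
#' @param with_library_size Add a `library_size` covariate column.
#' @return A [group_design()] for the dataset's samples.
#' @export
sim_design <- function(simdata, with_library_size = FALSE) {
  ct <- simdata$table
  cov <- if (with_library_size) {
    data.frame(library_size = as.numeric(library_sizes(ct)))
  } else NULL
  group_design(colnames(ct$counts),
               ct$sample_group[colnames(ct$counts)], covariates = cov)
}
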