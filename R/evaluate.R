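# Truth-aware performance metrics and the grid runner: sensitivity and FDR
# against a simulation's recorded truth, nominal-vs-observed FDR curves,
# standardized effect-size CDFs, and replicate aggregation by median and
# upper quartile.

#' Sensitivity and FDR of a differential-abundance call set
#'
#' Sensitivity is the fraction of true positives called (NA when the truth is
#' empty — the type-I regime); FDR is the fraction of calls that are false (0
#' when nothing is called).
#'
#' @param result A `da_result` (or character vector of called taxon IDs).
#' @param truth Character vector of true-positive taxon IDs (or the `truth`
#'   element of a `simulated_dataset`).
#' @param universe Optional taxon universe for consistency checking; defaults
#'   to the result's taxa.
#' @return List with `sensitivity`, `fdr`, `n_called`, `n_true`,
#'   `n_true_called`.
#' @export
confusion_metrics <- function(result, truth, universe = NULL) {
  called <- if (inherits(result, "da_result")) result$called else result
  if (is.list(truth) && !is.null(truth$taxa)) truth <- truth$taxa
  if (inherits(result, "da_result")) {
    universe <- result$table$taxon
  }
  if (!is.null(universe) && length(truth) && !all(truth %in% universe)) {
    stop("truth taxa outside the result's taxon universe")
  }
  n_called <- length(called)
  n_true <- length(truth)
  tp <- length(intersect(called, truth))
  list(
    sensitivity = if (n_true) tp / n_true else NA_real_,
    fdr = if (n_called) (n_called - tp) / n_called else 0,
    n_called = n_called,
    n_true = n_true,
    n_true_called = tp
  )
}

#' Observed FDR across a grid of nominal levels
#'
#' Re-thresholds a test's BH q-values at each nominal level and reports the
#' observed FDR against the truth, for nominal-vs-observed calibration plots.
#'
#' @param result A `da_result` with q-values.
#' @param truth True-positive taxon IDs.
#' @param nominal Strictly increasing grid of nominal FDR levels.
#' @return data.frame with columns `nominal`, `observed_fdr`, `n_called`.
#' @export
fdr_curve <- function(result, truth, nominal = c(0.01, 0.05, 0.1, 0.15, 0.2,
                                                 0.25)) {
  stopifnot(inherits(result, "da_result"))
  if (!length(nominal)) stop("empty nominal grid")
  if (any(diff(nominal) <= 0)) stop("nominal grid must be increasing")
  if (is.list(truth) && !is.null(truth$taxa)) truth <- truth$taxa
  q <- result$table$q
  taxa <- result$table$taxon
  rows <- lapply(nominal, function(a) {
    called <- taxa[!is.na(q) & q <= a]
    cm <- confusion_metrics(called, truth, universe = taxa)
    data.frame(nominal = a, observed_fdr = cm$fdr, n_called = cm$n_called)
  })
  do.call(rbind, rows)
}

#' Empirical CDF of per-taxon standardized effect sizes
#'
#' Cohen's d on the per-sample relative abundances, taxon by taxon; taxa with
#' zero pooled variance are skipped and counted. Used to characterize how much
#' systematic signal a supposedly null comparison carries.
#'
#' @param table A [count_table()].
#' @param design A [group_design()] with two groups.
#' @return List with `ecdf` (a step function), `effects` (finite d values),
#'   `median_effect`, and `n_skipped`.
#' @export
effect_size_cdf <- function(table, design) {
  counts <- values_of(table)
  g <- .two_groups(design, colnames(counts))
  props <- sweep(counts, 2, colSums(counts), "/")
  x1 <- props[, g$i1, drop = FALSE]; x2 <- props[, g$i2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- .row_vars(x1); v2 <- .row_vars(x2)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (m1 - m2) / sp
  finite <- is.finite(d)
  list(ecdf = stats::ecdf(d[finite]), effects = d[finite],
       median_effect = stats::median(d[finite]),
       n_skipped = sum(!finite))
}

#' Aggregate replicate records by median and upper quartile
#'
#' @param records data.frame with a `replicate` column, metric columns
#'   (`sensitivity`, `fdr`, ...), and any number of grouping columns.
#' @param metrics Metric column names to aggregate.
#' @return data.frame with one row per distinct combination of the grouping
#'   columns, carrying `<metric>_median` and `<metric>_uq` (type-7 75th
#'   percentile).
#' @export
summarize_replicates <- function(records, metrics = c("sensitivity", "fdr")) {
  stopifnot(is.data.frame(records), "replicate" %in% colnames(records))
  metrics <- intersect(metrics, colnames(records))
  keys <- setdiff(colnames(records), c(metrics, "replicate", "seed",
                                       "n_called", "n_true"))
  if (!length(keys)) {
    records$.all <- "all"
    keys <- ".all"
  }
  keystr <- do.call(paste, c(records[keys], sep = "\r"))
  out <- lapply(split(seq_len(nrow(records)), keystr), function(idx) {
    row <- records[idx[1], keys, drop = FALSE]
    for (mcol in metrics) {
      v <- records[idx, mcol]
      v <- v[!is.na(v)]
      row[[paste0(mcol, "_median")]] <-
        if (length(v)) stats::median(v) else NA_real_
      row[[paste0(mcol, "_uq")]] <-
        if (length(v)) stats::quantile(v, 0.75, type = 7, names = FALSE)
        else NA_real_
    }
    row$n_replicates <- length(idx)
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$.all <- NULL
  res
}

# Deterministic per-cell seed from the base seed and the cell parameters;
# stable under grid reordering and kept below 2^31.
.cell_seed <- function(base_seed, ...) {
  s <- paste(..., sep = "|")
  h <- sum(utf8ToInt(s) * seq_len(nchar(s))) %% 1000003L
  as.integer((as.numeric(base_seed) * 7919 + h) %% 2147483629 + 1)
}

#' Run a simulation x normalization x test grid
#'
#' For every cell of the grid: simulate a dataset, run each (method,
#' normalization) pipeline, and score sensitivity/FDR against the recorded
#' truth. Cell seeds are derived deterministically from the base seed and the
#' cell parameters, so reruns (and reordered grids) reproduce identical
#' records. Failing cells are recorded and the run continues.
#'
#' @param config List with elements:
#'   `template` (a `template_community`),
#'   `design_kind` (`"balanced_da"`, `"original_da"`, or
#'   `"compositional_da"`),
#'   `families` (character vector, ignored for compositional),
#'   `fold_changes`, `n_per_group`, `N_L` (numeric grids),
#'   `methods` (list of `list(method=, normalization=)` pairs),
#'   `replicates` (default 3), `base_seed` (default 1),
#'   `alpha` (default 0.05), and optional extras (`tp_fraction`, `spread`,
#'   `theta`, `gp_shape`, `rarefy_depth_quantile` default 0.15).
#' @return List with `records` (one row per cell x method x replicate) and
#'   `summary` (replicate medians and upper quartiles), plus `failures`.
#' @export
run_experiment <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$template), !is.null(cfg$methods))
  cfg$design_kind <- cfg$design_kind %||% "balanced_da"
  cfg$families <- cfg$families %||% "multinomial"
  cfg$fold_changes <- cfg$fold_changes %||% c(1.5, 2, 5, 10, 15)
  cfg$n_per_group <- cfg$n_per_group %||% 25
  cfg$N_L <- cfg$N_L %||% 2000
  cfg$replicates <- cfg$replicates %||% 3
  cfg$base_seed <- cfg$base_seed %||% 1
  cfg$alpha <- cfg$alpha %||% 0.05
  cfg$tp_fraction <- cfg$tp_fraction %||% 0.1
  cfg$spread <- cfg$spread %||% 0.5
  cfg$rarefy_depth_quantile <- cfg$rarefy_depth_quantile %||% 0.15
  if (cfg$design_kind == "compositional_da") cfg$families <- "multinomial"
  grid <- expand.grid(family = cfg$families, fold_change = cfg$fold_changes,
                      n_per_group = cfg$n_per_group, N_L = cfg$N_L,
                      replicate = seq_len(cfg$replicates),
                      stringsAsFactors = FALSE)
  records <- list()
  failures <- list()
  for (r in seq_len(nrow(grid))) {
    cell <- grid[r, ]
    seed <- .cell_seed(cfg$base_seed, cfg$design_kind, cell$family,
                       cell$fold_change, cell$n_per_group, cell$N_L,
                       cell$replicate)
    sim <- tryCatch(switch(cfg$design_kind,
      balanced_da = simulate_da_dataset(
        cfg$template, family = cell$family, n_per_group = cell$n_per_group,
        fold_change = cell$fold_change, tp_fraction = cfg$tp_fraction,
        design = "balanced", N_L = cell$N_L, spread = cfg$spread, seed = seed,
        theta = cfg$theta %||% cfg$template$theta,
        gp_shape = cfg$gp_shape %||% 10),
      original_da = simulate_da_dataset(
        cfg$template, family = cell$family, n_per_group = cell$n_per_group,
        fold_change = cell$fold_change, tp_fraction = cfg$tp_fraction,
        design = "original", N_L = cell$N_L, spread = cfg$spread, seed = seed,
        theta = cfg$theta %||% cfg$template$theta,
        gp_shape = cfg$gp_shape %||% 10),
      compositional_da = simulate_compositional_dataset(
        cfg$template, tp_fraction = cfg$tp_fraction,
        fold_change = cell$fold_change, n_per_group = cell$n_per_group,
        N_L = cell$N_L, spread = cfg$spread, seed = seed),
      stop("unknown design_kind")), error = function(e) e)
    if (inherits(sim, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(cell = r, stage = "simulate", message = conditionMessage(sim))
      next
    }
    des <- sim_design(sim)
    depth <- stats::quantile(library_sizes(sim$table),
                             cfg$rarefy_depth_quantile, type = 7,
                             names = FALSE)
    for (mm in cfg$methods) {
      res <- tryCatch({
        extra <- if (identical(mm$normalization, "rarefy")) {
          list(depth = max(1, floor(depth)), seed = seed + 1L)
        } else list()
        do.call(run_da, c(list(table = sim$table, design = des,
                               method = mm$method,
                               normalization = mm$normalization %||% "none",
                               alpha = cfg$alpha), extra))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(cell = r, stage = paste(mm$method, mm$normalization),
                     message = conditionMessage(res))
        next
      }
      cm <- confusion_metrics(res, sim$truth)
      records[[length(records) + 1]] <- data.frame(
        method = mm$method, normalization = mm$normalization %||% "none",
        family = cell$family, fold_change = cell$fold_change,
        n_per_group = cell$n_per_group, N_L = cell$N_L,
        replicate = cell$replicate, seed = seed,
        sensitivity = cm$sensitivity, fdr = cm$fdr,
        n_called = cm$n_called, n_true = cm$n_true,
        stringsAsFactors = FALSE
      )
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame()
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame()
  summary <- if (nrow(records)) summarize_replicates(records) else
    data.frame()
  list(records = records, summary = summary, failures = failures,
       config = cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
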