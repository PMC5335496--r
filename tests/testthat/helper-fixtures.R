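# Shared fixture builders. Everything is generated in code; no stored data.

toy_counts <- function(m, vals = NULL, taxa = NULL, samples = NULL) {
  if (is.null(vals)) vals <- seq_len(prod(m))
  x <- matrix(vals, m[1], m[2])
  rownames(x) <- taxa %||% sprintf("T%02d", seq_len(m[1]))
  colnames(x) <- samples %||% sprintf("S%02d", seq_len(m[2]))
  x
}

toy_table <- function(m, vals = NULL, taxa = NULL, samples = NULL, ...) {
  count_table(toy_counts(m, vals, taxa = taxa, samples = samples), ...)
}

two_group_design <- function(n_per_group, ids = NULL) {
  n <- 2 * n_per_group
  ids <- ids %||% sprintf("S%02d", seq_len(n))
  group_design(ids, rep(c("g1", "g2"), each = n_per_group))
}

# multinomial community table with chosen depths
community_table <- function(pi, depths, taxa = NULL, seed = 1) {
  set.seed(seed)
  cnt <- vapply(depths, function(N) stats::rmultinom(1, N, pi)[, 1],
                numeric(length(pi)))
  rownames(cnt) <- taxa %||% sprintf("T%03d", seq_along(pi))
  colnames(cnt) <- sprintf("S%03d", seq_along(depths))
  count_table(cnt)
}

# overdispersed (gamma-Poisson) one-environment table
overdispersed_table <- function(pi, depths, shape = 0.5, seed = 1) {
  set.seed(seed)
  cnt <- vapply(depths, function(N) {
    lam <- stats::rgamma(length(pi), shape = shape, rate = shape / (pi * N))
    stats::rpois(length(lam), lam)
  }, numeric(length(pi)))
  rownames(cnt) <- sprintf("T%03d", seq_along(pi))
  colnames(cnt) <- sprintf("S%03d", seq_along(depths))
  count_table(cnt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
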