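# brute-force BH step-up, kept deliberately naive
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

test_that("BH adjustment matches the step-up oracle and handles NaN", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(1)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  q <- bh_adjust(c(0.01, NaN, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(c(0.01, 0.04)))
  # q >= p elementwise
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p - 1e-12))
})

test_that("Mann-Whitney matches exact enumeration and degenerates sanely", {
  v <- matrix(c(1, 2, 3, 4, 5, 6,   # complete separation
                7, 7, 7, 7, 7, 7,   # constant
                1, 2, 3, 1, 2, 3),  # identical groups
              3, 6, byrow = TRUE,
              dimnames = list(c("sep", "const", "same"), sprintf("S%02d", 1:6)))
  des <- two_group_design(3, sprintf("S%02d", 1:6))
  r <- mann_whitney_test(v, des)
  expect_equal(r$table["sep", "stat"], 0)
  # exact two-sided p: 2 / choose(6, 3)
  expect_equal(r$table["sep", "p"], 2 / choose(6, 3))
  expect_equal(r$table["const", "p"], 1)
  expect_equal(r$table["same", "p"], 1)
})

test_that("Welch t separates shifted groups and survives constant groups", {
  set.seed(2)
  n <- 20
  des <- two_group_design(n / 2)
  v <- rbind(shift = c(rnorm(n / 2, 5), rnorm(n / 2, 0)),
             oneconst = c(rep(1, n / 2), rnorm(n / 2, 1)))
  colnames(v) <- sprintf("S%02d", 1:n)
  r <- welch_t_test(v + 10, des)
  expect_lt(r$table["shift", "p"], 1e-4)
  expect_true(is.finite(r$table["oneconst", "stat"]))
  # both groups constant and equal: p = 1
  v2 <- rbind(allsame = rep(3, n))
  colnames(v2) <- sprintf("S%02d", 1:n)
  expect_equal(welch_t_test(v2, des)$table$p, 1)
})

test_that("null type-I error is calibrated for welch and MW", {
  set.seed(3)
  m <- 500
  n <- 40
  des <- two_group_design(n / 2)
  v <- matrix(exp(rnorm(m * n)), m, n,
              dimnames = list(sprintf("T%03d", 1:m), sprintf("S%02d", 1:n)))
  band <- 3 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(mean(welch_t_test(v, des)$table$p <= 0.05) - 0.05), band)
  expect_lt(abs(mean(mann_whitney_test(v, des)$table$p <= 0.05) - 0.05), band)
})

test_that("ANCOM W equals the brute-force all-pairs oracle (m <= 20)", {
  set.seed(4)
  m <- 12
  n_per <- 25
  pi <- rep(1 / m, m)
  cnt <- cbind(
    sapply(seq_len(n_per), function(i) rmultinom(1, 500, pi)[, 1]),
    sapply(seq_len(n_per), function(i) rmultinom(1, 500, pi)[, 1])
  )
  cnt[1, seq_len(n_per)] <- cnt[1, seq_len(n_per)] * 8  # taxon 1 up x8 in group 1
  dimnames(cnt) <- list(sprintf("T%02d", 1:m), sprintf("S%02d", 1:(2 * n_per)))
  ct <- count_table(cnt)
  des <- two_group_design(n_per)
  r <- ancom_test(ct, des)
  W <- r$table$stat
  # independent oracle: wilcox.test per ordered pair, per-taxon BH
  logc <- log(cnt + 0.001)
  W_oracle <- sapply(seq_len(m), function(i) {
    ps <- sapply(setdiff(seq_len(m), i), function(j) {
      d <- logc[i, ] - logc[j, ]
      suppressWarnings(stats::wilcox.test(
        d[1:n_per], d[n_per + 1:n_per], exact = FALSE,
        correct = TRUE)$p.value)
    })
    sum(p.adjust(ps, "BH") <= 0.05)
  })
  expect_equal(W, W_oracle)
  expect_true(all(W >= 0 & W <= m - 1))
  expect_equal(which.max(W), 1)  # the inflated taxon attains the max W
})

test_that("ANCOM with m = 2 gives symmetric W and the pair shares one test", {
  set.seed(5)
  cnt <- matrix(rpois(20, 30) + 1, 2, 10,
                dimnames = list(c("A", "B"), sprintf("S%02d", 1:10)))
  ct <- count_table(cnt)
  r <- ancom_test(ct, two_group_design(5))
  expect_equal(r$table$stat[1], r$table$stat[2])
  expect_true(all(r$table$stat %in% c(0, 1)))
  expect_error(ancom_test(ct, two_group_design(5), pseudocount = 0), "> 0")
})

test_that("NB GLM is calibrated on NB nulls and recovers effect signs", {
  set.seed(6)
  m <- 400
  n <- 40
  des <- two_group_design(n / 2)
  cnt <- matrix(rnbinom(m * n, mu = 20, size = 2), m, n,
                dimnames = list(sprintf("T%03d", 1:m), sprintf("S%02d", 1:n)))
  ct <- count_table(cnt)
  band <- 3 * sqrt(0.05 * 0.95 / m)
  for (mode in c("wald", "exact")) {
    r <- nb_glm_test(ct, des, mode = mode)
    expect_lt(abs(mean(r$table$p <= 0.05, na.rm = TRUE) - 0.05), band)
  }

  # 200 taxa with a true 4x fold change in group 1: sign correct >= 95%
  m2 <- 200
  cnt2 <- matrix(0, m2, n)
  cnt2[, 1:(n / 2)] <- rnbinom(m2 * n / 2, mu = 80, size = 2)
  cnt2[, (n / 2 + 1):n] <- rnbinom(m2 * n / 2, mu = 20, size = 2)
  dimnames(cnt2) <- list(sprintf("T%03d", 1:m2), sprintf("S%02d", 1:n))
  sf <- stats::setNames(rep(1, n), colnames(cnt2))
  r2 <- nb_glm_test(count_table(cnt2), des, mode = "wald", size_factors = sf)
  expect_gte(mean(r2$table$lfc > 0, na.rm = TRUE), 0.95)
})

test_that("LFC shrinkage moves estimates toward zero, most at low counts", {
  set.seed(7)
  m <- 150
  n <- 20
  des <- two_group_design(n / 2)
  cnt <- matrix(rnbinom(m * n, mu = rep(c(2, 100), each = m / 2), size = 1),
                m, n, dimnames = list(sprintf("T%03d", 1:m),
                                      sprintf("S%02d", 1:n)))
  ct <- count_table(cnt)
  sh <- nb_glm_test(ct, des, mode = "wald", shrink_lfc = TRUE)
  un <- nb_glm_test(ct, des, mode = "wald", shrink_lfc = FALSE)
  ok <- !is.na(sh$table$lfc) & !is.na(un$table$lfc)
  expect_true(all(abs(sh$table$lfc[ok]) <= abs(un$table$lfc[ok]) + 1e-12))
})

test_that("voom weights are flat on homoskedastic data and the null is calibrated", {
  set.seed(8)
  m <- 400
  n <- 30
  des <- two_group_design(n / 2)
  # flat mean-variance trend: equal-mean Poisson-ish counts at high depth
  cnt <- matrix(rpois(m * n, 500), m, n,
                dimnames = list(sprintf("T%03d", 1:m), sprintf("S%02d", 1:n)))
  ct <- count_table(cnt)
  r <- voom_test(ct, des)
  band <- 3 * sqrt(0.05 * 0.95 / m)
  expect_lt(abs(mean(r$table$p <= 0.05, na.rm = TRUE) - 0.05), band)
  # moderated t tracks the ordinary t on flat-trend data
  y <- log2(sweep(cnt + 0.5, 2, colSums(cnt) + 1, "/") * 1e6)
  tt <- welch_t_test(y, des)
  expect_gt(cor(abs(r$table$stat), abs(tt$table$stat)), 0.97)

  # all-zero taxon is excluded from the ranking
  cnt0 <- rbind(cnt, zero = 0L)
  r0 <- voom_test(count_table(cnt0), des)
  expect_true(is.na(r0$table[r0$table$taxon == "zero", "p"]))
})

test_that("voom against limma's reference on the same data", {
  set.seed(9)
  m <- 200
  n <- 20
  des <- two_group_design(n / 2)
  cnt <- matrix(rnbinom(m * n, mu = 50, size = 1) + 1, m, n,
                dimnames = list(sprintf("T%03d", 1:m), sprintf("S%02d", 1:n)))
  ours <- voom_test(count_table(cnt), des)
  dm <- cbind(1, rep(c(1, 0), each = n / 2))
  v <- limma::voom(cnt, dm, lib.size = colSums(cnt) *
                     edgeR::calcNormFactors(cnt, method = "TMM"))
  fit <- limma::eBayes(limma::lmFit(v, dm))
  pref <- fit$p.value[, 2]
  expect_gt(cor(-log10(ours$table$p), -log10(pref), use = "complete.obs"),
            0.95)
})

test_that("the ZIG EM collapses without zeros and never decreases its likelihood", {
  set.seed(10)
  m <- 120
  n <- 20
  des <- two_group_design(n / 2)
  cnt <- matrix(rpois(m * n, 200) + 1, m, n,
                dimnames = list(sprintf("T%03d", 1:m), sprintf("S%02d", 1:n)))
  ct <- count_table(cnt)
  r <- suppressWarnings(zig_test(ct, des))
  expect_true(all(diff(r$params$loglik_trace) >=
                    -1e-6 * abs(r$params$loglik_trace[-1]) - 1e-8))
  # no zeros: reduces to a (moderated) t on the log values
  y <- log2(suppressWarnings(css_normalize(ct))$values + 1)
  tt <- welch_t_test(y, des)
  expect_gt(cor(abs(r$table$stat), abs(tt$table$stat)), 0.95)

  # sparse data: EM still monotone, zi_lognormal mode runs
  tpl <- make_synthetic_template(100, 0.85, seed = 2)
  sim <- simulate_da_dataset(tpl, n_per_group = 10, fold_change = 5,
                             tp_fraction = 0.1, seed = 3)
  rz <- suppressWarnings(zig_test(sim$table, sim_design(sim)))
  expect_true(all(diff(rz$params$loglik_trace) >=
                    -1e-6 * abs(rz$params$loglik_trace[-1]) - 1e-8))
  rl <- suppressWarnings(zig_test(sim$table, sim_design(sim),
                                  mode = "zi_lognormal"))
  expect_s3_class(rl, "da_result")
})

test_that("depth-linked zeros mislead the ZIG model where the rank test stays clean", {
  # Null data whose zero pattern is driven by library size (shallow vs deep
  # samples confounded with the groups): the Gaussian-component test still
  # rejects, while rarefy + Mann-Whitney stays near zero. This is the
  # ZIG model's characteristic failure mode on null comparisons.
  tpl <- make_synthetic_template(150, 0.9, seed = 5)
  rates <- sapply(1:3, function(s) {
    set.seed(s)
    Ns <- c(as.integer(round(exp(runif(10, log(300), log(800))))),
            as.integer(round(exp(runif(10, log(20000), log(60000))))))
    ct <- community_table(tpl$pi, Ns, seed = s + 50)
    des <- group_design(colnames(ct$counts), rep(c("a", "b"), each = 10))
    rz <- zig_test(ct, des)
    mwr <- run_da(ct, des, "mw", "rarefy", depth = min(library_sizes(ct)),
                  seed = s)
    c(zig = mean(rz$table$p <= 0.05, na.rm = TRUE),
      mw = mean(mwr$table$p <= 0.05, na.rm = TRUE))
  })
  expect_gt(mean(rates["zig", ]), mean(rates["mw", ]) + 0.05)
  expect_lte(mean(rates["mw", ]), 0.05)
})

test_that("a unit pseudocount before NB testing inflates type-I on uneven nulls", {
  tpl <- make_synthetic_template(200, 0.9, seed = 7)
  set.seed(20)
  Ns <- c(as.integer(round(runif(15, 2000, 4000))),
          as.integer(round(runif(15, 20000, 40000))))
  ct <- community_table(tpl$pi, Ns, seed = 21)
  des <- group_design(colnames(ct$counts), rep(c("lo", "hi"), each = 15))
  raw <- nb_glm_test(ct, des, mode = "wald")
  pseudo <- nb_glm_test(count_table(add_pseudocount(ct, 1)), des,
                        mode = "wald")
  expect_gt(mean(pseudo$table$p <= 0.05, na.rm = TRUE),
            mean(raw$table$p <= 0.05, na.rm = TRUE))
})

test_that("run_da wires normalizations to tests and rejects nonsense pairs", {
  tpl <- make_synthetic_template(80, 0.8, seed = 9)
  sim <- simulate_da_dataset(tpl, n_per_group = 8, fold_change = 5,
                             tp_fraction = 0.1, seed = 4)
  des <- sim_design(sim)
  r1 <- run_da(sim$table, des, "mw", "rarefy", depth = 500, seed = 1)
  expect_s3_class(r1, "da_result")
  expect_equal(r1$params$normalization, "rarefy")
  expect_s3_class(run_da(sim$table, des, "t", "none"), "da_result")
  expect_s3_class(run_da(sim$table, des, "t", "proportion"), "da_result")
  expect_error(run_da(sim$table, des, "ancom", "DESeqVS"), "integer counts")
  expect_error(run_da(sim$table, des, "starfish", "none"), "unknown")
  expect_warning(run_da(sim$table, des, "zig", "rarefy", depth = 500,
                        seed = 1), "library-size")
})
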