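test_that("multinomial templates are normalized row-sum fractions", {
  ct <- toy_table(c(3, 1), c(2, 3, 5))
  tpl <- fit_multinomial(ct)
  expect_equal(unname(tpl$pi), c(0.2, 0.3, 0.5))
  expect_equal(sum(tpl$pi), 1)
  two <- count_table(cbind(a = c(2, 3, 5), b = c(2, 3, 5)) |>
                       `rownames<-`(c("x", "y", "z")))
  expect_equal(fit_multinomial(two)$pi, tpl$pi, ignore_attr = TRUE)
  expect_error(fit_multinomial(count_table(
    matrix(0L, 2, 0, dimnames = list(c("a", "b"), NULL)))), "empty")
})

test_that("DM moments fitting recovers theta within 20% at 500 samples", {
  set.seed(31)
  m <- 60
  pi <- rgamma(m, shape = 1)
  pi <- pi / sum(pi)
  theta <- 0.1
  a <- pi * (1 - theta) / theta
  cnt <- sapply(1:500, function(i) {
    p <- rgamma(m, a); p <- p / sum(p)
    rmultinom(1, 2000, p)[, 1]
  })
  dimnames(cnt) <- list(sprintf("T%02d", 1:m), sprintf("S%03d", 1:500))
  fit <- fit_dirichlet_multinomial(count_table(cnt))
  expect_lt(abs(fit$theta - theta) / theta, 0.20)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)

  # multinomial data pushes theta to the lower clip region
  cnt2 <- sapply(1:300, function(i) rmultinom(1, 2000, pi)[, 1])
  dimnames(cnt2) <- dimnames(cnt)[c(1)] |> c(list(sprintf("S%03d", 1:300)))
  fit2 <- fit_dirichlet_multinomial(count_table(cnt2))
  expect_lt(fit2$theta, 0.005)
  expect_error(fit_dirichlet_multinomial(toy_table(c(3, 1), c(1, 2, 3))),
               ">= 2")
})

test_that("gamma-Poisson moments fitting recovers shape and flags the Poisson limit", {
  set.seed(32)
  m <- 50
  shape <- 2
  mu <- exp(rnorm(m, 3, 1))
  cnt <- sapply(1:500, function(i) {
    lam <- rgamma(m, shape = shape, rate = shape / mu)
    rpois(m, lam)
  })
  dimnames(cnt) <- list(sprintf("T%02d", 1:m), sprintf("S%03d", 1:500))
  fit <- fit_gamma_poisson(count_table(cnt))
  over <- setdiff(fit$taxon_ids, fit$poisson_limit)
  rel <- abs(fit$shape[fit$taxon_ids %in% over] - shape) / shape
  expect_lt(median(rel), 0.25)
  # moments identity: fitted gamma mean equals the observed mean
  ls <- colSums(cnt)
  y <- sweep(cnt, 2, ls, "/") * median(ls)
  expect_equal(unname(fit$shape / fit$rate), unname(rowMeans(y)),
               tolerance = 1e-9)

  # underdispersed taxon is flagged
  cnt2 <- rbind(cnt, flat = 5L)
  f2 <- fit_gamma_poisson(count_table(cnt2))
  expect_true("flat" %in% f2$poisson_limit)
})

test_that("synthetic templates hit the sparsity target and are deterministic", {
  tpl <- make_synthetic_template(400, 0.9, seed = 5)
  tpl_again <- make_synthetic_template(400, 0.9, seed = 5)
  expect_identical(tpl$pi, tpl_again$pi)
  set.seed(1)
  zf <- mean(replicate(20, mean(rmultinom(1, 2000, tpl$pi)[, 1] == 0)))
  expect_lt(abs(zf - 0.9), 0.05)
  big <- make_synthetic_template(2000, 0.9, seed = 6)
  expect_length(big$pi, 2000)
  expect_error(make_synthetic_template(5, 0.9), ">= 10")
})

test_that("clustering datasets mix templates as specified", {
  a <- make_synthetic_template(100, 0.8, seed = 1)
  b <- make_synthetic_template(100, 0.8, seed = 2)
  sim <- simulate_clustering_dataset(a, b, effect_size = 3, n_samples = 40,
                                     N_L = 2000, seed = 3)
  expect_equal(ncol(sim$table$counts), 40)
  expect_equal(unname(table(sim$table$sample_group)), c(20L, 20L),
               ignore_attr = TRUE)
  # mixing formula (checked on the recorded class ecosystems)
  taxa <- union(a$taxon_ids, b$taxon_ids)
  pa <- stats::setNames(rep(0, length(taxa)), taxa); pb <- pa
  pa[a$taxon_ids] <- a$pi; pb[b$taxon_ids] <- b$pi
  mix <- 3 * pa + pb
  expect_equal(sim$truth$class_pi$classA, mix / sum(mix))
  # ES -> infinity recovers the pure template
  simL <- simulate_clustering_dataset(a, b, effect_size = 1e9, seed = 3)
  expect_equal(max(abs(simL$truth$class_pi$classA - pa)), 0,
               tolerance = 1e-6)
  # ES = 1: identical ecosystems
  sim1 <- simulate_clustering_dataset(a, b, effect_size = 1, seed = 3)
  expect_equal(sim1$truth$class_pi$classA, sim1$truth$class_pi$classB)
  expect_error(simulate_clustering_dataset(a, b, effect_size = 0.5), ">= 1")
})

test_that("balanced truth identity: differential abundance iff differential relative abundance", {
  tpl <- make_synthetic_template(300, 0.9, seed = 11)
  sim <- simulate_da_dataset(tpl, n_per_group = 5, fold_change = 5,
                             tp_fraction = 0.1, design = "balanced", seed = 2)
  differs <- abs(sim$truth$pi_group1 - sim$truth$pi_group2) > 1e-14
  expect_setequal(names(which(differs)), sim$truth$taxa)
  expect_equal(length(sim$truth$taxa), 30)
  # group ecosystem vectors are proper distributions
  expect_equal(sum(sim$truth$pi_group1), 1, tolerance = 1e-12)
  expect_equal(sum(sim$truth$pi_group2), 1, tolerance = 1e-12)
  # fold change 1 embeds a null
  sim0 <- simulate_da_dataset(tpl, fold_change = 1, tp_fraction = 0.1,
                              seed = 2)
  expect_length(sim0$truth$taxa, 0)
  expect_equal(sim0$truth$pi_group1, sim0$truth$pi_group2)
})

test_that("the original (legacy) design shifts relative abundances one-sidedly", {
  tpl <- make_synthetic_template(200, 0.9, seed = 12)
  sim <- simulate_da_dataset(tpl, n_per_group = 10, fold_change = 10,
                             tp_fraction = 0.1, design = "original", seed = 3)
  # sampled ecosystems identical, inflation applied post-sampling
  expect_equal(sim$truth$pi_group1, sim$truth$pi_group2)
  expect_length(sim$truth$taxa, 20)
  g1 <- names(sim$table$sample_group)[sim$table$sample_group == "group1"]
  expect_gt(mean(colSums(sim$table$counts[, g1])),
            mean(colSums(sim$table$counts[, setdiff(colnames(sim$table$counts), g1)])))
})

test_that("compositional truth is ecosystem-level, not relative-abundance-level", {
  tpl <- make_synthetic_template(200, 0.9, seed = 13)
  sim <- simulate_compositional_dataset(tpl, tp_fraction = 0.1,
                                        fold_change = 5, n_per_group = 5,
                                        seed = 4)
  expect_length(sim$truth$taxa, 20)
  # every non-TP taxon's relative abundance strictly decreases in group 1
  non_tp <- setdiff(names(sim$truth$pi_group1), sim$truth$taxa)
  pos <- non_tp[sim$truth$pi_group2[non_tp] > 0]
  expect_true(all(sim$truth$pi_group1[pos] < sim$truth$pi_group2[pos]))
  # so the relative-abundance difference set is NOT the truth set
  differs <- names(which(abs(sim$truth$pi_group1 - sim$truth$pi_group2) > 1e-14))
  expect_gt(length(differs), length(sim$truth$taxa))
  # fold change -> 1 limit: groups coincide
  sim1 <- simulate_compositional_dataset(tpl, tp_fraction = 0.1,
                                         fold_change = 1 + 1e-12,
                                         n_per_group = 5, seed = 4)
  expect_equal(sim1$truth$pi_group1, sim1$truth$pi_group2, tolerance = 1e-9)
  expect_error(simulate_compositional_dataset(tpl, tp_fraction = 0.7,
                                              fold_change = 5), "0, 0.5")
})

test_that("null splits have empty truth and uneven mode hits the depth ratio", {
  tpl <- make_synthetic_template(150, 0.9, seed = 14)
  set.seed(15)
  depths <- as.integer(round(exp(runif(120, log(2000), log(80000)))))
  ct <- community_table(tpl$pi, depths, seed = 16)
  spr <- split_null(ct, 20, mode = "random", seed = 1)
  expect_length(spr$truth$taxa, 0)
  expect_equal(ncol(spr$table$counts), 40)

  spu <- split_null(ct, 20, mode = "uneven", target_ratio = 10, seed = 1)
  ls <- library_sizes(spu$table)
  ratio <- mean(ls[1:20]) / mean(ls[21:40])
  expect_lt(abs(ratio / 10 - 1), 0.2)
  for (npg in c(3, 20)) {
    expect_equal(ncol(split_null(ct, npg, seed = 2)$table$counts), 2 * npg)
  }
  expect_error(split_null(ct, 100, seed = 1), "not enough")
})

test_that("datasets are exactly reproducible from their seeds", {
  tpl <- make_synthetic_template(100, 0.85, seed = 17)
  s1 <- simulate_da_dataset(tpl, n_per_group = 8, fold_change = 5,
                            tp_fraction = 0.1, seed = 99)
  s2 <- simulate_da_dataset(tpl, n_per_group = 8, fold_change = 5,
                            tp_fraction = 0.1, seed = 99)
  expect_identical(s1$table$counts, s2$table$counts)
  expect_identical(s1$truth, s2$truth)
  # library-size law: median within 10% of N_L for n = 40
  s3 <- simulate_da_dataset(tpl, n_per_group = 20, fold_change = 1,
                            N_L = 2000, seed = 7)
  expect_lt(abs(median(library_sizes(s3$table)) / 2000 - 1), 0.1)
})

test_that("DM and GP count draws converge to the multinomial limit", {
  tpl <- make_synthetic_template(300, 0.9, seed = 11)
  runs <- function(fam, ...) {
    out <- sapply(1:3, function(s) {
      sim <- simulate_da_dataset(tpl, family = fam, n_per_group = 25,
                                 fold_change = 5, tp_fraction = 0.1,
                                 N_L = 2000, seed = s, ...)
      cm <- confusion_metrics(mann_whitney_test(sim$table, sim_design(sim)),
                              sim$truth)
      c(cm$sensitivity, cm$fdr)
    })
    rowMeans(out)
  }
  base <- runs("multinomial")
  dm <- runs("dirichlet_multinomial", theta = 1e-6)
  gp <- runs("gamma_poisson", gp_shape = 1e6)
  expect_lt(abs(dm[1] - base[1]), 0.08)
  expect_lt(abs(gp[1] - base[1]), 0.08)
  expect_lt(abs(dm[2] - base[2]), 0.08)
  expect_lt(abs(gp[2] - base[2]), 0.08)
})
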