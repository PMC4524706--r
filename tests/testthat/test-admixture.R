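test_that("K = 1 run is degenerate but still yields a likelihood", {
  sim <- simulate_msat(1, 15, 3, 5, drift_f = 0.2, seed = 41)
  run <- run_admixture_mcmc(sim$genotypes,
                            admixture_config(1, n_iterations = 400, seed = 1))
  expect_true(all(run$q_matrix == 1))
  expect_true(is.finite(run$est_ln_prob))
  expect_lte(run$est_ln_prob, run$ln_l_mean)
})

test_that("posterior Q rows are normalized and reproducible given a seed", {
  sim <- simulate_msat(2, 12, 4, 6, drift_f = 0.2, seed = 42)
  cfg <- admixture_config(3, n_iterations = 600, seed = 9)
  run1 <- run_admixture_mcmc(sim$genotypes, cfg)
  run2 <- run_admixture_mcmc(sim$genotypes, cfg)
  expect_equal(unname(rowSums(run1$q_matrix)), rep(1, 24), tolerance = 1e-9)
  expect_identical(run1$q_matrix, run2$q_matrix)
  expect_identical(run1$est_ln_prob, run2$est_ln_prob)
})

test_that("no-structure data at K = 2 gives symmetric membership on average", {
  sim <- simulate_msat(1, 40, 5, 8, drift_f = 0.2, seed = 43)
  run <- run_admixture_mcmc(sim$genotypes,
                            admixture_config(2, n_iterations = 2000, seed = 4))
  expect_equal(mean(run$q_matrix[, 1]), 0.5, tolerance = 0.12)
})

test_that("independent and correlated models both recover strong structure", {
  sim <- simulate_msat(2, 30, 5, 10, drift_f = 0.25, seed = 44)
  for (model in c("independent", "correlated")) {
    run <- run_admixture_mcmc(
      sim$genotypes,
      admixture_config(2, freq_model = model, n_iterations = 2500, seed = 5))
    expect_lt(q_error_vs_truth(run$q_matrix, sim$truth$q), 0.15)
  }
})

test_that("estimated ln prob at the true K beats K = 1 on structured data", {
  wins <- 0L
  for (s in 1:5) {
    sim <- simulate_msat(2, 25, 5, 10, drift_f = 0.25, seed = 50 + s)
    l2 <- run_admixture_mcmc(sim$genotypes,
            admixture_config(2, n_iterations = 1500, seed = s))$est_ln_prob
    l1 <- run_admixture_mcmc(sim$genotypes,
            admixture_config(1, n_iterations = 1500, seed = s))$est_ln_prob
    if (l2 > l1) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("Evanno delta-K follows the second-difference formula", {
  mk <- function(k, mean, d = 1 / sqrt(2)) {
    data.frame(k = k, ln_prob = c(mean + d, mean - d))  # sd exactly 1
  }
  df <- rbind(mk(1, -500), mk(2, -400), mk(3, -395), mk(4, -394))
  ev <- evanno_delta_k(df)
  expect_equal(ev$sd_ln_prob, rep(1, 4), tolerance = 1e-12)
  expect_true(is.na(ev$delta_k[1]) && is.na(ev$delta_k[4]))
  expect_equal(ev$delta_k[ev$k == 2], 95)  # |-395 + 800 - 500| / 1
  expect_equal(ev$delta_k[ev$k == 3], 4)
  expect_identical(attr(ev, "selected_k"), 2)

  # equal means -> delta K zero wherever defined
  df2 <- rbind(mk(1, -100), mk(2, -100), mk(3, -100))
  expect_equal(evanno_delta_k(df2)$delta_k[2], 0)

  # zero sd flagged as undefined, not an error
  df3 <- rbind(data.frame(k = 1, ln_prob = c(-10, -10)),
               data.frame(k = 2, ln_prob = c(-5, -5)),
               data.frame(k = 3, ln_prob = c(-4, -3)))
  expect_true(is.na(evanno_delta_k(df3)$delta_k[2]))
})

test_that("run alignment undoes label switching", {
  set.seed(61)
  q <- matrix(runif(15), 5)
  q <- q / rowSums(q)
  swapped <- q[, c(3, 1, 2)]
  al <- align_runs(list(q, swapped))
  expect_equal(al$consensus_q, q, tolerance = 1e-12)

  # single run: consensus is the run itself
  expect_equal(align_runs(list(q))$consensus_q, q, tolerance = 1e-12)

  # label-switched halves: aligned consensus must beat every unaligned
  # average (exhaustive-permutation oracle at K = 3)
  q2 <- q + matrix(rnorm(15, 0, 0.02), 5)
  q2 <- pmin(pmax(q2, 1e-6), 1)
  q2 <- q2 / rowSums(q2)
  runs <- list(q, q2[, c(2, 3, 1)])
  al2 <- align_runs(runs)
  cost_aligned <- sum((runs[[2]][, al2$permutations[[2]]] - q)^2)
  perms <- lineagemix:::permutations_of(3)
  costs <- vapply(perms, function(p) sum((runs[[2]][, p] - q)^2), numeric(1))
  expect_equal(cost_aligned, min(costs), tolerance = 1e-12)
  expect_lt(mean(abs(al2$consensus_q - q)), mean(abs((q + runs[[2]]) / 2 - q)))
})

test_that("delta-Qbar statistic and its antisymmetry", {
  expect_identical(delta_q_statistic(c(1, 1, 0, 0), c("a", "a", "b", "b")), 1)
  expect_identical(delta_q_statistic(rep(0.4, 6), rep(c("a", "b"), 3)), 0)
  set.seed(71)
  v <- runif(20)
  g <- factor(rep(c("x", "y"), c(12, 8)), levels = c("x", "y"))
  g_flip <- factor(g, levels = c("y", "x"))
  expect_equal(delta_q_statistic(v, g), -delta_q_statistic(v, g_flip),
               tolerance = 1e-12)
  expect_error(delta_q_statistic(v, rep("x", 20)), "two groups")
})

test_that("permutation test matches exhaustive enumeration on small pools", {
  res <- permutation_test_delta_q(c(1, 1, 0, 0), c("a", "a", "b", "b"),
                                  exhaustive = TRUE)
  expect_equal(res$p_value, 1 / 6)
  expect_identical(res$n_permutations, 6L)

  set.seed(81)
  v <- round(runif(9), 3)
  g <- rep(c("g1", "g2"), c(5, 4))
  ex <- permutation_test_delta_q(v, g, exhaustive = TRUE)
  mc <- permutation_test_delta_q(v, g, n_perm = 40000, seed = 3)
  expect_equal(mc$p_value, ex$p_value, tolerance = 0.02)

  # add-one estimator never returns zero
  v2 <- c(rep(1, 6), rep(0, 6))
  g2 <- rep(c("a", "b"), each = 6)
  mc2 <- permutation_test_delta_q(v2, g2, n_perm = 200, seed = 1)
  expect_gt(mc2$p_value, 0)
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(91)
  n_rep <- 400L
  rej <- 0L
  for (r in seq_len(n_rep)) {
    v <- rnorm(24)
    g <- rep(c("a", "b"), c(14, 10))
    p <- permutation_test_delta_q(v, g, n_perm = 199, seed = r)$p_value
    if (p <= 0.05) rej <- rej + 1L
  }
  # exact level 0.05 by the add-one construction; 3 binomial SDs ~ 0.033
  expect_gt(rej / n_rep, 0.017)
  expect_lt(rej / n_rep, 0.083)
})
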