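test_that("diversity indices match hand-evaluated formulas", {
  # alleles {100/100, 100/102}: A = 2, H_O = 0.5, unbiased H = 0.5
  gt <- genotype_table(c("s1", "s2"), "L1", matrix(c(100L, 100L)),
                       matrix(c(100L, 102L)))
  dt <- diversity_table(gt)
  expect_identical(dt$A, 2L)
  expect_equal(dt$h_obs, 0.5)
  expect_equal(dt$gene_div, (4 / 3) * (1 - (0.75^2 + 0.25^2)))

  # monomorphic locus: flagged, H values NA, Rs = 1
  gtm <- genotype_table(sprintf("i%02d", 1:13), c("Ppip05", "L45"),
                        cbind(rep(165L, 13), c(rep(200L, 6), rep(202L, 7))),
                        cbind(rep(165L, 13), c(rep(200L, 3), rep(204L, 10))))
  dtm <- diversity_table(gtm)
  expect_true(dtm$monomorphic[1])
  expect_identical(dtm$A[1], 1L)
  expect_equal(dtm$Rs[1], 1.0)
  expect_true(is.na(dtm$h_obs[1]))
  # summary means exclude the flagged locus
  expect_equal(attr(dtm, "mean")[["h_obs"]], dtm$h_obs[2])
})

test_that("column means exclude monomorphic cells (North-Africa arithmetic)", {
  # mean H_O over informative loci only: (0.62+0.15+0.77+0.69)/4 = 0.5575
  h_obs <- c(0.62, 0.15, 0.77, NA, 0.69)
  expect_equal(round(mean(h_obs, na.rm = TRUE), 2), 0.56)
})

test_that("rarefied richness: identity at full depth, monotone in g", {
  set.seed(6)
  sim <- simulate_msat(1, 30, 4, 8, drift_f = 0.2, seed = 6)
  gt <- sim$genotypes
  full <- diversity_table(gt, rarefaction_size = 60)
  expect_equal(full$Rs, as.numeric(full$A), tolerance = 1e-9)
  prev <- rep(0, 4)
  for (g in c(4, 10, 20, 40, 60)) {
    rs <- diversity_table(gt, rarefaction_size = g)$Rs
    expect_true(all(rs >= prev - 1e-9))
    expect_true(all(rs <= full$A + 1e-9))
    prev <- rs
  }
  expect_error(diversity_table(gt, rarefaction_size = 62), "exceeds")
})

test_that("gene diversity dominates observed heterozygosity under HWE", {
  set.seed(15)
  diffs <- replicate(40, {
    gt <- simulate_hwe_locus(40, c(0.4, 0.3, 0.2, 0.1), sample.int(1e6, 1))
    dt <- diversity_table(gt)
    dt$gene_div - dt$h_obs
  })
  expect_gt(mean(diffs, na.rm = TRUE), -0.02)
})

test_that("HWE Monte-Carlo test agrees with the two-allele exact oracle", {
  gtm <- genotype_table(paste0("i", 1:10), "L",
                        matrix(rep(100L, 10)), matrix(rep(100L, 10)))
  expect_identical(hwe_exact_test(gtm, "L")$p_value, 1)

  cases <- list(c(25L, 50L, 25L),   # exact HW proportions
                c(40L, 20L, 40L),   # strong heterozygote deficit
                c(10L, 60L, 30L))
  for (cs in cases) {
    a1 <- c(rep(100L, cs[1]), rep(100L, cs[2]), rep(102L, cs[3]))
    a2 <- c(rep(100L, cs[1]), rep(102L, cs[2]), rep(102L, cs[3]))
    gt <- genotype_table(sprintf("i%03d", seq_len(sum(cs))), "L",
                         matrix(a1), matrix(a2))
    p_mc <- hwe_exact_test(gt, "L", n_mc = 20000, seed = 2)$p_value
    p_ex <- hwe_exact_two_allele(cs[1], cs[2], cs[3])
    expect_lt(abs(p_mc - p_ex), 0.02)
  }
})

test_that("F-statistics: fixed differences give F_ST = 1, panmixia ~ 0", {
  gt <- genotype_table(paste0("s", 1:8), c("A", "B"),
                       cbind(c(rep(100L, 4), rep(104L, 4)),
                             c(rep(200L, 4), rep(204L, 4))),
                       cbind(c(rep(100L, 4), rep(104L, 4)),
                             c(rep(200L, 4), rep(204L, 4))))
  fs <- f_statistics(gt, rep(c("p1", "p2"), each = 4))
  expect_equal(fs$pairwise_fst["p1", "p2"], 1)
  expect_identical(diag(fs$pairwise_fst), c(p1 = 0, p2 = 0))
  expect_identical(fs$pairwise_fst, t(fs$pairwise_fst))

  # one panmictic population split at random in two: mean F_ST ~ 0
  set.seed(21)
  fst_vals <- replicate(50, {
    sim <- simulate_msat(1, 40, 5, 8, drift_f = 0.3, seed = sample.int(1e6, 1))
    f_statistics(sim$genotypes,
                 sample(rep(c("a", "b"), 20)))$pairwise_fst[1, 2]
  })
  expect_lt(abs(mean(fst_vals)), 0.01)
})

test_that("F-statistics are invariant to allele relabeling and sample order", {
  set.seed(31)
  sim <- simulate_msat(2, 25, 5, 6, drift_f = 0.15, seed = 31)
  gt <- sim$genotypes
  labels <- paste0("c", sim$truth$population)
  base <- f_statistics(gt, labels)

  # relabel alleles by a strictly monotone-breaking but injective map
  remap <- function(x) ifelse(is.na(x), NA_integer_, 1000L - x)
  gt2 <- genotype_table(gt$sample_ids, gt$locus_names,
                        remap(gt$a1), remap(gt$a2))
  rel <- f_statistics(gt2, labels)
  expect_equal(rel$pairwise_fst, base$pairwise_fst, tolerance = 1e-12)
  expect_equal(rel$fis_per_cluster, base$fis_per_cluster, tolerance = 1e-12)

  ord <- sample(length(gt$sample_ids))
  gt3 <- genotype_table(gt$sample_ids[ord], gt$locus_names,
                        gt$a1[ord, ], gt$a2[ord, ])
  per <- f_statistics(gt3, setNames(labels, gt$sample_ids))
  expect_equal(sort(per$pairwise_fst), sort(base$pairwise_fst),
               tolerance = 1e-12)
})

test_that("null-allele screen flags heterozygote deficits above 5%", {
  # strong deficit: mostly homozygotes at two alleles
  a1 <- c(rep(100L, 20), rep(102L, 18), rep(100L, 2))
  a2 <- c(rep(100L, 20), rep(102L, 18), rep(102L, 2))
  gt <- genotype_table(sprintf("i%02d", 1:40), "L", matrix(a1), matrix(a2))
  res <- null_allele_check(gt)
  expect_true(res$flagged)
  # locus at exact HW proportions should not be flagged
  a1h <- c(rep(100L, 15), rep(100L, 30), rep(102L, 15))
  a2h <- c(rep(100L, 15), rep(102L, 30), rep(102L, 15))
  gt2 <- genotype_table(sprintf("j%02d", 1:60), "L", matrix(a1h), matrix(a2h))
  expect_false(null_allele_check(gt2)$flagged)
})
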