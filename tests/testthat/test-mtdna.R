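test_that("haplotype collapsing counts, orders and re-expands", {
  h <- collapse_haplotypes(c(a = "ACGT", b = "ACGT", c = "ACGA"))
  expect_identical(h$counts, c(2L, 1L))
  expect_identical(unname(h$haplotypes), c("ACGT", "ACGA"))
  expect_identical(h$members[[1]], c("a", "b"))

  distinct <- setNames(c("AAAA", "AAAT", "AATT", "ATTT"), paste0("s", 1:4))
  hd <- collapse_haplotypes(distinct)
  expect_identical(hd$counts, rep(1L, 4))

  expect_error(collapse_haplotypes(c(a = "ACG", b = "ACGT")), "equal length")

  # multiset preservation: expand-by-counts gives back the input sequences
  set.seed(2)
  sim <- simulate_mtdna(n_per_lineage = c(W = 20, E = 10),
                        tau_per_lineage = 3, seed = 2)
  h2 <- collapse_haplotypes(sim$records)
  expect_identical(sum(h2$counts), length(sim$records))
  back <- expand_haplotypes(h2)
  expect_identical(sort(unname(back)), sort(unname(sim$records)))
  expect_setequal(names(back), names(sim$records))
})

test_that("nearest-reference lineage assignment with two-mutation radius", {
  west <- paste(rep("A", 20), collapse = "")
  east <- paste(c(rep("A", 2), rep("T", 18)), collapse = "")
  refs <- lineage_references(c("Western", "Eastern"), c(west, east))

  expect_identical(assign_lineage(west, refs),
                   list(lineage = "Western", distance = 0L))

  near_east <- paste(c(rep("A", 2), rep("T", 16), "G", "G"), collapse = "")
  res <- assign_lineage(near_east, refs)
  expect_identical(res$lineage, "Eastern")
  expect_identical(res$distance, 2L)

  far <- paste(c(rep("C", 10), rep("A", 10)), collapse = "")
  resf <- assign_lineage(far, refs)
  expect_identical(resf$lineage, "unassigned")

  # exact tie -> ambiguous, not an error
  refs2 <- lineage_references(c("L1", "L2"), c("AAAA", "TTAA"))
  expect_identical(assign_lineage("TAAA", refs2)$lineage, "ambiguous")

  tab <- assign_lineages(c(x = west, y = near_east), refs)
  expect_identical(tab$lineage, c("Western", "Eastern"))
})

test_that("K2P distance matches the closed form and the ape oracle", {
  expect_identical(k2p_distance("ACGT", "ACGT")$distance, 0)

  ts <- k2p_distance("ACGT", "GCGT")
  expect_equal(ts$p_transition, 0.25)
  expect_equal(ts$q_transversion, 0)
  expect_equal(ts$distance, -0.5 * log(0.5), tolerance = 1e-12)

  tv <- k2p_distance("ACGT", "CCGT")
  expect_equal(tv$q_transversion, 0.25)
  expect_equal(tv$distance, -0.5 * log(0.75) - 0.25 * log(0.5),
               tolerance = 1e-12)

  # independent oracle on random pairs
  set.seed(7)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    b <- strsplit(a, "")[[1]]
    idx <- sample(200, 12)
    b[idx] <- vapply(b[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    b <- paste(b, collapse = "")
    m <- ape::as.DNAbin(rbind(a = strsplit(tolower(a), "")[[1]],
                              b = strsplit(tolower(b), "")[[1]]))
    expect_equal(k2p_distance(a, b)$distance,
                 as.numeric(ape::dist.dna(m, model = "K80")),
                 tolerance = 1e-10)
  }

  # sites with N or gaps are excluded pairwise
  expect_identical(k2p_distance("ANGT", "AC-T")$n_sites, 2L)
  expect_error(k2p_distance("AG", "GA"), "saturated")
})

test_that("K2P distance is never below the p-distance", {
  set.seed(11)
  for (i in 1:20) {
    a <- sample(c("A", "C", "G", "T"), 150, replace = TRUE)
    b <- a
    idx <- sample(150, sample(1:25, 1))
    b[idx] <- vapply(b[idx], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
    res <- k2p_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    expect_gte(res$distance, res$p_transition + res$q_transversion - 1e-12)
  }
})

test_that("mean between-group K2P averages all cross pairs", {
  expect_identical(mean_between_group_k2p("ACGT", "ACGT"), 0)
  # identical-within groups degenerate to a single-pair distance
  g1 <- c("ACGTACGT", "ACGTACGT")
  g2 <- c("GCGTACGT", "GCGTACGT")
  expect_equal(mean_between_group_k2p(g1, g2),
               k2p_distance(g1[1], g2[1])$distance)
  expect_error(mean_between_group_k2p(character(0), g2), "non-empty")
})

test_that("ts/tv bias follows the K2P rate decomposition", {
  # pooled Pbar = 0.10, Qbar = 0.05 over one pair of 20 sites:
  # 2 transitions (A->G, C->T) + 1 transversion (T->A)
  x <- strsplit("AAAAACCCCCGGGGGTTTTT", "")[[1]]
  y <- x
  y[1] <- "G"; y[6] <- "T"; y[16] <- "A"
  rec <- c(s1 = paste(x, collapse = ""), s2 = paste(y, collapse = ""))
  res <- estimate_ts_tv_bias(rec)
  expect_equal(res$p_mean, 0.10)
  expect_equal(res$q_mean, 0.05)
  A <- 0.5 * log(1 / 0.75) - 0.25 * log(1 / 0.9)
  B <- 0.5 * log(1 / 0.9)
  expect_equal(res$r_bias, A / B, tolerance = 1e-12)
  expect_equal(res$r_bias, 2.230454, tolerance = 1e-6)

  # small-distance limit: R -> Pbar/Qbar
  x2 <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
  y2 <- x2
  y2[1] <- switch(x2[1], A = "G", G = "A", C = "T", T = "C")       # 1 ts
  y2[2] <- switch(x2[2], A = "C", G = "C", C = "A", T = "A")       # 1 tv
  lim <- estimate_ts_tv_bias(c(a = paste(x2, collapse = ""),
                               b = paste(y2, collapse = "")))
  expect_equal(lim$r_bias, lim$p_mean / lim$q_mean, tolerance = 0.01)

  expect_warning(r0 <- estimate_ts_tv_bias(c(a = "ACGT", b = "GCGT")),
                 "infinite")
  expect_identical(r0$r_bias, Inf)
})

test_that("expansion dating follows tau = 2*T*mu and is linear in tau", {
  cal <- dating_calibration(0.061, 1.8e6, 384, 1)
  d <- date_expansion(0.09267, cal)
  expect_equal(d$t_years, 0.09267 / (2 * 0.061 / (2 * 1.8e6) * 384),
               tolerance = 1e-12)
  expect_identical(date_expansion(0, cal)$t_years, 0)

  # forced by T = tau/(2 mu): mu = 1e-5 per fragment per year -> 10,000 y
  cal2 <- dating_calibration(1e-5 * 2 * 1e6 / 500, 1e6, 500, 1)
  expect_equal(date_expansion(0.2, cal2)$t_years, 10000, tolerance = 1e-9)

  # linearity: doubling tau doubles T exactly; CI transforms identically
  d1 <- date_expansion(0.4, cal, tau_ci = c(0.1, 0.9))
  d2 <- date_expansion(0.8, cal)
  expect_equal(d2$t_years, 2 * d1$t_years, tolerance = 1e-12)
  expect_equal(d1$t_ci, c(0.1, 0.9) / (2 * d1$mu_per_fragment),
               tolerance = 1e-12)

  expect_error(dating_calibration(0, 1, 1, 1), "positive")
})
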