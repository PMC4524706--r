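# Shared fixtures and small oracles, built in code at test time.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# mean absolute Q error against truth, minimised over column permutations
q_error_vs_truth <- function(q, truth) {
  K <- ncol(q)
  perms <- lineagemix:::permutations_of(K)
  min(vapply(perms, function(p) mean(abs(q[, p, drop = FALSE] - truth)),
             numeric(1)))
}

# brute-force minimal Steiner-MST weight for a small haplotype set:
# candidate intermediate nodes are all combinations of observed states at
# variable sites; up to `max_extra` of them may be added.
brute_force_steiner_weight <- function(seqs, max_extra = 2L) {
  m <- do.call(rbind, strsplit(seqs, ""))
  var_sites <- which(apply(m, 2L, function(col) length(unique(col)) > 1L))
  choices <- lapply(seq_len(ncol(m)), function(s) unique(m[, s]))
  grid <- do.call(expand.grid, c(choices, stringsAsFactors = FALSE))
  cands <- apply(grid, 1L, paste, collapse = "")
  cands <- setdiff(unique(cands), seqs)
  mstw <- function(ss) {
    mm <- do.call(rbind, strsplit(ss, ""))
    lineagemix:::mst_weight(lineagemix:::hamming_matrix(mm))
  }
  best <- mstw(seqs)
  for (extra in seq_len(max_extra)) {
    if (length(cands) < extra) break
    combs <- utils::combn(length(cands), extra)
    for (cidx in seq_len(ncol(combs))) {
      w <- mstw(c(seqs, cands[combs[, cidx]]))
      if (w < best) best <- w
    }
  }
  best
}

# exact two-allele HWE test by enumeration over heterozygote counts
hwe_exact_two_allele <- function(n11, n12, n22) {
  n <- n11 + n12 + n22
  n1 <- 2L * n11 + n12
  lprob <- function(h) {
    d1 <- (n1 - h) / 2
    d2 <- (2 * n - n1 - h) / 2
    lfactorial(n) - lfactorial(d1) - lfactorial(h) - lfactorial(d2) +
      h * log(2) + lfactorial(n1) + lfactorial(2 * n - n1) - lfactorial(2 * n)
  }
  hs <- seq(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
  lp <- vapply(hs, lprob, numeric(1))
  p <- exp(lp)
  sum(p[lp <= lprob(n12) + 1e-9]) / sum(p)
}

# simulate one panmictic-locus genotype table under HWE
simulate_hwe_locus <- function(n_ind, p_freq, seed) {
  set.seed(seed)
  k <- length(p_freq)
  copies <- sample.int(k, 2L * n_ind, replace = TRUE, prob = p_freq)
  a1 <- as.integer(100L + 2L * copies[seq_len(n_ind)])
  a2 <- as.integer(100L + 2L * copies[n_ind + seq_len(n_ind)])
  genotype_table(sprintf("i%03d", seq_len(n_ind)), "L1",
                 matrix(a1), matrix(a2))
}
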