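## Synthetic-data generators emulating the statistical structure the
## analysis assumes: two divergent mitochondrial haplogroups with star-like
## within-group genealogies, Balding-Nichols microsatellite genotypes with
## admixture, and moment-matched membership coefficients.

#' Simulate mitochondrial barcode sequences from two divergent lineages
#'
#' Two founder sequences differ at `divergence_mutations` uniformly chosen
#' sites; each sampled sequence is its lineage founder plus a
#' Poisson(tau/2) number of private mutations at uniform sites (star
#' genealogy, so the expected within-lineage pairwise difference equals
#' tau), each mutation a transition with odds `ts_tv_bias`:1. Defaults are
#' the conditions of the motivating study: 55 + 29 bats, a 384-bp COI
#' fragment, ~20 fixed differences between lineages, R = 5.46, and the
#' fitted per-lineage expansion parameters.
#'
#' @param n_per_lineage Named or unnamed integer vector of sample sizes.
#' @param fragment_length Fragment length L (bases).
#' @param divergence_mutations Fixed differences D between founders (<= L).
#' @param tau_per_lineage Expansion parameter tau per lineage (recycled).
#' @param ts_tv_bias Transition/transversion bias R.
#' @param seed Integer RNG seed.
#' @return List with `records` (named sequence vector), `metadata`
#'   (sample_id, mito_lineage), and `truth` (founders, per-sample mutation
#'   counts, spec).
#' @export
simulate_mtdna <- function(n_per_lineage = c(Western = 55, Eastern = 29),
                           fragment_length = 384L,
                           divergence_mutations = 20L,
                           tau_per_lineage = c(0.09267, 0.14595),
                           ts_tv_bias = 5.46, seed = 0L) {
  L <- as.integer(fragment_length)
  D <- as.integer(divergence_mutations)
  if (D > L) stop("divergence_mutations must not exceed fragment_length")
  if (any(tau_per_lineage < 0)) stop("tau must be non-negative")
  n_lin <- length(n_per_lineage)
  tau <- rep_len(tau_per_lineage, n_lin)
  lin_names <- names(n_per_lineage)
  if (is.null(lin_names)) lin_names <- paste0("lineage", seq_len(n_lin))
  set.seed(seed)
  founder1 <- sample(ACGT, L, replace = TRUE)
  founders <- list(founder1)
  if (n_lin > 1L) {
    div_sites <- sample.int(L, D)
    f2 <- founder1
    for (s in div_sites) f2[s] <- mutate_base(f2[s], ts_tv_bias)
    founders <- c(founders, rep(list(f2), n_lin - 1L))
  }
  records <- character(0)
  lineage <- character(0)
  mut_counts <- integer(0)
  for (g in seq_len(n_lin)) {
    n <- n_per_lineage[g]
    prefix <- paste0(substr(lin_names[g], 1L, 1L), g, "_")
    nmut <- stats::rpois(n, tau[g] / 2)
    for (i in seq_len(n)) {
      s <- founders[[g]]
      if (nmut[i] > 0L) {
        for (site in sample.int(L, nmut[i], replace = TRUE)) {
          s[site] <- mutate_base(s[site], ts_tv_bias)
        }
      }
      records <- c(records, paste(s, collapse = ""))
      names(records)[length(records)] <- sprintf("%s%03d", prefix, i)
      lineage <- c(lineage, lin_names[g])
      mut_counts <- c(mut_counts, nmut[i])
    }
  }
  list(
    records = records,
    metadata = data.frame(sample_id = names(records), mito_lineage = lineage,
                          stringsAsFactors = FALSE),
    truth = list(founders = vapply(founders, paste, character(1), collapse = ""),
                 mutation_counts = stats::setNames(mut_counts, names(records)),
                 tau = tau, divergence_mutations = D,
                 ts_tv_bias = ts_tv_bias, seed = seed)
  )
}

#' Simulate multilocus microsatellite genotypes (Balding-Nichols admixture)
#'
#' Ancestral allele frequencies per locus are symmetric-Dirichlet draws;
#' population k frequencies are Dirichlet(p_anc (1-F_k)/F_k), so F_k is the
#' expected differentiation (F_ST) of population k from the ancestral pool.
#' Individual admixture proportions are Dirichlet(alpha), or one-hot
#' population membership when `admixture_alpha = 0`; each allele copy picks
#' an origin population from q and then an allele from that population's
#' frequencies. Allele labels are arbitrary fragment sizes (all downstream
#' statistics are label-invariant).
#'
#' @param k_pops Number of subpopulations K.
#' @param n_per_pop Samples per population (recycled to length K).
#' @param n_loci Number of loci (default 5, the study's panel size).
#' @param alleles_per_locus Ancestral alleles per locus (default 10).
#' @param drift_f Drift parameter F per population in (0,1) (recycled).
#' @param admixture_alpha Dirichlet admixture parameter; 0 = pure ancestry.
#' @param seed Integer RNG seed.
#' @return List with `genotypes` (a [genotype_table()]), and `truth`
#'   (q matrix, population frequencies, ancestral frequencies, populations).
#' @export
simulate_msat <- function(k_pops = 2L, n_per_pop = 50L, n_loci = 5L,
                          alleles_per_locus = 10L, drift_f = 0.2,
                          admixture_alpha = 0, seed = 0L) {
  K <- as.integer(k_pops)
  npp <- rep_len(as.integer(n_per_pop), K)
  Fd <- rep_len(drift_f, K)
  if (any(Fd <= 0 | Fd >= 1)) stop("drift_f must lie strictly in (0, 1)")
  if (alleles_per_locus < 2L) stop("need at least two alleles per locus")
  set.seed(seed)
  n <- sum(npp)
  pop <- rep(seq_len(K), npp)
  J <- as.integer(alleles_per_locus)
  # allele labels: plausible fragment sizes, distinct per locus
  labels <- lapply(seq_len(n_loci), function(j) 100L + 2L * (seq_len(J) - 1L))
  p_anc <- lapply(seq_len(n_loci), function(j) rdirichlet1(rep(1, J)))
  p_pop <- lapply(seq_len(n_loci), function(j) {
    t(vapply(seq_len(K),
             function(k) rdirichlet1(p_anc[[j]] * (1 - Fd[k]) / Fd[k]),
             numeric(J)))
  })
  qmat <- if (admixture_alpha == 0) {
    m <- matrix(0, n, K); m[cbind(seq_len(n), pop)] <- 1; m
  } else {
    t(vapply(seq_len(n), function(i) rdirichlet1(rep(admixture_alpha, K)),
             numeric(K)))
  }
  a1 <- a2 <- matrix(NA_integer_, n, n_loci)
  for (j in seq_len(n_loci)) {
    for (copy in 1:2) {
      origin <- vapply(seq_len(n), function(i) {
        sample.int(K, 1L, prob = qmat[i, ])
      }, integer(1))
      allele <- vapply(seq_len(n), function(i) {
        sample.int(J, 1L, prob = p_pop[[j]][origin[i], ])
      }, integer(1))
      if (copy == 1L) a1[, j] <- labels[[j]][allele] else a2[, j] <- labels[[j]][allele]
    }
  }
  ids <- sprintf("P%d_%03d", pop, stats::ave(pop, pop, FUN = seq_along))
  gt <- genotype_table(ids, paste0("L", seq_len(n_loci)), a1, a2)
  list(genotypes = gt,
       truth = list(q = qmat, p_pop = p_pop, p_anc = p_anc,
                    population = pop, drift_f = Fd, seed = seed))
}

#' Simulate membership coefficients for two groups (moment-matched Beta)
#'
#' Each group is drawn from a Beta distribution whose parameters are solved
#' from the requested (mean, SD) by moment matching; the defaults are the
#' printed group moments of the motivating study (0.60 +/- 0.34, n = 60
#' versus 0.28 +/- 0.23, n = 38).
#'
#' @param n Group sizes (length 2).
#' @param means Target means in (0,1) (length 2).
#' @param sds Target SDs; must satisfy SD^2 < mean(1-mean).
#' @param seed Integer RNG seed.
#' @return List with `values` (numeric vector), `labels` (group factor),
#'   and `shapes` (Beta parameters per group).
#' @export
simulate_q_values <- function(n = c(60L, 38L), means = c(0.60, 0.28),
                              sds = c(0.34, 0.23), seed = 0L) {
  if (length(n) != 2L || length(means) != 2L || length(sds) != 2L) {
    stop("n, means and sds must each have length 2")
  }
  if (any(means <= 0 | means >= 1)) stop("means must lie strictly in (0, 1)")
  shapes <- vector("list", 2L)
  for (g in 1:2) {
    v <- sds[g]^2
    bound <- means[g] * (1 - means[g])
    if (v >= bound) {
      stop("group ", g, ": SD^2 (", signif(v, 4),
           ") must be < mean(1-mean) (", signif(bound, 4),
           ") for a Beta distribution")
    }
    nu <- bound / v - 1
    shapes[[g]] <- c(shape1 = means[g] * nu, shape2 = (1 - means[g]) * nu)
  }
  set.seed(seed)
  vals <- c(stats::rbeta(n[1L], shapes[[1L]][1L], shapes[[1L]][2L]),
            stats::rbeta(n[2L], shapes[[2L]][1L], shapes[[2L]][2L]))
  labels <- factor(rep(c("group1", "group2"), n), levels = c("group1", "group2"))
  list(values = vals, labels = labels, shapes = shapes)
}
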