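## Microsatellite summary statistics: diversity indices, rarefied allelic
## richness, Monte-Carlo exact HWE tests, Weir-Cockerham F-statistics and a
## heterozygote-deficit null-allele flag.

# internal: subset a genotype table by sample ids (NULL = all)
gt_subset <- function(gt, subset = NULL) {
  if (is.null(subset)) return(gt)
  idx <- match(subset, gt$sample_ids)
  if (anyNA(idx)) {
    stop("unknown sample ids in subset: ",
         paste(subset[is.na(idx)], collapse = ", "))
  }
  structure(list(sample_ids = gt$sample_ids[idx],
                 locus_names = gt$locus_names,
                 a1 = gt$a1[idx, , drop = FALSE],
                 a2 = gt$a2[idx, , drop = FALSE]),
            class = "genotype_table")
}

# internal: rarefied allelic richness from allele copy counts
rarefied_richness <- function(copy_counts, g) {
  n_g <- sum(copy_counts)
  if (g > n_g) stop("rarefaction size exceeds available gene copies")
  sum(1 - exp(lchoose(n_g - copy_counts, g) - lchoose(n_g, g)))
}

#' Per-locus diversity indices
#'
#' For each locus among the chosen samples: number of alleles A, rarefied
#' allelic richness Rs (expected allele count in a random draw of `g` gene
#' copies), observed heterozygosity H_O, and unbiased gene diversity
#' H = n_g/(n_g-1) (1 - sum p_i^2). Monomorphic loci report H_O and H as
#' `NA` with `monomorphic = TRUE` (the dash cells of classical diversity
#' tables); column means and SDs (attributes `"mean"`, `"sd"`) exclude them.
#'
#' @param gt A [genotype_table()].
#' @param subset Optional sample ids to restrict to.
#' @param rarefaction_size Gene copies `g` to rarefy to; default
#'   2 x the smallest per-locus typed sample size in the subset.
#' @return Data frame (one row per locus) with columns locus, n, A, Rs,
#'   h_obs, gene_div, monomorphic; attributes `mean` and `sd` hold
#'   column summaries over informative loci.
#' @export
diversity_table <- function(gt, subset = NULL, rarefaction_size = NULL) {
  if (!is.null(subset) && length(subset) == 0L) stop("empty subset")
  gt <- gt_subset(gt, subset)
  typed_per_locus <- colSums(!is.na(gt$a1))
  if (any(typed_per_locus == 0L)) {
    stop("locus with no typed individuals in subset: ",
         paste(gt$locus_names[typed_per_locus == 0L], collapse = ", "))
  }
  if (is.null(rarefaction_size)) rarefaction_size <- 2L * min(typed_per_locus)
  if (rarefaction_size > 2L * min(typed_per_locus)) {
    stop("rarefaction_size exceeds 2 x smallest typed sample across loci")
  }
  rows <- lapply(seq_along(gt$locus_names), function(j) {
    a1 <- gt$a1[, j]; a2 <- gt$a2[, j]
    typed <- !is.na(a1)
    copies <- c(a1[typed], a2[typed])
    cnt <- table(copies)
    n_g <- length(copies)
    p <- as.numeric(cnt) / n_g
    A <- length(cnt)
    mono <- A == 1L
    data.frame(
      locus = gt$locus_names[j],
      n = sum(typed),
      A = A,
      Rs = rarefied_richness(as.numeric(cnt), rarefaction_size),
      h_obs = if (mono) NA_real_ else mean(a1[typed] != a2[typed]),
      gene_div = if (mono) NA_real_ else n_g / (n_g - 1) * (1 - sum(p^2)),
      monomorphic = mono,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  num <- c("n", "A", "Rs", "h_obs", "gene_div")
  attr(out, "mean") <- vapply(out[num], mean, numeric(1), na.rm = TRUE)
  attr(out, "sd") <- vapply(out[num], stats::sd, numeric(1), na.rm = TRUE)
  attr(out, "rarefaction_size") <- rarefaction_size
  out
}

# internal: log conditional probability of a genotype table given allele
# counts (Levene/Guo-Thompson); constant terms in the allele counts omitted
# since they cancel in comparisons. Alleles must be coded 1..k; lgam is a
# precomputed lgamma(1:(n+1)) lookup.
log_table_prob <- function(g1, g2, k, lgam) {
  het <- sum(g1 != g2)
  code <- (pmin(g1, g2) - 1L) * k + pmax(g1, g2)
  tab <- tabulate(code, nbins = k * k)
  het * log(2) - sum(lgam[tab + 1L])
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Guo-Thompson style: gene copies at the locus are repeatedly shuffled into
#' diploid genotypes; the p-value is the proportion of shuffles whose
#' conditional table probability is less than or equal to the observed one
#' (add-one corrected). Monomorphic loci return p = 1 by convention.
#'
#' @param gt A [genotype_table()].
#' @param locus Locus name.
#' @param subset Optional sample ids.
#' @param n_mc Number of Monte-Carlo shuffles.
#' @param seed Integer RNG seed.
#' @return List with `locus_name`, `p_value`, `n_permutations`, `n_typed`.
#' @export
hwe_exact_test <- function(gt, locus, subset = NULL, n_mc = 10000L, seed = 0L) {
  gt <- gt_subset(gt, subset)
  j <- match(locus, gt$locus_names)
  if (is.na(j)) stop("unknown locus: ", locus)
  a1 <- gt$a1[, j]; a2 <- gt$a2[, j]
  typed <- !is.na(a1)
  if (sum(typed) < 2L) stop("need at least two typed individuals")
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  if (length(alleles) == 1L) {
    return(list(locus_name = locus, p_value = 1, n_permutations = 0L,
                n_typed = sum(typed)))
  }
  g1 <- match(a1[typed], alleles)
  g2 <- match(a2[typed], alleles)
  k <- length(alleles)
  n <- length(g1)
  lgam <- lgamma(seq_len(n + 1L))
  lp_obs <- log_table_prob(g1, g2, k, lgam)
  copies <- c(g1, g2)
  set.seed(seed)
  hits <- 0L
  idx1 <- seq_len(n)
  idx2 <- n + idx1
  for (b in seq_len(n_mc)) {
    perm <- sample(copies)
    if (log_table_prob(perm[idx1], perm[idx2], k, lgam) <= lp_obs + 1e-9) {
      hits <- hits + 1L
    }
  }
  list(locus_name = locus, p_value = (1 + hits) / (n_mc + 1),
       n_permutations = n_mc, n_typed = n)
}

# internal: Weir-Cockerham variance components for one locus across r
# populations. Returns per-allele component sums (a, b, c).
wc_components <- function(a1, a2, pop) {
  pops <- unique(pop)
  r <- length(pops)
  typed <- !is.na(a1)
  ni <- vapply(pops, function(p) sum(typed & pop == p), numeric(1))
  if (any(ni < 1)) return(NULL)
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  nbar <- mean(ni)
  n_tot <- sum(ni)
  nc <- if (r > 1) (n_tot - sum(ni^2) / n_tot) / (r - 1) else nbar
  a_sum <- b_sum <- c_sum <- 0
  for (al in alleles) {
    pi <- vapply(pops, function(p) {
      w <- typed & pop == p
      sum((a1[w] == al) + (a2[w] == al)) / (2 * sum(w))
    }, numeric(1))
    hi <- vapply(pops, function(p) {
      w <- typed & pop == p
      mean(a1[w] != a2[w] & (a1[w] == al | a2[w] == al))
    }, numeric(1))
    pbar <- sum(ni * pi) / n_tot
    hbar <- sum(ni * hi) / n_tot
    s2 <- if (r > 1) sum(ni * (pi - pbar)^2) / ((r - 1) * nbar) else 0
    if (r > 1) {
      a_sum <- a_sum + nbar / nc *
        (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b_sum <- b_sum + nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    } else {
      b_sum <- b_sum + nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (2 * nbar - 1) / (4 * nbar) * hbar)
    }
    c_sum <- c_sum + hbar / 2
  }
  c(a = a_sum, b = b_sum, c = c_sum)
}

#' Weir-Cockerham F-statistics on supplied cluster labels
#'
#' Multi-allelic variance-components estimators, summed over alleles and
#' loci. Pairwise F_ST is computed cluster pair by cluster pair; F_IS per
#' cluster comes from the within-cluster components. Loci with no typed
#' individual in one member of a pair are skipped for that pair with a
#' warning.
#'
#' @param gt A [genotype_table()].
#' @param cluster_assignment Character vector of cluster labels, either
#'   named by sample id or aligned with `gt$sample_ids`.
#' @return Object of class `fstats_result`: list with `cluster_labels`,
#'   `pairwise_fst` (symmetric matrix, zero diagonal), `fis_per_cluster`.
#' @export
f_statistics <- function(gt, cluster_assignment) {
  if (!is.null(names(cluster_assignment))) {
    cluster_assignment <- cluster_assignment[gt$sample_ids]
  }
  if (length(cluster_assignment) != length(gt$sample_ids)) {
    stop("cluster_assignment must cover every sample")
  }
  pop <- as.character(cluster_assignment)
  clusters <- unique(pop)
  if (length(clusters) < 2L) stop("need at least two clusters for F_ST")
  for (cl in clusters) {
    if (sum(pop == cl & rowSums(!is.na(gt$a1)) > 0) < 2L) {
      stop("cluster '", cl, "' has fewer than two typed individuals")
    }
  }
  K <- length(clusters)
  fst <- matrix(0, K, K, dimnames = list(clusters, clusters))
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      sel <- pop %in% clusters[c(i, j)]
      acc <- c(a = 0, b = 0, c = 0)
      for (l in seq_along(gt$locus_names)) {
        a1 <- gt$a1[sel, l]; a2 <- gt$a2[sel, l]
        sub_pop <- pop[sel]
        ok <- vapply(clusters[c(i, j)],
                     function(p) any(!is.na(a1[sub_pop == p])), logical(1))
        if (!all(ok)) {
          warning("locus ", gt$locus_names[l],
                  " skipped for pair ", clusters[i], "/", clusters[j],
                  " (all calls missing in one cluster)")
          next
        }
        comp <- wc_components(a1, a2, sub_pop)
        if (!is.null(comp)) acc <- acc + comp
      }
      fst[i, j] <- fst[j, i] <- acc[["a"]] / sum(acc)
    }
  }
  fis <- vapply(clusters, function(cl) {
    acc <- c(b = 0, c = 0)
    for (l in seq_along(gt$locus_names)) {
      w <- pop == cl
      comp <- wc_components(gt$a1[w, l], gt$a2[w, l], rep(cl, sum(w)))
      if (!is.null(comp)) acc <- acc + comp[c("b", "c")]
    }
    1 - acc[["c"]] / sum(acc)
  }, numeric(1))
  structure(list(cluster_labels = clusters, pairwise_fst = fst,
                 fis_per_cluster = fis),
            class = "fstats_result")
}

#' Heterozygote-deficit null-allele screen
#'
#' Chakraborty-style estimator of the null-allele frequency at each locus,
#' r = (H_e - H_o) / (H_e + H_o), flagged when it exceeds `threshold`
#' (classically 5%). Monomorphic loci report `NA`.
#'
#' @param gt A [genotype_table()].
#' @param subset Optional sample ids.
#' @param threshold Flagging threshold (default 0.05).
#' @return Data frame with locus, h_obs, gene_div, null_freq, flagged.
#' @export
null_allele_check <- function(gt, subset = NULL, threshold = 0.05) {
  dt <- diversity_table(gt, subset)
  r <- (dt$gene_div - dt$h_obs) / (dt$gene_div + dt$h_obs)
  data.frame(locus = dt$locus, h_obs = dt$h_obs, gene_div = dt$gene_div,
             null_freq = r, flagged = !is.na(r) & r > threshold,
             stringsAsFactors = FALSE)
}
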