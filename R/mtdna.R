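## Mitochondrial-sequence computations: haplotypes, lineage assignment,
## K2P distances, ts/tv bias, mismatch distributions, expansion fit & dating.

# internal: character matrix (samples x sites) from a named sequence vector
seq_matrix <- function(records, require_equal = TRUE) {
  if (length(records) == 0L) return(matrix(character(0), 0, 0))
  lens <- nchar(records)
  if (require_equal && length(unique(lens)) != 1L) {
    stop("sequences must be aligned to equal length; got lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  m <- do.call(rbind, strsplit(toupper(records), ""))
  rownames(m) <- names(records)
  m
}

ACGT <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

# internal: site-level comparison of two character vectors under pairwise
# deletion: sites with non-ACGT in either member are excluded
pair_sites <- function(x, y) {
  ok <- x %in% ACGT & y %in% ACGT
  list(x = x[ok], y = y[ok], n = sum(ok))
}

#' Collapse aligned sequences to unique haplotypes
#'
#' Identical sequences are merged; the result records each haplotype's
#' multiplicity and member sample ids, ordered by decreasing count with ties
#' broken by first occurrence in the input.
#'
#' @param records Named character vector of equal-length aligned sequences.
#' @return An object of class `haplotype_set`: list with `haplotypes` (named
#'   `H1`, `H2`, ...), `counts`, and `members` (list of sample-id vectors).
#' @examples
#' collapse_haplotypes(c(a = "ACGT", b = "ACGT", c = "ACGA"))
#' @export
collapse_haplotypes <- function(records) {
  if (length(records) == 0L) {
    return(structure(list(haplotypes = character(0), counts = integer(0),
                          members = list()), class = "haplotype_set"))
  }
  seq_matrix(records)  # validates equal lengths
  seqs <- toupper(records)
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  counts <- as.integer(table(factor(seqs, levels = uniq)))
  ord <- order(-counts, seq_along(uniq))
  uniq <- uniq[ord]
  counts <- counts[ord]
  members <- lapply(uniq, function(s) names(seqs)[seqs == s])
  names(uniq) <- paste0("H", seq_along(uniq))
  structure(list(haplotypes = uniq, counts = counts, members = members),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("haplotype_set:", length(x$haplotypes), "haplotypes from",
      sum(x$counts), "sequences\n")
  invisible(x)
}

#' Expand a haplotype set back to per-sample sequences
#' @param haps A `haplotype_set`.
#' @return Named character vector, one entry per original sample.
#' @export
expand_haplotypes <- function(haps) {
  ids <- unlist(haps$members, use.names = FALSE)
  seqs <- rep(unname(haps$haplotypes), haps$counts)
  stats::setNames(seqs, ids)
}

#' Count nucleotide differences between two aligned sequences
#'
#' Pairwise deletion: sites with `N`, gaps or other ambiguity codes in either
#' sequence are excluded from the comparison.
#'
#' @param seq_a,seq_b Equal-length DNA strings.
#' @return Integer number of differing compared sites.
#' @export
count_differences <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be of equal length")
  x <- strsplit(toupper(seq_a), "")[[1L]]
  y <- strsplit(toupper(seq_b), "")[[1L]]
  p <- pair_sites(x, y)
  sum(p$x != p$y)
}

#' Define lineage reference sequences
#'
#' @param lineage_name Character vector of lineage labels (e.g. Western,
#'   Eastern).
#' @param reference_sequence DNA strings, one per lineage, all of the
#'   analysis fragment length.
#' @param max_distance Assignment radius in mutations (default 2, matching
#'   barcode assignment by near-identity to reference specimens).
#' @return Data frame of class `lineage_references`.
#' @export
lineage_references <- function(lineage_name, reference_sequence,
                               max_distance = 2L) {
  if (length(lineage_name) != length(reference_sequence)) {
    stop("one reference sequence per lineage name required")
  }
  if (length(unique(nchar(reference_sequence))) > 1L) {
    stop("reference sequences must all have the analysis fragment length")
  }
  structure(data.frame(lineage_name = as.character(lineage_name),
                       reference_sequence = toupper(reference_sequence),
                       max_distance = as.integer(max_distance),
                       stringsAsFactors = FALSE),
            class = c("lineage_references", "data.frame"))
}

#' Assign a sequence to the nearest reference lineage
#'
#' The label of the nearest reference (by nucleotide-difference count under
#' pairwise deletion) is returned when the distance is within that
#' reference's `max_distance`; otherwise `"unassigned"`. An exact tie
#' between references yields `"ambiguous"`.
#'
#' @param record A single DNA string (length must equal reference length).
#' @param refs A [lineage_references()] table.
#' @return List with `lineage` and `distance`.
#' @export
assign_lineage <- function(record, refs) {
  if (nrow(refs) < 1L) stop("at least one reference required")
  if (nchar(record) != nchar(refs$reference_sequence[1L])) {
    stop("record length (", nchar(record), ") differs from reference length (",
         nchar(refs$reference_sequence[1L]), ")")
  }
  d <- vapply(refs$reference_sequence,
              function(r) count_differences(record, r), integer(1))
  i <- which(d == min(d))
  if (length(i) > 1L) {
    return(list(lineage = "ambiguous", distance = min(d)))
  }
  if (d[i] > refs$max_distance[i]) {
    return(list(lineage = "unassigned", distance = unname(d[i])))
  }
  list(lineage = refs$lineage_name[i], distance = unname(d[i]))
}

#' Assign many sequences to lineages
#' @param records Named character vector of sequences.
#' @param refs A [lineage_references()] table.
#' @return Data frame with sample_id, lineage, distance.
#' @export
assign_lineages <- function(records, refs) {
  res <- lapply(records, assign_lineage, refs = refs)
  data.frame(sample_id = names(records),
             lineage = vapply(res, `[[`, character(1), "lineage"),
             distance = vapply(res, `[[`, numeric(1), "distance"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Kimura two-parameter distance between two sequences
#'
#' Computes the transition fraction P, the transversion fraction Q and the
#' K2P distance d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q) over compared sites
#' (pairwise deletion of sites with N/gaps in either member).
#'
#' @param seq_a,seq_b Equal-length DNA strings.
#' @return List with `p_transition`, `q_transversion`, `distance`, `n_sites`.
#' @examples
#' k2p_distance("ACGT", "GCGT")$distance  # one transition, d = -ln(0.5)/2
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences must be of equal length")
  x <- strsplit(toupper(seq_a), "")[[1L]]
  y <- strsplit(toupper(seq_b), "")[[1L]]
  p <- pair_sites(x, y)
  if (p$n == 0L) stop("no comparable sites between the two sequences")
  diff <- p$x != p$y
  ts <- diff & ((p$x %in% PURINES) == (p$y %in% PURINES))
  P <- sum(ts) / p$n
  Q <- sum(diff & !ts) / p$n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("K2P distance saturated (1-2P-Q or 1-2Q non-positive)")
  }
  list(p_transition = P, q_transversion = Q,
       distance = -0.5 * log(w1) - 0.25 * log(w2), n_sites = p$n)
}

#' Mean between-group K2P distance
#'
#' Arithmetic mean of [k2p_distance()] over all cross-group sequence pairs;
#' used e.g. as the calibration distance between two mitochondrial lineages.
#'
#' @param group_a,group_b Character vectors of aligned sequences.
#' @return Mean distance (substitutions/site).
#' @export
mean_between_group_k2p <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  d <- outer(seq_along(group_a), seq_along(group_b),
             Vectorize(function(i, j) k2p_distance(group_a[[i]], group_b[[j]])$distance))
  mean(d)
}

#' Estimate the transition/transversion bias R
#'
#' Pools transition and transversion fractions over all sequence pairs
#' (pairwise deletion), then decomposes the K2P distance into its
#' transitional component A = 1/2 ln(1/(1-2P-Q)) - 1/4 ln(1/(1-2Q)) and
#' transversional component B = 1/2 ln(1/(1-2Q)); R = A/B. This matches the
#' rate-bias convention R = alpha/(2 beta) of the K2P model. If no
#' transversions are observed R is infinite (with a warning).
#'
#' @param records Named character vector of >= 2 aligned sequences.
#' @return List with `r_bias`, pooled `p_mean`, `q_mean`.
#' @export
estimate_ts_tv_bias <- function(records) {
  if (length(records) < 2L) stop("need at least two sequences")
  m <- seq_matrix(records)
  n <- nrow(m)
  ts_tot <- 0; tv_tot <- 0; sites_tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- pair_sites(m[i, ], m[j, ])
      diff <- p$x != p$y
      ts <- diff & ((p$x %in% PURINES) == (p$y %in% PURINES))
      ts_tot <- ts_tot + sum(ts)
      tv_tot <- tv_tot + sum(diff & !ts)
      sites_tot <- sites_tot + p$n
    }
  }
  P <- ts_tot / sites_tot
  Q <- tv_tot / sites_tot
  if (Q == 0) {
    warning("no transversions observed; R reported as infinite")
    return(list(r_bias = Inf, p_mean = P, q_mean = Q))
  }
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) stop("pooled P/Q saturated; R not estimable")
  A <- 0.5 * log(1 / w1) - 0.25 * log(1 / w2)
  B <- 0.5 * log(1 / w2)
  list(r_bias = A / B, p_mean = P, q_mean = Q)
}

#' Mismatch distribution of a set of aligned sequences
#'
#' Histogram of pairwise nucleotide-difference counts over all unordered
#' pairs; the substrate of demographic-expansion analysis.
#'
#' @param records Named character vector of >= 2 aligned sequences.
#' @return Object of class `mismatch_distribution`: list with `counts`
#'   (named by difference value `0..J`) and `n_pairs`.
#' @export
mismatch_distribution <- function(records) {
  if (length(records) < 2L) stop("need at least two sequences")
  m <- seq_matrix(records)
  n <- nrow(m)
  ok <- matrix(m %in% ACGT, nrow = n)
  diffs <- integer(n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      cmp <- ok[i, ] & ok[j, ]
      diffs[k] <- sum(m[i, cmp] != m[j, cmp])
    }
  }
  jmax <- max(diffs)
  counts <- tabulate(diffs + 1L, nbins = jmax + 1L)
  names(counts) <- 0:jmax
  structure(list(counts = counts, n_pairs = length(diffs)),
            class = "mismatch_distribution")
}

#' Expected mismatch distribution under a sudden expansion
#'
#' Rogers-Harpending family: a population at mutation-scaled size theta0
#' grows instantaneously to theta1 at mutational time tau before present.
#' With theta0 -> 0 and theta1 -> Inf the expectation approaches
#' Poisson(tau).
#'
#' @param j_max Largest difference count to evaluate.
#' @param tau Mutational time since expansion (>= 0).
#' @param theta0,theta1 Pre-/post-expansion scaled sizes.
#' @return Numeric vector of expected relative frequencies for j = 0..j_max.
#' @export
expected_mismatch <- function(j_max, tau, theta0, theta1) {
  j <- 0:j_max
  feq <- function(th) if (th <= 0) c(1, rep(0, j_max)) else th^j / (1 + th)^(j + 1)
  f1 <- feq(theta1)
  f0 <- feq(theta0)
  theta1 <- max(theta1, 1e-9)
  lpois <- j * log(max(tau, 1e-300)) - lgamma(j + 1)
  damp <- exp(-tau * (theta1 + 1) / theta1)
  conv <- vapply(j, function(jj) {
    i <- 0:jj
    sum(exp(lpois[i + 1L]) * (f0[jj - i + 1L] - f1[jj - i + 1L]))
  }, numeric(1))
  if (tau <= 0) return(f0)
  pmax(f1 + damp * conv, 0)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of the Rogers-Harpending expectation to the observed
#' relative frequencies, by coarse grid search over (tau, theta0, theta1)
#' followed by bounded quasi-Newton refinement; ties in SSD are broken
#' towards the smallest tau.
#'
#' @param mm A [mismatch_distribution()] (counts may be non-integer when a
#'   theoretical curve is fitted).
#' @return Object of class `expansion_fit`: list with `tau`, `theta0`,
#'   `theta1`, `ssd_obs`, and placeholders `p_value`, `tau_ci` completed by
#'   [bootstrap_expansion_test()].
#' @export
fit_expansion <- function(mm) {
  if (mm$n_pairs < 1) stop("need at least one sequence pair")
  f_obs <- mm$counts / sum(mm$counts)
  jmax <- length(f_obs) - 1L
  ssd <- function(par) {
    sum((f_obs - expected_mismatch(jmax, par[1L], par[2L], par[3L]))^2)
  }
  mean_j <- sum((0:jmax) * f_obs)
  tau_hi <- max(4, 2 * (jmax + 1))
  grid <- expand.grid(tau = unique(c(0, mean_j, seq(0, tau_hi, length.out = 21))),
                      theta0 = c(0, 0.5, 2),
                      theta1 = c(1, 10, 1000))
  grid_ssd <- apply(grid, 1L, ssd)
  starts <- grid[order(grid_ssd)[1:4], , drop = FALSE]
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- stats::nlminb(as.numeric(starts[s, ]), ssd,
                         lower = c(0, 0, 1e-3),
                         upper = c(4 * tau_hi, 100, 1e5))
    cand <- list(par = fit$par, ssd = fit$objective)
    if (is.null(best) || cand$ssd < best$ssd - 1e-12 ||
        (abs(cand$ssd - best$ssd) <= 1e-12 && cand$par[1L] < best$par[1L])) {
      best <- cand
    }
  }
  structure(list(tau = best$par[1L], theta0 = best$par[2L],
                 theta1 = best$par[3L], ssd_obs = best$ssd,
                 n_pairs = mm$n_pairs, j_max = jmax,
                 p_value = NA_real_, tau_ci = c(NA_real_, NA_real_)),
            class = "expansion_fit")
}

# internal: star-genealogy sample of n sequences, expansion parameter tau,
# ts:tv odds r_bias : 1 per mutation event
simulate_star_lineage <- function(n, L, tau, r_bias, founder = NULL,
                                  prefix = "s") {
  if (is.null(founder)) founder <- sample(ACGT, L, replace = TRUE)
  out <- matrix(rep(founder, n), nrow = n, byrow = TRUE)
  nmut <- stats::rpois(n, tau / 2)
  for (i in seq_len(n)) {
    if (nmut[i] == 0L) next
    sites <- sample.int(L, nmut[i], replace = TRUE)
    for (s in sites) out[i, s] <- mutate_base(out[i, s], r_bias)
  }
  stats::setNames(apply(out, 1L, paste, collapse = ""),
                  sprintf("%s%03d", prefix, seq_len(n)))
}

# internal: single substitution with transition odds r_bias : 1
mutate_base <- function(base, r_bias) {
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  if (stats::runif(1) < r_bias / (r_bias + 1)) {
    ts_map[[base]]
  } else {
    sample(setdiff(ACGT, c(base, ts_map[[base]])), 1L)
  }
}

#' Parametric-bootstrap goodness-of-fit test for the expansion model
#'
#' Simulates `n_iter` datasets of the same sample size and fragment length
#' under the fitted expansion (star genealogy with per-tip Poisson(tau/2)
#' private mutations and transition:transversion odds `r_bias`:1), refits
#' each, and completes the fit with `p_value` = P(SSD_sim >= SSD_obs) and a
#' 2.5/97.5 percentile interval for the refitted tau.
#'
#' @param records The observed aligned sequences.
#' @param fit An [fit_expansion()] result for those sequences.
#' @param n_iter Number of bootstrap iterations (default 10000; < 100 warns).
#' @param seed Integer RNG seed.
#' @param r_bias Transition/transversion bias used by the simulator.
#' @return The completed `expansion_fit`.
#' @export
bootstrap_expansion_test <- function(records, fit, n_iter = 10000L, seed = 0L,
                                     r_bias = 5.46) {
  if (n_iter < 100L) warning("n_iter < 100: bootstrap p-value will be unstable")
  n <- length(records)
  L <- nchar(records[[1L]])
  set.seed(seed)
  ssd_sim <- numeric(n_iter)
  tau_sim <- numeric(n_iter)
  for (b in seq_len(n_iter)) {
    sim <- simulate_star_lineage(n, L, fit$tau, r_bias)
    refit <- fit_expansion(mismatch_distribution(sim))
    ssd_sim[b] <- refit$ssd_obs
    tau_sim[b] <- refit$tau
  }
  fit$p_value <- mean(ssd_sim >= fit$ssd_obs - 1e-15)
  fit$tau_ci <- unname(stats::quantile(tau_sim, c(0.025, 0.975)))
  fit
}

#' Calibration for expansion dating
#'
#' Converts a between-lineage K2P distance and an external divergence time
#' into a per-fragment per-generation mutation rate.
#'
#' @param distance Between-lineage K2P distance (substitutions/site).
#' @param divergence_years Calibration divergence time in years.
#' @param fragment_length Analysed fragment length L in bases.
#' @param generation_years Generation time in years (default 1).
#' @return Object of class `dating_calibration`.
#' @export
dating_calibration <- function(distance, divergence_years, fragment_length,
                               generation_years = 1) {
  vals <- c(distance, divergence_years, fragment_length, generation_years)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all calibration quantities must be strictly positive")
  }
  structure(list(distance = distance, divergence_years = divergence_years,
                 fragment_length = fragment_length,
                 generation_years = generation_years),
            class = "dating_calibration")
}

#' Date an expansion from tau via tau = 2*T*mu
#'
#' The per-site per-year rate is distance/(2 * divergence_years); scaled by
#' fragment length and generation time it gives mu, the mutation rate per
#' fragment per generation. T = tau/(2 mu) generations, reported in years.
#' Confidence bounds for tau transform identically.
#'
#' @param tau Expansion parameter (mutational time units).
#' @param cal A [dating_calibration()].
#' @param tau_ci Optional length-2 interval for tau.
#' @return List with `mu_per_fragment`, `t_years`, `t_ci`.
#' @examples
#' cal <- dating_calibration(0.061, 1.8e6, 384, 1)
#' date_expansion(0.09267, cal)$t_years  # ~7.1 kyr
#' @export
date_expansion <- function(tau, cal, tau_ci = NULL) {
  if (tau < 0) stop("tau must be non-negative")
  mu <- cal$distance / (2 * cal$divergence_years) * cal$fragment_length *
    cal$generation_years
  if (mu <= 0) stop("calibration yields zero mutation rate")
  to_years <- function(tv) tv / (2 * mu) * cal$generation_years
  list(mu_per_fragment = mu,
       t_years = to_years(tau),
       t_ci = if (is.null(tau_ci)) c(NA_real_, NA_real_) else to_years(tau_ci))
}
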