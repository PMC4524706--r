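## Bayesian admixture clustering of multilocus diploid genotypes
## (Structure-style Gibbs sampler), Evanno's delta-K model selection,
## label-switching alignment across runs, and the delta-Qbar permutation
## test on group mean membership coefficients.

#' Configuration for one admixture MCMC run
#'
#' Defaults mirror a classical Structure analysis of microsatellites: the
#' admixture model with the correlated allele-frequency (F-)model,
#' lambda = 1, 110,000 sweeps with 10% burn-in.
#'
#' @param k_clusters Number of clusters K (>= 1).
#' @param lambda Dirichlet prior parameter for allele frequencies.
#' @param alpha_init Initial admixture Dirichlet parameter alpha (updated by
#'   Metropolis with a Uniform(0, `alpha_max`) prior).
#' @param freq_model `"correlated"` (default) or `"independent"`.
#' @param n_iterations Total MCMC sweeps.
#' @param burn_in_fraction Fraction of sweeps discarded (in (0,1)).
#' @param seed Integer RNG seed.
#' @param alpha_max Upper bound of the uniform prior on alpha.
#' @return List of class `admixture_config`.
#' @export
admixture_config <- function(k_clusters, lambda = 1, alpha_init = 1,
                             freq_model = c("correlated", "independent"),
                             n_iterations = 110000L, burn_in_fraction = 0.10,
                             seed = 0L, alpha_max = 10) {
  freq_model <- match.arg(freq_model)
  if (k_clusters < 1L) stop("k_clusters must be >= 1")
  if (lambda <= 0) stop("lambda must be positive")
  if (alpha_init <= 0) stop("alpha_init must be positive")
  if (burn_in_fraction <= 0 || burn_in_fraction >= 1) {
    stop("burn_in_fraction must lie in (0, 1)")
  }
  structure(list(k_clusters = as.integer(k_clusters), lambda = lambda,
                 alpha_init = alpha_init, freq_model = freq_model,
                 n_iterations = as.integer(n_iterations),
                 burn_in_fraction = burn_in_fraction,
                 seed = as.integer(seed), alpha_max = alpha_max),
            class = "admixture_config")
}

# internal: one Dirichlet draw via gamma variates
rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape)
  if (all(g == 0)) g <- rep(1, length(shape))
  g / sum(g)
}

#' Run the admixture-model Gibbs sampler
#'
#' Data augmentation over the origin cluster of every allele copy:
#' Z | P,Q multinomial; allele frequencies P | Z Dirichlet(lambda + counts)
#' under the independent model, or Dirichlet(p_A (1-F_k)/F_k + counts) under
#' the correlated model (ancestral frequencies p_A and per-cluster drift F_k
#' updated by Metropolis); admixture proportions Q | Z Dirichlet(alpha +
#' counts); alpha by log-scale random-walk Metropolis. Missing calls are
#' skipped. The per-sweep data log-likelihood ln P(X | P, Q) is recorded and
#' summarised as L(K) = mean - variance/2 over retained sweeps (the
#' "estimated ln probability of data" consumed by Evanno's delta-K).
#'
#' @param gt A [genotype_table()].
#' @param cfg An [admixture_config()].
#' @return Object of class `admixture_run`: list with `q_matrix`
#'   (individuals x K posterior means, rows sum to 1), `p_freqs` (list per
#'   locus of K x alleles posterior means), `ln_l_mean`, `ln_l_var`,
#'   `est_ln_prob`, `alpha_posterior_mean`, `drift_f` (correlated model),
#'   `k_clusters`, `alpha_acceptance`.
#' @export
run_admixture_mcmc <- function(gt, cfg) {
  K <- cfg$k_clusters
  n <- length(gt$sample_ids)
  L <- length(gt$locus_names)
  set.seed(cfg$seed)

  # recode alleles per locus to 1..J_l and flatten observed copies
  allele_levels <- lapply(seq_len(L), function(j) {
    sort(unique(c(gt$a1[, j], gt$a2[, j])))
  })
  ind_idx <- integer(0); loc_idx <- integer(0); al_idx <- integer(0)
  for (j in seq_len(L)) {
    typed <- which(!is.na(gt$a1[, j]))
    lev <- allele_levels[[j]]
    ind_idx <- c(ind_idx, typed, typed)
    loc_idx <- c(loc_idx, rep(j, 2L * length(typed)))
    al_idx <- c(al_idx, match(gt$a1[typed, j], lev), match(gt$a2[typed, j], lev))
  }
  M <- length(ind_idx)
  if (M == 0L) stop("no typed genotype calls")
  J <- vapply(allele_levels, length, integer(1))

  # state
  P <- lapply(seq_len(L), function(j) {
    m <- matrix(stats::rgamma(K * J[j], shape = cfg$lambda), K, J[j])
    m / rowSums(m)
  })
  Q <- matrix(1 / K, n, K)
  alpha <- cfg$alpha_init
  pA <- lapply(seq_len(L), function(j) rep(1 / J[j], J[j]))
  Fk <- rep(0.1, K)
  correlated <- cfg$freq_model == "correlated"

  n_burn <- max(1L, floor(cfg$n_iterations * cfg$burn_in_fraction))
  n_keep <- cfg$n_iterations - n_burn
  q_sum <- matrix(0, n, K)
  p_sum <- lapply(seq_len(L), function(j) matrix(0, K, J[j]))
  ll_kept <- numeric(n_keep)
  alpha_sum <- 0
  fk_sum <- rep(0, K)
  alpha_acc <- 0L; alpha_try <- 0L

  copy_by_locus <- split(seq_len(M), loc_idx)
  qcnt_base <- (ind_idx - 1L) * K

  for (it in seq_len(cfg$n_iterations)) {
    # P gathered per copy: W[m, k] = Q[ind, k] * P_l[k, allele]
    Pg <- matrix(0, M, K)
    for (j in seq_len(L)) {
      rows <- copy_by_locus[[as.character(j)]]
      Pg[rows, ] <- t(P[[j]][, al_idx[rows], drop = FALSE])
    }
    W <- Q[ind_idx, , drop = FALSE] * Pg
    rs <- rowSums(W)
    ll <- sum(log(rs))

    if (K == 1L) {
      z <- rep(1L, M)
    } else {
      u <- stats::runif(M) * rs
      cw <- W
      for (k in 2:K) cw[, k] <- cw[, k] + cw[, k - 1L]
      z <- rep(1L, M)
      for (k in seq_len(K - 1L)) z <- z + (u > cw[, k])
    }

    # update P
    for (j in seq_len(L)) {
      rows <- copy_by_locus[[as.character(j)]]
      cnt <- matrix(tabulate((z[rows] - 1L) * J[j] + al_idx[rows],
                             nbins = K * J[j]),
                    nrow = K, byrow = TRUE)
      prior <- if (correlated) {
        matrix(rep(pA[[j]], each = K) * (1 - Fk) / Fk, nrow = K)
      } else {
        matrix(cfg$lambda, K, J[j])
      }
      for (k in seq_len(K)) {
        P[[j]][k, ] <- rdirichlet1(prior[k, ] + cnt[k, ])
      }
    }

    # update Q
    if (K > 1L) {
      qcnt <- matrix(tabulate(qcnt_base + z, nbins = n * K),
                     nrow = n, byrow = TRUE)
      gmat <- matrix(stats::rgamma(n * K, shape = alpha + qcnt), n, K)
      Q <- gmat / rowSums(gmat)

      # update alpha: log-scale random walk, Uniform(0, alpha_max) prior
      alpha_try <- alpha_try + 1L
      prop <- alpha * exp(stats::rnorm(1, 0, 0.3))
      if (prop < cfg$alpha_max) {
        lp <- function(a) {
          n * (lgamma(K * a) - K * lgamma(a)) + (a - 1) * sum(log(pmax(Q, 1e-300)))
        }
        if (log(stats::runif(1)) < lp(prop) - lp(alpha) + log(prop) - log(alpha)) {
          alpha <- prop
          alpha_acc <- alpha_acc + 1L
        }
      }
    }

    # update correlated-model hyperparameters
    if (correlated) {
      ldirich <- function(x, shape) {
        sum((shape - 1) * log(pmax(x, 1e-300))) + lgamma(sum(shape)) -
          sum(lgamma(shape))
      }
      for (j in seq_len(L)) {
        if (J[j] < 2L) next
        prop <- pA[[j]]
        ij <- sample.int(J[j], 2L)
        d <- stats::runif(1, 0, 0.1) * prop[ij[1L]]
        prop[ij[1L]] <- prop[ij[1L]] - d
        prop[ij[2L]] <- prop[ij[2L]] + d
        if (all(prop > 1e-9)) {
          cur_lp <- prop_lp <- 0
          for (k in seq_len(K)) {
            cur_lp <- cur_lp + ldirich(P[[j]][k, ], pA[[j]] * (1 - Fk[k]) / Fk[k])
            prop_lp <- prop_lp + ldirich(P[[j]][k, ], prop * (1 - Fk[k]) / Fk[k])
          }
          cur_lp <- cur_lp + ldirich(pA[[j]], rep(cfg$lambda, J[j]))
          prop_lp <- prop_lp + ldirich(prop, rep(cfg$lambda, J[j]))
          if (log(stats::runif(1)) < prop_lp - cur_lp) pA[[j]] <- prop
        }
      }
      for (k in seq_len(K)) {
        cur <- Fk[k]
        lo <- log(cur / (1 - cur)) + stats::rnorm(1, 0, 0.4)
        prop <- 1 / (1 + exp(-lo))
        lp_f <- function(f) {
          s <- 0
          for (j in seq_len(L)) {
            s <- s + ldirich(P[[j]][k, ], pA[[j]] * (1 - f) / f)
          }
          s  # Uniform(0,1) prior on F_k
        }
        # Jacobian of the logit random walk: log f(1-f)
        if (log(stats::runif(1)) < lp_f(prop) - lp_f(cur) +
            log(prop * (1 - prop)) - log(cur * (1 - cur))) {
          Fk[k] <- prop
        }
      }
    }

    if (it > n_burn) {
      idx <- it - n_burn
      ll_kept[idx] <- ll
      q_sum <- q_sum + Q
      for (j in seq_len(L)) p_sum[[j]] <- p_sum[[j]] + P[[j]]
      alpha_sum <- alpha_sum + alpha
      fk_sum <- fk_sum + Fk
    }
  }

  if (K > 1L && alpha_try > 0L && alpha_acc / alpha_try < 0.01) {
    warning("alpha acceptance rate below 1%; chain may be poorly mixed")
  }
  q_bar <- q_sum / n_keep
  q_bar <- q_bar / rowSums(q_bar)
  rownames(q_bar) <- gt$sample_ids
  ln_mean <- mean(ll_kept)
  ln_var <- stats::var(ll_kept)
  structure(list(
    q_matrix = q_bar,
    p_freqs = lapply(p_sum, function(x) x / n_keep),
    ln_l_mean = ln_mean, ln_l_var = ln_var,
    est_ln_prob = ln_mean - ln_var / 2,
    alpha_posterior_mean = if (K > 1L) alpha_sum / n_keep else NA_real_,
    drift_f = if (correlated) fk_sum / n_keep else NULL,
    k_clusters = K,
    alpha_acceptance = if (alpha_try > 0L) alpha_acc / alpha_try else NA_real_
  ), class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat("admixture_run: K =", x$k_clusters, ", L(K) =",
      format(x$est_ln_prob, digits = 6), "\n")
  invisible(x)
}

#' Evanno's delta-K table from a grid of runs
#'
#' delta-K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K)),
#' defined for interior K with positive SD over runs; the argmax is the
#' selected number of clusters.
#'
#' @param results Either a data frame with columns `k` and `ln_prob`
#'   (one row per run), or a list of [run_admixture_mcmc()] results.
#' @return Object of class `evanno_table`: data frame with k, n_runs,
#'   mean_ln_prob, sd_ln_prob, delta_k; attribute `selected_k`.
#' @export
evanno_delta_k <- function(results) {
  if (!is.data.frame(results)) {
    results <- data.frame(
      k = vapply(results, `[[`, integer(1), "k_clusters"),
      ln_prob = vapply(results, `[[`, numeric(1), "est_ln_prob")
    )
  }
  ks <- sort(unique(results$k))
  if (length(ks) < 3L || any(diff(ks) != 1L)) {
    stop("need at least three consecutive K values")
  }
  mu <- vapply(ks, function(k) mean(results$ln_prob[results$k == k]), numeric(1))
  sdv <- vapply(ks, function(k) stats::sd(results$ln_prob[results$k == k]), numeric(1))
  nr <- vapply(ks, function(k) sum(results$k == k), numeric(1))
  if (any(nr < 2L)) stop("need at least two runs per K")
  dk <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1L, length(ks))]) {
    if (!is.na(sdv[i]) && sdv[i] > 0) {
      dk[i] <- abs(mu[i + 1L] - 2 * mu[i] + mu[i - 1L]) / sdv[i]
    }
  }
  out <- data.frame(k = ks, n_runs = nr, mean_ln_prob = mu,
                    sd_ln_prob = sdv, delta_k = dk)
  attr(out, "selected_k") <- if (all(is.na(dk))) NA_integer_ else
    ks[which.max(dk)]
  class(out) <- c("evanno_table", "data.frame")
  out
}

# internal: all permutations of 1..k
permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in permutations_of(k - 1L)) {
      rest <- setdiff(seq_len(k), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Align membership matrices across runs (label switching)
#'
#' Cluster labels are arbitrary per run. Each run's columns are permuted
#' (exhaustively over K! permutations, exact for K <= 8) to minimise the
#' summed squared difference to the incrementally built reference mean;
#' the permutation-averaged consensus Q is returned.
#'
#' @param runs List of Q matrices (or [run_admixture_mcmc()] results) with
#'   identical dimensions.
#' @return Object of class `aligned_runs`: list with `consensus_q` and
#'   `permutations` (list of integer vectors, one per run).
#' @export
align_runs <- function(runs) {
  qs <- lapply(runs, function(r) if (inherits(r, "admixture_run")) r$q_matrix else r)
  dims <- vapply(qs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all runs must have the same individuals and K")
  }
  K <- ncol(qs[[1L]])
  perms <- permutations_of(K)
  used <- vector("list", length(qs))
  used[[1L]] <- seq_len(K)
  acc <- qs[[1L]]
  for (r in seq_along(qs)[-1L]) {
    ref <- acc / (r - 1)
    costs <- vapply(perms, function(p) sum((qs[[r]][, p, drop = FALSE] - ref)^2),
                    numeric(1))
    best <- perms[[which.min(costs)]]
    used[[r]] <- best
    acc <- acc + qs[[r]][, best, drop = FALSE]
  }
  consensus <- acc / length(qs)
  consensus <- consensus / rowSums(consensus)
  structure(list(consensus_q = consensus, permutations = used),
            class = "aligned_runs")
}

#' Difference in group mean membership (delta-Qbar)
#'
#' Signed difference (mean over group 1) - (mean over group 2) of a
#' designated membership-coefficient column, the statistic used to ask
#' whether individuals carrying different mitochondrial lineages differ in
#' their nuclear cluster membership.
#'
#' @param q_column Numeric membership values in `[0, 1]`.
#' @param labels Two-group assignment (factor or character); group 1 is the
#'   first factor level (first unique value for character input).
#' @return Signed delta-Qbar.
#' @export
delta_q_statistic <- function(q_column, labels) {
  f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  if (nlevels(f) != 2L) stop("labels must define exactly two groups")
  sizes <- table(f)
  if (any(sizes == 0L)) stop("both groups must be non-empty")
  mean(q_column[f == levels(f)[1L]]) - mean(q_column[f == levels(f)[2L]])
}

#' Permutation test for delta-Qbar
#'
#' Pools all values and repeatedly re-partitions them at random into groups
#' of the original sizes (sampling without replacement), recomputing
#' delta-Qbar each time. The add-one p-value estimator is used, so p is
#' never exactly 0. With `exhaustive = TRUE` all distinct partitions are
#' enumerated and the exact p-value is returned (feasible for small pools).
#'
#' @param q_column Numeric membership values.
#' @param labels Two-group assignment (group 1 = first level).
#' @param n_perm Number of random partitions (default 100000).
#' @param seed Integer RNG seed.
#' @param sidedness `"greater"` (default, one-sided), `"less"` or
#'   `"two-sided"`.
#' @param exhaustive Enumerate all partitions instead of sampling.
#' @return Object of class `group_q_stat`: list with `group_sizes`,
#'   `mean_q_per_group`, `delta_q`, `p_value`, `n_permutations`.
#' @export
permutation_test_delta_q <- function(q_column, labels, n_perm = 100000L,
                                     seed = 0L,
                                     sidedness = c("greater", "less", "two-sided"),
                                     exhaustive = FALSE) {
  sidedness <- match.arg(sidedness)
  f <- if (is.factor(labels)) labels else factor(labels, levels = unique(labels))
  if (nlevels(f) != 2L) stop("labels must define exactly two groups")
  n1 <- sum(f == levels(f)[1L])
  n2 <- sum(f == levels(f)[2L])
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  obs <- delta_q_statistic(q_column, f)
  pool <- q_column
  n <- length(pool)
  stat_of <- function(idx) mean(pool[idx]) - mean(pool[-idx])
  hit <- function(d) {
    switch(sidedness,
           greater = d >= obs - 1e-12,
           less = d <= obs + 1e-12,
           `two-sided` = abs(d) >= abs(obs) - 1e-12)
  }
  if (exhaustive) {
    if (choose(n, n1) > 5e5) stop("pool too large for exhaustive enumeration")
    combs <- utils::combn(n, n1)
    d <- apply(combs, 2L, stat_of)
    p <- mean(hit(d))
    n_used <- ncol(combs)
  } else {
    if (n_perm < 1L) stop("n_perm must be >= 1")
    set.seed(seed)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (hit(stat_of(sample.int(n, n1)))) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(
    group_sizes = c(n1, n2),
    mean_q_per_group = c(mean(pool[f == levels(f)[1L]]),
                         mean(pool[f == levels(f)[2L]])),
    delta_q = obs, p_value = p, n_permutations = n_used,
    sidedness = sidedness
  ), class = "group_q_stat")
}
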