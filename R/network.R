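## Median-joining haplotype network (Bandelt-style): observed haplotypes plus
## inferred median (Steiner) vectors, connected by a minimum-spanning network.

# internal: hamming distance matrix between rows of a character matrix
hamming_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

# internal: edges of the epsilon-relaxed minimum-spanning network.
# An edge (u,v) of weight w is kept iff u and v are not already connected
# using only edges of weight < w - epsilon (epsilon = 0 gives the union of
# all minimum spanning trees).
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n < 2L) return(data.frame(from = integer(0), to = integer(0), weight = integer(0)))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  keep <- logical(length(w))
  for (k in seq_along(w)) {
    thr <- w[k] - epsilon
    # components under edges with weight < thr
    comp <- seq_len(n)
    ord <- which(w < thr)
    for (e in ord) {
      a <- comp[pairs[e, 1L]]; b <- comp[pairs[e, 2L]]
      if (a != b) comp[comp == b] <- a
    }
    keep[k] <- comp[pairs[k, 1L]] != comp[pairs[k, 2L]]
  }
  data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L], weight = w[keep])
}

# internal: total weight of a minimum spanning tree of d (Prim)
mst_weight <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0L)
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- d[1L, ]
  total <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    total <- total + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  total
}

# internal: quasi-median sequences of three haplotype rows. Majority state
# per site; sites where all three states differ expand combinatorially
# (capped), falling back to the first sequence's state beyond the cap.
quasi_medians <- function(a, b, c, max_expand = 3L) {
  L <- length(a)
  med <- a
  three_way <- integer(0)
  for (s in seq_len(L)) {
    states <- c(a[s], b[s], c[s])
    tab <- table(states)
    if (max(tab) >= 2L) {
      med[s] <- names(tab)[which.max(tab)]
    } else {
      three_way <- c(three_way, s)
    }
  }
  if (length(three_way) == 0L) return(list(med))
  if (length(three_way) > max_expand) {
    return(list(med))  # med already holds a's state at unresolved sites
  }
  choices <- lapply(three_way, function(s) c(a[s], b[s], c[s]))
  grid <- do.call(expand.grid, c(choices, stringsAsFactors = FALSE))
  out <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    m <- med
    m[three_way] <- as.character(grid[r, ])
    out[[r]] <- m
  }
  out
}

#' Median-joining network of haplotypes
#'
#' Builds the epsilon-relaxed minimum-spanning network over the observed
#' haplotypes, then iteratively adds consensus (median) vectors of node
#' triplets whenever they reduce the total connection cost, pruning median
#' vectors that end up unused. Observed haplotypes are always retained;
#' inferred nodes are flagged as medians (the unsampled intermediate
#' haplotypes classically drawn as black dots).
#'
#' @param haps A [collapse_haplotypes()] result, or a character vector of
#'   distinct equal-length sequences.
#' @param epsilon Integer relaxation parameter (default 0: strict minimum
#'   connection cost).
#' @param max_iter Safety cap on median-addition rounds.
#' @return Object of class `haplotype_network`: list with `nodes` (data
#'   frame: label, sequence, is_median, count) and `edges` (data frame:
#'   from, to, weight, using node labels).
#' @export
median_joining_network <- function(haps, epsilon = 0L, max_iter = 25L) {
  if (inherits(haps, "haplotype_set")) {
    seqs <- haps$haplotypes
    counts <- haps$counts
  } else {
    seqs <- haps
    if (is.null(names(seqs))) names(seqs) <- paste0("H", seq_along(seqs))
    counts <- rep(1L, length(seqs))
  }
  if (length(seqs) < 2L) stop("need at least two haplotypes")
  if (anyDuplicated(seqs)) stop("haplotypes must be pairwise distinct")
  m <- seq_matrix(seqs)
  n_obs <- nrow(m)
  is_median <- rep(FALSE, n_obs)

  for (iter in seq_len(max_iter)) {
    d <- hamming_matrix(m)
    E <- msn_edges(d, epsilon)
    base_w <- mst_weight(d)
    adj <- matrix(FALSE, nrow(m), nrow(m))
    adj[cbind(E$from, E$to)] <- TRUE
    adj <- adj | t(adj)
    # candidate medians from triplets with at least two MSN links
    cand_seqs <- list(); cand_cost <- numeric(0)
    nn <- nrow(m)
    if (nn >= 3L) {
      for (i in seq_len(nn - 2L)) for (j in (i + 1L):(nn - 1L)) for (k in (j + 1L):nn) {
        if (adj[i, j] + adj[i, k] + adj[j, k] < 2L) next
        for (med in quasi_medians(m[i, ], m[j, ], m[k, ])) {
          if (any(apply(m, 1L, function(r) all(r == med)))) next
          cost <- sum(m[i, ] != med) + sum(m[j, ] != med) + sum(m[k, ] != med)
          cand_seqs <- c(cand_seqs, list(med))
          cand_cost <- c(cand_cost, cost)
        }
      }
    }
    if (length(cand_seqs) == 0L) break
    lambda <- min(cand_cost)
    pick <- which(cand_cost <= lambda + epsilon)
    new_rows <- unique(vapply(cand_seqs[pick], paste, character(1), collapse = ""))
    m_try <- rbind(m, do.call(rbind, strsplit(new_rows, "")))
    w_try <- mst_weight(hamming_matrix(m_try))
    if (w_try >= base_w) break
    m <- m_try
    is_median <- c(is_median, rep(TRUE, length(new_rows)))
  }

  # prune median nodes whose removal does not increase the MST weight
  repeat {
    d <- hamming_matrix(m)
    E <- msn_edges(d, epsilon)
    deg <- tabulate(c(E$from, E$to), nbins = nrow(m))
    w_full <- mst_weight(d)
    dropped <- FALSE
    for (v in rev(which(is_median))) {
      if (deg[v] > 2L) next
      keep <- setdiff(seq_len(nrow(m)), v)
      if (mst_weight(d[keep, keep, drop = FALSE]) <= w_full) {
        m <- m[keep, , drop = FALSE]
        is_median <- is_median[keep]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }

  d <- hamming_matrix(m)
  E <- msn_edges(d, epsilon)
  labels <- c(names(seqs), if (sum(is_median) > 0L)
    paste0("mv", seq_len(sum(is_median))) else character(0))
  nodes <- data.frame(
    label = labels,
    sequence = apply(m, 1L, paste, collapse = ""),
    is_median = is_median,
    count = c(counts, rep(0L, sum(is_median))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  edges <- data.frame(from = labels[E$from], to = labels[E$to],
                      weight = E$weight, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network:", nrow(x$nodes), "nodes (",
      sum(x$nodes$is_median), "median vectors ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Export a haplotype network as an edge-list table
#' @param net A `haplotype_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
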