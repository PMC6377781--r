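# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (nested loops, exhaustive enumeration) and never call
# the code paths they verify.

# upper-tail hypergeometric by direct PMF summation over binomials
oracle_hyper_upper <- function(k, N, K, n) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# overlap rate straight from set arithmetic
oracle_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  min(length(a), length(b)) / length(union(a, b))
}

# exhaustive average-linkage agglomeration stopped at the cut height.
# UPGMA merge heights are monotone, so stopping when the next merge
# exceeds the cut equals cutting the full tree at that height.
oracle_average_linkage <- function(d, cut) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL
    bestd <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd - 1e-12) {
          bestd <- dd
          best <- c(i, j)
        }
      }
    }
    if (bestd > cut) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
  memb
}

# canonical form of a partition label vector, for comparing clusterings
# that may label clusters differently
canonical_partition <- function(memb) {
  match(memb, unique(memb))
}

# nested-loop grouping of profiles by key
oracle_group_counts <- function(keys) {
  uniq <- character(0)
  counts <- integer(0)
  for (k in keys) {
    i <- match(k, uniq)
    if (is.na(i)) {
      uniq <- c(uniq, k)
      counts <- c(counts, 1L)
    } else {
      counts[i] <- counts[i] + 1L
    }
  }
  stats::setNames(counts, uniq)
}

# random pathway database for clustering tests
random_db <- function(n, universe = 40L, size_range = c(4L, 12L)) {
  lapply(seq_len(n), function(i) {
    sz <- sample(seq(size_range[1], size_range[2]), 1L)
    pathway(id = sprintf("P%02d", i),
            genes = sample(sprintf("g%03d", seq_len(universe)), sz))
  })
}

# tiny cohort straight from a matrix of linear fold changes
linear_cohort <- function(fc_linear, p = NULL, id = "c1",
                          gene_id = sprintf("G%02d", seq_len(nrow(fc_linear)))) {
  cohort_table(id, paste0("T", seq_len(ncol(fc_linear))), fc_linear,
               gene_id, pvalue = p, fc_scale = "linear_signed")
}
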