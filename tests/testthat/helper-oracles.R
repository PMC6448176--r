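# Independent brute-force oracles used to check the implementation paths.

# O(n^3) average-linkage agglomeration from first principles: repeatedly
# merge the pair of active clusters with the smallest unweighted mean of
# all pairwise member distances. Returns merge heights (in merge order)
# and the partition after each merge.
oracle_upgma <- function(d) {
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("d", seq_len(n))
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  avg_dist <- function(a, b) mean(d[a, b])
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          dd <- avg_dist(clusters[[i]], clusters[[j]])
          if (dd < best_d) { best_d <- dd; best <- c(i, j) }
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1L]] <- merged
    heights <- c(heights, best_d)
    memb <- integer(n)
    for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
    partitions[[length(partitions) + 1L]] <- stats::setNames(memb, ids)
  }
  list(heights = heights, partitions = partitions, ids = ids)
}

# Partition of the oracle tree at a cut height (closed boundary: merges at
# height <= h join).
oracle_cut <- function(oracle, h) {
  k <- sum(oracle$heights <= h + 1e-12)
  if (k == 0L) {
    return(stats::setNames(seq_along(oracle$ids), oracle$ids))
  }
  oracle$partitions[[k]]
}

# Canonical form of a flat partition: cluster labels renumbered by first
# appearance, so two partitions are equal iff the groupings are equal.
canonical_partition <- function(cl) {
  cl <- cl[order(names(cl))]
  stats::setNames(match(cl, unique(cl)), names(cl))
}

# Exhaustive pair-by-pair counting over labeled items.
oracle_pair_counts <- function(clusters, labels) {
  ids <- names(labels)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        same_cl <- clusters[[ids[i]]] == clusters[[ids[j]]]
        same_lab <- labels[[ids[i]]] == labels[[ids[j]]]
        if (same_cl && same_lab) tp <- tp + 1L
        else if (same_cl && !same_lab) fp <- fp + 1L
        else if (!same_cl && same_lab) fn <- fn + 1L
        else tn <- tn + 1L
      }
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Random symmetric distance matrix with zero diagonal and continuous
# entries (ties have probability zero).
random_distance_matrix <- function(n, ids = paste0("d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2)
  d + t(d)
}

# Small separable synthetic fixture shared by pipeline tests: zero noise
# operators, topics with distinct core terms.
separable_fixture <- function(n_patients = 2, items = 60, codes = c("N17", "I10", "E11"),
                              coded_fraction = 0.5, seed = 11,
                              variants = TRUE) {
  topics <- default_topics(codes)
  if (!variants) topics$variants <- ""
  generate_corpus(synth_config(
    n_patients = n_patients,
    items_per_patient = c(items, items),
    topics = topics,
    coded_fraction = coded_fraction,
    noise = noise_config(0, 0, 0),
    seed = seed))
}
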