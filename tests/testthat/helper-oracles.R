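# Independent oracle implementations used across tests. These deliberately
# avoid the package's code paths (and ape where the point is independence).

# Forward pure-birth simulation of the same documented law as
# simulate_tree(), tracking only pairwise MRCA times; returns the mean
# pairwise patristic distance. Lineages are sets of (future) tip slots.
oracle_yule_mean_pairwise <- function(n_tips, birth_rate) {
  # each lineage is an integer id; record split times in a matrix over
  # current lineages: dist(i, j) = 2 * (T - t_split(i, j))
  t_split <- matrix(0, n_tips, n_tips)  # grows logically; index by lineage id
  active <- c(1L, 2L)
  next_id <- 3L
  t <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + rexp(1L, k * birth_rate)
    i <- active[sample.int(k, 1L)]
    c1 <- next_id; c2 <- next_id + 1L; next_id <- next_id + 2L
    # children inherit the parent's split times to all other lineages
    for (j in setdiff(active, i)) {
      t_split[c1, j] <- t_split[j, c1] <- t_split[i, j]
      t_split[c2, j] <- t_split[j, c2] <- t_split[i, j]
    }
    t_split[c1, c2] <- t_split[c2, c1] <- t
    active <- c(setdiff(active, i), c1, c2)
    if (next_id > nrow(t_split)) {
      t_split <- rbind(cbind(t_split, matrix(0, nrow(t_split), n_tips)),
                       matrix(0, n_tips, ncol(t_split) + n_tips))
    }
  }
  t_final <- t + rexp(1L, n_tips * birth_rate)
  pairs <- combn(active, 2L)
  mean(2 * (t_final - t_split[cbind(pairs[1L, ], pairs[2L, ])]))
}

# Brute-force mean nearest-taxon distance from a plain distance matrix.
oracle_mntd <- function(taxa, dmat) {
  vals <- vapply(taxa, function(a) {
    min(vapply(setdiff(taxa, a), function(b) dmat[a, b], 0))
  }, 0)
  mean(vals)
}

# Naive complete-linkage clustering at an identity threshold: repeatedly
# merge the two clusters whose maximum pairwise dissimilarity is smallest,
# while it does not exceed 1 - t. Independent of hclust/cutree.
oracle_complete_linkage <- function(idm, t) {
  clusters <- as.list(rownames(idm))
  repeat {
    n <- length(clusters)
    if (n == 1L) break
    best <- NULL; best_d <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d <- max(1 - idm[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > 1 - t + 1e-9) break
    clusters[[best[1L]]] <- sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    clusters <- clusters[-best[2L]]
  }
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, `[[`, "", 1L))]
}

# Canonical form of a partition (list of character vectors) for comparison.
canon_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[[`, "", 1L))]
}

# Random ultrametric test tree.
random_test_tree <- function(n, seed) {
  pcgpipe::simulate_tree(n, 1, 0, seed = seed)
}
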