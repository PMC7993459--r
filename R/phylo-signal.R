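#' Mean nearest-taxon distance (MNTD) of a set of tips
#'
#' Mean, over the given taxa, of the patristic distance to the nearest other
#' taxon in the set.
#'
#' @param taxa character vector of tip labels (>= 2).
#' @param tree phylo object, or a precomputed cophenetic distance matrix.
#' @return mean nearest-taxon distance (branch-length units).
#' @export
mntd <- function(taxa, tree) {
  dmat <- cophenetic_of(tree)
  taxa <- unique(taxa)
  unknown <- setdiff(taxa, rownames(dmat))
  if (length(unknown)) stop_pcg("unknown tip(s): ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2L) stop_pcg("need at least 2 taxa")
  sub <- dmat[taxa, taxa, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

cophenetic_of <- function(tree) {
  if (is.matrix(tree)) return(tree)
  if (!inherits(tree, "phylo")) stop_pcg("tree must be a phylo object or matrix")
  ape::cophenetic.phylo(tree)
}

# between-set nearest-taxon distance, symmetrized
mntd_between <- function(a, b, dmat) {
  sub <- dmat[a, b, drop = FALSE]
  mean(c(apply(sub, 1, min), apply(sub, 2, min)))
}

#' Nearest Taxon Index: z-score of MNTD against a null of random tips
#'
#' The observed [mntd()] of the community is compared to the distribution of
#' MNTD for equally many tips drawn uniformly without replacement from the
#' pool. The z-score keeps the sign of the raw distances: co-occurring taxa
#' *closer* than expected give negative z (phylogenetic clustering), more
#' distant than expected positive z (overdispersion). Calls use a +/- 2
#' threshold. With `exhaustive = TRUE` (or automatically when the number of
#' subsets is small) the null is enumerated exactly instead of sampled.
#'
#' @param taxa community members (tip labels), a subset of `pool`.
#' @param tree phylo object or cophenetic matrix.
#' @param pool tip pool for the null (default: all tips of the tree).
#' @param n_null number of null draws (>= 99).
#' @param seed integer seed.
#' @param exhaustive force (TRUE) or forbid (FALSE) exact enumeration of all
#'   subsets; `NULL` enumerates when there are at most `max_enum` subsets.
#' @param max_enum enumeration cap (default 5000 subsets).
#' @return object of class `dispersion_result`: list with `mntd_observed`,
#'   `null_mean`, `null_sd`, `z`, `call` in
#'   clustered/overdispersed/random/undefined, `n_null`, `method`.
#' @export
nti <- function(taxa, tree, pool = NULL, n_null = 999, seed = 1,
                exhaustive = NULL, max_enum = 5000) {
  dmat <- cophenetic_of(tree)
  pool <- unique(pool %||% rownames(dmat))
  taxa <- unique(taxa)
  if (!all(taxa %in% pool)) {
    stop_pcg("taxa not in pool: ", paste(setdiff(taxa, pool), collapse = ", "))
  }
  unknown <- setdiff(pool, rownames(dmat))
  if (length(unknown)) stop_pcg("unknown tip(s): ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2L) stop_pcg("need at least 2 taxa")
  check_number(n_null, "n_null", lower = 99)
  obs <- mntd(taxa, dmat)
  k <- length(taxa)
  n_subsets <- choose(length(pool), k)
  do_enum <- isTRUE(exhaustive) ||
    (is.null(exhaustive) && n_subsets <= max_enum)
  nulls <- if (do_enum) {
    combos <- utils::combn(pool, k)
    apply(combos, 2, function(tx) mntd(tx, dmat))
  } else {
    with_seed(seed, {
      vapply(seq_len(n_null), function(i) mntd(sample(pool, k), dmat), 0)
    })
  }
  dispersion_result(obs, nulls,
                    method = if (do_enum) "exhaustive" else "randomized")
}

#' Between-community nearest-taxon dispersion (beta-NTI variant)
#'
#' The observed statistic is the symmetrized between-community MNTD: the mean
#' over members of one community of the patristic distance to the nearest
#' member of the other. The null redraws both memberships (sizes preserved)
#' uniformly from the pool. Significantly positive z indicates turnover
#' between phylogenetically distant memberships (heterogeneous selection);
#' significantly negative z indicates memberships more similar than expected
#' (homogeneous selection).
#'
#' @param taxa_a,taxa_b the two community memberships (tip labels, nonempty,
#'   subsets of `pool`).
#' @inheritParams nti
#' @return a `dispersion_result` (see [nti()]).
#' @export
beta_nti <- function(taxa_a, taxa_b, tree, pool = NULL, n_null = 999,
                     seed = 1) {
  dmat <- cophenetic_of(tree)
  pool <- unique(pool %||% rownames(dmat))
  taxa_a <- unique(taxa_a); taxa_b <- unique(taxa_b)
  if (length(taxa_a) == 0 || length(taxa_b) == 0) {
    stop_pcg("both communities must be nonempty")
  }
  bad <- setdiff(c(taxa_a, taxa_b), pool)
  if (length(bad)) stop_pcg("taxa not in pool: ", paste(bad, collapse = ", "))
  check_number(n_null, "n_null", lower = 99)
  obs <- mntd_between(taxa_a, taxa_b, dmat)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(i) {
      mntd_between(sample(pool, length(taxa_a)),
                   sample(pool, length(taxa_b)), dmat)
    }, 0)
  })
  dispersion_result(obs, nulls, method = "randomized")
}

dispersion_result <- function(obs, nulls, method, threshold = 2) {
  mu <- mean(nulls)
  sdv <- sd(nulls)
  if (!is.finite(sdv) || sdv == 0) {
    z <- NA_real_; call <- "undefined"
  } else {
    z <- (obs - mu) / sdv
    call <- if (z <= -threshold) "clustered"
      else if (z >= threshold) "overdispersed" else "random"
  }
  structure(list(mntd_observed = obs, null_mean = mu, null_sd = sdv,
                 z = z, call = call, n_null = length(nulls), method = method),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Nearest-taxon dispersion (%s null, n = %d)\n",
              x$method, x$n_null))
  cat(sprintf("  observed MNTD = %.4g, null %.4g +/- %.4g\n",
              x$mntd_observed, x$null_mean, x$null_sd))
  if (is.na(x$z)) {
    cat("  z undefined (degenerate null) -> call: undefined\n")
  } else {
    cat(sprintf("  z = %.3f  ->  call: %s\n", x$z, x$call))
  }
  invisible(x)
}
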