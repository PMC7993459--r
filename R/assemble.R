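#' Specify a niche by its required traits
#'
#' A niche is labelled by the set of traits (or functions) needed to occupy
#' it. Species covering all required traits are *eligible*; everyone else has
#' zero abundance in every sample of the niche. Optional selection is encoded
#' as per-species fitness weights (constant, or per-sample via `gradient`).
#'
#' @param required_traits nonempty character vector of trait or function ids.
#' @param advantage named numeric vector of per-species fitness weights
#'   (> 0); unnamed species default to 1.
#' @param gradient optional function `(species, sample_index) -> weight`
#'   or a species x sample weight matrix, multiplying `advantage`.
#' @return an object of class `niche_spec`.
#' @export
make_niche <- function(required_traits, advantage = NULL, gradient = NULL) {
  if (length(required_traits) == 0) stop_pcg("required_traits must be nonempty")
  if (!is.null(advantage)) {
    if (is.null(names(advantage)) || any(advantage <= 0)) {
      stop_pcg("advantage must be a named vector of positive weights")
    }
  }
  structure(list(required_traits = required_traits, advantage = advantage,
                 gradient = gradient),
            class = "niche_spec")
}

#' Draw local communities under dispersal-limited (neutral or weighted) sampling
#'
#' The core sampling law of the simulator. For sample `s`, taxon `i` receives
#' a latent mass `g_i ~ Gamma(shape = depth * m * p_i * w_i * v_i,
#' rate = v_i)`; relative abundances are `g / sum(g)` and counts are
#' multinomial at `depth` reads. With all weights equal to 1 this is exactly
#' the dispersal-limited Dirichlet-multinomial with concentration
#' `depth * m * p`: `m` is the migration (dispersal) parameter and `p` the
#' metacommunity relative abundances.
#'
#' Selection enters through two channels:
#'
#' * `weights` (`w`) multiplies the *expected share* — a classical fitness
#'   multiplier on effective immigration (mean share proportional to
#'   `p * w`);
#' * `stability` (`v`) multiplies the *concentration* of the local
#'   population at fixed mean — persistence: a taxon with `v > 1` fluctuates
#'   less and hence occupies more samples than a neutral taxon of the same
#'   mean abundance. This is the channel the neutral-fit stage can detect; a
#'   pure `w` reweighting is mathematically absorbed into the metacommunity
#'   and is undetectable from occupancy--abundance data.
#'
#' @param p named metacommunity relative abundances (simplex).
#' @param n_samples number of samples.
#' @param depth reads per sample.
#' @param m migration parameter in (0, 1].
#' @param weights share (fitness) multipliers: scalar, per-taxon vector, or
#'   taxa x samples matrix.
#' @param stability persistence multipliers, same shapes accepted.
#' @param seed integer seed.
#' @return integer count matrix (taxa x samples), all column sums `depth`.
#' @export
sample_neutral_community <- function(p, n_samples, depth, m, weights = 1,
                                     stability = 1, seed = 1) {
  if (is.null(names(p))) stop_pcg("p must be a named abundance vector")
  if (any(p < 0) || sum(p) <= 0) stop_pcg("p must be non-negative, not all zero")
  p <- p / sum(p)
  check_number(n_samples, "n_samples", lower = 1)
  check_number(depth, "depth", lower = 1)
  check_number(m, "m", lower = 1e-12, upper = 1)
  K <- length(p)
  expand <- function(x, what) {
    out <- if (is.matrix(x)) {
      if (nrow(x) != K || ncol(x) != n_samples) {
        stop_pcg(what, " matrix must be taxa x samples")
      }
      x
    } else {
      matrix(rep_len(x, K), K, n_samples)
    }
    if (any(out <= 0)) stop_pcg(what, " must be positive")
    out
  }
  W <- expand(weights, "weights")
  V <- expand(stability, "stability")
  with_seed(seed, {
    counts <- matrix(0L, K, n_samples,
                     dimnames = list(names(p), paste0("S", seq_len(n_samples))))
    for (s in seq_len(n_samples)) {
      g <- rgamma(K, shape = depth * m * p * W[, s] * V[, s], rate = V[, s])
      if (all(g == 0)) g[which.max(p * W[, s])] <- 1  # gamma underflow guard
      counts[, s] <- as.integer(rmultinom(1L, as.integer(depth), g / sum(g)))
    }
    counts
  })
}

#' Assemble samples of a niche from a tree, traits and a niche spec
#'
#' Determines the eligible species (those whose traits cover
#' `niche$required_traits`), then draws samples with
#' [sample_neutral_community()]. Species lacking the required traits get zero
#' counts in every sample; taxa never observed are trimmed from the returned
#' table.
#'
#' @param tree phylo object (tip labels define the species universe).
#' @param traits trait table from [evolve_traits()].
#' @param niche a [make_niche()] object.
#' @param n_samples,depth,m sampling design (see
#'   [sample_neutral_community()]).
#' @param metacommunity optional named simplex over the eligible species;
#'   defaults to uniform.
#' @param seed integer seed.
#' @param trim drop all-zero taxon rows (default TRUE).
#' @return integer count matrix (taxa x samples).
#' @export
assemble_samples <- function(tree, traits, niche, n_samples, depth, m,
                             metacommunity = NULL, seed = 1, trim = TRUE) {
  if (!inherits(niche, "niche_spec")) stop_pcg("niche must be a niche_spec")
  species <- sort(tree$tip.label)
  elig <- eligible_species(traits, niche$required_traits, species = species)
  if (length(elig) == 0) {
    stop_pcg("no species covers the required trait(s): ",
             paste(niche$required_traits, collapse = ", "))
  }
  p <- rep(0, length(species)); names(p) <- species
  if (is.null(metacommunity)) {
    p[elig] <- 1 / length(elig)
  } else {
    if (is.null(names(metacommunity)) || !all(names(metacommunity) %in% elig)) {
      stop_pcg("metacommunity must be named over the eligible species")
    }
    p[names(metacommunity)] <- metacommunity / sum(metacommunity)
  }
  w <- rep(1, length(species)); names(w) <- species
  if (!is.null(niche$advantage)) {
    unknown <- setdiff(names(niche$advantage), species)
    if (length(unknown)) stop_pcg("advantage for unknown species: ",
                                  paste(unknown, collapse = ", "))
    w[names(niche$advantage)] <- niche$advantage
  }
  weights <- if (!is.null(niche$gradient)) {
    G <- if (is.matrix(niche$gradient)) {
      niche$gradient[species, , drop = FALSE]
    } else {
      outer(species, seq_len(n_samples),
            Vectorize(function(sp, s) niche$gradient(sp, s)))
    }
    G * w
  } else {
    w
  }
  # a fitness advantage also stabilizes the advantaged population
  counts <- sample_neutral_community(p, n_samples, depth, m,
                                     weights = weights, stability = weights,
                                     seed = seed)
  # eligibility invariant: only eligible species can appear
  counts[setdiff(species, elig), ] <- 0L
  if (trim) counts <- trim_zero_taxa(counts)
  counts
}
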