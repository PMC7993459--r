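#' Expected Jukes--Cantor sequence identity at a given distance
#'
#' Under the JC69 model, two sequences separated by patristic distance `d`
#' (expected substitutions per site) have expected per-site identity
#' `1/4 + 3/4 * exp(-4 d / 3)`.
#'
#' @param d patristic distance(s).
#' @return expected identity in (0.25, 1].
#' @export
jc_expected_identity <- function(d) 0.25 + 0.75 * exp(-4 * d / 3)

#' Evolve marker sequences along a tree under Jukes--Cantor
#'
#' A uniform-random root sequence evolves down the tree; on a branch of
#' length `b` each site switches to one of the three other bases with total
#' probability `3/4 * (1 - exp(-4 b / 3))`. Expected pairwise identity
#' therefore decays with patristic distance as [jc_expected_identity()].
#'
#' @param tree a phylo object with branch lengths (substitutions/site).
#' @param length sequence length in bases (>= 100).
#' @param seed integer seed.
#' @return named character vector of equal-length A/C/G/T strings, one per
#'   tip, in `tree$tip.label` order.
#' @export
evolve_sequences <- function(tree, length = 1000, seed = 1) {
  if (!inherits(tree, "phylo")) stop_pcg("tree must be a phylo object")
  if (is.null(tree$edge.length)) stop_pcg("tree must have branch lengths")
  check_number(length, "length", lower = 100)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    n_tip <- ape::Ntip(tree)
    n_node <- tree$Nnode
    seqs <- vector("list", n_tip + n_node)
    root <- n_tip + 1L
    seqs[[root]] <- sample.int(4L, length, replace = TRUE)
    tree <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; chd <- tree$edge[e, 2L]
      b <- tree$edge.length[e]
      s <- seqs[[par]]
      p_sub <- 0.75 * (1 - exp(-4 * b / 3))
      if (p_sub > 0) {
        hit <- which(runif(length) < p_sub)
        if (length(hit)) {
          # substitute to one of the three other bases, uniformly
          s[hit] <- ((s[hit] - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L
        }
      }
      seqs[[chd]] <- s
    }
    out <- vapply(seq_len(n_tip), function(i) {
      paste(bases[seqs[[i]]], collapse = "")
    }, "")
    names(out) <- tree$tip.label
    out
  })
}
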