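#' Four-species worked example: family F, genera G1/G2, species SA--SD
#'
#' Builds the canonical toy system used throughout the package: an
#' ultrametric four-tip tree `((SA,SB)G1,(SC,SD)G2)F`, a trait table, and
#' calibrated marker sequences with a planted identity hierarchy. Sequence
#' identities are calibrated (substitutions are planted at disjoint sites, not
#' simulated) so that clusters form at known thresholds of the default PCG
#' ladder:
#'
#' * within a species (ESV variants, if any): identity >= 0.996 — clusters at 0.99;
#' * within a genus: identity 0.98 — genus clusters fix at 0.97;
#' * across genera: identity ~0.928 — the family clusters at 0.92.
#'
#' Case `"A"` carries three conserved traits: *rectangle* (grey function) on
#' the root stem, *triangle* (blue) on the G1 branch, *diamond* (green) on the
#' G2 branch. Case `"B"` adds four *star* traits, all encoding the same
#' yellow function: convergent, independent origins on the terminal branches
#' of SA, SC and SD, and a horizontally transferred star on SB donated from
#' the SC lineage.
#'
#' @param case `"A"` (divergent conserved traits only) or `"B"` (adds
#'   convergent + HGT star traits).
#' @param length sequence length (>= 200; default 1000).
#' @param k_esv number of sequence variants per species (each variant within
#'   two substitutions of its species base sequence).
#' @return a list with elements `tree` (phylo), `traits` (data.frame),
#'   `sequences` (named character vector; ids `SA_1 ...` when `k_esv > 1`,
#'   else species names), and `calibration` (the planted thresholds).
#' @examples
#' fx <- fig1_fixture("A")
#' fx$traits
#' @export
fig1_fixture <- function(case = c("A", "B"), length = 1000, k_esv = 1) {
  if (!is.character(case) || !case[1] %in% c("A", "B")) {
    stop_pcg("unknown case '", paste(case[1]), "': must be \"A\" or \"B\"")
  }
  case <- case[1]
  check_number(length, "length", lower = 200)
  check_number(k_esv, "k_esv", lower = 1)
  length <- as.integer(length); k_esv <- as.integer(k_esv)

  tree <- ape::read.tree(
    text = "((SA:0.010,SB:0.010)G1:0.025,(SC:0.010,SD:0.010)G2:0.025)F;"
  )

  events <- list(
    list(trait_id = "rectangle", function_id = "grey",
         origin = "branch_conserved", branch = "root"),
    list(trait_id = "triangle", function_id = "blue",
         origin = "branch_conserved", branch = "G1"),
    list(trait_id = "diamond", function_id = "green",
         origin = "branch_conserved", branch = "G2")
  )
  if (case == "B") {
    events <- c(events, list(
      list(trait_id = "star_sa", function_id = "yellow",
           origin = "convergent", branch = "SA"),
      list(trait_id = "star_sc", function_id = "yellow",
           origin = "convergent", branch = "SC"),
      list(trait_id = "star_sd", function_id = "yellow",
           origin = "convergent", branch = "SD"),
      list(trait_id = "star_sb", function_id = "yellow",
           origin = "hgt", branch = "SC", recipient = "SB")
    ))
  }
  traits <- evolve_traits(tree, events)

  seqs <- fig1_sequences(length, k_esv)

  list(
    tree = tree,
    traits = traits,
    sequences = seqs,
    calibration = list(
      esv_threshold = 0.99, genus_threshold = 0.97, family_threshold = 0.92,
      within_genus_identity = 1 - 2 * round(0.010 * length) / length,
      between_genus_identity =
        1 - (2 * round(0.025 * length) + 2 * round(0.010 * length)) / length
    )
  )
}

# Planted-substitution sequences. Sites are allocated in disjoint blocks:
# genus blocks (round(0.025 L) sites each), species blocks (round(0.010 L)),
# then one reserved site per extra ESV variant. The fixture is a fixed
# constant: randomness only sets the (arbitrary) base sequence, under a
# fixed internal seed.
fig1_sequences <- function(length, k_esv) {
  g <- round(0.025 * length)  # genus-branch substitutions
  s <- round(0.010 * length)  # species-branch substitutions
  need <- 2 * g + 4 * s + 4 * (k_esv - 1)
  if (need > length) stop_pcg("sequence length ", length,
                              " too short for k_esv = ", k_esv)
  bases <- c("A", "C", "G", "T")
  with_seed(760001, {
    root <- sample.int(4L, length, replace = TRUE)
    blocks <- list(
      G1 = seq_len(g), G2 = g + seq_len(g),
      SA = 2 * g + seq_len(s), SB = 2 * g + s + seq_len(s),
      SC = 2 * g + 2 * s + seq_len(s), SD = 2 * g + 3 * s + seq_len(s)
    )
    esv_sites <- 2 * g + 4 * s + seq_len(max(0, 4 * (k_esv - 1)))
    mutate <- function(x, sites) {
      x[sites] <- ((x[sites] - 1L + sample.int(3L, base::length(sites),
                                               replace = TRUE)) %% 4L) + 1L
      x
    }
    species <- c("SA", "SB", "SC", "SD")
    genus_of <- c(SA = "G1", SB = "G1", SC = "G2", SD = "G2")
    genus_seq <- list(G1 = mutate(root, blocks$G1), G2 = mutate(root, blocks$G2))
    base_seq <- lapply(species, function(sp) {
      mutate(genus_seq[[genus_of[[sp]]]], blocks[[sp]])
    })
    names(base_seq) <- species
    out <- character(0)
    for (si in seq_along(species)) {
      sp <- species[si]
      if (k_esv == 1L) {
        out[sp] <- paste(bases[base_seq[[sp]]], collapse = "")
      } else {
        site0 <- esv_sites[(si - 1L) * (k_esv - 1L) + seq_len(k_esv - 1L)]
        for (v in seq_len(k_esv)) {
          x <- base_seq[[sp]]
          if (v > 1L) x <- mutate(x, site0[v - 1L])
          out[paste0(sp, "_", v)] <- paste(bases[x], collapse = "")
        }
      }
    }
    out
  })
}
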