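#' Place traits on a phylogeny
#'
#' Traits are placed on branches and inherited by all descendant tips.
#' A branch is named by the label of the node (tip or internal) it leads to;
#' `"root"` denotes the root stem, whose descendants are all tips. Three
#' origins are supported:
#'
#' * `branch_conserved` — a trait fixed on a branch, present in every tip of
#'   the clade it subtends (divergent evolution of a conserved trait);
#' * `convergent` — identical placement rule, but the trait shares its
#'   `function_id` with traits of independent origin elsewhere on the tree;
#' * `hgt` — horizontal transfer: the trait is carried by the tips descending
#'   from the `recipient` branch, while `branch` records the donor lineage.
#'
#' @param tree a phylo object; internal nodes may carry labels.
#' @param events list of events, each a list/row with fields `trait_id`,
#'   `function_id`, `origin` (one of `"branch_conserved"`, `"convergent"`,
#'   `"hgt"`), `branch`, and for hgt additionally `recipient`.
#' @param seed unused at present (trait placement is deterministic); kept so
#'   all generator stages share one calling convention.
#' @return a `data.frame` (one row per species x trait) with columns
#'   `species`, `trait_id`, `function_id`, `origin`, `origin_branch`.
#' @examples
#' tr <- ape::read.tree(text = "((SA:1,SB:1)G1:1,(SC:1,SD:1)G2:1)F;")
#' evolve_traits(tr, list(
#'   list(trait_id = "rectangle", function_id = "grey",
#'        origin = "branch_conserved", branch = "root")
#' ))
#' @export
evolve_traits <- function(tree, events, seed = NULL) {
  if (!inherits(tree, "phylo")) stop_pcg("tree must be a phylo object")
  origins <- c("branch_conserved", "convergent", "hgt")
  seen <- character(0)
  rows <- list()
  for (ev in events) {
    ev <- as.list(ev)
    for (f in c("trait_id", "function_id", "origin", "branch")) {
      if (is.null(ev[[f]])) stop_pcg("trait event missing field '", f, "'")
    }
    if (!ev$origin %in% origins) {
      stop_pcg("unknown trait origin '", ev$origin, "'")
    }
    if (ev$trait_id %in% seen) {
      stop_pcg("duplicate trait_id '", ev$trait_id,
               "' with conflicting placement")
    }
    seen <- c(seen, ev$trait_id)
    carrier_branch <- if (ev$origin == "hgt") {
      if (is.null(ev$recipient)) stop_pcg("hgt event '", ev$trait_id,
                                          "' needs a recipient branch")
      if (identical(ev$recipient, ev$branch)) {
        stop_pcg("hgt event '", ev$trait_id,
                 "': donor and recipient branch coincide")
      }
      ev$recipient
    } else {
      ev$branch
    }
    tips <- descendant_tips(tree, carrier_branch)
    rows[[length(rows) + 1L]] <- data.frame(
      species = tips,
      trait_id = ev$trait_id,
      function_id = ev$function_id,
      origin = ev$origin,
      origin_branch = ev$branch,
      stringsAsFactors = FALSE
    )
  }
  tab <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(species = character(0), trait_id = character(0),
               function_id = character(0), origin = character(0),
               origin_branch = character(0))
  }
  rownames(tab) <- NULL
  tab
}

# Tips descending from the branch leading to the named node.
descendant_tips <- function(tree, branch) {
  if (identical(branch, "root")) return(sort(tree$tip.label))
  if (branch %in% tree$tip.label) return(branch)
  nl <- tree$node.label
  if (!is.null(nl) && branch %in% nl) {
    node <- ape::Ntip(tree) + match(branch, nl)
    return(sort(ape::extract.clade(tree, node)$tip.label))
  }
  stop_pcg("branch '", branch, "' matches no tip or internal node label")
}

#' Species satisfying a niche's trait requirements
#'
#' A species covers a requirement if it carries a trait whose `trait_id` or
#' `function_id` equals the requirement; it is eligible for a niche if it
#' covers every required trait.
#'
#' @param traits a trait table from [evolve_traits()].
#' @param required character vector of trait or function ids.
#' @param species optional universe of species (defaults to those in
#'   `traits`).
#' @return character vector of eligible species (sorted).
#' @export
eligible_species <- function(traits, required, species = NULL) {
  if (length(required) == 0) stop_pcg("required trait set must be nonempty")
  species <- species %||% sort(unique(traits$species))
  ok <- vapply(species, function(sp) {
    have <- traits[traits$species == sp, , drop = FALSE]
    all(required %in% c(have$trait_id, have$function_id))
  }, TRUE)
  sort(species[ok])
}
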