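#' Simulate an ultrametric birth--death tree
#'
#' Forward-time Gillespie simulation. Starting from two lineages at the root,
#' each extant lineage splits at rate `birth_rate` and dies at rate
#' `death_rate`. The process runs until `n_tips` lineages are extant; the tree
#' is then closed by one further exponential waiting time (rate
#' `n_tips * (birth_rate + death_rate)`), so all extant tips end at the same
#' time and the tree is ultrametric. Extinct side branches are pruned. Runs
#' that go extinct before reaching `n_tips` are restarted, up to
#' `max_retries` times.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth_rate speciation rate (> death_rate).
#' @param death_rate extinction rate (>= 0).
#' @param seed integer seed; the result is a deterministic function of it.
#' @param max_retries restarts allowed after extinction.
#' @return an [ape::phylo] tree with tips `t1 ... tn`.
#' @examples
#' tr <- simulate_tree(8, 1, 0, seed = 1)
#' @export
simulate_tree <- function(n_tips, birth_rate, death_rate = 0, seed = 1,
                          max_retries = 100) {
  check_number(n_tips, "n_tips", lower = 2)
  check_number(birth_rate, "birth_rate", lower = 1e-12)
  check_number(death_rate, "death_rate", lower = 0)
  if (birth_rate <= death_rate) stop_pcg("birth_rate must exceed death_rate")
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      sim <- sim_bd_once(n_tips, birth_rate, death_rate)
      if (!is.null(sim)) return(bd_to_phylo(sim))
    }
    stop_pcg("could not reach ", n_tips, " tips in ", max_retries,
             " attempts at birth=", birth_rate, ", death=", death_rate)
  })
}

# One forward realization; NULL on extinction. Lineage bookkeeping in flat
# vectors: parent id, start/end times, children ids, fate.
sim_bd_once <- function(n_tips, b, d, max_events = 100000L) {
  n_max <- 4L * n_tips + 8L
  parent <- integer(n_max); t0 <- numeric(n_max); t1 <- numeric(n_max)
  child1 <- integer(n_max); child2 <- integer(n_max)
  dead <- logical(n_max)
  n_lin <- 2L
  parent[1:2] <- 0L; t0[1:2] <- 0
  alive <- c(1L, 2L)
  t <- 0
  ev <- 0L
  repeat {
    k <- length(alive)
    if (k == 0L) return(NULL)
    if (k == n_tips) {
      t <- t + rexp(1L, k * (b + d))
      t1[alive] <- t
      return(list(parent = parent[1:n_lin], t0 = t0[1:n_lin], t1 = t1[1:n_lin],
                  child1 = child1[1:n_lin], child2 = child2[1:n_lin],
                  dead = dead[1:n_lin], alive = alive))
    }
    ev <- ev + 1L
    if (ev > max_events) return(NULL)
    t <- t + rexp(1L, k * (b + d))
    i <- alive[sample.int(k, 1L)]
    if (runif(1L) < b / (b + d)) {
      if (n_lin + 2L > n_max) {  # grow storage
        grow <- function(x) c(x, x[seq_len(n_max)] * 0L)
        parent <- c(parent, integer(n_max)); t0 <- c(t0, numeric(n_max))
        t1 <- c(t1, numeric(n_max)); child1 <- c(child1, integer(n_max))
        child2 <- c(child2, integer(n_max)); dead <- c(dead, logical(n_max))
        n_max <- 2L * n_max
      }
      c1 <- n_lin + 1L; c2 <- n_lin + 2L; n_lin <- n_lin + 2L
      parent[c(c1, c2)] <- i; t0[c(c1, c2)] <- t
      t1[i] <- t; child1[i] <- c1; child2[i] <- c2
      alive <- c(alive[alive != i], c1, c2)
    } else {
      t1[i] <- t; dead[i] <- TRUE
      alive <- alive[alive != i]
    }
  }
}

bd_to_phylo <- function(sim) {
  lab <- character(length(sim$parent))
  lab[sim$alive] <- paste0("t", seq_along(sim$alive))
  lab[sim$dead] <- paste0("dead", which(sim$dead))
  len <- sim$t1 - sim$t0
  nwk_of <- function(i) {
    if (sim$child1[i] == 0L) {
      paste0(lab[i], ":", format(len[i], digits = 12))
    } else {
      paste0("(", nwk_of(sim$child1[i]), ",", nwk_of(sim$child2[i]), "):",
             format(len[i], digits = 12))
    }
  }
  tr <- ape::read.tree(text = paste0("(", nwk_of(1L), ",", nwk_of(2L), ");"))
  if (any(sim$dead)) {
    tr <- ape::drop.tip(tr, lab[sim$dead])
  }
  tr
}

#' Scale a tree to a given root-to-tip height
#'
#' @param tree a phylo object.
#' @param height target height (branch-length units).
#' @return the rescaled tree.
#' @export
scale_tree_height <- function(tree, height) {
  check_number(height, "height", lower = 1e-12)
  h <- max(ape::node.depth.edgelength(tree))
  if (h <= 0) stop_pcg("tree has zero height")
  tree$edge.length <- tree$edge.length * (height / h)
  tree
}
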