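fig1_tree <- ape::read.tree(
  text = "((SA:0.01,SB:0.01)G1:0.025,(SC:0.01,SD:0.01)G2:0.025)F;"
)

test_that("branch-conserved traits propagate to exactly the subtended clade", {
  tab <- evolve_traits(fig1_tree, list(
    list(trait_id = "rectangle", function_id = "grey",
         origin = "branch_conserved", branch = "root"),
    list(trait_id = "triangle", function_id = "blue",
         origin = "branch_conserved", branch = "G1")
  ))
  expect_setequal(tab$species[tab$trait_id == "rectangle"],
                  c("SA", "SB", "SC", "SD"))
  expect_setequal(tab$species[tab$trait_id == "triangle"], c("SA", "SB"))
})

test_that("removing a genus event only affects that genus (locality)", {
  full <- evolve_traits(fig1_tree, list(
    list(trait_id = "triangle", function_id = "blue",
         origin = "branch_conserved", branch = "G1"),
    list(trait_id = "diamond", function_id = "green",
         origin = "branch_conserved", branch = "G2")
  ))
  reduced <- evolve_traits(fig1_tree, list(
    list(trait_id = "diamond", function_id = "green",
         origin = "branch_conserved", branch = "G2")
  ))
  expect_false(any(reduced$trait_id == "triangle"))
  a <- reduced[reduced$trait_id == "diamond", ]
  b <- full[full$trait_id == "diamond", ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("hgt traits land on the recipient and record the donor branch", {
  tab <- evolve_traits(fig1_tree, list(
    list(trait_id = "star_sb", function_id = "yellow", origin = "hgt",
         branch = "SC", recipient = "SB")
  ))
  expect_identical(tab$species, "SB")
  expect_identical(tab$origin_branch, "SC")
  expect_error(evolve_traits(fig1_tree, list(
    list(trait_id = "x", function_id = "y", origin = "hgt",
         branch = "SC", recipient = "SC")
  )), "coincide")
})

test_that("duplicate trait ids and unknown branches are rejected", {
  expect_error(evolve_traits(fig1_tree, list(
    list(trait_id = "t", function_id = "f",
         origin = "branch_conserved", branch = "G1"),
    list(trait_id = "t", function_id = "f",
         origin = "branch_conserved", branch = "G2")
  )), "duplicate")
  expect_error(evolve_traits(fig1_tree, list(
    list(trait_id = "t", function_id = "f",
         origin = "branch_conserved", branch = "nope")
  )), "matches no tip")
})

test_that("clade coverage is exact on random trees (property)", {
  for (s in 1:5) {
    set.seed(s)
    tr <- random_test_tree(20, seed = s)
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
    node <- sample(2:tr$Nnode, 1)  # skip the root
    tab <- evolve_traits(tr, list(
      list(trait_id = "t", function_id = "f",
           origin = "branch_conserved", branch = paste0("n", node))
    ))
    expected <- ape::extract.clade(tr, ape::Ntip(tr) + node)$tip.label
    expect_setequal(tab$species, expected)
  }
})

test_that("eligible_species matches on trait ids and function ids", {
  tab <- evolve_traits(fig1_tree, list(
    list(trait_id = "rectangle", function_id = "grey",
         origin = "branch_conserved", branch = "root"),
    list(trait_id = "triangle", function_id = "blue",
         origin = "branch_conserved", branch = "G1")
  ))
  expect_setequal(eligible_species(tab, "triangle"), c("SA", "SB"))
  expect_setequal(eligible_species(tab, "blue"), c("SA", "SB"))
  expect_setequal(eligible_species(tab, c("grey", "triangle")), c("SA", "SB"))
  expect_length(eligible_species(tab, "absent_trait"), 0)
})
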