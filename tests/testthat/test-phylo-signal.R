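fig1_tree <- ape::read.tree(
  text = "((SA:1,SB:1)G1:1,(SC:1,SD:1)G2:1)F;"
)

test_that("mntd of a single pair is their patristic distance", {
  expect_equal(mntd(c("SA", "SB"), fig1_tree), 2)
  expect_equal(mntd(c("SA", "SC"), fig1_tree), 4)
  expect_error(mntd(c("SA", "SX"), fig1_tree), "SX")
  expect_error(mntd("SA", fig1_tree), "at least 2")
})

test_that("mntd equals the brute-force all-pairs computation (property)", {
  for (s in 1:5) {
    tr <- random_test_tree(15, seed = s)
    dm <- ape::cophenetic.phylo(tr)
    set.seed(s)
    taxa <- sample(tr$tip.label, 7)
    expect_equal(mntd(taxa, tr), oracle_mntd(taxa, dm))
    expect_equal(mntd(tr$tip.label, tr), oracle_mntd(tr$tip.label, dm))
  }
})

test_that("a zero-length sister taxon can only lower the mntd", {
  tr <- ape::read.tree(text = "(((A:0,A2:0):1,B:1):1,C:2);")
  with_a <- mntd(c("A", "B", "C"), tr)
  with_both <- mntd(c("A", "A2", "B", "C"), tr)
  expect_lte(with_both, with_a)
})

test_that("degenerate nulls give an undefined call", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  r <- nti(c("A", "B"), tr, pool = c("A", "B"))
  expect_identical(r$call, "undefined")
  expect_true(is.na(r$z))
})

test_that("the 4-tip exhaustive null matches a full-enumeration oracle", {
  dm <- ape::cophenetic.phylo(fig1_tree)
  r <- nti(c("SA", "SB"), fig1_tree, exhaustive = TRUE)
  pairs <- combn(c("SA", "SB", "SC", "SD"), 2)
  null_vals <- apply(pairs, 2, function(tx) dm[tx[1], tx[2]])
  z_oracle <- (dm["SA", "SB"] - mean(null_vals)) / sd(null_vals)
  expect_equal(r$z, z_oracle, tolerance = 1e-12)
  expect_identical(r$method, "exhaustive")
})

test_that("randomized nulls converge to the exhaustive enumeration", {
  tr <- random_test_tree(8, seed = 12)
  set.seed(12)
  taxa <- sample(tr$tip.label, 4)
  ex <- nti(taxa, tr, exhaustive = TRUE)
  rn <- nti(taxa, tr, n_null = 9999, seed = 3, exhaustive = FALSE)
  se <- rn$null_sd / sqrt(rn$n_null)
  expect_lt(abs(rn$null_mean - ex$null_mean), 2 * se + 1e-9)
})

test_that("z is invariant to uniform branch-length scaling", {
  tr <- random_test_tree(12, seed = 4)
  set.seed(4)
  taxa <- sample(tr$tip.label, 5)
  r1 <- nti(taxa, tr, n_null = 499, seed = 8, exhaustive = FALSE)
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 37
  r2 <- nti(taxa, tr2, n_null = 499, seed = 8, exhaustive = FALSE)
  expect_equal(r1$z, r2$z, tolerance = 1e-9)
})

test_that("between-community mntd of identical communities is zero", {
  r <- beta_nti(c("SA", "SB"), c("SA", "SB"), fig1_tree, n_null = 199,
                seed = 1)
  expect_equal(r$mntd_observed, 0)
  expect_lte(r$z, 0)
  expect_error(beta_nti(character(0), "SA", fig1_tree), "nonempty")
})

test_that("mntd and the between-community variant agree with picante", {
  skip_if_not_installed("picante")
  tr <- random_test_tree(12, seed = 77)
  dm <- ape::cophenetic.phylo(tr)
  set.seed(77)
  taxa <- sample(tr$tip.label, 6)
  comm <- matrix(as.integer(tr$tip.label %in% taxa), nrow = 1,
                 dimnames = list("c1", tr$tip.label))
  expect_equal(mntd(taxa, tr),
               picante::mntd(comm, dm, abundance.weighted = FALSE))
  set.seed(78)
  taxa_b <- sample(tr$tip.label, 5)
  comm2 <- rbind(comm,
                 c2 = as.integer(tr$tip.label %in% taxa_b))
  cd <- picante::comdistnt(comm2, dm, abundance.weighted = FALSE)
  expect_equal(pcgpipe:::mntd_between(taxa, taxa_b, dm), as.numeric(cd))
})
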