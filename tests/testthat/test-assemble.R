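fx <- fig1_fixture("A")

test_that("every sample's counts sum to the declared depth", {
  p <- setNames(rep(0.25, 4), c("SA", "SB", "SC", "SD"))
  cc <- sample_neutral_community(p, n_samples = 25, depth = 300, m = 0.05,
                                 seed = 1)
  expect_true(all(colSums(cc) == 300))
  expect_true(all(cc >= 0))
})

test_that("assembly is seed-deterministic", {
  p <- setNames(rep(0.25, 4), c("SA", "SB", "SC", "SD"))
  expect_identical(sample_neutral_community(p, 10, 100, 0.1, seed = 3),
                   sample_neutral_community(p, 10, 100, 0.1, seed = 3))
  expect_false(identical(sample_neutral_community(p, 10, 100, 0.1, seed = 3),
                         sample_neutral_community(p, 10, 100, 0.1, seed = 4)))
})

test_that("species lacking the required traits never appear", {
  niche <- make_niche("triangle")
  cc <- assemble_samples(fx$tree, fx$traits, niche, n_samples = 30,
                         depth = 500, m = 0.5, seed = 2, trim = FALSE)
  expect_true(all(cc[c("SC", "SD"), ] == 0L))
  expect_true(any(cc[c("SA", "SB"), ] > 0L))
  cc1 <- assemble_samples(fx$tree, fx$traits, make_niche("rectangle"),
                          n_samples = 10, depth = 500, m = 0.5, seed = 2)
  expect_setequal(rownames(cc1), c("SA", "SB", "SC", "SD"))
})

test_that("a niche nobody can occupy is rejected with the unmet traits named", {
  expect_error(
    assemble_samples(fx$tree, fx$traits, make_niche("flagellum"),
                     n_samples = 5, depth = 100, m = 0.5),
    "flagellum"
  )
})

test_that("a fitness advantage shifts the mean share to w*p/sum(w*p)", {
  # high-migration, high-depth limit; Monte-Carlo over 100 seeds
  p <- setNames(rep(0.25, 4), c("SA", "SB", "SC", "SD"))
  w <- c(SA = 5, SB = 1, SC = 1, SD = 1)
  shares <- vapply(1:100, function(s) {
    cc <- sample_neutral_community(p, n_samples = 1, depth = 5000, m = 1,
                                   weights = w, stability = w, seed = s)
    cc["SA", 1] / 5000
  }, 0)
  target <- 5 * 0.25 / (5 * 0.25 + 0.75)
  se <- sd(shares) / sqrt(length(shares))
  expect_lt(abs(mean(shares) - target), 2 * se + 0.005)
})

test_that("neutral occupancy agrees with the model's detection probability", {
  # loop-closer between the generator and the fitting stage
  set.seed(7)
  pv <- rlnorm(40, 0, 1); pv <- pv / sum(pv); names(pv) <- paste0("t", 1:40)
  depth <- 500; m <- 0.01; n_s <- 400
  cc <- sample_neutral_community(pv, n_s, depth, m, seed = 8)
  occ <- rowMeans(cc > 0)
  pred <- pcgpipe:::detect_prob(pv, depth * m,
                                pcgpipe:::depth_bins(colSums(cc)))
  se <- sqrt(pred * (1 - pred) / n_s)
  expect_true(all(abs(occ - pred) <= 4 * se + 0.01))
})
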