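test_that("predicted occupancy honours its limits and symmetry", {
  expect_equal(predicted_occupancy(0, N = 100, m = 0.5), 0)
  expect_equal(predicted_occupancy(1, N = 100, m = 0.5), 1)
  expect_equal(predicted_occupancy(1e-12, N = 1000, m = 0.1), 0,
               tolerance = 1e-6)
  expect_equal(predicted_occupancy(0.3, N = 100, m = 0.5, d = 0), 1)
  # Beta(5, 5) is symmetric about 1/2
  expect_equal(predicted_occupancy(0.5, N = 20, m = 0.5, d = 0.5), 0.5)
  # monotone increasing in p
  p <- seq(0.01, 0.99, by = 0.01)
  occ <- predicted_occupancy_vec <- vapply(p, predicted_occupancy, 0,
                                           N = 500, m = 0.02, d = 1 / 500)
  expect_true(all(diff(occ) >= 0))
})

test_that("predicted occupancy matches Monte-Carlo Beta sampling", {
  set.seed(10)
  for (case in list(c(p = 0.05, Nm = 5, d = 0.01),
                    c(p = 0.3, Nm = 50, d = 0.002),
                    c(p = 0.01, Nm = 1, d = 0.05))) {
    n_mc <- 40000
    x <- rbeta(n_mc, case["Nm"] * case["p"], case["Nm"] * (1 - case["p"]))
    mc <- mean(x > case["d"])
    an <- predicted_occupancy(case[["p"]], N = 100, m = case[["Nm"]] / 100,
                              d = case[["d"]])
    se <- sqrt(mc * (1 - mc) / n_mc)
    expect_lt(abs(mc - an), 3 * se + 1e-4)
  }
})

test_that("the migration parameter is recovered from simulated data", {
  set.seed(21)
  pv <- rlnorm(150, 0, 2); pv <- pv / sum(pv); names(pv) <- paste0("t", 1:150)
  m_true <- 0.1
  cc <- sample_neutral_community(pv, 150, 1500, m_true, seed = 22)
  fit <- sloan_fit(cc, seed = 23)
  expect_lt(abs(fit$m_hat - m_true), 0.03)
  expect_identical(fit$verdict, "neutral")
  expect_true(all(fit$per_taxon$predicted >= 0 & fit$per_taxon$predicted <= 1))
  # calls are consistent with the reported bands
  resid <- fit$per_taxon$occupancy - fit$per_taxon$predicted
  expect_identical(fit$per_taxon$call == "above", resid > fit$per_taxon$band_hi)
  expect_identical(fit$per_taxon$call == "below", resid < fit$per_taxon$band_lo)
})

test_that("sloan_fit is deterministic given its seed", {
  ds <- generate_scenario(2, "A", seed = 4)
  f1 <- sloan_fit(ds$table, seed = 9)
  f2 <- sloan_fit(ds$table, seed = 9)
  expect_identical(f1$per_taxon, f2$per_taxon)
  expect_identical(f1$verdict, f2$verdict)
})

test_that("refit_excluding nothing reproduces the original fit", {
  ds <- generate_scenario(2, "A", seed = 5)
  f <- sloan_fit(ds$table, seed = 1)
  f0 <- refit_excluding(ds$table, character(0), seed = 1)
  expect_equal(f0$m_hat, f$m_hat)
  expect_identical(f0$verdict, f$verdict)
})

test_that("excluding down to fewer than 5 taxa is undecidable", {
  ds <- generate_scenario(2, "A", seed = 6)
  drop <- rownames(ds$table)[-(1:3)]
  f <- refit_excluding(ds$table, drop)
  expect_identical(f$verdict, "undecidable")
})

test_that("preconditions on table size are enforced", {
  tab <- matrix(5L, 3, 10, dimnames = list(paste0("t", 1:3), paste0("s", 1:10)))
  expect_error(sloan_fit(tab), "5 observed taxa")
  tab2 <- matrix(5L, 10, 3, dimnames = list(paste0("t", 1:10), paste0("s", 1:3)))
  expect_error(sloan_fit(tab2), "5 non-empty samples")
})

test_that("model methods behave like a fitted model object", {
  ds <- generate_scenario(2, "A", seed = 7)
  f <- sloan_fit(ds$table, seed = 2)
  expect_named(coef(f), c("m", "Nm"))
  expect_equal(unname(residuals(f)),
               f$per_taxon$occupancy - f$per_taxon$predicted)
  pr <- predict(f, newdata = c(0.001, 0.01, 0.4))
  expect_true(all(diff(pr) > 0))
  sims <- simulate(f, nsim = 2, seed = 3)
  expect_length(sims, 2L)
  expect_equal(dim(sims[[1]]), dim(f$table))
  expect_output(print(f), "verdict")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})

test_that("pooling two disjoint niches is flagged as non-neutral", {
  # two-niche design sampled jointly: the occupancy ceiling at half the
  # samples cannot be reconciled with any single neutral metacommunity once
  # dispersal limitation is mild enough to make occupancies informative
  for (s in 1:3) {
    ds <- generate_scenario(4, "A", params = list(m = 0.005), seed = s)
    pooled <- sloan_fit(ds$table, seed = s)
    expect_false(identical(pooled$verdict, "neutral"))
    # split by the generating niches, each half is neutral again
    n1 <- grepl("^N1_", colnames(ds$table))
    half <- ds$table[, n1]
    half <- half[rowSums(half) > 0, ]
    expect_identical(sloan_fit(half, seed = s)$verdict, "neutral")
  }
})
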