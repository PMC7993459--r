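mk_table <- function(m, taxa = NULL, samples = NULL) {
  taxa <- taxa %||% paste0("t", seq_len(nrow(m)))
  samples <- samples %||% paste0("s", seq_len(ncol(m)))
  dimnames(m) <- list(taxa, samples)
  storage.mode(m) <- "integer"
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("beta distances match hand computations", {
  tab <- mk_table(matrix(c(2, 2, 0, 0, 2, 2), nrow = 3))
  d <- as.matrix(beta_distance(tab, "bray_curtis"))
  expect_equal(d["s1", "s2"], 0.5)  # (2,2,0) vs (0,2,2)
  dj <- as.matrix(beta_distance(tab, "jaccard"))
  expect_equal(dj["s1", "s2"], 2 / 3)  # share 1 of 3 taxa
})

test_that("identical samples are at distance 0, disjoint ones at 1", {
  tab <- mk_table(matrix(c(5, 3, 0, 0, 5, 3, 0, 0, 0, 0, 2, 7), nrow = 4))
  for (met in c("bray_curtis", "jaccard")) {
    d <- as.matrix(beta_distance(tab, met))
    expect_equal(d["s1", "s2"], 0)
    expect_equal(d["s1", "s3"], 1)
  }
})

test_that("all-zero samples are rejected by name", {
  tab <- mk_table(matrix(c(1, 2, 0, 0), nrow = 2))
  expect_error(beta_distance(tab, "bray_curtis"), "s2")
})

test_that("two-block tables are recovered as two classes", {
  set.seed(1)
  block <- function(base) {
    vapply(1:10, function(i) pmax(0L, as.integer(base + rpois(8, 2))), integer(8))
  }
  tab <- mk_table(cbind(block(c(40, 30, 20, 10, 0, 0, 0, 0)),
                        block(c(0, 0, 0, 0, 40, 30, 20, 10))),
                  samples = paste0("s", 1:20))
  d <- beta_distance(tab, "bray_curtis")
  pt <- find_classes(d, table = tab, seed = 1)
  expect_equal(pt$k, 2L)
  expect_equal(length(unique(pt$labels[1:10])), 1L)
  expect_equal(length(unique(pt$labels[11:20])), 1L)
  expect_lte(pt$p_value, 0.05)
  # and the label-permutation statistic is maximal on the true labels
  cs <- class_significance(d, rep(1:2, each = 10), n_perm = 199, seed = 1)
  expect_equal(cs$p_value, 1 / 200)
})

test_that("an exchangeable (all-equal) distance matrix yields a single class", {
  m <- matrix(0.7, 12, 12); diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("s", 1:12)
  pt <- find_classes(stats::as.dist(m), seed = 1)
  expect_equal(pt$k, 1L)
})

test_that("fewer than 4 samples is undecidable, not an error", {
  m <- matrix(0.5, 3, 3); diag(m) <- 0
  pt <- find_classes(stats::as.dist(m))
  expect_identical(pt$status, "undecidable")
  expect_equal(pt$k, 1L)
})

test_that("partitions are invariant to sample order", {
  set.seed(2)
  tab <- mk_table(cbind(matrix(rpois(80, 20), 8, 10),
                        rbind(matrix(0L, 4, 10), matrix(rpois(40, 20), 4, 10))),
                  samples = paste0("s", 1:20))
  tab[tab < 0] <- 0L
  d <- beta_distance(tab, "bray_curtis")
  pt1 <- find_classes(d, table = tab, seed = 5)
  perm <- sample(20)
  tab2 <- tab[, perm]
  pt2 <- find_classes(beta_distance(tab2, "bray_curtis"), table = tab2, seed = 5)
  expect_equal(pt1$k, pt2$k)
  expect_identical(pt1$labels[colnames(tab)], pt2$labels[colnames(tab)])
})

test_that("the permutation p-value respects the statistic's sign", {
  set.seed(3)
  m <- matrix(runif(100, 0.4, 0.6), 10, 10); m <- (m + t(m)) / 2; diag(m) <- 0
  d <- stats::as.dist(m)
  # labels chosen to make within-class distances larger than between
  lab <- rep(1:2, 5)
  res <- class_significance(d, lab, n_perm = 199, seed = 4)
  if (res$statistic <= 0) expect_gt(res$p_value, 0.5)
  expect_error(class_significance(d, rep(1, 10)), "2 classes")
})
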