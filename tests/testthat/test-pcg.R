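test_that("pairwise identity matches direct computation and validates input", {
  s <- c(a = "ACGT", b = "ACGA", c = "ACGT")
  idm <- pairwise_identity(s)
  expect_equal(idm["a", "b"], 0.75)
  expect_equal(idm["a", "c"], 1)
  expect_true(isSymmetric(idm))
  expect_error(pairwise_identity(c(a = "ACGT", b = "ACG")), "mismatch")
  expect_error(pairwise_identity(c("ACGT", "ACGA")), "names")
})

test_that("identity of simulated sequences matches the JC expectation", {
  d <- 0.3
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
  s <- evolve_sequences(tr, length = 1000, seed = 77)
  obs <- pairwise_identity(s)["a", "b"]
  expected <- jc_expected_identity(d)
  se <- sqrt(expected * (1 - expected) / 1000)
  expect_lt(abs(obs - expected), 3 * se)
})

test_that("threshold 1.0 clusters are exact-duplicate groups", {
  s <- c(x = "AAAA", y = "AAAA", z = "AAAT")
  expect_identical(cluster_at_threshold(s, 1.0),
                   list(c("x", "y"), "z"))
})

test_that("clustering matches a brute-force complete-linkage oracle", {
  tr <- random_test_tree(6, seed = 31)
  tr <- scale_tree_height(tr, 0.3)
  s <- evolve_sequences(tr, length = 300, seed = 32)
  idm <- pairwise_identity(s)
  for (t in c(1.0, 0.99, 0.97, 0.95, 0.9, 0.85, 0.75, 0.6)) {
    expect_identical(canon_partition(cluster_at_threshold(idm, t)),
                     canon_partition(oracle_complete_linkage(idm, t)),
                     label = paste("threshold", t))
  }
})

test_that("clustering is invariant to input order", {
  fx <- fig1_fixture("A", k_esv = 2)
  s <- fx$sequences
  set.seed(5)
  expect_identical(cluster_at_threshold(s, 0.97),
                   cluster_at_threshold(s[sample(length(s))], 0.97))
})

test_that("pcg_search enforces its preconditions", {
  fx <- fig1_fixture("A")
  tab <- matrix(1L, 4, 3, dimnames = list(c("SA", "SB", "SC", "SD"),
                                          paste0("s", 1:3)))
  expect_error(pcg_search(fx$sequences, tab, thresholds = c(0.9, 0.97)),
               "descending")
  tab2 <- tab[1:3, ]
  expect_error(pcg_search(fx$sequences, tab2), "SD")
})

test_that("PCGs are disjoint, ubiquitous, and order-invariant", {
  ds <- generate_scenario(1, "A", seed = 21)
  res <- pcg_search(ds$sequences, ds$table)
  members <- unlist(lapply(res$pcgs, `[[`, "members"))
  expect_false(anyDuplicated(members) > 0)
  for (p in res$pcgs) {
    expect_true(all(colSums(ds$table[p$members, , drop = FALSE]) >= 1))
    expect_true(all(p$per_sample_presence))
  }
  expect_setequal(c(members, res$residual), rownames(ds$table))
  # permuting sequence order changes nothing
  set.seed(1)
  perm <- sample(length(ds$sequences))
  res2 <- pcg_search(ds$sequences[perm], ds$table)
  expect_identical(lapply(res$pcgs, `[[`, "members"),
                   lapply(res2$pcgs, `[[`, "members"))
})

test_that("coarsening the ladder merges but never splits PCG membership", {
  ds <- generate_scenario(4, "A", seed = 8)
  full <- pcg_search(ds$sequences, ds$table,
                     thresholds = c(1, 0.99, 0.97, 0.95, 0.92, 0.90))
  coarse <- pcg_search(ds$sequences, ds$table, thresholds = c(1, 0.97, 0.92))
  for (p in full$pcgs) {
    holder <- vapply(coarse$pcgs, function(q) all(p$members %in% q$members),
                     TRUE)
    expect_equal(sum(holder), 1L)
  }
})

test_that("a single-class partition reproduces the pooled search", {
  ds <- generate_scenario(2, "A", seed = 9)
  lab <- setNames(rep(1L, ncol(ds$table)), colnames(ds$table))
  per <- pcg_per_class(ds$sequences, ds$table, lab)
  pooled <- pcg_search(ds$sequences, ds$table)
  expect_identical(lapply(per[["1"]]$pcgs, `[[`, "members"),
                   lapply(pooled$pcgs, `[[`, "members"))
})

test_that("class-wise PCGs are robust to halving the class (subsampling)", {
  ok <- 0
  for (s in 1:10) {
    ds <- generate_scenario(2, "A", seed = 30 + s)
    ref <- pcg_search(ds$sequences, ds$table)
    set.seed(s)
    half <- sample(colnames(ds$table), ncol(ds$table) %/% 2)
    sub <- ds$table[, half]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    res <- pcg_search(ds$sequences[rownames(sub)], sub)
    same <- length(res$pcgs) == length(ref$pcgs) &&
      all(vapply(seq_along(ref$pcgs), function(i) {
        setequal(unique(sub("_.*", "", ref$pcgs[[i]]$members)),
                 unique(sub("_.*", "", res$pcgs[[i]]$members))) &&
          ref$pcgs[[i]]$threshold == res$pcgs[[i]]$threshold
      }, TRUE))
    ok <- ok + same
  }
  expect_gte(ok, 9)
})

test_that("tiny classes are flagged unreliable but still computed", {
  fx <- fig1_fixture("A")
  tab <- matrix(3L, 4, 3, dimnames = list(c("SA", "SB", "SC", "SD"),
                                          paste0("s", 1:3)))
  lab <- setNames(c(1L, 1L, 2L), colnames(tab))
  res <- pcg_per_class(fx$sequences, tab, lab)
  expect_true(isTRUE(attr(res[["2"]], "unreliable")))
  expect_gt(length(res[["2"]]$pcgs), 0)
})
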