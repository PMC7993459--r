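#' Beta-diversity distances between samples
#'
#' Bray--Curtis on relative abundances or Jaccard on presence/absence,
#' computed with [vegan::vegdist()]. Distances are in \[0, 1\].
#'
#' @param table integer count matrix (taxa x samples), >= 2 samples.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return a [stats::dist] over samples with attribute `metric`.
#' @export
beta_distance <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  validate_abundance(table)
  if (ncol(table) < 2L) stop_pcg("need at least 2 samples")
  zero <- colnames(table)[colSums(table) == 0]
  if (length(zero)) stop_pcg("all-zero sample(s): ", paste(zero, collapse = ", "))
  comm <- t(table)  # vegan wants samples as rows
  d <- if (metric == "bray_curtis") {
    vegan::vegdist(comm / rowSums(comm), method = "bray")
  } else {
    vegan::vegdist(comm, method = "jaccard", binary = TRUE)
  }
  attr(d, "metric") <- metric
  d
}

#' Discover community classes from a distance matrix
#'
#' Hierarchical clustering (average linkage by default); the number of
#' classes is the `k` maximizing the mean silhouette width over `k_range`,
#' retained only if the within/between permutation test
#' ([class_significance()]) is significant at `alpha` — otherwise a single
#' class is returned. Fewer than 4 samples cannot support class discovery
#' and yield status `"undecidable"` with `k = 1`.
#'
#' @param dist a [stats::dist] over samples (e.g. from [beta_distance()]).
#' @param k_range candidate class numbers (default `2:8`, clipped to
#'   `n - 1`).
#' @param linkage linkage method for [stats::hclust()].
#' @param n_perm permutations for the label-permutation significance test
#'   (used when no `table` is supplied).
#' @param alpha significance level for retaining `k > 1`.
#' @param seed integer seed (null models).
#' @param table optional count matrix (taxa x samples) behind `dist`. When
#'   given, significance is judged against a *taxon-shuffle* null: each
#'   taxon's counts are independently permuted across samples (per-taxon
#'   abundance and occupancy preserved, sample classes destroyed), the whole
#'   cluster-selection procedure is re-run, and the observed best silhouette
#'   is compared to the null best silhouettes. Because the null passes
#'   through the same selection step, this is calibrated even though the
#'   partition was chosen from the data — the plain label-permutation test
#'   is not, for data-derived partitions.
#' @param n_null taxon-shuffle null replicates (default 99).
#' @param min_class_size candidate class numbers are only admissible when
#'   every resulting class has at least this many samples (a class must
#'   carry enough samples to reconstruct its metacommunity downstream);
#'   default 10. Applied only in the table-calibrated branch.
#' @return object of class `class_partition`: list with `labels` (named
#'   integer vector; classes renumbered in order of first appearance),
#'   `k`, `silhouette` (mean width, `NA` for k = 1), `p_value`, `status`
#'   (`"ok"` or `"undecidable"`).
#' @export
find_classes <- function(dist, k_range = 2:8, linkage = "average",
                         n_perm = 999, alpha = 0.05, seed = 1,
                         table = NULL, n_null = 99, min_class_size = 10) {
  if (!inherits(dist, "dist")) stop_pcg("dist must be a 'dist' object")
  n <- attr(dist, "Size")
  ids <- attr(dist, "Labels") %||% as.character(seq_len(n))
  one_class <- function(status, p = NA_real_) {
    structure(list(labels = setNames(rep(1L, n), ids), k = 1L,
                   silhouette = NA_real_, p_value = p, status = status),
              class = "class_partition")
  }
  if (n < 4L) return(one_class("undecidable"))
  # canonical sample order for order-invariance of hclust tie-breaking
  ord <- order(ids)
  m <- as.matrix(dist)[ord, ord]
  dd <- stats::as.dist(m)
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (length(k_range) == 0) return(one_class("ok", p = 1))
  best_sil <- function(d) {
    hc <- hclust(d, method = linkage)
    sil <- vapply(k_range, function(k) {
      mean(cluster::silhouette(cutree(hc, k = k), d)[, "sil_width"])
    }, 0)
    list(sil = sil, hc = hc)
  }
  obs <- best_sil(dd)
  if (!is.null(table)) {
    validate_abundance(table)
    valid <- vapply(k_range, function(k) {
      min(tabulate(cutree(obs$hc, k = k))) >= min_class_size
    }, TRUE)
    if (!any(valid)) return(one_class("ok", p = NA_real_))
    metric <- attr(dist, "metric") %||% "bray_curtis"
    tab <- table[, ids[ord], drop = FALSE]
    s_null <- with_seed(seed, {
      vapply(seq_len(n_null), function(b) {
        shuf <- tab
        for (i in seq_len(nrow(shuf))) {
          shuf[i, ] <- shuf[i, sample.int(ncol(shuf))]
        }
        keep <- colSums(shuf) > 0
        if (sum(keep) < 4L) return(rep(NA_real_, length(k_range)))
        ksub <- k_range[k_range <= sum(keep) - 1L]
        dn <- beta_distance(shuf[, keep, drop = FALSE], metric = metric)
        out <- rep(NA_real_, length(k_range))
        hcn <- hclust(dn, method = linkage)
        out[k_range %in% ksub] <- vapply(ksub, function(k) {
          mean(cluster::silhouette(cutree(hcn, k = k), dn)[, "sil_width"])
        }, 0)
        out
      }, numeric(length(k_range)))
    })
    if (is.null(dim(s_null))) s_null <- matrix(s_null, nrow = 1L)
    null_mean <- rowMeans(s_null, na.rm = TRUE)
    gap <- obs$sil - null_mean
    gap[!valid] <- -Inf
    k_best <- k_range[which.max(gap)]
    gap_null <- apply((s_null - null_mean)[valid, , drop = FALSE], 2,
                      max, na.rm = TRUE)
    pval <- (1 + sum(gap_null >= max(gap))) / (1 + ncol(s_null))
  } else {
    k_best <- k_range[which.max(obs$sil)]
    labels0 <- cutree(obs$hc, k = k_best)
    pval <- class_significance(dd, labels0, n_perm = n_perm,
                               seed = seed)$p_value
  }
  labels <- cutree(obs$hc, k = k_best)
  if (pval > alpha) return(one_class("ok", p = pval))
  # renumber classes by first appearance in canonical id order, then
  # return in the caller's sample order
  labels <- match(labels, unique(labels))
  labels <- setNames(labels[match(ids, ids[ord])], ids)
  structure(list(labels = labels, k = k_best,
                 silhouette = max(obs$sil), p_value = pval, status = "ok"),
            class = "class_partition")
}

#' @export
print.class_partition <- function(x, ...) {
  cat(sprintf("Community classes: k = %d (%s)\n", x$k, x$status))
  if (!is.na(x$p_value)) cat(sprintf("  within/between permutation p = %.4g\n", x$p_value))
  if (!is.na(x$silhouette)) cat(sprintf("  mean silhouette = %.3f\n", x$silhouette))
  print(table(x$labels))
  invisible(x)
}

#' Permutation test for class separation
#'
#' Tests whether between-class distances exceed within-class distances:
#' statistic = mean between-class distance minus mean within-class distance;
#' the null permutes class labels across samples. The p-value is
#' `(1 + #\{permuted >= observed\}) / (1 + n_perm)`. Classes of size one
#' contribute no within-class pairs; if every class is a singleton the
#' statistic uses between-class terms against the overall mean and the
#' result is flagged.
#'
#' @param dist a [stats::dist] over samples.
#' @param labels class labels (vector along samples, or named).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `statistic`, `p_value`, `n_perm`,
#'   `singleton_classes` flag.
#' @export
class_significance <- function(dist, labels, n_perm = 999, seed = 1) {
  if (!inherits(dist, "dist")) stop_pcg("dist must be a 'dist' object")
  check_number(n_perm, "n_perm", lower = 99)
  n <- attr(dist, "Size")
  if (length(labels) != n) stop_pcg("labels must match the number of samples")
  if (length(unique(labels)) < 2L) stop_pcg("need at least 2 classes")
  m <- as.matrix(dist)
  stat <- function(lab) {
    same <- outer(lab, lab, "==") & upper.tri(m)
    diff <- (!outer(lab, lab, "==")) & upper.tri(m)
    w <- if (any(same)) mean(m[same]) else mean(m[upper.tri(m)])
    mean(m[diff]) - w
  }
  obs <- stat(labels)
  singleton <- any(tabulate(match(labels, unique(labels))) == 1L)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) stat(sample(labels)) >= obs, TRUE))
  })
  list(statistic = obs, p_value = (1 + exceed) / (1 + n_perm),
       n_perm = n_perm, singleton_classes = singleton)
}
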