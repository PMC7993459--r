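#' Pairwise identity matrix of aligned sequences
#'
#' Fraction of matching positions between every pair of equal-length
#' (pre-aligned, ungapped) sequences.
#'
#' @param seqs named character vector of equal-length sequences.
#' @return symmetric matrix of identities in \[0, 1\] with unit diagonal.
#' @export
pairwise_identity <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop_pcg("sequences must have unique names")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    ref <- names(seqs)[1L]
    bad <- names(seqs)[lens != lens[1L]][1L]
    stop_pcg("sequence length mismatch between '", ref, "' (", lens[1L],
             ") and '", bad, "' (", nchar(seqs[bad]), ")")
  }
  n <- length(seqs)
  chm <- vapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]],
                character(lens[1L]))
  out <- matrix(1, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        idt <- mean(chm[, i] == chm[, j])
        out[i, j] <- idt
        out[j, i] <- idt
      }
    }
  }
  out
}

#' Cluster sequences at an identity threshold
#'
#' Complete-linkage hierarchical clustering on `1 - identity`, cut so that
#' every within-cluster pair has identity at least `t` (the threshold is a
#' guaranteed identity floor). Input order does not matter: sequences are
#' processed in lexicographic id order.
#'
#' @param seqs named character vector of aligned sequences, or a precomputed
#'   identity matrix from [pairwise_identity()].
#' @param t identity threshold in (0, 1\].
#' @return list of character vectors (the partition), clusters ordered by
#'   their first member id.
#' @export
cluster_at_threshold <- function(seqs, t) {
  check_number(t, "t", lower = 1e-9, upper = 1)
  idm <- if (is.matrix(seqs)) seqs else pairwise_identity(seqs)
  ids <- sort(rownames(idm))
  idm <- idm[ids, ids, drop = FALSE]
  if (length(ids) == 1L) return(list(ids))
  d <- stats::as.dist(1 - idm)
  hc <- hclust(d, method = "complete")
  grp <- cutree(hc, h = 1 - t + 1e-9)
  parts <- unname(split(ids, grp))
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[[`, "", 1L))]
}

#' Determine Phylogenetic Core Groups by descending the identity ladder
#'
#' Implements the PCG determination procedure: cluster the not-yet-assigned
#' sequences at the highest identity threshold; every cluster whose summed
#' member counts reach `min_count` in *every* sample becomes a PCG fixed at
#' that threshold and its members are removed; descend to the next threshold
#' and repeat. Sequences never captured are reported as the non-core
#' residual (non-phylogenetic-core populations).
#'
#' @param seqs named character vector of aligned sequences (ids must all be
#'   rows of `table`).
#' @param table integer count matrix (taxa x samples).
#' @param thresholds strictly descending identity ladder (default
#'   `c(1, 0.99, 0.97, 0.95, 0.92, 0.90)`).
#' @param min_count reads required in a sample to count as present
#'   (default 1).
#' @return object of class `pcg_set`: list with `pcgs` (list of PCG records:
#'   `pcg_id`, `threshold`, `members`, `representative`,
#'   `per_sample_presence`), `residual` (unassigned sequence ids),
#'   `thresholds`.
#' @export
pcg_search <- function(seqs, table,
                       thresholds = c(1, 0.99, 0.97, 0.95, 0.92, 0.90),
                       min_count = 1) {
  validate_abundance(table)
  if (length(seqs) == 0 || ncol(table) == 0) {
    stop_pcg("need at least one sequence and one sample")
  }
  if (any(diff(thresholds) >= 0)) {
    stop_pcg("thresholds must be strictly descending")
  }
  check_number(min_count, "min_count", lower = 1)
  missing <- setdiff(names(seqs), rownames(table))
  if (length(missing)) {
    stop_pcg("sequence id(s) absent from the table: ",
             paste(missing, collapse = ", "))
  }
  idm <- pairwise_identity(seqs)
  unassigned <- sort(names(seqs))
  pcgs <- list()
  for (t in thresholds) {
    if (length(unassigned) == 0L) break
    parts <- cluster_at_threshold(idm[unassigned, unassigned, drop = FALSE], t)
    for (members in parts) {
      counts <- table[members, , drop = FALSE]
      per_sample <- colSums(counts) >= min_count
      if (all(per_sample)) {
        pcgs[[length(pcgs) + 1L]] <- list(
          pcg_id = paste0("PCG", length(pcgs) + 1L),
          threshold = t,
          members = members,
          representative = members[1L],
          per_sample_presence = per_sample
        )
        unassigned <- setdiff(unassigned, members)
      }
    }
  }
  structure(list(pcgs = pcgs, residual = unassigned, thresholds = thresholds,
                 min_count = min_count),
            class = "pcg_set")
}

#' @export
print.pcg_set <- function(x, ...) {
  cat(sprintf("PCG search: %d PCG(s), %d non-core sequence(s)\n",
              length(x$pcgs), length(x$residual)))
  for (p in x$pcgs) {
    cat(sprintf("  %s @ %.2f: %s\n", p$pcg_id, p$threshold,
                paste(p$members, collapse = ", ")))
  }
  if (length(x$residual)) {
    cat("  non-core:", paste(x$residual, collapse = ", "), "\n")
  }
  invisible(x)
}

#' PCG determination within each community class
#'
#' Runs [pcg_search()] independently on each class's sample subset (the
#' class-wise search is the robust variant: a class's core is not diluted by
#' samples of other classes). Sequences unobserved within a class are left
#' out of that class's search. Classes with fewer than 2 samples are
#' computed but flagged unreliable.
#'
#' @param seqs named character vector of aligned sequences.
#' @param table integer count matrix (taxa x samples).
#' @param partition a `class_partition` from [find_classes()], or a named
#'   vector of class labels along samples.
#' @inheritParams pcg_search
#' @return named list (one entry per class) of `pcg_set` objects; entries
#'   carry an `unreliable` attribute when based on fewer than 2 samples.
#' @export
pcg_per_class <- function(seqs, table, partition,
                          thresholds = c(1, 0.99, 0.97, 0.95, 0.92, 0.90),
                          min_count = 1) {
  labels <- if (inherits(partition, "class_partition")) partition$labels
            else partition
  validate_abundance(table)
  if (is.null(names(labels))) {
    if (length(labels) != ncol(table)) {
      stop_pcg("partition must cover the table's samples")
    }
    names(labels) <- colnames(table)
  }
  if (!all(colnames(table) %in% names(labels))) {
    stop_pcg("partition must cover the table's samples")
  }
  out <- list()
  for (cl in sort(unique(labels))) {
    cols <- colnames(table)[labels[colnames(table)] == cl]
    sub <- table[, cols, drop = FALSE]
    present <- rownames(sub)[rowSums(sub) > 0]
    res <- pcg_search(seqs[intersect(names(seqs), present)], sub,
                      thresholds = thresholds, min_count = min_count)
    if (length(cols) < 2L) attr(res, "unreliable") <- TRUE
    out[[as.character(cl)]] <- res
  }
  out
}
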