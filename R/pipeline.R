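#' Map pipeline evidence to a niche-type label
#'
#' The decision table combining class existence, the neutral-model verdict,
#' and the phylogenetic dispersion call:
#'
#' | verdict            | dispersion               | label                    |
#' |--------------------|--------------------------|--------------------------|
#' | neutral            | clustered                | `neutral_phylo_niche`    |
#' | neutral            | overdispersed            | `neutral_nonphylo_niche` |
#' | subset_departure   | (refit neutral = TRUE)   | `mixed_neutral_selective`|
#' | global_departure   | clustered                | `selective_phylo_niche`  |
#' | global_departure   | overdispersed or random  | `other_interactions`     |
#' | anything else      |                          | `undecidable`            |
#'
#' The label is a pure function of its inputs.
#'
#' @param classes_exist were community classes found (k > 1)?
#' @param verdict neutral-model verdict (`neutral`, `subset_departure`,
#'   `global_departure`, `undecidable`).
#' @param dispersion a dispersion call (`clustered`, `overdispersed`,
#'   `random`, `undefined`) or a `dispersion_result`.
#' @param refit_neutral for subset departures: did refitting without the
#'   departing taxa give a neutral verdict?
#' @return object of class `niche_call`: list with `label` and `evidence`.
#' @export
classify_niche <- function(classes_exist, verdict, dispersion,
                           refit_neutral = NULL) {
  check_flag(classes_exist, "classes_exist")
  if (inherits(dispersion, "dispersion_result")) dispersion <- dispersion$call
  label <- if (verdict == "neutral" && dispersion == "clustered") {
    "neutral_phylo_niche"
  } else if (verdict == "neutral" && dispersion == "overdispersed") {
    "neutral_nonphylo_niche"
  } else if (verdict == "subset_departure" && isTRUE(refit_neutral)) {
    "mixed_neutral_selective"
  } else if (verdict == "global_departure" && dispersion == "clustered") {
    "selective_phylo_niche"
  } else if (verdict == "global_departure" &&
             dispersion %in% c("overdispersed", "random")) {
    "other_interactions"
  } else {
    "undecidable"
  }
  structure(list(label = label,
                 evidence = list(classes_exist = classes_exist,
                                 verdict = verdict, dispersion = dispersion,
                                 refit_neutral = refit_neutral)),
            class = "niche_call")
}

#' @export
print.niche_call <- function(x, ...) {
  ev <- x$evidence
  cat(sprintf("Niche call: %s\n", x$label))
  cat(sprintf("  classes: %s  verdict: %s  dispersion: %s%s\n",
              ev$classes_exist, ev$verdict, ev$dispersion,
              if (!is.null(ev$refit_neutral)) {
                paste0("  refit neutral: ", ev$refit_neutral)
              } else ""))
  invisible(x)
}

#' Run the full PCG detection pipeline
#'
#' Stages, in order: beta-diversity distances and community-class discovery;
#' per-class neutral-model fit (whole dataset when a single class); for
#' subset departures, an automatic refit excluding the departing taxa — if
#' the refit is *still* non-neutral the departure is not attributable to a
#' subset and the verdict is escalated to `global_departure`; per-class
#' nearest-taxon dispersion against the full tree-tip pool; per-class PCG
#' determination; and the final niche-type classification per class.
#'
#' @param table integer count matrix (taxa x samples).
#' @param seqs named character vector of aligned sequences (ids = table
#'   taxa).
#' @param tree phylo object whose tips include all table taxa (extra tips
#'   act as the regional pool for the dispersion null).
#' @param config named list overriding defaults: `metric`
#'   (`"bray_curtis"`), `k_max` (8), `n_perm` (999), `alpha` (0.05), `ci`
#'   (0.95), `n_sim` (150), `thresholds` (identity ladder), `min_count`
#'   (1), `n_null` (999), `escalate` (TRUE).
#' @param seed integer master seed.
#' @return object of class `pcg_report`: list with `partition`, per-class
#'   `fits`, `refits`, `dispersion`, `pcgs`, `calls`, plus `config`.
#' @export
run_pipeline <- function(table, seqs, tree, config = list(), seed = 1) {
  defaults <- list(metric = "jaccard", k_max = 8L, n_perm = 999L,
                   alpha = 0.05, ci = 0.95, n_sim = 150L,
                   thresholds = c(1, 0.99, 0.97, 0.95, 0.92, 0.90),
                   min_count = 1L, n_null = 999L, escalate = TRUE)
  cfg <- utils::modifyList(defaults, config)
  validate_abundance(table)
  miss_tree <- setdiff(rownames(table), tree$tip.label)
  miss_seq <- setdiff(rownames(table), names(seqs))
  extra_seq <- setdiff(names(seqs), rownames(table))
  if (length(miss_tree)) {
    stop_pcg("taxa absent from tree: ", paste(miss_tree, collapse = ", "))
  }
  if (length(miss_seq) || length(extra_seq)) {
    stop_pcg("sequence/table id mismatch; missing: ",
             paste(miss_seq, collapse = ", "), "; extra: ",
             paste(extra_seq, collapse = ", "))
  }

  d <- beta_distance(table, metric = cfg$metric)
  partition <- find_classes(d, k_range = 2:cfg$k_max, n_perm = cfg$n_perm,
                            alpha = cfg$alpha, table = table,
                            seed = derive_seed(seed, "classes"))
  labels <- partition$labels
  classes <- sort(unique(labels))
  dmat <- ape::cophenetic.phylo(tree)
  pool <- rownames(dmat)

  fits <- refits <- dispersion <- calls <- list()
  for (cl in classes) {
    cl_id <- as.character(cl)
    cols <- names(labels)[labels == cl]
    sub <- table[, cols, drop = FALSE]
    fit <- tryCatch(
      sloan_fit(sub, ci = cfg$ci, n_sim = cfg$n_sim,
                seed = derive_seed(seed, "neutral") + cl),
      error = function(e) {
        structure(list(verdict = "undecidable", reason = conditionMessage(e)),
                  class = "sloan_fit")
      }
    )
    verdict <- fit$verdict
    refit_neutral <- NULL
    refit <- NULL
    if (identical(verdict, "subset_departure")) {
      dep <- fit$per_taxon$taxon[fit$per_taxon$call != "neutral"]
      refit <- refit_excluding(fit, dep, ci = cfg$ci, n_sim = cfg$n_sim,
                               seed = derive_seed(seed, "neutral") + cl + 499L)
      refit_neutral <- identical(refit$verdict, "neutral")
      if (cfg$escalate && identical(refit$verdict, "global_departure")) {
        # departure not attributable to the called subset: community-wide
        verdict <- "global_departure"
        refit_neutral <- NULL
      }
      if (cfg$escalate && identical(refit$verdict, "subset_departure")) {
        verdict <- "global_departure"
        refit_neutral <- NULL
      }
    }
    present <- rownames(sub)[rowSums(sub) > 0]
    disp <- if (length(present) >= 2 && length(present) < length(pool)) {
      nti(present, dmat, pool = pool, n_null = cfg$n_null,
          seed = derive_seed(seed, "nti") + cl, exhaustive = FALSE)
    } else {
      dispersion_result(NA_real_, c(0, 0), method = "degenerate")
    }
    fits[[cl_id]] <- fit
    refits[[cl_id]] <- refit
    dispersion[[cl_id]] <- disp
    calls[[cl_id]] <- classify_niche(partition$k > 1L, verdict, disp$call,
                                     refit_neutral)
  }
  pcgs <- pcg_per_class(seqs, table, partition,
                        thresholds = cfg$thresholds,
                        min_count = cfg$min_count)
  structure(list(partition = partition, fits = fits, refits = refits,
                 dispersion = dispersion, pcgs = pcgs, calls = calls,
                 config = cfg, seed = seed),
            class = "pcg_report")
}

#' @export
print.pcg_report <- function(x, ...) {
  cat("== PCG pipeline report ==\n")
  print(x$partition)
  for (cl in names(x$calls)) {
    cat(sprintf("\n-- class %s --\n", cl))
    print(x$fits[[cl]])
    print(x$dispersion[[cl]])
    print(x$calls[[cl]])
    print(x$pcgs[[cl]])
  }
  invisible(x)
}
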