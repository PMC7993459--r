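#' Predicted occupancy under the neutral community model
#'
#' In the dispersal-limited neutral model, the local relative abundance of a
#' taxon with metacommunity abundance `p` follows
#' `Beta(N m p, N m (1 - p))`. Its predicted occupancy at detection limit `d`
#' is the survival function of that Beta at `d`. Limits: `p <= 0` gives 0,
#' `p >= 1` gives 1, and `d = 0` gives 1.
#'
#' @param p metacommunity relative abundance(s) in \[0, 1\].
#' @param N sample size (reads per sample).
#' @param m migration parameter in (0, 1\].
#' @param d detection limit on relative abundance (default one read, `1/N`).
#' @return occupancy probability in \[0, 1\], monotone increasing in `p`.
#' @examples
#' predicted_occupancy(0.5, N = 20, m = 0.5, d = 0.5)  # Beta(5, 5): 0.5
#' @export
predicted_occupancy <- function(p, N, m, d = 1 / N) {
  check_number(N, "N", lower = 1)
  check_number(m, "m", lower = 1e-12, upper = 1)
  check_number(d, "d", lower = 0, upper = 1 - 1e-12)
  out <- numeric(length(p))
  out[p <= 0] <- 0
  out[p >= 1] <- 1
  mid <- which(p > 0 & p < 1)
  if (length(mid)) {
    if (d == 0) {
      out[mid] <- 1
    } else {
      out[mid] <- pbeta(d, N * m * p[mid], N * m * (1 - p[mid]),
                        lower.tail = FALSE)
    }
  }
  out
}

# ---- internal machinery of the occupancy fit -------------------------------

# Collapse per-sample depths into at most `max_bins` (depth, weight) bins so
# the Beta-binomial detection probability can average over unequal depths
# cheaply.
depth_bins <- function(depths, max_bins = 8L) {
  u <- sort(unique(depths))
  if (length(u) <= max_bins) {
    w <- as.numeric(table(factor(depths, levels = u))) / length(depths)
    return(list(n = u, w = w))
  }
  qs <- quantile(depths, probs = (seq_len(max_bins) - 0.5) / max_bins, type = 1)
  list(n = as.numeric(qs), w = rep(1 / max_bins, max_bins))
}

# Detection probability P(count >= 1) for a taxon with Beta(a, b) local
# relative abundance read-sampled at the binned depths: one minus the
# Beta-binomial zero mass, averaged over depth bins.
detect_prob <- function(p, Nm, bins) {
  a <- Nm * p
  b <- Nm * (1 - p)
  absent <- 0
  for (j in seq_along(bins$n)) {
    absent <- absent + bins$w[j] * exp(lbeta(a, b + bins$n[j]) - lbeta(a, b))
  }
  out <- 1 - absent
  out[p <= 0] <- 0
  out[p >= 1] <- 1
  out
}

# Least-squares fit of the composite parameter Nm (depth x migration) to the
# observed occupancy-abundance cloud. The SSE profile over Nm need not be
# unimodal, so a log-spaced grid brackets the global minimum before the
# local search.
fit_Nm <- function(p, o, bins) {
  upper <- max(bins$n)
  sse <- function(Nm) sum((o - detect_prob(p, Nm, bins))^2)
  grid <- exp(seq(log(1e-4), log(upper), length.out = 50))
  vals <- vapply(grid, sse, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  optimize(sse, c(lo, hi))$minimum
}

# One neutral resimulation of the whole table (exact Dirichlet-multinomial
# via normalized gammas), refit, and residuals — the building block of the
# neutral envelope. Returns NULL if fewer than 5 pseudo-taxa are detected.
neutral_resim <- function(pv, Nm, depths, n_s, bins) {
  K <- length(pv)
  g <- matrix(rgamma(K * n_s, shape = Nm * pv), K, n_s)
  empty <- colSums(g) == 0
  if (any(empty)) g[which.max(pv), empty] <- 1
  x <- sweep(g, 2, colSums(g), "/")
  cnt <- matrix(0L, K, n_s)
  for (s in seq_len(n_s)) {
    cnt[, s] <- as.integer(rmultinom(1L, depths[s], x[, s]))
  }
  det <- cnt > 0L
  ostar <- rowMeans(det)
  keep <- ostar > 0
  if (sum(keep) < 5L) return(NULL)
  pstar <- rowMeans(sweep(cnt, 2, depths, "/"))[keep]
  ostar <- ostar[keep]
  Nmstar <- fit_Nm(pstar, ostar, bins)
  list(p = pstar, resid = ostar - detect_prob(pstar, Nmstar, bins),
       Nm = Nmstar)
}

# Local quantile band of envelope residuals as a function of log abundance:
# for each of G grid points, quantiles over the nb nearest envelope points.
band_curves <- function(lp, rr, alpha, nb = 200L, G = 40L) {
  gr <- seq(min(lp), max(lp), length.out = G)
  nb <- min(nb, length(lp))
  qlo <- qhi <- numeric(G)
  for (g in seq_len(G)) {
    idx <- order(abs(lp - gr[g]))[seq_len(nb)]
    qlo[g] <- quantile(rr[idx], alpha)
    qhi[g] <- quantile(rr[idx], 1 - alpha)
  }
  list(gr = gr, qlo = qlo, qhi = qhi)
}

band_eval <- function(bc, lp) {
  list(lo = approx(bc$gr, bc$qlo, xout = lp, rule = 2)$y,
       hi = approx(bc$gr, bc$qhi, xout = lp, rule = 2)$y)
}

#' Fit the neutral community model to an abundance table
#'
#' Fits the occupancy--abundance formulation of the neutral model: the
#' migration parameter `m` minimizes the squared distance between observed
#' occupancy frequencies and the model's detection probability (a
#' Beta-binomial survival, averaged over per-sample depths). Each taxon is
#' then called `above`, `below` or `neutral` against a *neutral envelope*:
#' the fitted model is resimulated (`n_sim` full pseudo-datasets, with the
#' plug-in parameters jittered by their estimated sampling uncertainty, so
#' the envelope marginalizes over estimation error), and the pooled pseudo
#' residuals give local quantile bands as a function of observed abundance.
#'
#' The verdict compares the number of departing taxa against the null
#' distribution of that number in the envelope itself: `neutral` when the
#' count is within its 97.5% null quantile, otherwise `subset_departure`
#' when fewer than half of the taxa depart and `global_departure` when at
#' least half do.
#'
#' @param table integer count matrix (taxa x samples); at least 5 samples
#'   and, after removing never-observed taxa, at least 5 taxa. Samples with
#'   zero total are dropped.
#' @param ci level of the per-taxon envelope bands (default 0.95).
#' @param n_sim envelope resimulations (default 150).
#' @param n_pilot pilot resimulations used to estimate the sampling spread
#'   of the fitted migration parameter (default 30).
#' @param seed integer seed for the envelope.
#' @return an object of class `sloan_fit`: list with elements `m_hat`,
#'   `Nm_hat`, `fit_quality` (generalized R^2), `per_taxon` (data.frame with
#'   `p`, `occupancy`, `predicted`, `band_lo`, `band_hi`, `call`), `n_dep`,
#'   `dep_threshold`, `verdict`, `depth`, `n_samples`, `ci`.
#' @seealso [refit_excluding()], [predicted_occupancy()]
#' @export
sloan_fit <- function(table, ci = 0.95, n_sim = 150, n_pilot = 30, seed = 1) {
  validate_abundance(table)
  check_number(ci, "ci", lower = 0.5, upper = 0.999)
  table <- table[, colSums(table) > 0, drop = FALSE]
  table <- trim_zero_taxa(table)
  if (ncol(table) < 5L) stop_pcg("need at least 5 non-empty samples")
  if (nrow(table) < 5L) stop_pcg("need at least 5 observed taxa")
  depths <- colSums(table)
  bins <- depth_bins(depths)
  n_s <- ncol(table)
  K <- nrow(table)
  rel <- sweep(table, 2, depths, "/")
  p <- rowMeans(rel)
  o <- rowMeans(table > 0L)
  se_lp <- apply(rel, 1, sd) / sqrt(n_s) / p  # se of log p-hat (delta method)
  Nm <- fit_Nm(p, o, bins)
  ohat <- detect_prob(p, Nm, bins)
  resid <- o - ohat
  sst <- sum((o - mean(o))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_

  env <- with_seed(seed, {
    pilot <- lapply(seq_len(n_pilot), function(i) {
      neutral_resim(p, Nm, depths, n_s, bins)
    })
    pilot <- pilot[!vapply(pilot, is.null, TRUE)]
    dNm <- if (length(pilot) >= 3L) {
      sd(log(vapply(pilot, `[[`, 0, "Nm")))
    } else 0
    if (!is.finite(dNm)) dNm <- 0
    ps <- rs <- simid <- vector("list", n_sim)
    for (bt in seq_len(n_sim)) {
      pj <- p * exp(rnorm(K, 0, se_lp))
      pj <- pj / sum(pj)
      sm <- neutral_resim(pj, Nm * exp(rnorm(1L, 0, dNm)), depths, n_s, bins)
      if (is.null(sm)) next
      ps[[bt]] <- sm$p
      rs[[bt]] <- sm$resid
      simid[[bt]] <- rep(bt, length(sm$p))
    }
    list(lp = log(unlist(ps)), rr = unlist(rs), sid = unlist(simid))
  })
  if (length(env$rr) < 50L) stop_pcg("neutral envelope failed (too few usable resimulations)")

  alpha <- (1 - ci) / 2
  bc <- band_curves(env$lp, env$rr, alpha)
  be <- band_eval(bc, log(p))
  call <- rep("neutral", K)
  call[resid > be$hi] <- "above"
  call[resid < be$lo] <- "below"

  bs <- band_eval(bc, env$lp)
  ndep_star <- tapply((env$rr > bs$hi) | (env$rr < bs$lo), env$sid, sum)
  dep_threshold <- max(1, quantile(ndep_star, 0.975, type = 1))
  n_dep <- sum(call != "neutral")
  verdict <- if (n_dep <= dep_threshold) {
    "neutral"
  } else if (n_dep / K < 0.5) {
    "subset_departure"
  } else {
    "global_departure"
  }

  structure(list(
    m_hat = Nm / mean(depths),
    Nm_hat = Nm,
    fit_quality = r2,
    per_taxon = data.frame(
      taxon = rownames(table), p = p, occupancy = o, predicted = ohat,
      band_lo = be$lo, band_hi = be$hi, call = call,
      row.names = NULL, stringsAsFactors = FALSE
    ),
    n_dep = n_dep,
    dep_threshold = as.numeric(dep_threshold),
    verdict = verdict,
    depth = mean(depths),
    n_samples = n_s,
    n_taxa = K,
    ci = ci,
    boundary = Nm <= 2e-4 || Nm >= max(bins$n) * (1 - 1e-6),
    excluded = character(0),
    table = table,
    seed = seed
  ), class = "sloan_fit")
}

#' Refit the neutral model after excluding taxa
#'
#' Removes the given taxa (e.g. those called `above`/`below` by
#' [sloan_fit()]) and refits on the reduced table; samples left without
#' reads are dropped. If fewer than 5 taxa remain the result has verdict
#' `"undecidable"`.
#'
#' @param table count matrix (taxa x samples) or a `sloan_fit` object (its
#'   stored table is reused).
#' @param exclude character vector of taxon ids to drop.
#' @param ... passed on to [sloan_fit()].
#' @return a `sloan_fit` object (with `excluded` recording the drop), or an
#'   undecidable stub when too few taxa remain.
#' @export
refit_excluding <- function(table, exclude, ...) {
  if (inherits(table, "sloan_fit")) table <- table$table
  validate_abundance(table)
  keep <- setdiff(rownames(table), exclude)
  reduced <- trim_zero_taxa(table[keep, , drop = FALSE])
  if (nrow(reduced) < 5L) {
    return(structure(list(
      verdict = "undecidable", excluded = exclude,
      reason = "fewer than 5 taxa after exclusion"
    ), class = "sloan_fit"))
  }
  fit <- sloan_fit(reduced, ...)
  fit$excluded <- exclude
  fit
}

# ---- sloan_fit methods -----------------------------------------------------

#' @export
print.sloan_fit <- function(x, ...) {
  cat("Neutral community model fit\n")
  if (identical(x$verdict, "undecidable")) {
    cat("  verdict: undecidable (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  taxa: %d   samples: %d   mean depth: %.0f\n",
              x$n_taxa, x$n_samples, x$depth))
  cat(sprintf("  m-hat: %.4g   (Nm = %.3g)   fit R^2: %.3f\n",
              x$m_hat, x$Nm_hat, x$fit_quality))
  cat(sprintf("  departing taxa: %d (null threshold %g)  ->  verdict: %s\n",
              x$n_dep, x$dep_threshold, x$verdict))
  if (length(x$excluded)) {
    cat("  refit excluding:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.sloan_fit <- function(object, ...) {
  print(object)
  if (!identical(object$verdict, "undecidable")) {
    tab <- table(object$per_taxon$call)
    cat("  calls:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
    dep <- object$per_taxon[object$per_taxon$call != "neutral", , drop = FALSE]
    if (nrow(dep)) {
      cat("  departing:\n")
      print(dep[, c("taxon", "p", "occupancy", "predicted", "call")],
            row.names = FALSE, digits = 3)
    }
  }
  invisible(object)
}

#' @export
coef.sloan_fit <- function(object, ...) c(m = object$m_hat, Nm = object$Nm_hat)

#' Predicted occupancy from a fitted neutral model
#'
#' @param object a `sloan_fit`.
#' @param newdata optional vector of metacommunity relative abundances;
#'   defaults to the fitted taxa.
#' @param ... ignored.
#' @return vector of predicted occupancies.
#' @export
predict.sloan_fit <- function(object, newdata = NULL, ...) {
  p <- newdata %||% object$per_taxon$p
  detect_prob(p, object$Nm_hat, depth_bins(colSums(object$table)))
}

#' @export
residuals.sloan_fit <- function(object, ...) {
  setNames(object$per_taxon$occupancy - object$per_taxon$predicted,
           object$per_taxon$taxon)
}

#' Simulate count tables from a fitted neutral model
#'
#' @param object a `sloan_fit`.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param ... ignored.
#' @return list of integer count matrices of the fitted dimensions.
#' @export
simulate.sloan_fit <- function(object, nsim = 1, seed = 1, ...) {
  depths <- colSums(object$table)
  p <- setNames(object$per_taxon$p, object$per_taxon$taxon)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      cnt <- sample_neutral_community(p / sum(p), length(depths),
                                      round(mean(depths)),
                                      m = min(1, object$m_hat), seed = NULL)
      cnt
    })
  })
}

#' Occupancy--abundance plot of a neutral fit
#'
#' Observed per-taxon occupancy against mean relative abundance (log axis),
#' the fitted neutral expectation, the envelope band, and departing taxa
#' highlighted.
#'
#' @param x a `sloan_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sloan_fit <- function(x, ...) {
  pt <- x$per_taxon
  ord <- order(pt$p)
  plot(pt$p, pt$occupancy, log = "x",
       xlab = "mean relative abundance", ylab = "occupancy",
       pch = 19, col = ifelse(pt$call == "neutral", "grey40",
                              ifelse(pt$call == "above", "firebrick", "royalblue")),
       ylim = c(0, 1), ...)
  polygon(c(pt$p[ord], rev(pt$p[ord])),
          c(pmin(1, pmax(0, pt$predicted[ord] + pt$band_hi[ord])),
            rev(pmin(1, pmax(0, pt$predicted[ord] + pt$band_lo[ord])))),
          col = adjustcolor("grey", 0.3), border = NA)
  lines(pt$p[ord], pt$predicted[ord], lwd = 2)
  legend("topleft", bty = "n", pch = 19,
         col = c("grey40", "firebrick", "royalblue"),
         legend = c("neutral", "above", "below"))
  invisible(x)
}
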