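# FDIST-style F_ST-outlier machinery: a joint (He, F_ST) null cloud from
# the island-model coalescent, kernel-density p-values conditional on He,
# and conditional quantile envelopes.

#' Build the joint (He, F_ST) null distribution
#'
#' Simulates `n_sims` independent SNPs under the island model and summarises
#' each to its (mean He, F_ST) pair.  This cloud is the neutral reference
#' against which observed loci are ranked.
#'
#' @param config an [island_model_config()].
#' @param n_sims number of simulated loci (default 50000; inference needs at
#'   least ~1000).
#' @param seed RNG seed; identical seeds give identical clouds.
#' @return A `null_cloud`: data frame of `(he, fst)` points plus provenance
#'   (`config`, `seed`, `n_sims`).
#' @export
build_null <- function(config, n_sims = 50000L, seed = NULL) {
  stopifnot(inherits(config, "island_model_config"), n_sims >= 1L)
  with_seed(seed, {
    he <- numeric(n_sims); fst <- numeric(n_sims)
    for (i in seq_len(n_sims)) {
      s <- summarize_loci(simulate_island_snp(config))
      he[i] <- s$mean_he; fst[i] <- s$global_fst
    }
    structure(list(points = data.frame(he = he, fst = fst),
                   config = config, seed = seed,
                   n_sims = as.integer(n_sims)),
              class = "null_cloud")
  })
}

# Silverman's rule-of-thumb bandwidth on the He coordinate.
.silverman <- function(x) {
  n <- length(x)
  s <- min(sd(x), diff(quantile(x, c(0.25, 0.75), names = FALSE)) / 1.34)
  if (s <= 0) s <- sd(x)
  if (s <= 0) s <- 1e-3
  0.9 * s * n^(-1 / 5)
}

#' He-conditional kernel-density p-value for an observed (He, F_ST) point
#'
#' Null points are weighted by a Gaussian kernel on their He distance to the
#' observed He (bandwidth by Silverman's rule unless given), and the
#' p-value is the weighted proportion of null F_ST values at least as large
#' as the observed one (upper tail; `tail = "two"` doubles the smaller
#' tail).  Add-one smoothing on the kernel's effective sample size keeps the
#' p-value strictly inside (0, 1): an observation above every comparable
#' null point reports `1 / (n_eff + 1)`.
#'
#' @param observed numeric `c(he, fst)` (or a `summary_stats` object).
#' @param null a [build_null()] cloud.
#' @param bandwidth `"silverman"` or a positive number.
#' @param tail `"upper"` (default) or `"two"`.
#' @return list with `p_value`, `n_eff`, `bandwidth`, and
#'   `support_warning` (`TRUE` when the observed He falls outside the
#'   cloud's kernel support and the nearest-neighbourhood fallback was
#'   used).
#' @export
kde_pvalue <- function(observed, null, bandwidth = "silverman",
                       tail = c("upper", "two")) {
  tail <- match.arg(tail)
  stopifnot(inherits(null, "null_cloud"))
  if (inherits(observed, "summary_stats"))
    observed <- c(observed$mean_he, observed$global_fst)
  he_obs <- observed[1]; fst_obs <- observed[2]
  pts <- null$points
  if (nrow(pts) < 2L || sd(pts$he) == 0 && sd(pts$fst) == 0)
    stop("degenerate null cloud", call. = FALSE)
  h <- if (identical(bandwidth, "silverman")) .silverman(pts$he)
       else as.numeric(bandwidth)
  w <- exp(-0.5 * ((pts$he - he_obs) / h)^2)
  support_warning <- FALSE
  if (sum(w) < .Machine$double.eps * nrow(pts) || max(w) < 1e-12) {
    warning("observed He outside the null support; ",
            "falling back to the nearest He neighbourhood", call. = FALSE)
    support_warning <- TRUE
    d <- abs(pts$he - he_obs)
    nn <- order(d)[seq_len(max(20L, ceiling(0.01 * nrow(pts))))]
    w <- numeric(nrow(pts)); w[nn] <- 1
  }
  n_eff <- sum(w)^2 / sum(w^2)
  # weighted exceedance with ties counted fully (conservative, valid):
  # small-sample allele counts make (He, F_ST) discrete, so the tie mass
  # is also reported — a calibration check can turn it into the usual
  # randomized PIT while the deployed p-value stays deterministic
  prop_gt <- sum(w * (pts$fst > fst_obs + 1e-12)) / sum(w)
  prop_eq <- sum(w * (abs(pts$fst - fst_obs) <= 1e-12)) / sum(w)
  p_up <- ((prop_gt + prop_eq) * n_eff + 1) / (n_eff + 1)
  p <- if (tail == "upper") p_up else {
    prop_lo <- sum(w * (pts$fst <= fst_obs + 1e-12)) / sum(w)
    p_lo <- (prop_lo * n_eff + 1) / (n_eff + 1)
    min(1, 2 * min(p_up, p_lo))
  }
  list(p_value = p, n_eff = n_eff, bandwidth = h,
       prop_gt = prop_gt, prop_eq = prop_eq,
       support_warning = support_warning)
}

#' Scan observed loci for F_ST outliers against a null cloud
#'
#' Computes each locus's (mean He, F_ST) as in [summarize_loci()], ranks it
#' with [kde_pvalue()], and flags loci with `p < alpha`.  Quantile envelopes
#' of F_ST conditional on He (levels 0.025 / 0.5 / 0.975) are returned for
#' plotting, the usual joint-distribution figure of this kind of test.
#'
#' @param observed a [frequency_matrix()] or [locus_set()].
#' @param null a [build_null()] cloud.
#' @param grouping optional labels pooling populations into the compared
#'   units (e.g. two subdivisions) before computing He and F_ST.
#' @param alpha flag threshold (default 0.05, no multiple-testing
#'   correction, mirroring the published analysis).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted flags.
#' @param tail passed to [kde_pvalue()].
#' @return An `outlier_report`: per-locus table (`locus`, `he`, `fst`,
#'   `p_value`, `flag`), excluded loci with reasons, and the envelope data
#'   frame.
#' @export
outlier_scan <- function(observed, null, grouping = NULL, alpha = 0.05,
                         adjust = c("none", "BH"), tail = "upper") {
  adjust <- match.arg(adjust)
  stopifnot(inherits(null, "null_cloud"))
  if (inherits(observed, "frequency_matrix")) {
    p <- observed$freq; n <- observed$n_alleles
  } else if (inherits(observed, "locus_set")) {
    p <- observed$counts / observed$n_alleles; n <- observed$n_alleles
  } else stop("observed must be a frequency_matrix or locus_set",
              call. = FALSE)
  if (!is.null(grouping)) {
    cnt <- t(rowsum(t(p * n), grouping))
    n <- t(rowsum(t(n), grouping))
    p <- cnt / n
  }
  if (ncol(p) < 2L) stop("need at least two populations", call. = FALSE)
  loci <- rownames(p)
  if (is.null(loci)) loci <- paste0("locus", seq_len(nrow(p)))
  excluded <- data.frame(locus = character(0), reason = character(0))
  rows <- vector("list", nrow(p))
  for (l in seq_len(nrow(p))) {
    pl <- p[l, ]; nl <- n[l, ]
    if (anyNA(pl)) {
      excluded <- rbind(excluded,
                        data.frame(locus = loci[l], reason = "missing cell"))
      next
    }
    if (all(pl == 0) || all(pl == 1)) {
      excluded <- rbind(excluded,
                        data.frame(locus = loci[l], reason = "monomorphic"))
      next
    }
    he <- mean(2 * pl * (1 - pl) * nl / (nl - 1))
    fst <- .wc_fst_multilocus(matrix(pl, nrow = 1), matrix(nl, nrow = 1))
    kp <- kde_pvalue(c(he, fst), null, tail = tail)
    rows[[l]] <- data.frame(locus = loci[l], he = he, fst = fst,
                            p_value = kp$p_value,
                            support_warning = kp$support_warning)
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L)
    stop("no analysable locus (all excluded)", call. = FALSE)
  p_flag <- if (adjust == "BH") p.adjust(tab$p_value, "BH") else tab$p_value
  tab$flag <- p_flag < alpha
  structure(list(loci = tab, excluded = excluded,
                 envelope = null_envelope(null),
                 alpha = alpha, adjust = adjust),
            class = "outlier_report")
}

#' Conditional F_ST quantile envelope over a He grid
#'
#' For each grid point the null points are kernel-weighted by He distance
#' and weighted F_ST quantiles are taken, giving the confidence-band curves
#' of the joint-distribution plot.
#'
#' @param null a [build_null()] cloud.
#' @param levels quantile levels (default `c(0.025, 0.5, 0.975)`).
#' @param grid_size points on the He grid.
#' @export
null_envelope <- function(null, levels = c(0.025, 0.5, 0.975),
                          grid_size = 40L) {
  pts <- null$points
  h <- .silverman(pts$he)
  grid <- seq(quantile(pts$he, 0.02), quantile(pts$he, 0.98),
              length.out = grid_size)
  out <- lapply(grid, function(g) {
    w <- exp(-0.5 * ((pts$he - g) / h)^2)
    q <- .weighted_quantile(pts$fst, w, levels)
    data.frame(he = g, level = levels, fst = q)
  })
  do.call(rbind, out)
}

# Weighted quantiles by inverting the weighted ECDF (linear interpolation).
.weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1]
    if (is.na(i)) x[length(x)] else x[i]
  }, numeric(1))
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("F_ST outlier scan:", nrow(x$loci), "loci,",
      sum(x$loci$flag), "flagged at alpha =", x$alpha, "\n")
  if (nrow(x$excluded))
    cat("  excluded:", paste(x$excluded$locus, collapse = ", "), "\n")
  invisible(x)
}
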