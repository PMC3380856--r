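# ABC-style neutrality goodness-of-fit: Euclidean distance between an
# observed summary-statistic vector S* and the vectors S of a simulated
# neutral ensemble.

#' Euclidean distance between two summary-statistic vectors
#'
#' `d = sqrt(sum((s_i - s*_i)^2))` on the fixed vector layout of
#' [as_summary_vector()].  With `scale` given (typically the null ensemble's
#' per-coordinate standard deviations), each coordinate is divided by its
#' scale first, which puts He and F_ST summaries on comparable footing.
#'
#' @param s,s_star `summary_stats` objects or plain numeric vectors of the
#'   same layout.
#' @param scale optional positive vector of per-coordinate scales.
#' @export
euclidean_distance <- function(s, s_star, scale = NULL) {
  a <- as_summary_vector(s); b <- as_summary_vector(s_star)
  if (length(a) != length(b))
    stop("summary vectors differ in length (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a),
                                                             names(b))) {
    bad <- which(names(a) != names(b))[1]
    stop("summary vector layout mismatch at coordinate '", names(a)[bad],
         "' vs '", names(b)[bad], "'", call. = FALSE)
  }
  d <- a - b
  if (!is.null(scale)) {
    stopifnot(length(scale) == length(d), all(scale > 0))
    d <- d / scale
  }
  sqrt(sum(d^2))
}

#' Neutrality goodness-of-fit of an observed locus set
#'
#' Computes the distance from the observed summary vector to every vector of
#' a simulated neutral ensemble and reports mean / median / minimum.  With
#' `standardization = "null_sd"` (the default) every coordinate is divided
#' by the ensemble's standard deviation first, since raw summaries mix
#' scales.  The internal baseline — the distance of each simulation to the
#' ensemble mean — is reported alongside, so one observed data set can be
#' called a poorer fit to neutrality than another.
#'
#' @param observed a `summary_stats` object (or summary vector).
#' @param ensemble list of `summary_stats` objects (or a matrix with one
#'   summary vector per row).
#' @param standardization `"null_sd"` or `"none"`.
#' @param keep_distances return the per-simulation distance sample?
#' @return A `fit_report` with `mean_distance`, `median_distance`,
#'   `min_distance`, `baseline_mean_distance`, `n_sims`, `standardization`,
#'   and (optionally) `distances` / `baseline_distances`.
#' @export
neutrality_fit <- function(observed, ensemble,
                           standardization = c("null_sd", "none"),
                           keep_distances = FALSE) {
  standardization <- match.arg(standardization)
  obs <- as_summary_vector(observed)
  mat <- if (is.matrix(ensemble)) ensemble
         else do.call(rbind, lapply(ensemble, as_summary_vector))
  if (nrow(mat) == 0L) stop("ensemble is empty", call. = FALSE)
  degenerate <- nrow(mat) == 1L
  if (degenerate)
    warning("ensemble of size 1: mean = min, fit is degenerate",
            call. = FALSE)
  scale <- NULL
  if (standardization == "null_sd") {
    scale <- apply(mat, 2, sd)
    scale[!is.finite(scale) | scale <= 0] <- 1   # constant coordinate
  }
  dist_to <- function(v) {
    d <- sweep(mat, 2, v, "-")
    if (!is.null(scale)) d <- sweep(d, 2, scale, "/")
    sqrt(rowSums(d^2))
  }
  distances <- dist_to(obs)
  baseline <- dist_to(colMeans(mat))
  structure(list(mean_distance = mean(distances),
                 median_distance = median(distances),
                 min_distance = min(distances),
                 baseline_mean_distance = mean(baseline),
                 n_sims = nrow(mat), standardization = standardization,
                 degenerate = degenerate,
                 distances = if (keep_distances) distances,
                 baseline_distances = if (keep_distances) baseline),
            class = "fit_report")
}

#' @importFrom stats median
#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(paste0("Neutrality fit over %d simulations (%s ",
                     "standardization)\n"), x$n_sims, x$standardization))
  cat(sprintf("  mean = %.3f  median = %.3f  min = %.3f  (baseline mean = %.3f)\n",
              x$mean_distance, x$median_distance, x$min_distance,
              x$baseline_mean_distance))
  invisible(x)
}
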