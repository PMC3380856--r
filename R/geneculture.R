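# Gene-culture correlation stage: tie-corrected Spearman correlation of
# allele frequencies against archaeological maize-pollen dates, and
# subdivision-level t-tests on population frequencies.

#' Tie-corrected Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks are assigned to ties and rho is the Pearson correlation of the
#' two rank vectors (the tie-corrected form; the textbook
#' `1 - 6 sum(d^2) / (n (n^2 - 1))` shortcut agrees only without ties).
#' The two-tailed p-value uses `t = rho sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return A `correlation_result`: `rho`, `p_value`, `n`, `t`, and the
#'   method string.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("n < 3: need at least three pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("constant vector: rho undefined", call. = FALSE)
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    tstat <- sign(rho) * Inf; p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(rho = rho, p_value = p, n = n, t = tstat,
                 method = "spearman mid-rank, t approximation"),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.6f  (n = %d, t = %.3f, two-tailed p = %.4g)\n",
              x$rho, x$n, x$t, x$p_value))
  invisible(x)
}

#' Compare allele frequencies between two subdivisions with a t-test
#'
#' The unit of analysis is the population: each population contributes its
#' alt-allele frequency with equal weight, and the two groups of
#' frequencies are compared with a two-tailed t-test (Welch by default;
#' pooled-variance available since group variances can differ a lot between
#' agriculturalist and hunter-gatherer panels).
#'
#' @param table a [population_table()].
#' @param group_a,group_b subdivision labels, each with at least two
#'   populations.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A `t_test_result` with `t`, `df`, `p_value`, the group means and
#'   SDs, and the variant used.
#' @export
subdivision_t_test <- function(table, group_a, group_b,
                               variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  stopifnot(inherits(table, "population_table"))
  freq_of <- function(g) {
    sub <- table[table$subdivision == g, , drop = FALSE]
    if (nrow(sub) < 2L)
      stop("group '", g, "' has fewer than 2 populations", call. = FALSE)
    class(sub) <- class(table)
    allele_frequency(sub)$p_alt
  }
  fa <- freq_of(group_a); fb <- freq_of(group_b)
  if (sd(fa) == 0 && sd(fb) == 0 && mean(fa) == mean(fb)) {
    res <- list(statistic = c(t = 0),
                parameter = c(df = length(fa) + length(fb) - 2),
                p.value = 1)
  } else {
    res <- t.test(fa, fb, var.equal = (variant == "pooled"))
  }
  structure(list(t = unname(res$statistic), df = unname(res$parameter),
                 p_value = res$p.value, variant = variant,
                 mean_a = mean(fa), mean_b = mean(fb),
                 sd_a = sd(fa), sd_b = sd(fb),
                 n_a = length(fa), n_b = length(fb),
                 group_a = group_a, group_b = group_b),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s vs %s (%s t-test): t = %.3f, df = %.2f, p = %.4g\n",
              x$group_a, x$group_b, x$variant, x$t, x$df, x$p_value))
  cat(sprintf("  means: %.4f vs %.4f\n", x$mean_a, x$mean_b))
  invisible(x)
}

#' Read an archaeological pollen-date table
#'
#' Schema: `population, site, region, radiocarbon_bp, calendar_bp,
#' frequency`.  Calendar ages are used as-is (radiocarbon calibration is
#' out of scope; the packaged table carries pre-calibrated calendar years).
#'
#' @param path CSV path.
#' @export
read_pollen_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("population", "site", "region", "radiocarbon_bp",
                "calendar_bp", "frequency")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(tab$calendar_bp <= 0, na.rm = TRUE) ||
      any(tab$radiocarbon_bp <= 0, na.rm = TRUE))
    stop("ages must be positive", call. = FALSE)
  ok <- !is.na(tab$frequency)
  if (any(tab$frequency[ok] < 0 | tab$frequency[ok] > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  structure(tab, class = c("pollen_table", "data.frame"))
}

#' Correlate allele frequencies with maize-pollen dates
#'
#' Joins the pollen records to population allele frequencies (inline
#' frequencies in the pollen table take precedence; otherwise frequencies
#' are computed from the genotype table by direct counting), then runs the
#' tie-corrected Spearman correlation of calendar age against frequency.
#' The joined table is the scatter data for the usual
#' frequency-versus-age figure.
#'
#' @param pollen a [read_pollen_table()] data frame (or any data frame with
#'   the same columns).
#' @param table optional [population_table()] used to fill in missing
#'   frequencies by population name.
#' @return list with `data` (the joined table), `correlation` (a
#'   [spearman_cor()] result) and `n`.
#' @export
frequency_vs_age_report <- function(pollen, table = NULL) {
  freq <- pollen$frequency
  need <- is.na(freq)
  if (any(need)) {
    if (is.null(table))
      stop("pollen table lacks frequencies for: ",
           paste(pollen$population[need], collapse = ", "),
           " and no genotype table was given", call. = FALSE)
    af <- allele_frequency(table)
    idx <- match(pollen$population[need], af$population)
    if (anyNA(idx))
      stop("population(s) not in the genotype table: ",
           paste(pollen$population[need][is.na(idx)], collapse = ", "),
           call. = FALSE)
    freq[need] <- af$p_alt[idx]
  }
  if (length(freq) < 3L)
    stop("n < 3: need at least three population/site pairs", call. = FALSE)
  corr <- spearman_cor(pollen$calendar_bp, freq)
  data <- data.frame(population = pollen$population, site = pollen$site,
                     calendar_bp = pollen$calendar_bp, frequency = freq,
                     stringsAsFactors = FALSE)
  list(data = data, correlation = corr, n = nrow(data))
}
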