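# Allele-age estimation: the Kimura-Ohta frequency method and two
# intra-allelic LD-decay estimators (a moment estimator and a
# composite-likelihood Metropolis-Hastings sampler).

#' Demographic parameters for allele-age conversion and priors
#'
#' @param n_effective diploid effective population size used to convert ages
#'   from 2N-generation units to generations (default 720, the value used in
#'   the published frequency-based estimates).
#' @param generation_years years per generation (default 25).
#' @param growth_rate per-generation proportional population growth
#'   (default 0.005); sets the intra-allelic coalescent prior of the MCMC
#'   estimator.
#' @param sampled_fraction proportion of the population sampled
#'   (default 2e-4); recorded with the estimate.
#' @export
demography_params <- function(n_effective = 720, generation_years = 25,
                              growth_rate = 0.005,
                              sampled_fraction = 2e-4) {
  stopifnot(n_effective > 0, generation_years > 0, growth_rate > 0,
            sampled_fraction > 0, sampled_fraction <= 1)
  structure(list(n_effective = n_effective,
                 generation_years = generation_years,
                 growth_rate = growth_rate,
                 sampled_fraction = sampled_fraction),
            class = "demography_params")
}

.age_estimate <- function(age_2N, method, params, ci_low = NA_real_,
                          ci_high = NA_real_, posterior = NULL,
                          extra = list()) {
  gens <- age_2N * 2 * params$n_effective
  structure(c(list(age_2N_units = age_2N,
                   age_generations = gens,
                   age_years = gens * params$generation_years,
                   method = method,
                   ci_low = ci_low, ci_high = ci_high,
                   posterior_samples = posterior,
                   params = params), extra),
            class = "age_estimate")
}

#' Kimura-Ohta frequency-based allele age
#'
#' For a neutral allele at population frequency `p`, the expected age in
#' units of 2N generations is `E(t1) = [-2 p / (1 - p)] ln(p)`.  Conversion
#' to generations multiplies by `2 * n_effective`, and to years by the
#' generation time.  The function is strictly increasing in `p` on (0, 1)
#' and approaches 2 (in 2N units) as `p -> 1`.
#'
#' @param p allele frequency, strictly inside (0, 1).
#' @param params a [demography_params()].
#' @return An `age_estimate` with the three time scales and
#'   `method = "kimura_ohta"`.
#' @references Kimura & Ohta (1973) Genetics 75:199-212.
#' @export
kimura_ohta_age <- function(p, params = demography_params()) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("p must lie strictly inside (0, 1): age undefined at fixation/absence",
         call. = FALSE)
  .age_estimate((-2 * p / (1 - p)) * log(p), "kimura_ohta", params)
}

#' Build a haplotype panel around a focal derived allele
#'
#' A panel records, for each sampled chromosome, whether it carries the focal
#' derived allele and its alleles at `M` flanking markers, together with the
#' per-marker recombination fraction to the focal site.
#'
#' @param carrier logical (or 0/1) vector, one entry per chromosome.
#' @param markers matrix of marker alleles (chromosomes x markers), coded
#'   0/1.
#' @param rec_frac numeric vector of recombination fractions to the focal
#'   site, in `[0, 0.5]`, one per marker.
#' @param ancestral optional 0/1 vector giving the ancestral (founder)
#'   haplotype at the markers; when absent the per-marker modal allele among
#'   carriers is used.
#' @param bp optional marker base-pair positions (metadata).
#' @export
haplotype_panel <- function(carrier, markers, rec_frac, ancestral = NULL,
                            bp = NULL) {
  carrier <- as.logical(carrier)
  markers <- as.matrix(markers)
  stopifnot(length(carrier) == nrow(markers),
            length(rec_frac) == ncol(markers))
  if (!any(carrier)) stop("panel needs at least one carrier chromosome",
                          call. = FALSE)
  if (any(rec_frac < 0 | rec_frac > 0.5))
    stop("recombination fractions must lie in [0, 0.5]", call. = FALSE)
  if (!is.null(ancestral) && length(ancestral) != ncol(markers))
    stop("ancestral haplotype length must equal the marker count",
         call. = FALSE)
  if (is.null(colnames(markers)))
    colnames(markers) <- paste0("m", seq_len(ncol(markers)))
  structure(list(carrier = carrier, markers = markers,
                 rec_frac = as.numeric(rec_frac), ancestral = ancestral,
                 bp = bp),
            class = "haplotype_panel")
}

#' Read a haplotype panel from TSV files
#'
#' The panel file has one row per chromosome: `id`, `carrier` (0/1), then one
#' 0/1 column per marker.  The companion map file has columns `marker`,
#' `rec_frac` and optionally `bp`.
#'
#' @param path panel TSV.
#' @param map_path marker map TSV.
#' @export
read_haplotype_panel <- function(path, map_path) {
  pan <- read.csv(path, sep = "\t", check.names = FALSE)
  map <- read.csv(map_path, sep = "\t", check.names = FALSE)
  stopifnot(all(c("id", "carrier") %in% names(pan)),
            all(c("marker", "rec_frac") %in% names(map)))
  mk <- as.matrix(pan[, setdiff(names(pan), c("id", "carrier")),
                      drop = FALSE])
  if (!identical(colnames(mk), as.character(map$marker)))
    stop("marker columns and map rows disagree", call. = FALSE)
  haplotype_panel(pan$carrier, mk, map$rec_frac,
                  bp = if ("bp" %in% names(map)) map$bp else NULL)
}

# Ancestral allele per marker: given, or modal among carriers.
.panel_ancestral <- function(panel) {
  if (!is.null(panel$ancestral)) return(as.integer(panel$ancestral))
  carr <- panel$markers[panel$carrier, , drop = FALSE]
  as.integer(colMeans(carr) >= 0.5)
}

# Background frequency of the *ancestral* allele at each marker, the plain
# proportion among non-carrier chromosomes (kept unsmoothed so estimates
# are exactly invariant to duplicating every chromosome).
.panel_background <- function(panel, anc) {
  non <- panel$markers[!panel$carrier, , drop = FALSE]
  if (nrow(non) == 0L)
    stop("panel has no non-carrier chromosomes to estimate background ",
         "marker frequencies from", call. = FALSE)
  match_anc <- non == rep(anc, each = nrow(non))
  colSums(match_anc) / nrow(non)
}

#' Moment estimator of allele age from LD decay at one marker
#'
#' Among chromosomes carrying the focal allele, the proportion `y` still
#' carrying the ancestral allele at a flanking marker decays with age as
#' `exp(-c t)` (recombination fraction `c`, age `t` in generations), apart
#' from recombinants that happen to re-acquire the ancestral allele from the
#' background at frequency `q`.  The corrected retention is
#' `y' = (y - q) / (1 - q)` and the estimate `t = -ln(y') / c`, clamped at 0
#' when `y' >= 1` and undefined when `y' <= 0`.
#'
#' @param panel a [haplotype_panel()].
#' @param marker marker index (or name).
#' @param params a [demography_params()] (unit conversion only).
#' @return An `age_estimate` (`method = "moment_ld"`); `age_generations` is
#'   `NA` with `undefined = TRUE` when `y' <= 0`.
#' @references Slatkin & Rannala (2000) Annu Rev Genomics Hum Genet 1:225-249
#'   review the exponential-decay moment argument.
#' @export
moment_ld_age <- function(panel, marker, params = demography_params()) {
  stopifnot(inherits(panel, "haplotype_panel"))
  if (is.character(marker)) marker <- match(marker, colnames(panel$markers))
  cfrac <- panel$rec_frac[marker]
  if (is.na(cfrac)) stop("unknown marker", call. = FALSE)
  if (cfrac == 0) stop("uninformative marker (recombination fraction 0)",
                       call. = FALSE)
  anc <- .panel_ancestral(panel)
  q <- .panel_background(panel, anc)[marker]
  carr <- panel$markers[panel$carrier, marker]
  y <- mean(carr == anc[marker])
  if (q >= 1) {
    est <- .age_estimate(NA_real_, "moment_ld", params,
                         extra = list(undefined = TRUE, y = y, q = q))
    est$age_generations <- NA_real_; est$age_years <- NA_real_
    return(est)
  }
  yp <- (y - q) / (1 - q)
  if (yp >= 1) {
    gens <- 0
  } else if (yp <= 0) {
    est <- .age_estimate(NA_real_, "moment_ld", params,
                         extra = list(undefined = TRUE, y = y, q = q))
    est$age_generations <- NA_real_; est$age_years <- NA_real_
    return(est)
  } else {
    gens <- -log(yp) / cfrac
  }
  .age_estimate(gens / (2 * params$n_effective), "moment_ld", params,
                extra = list(undefined = FALSE, y = y, q = q))
}

# Log composite likelihood of age t (generations) given per-marker sufficient
# statistics: k = carriers matching the ancestral allele, n = carriers,
# c = recombination fraction.  A carrier lineage retains the ancestral
# allele with probability exp(-c t) and otherwise draws it from the
# background.  The background frequency of the ancestral allele at each
# marker is a nuisance: it is integrated over its Jeffreys-posterior given
# the non-carrier counts, using equal-weight quantile quadrature nodes in
# `qnodes` (an M x J matrix), which propagates background uncertainty into
# the age posterior.
.ld_loglik <- function(t, k, n, cfrac, qnodes) {
  ret <- exp(-cfrac * t)
  pm <- ret * (1 - qnodes) + qnodes
  pm <- pmin(pmax(pm, 1e-12), 1 - 1e-12)
  ll <- k * log(pm) + (n - k) * log(1 - pm)      # M x J
  mx <- apply(ll, 1, max)
  sum(mx + log(rowMeans(exp(ll - mx))))
}

# Quadrature nodes for the background-frequency posterior at each marker:
# Beta(c + 1/2, n - c + 1/2) quantiles at J equally spaced probabilities.
.background_nodes <- function(panel, anc, J = 7L) {
  non <- panel$markers[!panel$carrier, , drop = FALSE]
  if (nrow(non) == 0L)
    stop("panel has no non-carrier chromosomes to estimate background ",
         "marker frequencies from", call. = FALSE)
  cnt <- colSums(non == rep(anc, each = nrow(non)))
  probs <- (seq_len(J) - 0.5) / J
  t(vapply(seq_along(cnt),
           function(m) qbeta(probs, cnt[m] + 0.5,
                             nrow(non) - cnt[m] + 0.5),
           numeric(J)))
}

#' Bayesian MCMC allele age from multi-marker LD decay
#'
#' A Metropolis-Hastings sampler over the allele age `t` (generations).  The
#' likelihood is the composite product over informative markers of the
#' per-carrier retention/recombination probabilities (star-shaped
#' intra-allelic genealogy, the regime produced by rapid population growth).
#' The prior is the exponential age distribution induced by the intra-allelic
#' coalescent under per-generation growth `growth_rate` (rate =
#' `growth_rate`, so mean age `1/growth_rate` generations); the sampled
#' fraction is recorded but does not sharpen this prior.  The proposal is a
#' log-normal random walk whose scale adapts during burn-in towards 20-50%
#' acceptance.
#'
#' @param panel a [haplotype_panel()].
#' @param params a [demography_params()].
#' @param iterations total MCMC iterations (default 1e5; published analyses
#'   of this kind use up to 2e6).
#' @param burn_in discarded initial iterations (default 20%).
#' @param seed RNG seed for a reproducible chain.
#' @return An `age_estimate` (`method = "mcmc_ld"`) with posterior mean (the
#'   point estimate), mode, central 95% credible interval in years
#'   (`ci_low`, `ci_high`), the retained posterior sample, and the realised
#'   acceptance rate.  A non-mixing chain (acceptance below 1% or above 99%
#'   after adaptation) sets `mixing_warning = TRUE` and emits a warning.
#' @export
mcmc_ld_age <- function(panel, params = demography_params(),
                        iterations = 1e5L, burn_in = round(iterations / 5),
                        seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"), iterations > burn_in)
  if (ncol(panel$markers) == 0L)
    stop("zero informative markers", call. = FALSE)
  # markers with c = 0 contribute a likelihood constant in t, so with no
  # recombining marker the posterior simply reproduces the prior
  anc <- .panel_ancestral(panel)
  qnodes <- .background_nodes(panel, anc)
  cfrac <- panel$rec_frac
  carr <- panel$markers[panel$carrier, , drop = FALSE]
  k <- colSums(carr == rep(anc, each = nrow(carr)))
  n_carr <- sum(panel$carrier)
  prior_rate <- params$growth_rate
  with_seed(seed, {
    t_cur <- 1 / prior_rate                       # prior mean start
    ll_cur <- .ld_loglik(t_cur, k, n_carr, cfrac, qnodes)
    lp_cur <- ll_cur - prior_rate * t_cur
    sigma <- 0.5
    n_keep <- iterations - burn_in
    keep <- numeric(n_keep)
    acc_window <- 0L; acc_total <- 0L; n_post <- 0L
    for (i in seq_len(iterations)) {
      t_prop <- t_cur * exp(sigma * rnorm(1))
      ll_prop <- .ld_loglik(t_prop, k, n_carr, cfrac, qnodes)
      lp_prop <- ll_prop - prior_rate * t_prop
      # log proposal ratio for the log-normal walk is log(t_prop/t_cur)
      if (log(runif(1)) < lp_prop - lp_cur + log(t_prop / t_cur)) {
        t_cur <- t_prop; lp_cur <- lp_prop
        acc_window <- acc_window + 1L
        if (i > burn_in) acc_total <- acc_total + 1L
      }
      if (i <= burn_in && i %% 100L == 0L) {      # adapt towards 20-50%
        rate <- acc_window / 100
        if (rate < 0.2) sigma <- sigma * 0.8
        if (rate > 0.5) sigma <- sigma * 1.25
        acc_window <- 0L
      }
      if (i > burn_in) { n_post <- n_post + 1L; keep[n_post] <- t_cur }
    }
    acc_rate <- acc_total / n_keep
    mixing_warning <- acc_rate < 0.01 || acc_rate > 0.99
    if (mixing_warning)
      warning(sprintf("MCMC chain mixing poor (acceptance %.1f%%)",
                      100 * acc_rate), call. = FALSE)
    dens <- density(keep)
    ci <- quantile(keep, c(0.025, 0.975), names = FALSE)
    gy <- params$generation_years
    est <- .age_estimate(mean(keep) / (2 * params$n_effective), "mcmc_ld",
                         params,
                         ci_low = ci[1] * gy, ci_high = ci[2] * gy,
                         posterior = keep,
                         extra = list(posterior_mode_generations =
                                        dens$x[which.max(dens$y)],
                                      acceptance_rate = acc_rate,
                                      mixing_warning = mixing_warning,
                                      iterations = iterations,
                                      burn_in = burn_in, seed = seed))
    est
  })
}

#' @export
print.age_estimate <- function(x, ...) {
  cat(sprintf("Allele age (%s): %.3f x 2N gen = %.0f generations = %.0f years\n",
              x$method, x$age_2N_units, x$age_generations, x$age_years))
  if (!is.na(x$ci_low))
    cat(sprintf("  95%% CI: %.0f - %.0f years\n", x$ci_low, x$ci_high))
  invisible(x)
}
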