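# Frequency-based and LD-based allele-age estimators.

test_that("Kimura-Ohta ages reproduce the closed form and its limits", {
  est <- kimura_ohta_age(0.5)
  expect_equal(est$age_2N_units, 2 * log(2))
  expect_lt(abs(kimura_ohta_age(0.9999)$age_2N_units - 2), 1e-3)
  # direct arithmetic at the published parameter values
  est2 <- kimura_ohta_age(0.154, demography_params(n_effective = 720,
                                                   generation_years = 25))
  expect_equal(est2$age_2N_units, (-2 * 0.154 / 0.846) * log(0.154))
  expect_equal(est2$age_years, est2$age_2N_units * 2 * 720 * 25)
  expect_equal(round(est2$age_years), 24519)
  expect_error(kimura_ohta_age(0), "strictly inside")
  expect_error(kimura_ohta_age(1), "strictly inside")
  # strictly increasing in p: older alleles are commoner under neutrality
  grid <- vapply(seq(0.01, 0.99, by = 0.01),
                 function(p) kimura_ohta_age(p)$age_2N_units, numeric(1))
  expect_true(all(diff(grid) > 0))
  # unit conversions stay mutually consistent
  expect_equal(est$age_generations,
               est$age_2N_units * 2 * est$params$n_effective)
  expect_equal(est$age_years,
               est$age_generations * est$params$generation_years)
})

test_that("the moment LD estimator inverts the decay model", {
  # full retention -> age zero; retention at background level -> undefined
  M <- 3L
  full <- haplotype_panel(carrier = c(rep(TRUE, 50), rep(FALSE, 200)),
                          markers = rbind(matrix(1L, 50, M),
                                          matrix(0L, 200, M)),
                          rec_frac = rep(0.01, M),
                          ancestral = rep(1L, M))
  expect_equal(moment_ld_age(full, 1)$age_generations, 0)
  lost <- haplotype_panel(carrier = c(rep(TRUE, 50), rep(FALSE, 200)),
                          markers = rbind(matrix(0L, 50, M),
                                          matrix(0L, 200, M)),
                          rec_frac = rep(0.01, M),
                          ancestral = rep(1L, M))
  expect_true(isTRUE(moment_ld_age(lost, 1)$undefined))
  expect_error(moment_ld_age(haplotype_panel(TRUE, matrix(1, 1, 1), 0,
                                             ancestral = 1), 1),
               "uninformative")
  # y' = exp(-1) at c = 0.01 -> ~100 generations (background ~0 from many
  # non-carriers, so the correction is tiny)
  n_carr <- 1000L
  k <- round(n_carr * exp(-1))
  panel <- haplotype_panel(carrier = c(rep(TRUE, n_carr), rep(FALSE, 1000)),
                           markers = rbind(cbind(c(rep(1L, k),
                                                   rep(0L, n_carr - k))),
                                           cbind(rep(0L, 1000))),
                           rec_frac = 0.01, ancestral = 1L)
  expect_lt(abs(moment_ld_age(panel, 1)$age_generations - 100), 5)
})

test_that("the moment estimator is invariant to marker relabeling and
           chromosome duplication", {
  sc <- age_panel_scenario(true_age_generations = 300,
                           n_carriers = 300, n_noncarriers = 300,
                           rec_frac = c(0.004, 0.008),
                           background_freq = 0.3)
  panel <- simulate_age_panel(sc, seed = 5)
  t0 <- moment_ld_age(panel, 1)$age_generations
  # flip the 0/1 coding of marker 1 (ancestral given, flipped accordingly)
  flipped <- panel
  flipped$markers[, 1] <- 1L - flipped$markers[, 1]
  flipped$ancestral[1] <- 1L - flipped$ancestral[1]
  expect_equal(moment_ld_age(flipped, 1)$age_generations, t0)
  dup <- haplotype_panel(rep(panel$carrier, 2),
                         rbind(panel$markers, panel$markers),
                         panel$rec_frac, panel$ancestral)
  expect_equal(moment_ld_age(dup, 1)$age_generations, t0)
})

test_that("an uninformative panel returns the prior from the MCMC", {
  sc <- age_panel_scenario(true_age_generations = 300, n_carriers = 200,
                           n_noncarriers = 200,
                           rec_frac = rep(0, 5), background_freq = 0.4)
  panel <- simulate_age_panel(sc, seed = 2)
  est <- mcmc_ld_age(panel, iterations = 20000, burn_in = 4000, seed = 3)
  # compare the posterior sample with the exponential prior (rate = growth)
  ks_dist <- suppressWarnings(
    ks.test(est$posterior_samples, "pexp",
            rate = est$params$growth_rate)$statistic)
  expect_lt(unname(ks_dist), 0.1)
})

test_that("single-marker MCMC agrees with the moment estimator", {
  sc <- age_panel_scenario(true_age_generations = 300, n_carriers = 500,
                           n_noncarriers = 500, rec_frac = 0.005,
                           background_freq = 0.5)
  panel <- simulate_age_panel(sc, seed = 9)
  mom <- moment_ld_age(panel, 1)$age_generations
  est <- mcmc_ld_age(panel, iterations = 20000, burn_in = 4000, seed = 10)
  expect_lt(abs(est$posterior_mode_generations - mom), 0.30 * mom)
})

test_that("the posterior concentrates as the carrier count grows", {
  width <- function(n_carr, seed) {
    sc <- age_panel_scenario(true_age_generations = 300,
                             n_carriers = n_carr, n_noncarriers = 300)
    est <- mcmc_ld_age(simulate_age_panel(sc, seed = seed),
                       iterations = 15000, burn_in = 3000, seed = seed)
    est$ci_high - est$ci_low
  }
  w_small <- mean(vapply(1:3, function(s) width(40L, s), numeric(1)))
  w_large <- mean(vapply(1:3, function(s) width(800L, s), numeric(1)))
  expect_lt(w_large, w_small)
})

test_that("haplotype panels round-trip through their TSV pair", {
  p <- tempfile(fileext = ".tsv"); m <- tempfile(fileext = ".tsv")
  writeLines(c("id\tcarrier\tm1\tm2", "c1\t1\t1\t0", "c2\t1\t1\t1",
               "n1\t0\t0\t1"), p)
  writeLines(c("marker\trec_frac", "m1\t0.005", "m2\t0.01"), m)
  pan <- read_haplotype_panel(p, m)
  expect_s3_class(pan, "haplotype_panel")
  expect_equal(sum(pan$carrier), 2L)
  expect_equal(pan$rec_frac, c(0.005, 0.01))
  writeLines(c("marker\trec_frac", "mX\t0.005", "m2\t0.01"), m)
  expect_error(read_haplotype_panel(p, m), "disagree")
})
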