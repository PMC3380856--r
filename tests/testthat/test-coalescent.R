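# Structured-coalescent simulators and summary statistics.

test_that("single-deme pairwise coalescence time matches 2N generations", {
  cfg <- island_model_config(n_demes = 1L, n_groups = 1L, deme_size = 50,
                             m_within = 0, m_between = 0,
                             sample_spec = data.frame(deme = 1,
                                                      n_diploid = 1))
  set.seed(21)
  tm <- replicate(1500, simulate_island_snp(cfg)$tmrca)
  # E[T2] = 2 * deme_size generations, sd equal to the mean
  expect_lt(abs(mean(tm) - 100) / 100, 0.08)
})

test_that("every island locus is polymorphic in the pooled sample", {
  cfg <- island_model_config(n_demes = 10L, n_groups = 2L, deme_size = 30,
                             target_fst = 0.1,
                             sample_spec = data.frame(deme = c(1, 6),
                                                      n_diploid = c(10, 10)))
  set.seed(5)
  for (i in 1:50) {
    loc <- simulate_island_snp(cfg)
    d <- sum(loc$derived)
    expect_gt(d, 0)
    expect_lt(d, sum(loc$n_alleles))
  }
  # zero migration with a multi-deme sample cannot coalesce
  cfg0 <- island_model_config(n_demes = 10L, n_groups = 2L, deme_size = 30,
                              m_within = 0, m_between = 0,
                              sample_spec = data.frame(deme = c(1, 6),
                                                       n_diploid = c(2, 2)))
  expect_error(simulate_island_snp(cfg0, seed = 1), "migration")
})

test_that("mutations land on branches proportionally to length", {
  # 3 leaves in one deme.  With one mutation placed uniformly on branch
  # length per tree, P(singleton) = E[L1 / L] where, in units of 2N with
  # X = scaled 3-lineage epoch and Y = 2-lineage epoch (iid Exp(1)),
  # L1 = X + Y and L = X + 2 Y.  That expectation is computed here by
  # direct quadrature over the two exponentials, independent of the
  # simulator.
  f <- function(y) vapply(y, function(yy)
    integrate(function(x) (x + yy) / (x + 2 * yy) * exp(-x), 0,
              Inf)$value * exp(-yy), numeric(1))
  p_singleton <- integrate(f, 0, Inf)$value
  set.seed(31)
  counts <- integer(2)
  for (i in 1:3000) {
    res <- genecult:::island_snp_cpp(c(0L, 0L, 0L), 1L, 0L, 50, 0, 0)
    counts[sum(res$derived)] <- counts[sum(res$derived)] + 1L
  }
  cs <- suppressWarnings(chisq.test(counts,
                                    p = c(p_singleton, 1 - p_singleton)))
  expect_gt(cs$p.value, 0.01)
})

test_that("island demes within a group are exchangeable", {
  spec_a <- data.frame(deme = c(1, 2), n_diploid = c(15, 15))
  spec_b <- data.frame(deme = c(3, 4), n_diploid = c(15, 15))
  fst_of <- function(spec, seed) {
    cfg <- island_model_config(n_demes = 10L, n_groups = 1L,
                               deme_size = 40, m_within = 0.01,
                               m_between = 0, sample_spec = spec)
    set.seed(seed)
    replicate(400, summarize_loci(simulate_island_snp(cfg))$global_fst)
  }
  ks <- suppressWarnings(ks.test(fst_of(spec_a, 1), fst_of(spec_b, 2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("settlement regions have exactly n_snps segregating sites and a
           panmixia limit", {
  dem0 <- settlement_demography(ancestral_size_range = c(830, 830),
                                split_time_range_years = c(1, 1))
  set.seed(7)
  mean_pw <- replicate(800, {
    ls <- simulate_settlement_region(dem0, n_snps = 20)
    pooled <- rowSums(ls$counts)
    expect_true(all(pooled > 0 & pooled < sum(ls$n_alleles[1, ])))
    mean(summarize_loci(ls)$pairwise_fst)
  })
  expect_lt(abs(mean(mean_pw)), 0.01)
})

test_that("settlement differentiation grows with split time", {
  set.seed(17)
  mean_fst_at <- function(years) {
    dem <- settlement_demography(ancestral_size_range = c(400, 400),
                                 split_time_range_years = c(years, years))
    mean(replicate(300, mean(summarize_loci(
      simulate_settlement_region(dem, n_snps = 10))$pairwise_fst)))
  }
  fsts <- vapply(c(1000, 6350, 18000, 40000), mean_fst_at, numeric(1))
  expect_true(all(diff(fsts) > 0))
})

test_that("summary statistics match hand-evaluated oracles", {
  ls <- locus_set(matrix(c(10L, 2L), nrow = 1), c(20L, 20L))
  s <- summarize_loci(ls)
  expect_equal(s$global_fst, oracle_wc_theta(c(20, 20), c(0.5, 0.1)))
  expect_equal(unname(s$pairwise_fst), s$global_fst)
  # He at p = 0.5, 2n = 20, unbiased: (20/19) * 0.5
  ls2 <- locus_set(matrix(c(10L, 10L), nrow = 1), c(20L, 20L))
  expect_equal(summarize_loci(ls2)$mean_he, 0.5 * 20 / 19)
  # identical counts across demes: raw global F_ST at or below zero
  expect_lte(summarize_loci(ls2)$global_fst, 0)
  # grouping pools demes before summarising
  ls3 <- locus_set(matrix(c(5L, 5L, 2L), nrow = 1), c(20L, 20L, 20L))
  s3 <- summarize_loci(ls3, grouping = c("g1", "g1", "g2"))
  expect_equal(s3$global_fst, oracle_wc_theta(c(40, 20), c(0.25, 0.1)))
})

test_that("the summary vector layout is fixed and complete", {
  ls <- locus_set(matrix(c(3L, 8L, 2L, 5L, 9L, 1L), nrow = 2),
                  c(20L, 20L, 20L))
  v <- as_summary_vector(summarize_loci(ls))
  expect_identical(names(v)[1:2], c("mean_he", "global_fst"))
  expect_length(v, 2 + 3)          # 3 deme pairs
})
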