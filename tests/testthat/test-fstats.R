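# Hierarchical AMOVA and pairwise F_ST against independent oracles.

test_that("sums of squares match explicit allele enumeration on small toys", {
  set.seed(42)
  for (rep in 1:10) {
    P <- sample(3:4, 1)
    Ni <- 2L * sample(5:40, P, replace = TRUE)
    Ki <- vapply(Ni, function(N) sample.int(N + 1L, 1L) - 1L, integer(1))
    if (sum(Ki) == 0 || sum(Ki) == sum(Ni)) next
    grp <- c("g1", "g2", sample(c("g1", "g2"), P - 2, replace = TRUE))
    ora <- oracle_ss(Ni, Ki, grp)
    mod <- genecult:::.amova_three_level(Ni, Ki, grp)
    expect_equal(mod$ss_among_groups, unname(ora$among_groups))
    expect_equal(mod$ss_among_pops, unname(ora$among_pops))
    expect_equal(mod$ss_within, unname(ora$within))
  }
})

test_that("degenerate designs behave: maximal and zero differentiation", {
  # two populations fixed for opposite alleles, one group each
  tab <- population_table(c("a", "b"), c("g1", "g2"), c(10, 10),
                          c(10, 0), c(0, 0), c(0, 10))
  a <- amova(tab, n_permutations = 200, seed = 1)
  expect_equal(a$fct, 1)
  expect_equal(a$fst, 1)
  # four identical populations split 2 + 2: no among-level variance
  tab0 <- population_table(paste0("p", 1:4), rep(c("g1", "g2"), each = 2),
                           rep(20, 4), rep(12, 4), rep(6, 4), rep(2, 4))
  a0 <- amova(tab0, n_permutations = 200, seed = 1)
  expect_lte(a0$fct, 1e-12)
  expect_lte(a0$fsc, 1e-12)
  expect_equal(max(0, a0$fct), 0)
  # monomorphic locus flagged, indices undefined
  mono <- population_table(c("a", "b"), c("g1", "g2"), c(10, 10),
                           c(10, 10), c(0, 0), c(0, 0))
  am <- amova(mono, n_permutations = 10)
  expect_true(am$monomorphic)
  expect_true(is.na(am$fct))
  expect_error(amova(tab, grouping = setNames(rep("g", 2), tab$population)),
               "two groups")
})

test_that("within-group F_ST equals the enumerated one-level ANOVA", {
  tab <- population_table(c("a", "b"), c("g", "g"), c(10, 10),
                          c(8, 0), c(2, 2), c(0, 8))   # p = 0.1 vs 0.9
  w <- within_group_fst(tab, "g", n_permutations = 200, seed = 7)
  # independent route: explicit enumeration + WC mean squares
  expect_equal(w$fst, oracle_wc_theta(c(20, 20), c(0.1, 0.9)))
  # and on the published table, against the mean-square oracle directly
  t1 <- abca1_fixtures()$table1
  sa <- t1[t1$subdivision == "sa_hunter_gatherer", ]
  th <- oracle_wc_theta(2 * sa$n, (sa$n_ra + 2 * sa$n_aa) / (2 * sa$n))
  w_sa <- within_group_fst(t1, "sa_hunter_gatherer", n_permutations = 100,
                           seed = 1)
  expect_equal(w_sa$fst, th)
  expect_error(within_group_fst(t1, "not_there"), "fewer than 2")
})

test_that("results are invariant to row order and allele relabeling", {
  t1 <- abca1_fixtures()$table1
  a <- amova(t1, n_permutations = 50, seed = 3)
  shuffled <- t1[sample(nrow(t1)), ]
  class(shuffled) <- class(t1)
  a2 <- amova(shuffled, n_permutations = 50, seed = 3)
  expect_equal(a2$fct, a$fct)
  expect_equal(a2$fst, a$fst)
  # ref <-> alt swap
  swapped <- population_table(t1$population, t1$subdivision, t1$n,
                              n_rr = t1$n_aa, n_ra = t1$n_ra,
                              n_aa = t1$n_rr)
  a3 <- amova(swapped, n_permutations = 50, seed = 3)
  expect_equal(a3$fct, a$fct)
  expect_equal(a3$fsc, a$fsc)
  expect_equal(a3$fst, a$fst)
})

test_that("identical seeds give identical permutation p-values", {
  t1 <- abca1_fixtures()$table1
  a1 <- amova(t1, n_permutations = 300, seed = 11)
  a2 <- amova(t1, n_permutations = 300, seed = 11)
  expect_identical(c(a1$p_fct, a1$p_fsc, a1$p_fst),
                   c(a2$p_fct, a2$p_fsc, a2$p_fst))
})

test_that("permutation p-values are uniform under an exchangeable null", {
  set.seed(99)
  pvals <- replicate(200, {
    tab <- exchangeable_table()
    within_group_fst(tab, "g", n_permutations = 199)$p_value
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pairwise F_ST matches the Weir-Cockerham oracle", {
  fm <- frequency_matrix(matrix(c(0.2, 0.4), nrow = 1,
                                dimnames = list("l1", c("a", "b"))),
                         matrix(c(100, 100), nrow = 1,
                                dimnames = list("l1", c("a", "b"))))
  pw <- pairwise_fst(fm)
  expect_equal(pw["a", "b"], oracle_wc_theta(c(100, 100), c(0.2, 0.4)))
  expect_equal(diag(pw), c(a = 0, b = 0))
  # identical vectors -> raw estimate at or below zero
  fm0 <- frequency_matrix(matrix(c(0.3, 0.3), nrow = 1), c(50, 50))
  expect_lte(pairwise_fst(fm0)[1, 2], 0)
  # opposite fixation -> 1
  fm1 <- frequency_matrix(matrix(c(0, 1), nrow = 1), c(50, 50))
  expect_equal(pairwise_fst(fm1)[1, 2], 1)
  # a pair with no complete locus is flagged NA, not silently zero
  fm_all_na <- frequency_matrix(matrix(c(0.3, NA), nrow = 1), 50)
  expect_true(is.na(pairwise_fst(fm_all_na)[1, 2]))
})
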