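# Hierarchical F-statistics on single-SNP allele counts.
#
# The AMOVA here is the allele-level nested ANOVA: each diploid individual
# contributes its two alleles as exchangeable observations (no
# within-individual level), the standard single-locus treatment for genotype
# count data.  Sums of squares are computed in closed form from per-population
# allele counts; variance components use the usual unequal-size nested ANOVA
# coefficients.

# Closed-form sums of squares and variance components for the two-level
# (populations only) design.  Ni = allele counts (2n), Ki = alt-allele counts.
.amova_one_level <- function(Ni, Ki) {
  P <- length(Ni); N <- sum(Ni)
  p_i <- Ki / Ni; p <- sum(Ki) / N
  ss_within <- sum(Ki - Ki^2 / Ni)          # = sum Ni * p_i (1 - p_i)
  ss_among  <- sum(Ni * (p_i - p)^2)
  n_c <- (N - sum(Ni^2) / N) / (P - 1)
  sigma_c <- ss_within / (N - P)
  sigma_a <- (ss_among / (P - 1) - sigma_c) / n_c
  list(ss_among = ss_among, ss_within = ss_within,
       sigma_a = sigma_a, sigma_c = sigma_c,
       fst = sigma_a / (sigma_a + sigma_c))
}

# Three-level design: groups / populations within groups / within populations.
# grp is an integer or character vector of group labels per population.
.amova_three_level <- function(Ni, Ki, grp) {
  grp <- as.character(grp)
  P <- length(Ni); G <- length(unique(grp)); N <- sum(Ni)
  p_i <- Ki / Ni
  Ag <- tapply(Ni, grp, sum); Kg <- tapply(Ki, grp, sum)
  p_g <- Kg / Ag; p <- sum(Ki) / N
  ss_wp <- sum(Ki - Ki^2 / Ni)
  ss_ap <- sum(Ni * (p_i - p_g[grp])^2)
  ss_ag <- sum(Ag * (p_g - p)^2)
  sum_ni2_g <- tapply(Ni^2, grp, sum)
  n_ppp <- (N - sum(Ag^2) / N) / (G - 1)
  sigma_c <- ss_wp / (N - P)
  if (P == G) {
    # every group holds a single population: no among-pops-within level,
    # the design collapses to a one-level ANOVA among groups
    sigma_b <- 0
    sigma_a <- (ss_ag / (G - 1) - sigma_c) / n_ppp
  } else {
    n_p  <- (N - sum(sum_ni2_g / Ag)) / (P - G)
    n_pp <- (sum(sum_ni2_g / Ag) - sum(Ni^2) / N) / (G - 1)
    sigma_b <- (ss_ap / (P - G) - sigma_c) / n_p
    sigma_a <- (ss_ag / (G - 1) - sigma_c - n_pp * sigma_b) / n_ppp
  }
  tot <- sigma_a + sigma_b + sigma_c
  list(ss_among_groups = ss_ag, ss_among_pops = ss_ap, ss_within = ss_wp,
       sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
       fct = sigma_a / tot, fsc = sigma_b / (sigma_b + sigma_c),
       fst = (sigma_a + sigma_b) / tot)
}

# Random reallocation of alt alleles among populations with fixed sizes
# (equivalent to permuting the 0/1 allele vector): sequential multivariate
# hypergeometric draws, vectorised over B permutations.  Returns a P x B
# matrix of permuted alt counts.
.permute_alleles <- function(Ni, K_total, B) {
  P <- length(Ni)
  out <- matrix(0, nrow = P, ncol = B)
  k_rem <- rep(K_total, B)
  n_rem <- sum(Ni)
  for (i in seq_len(P - 1L)) {
    x <- rhyper(B, m = k_rem, n = n_rem - k_rem, k = Ni[i])
    out[i, ] <- x
    k_rem <- k_rem - x
    n_rem <- n_rem - Ni[i]
  }
  out[P, ] <- k_rem
  out
}

# Vectorised one-level F_ST over columns of a P x B matrix of alt counts.
.fst_columns <- function(Ni, Kmat) {
  P <- length(Ni); N <- sum(Ni)
  p_mat <- Kmat / Ni
  pbar <- colSums(Kmat) / N
  ss_w <- colSums(Kmat - Kmat^2 / Ni)
  ss_a <- colSums(Ni * sweep(p_mat, 2, pbar, "-")^2)
  n_c <- (N - sum(Ni^2) / N) / (P - 1)
  sc <- ss_w / (N - P)
  sa <- (ss_a / (P - 1) - sc) / n_c
  sa / (sa + sc)
}

#' Hierarchical AMOVA on a population genotype table
#'
#' Partitions allelic variance into among-groups, among-populations-within-
#' groups, and within-population components and reports the fixation indices
#' `F_CT = sigma_a / sigma_total`, `F_SC = sigma_b / (sigma_b + sigma_c)` and
#' `F_ST = (sigma_a + sigma_b) / sigma_total`.  Significance is assessed by
#' permutation: whole populations are permuted among groups for `F_CT`;
#' alleles are permuted among populations within groups for `F_SC`, and among
#' all populations for `F_ST`.  P-values count the observed statistic in both
#' numerator and denominator, so the smallest attainable value is
#' `1 / (n_permutations + 1)`.
#'
#' Negative variance components are retained in the result; percentage-of-
#' variance displays clamp them at zero ([summary()]).
#'
#' @param table a [population_table()].
#' @param grouping either the name of a column of `table` (default
#'   `"subdivision"`) or a named character vector mapping population to
#'   group.
#' @param n_permutations permutations per index (default 10000).
#' @param seed integer seed for the permutation RNG (identical seed gives
#'   identical p-values); `NULL` uses the session RNG.
#' @return An `amova_result` with variance components `sigma_among_groups`,
#'   `sigma_among_pops_within`, `sigma_within_pops`, indices `fct`, `fsc`,
#'   `fst`, permutation p-values, and bookkeeping fields.  Indices are `NA`
#'   with `monomorphic = TRUE` when the locus carries no variation.
#' @references Excoffier, Smouse & Quattro (1992) Genetics 131:479-491
#'   for the variance partition; Weir (1996) Genetic Data Analysis II for
#'   the unequal-size coefficients.
#' @export
amova <- function(table, grouping = "subdivision", n_permutations = 10000L,
                  seed = NULL) {
  stopifnot(inherits(table, "population_table"))
  grp <- .resolve_grouping(table, grouping)
  if (length(unique(grp)) < 2L)
    stop("amova needs at least two groups (F_CT undefined for one)",
         call. = FALSE)
  Ni <- 2L * table$n
  Ki <- table$n_ra + 2L * table$n_aa
  K <- sum(Ki)
  if (K == 0L || K == sum(Ni)) {
    return(structure(list(monomorphic = TRUE,
                          sigma_among_groups = NA_real_,
                          sigma_among_pops_within = NA_real_,
                          sigma_within_pops = NA_real_,
                          fct = NA_real_, fsc = NA_real_, fst = NA_real_,
                          p_fct = NA_real_, p_fsc = NA_real_,
                          p_fst = NA_real_,
                          n_permutations = n_permutations, seed = seed),
                     class = "amova_result"))
  }
  obs <- .amova_three_level(Ni, Ki, grp)
  with_seed(seed, {
    B <- as.integer(n_permutations)
    # F_CT: permute whole populations among groups
    fct_perm <- numeric(B)
    for (b in seq_len(B)) {
      fct_perm[b] <- .amova_three_level(Ni, Ki, sample(grp))$fct
    }
    p_fct <- (1 + sum(fct_perm >= obs$fct - 1e-12)) / (B + 1)
    one_pop_groups <- length(Ni) == length(unique(grp))
    if (one_pop_groups) {
      # no among-pops-within level: F_SC has no permutation null, F_ST
      # reduces to the one-level among-group statistic
      p_fsc <- NA_real_
      Kall <- .permute_alleles(Ni, K, B)
      fst_perm <- .fst_columns(Ni, Kall)
      p_fst <- (1 + sum(fst_perm >= obs$fst - 1e-12)) / (B + 1)
    } else {
      # F_SC: permute alleles among populations within each group
      Kperm <- matrix(0, nrow = length(Ni), ncol = B)
      for (g in unique(grp)) {
        idx <- which(grp == g)
        Kperm[idx, ] <- if (length(idx) == 1L) Ki[idx]
                        else .permute_alleles(Ni[idx], sum(Ki[idx]), B)
      }
      fsc_perm <- .fsc_columns(Ni, Kperm, grp)
      p_fsc <- (1 + sum(fsc_perm >= obs$fsc - 1e-12)) / (B + 1)
      # F_ST: permute alleles among all populations
      Kall <- .permute_alleles(Ni, K, B)
      fst_perm <- .fst_three_level_columns(Ni, Kall, grp)
      p_fst <- (1 + sum(fst_perm >= obs$fst - 1e-12)) / (B + 1)
    }
  })
  structure(list(monomorphic = FALSE,
                 sigma_among_groups = obs$sigma_a,
                 sigma_among_pops_within = obs$sigma_b,
                 sigma_within_pops = obs$sigma_c,
                 fct = obs$fct, fsc = obs$fsc, fst = obs$fst,
                 p_fct = p_fct, p_fsc = p_fsc, p_fst = p_fst,
                 n_permutations = as.integer(n_permutations), seed = seed,
                 grouping = grp),
            class = "amova_result")
}

# F_SC over permuted allele-count columns (group totals are preserved by the
# within-group permutation, so only sigma_b and sigma_c move).
.fsc_columns <- function(Ni, Kmat, grp) {
  grp <- as.character(grp)
  P <- length(Ni); G <- length(unique(grp)); N <- sum(Ni)
  Ag <- tapply(Ni, grp, sum)
  Kg <- rowsum(Kmat, grp)                       # G x B, constant across B
  pg <- Kg / as.vector(Ag[rownames(Kg)])
  ss_wp <- colSums(Kmat - Kmat^2 / Ni)
  pg_rows <- pg[grp, , drop = FALSE]
  ss_ap <- colSums(Ni * (Kmat / Ni - pg_rows)^2)
  sum_ni2_g <- tapply(Ni^2, grp, sum)
  n_p <- (N - sum(sum_ni2_g / Ag)) / (P - G)
  sc <- ss_wp / (N - P)
  sb <- (ss_ap / (P - G) - sc) / n_p
  sb / (sb + sc)
}

# Full three-level F_ST over permuted allele-count columns.
.fst_three_level_columns <- function(Ni, Kmat, grp) {
  grp <- as.character(grp)
  P <- length(Ni); G <- length(unique(grp)); N <- sum(Ni)
  Ag <- tapply(Ni, grp, sum)
  Kg <- rowsum(Kmat, grp)
  pg <- Kg / as.vector(Ag[rownames(Kg)])
  pbar <- colSums(Kmat) / N
  ss_wp <- colSums(Kmat - Kmat^2 / Ni)
  pg_rows <- pg[grp, , drop = FALSE]
  ss_ap <- colSums(Ni * (Kmat / Ni - pg_rows)^2)
  ss_ag <- colSums(as.vector(Ag[rownames(Kg)]) *
                   sweep(pg, 2, pbar, "-")^2)
  sum_ni2_g <- tapply(Ni^2, grp, sum)
  n_p   <- (N - sum(sum_ni2_g / Ag)) / (P - G)
  n_pp  <- (sum(sum_ni2_g / Ag) - sum(Ni^2) / N) / (G - 1)
  n_ppp <- (N - sum(Ag^2) / N) / (G - 1)
  sc <- ss_wp / (N - P)
  sb <- (ss_ap / (P - G) - sc) / n_p
  sa <- (ss_ag / (G - 1) - sc - n_pp * sb) / n_ppp
  (sa + sb) / (sa + sb + sc)
}

.resolve_grouping <- function(table, grouping) {
  if (length(grouping) == 1L && grouping %in% names(table))
    return(as.character(table[[grouping]]))
  if (!is.null(names(grouping))) {
    miss <- setdiff(table$population, names(grouping))
    if (length(miss))
      stop("grouping lacks population(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    return(as.character(grouping[table$population]))
  }
  stop("grouping must be a column name or a named population->group vector",
       call. = FALSE)
}

#' One-level AMOVA F_ST within a single group of populations
#'
#' Restricts the table to the populations of one subdivision and runs the
#' two-level (populations / within-populations) variance partition; the
#' permutation test reallocates alleles among the group's populations.
#'
#' @inheritParams amova
#' @param group subdivision label.
#' @return list with `fst`, `p_value`, `sigma_among`, `sigma_within`,
#'   `n_populations`, `n_permutations`, `seed`.
#' @export
within_group_fst <- function(table, group, n_permutations = 10000L,
                             seed = NULL) {
  stopifnot(inherits(table, "population_table"))
  sub <- table[table$subdivision == group, , drop = FALSE]
  if (nrow(sub) < 2L)
    stop("group '", group, "' has fewer than 2 populations", call. = FALSE)
  Ni <- 2L * sub$n
  Ki <- sub$n_ra + 2L * sub$n_aa
  if (sum(Ki) == 0L || sum(Ki) == sum(Ni))
    return(list(fst = NA_real_, p_value = NA_real_, monomorphic = TRUE,
                n_populations = nrow(sub)))
  obs <- .amova_one_level(Ni, Ki)
  p <- with_seed(seed, {
    B <- as.integer(n_permutations)
    perm <- .fst_columns(Ni, .permute_alleles(Ni, sum(Ki), B))
    (1 + sum(perm >= obs$fst - 1e-12)) / (B + 1)
  })
  list(fst = obs$fst, p_value = p, sigma_among = obs$sigma_a,
       sigma_within = obs$sigma_c, monomorphic = FALSE,
       n_populations = nrow(sub), n_permutations = as.integer(n_permutations),
       seed = seed)
}

#' Pairwise F_ST matrix
#'
#' Weir-Cockerham-style two-population estimator for allele-count data
#' (the variance-component ratio of the one-level nested ANOVA, equivalent to
#' the haploid Weir-Cockerham theta).  For a [frequency_matrix()] the
#' estimator is the multi-locus ratio of sums.  The diagonal is zero;
#' negative estimates are reported raw.  Pairs with a missing cell at every
#' locus are `NA`.
#'
#' @param x a [population_table()] or [frequency_matrix()].
#' @return symmetric numeric matrix with population dimnames.
#' @export
pairwise_fst <- function(x) {
  if (inherits(x, "population_table")) {
    af <- allele_frequency(x)
    f <- matrix(af$p_alt, nrow = 1)
    colnames(f) <- af$population
    x <- frequency_matrix(f, matrix(af$n_alleles, nrow = 1,
                                    dimnames = list(NULL, af$population)))
  }
  stopifnot(inherits(x, "frequency_matrix"))
  pops <- colnames(x$freq)
  P <- length(pops)
  if (P < 2L) stop("need at least two populations", call. = FALSE)
  out <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) for (j in seq(i + 1L, P)) {
    out[i, j] <- out[j, i] <-
      .wc_fst_multilocus(x$freq[, c(i, j), drop = FALSE],
                         x$n_alleles[, c(i, j), drop = FALSE])
  }
  out
}

# Multi-locus Weir-Cockerham theta (ratio of sums over loci) from allele
# frequencies p (loci x pops) and allele sample sizes n (loci x pops).
# Monomorphic loci contribute zero to both sums and are numerically safe.
.wc_fst_multilocus <- function(p, n) {
  num <- 0; den <- 0
  r <- ncol(p)
  for (l in seq_len(nrow(p))) {
    pl <- p[l, ]; nl <- n[l, ]
    ok <- !is.na(pl)
    if (sum(ok) < 2L) next
    pl <- pl[ok]; nl <- nl[ok]; rl <- length(pl)
    N <- sum(nl)
    pbar <- sum(nl * pl) / N
    msg <- sum(nl * pl * (1 - pl)) / sum(nl - 1)
    msp <- sum(nl * (pl - pbar)^2) / (rl - 1)
    nc <- (N - sum(nl^2) / N) / (rl - 1)
    num <- num + (msp - msg)
    den <- den + (msp + (nc - 1) * msg)
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' @export
print.amova_result <- function(x, ...) {
  if (isTRUE(x$monomorphic)) {
    cat("AMOVA: locus monomorphic, indices undefined\n")
    return(invisible(x))
  }
  comp <- c(x$sigma_among_groups, x$sigma_among_pops_within,
            x$sigma_within_pops)
  pct <- pmax(comp, 0); pct <- 100 * pct / sum(pct)
  cat("Hierarchical AMOVA (allele level)\n")
  cat(sprintf("  Among groups:            sigma^2 = %8.5f  (%5.1f%%)\n",
              comp[1], pct[1]))
  cat(sprintf("  Among pops within groups: sigma^2 = %8.5f  (%5.1f%%)\n",
              comp[2], pct[2]))
  cat(sprintf("  Within populations:      sigma^2 = %8.5f  (%5.1f%%)\n",
              comp[3], pct[3]))
  cat(sprintf("  F_CT = %.4f (p = %.4g)   F_SC = %.4f (p = %.4g)   F_ST = %.4f (p = %.4g)\n",
              x$fct, x$p_fct, x$fsc, x$p_fsc, x$fst, x$p_fst))
  cat(sprintf("  %d permutations\n", x$n_permutations))
  invisible(x)
}
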