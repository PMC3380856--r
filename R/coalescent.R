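# R-side configuration and wrappers for the structured-coalescent
# simulators, plus the summary statistics (He / F_ST vectors) computed from
# their output.

#' Configure the (hierarchical) island model
#'
#' `n_demes` demes of diploid size `deme_size` are split into `n_groups`
#' equal groups.  A lineage leaves its deme with per-generation probability
#' `m_within + m_between`; the within-group part moves it to a uniformly
#' chosen other deme of its own group, the between-group part to a uniformly
#' chosen deme of another group.  Hierarchy means `m_within >= m_between`.
#'
#' Instead of migration rates, `target_fst` may be supplied: total migration
#' is then solved from the island-model equilibrium `F_ST = 1 / (1 + 4 N m)`
#' and spread uniformly over destination demes (so the model is
#' non-hierarchical unless rates are given explicitly).
#'
#' @param n_demes number of demes (default 100).
#' @param n_groups number of groups (default 2); must divide `n_demes`.
#' @param deme_size diploid deme size (default 50).
#' @param m_within,m_between per-generation migration rates (totals, see
#'   above).
#' @param target_fst optional equilibrium F_ST used to solve for migration.
#' @param sample_spec data frame with columns `deme` (1-based index) and
#'   `n_diploid`, saying where the sample is taken.  Default: one deme per
#'   group, 68 and 35 diploids (mirroring the published two-subdivision
#'   comparisons).
#' @export
island_model_config <- function(n_demes = 100L, n_groups = 2L,
                                deme_size = 50, m_within = NULL,
                                m_between = NULL, target_fst = NULL,
                                sample_spec = NULL) {
  n_demes <- as.integer(n_demes); n_groups <- as.integer(n_groups)
  if (n_demes %% n_groups != 0L)
    stop("n_groups must divide n_demes evenly", call. = FALSE)
  if (is.null(m_within) != is.null(m_between))
    stop("give both m_within and m_between, or neither", call. = FALSE)
  if (is.null(m_within)) {
    if (is.null(target_fst))
      stop("give migration rates or target_fst", call. = FALSE)
    stopifnot(target_fst > 0, target_fst < 1)
    m_tot <- (1 / target_fst - 1) / (4 * deme_size)
    gsz <- n_demes / n_groups
    # spread uniformly over all destination demes
    m_within <- m_tot * (gsz - 1) / (n_demes - 1)
    m_between <- m_tot * (n_demes - gsz) / (n_demes - 1)
  }
  if (m_within < 0 || m_within > 1 || m_between < 0 || m_between > 1)
    stop("migration rates must lie in [0, 1]", call. = FALSE)
  if (is.null(sample_spec)) {
    gsz <- n_demes / n_groups
    demes <- 1L + gsz * (seq_len(min(n_groups, 2L)) - 1L)
    sample_spec <- data.frame(deme = demes,
                              n_diploid = c(68L, 35L)[seq_along(demes)])
  }
  stopifnot(all(sample_spec$deme >= 1L), all(sample_spec$deme <= n_demes),
            all(sample_spec$n_diploid > 0))
  structure(list(n_demes = n_demes, n_groups = n_groups,
                 deme_size = deme_size, m_within = m_within,
                 m_between = m_between, target_fst = target_fst,
                 sample_spec = sample_spec),
            class = "island_model_config")
}

#' Configure the three-deme settlement demography
#'
#' Three demes of diploid size `present_size` descend from a single
#' ancestral population.  Backwards in time each deme shrinks exponentially
#' from `present_size` to the ancestral size at the split, where all demes
#' merge into the constant-size ancestral population.  The split time and
#' ancestral size are drawn uniformly from their ranges for every simulated
#' replicate, which sweeps growth rates from strong expansion down to a
#' constant population.
#'
#' @param present_size current diploid effective size per deme (default 830).
#' @param ancestral_size_range diploid range of the ancestral population
#'   (default `c(70, 830)`).
#' @param split_time_range_years calendar range of the split (default
#'   `c(6350, 18000)` years before present).
#' @param generation_years years per generation (default 25).
#' @param migration_post_split per-generation migration among the three
#'   demes after the split, forward in time (default 0).
#' @param sample_sizes diploids sampled per deme; default `c(68, 35, 23)`,
#'   the sizes of the three published subdivision panels.
#' @export
settlement_demography <- function(present_size = 830,
                                  ancestral_size_range = c(70, 830),
                                  split_time_range_years = c(6350, 18000),
                                  generation_years = 25,
                                  migration_post_split = 0,
                                  sample_sizes = c(68L, 35L, 23L)) {
  stopifnot(present_size > 0,
            length(ancestral_size_range) == 2L,
            ancestral_size_range[1] <= ancestral_size_range[2],
            ancestral_size_range[1] > 0,
            length(split_time_range_years) == 2L,
            split_time_range_years[1] <= split_time_range_years[2],
            generation_years > 0, migration_post_split >= 0,
            length(sample_sizes) == 3L, all(sample_sizes > 0))
  structure(list(n_demes = 3L, present_size = present_size,
                 ancestral_size_range = ancestral_size_range,
                 split_time_range_years = split_time_range_years,
                 generation_years = generation_years,
                 migration_post_split = migration_post_split,
                 sample_sizes = as.integer(sample_sizes)),
            class = "settlement_demography")
}

# Internal: deme index (0-based) per sampled chromosome for a sample spec.
.chrom_demes <- function(demes, n_diploid) {
  rep(as.integer(demes) - 1L, times = 2L * as.integer(n_diploid))
}

#' Simulate one SNP under the island model
#'
#' Runs the structured coalescent of the sampled chromosomes (migration as
#' backwards lineage movement) and places a single mutation uniformly on the
#' genealogy's branch length, so the locus is always polymorphic in the
#' pooled sample.
#'
#' @param config an [island_model_config()].
#' @param seed RNG seed (`NULL` = session RNG).
#' @return A `simulated_locus`: derived-allele count and allele sample size
#'   per sampled deme, plus `tmrca` and `tree_length` in generations.
#' @export
simulate_island_snp <- function(config, seed = NULL) {
  stopifnot(inherits(config, "island_model_config"))
  with_seed(seed, {
    sd <- .chrom_demes(config$sample_spec$deme, config$sample_spec$n_diploid)
    gsz <- config$n_demes / config$n_groups
    deme_group <- rep(seq_len(config$n_groups) - 1L, each = gsz)
    res <- island_snp_cpp(sd, config$n_demes, deme_group, config$deme_size,
                          config$m_within, config$m_between)
    demes <- as.integer(config$sample_spec$deme) - 1L
    derived <- vapply(demes, function(d) sum(res$derived[sd == d]),
                      integer(1))
    structure(list(derived = derived,
                   n_alleles = 2L * as.integer(config$sample_spec$n_diploid),
                   deme = config$sample_spec$deme,
                   tmrca = res$tmrca, tree_length = res$tree_length),
              class = "simulated_locus")
  })
}

#' Simulate a linked region under the settlement demography
#'
#' Draws the split time and ancestral size uniformly from their ranges, runs
#' the three-deme coalescent and places `n_snps` mutations.  By default all
#' markers share one genealogy (a fully linked region); `linked = FALSE`
#' simulates an independent genealogy per SNP under the same parameter draw.
#'
#' @param params a [settlement_demography()].
#' @param n_snps segregating sites per region (default 20).
#' @param sample_sizes per-deme diploid sample sizes (defaults to the ones
#'   in `params`).
#' @param linked single genealogy for all SNPs (default `TRUE`)?
#' @param seed RNG seed.
#' @return A `locus_set`: matrix of derived counts (loci x demes), matching
#'   allele sample sizes, and the drawn `split_gen` / `ancestral_size`.
#' @export
simulate_settlement_region <- function(params, n_snps = 20L,
                                       sample_sizes = NULL, linked = TRUE,
                                       seed = NULL) {
  stopifnot(inherits(params, "settlement_demography"), n_snps >= 1L)
  if (is.null(sample_sizes)) sample_sizes <- params$sample_sizes
  if (any(sample_sizes > params$present_size))
    warning("sample larger than a deme's diploid size; coalescent still ",
            "defined", call. = FALSE)
  with_seed(seed, {
    split_years <- runif(1, params$split_time_range_years[1],
                         params$split_time_range_years[2])
    split_gen <- split_years / params$generation_years
    anc <- runif(1, params$ancestral_size_range[1],
                 params$ancestral_size_range[2])
    sd <- .chrom_demes(seq_len(params$n_demes), sample_sizes)
    if (linked) {
      res <- settlement_snps_cpp(sd, params$n_demes, params$present_size,
                                 anc, split_gen,
                                 params$migration_post_split,
                                 as.integer(n_snps))
      counts <- res$counts
    } else {
      counts <- matrix(0L, nrow = n_snps, ncol = params$n_demes)
      for (s in seq_len(n_snps)) {
        res <- settlement_snps_cpp(sd, params$n_demes, params$present_size,
                                   anc, split_gen,
                                   params$migration_post_split, 1L)
        counts[s, ] <- res$counts[1, ]
      }
    }
    colnames(counts) <- paste0("deme", seq_len(params$n_demes))
    locus_set(counts, 2L * as.integer(sample_sizes),
              meta = list(split_gen = split_gen,
                          split_years = split_years,
                          ancestral_size = anc))
  })
}

#' Bundle per-deme derived-allele counts for a set of loci
#'
#' @param counts integer matrix, loci in rows, demes/populations in columns.
#' @param n_alleles allele sample sizes: a vector (one per deme) or a matrix
#'   matching `counts`.
#' @param meta optional list of provenance fields.
#' @export
locus_set <- function(counts, n_alleles, meta = list()) {
  counts <- as.matrix(counts)
  if (is.null(dim(n_alleles)))
    n_alleles <- matrix(n_alleles, nrow = nrow(counts), ncol = ncol(counts),
                        byrow = TRUE)
  stopifnot(identical(dim(counts), dim(n_alleles)),
            all(counts <= n_alleles), all(counts >= 0))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("deme", seq_len(ncol(counts)))
  dimnames(n_alleles) <- dimnames(counts)
  structure(list(counts = counts, n_alleles = n_alleles, meta = meta),
            class = "locus_set")
}

#' Summary-statistic vector of a locus set
#'
#' The S-vector layout is fixed: mean expected heterozygosity (per-locus
#' unbiased He averaged within demes, then across demes and loci), the
#' global multi-locus Weir-Cockerham F_ST across all demes, then the
#' pairwise F_ST of every deme pair in column order
#' (1-2, 1-3, ..., 2-3, ...).  Monomorphic loci contribute He = 0 and drop
#' out of the F_ST ratio of sums harmlessly.
#'
#' @param loci a [locus_set()] or [frequency_matrix()].
#' @param grouping optional character vector of deme labels; when given,
#'   demes are pooled by label before summarising.
#' @return A `summary_stats` list: `mean_he`, `global_fst`, `pairwise_fst`
#'   (named vector), `per_locus_he`.  [as_summary_vector()] flattens it for
#'   distance computations.
#' @export
summarize_loci <- function(loci, grouping = NULL) {
  if (inherits(loci, "frequency_matrix")) {
    p <- loci$freq; n <- loci$n_alleles
  } else if (inherits(loci, "locus_set")) {
    p <- loci$counts / loci$n_alleles; n <- loci$n_alleles
  } else if (inherits(loci, "simulated_locus")) {
    p <- matrix(loci$derived / loci$n_alleles, nrow = 1,
                dimnames = list(NULL, paste0("deme", loci$deme)))
    n <- matrix(loci$n_alleles, nrow = 1, dimnames = dimnames(p))
  } else stop("unsupported input", call. = FALSE)
  if (!is.null(grouping)) {
    stopifnot(length(grouping) == ncol(p))
    cnt <- p * n
    cnt <- t(rowsum(t(cnt), grouping))
    n <- t(rowsum(t(n), grouping))
    p <- cnt / n
  }
  if (nrow(p) < 1L) stop("need at least one locus", call. = FALSE)
  he <- 2 * p * (1 - p) * n / (n - 1)              # unbiased, per cell
  per_locus_he <- rowMeans(he, na.rm = TRUE)
  demes <- colnames(p)
  pw <- c()
  if (length(demes) >= 2L) {
    for (i in seq_len(length(demes) - 1L)) for (j in seq(i + 1L,
                                                          length(demes))) {
      v <- .wc_fst_multilocus(p[, c(i, j), drop = FALSE],
                              n[, c(i, j), drop = FALSE])
      pw <- c(pw, setNames(v, paste0(demes[i], ":", demes[j])))
    }
  }
  structure(list(mean_he = mean(per_locus_he),
                 global_fst = .wc_fst_multilocus(p, n),
                 pairwise_fst = pw,
                 per_locus_he = per_locus_he),
            class = "summary_stats")
}

#' Flatten a summary_stats object to its fixed-layout numeric vector
#'
#' Layout: `mean_he`, `global_fst`, then the pairwise F_ST entries in deme
#' column order.  This is the vector the Euclidean neutrality fit works on.
#'
#' @param s a `summary_stats` object (or a numeric vector, returned as-is).
#' @export
as_summary_vector <- function(s) {
  if (is.numeric(s)) return(s)
  stopifnot(inherits(s, "summary_stats"))
  c(mean_he = s$mean_he, global_fst = s$global_fst, s$pairwise_fst)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Summary stats: mean He = %.4f, global F_ST = %.4f\n",
              x$mean_he, x$global_fst))
  if (length(x$pairwise_fst)) {
    cat("  pairwise F_ST:\n")
    for (nm in names(x$pairwise_fst))
      cat(sprintf("    %s: %.4f\n", nm, x$pairwise_fst[nm]))
  }
  invisible(x)
}
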