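# Synthetic-data generators.  They produce inputs with the statistical
# structure the analysis assumes — genotype-count tables under drift with
# optional directional selection in one subdivision, and haplotype panels
# around a focal derived allele of known age — so every stage of the
# inference chain can be validated without external data.

#' Scenario for forward Wright-Fisher drift tables
#'
#' Defaults mirror the selective scenario the analysis is after: villages of
#' effective size 830 diploids (the settlement-demography size), weak
#' inter-village gene flow (m = 0.005), a standing variant at frequency
#' 0.15, and 360 generations — the maize-domestication era at 25
#' years/generation.
#'
#' @param n_populations_per_group populations per group (recycled over
#'   groups).
#' @param group_labels group (subdivision) labels.
#' @param founder_frequency initial alt-allele frequency in every
#'   population.
#' @param generations forward generations simulated.
#' @param deme_size diploid size per population.
#' @param migration per-generation mixing rate towards the metapopulation
#'   mean frequency.
#' @param selection_s additive selection coefficient for the alt allele
#'   (genotype fitnesses 1, 1 + s/2, 1 + s), applied only in
#'   `selected_group`; 0 is neutral everywhere.
#' @param selected_group label of the group under selection (default the
#'   first).
#' @param sample_n diploid individuals sampled per population at the end.
#' @export
drift_scenario <- function(n_populations_per_group = 2L,
                           group_labels = c("A", "B"),
                           founder_frequency = 0.15,
                           generations = 360L, deme_size = 830L,
                           migration = 0.005, selection_s = 0,
                           selected_group = group_labels[1],
                           sample_n = 50L) {
  stopifnot(founder_frequency >= 0, founder_frequency <= 1,
            generations >= 1L, deme_size >= 1L,
            migration >= 0, migration <= 1,
            selection_s >= -1, selection_s <= 1, sample_n >= 1L)
  structure(list(n_populations_per_group =
                   as.integer(n_populations_per_group),
                 group_labels = group_labels,
                 founder_frequency = founder_frequency,
                 generations = as.integer(generations),
                 deme_size = as.integer(deme_size),
                 migration = migration, selection_s = selection_s,
                 selected_group = selected_group,
                 sample_n = as.integer(sample_n)),
            class = "drift_scenario")
}

#' Simulate a population genotype table under drift (and selection)
#'
#' Forward Wright-Fisher simulation per population: each generation the
#' frequency is (1) mixed towards the metapopulation mean at rate `m`,
#' (2) pushed by additive viability selection in the designated group, then
#' (3) resampled binomially over `2N` alleles.  Final genotype counts are
#' drawn multinomially under Hardy-Weinberg at each population's final
#' frequency.  Fixation and loss are allowed.
#'
#' @param scenario a [drift_scenario()].
#' @param seed RNG seed.
#' @return A [population_table()] whose `subdivision` column holds the
#'   group labels.
#' @export
simulate_drift_table <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "drift_scenario"))
  with_seed(seed, {
    npg <- rep_len(scenario$n_populations_per_group,
                   length(scenario$group_labels))
    grp <- rep(scenario$group_labels, times = npg)
    P <- length(grp)
    p <- rep(scenario$founder_frequency, P)
    N2 <- 2 * scenario$deme_size
    s <- scenario$selection_s
    sel <- grp == scenario$selected_group
    for (g in seq_len(scenario$generations)) {
      p <- (1 - scenario$migration) * p + scenario$migration * mean(p)
      if (s != 0) {
        # additive viability selection: p' = p (1 + s (1 + p) / 2)/(1 + s p)
        ps <- p[sel]
        p[sel] <- ps * (1 + s * (1 + ps) / 2) / (1 + s * ps)
      }
      p <- rbinom(P, N2, p) / N2
    }
    n <- scenario$sample_n
    geno <- vapply(p, function(pp) {
      pr <- c((1 - pp)^2, 2 * pp * (1 - pp), pp^2)
      rmultinom(1, n, pr)[, 1]
    }, numeric(3))
    population_table(population = paste0(grp, "_",
                                         unlist(lapply(npg, seq_len))),
                     subdivision = grp, n = rep(n, P),
                     n_rr = geno[1, ], n_ra = geno[2, ], n_aa = geno[3, ],
                     locus_id = "synthetic_drift",
                     extra = data.frame(true_final_freq = p))
  })
}

#' Scenario for synthetic intra-allelic haplotype panels
#'
#' @param true_age_generations age of the focal derived allele.
#' @param n_carriers,n_noncarriers chromosomes of each kind.
#' @param rec_frac per-marker recombination fractions to the focal site.
#' @param background_freq per-marker background frequency of the ancestral
#'   marker allele (recycled).
#' @param growth_rate recorded for downstream priors.
#' @export
age_panel_scenario <- function(true_age_generations = 300,
                               n_carriers = 500L, n_noncarriers = 500L,
                               rec_frac = seq(5e-4, 1e-2, length.out = 19L),
                               background_freq = 0.5,
                               growth_rate = 0.005) {
  stopifnot(true_age_generations > 0, n_carriers >= 1L,
            all(rec_frac >= 0), all(rec_frac <= 0.5))
  structure(list(true_age_generations = true_age_generations,
                 n_carriers = as.integer(n_carriers),
                 n_noncarriers = as.integer(n_noncarriers),
                 rec_frac = rec_frac,
                 background_freq = rep_len(background_freq,
                                           length(rec_frac)),
                 growth_rate = growth_rate),
            class = "age_panel_scenario")
}

#' Simulate a haplotype panel around a derived allele of known age
#'
#' The intra-allelic genealogy of the carriers is taken as star-shaped (the
#' regime produced by rapid exponential growth): each carrier lineage spans
#' the full allele age, retains the ancestral allele at marker `i` with
#' probability `exp(-c_i * t)`, and otherwise draws that marker from the
#' background frequency.  Non-carriers are drawn entirely from the
#' background.  The ancestral haplotype is all-ones.
#'
#' @param scenario an [age_panel_scenario()].
#' @param seed RNG seed.
#' @return A [haplotype_panel()] with the true ancestral haplotype attached.
#' @export
simulate_age_panel <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "age_panel_scenario"))
  with_seed(seed, {
    M <- length(scenario$rec_frac)
    t <- scenario$true_age_generations
    q <- scenario$background_freq            # freq of ancestral allele (=1)
    nc <- scenario$n_carriers; nn <- scenario$n_noncarriers
    retain <- matrix(runif(nc * M) < rep(exp(-scenario$rec_frac * t),
                                         each = nc), nc, M)
    background_draw <- matrix(runif(nc * M) < rep(q, each = nc), nc, M)
    carriers <- ifelse(retain, 1L, as.integer(background_draw))
    noncarr <- matrix(as.integer(runif(nn * M) < rep(q, each = nn)), nn, M)
    haplotype_panel(carrier = c(rep(TRUE, nc), rep(FALSE, nn)),
                    markers = rbind(carriers, noncarr),
                    rec_frac = scenario$rec_frac,
                    ancestral = rep(1L, M))
  })
}

#' Packaged transcriptions of the published data tables
#'
#' Returns the genotype-count table of the 50 Native American populations
#' (1905 individuals, three subsistence subdivisions) and the seven-row
#' maize-pollen date table.  Counts, ages and the printed two-decimal
#' frequency column are verbatim transcriptions.  Three rows of the
#' genotype table carry a printed frequency that disagrees with the one
#' recomputed from the row's own counts (Zapotec 0.24 vs 0.23, Guaymi 0.15
#' vs 0.14, Hulliche 0.11 vs 0.12); the `printed_cys` column preserves the
#' printed values so the disagreement stays visible.
#'
#' @return list with elements `table1` (a [population_table()], extra
#'   column `printed_cys`) and `table2` (a [read_pollen_table()] data
#'   frame).
#' @export
abca1_fixtures <- function() {
  t1 <- read_population_table(system.file("extdata", "table1.csv",
                                          package = "genecult"),
                              locus_id = "ABCA1_Arg230Cys")
  t2 <- read_pollen_table(system.file("extdata", "table2.csv",
                                      package = "genecult"))
  list(table1 = t1, table2 = t2)
}
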