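# Independent oracles used across the suite.  They deliberately avoid the
# package's closed-form implementations: sums of squares are computed by
# explicit enumeration over individual alleles, and the two-population
# F_ST oracle evaluates the Weir-Cockerham estimator from its textbook
# mean-square definition.

# Explicit allele-level sums of squares for a nested groups/populations
# design.  Ni = allele counts, Ki = alt counts, grp = group label per pop.
oracle_ss <- function(Ni, Ki, grp) {
  x <- unlist(mapply(function(K, N) c(rep(1, K), rep(0, N - K)), Ki, Ni,
                     SIMPLIFY = FALSE))
  pop <- rep(seq_along(Ni), Ni)
  g <- grp[pop]
  pm <- tapply(x, pop, mean)
  gm <- tapply(x, g, mean)
  list(among_groups = sum((gm[g] - mean(x))^2),
       among_pops = sum((pm[pop] - gm[g])^2),
       within = sum((x - pm[pop])^2))
}

# Haploid Weir-Cockerham theta for any number of populations, straight from
# the mean squares (MSP, MSG) definition.
oracle_wc_theta <- function(n_alleles, p) {
  r <- length(p); N <- sum(n_alleles)
  pbar <- sum(n_alleles * p) / N
  msg <- sum(n_alleles * p * (1 - p)) / sum(n_alleles - 1)
  msp <- sum(n_alleles * (p - pbar)^2) / (r - 1)
  nc <- (N - sum(n_alleles^2) / N) / (r - 1)
  (msp - msg) / (msp + (nc - 1) * msg)
}

# Small exchangeable genotype table: every population drawn from the same
# Hardy-Weinberg multinomial, so any allele permutation null is true.
exchangeable_table <- function(n_pops = 5L, n = 30L, p = 0.3) {
  geno <- vapply(seq_len(n_pops), function(i) {
    pr <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    rmultinom(1, n, pr)[, 1]
  }, numeric(3))
  population_table(paste0("pop", seq_len(n_pops)),
                   subdivision = rep("g", n_pops), n = rep(n, n_pops),
                   n_rr = geno[1, ], n_ra = geno[2, ], n_aa = geno[3, ])
}

# Minimal two-population, one-biallelic-site VCF written to a temp file.
write_toy_vcf <- function(path, gts = c("0/0", "0/1", "1/1",
                                        "0/0", "0/1", "1/1"),
                          extra_site = FALSE) {
  samples <- paste0("S", seq_along(gts))
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=9>",
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             paste(c("9", "1000", "rs1", "G", "A", ".", "PASS", ".", "GT",
                     gts), collapse = "\t"))
  if (extra_site)
    lines <- c(lines,
               paste(c("9", "2000", "rs2", "G", "A,T", ".", "PASS", ".",
                       "GT", gts), collapse = "\t"))
  writeLines(lines, path)
  data.frame(sample = samples,
             population = rep(c("popA", "popB"), each = length(gts) / 2),
             subdivision = "g", stringsAsFactors = FALSE)
}

# 20-locus set of three-deme frequencies produced by the forward drift
# generator: one drift table per locus, founder frequencies spread over
# (0.1, 0.9).  Returns a locus_set comparable with the settlement summaries.
drift_locus_set <- function(s = 0, n_loci = 20L, generations = 400L,
                            deme_size = 830L, sample_n = 50L,
                            founder = NULL, seed = NULL) {
  with_seed_local <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  with_seed_local(seed, {
    if (is.null(founder)) founder <- runif(n_loci, 0.1, 0.9)
    counts <- matrix(0L, n_loci, 3)
    for (l in seq_len(n_loci)) {
      sc <- drift_scenario(n_populations_per_group = 1L,
                           group_labels = c("d1", "d2", "d3"),
                           founder_frequency = founder[l],
                           generations = generations,
                           deme_size = deme_size, migration = 0,
                           selection_s = s, selected_group = "d1",
                           sample_n = sample_n)
      tab <- simulate_drift_table(sc)
      counts[l, ] <- tab$n_ra + 2L * tab$n_aa
    }
    colnames(counts) <- c("deme1", "deme2", "deme3")
    locus_set(counts, rep(2L * sample_n, 3))
  })
}
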