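#' Build a population genotype table for one biallelic SNP
#'
#' A population table holds, for each population, the three genotype counts of
#' a single biallelic SNP together with a subdivision label (and optional
#' country / coordinate metadata).  It is the elementary data structure of the
#' package: AMOVA, subdivision comparisons and the frequency-based allele age
#' all start from it.
#'
#' @param population character vector of unique population names.
#' @param subdivision character vector of subdivision labels.  The three
#'   labels used for the published data are
#'   `"mesoamerican_agriculturalist"`, `"andean_agriculturalist"` and
#'   `"sa_hunter_gatherer"`, but any label set is accepted so synthetic
#'   scenarios can define their own.
#' @param n integer vector, individuals sampled per population.
#' @param n_rr,n_ra,n_aa integer vectors of genotype counts
#'   (ref/ref, ref/alt, alt/alt).  Must satisfy `n_rr + n_ra + n_aa == n`.
#' @param country,lat,lon optional metadata (country name, decimal degrees).
#'   Coordinates are carried along but used by no statistic.
#' @param locus_id single string naming the SNP.
#' @param extra optional data frame of additional per-population columns
#'   (carried through unchanged).
#'
#' @return A `population_table`: a data frame with one row per population and
#'   columns `population`, `subdivision`, `country`, `lat`, `lon`, `n`,
#'   `n_rr`, `n_ra`, `n_aa` (plus any extra columns), and attribute
#'   `locus_id`.
#' @seealso [read_population_table()], [allele_frequency()], [amova()]
#' @export
population_table <- function(population, subdivision, n, n_rr, n_ra, n_aa,
                             country = NA_character_, lat = NA_real_,
                             lon = NA_real_, locus_id = "locus",
                             extra = NULL) {
  population <- as.character(population)
  if (length(population) == 0L) stop("no populations", call. = FALSE)
  if (anyDuplicated(population))
    stop("population names must be unique; duplicated: ",
         paste(unique(population[duplicated(population)]), collapse = ", "),
         call. = FALSE)
  n <- as.integer(n); n_rr <- as.integer(n_rr)
  n_ra <- as.integer(n_ra); n_aa <- as.integer(n_aa)
  if (any(c(n, n_rr, n_ra, n_aa) < 0L, na.rm = TRUE))
    stop("genotype counts must be non-negative", call. = FALSE)
  bad <- which(n_rr + n_ra + n_aa != n)
  if (length(bad))
    stop("genotype counts do not sum to n for population(s): ",
         paste(population[bad], collapse = ", "), call. = FALSE)
  tab <- data.frame(population = population,
                    subdivision = as.character(subdivision),
                    country = country, lat = as.numeric(lat),
                    lon = as.numeric(lon),
                    n = n, n_rr = n_rr, n_ra = n_ra, n_aa = n_aa,
                    stringsAsFactors = FALSE)
  if (!is.null(extra)) tab <- cbind(tab, extra)
  structure(tab, locus_id = as.character(locus_id)[1],
            class = c("population_table", "data.frame"))
}

#' Read a population genotype table from CSV/TSV
#'
#' The documented schema is a header row containing at least
#' `population, subdivision, n, n_rr, n_ra, n_aa`; the metadata columns
#' `country`, `lat`, `lon` are optional, and any further columns are carried
#' through.  Row order is preserved.
#'
#' @param path path to the delimited file.
#' @param dialect `"csv"` or `"tsv"`.
#' @param locus_id locus name stored on the result.
#' @return A [population_table()].
#' @export
read_population_table <- function(path, dialect = c("csv", "tsv"),
                                  locus_id = "locus") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = if (dialect == "csv") "," else "\t",
                  stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("population", "subdivision", "n", "n_rr", "n_ra", "n_aa")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) stop("no populations", call. = FALSE)
  opt <- function(col, default) if (col %in% names(raw)) raw[[col]] else default
  extra_cols <- setdiff(names(raw), c(required, "country", "lat", "lon"))
  population_table(
    population = raw$population, subdivision = raw$subdivision,
    n = raw$n, n_rr = raw$n_rr, n_ra = raw$n_ra, n_aa = raw$n_aa,
    country = opt("country", NA_character_),
    lat = opt("lat", NA_real_), lon = opt("lon", NA_real_),
    locus_id = locus_id,
    extra = if (length(extra_cols)) raw[extra_cols] else NULL)
}

#' Read genotype counts for one biallelic site from a VCF
#'
#' Parses the GT field of a single site and aggregates genotype counts per
#' population according to a sample map.  Missing genotypes (`./.`) are
#' excluded, reducing that population's `n` (direct counting, no imputation);
#' unmapped samples are dropped with a warning.
#'
#' @param path path to a VCF (v4.x) file.
#' @param locus site as `"chrom:pos"`.
#' @param sample_map data frame with columns `sample`, `population`,
#'   `subdivision`.
#' @param locus_id locus name for the result (defaults to `locus`).
#' @return A [population_table()].
#' @export
read_vcf_biallelic <- function(path, locus, sample_map, locus_id = locus) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(all(c("sample", "population", "subdivision") %in%
                names(sample_map)))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  key <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  hit <- which(key == locus)
  if (length(hit) == 0L) stop("locus not found: ", locus, call. = FALSE)
  hit <- hit[1]
  alt <- fix[hit, "ALT"]
  if (is.na(alt) || grepl(",", alt))
    stop("site ", locus, " is not biallelic", call. = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")[hit, ]
  samples <- names(gt)
  mapped <- samples %in% sample_map$sample
  if (any(!mapped)) {
    warning("excluding unmapped sample(s): ",
            paste(samples[!mapped], collapse = ", "), call. = FALSE)
    gt <- gt[mapped]; samples <- samples[mapped]
  }
  idx <- match(samples, sample_map$sample)
  pop <- sample_map$population[idx]
  # normalise GT: phased or unphased, count alt alleles; NA if any missing
  dose <- vapply(strsplit(gt, "[/|]"), function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  keep <- !is.na(dose)
  pops <- unique(sample_map$population)
  cnt <- function(p, d) sum(pop == p & keep & dose == d)
  n_rr <- vapply(pops, cnt, integer(1), d = 0L)
  n_ra <- vapply(pops, cnt, integer(1), d = 1L)
  n_aa <- vapply(pops, cnt, integer(1), d = 2L)
  subdiv <- sample_map$subdivision[match(pops, sample_map$population)]
  population_table(pops, subdiv, n = n_rr + n_ra + n_aa,
                   n_rr = n_rr, n_ra = n_ra, n_aa = n_aa,
                   locus_id = locus_id)
}

#' Allele frequencies by direct counting
#'
#' `p_alt = (n_ra + 2 n_aa) / (2 n)`, kept at full precision; rounding only
#' happens at display time ([display_frequency()]).
#'
#' @param rec a [population_table()] (vectorised over rows) or a single-row
#'   subset of one.
#' @return data frame with columns `population`, `p_ref`, `p_alt`,
#'   `n_alleles`.
#' @export
allele_frequency <- function(rec) {
  stopifnot(inherits(rec, "population_table"))
  if (any(rec$n == 0L))
    stop("allele frequency undefined for n = 0 (population(s): ",
         paste(rec$population[rec$n == 0L], collapse = ", "), ")",
         call. = FALSE)
  p_alt <- (rec$n_ra + 2 * rec$n_aa) / (2 * rec$n)
  data.frame(population = rec$population, p_ref = 1 - p_alt, p_alt = p_alt,
             n_alleles = 2L * rec$n, stringsAsFactors = FALSE)
}

#' Two-decimal display frequency (half-up rounding)
#'
#' The published frequency columns print two decimals; comparisons against
#' them use this helper so the full-precision internal values are untouched.
#'
#' @param p numeric vector of proportions.
#' @param digits decimals shown.
#' @export
display_frequency <- function(p, digits = 2L) round_half_up(p, digits)

#' Expected heterozygosity of a biallelic locus
#'
#' Biased form `2 p (1 - p)`; the unbiased form multiplies by
#' `n_alleles / (n_alleles - 1)`.
#'
#' @param p allele proportion in `[0, 1]`.
#' @param n_alleles number of sampled alleles (`2 n`); required when
#'   `unbiased = TRUE`.
#' @param unbiased apply the small-sample correction?
#' @export
expected_heterozygosity <- function(p, n_alleles = NULL, unbiased = FALSE) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  he <- 2 * p * (1 - p)
  if (unbiased) {
    if (is.null(n_alleles) || any(n_alleles < 2))
      stop("unbiased form needs n_alleles >= 2", call. = FALSE)
    he <- he * n_alleles / (n_alleles - 1)
  }
  he
}

#' Unweighted mean alt-allele frequency of a subdivision
#'
#' The arithmetic mean of the per-population `p_alt` over all populations
#' carrying the given subdivision label (each population counts once,
#' regardless of its sample size).
#'
#' @param table a [population_table()].
#' @param subdivision a subdivision label present in the table.
#' @export
subdivision_mean_frequency <- function(table, subdivision) {
  stopifnot(inherits(table, "population_table"))
  valid <- unique(table$subdivision)
  if (!subdivision %in% valid)
    stop("unknown subdivision '", subdivision, "'; valid labels: ",
         paste(valid, collapse = ", "), call. = FALSE)
  sub <- table[table$subdivision == subdivision, , drop = FALSE]
  class(sub) <- class(table)
  mean(allele_frequency(sub)$p_alt)
}

#' Total number of sampled individuals
#'
#' @param table a [population_table()].
#' @param subset optional subdivision label restricting the sum.
#' @export
total_sample_size <- function(table, subset = NULL) {
  stopifnot(inherits(table, "population_table"))
  if (is.null(subset)) return(sum(table$n))
  sum(table$n[table$subdivision %in% subset])
}

#' @export
print.population_table <- function(x, ...) {
  cat("Population genotype table: locus", attr(x, "locus_id"), "-",
      nrow(x), "populations,", sum(x$n), "individuals\n")
  NextMethod()
  invisible(x)
}

#' Build a loci-by-populations frequency matrix
#'
#' Holds alt-allele frequencies per locus and population with the per-cell
#' allele sample sizes (needed by every F_ST estimator) and a subdivision
#' label per population.  Missing cells are `NA` and are flagged, never
#' silently treated as zero.
#'
#' @param freq numeric matrix (loci in rows, populations in columns) of
#'   alt-allele frequencies in `[0, 1]`.
#' @param n_alleles matrix (or vector recycled per column) of allele sample
#'   sizes; must be positive wherever `freq` is present.
#' @param subdivision named character vector of subdivision labels, one per
#'   population column.
#' @return A `frequency_matrix` object.
#' @export
frequency_matrix <- function(freq, n_alleles, subdivision = NULL) {
  freq <- as.matrix(freq)
  if (is.null(dim(n_alleles)))
    n_alleles <- matrix(n_alleles, nrow = nrow(freq), ncol = ncol(freq),
                        byrow = TRUE)
  n_alleles <- as.matrix(n_alleles)
  stopifnot(identical(dim(freq), dim(n_alleles)))
  ok <- !is.na(freq)
  if (any(freq[ok] < 0 | freq[ok] > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  if (any(n_alleles[ok] <= 0))
    stop("allele sample sizes must be positive where a frequency is present",
         call. = FALSE)
  if (is.null(colnames(freq)))
    colnames(freq) <- paste0("pop", seq_len(ncol(freq)))
  if (is.null(rownames(freq)))
    rownames(freq) <- paste0("locus", seq_len(nrow(freq)))
  dimnames(n_alleles) <- dimnames(freq)
  if (is.null(subdivision))
    subdivision <- setNames(rep(NA_character_, ncol(freq)), colnames(freq))
  structure(list(freq = freq, n_alleles = n_alleles,
                 subdivision = subdivision),
            class = "frequency_matrix")
}

#' Read a frequency matrix and its companion sample-size file
#'
#' First column is the locus id, remaining columns are populations; the
#' companion file has the same layout and carries allele sample sizes.
#'
#' @param path frequencies CSV.
#' @param sizes_path allele sample sizes CSV (same layout).
#' @param subdivision optional named character vector of labels per
#'   population.
#' @export
read_frequency_matrix <- function(path, sizes_path, subdivision = NULL) {
  fr <- read.csv(path, check.names = FALSE)
  sz <- read.csv(sizes_path, check.names = FALSE)
  f <- as.matrix(fr[, -1, drop = FALSE]); rownames(f) <- fr[[1]]
  s <- as.matrix(sz[, -1, drop = FALSE]); rownames(s) <- sz[[1]]
  if (!identical(dimnames(f), dimnames(s)))
    stop("frequency and size files disagree on loci/populations",
         call. = FALSE)
  frequency_matrix(f, s, subdivision)
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat("Frequency matrix:", nrow(x$freq), "loci x", ncol(x$freq),
      "populations\n")
  invisible(x)
}
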