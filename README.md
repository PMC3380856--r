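# genecult

Population-genetic inference for a gene–culture coevolution question:
did the spread of maize agriculture drive the frequency of the
*ABCA1* Arg230Cys variant (rs9282541, derived allele private to the
Americas) in Mesoamerican populations?  The package implements the full
chain of analyses used to address that question on single-SNP genotype
count data, for population geneticists and human-evolution researchers
who want each stage as a reusable, tested building block:

* **Hierarchical AMOVA** on genotype counts — variance components among
  subdivisions / among populations within subdivisions / within
  populations, with the fixation indices
  F<sub>CT</sub> = σ²ₐ/σ²ₜ, F<sub>SC</sub> = σ²_b/(σ²_b+σ²_c),
  F<sub>ST</sub> = (σ²ₐ+σ²_b)/σ²ₜ and permutation p-values
  (`amova()`, `within_group_fst()`, `pairwise_fst()`).
* **Allele ages** — the Kimura–Ohta frequency method
  E(t₁) = [−2p/(1−p)] ln p (in units of 2N generations), and
  intra-allelic LD-decay estimators: the moment inversion
  t̂ = −ln(y′)/c and a Bayesian MCMC sampler over the age with the
  marker backgrounds integrated out (`kimura_ohta_age()`,
  `moment_ld_age()`, `mcmc_ld_age()`).
* **Coalescent simulators** in C++ — a (hierarchical) island model for
  the F<sub>ST</sub>-outlier null and a three-deme settlement demography
  with exponential size change into a single ancestral population
  (`simulate_island_snp()`, `simulate_settlement_region()`).
* **FDIST-style outlier test** — joint (He, F<sub>ST</sub>) null cloud,
  He-conditional kernel p-values, quantile envelopes
  (`build_null()`, `kde_pvalue()`, `outlier_scan()`).
* **ABC-style neutrality fit** — Euclidean distance ∂ = ‖S − S\*‖
  between observed and simulated summary-statistic vectors
  (`neutrality_fit()`).
* **Gene–culture correlation** — tie-corrected Spearman correlation of
  allele frequencies with archaeological *Zea* pollen dates, and
  subdivision t-tests (`spearman_cor()`, `frequency_vs_age_report()`,
  `subdivision_t_test()`).
* **Synthetic data** — forward Wright–Fisher tables under drift ±
  selection and intra-allelic haplotype panels of known age, so every
  stage is testable without external downloads
  (`simulate_drift_table()`, `simulate_age_panel()`).

The published genotype table (50 Native American populations, 1905
individuals, three subsistence subdivisions) and the seven-site maize
pollen table ship as plain-CSV fixtures (`abca1_fixtures()`).

## Worked example

```r
library(genecult)
fx <- abca1_fixtures()

amova(fx$table1, n_permutations = 10000, seed = 42)
#> Hierarchical AMOVA (allele level)
#>   Among groups:            sigma^2 =  0.00480  (  3.9%)
#>   Among pops within groups: sigma^2 =  0.00300  (  2.4%)
#>   Within populations:      sigma^2 =  0.11530  ( 93.7%)
#>   F_CT = 0.0390 (p = 0.0002)   F_SC = 0.0254 (p = 9.999e-05)   F_ST = 0.0634 (p = 9.999e-05)
#>   10000 permutations

frequency_vs_age_report(fx$table2)$correlation
#> Spearman rho = 0.936975  (n = 7, t = 5.996, two-tailed p = 0.001851)

kimura_ohta_age(subdivision_mean_frequency(fx$table1,
                                           "mesoamerican_agriculturalist"))
#> Allele age (kimura_ohta): 0.680 x 2N gen = 979 generations = 24476 years

subdivision_t_test(fx$table1, "mesoamerican_agriculturalist",
                   "andean_agriculturalist")
#> mesoamerican_agriculturalist vs andean_agriculturalist (welch t-test): t = 4.663, df = 17.30, p = 0.0002134
#>   means: 0.1536 vs 0.0393
```

Read it as: about 3.9% of allelic variance separates the three
subsistence subdivisions (permutation p < 10⁻³), Mesoamerican
frequencies are markedly higher than Andean ones, the Mesoamerican mean
frequency dates the allele to roughly 24.5 thousand years under the
frequency method's stated conventions, and allele frequency tracks the
local antiquity of maize almost monotonically (ρ = 0.937, p ≈ 0.002)
across the seven populations paired with nearby *Zea* pollen records.

A one-call orchestration over all stages, with a machine-readable JSON
report, is `run_full_analysis(analysis_config(seed = 1))`.  The
simulation-based stages (outlier scan against an island-model null,
settlement-demography neutrality fit, MCMC LD age) are exercised on
synthetic data in the test suite; see the methods vignette
(`vignettes/genecult-methods.Rmd`) for the models, parameter defaults
and their rationale.

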