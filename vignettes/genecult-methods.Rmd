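---
title: "Models and methods behind genecult"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind genecult}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genecult)
```

`genecult` implements the inference chain of a gene–culture coevolution
analysis of a single biallelic variant — the *ABCA1* Arg230Cys
(rs9282541) polymorphism, whose derived Cys allele is private to the
Americas — across Native American populations grouped by ancient
subsistence mode.  This vignette explains the statistical models, the
choices made where the design was genuinely open, and what the synthetic
validations do and do not demonstrate.

## The data model

The elementary input is a population genotype table: one row per
population with sample size `n` and the three genotype counts of a
single SNP, plus a subdivision label (Mesoamerican agriculturalist,
Andean agriculturalist, South American hunter-gatherer/forager for the
packaged data; any label set is accepted).  Allele frequencies are
obtained by direct counting, `p_alt = (n_ra + 2 n_aa) / (2n)`, kept at
full precision; two-decimal rounding (half away from zero) happens only
in `display_frequency()`, because the published table prints two
decimals.

Three rows of the packaged table print a frequency that disagrees with
the frequency recomputed from the row's own genotype counts: Zapotec
(counts give 0.23, printed 0.24), Guaymí (0.14 vs 0.15) and Hulliche
(0.12 vs 0.11).  The fixture stores the counts verbatim *and* the
printed column (`printed_cys`), so the disagreement stays visible rather
than being silently resolved either way.  The pollen table (seven
Mesoamerican/Central American populations paired with *Zea* pollen
dates) carries both radiocarbon and calendar ages; calendar ages are
used as-is — radiocarbon calibration is out of scope.

## Hierarchical AMOVA

`amova()` partitions allelic variance at three levels: among
subdivisions, among populations within subdivisions, and within
populations.  Each diploid individual contributes its two alleles as
exchangeable observations (no within-individual level), the standard
single-locus treatment when only genotype counts are available.  Sums of
squares have closed forms in the per-population allele counts; variance
components use the classical unequal-size nested-ANOVA coefficients, and
the indices are

$$F_{CT} = \frac{\sigma_a^2}{\sigma_T^2},\qquad
  F_{SC} = \frac{\sigma_b^2}{\sigma_b^2+\sigma_c^2},\qquad
  F_{ST} = \frac{\sigma_a^2+\sigma_b^2}{\sigma_T^2}.$$

Negative variance components are retained in the stored result and
clamped at zero only for percentage-of-variance display.  Significance
is by permutation: whole populations among groups for $F_{CT}$; alleles
among populations (within groups for $F_{SC}$, globally for $F_{ST}$) —
the allele permutation is drawn directly as a multivariate
hypergeometric reallocation, which is equivalent to permuting the 0/1
allele vector and vectorises over all permutations.  P-values include
the observed statistic in numerator and denominator, so the smallest
attainable value with $B$ permutations is $1/(B+1)$; the default is
$B = 10{,}000$.

The degenerate design in which every group holds a single population
collapses to a one-level ANOVA among groups ($\sigma_b^2 = 0$, $F_{SC}$
undefined).  Pairwise and within-group $F_{ST}$ use the same machinery;
for frequency matrices the multi-locus estimator is the
Weir–Cockerham-style ratio of sums over loci, under which monomorphic
loci contribute zero to both sums.

On the packaged table this AMOVA gives $F_{CT} = 0.039$ and
within-hunter-gatherer $F_{ST} = 0.072$ (both $p < 10^{-3}$), with the
same qualitative structure as originally reported (significant
among-subdivision differentiation; the strongest within-subdivision
structure among the South American hunter-gatherers; essentially none in
the Andes at conventional significance).  The sums of squares are
verified in the test suite against explicit enumeration over individual
alleles.

## Allele ages

**Frequency method.**  For a neutral derived allele at frequency $p$,
the expected age in units of $2N$ generations is
$E(t_1) = [-2p/(1-p)]\ln p$ — strictly increasing in $p$ and approaching
2 as $p \to 1$.  `kimura_ohta_age()` evaluates this exactly and converts
with a diploid effective size (default 720) and generation time (default
25 y).  Under this explicit convention the Mesoamerican mean frequency
(0.1536) dates the allele to roughly 24,500 years and the continental
mean to less than that; the convention is reported with every estimate
because frequency-based ages are only defined up to the chosen time
units.

**LD decay.**  Among chromosomes carrying the focal allele, the
proportion $y$ retaining the ancestral allele at a flanking marker with
recombination fraction $c$ decays as $e^{-ct}$, up to recombinants that
re-acquire the ancestral allele from the background at frequency $q$:
the corrected retention is $y' = (y-q)/(1-q)$ and the moment estimate is
$\hat t = -\ln(y')/c$ (clamped at 0 when $y' \ge 1$, undefined when
$y' \le 0$).  The background $q$ is the plain proportion among
non-carrier chromosomes, left unsmoothed so the estimator is exactly
invariant to duplicating every chromosome.

**Bayesian MCMC.**  `mcmc_ld_age()` samples the age $t$ by
Metropolis–Hastings with a log-normal random walk whose scale adapts
during burn-in towards 20–50% acceptance.  The likelihood is a composite
product over markers and carriers of the retention/recombination
probability $p_m(t) = e^{-c_m t}(1-q_m) + q_m$, which is exact under a
star-shaped intra-allelic genealogy — the regime rapid exponential
growth produces — and reduces to per-marker binomial sufficient
statistics.  Two numerical choices matter:

* the background frequencies $q_m$ are *nuisances*, not constants:
  each is integrated over its Jeffreys Beta posterior given the
  non-carrier counts (seven equal-weight quantile quadrature nodes).
  Plugging in point estimates instead visibly under-covers the true age;
* the prior on $t$ is the exponential age distribution induced by
  per-generation growth $r$ (rate $r$, default 0.005, so mean age
  $1/r = 200$ generations); the sampled fraction is recorded but does
  not sharpen this prior.  Markers with $c = 0$ contribute a likelihood
  constant in $t$, so a panel with no recombining marker returns the
  prior rather than an error.

Defaults are 100,000 iterations with 20% burn-in (production analyses of
this kind run into the millions; the posterior here is one-dimensional
and mixes long before that).  The returned point estimate is the
posterior mean; mode and central 95% interval are included.

## Coalescent simulators

Both simulators are continuous-time structured coalescents written in
C++, archive every branch with the set of sample chromosomes it
subtends, and place mutations uniformly on total branch length.  Because
every non-root branch subtends a proper subset of the sample, each
simulated SNP is polymorphic in the pooled sample by construction
(fixed-S conditioning).  All randomness flows through R's RNG, so
`set.seed()` governs the C++ code too.

**Hierarchical island model** (`simulate_island_snp()`): `n_demes`
demes (default 100) of diploid size 50 in equal groups; a lineage
emigrates at total rate `m_within + m_between`, moving to a uniformly
chosen other deme of its own group or of another group respectively.
Alternatively `target_fst` solves the total migration rate from the
equilibrium relation $F_{ST} = 1/(1+4Nm)$ and spreads it uniformly over
destinations.  The published analysis does not state its migration rates
or deme sizes, so the null is parameterised by the user-supplied target
differentiation.

**Settlement demography** (`simulate_settlement_region()`): three demes
of present size 830 diploids whose sizes decline exponentially backwards
to a single ancestral population of 70–830 diploids at a split drawn
uniformly between 6,350 and 18,000 years ago (25 y/generation); the
ancestral population is then constant.  Drawing the ancestral size
sweeps growth rates continuously from strong expansion down to a
constant-size history.  Post-split migration defaults to zero and is
configurable.  Default samples are 68/35/23 diploids, the sizes of the
three observed subdivision panels; a region carries 20 fully linked SNPs
on one genealogy (an unlinked mode simulates an independent genealogy
per SNP, since the original marker layout is ambiguous).  Inhomogeneous
coalescence times are drawn exactly by inverting the integrated rate
$\Lambda(s) = \lambda_0(e^{gs}-1)/g$.

`summarize_loci()` turns per-deme derived counts into the fixed-layout
summary vector: mean unbiased heterozygosity (per locus, averaged within
demes, then across demes and loci), the global multi-locus
Weir–Cockerham $F_{ST}$, then pairwise $F_{ST}$ per deme pair in column
order.

## The F_ST-outlier test

`build_null()` simulates the joint null cloud of (He, $F_{ST}$) pairs
(50,000 draws by default) and `kde_pvalue()` ranks an observed locus
within it *conditionally on He*: null points are weighted by a Gaussian
kernel on their He distance (Silverman bandwidth by default) and the
p-value is the weighted proportion of null $F_{ST}$ at least as large as
the observed one, with add-one smoothing on the kernel's effective
sample size so an observation above every comparable point reports
$1/(n_\mathrm{eff}+1)$.  This conditional upper-tail construction
follows the fdist tradition of judging differentiation against
heterozygosity; flags use $\alpha = 0.05$ with no multiple-testing
correction by default (a Benjamini–Hochberg option exists).

One honesty note: single-SNP samples are discrete, and common
configurations (all singletons, for instance) collapse onto single
(He, $F_{ST}$) atoms.  The deployed p-value counts ties fully and is
therefore *valid but conservative*: its null flag rate sits at or
somewhat below the nominal 5%, and its distribution is uniform only up
to that discreteness.  `kde_pvalue()` reports the weighted
strictly-greater and tie masses separately, so calibration checks can
form the standard randomized PIT — which is exactly uniform for a
well-calibrated discrete test — without changing the deterministic
p-value users see.  Quantile envelopes of $F_{ST}$ conditional on He
(2.5 / 50 / 97.5%) reproduce the familiar joint-distribution plot.

## Neutrality goodness-of-fit

`neutrality_fit()` measures the Euclidean distance
$\partial = \lVert S - S^* \rVert$ between the observed summary vector
and each member of a simulated neutral ensemble, reporting mean, median
and minimum, together with the ensemble's internal baseline (each
simulation against the ensemble mean) so that two observed data sets can
be ranked by fidelity to the neutral model.  Because the coordinates mix
scales (He against $F_{ST}$), each is divided by the ensemble standard
deviation by default (`standardization = "null_sd"`); the raw mode is
retained because the original analysis does not state whether its
distances were standardized.

## Gene–culture correlation

`spearman_cor()` is the tie-corrected (mid-rank) Spearman correlation
with the two-tailed t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df.  Mid-ranks are essential:
on the packaged pollen table they give $\rho = 0.936975$
($p \approx 0.0019$) exactly as published, while the no-tie shortcut
$1 - 6\sum d^2/(n(n^2-1))$ would give 0.9375.  Subdivision comparisons
use a two-tailed t-test on per-population frequencies (each population
one unit, unweighted), Welch by default since group sizes and variances
differ; the pooled variant is available because the original choice is
unstated.  The published per-comparison p-values (0.1316 / 0.0022 /
0.0174 / 0.351) are not recovered by either variant on the printed
frequencies, so only the qualitative contrasts (Mesoamerica above the
Andes and the hunter-gatherers) are asserted.

## Synthetic data: what it emulates, and what it does not

`simulate_drift_table()` is a forward Wright–Fisher generator: per
generation each population mixes towards the metapopulation mean at rate
$m$, experiences additive viability selection (fitnesses
$1, 1+s/2, 1+s$) in one designated group, and resamples $2N$ alleles
binomially; final genotype counts are multinomial under Hardy–Weinberg.
Defaults describe the selective scenario the analysis targets: villages
of 830 diploids, $m = 0.005$, a standing variant at frequency 0.15, and
360 generations — the maize-domestication era at 25 y/generation.  With
these parameters the neutral equilibrium differentiation is
$1/(1+4Nm) \approx 0.057$, which is how the island null is matched
analytically in the power checks.

`simulate_age_panel()` generates intra-allelic haplotype panels under
the same star-genealogy assumption the MCMC likelihood makes: each
carrier retains the ancestral allele at marker $i$ with probability
$e^{-c_i t}$ and otherwise draws from the background.  Validations on
these panels therefore test estimator correctness under the stated
model, *not* robustness to non-star genealogies, marker ascertainment,
genotyping error, or real LD structure.  Likewise the drift generator
has no linkage and idealised migration; passing tests show the inference
machinery is calibrated and powerful under the assumed conditions, not
that real data meet those conditions.

## Problem sizes used by the test suite

The packaged checks run at desk scale, chosen so the full suite
completes in a few minutes while keeping Monte-Carlo error well inside
the asserted tolerances: 5,000 island loci for the equilibrium check
(±0.05 on $F_{ST} = 0.5$), null clouds of 2,000 with 1,000 evaluation
loci for calibration, 50 replicates for the power and discrimination
checks, 100 panels at 15,000 MCMC iterations for coverage, and 10,000
permutations for the AMOVA p-values.  Production analyses should scale
the null cloud to the 50,000 draws and the settlement ensemble to the
100,000 genealogies used in the original study; the interfaces take
these as ordinary arguments.

## Known limitations

* The AMOVA point values printed in the original table (3.6% / 5.3%)
  are not reproducible from the printed genotype counts under any
  standard estimator convention we tried (allele-level, genotype-level
  with a within-individual component, Weir–Cockerham diploid theta,
  plausible subsets and poolings); leave-one-out experiments suggest the
  original runs used a slightly different dataset version.  This package
  reports the faithful estimates from the counts as printed.
* The MCMC age estimator is a composite-likelihood approximation under a
  star genealogy, not a full ancestral-recombination-graph sampler; it
  is a desk-scale stand-in for the decay signal that dedicated
  intra-allelic coalescent software exploits, and its credible intervals
  are calibrated only under its own assumptions.
* The outlier p-value is conservative under strong discreteness (few
  copies of the derived allele), exactly where single-SNP inference is
  weakest anyway.
* No recombination inside the island-model simulator; selection exists
  only in the forward generator.
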