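---
title: "Models and methods behind holotracer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind holotracer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotracer)
```

holotracer implements the quantitative layer of a holobiont
nutrient-cycling experiment: a stable-isotope pulse-chase on symbiotic,
dark-incubated symbiotic, and menthol-bleached (aposymbiotic) jellyfish,
closed-chamber respirometry, an allometric size calibration, and a 16S
community survey of the same animals. This vignette explains the models,
the tunable parameters, what the synthetic-data generator does and does
not emulate, and the design decisions taken where more than one
defensible choice existed.

## Isotope conversions and enrichment

Instrument output in delta notation (per-mil deviation from an
international standard) is converted to atom percent with
$AP = 100R/(1+R)$, $R = R_{std}(1 + \delta/1000)$. The reference ratios
are fixed constants: $R_{PDB} = 0.0112372$ for carbon and
$R_{air} = 0.0036765$ for nitrogen; the conversion is a strict bijection
from $(-1000, \infty)$ onto $(0, 100)$ and the package guarantees a
round-trip error below $10^{-9}$ per mil.

Enrichment is atom percent excess, $APE = AP_{sample} - AP_{control}$,
computed against *measured* natural-abundance controls rather than
theoretical values: `ape_table()` takes the control level from the T0
samples of the experiment itself (around 1.081 AP for carbon and 0.368
for nitrogen in this system). Whether T0 controls should be pooled
across symbiotic states or matched within state is not decidable from
first principles; both are offered (`control_mode = "pooled"`, the
default, or `"per_state"`). Negative APE — possible when a sample sits
below the control mean — is retained and flagged, never truncated, so
the downstream test statistics keep their distributions.

Samples spiked with acetanilide (to add mass or dilute strong
enrichment) are inverted through the element mass balance; acetanilide's
element mass fractions (0.7109 C, 0.1036 N) come from C8H9NO with IUPAC
atomic weights. Instrument precision is summarised as percent relative
standard deviation using the sample (n − 1) standard deviation, the
convention in stable-isotope reporting. Duplicate instrument readings
are averaged per sample-fraction-element; single readings (low-mass
algal pellets) pass through unchanged.

## Respirometry

The closed-chamber oxygen flux is
$\mathrm{rate} = \Delta O_2 (V_{chamber} - V_{medusa}) / (T \cdot WW)$.
The medusa's displacement volume is its wet weight divided by seawater
density, a single configurable constant (1022.6 g/L for 35 PSS-78,
28 °C, 1 atm) rather than a full equation of state — the experiment
fixes salinity and temperature, so one density suffices. Fluxes are
stored signed (positive = net O2 production); respiration is reported
positive. Gross production for a light-incubated symbiotic animal pairs
its own net production with the *treatment-mean* dark respiration,
because each animal is measured under only one light condition; this is
an acknowledged approximation (light and dark respiration differ
systematically).

## Allometric calibration

Wet weight is regressed on bell diameter with OLS polynomials of degree
1 and 2, compared by the Gaussian-likelihood information criterion
$n\log(RSS/n) + 2k$ with $k$ counting coefficients plus the error
variance, and RSS floored at $10^{-12}$ so noise-free calibrations keep
a finite criterion. The small-sample correction (AICc,
$+2k(k+1)/(n-k-1)$) is applied by default: the calibration sets here
have n of 12 and 35, far below the n/k ≈ 40 rule of thumb where plain
AIC becomes safe, and at n = 12 plain AIC picks a spurious quadratic in
roughly a quarter of replicates while AICc keeps the error near the
intended level. Plain AIC remains available via
`small_sample = FALSE`. Ties go to the lower degree, and only the two
published functional forms are considered — no intercept-free or
higher-degree candidates.

## Community analysis

**Contamination filter.** An ASV is removed when at least 10 % of its
reads across all libraries occur in the extraction control. The
denominator includes the control's own reads by default; because the
verbal rule "occurrence in the control compared to all samples" is
ambiguous, a biological-samples-only denominator is available behind
`include_control_in_total = FALSE`. An ASV absent from the control can
never be removed.

**Alpha diversity.** Richness and Hill numbers of order 1 and 2 are
estimated at a common base depth (default: the minimum library size,
so the default analysis only rarefies downward). Interpolation uses the
analytic hypergeometric expectations — classical rarefaction for
richness, the expected plug-in entropy (exponentiated) for order 1, and
the closed-form unbiased Simpson estimator
$1/(1/m + (1 - 1/m)\sum x_i(x_i-1)/(n(n-1)))$, valid at any depth, for
order 2. Extrapolation beyond a library's depth uses the Chao1-based
richness estimator and, for order 1, a sample-fraction-weighted blend of
observed and asymptotic (coverage-corrected) entropy; it is capped at
twice the observed depth, the accepted reliability limit for these
estimators. At a sample's own depth all three reduce exactly to the
observed Hill numbers, and the ordering richness ≥ D1 ≥ D2 is preserved
by construction. Values larger than 1 in the order-1 and order-2 columns
of summary tables are effective ASV counts, not raw entropies; raw
Shannon entropy is emitted alongside for transparency. Faith
phylogenetic diversity is the total branch length spanning the observed
ASVs (root included) on a user-supplied Newick tree, computed on
unrarefied presences — whether rarefied or unrarefied data should feed
Faith PD is left open in most published workflows, and unrarefied is the
choice documented here. Evenness defaults to Pielou's $H/\ln S$ on
unrarefied proportions, with the Hill-ratio alternative
(`evenness = "hill_ratio"`) behind a flag.

**Beta diversity.** Bray-Curtis dissimilarities are computed on
relative abundances (unrarefied). NMDS uses stress-1 minimisation with
50 seeded random restarts (via vegan's engine, the same tool the
field uses). PERMANOVA partitions squared dissimilarities into among-
and within-group components; the p-value comes from unrestricted
permutation of sample labels (999 by default, seeded), or from complete
enumeration of all distinct relabellings in `method = "exhaustive"`,
which the test suite checks against a brute-force oracle. Pairwise
PERMANOVAs are Holm-corrected. The dispersion analysis pools each
group's within-group pairwise dissimilarities and compares groups by
Kruskal-Wallis with exact pairwise Wilcoxon tests (Holm-corrected);
because a boxplot axis can be read either way, both dissimilarities and
similarities (1 − d) are reported.

**Membership sets.** The core microbiome holds ASVs present in every
medusa, the symbiome those present in every symbiotic sample, the
apobiome those present in every aposymbiotic sample; core ⊆ symbiome ∩
apobiome always.

## The synthetic study generator

The generator's defaults are the study conditions, not free dials: three
treatments of five medusae across T0/pulse/chase3h/chase6h with host and
algal fractions, duplicate instrument readings (three designated algal
cells yield singles), measurement noise of 1.4 %RSD for carbon and
4.1 %RSD for nitrogen applied as relative Gaussian noise on the
atom-percent scale (the delta-scale alternative degenerates near
delta = 0), trajectory means following the published ordering (light
symbiotic algae most enriched in 13C, peaking at the first chase;
aposymbiotic hosts with the steepest 15N turnover), respiration of
28 ± 14 (symbiotic, dark) and 49 ± 8 (aposymbiotic) µg O2/g/h with net
production tuned so Pg:R centres on 2, the published calibration
polynomials with sigma = 0.05 g, and a four-medusa feeding experiment
whose algal-to-host relative enrichment is drawn at 36.7 ± 4.6 % (13C)
and 70.3 ± 4.0 % (15N).

The community model is a two-stage Dirichlet-multinomial. The two
dominant taxa (a Moraxellaceae *Acinetobacter* and a *Pseudomonas*)
carry a tight Beta-distributed 85 % of reads in every treatment — the
published heterogeneity lives below the dominants, not in them — while
the sub-dominant composition is drawn with treatment-specific
concentration (SymD 300, SymL 150, ApoL 20, mirroring the published
ordering of within-treatment variability). Aposymbiotic samples
additionally host a per-sample random subset of 20–70 invader taxa: the
bleached host is modelled as open to invasion, which simultaneously
raises richness and between-sample turnover, the two signatures of the
aposymbiotic group. One aposymbiotic sample is a designated
high-richness outlier with eroded (66 %) dominance. Membership and
contamination structure is planted exactly — ten core ASVs forced
present everywhere, two symbiome-only and two apobiome-only members,
and seven contaminants (six exclusive to the control) that meet the
10 % rule by construction; forced absences zero the group-minimum count
so essentially no reads are displaced. A random bifurcating tree with
exponential branch lengths (mean 0.002, giving Faith PD magnitudes of
0.2–0.6) covers the pool.

What the generator does *not* emulate: real 16S data have hundreds of
ASVs with phylogenetically structured abundances, compositional
correlations between taxa, and library-size artefacts from PCR and
sequencing; the synthetic communities are lower-rank than real ones (the
NMDS of a simulated table often reaches near-zero stress, where the real
ordination sat just under 0.078). Passing tests therefore demonstrate
correctness of the estimators and the inference machinery under the
assumed model, not robustness to real-data pathologies. Likewise the
isotope generator draws independent Gaussian noise — no instrument
drift, memory, or concentration-dependent linearity effects.

## Statistical layer and its limits

Enrichment above control is tested with Welch upper-tailed two-sample
t-tests, Holm-corrected per family; treatment comparisons that fail
parametric assumptions use Kruskal-Wallis with exact pairwise Wilcoxon
tests; enrichment-covariate relationships use OLS with adjusted R².
Mixed-effect models used for some repeated-measures contrasts in
comparable experimental designs are deliberately out of scope: no
random-effects structure can be inferred from the fixed design here, so
the package provides documented fixed-effect equivalents instead and
flags the difference. With the generator's default settings the weakest
cells (aposymbiotic algal fractions a few hundredths of an AP point
above control, under 1.4-4.1 %RSD noise) are not reliably significant
after family-wise correction — a real power limit of the design, not a
software artefact.

## Numerical choices and degenerate inputs

Ties in model selection go to the simpler model; RSS is floored at
1e-12; PERMANOVA permutation p-values use the add-one convention
$(1 + \#\{F^* \ge F\})/(1 + n_{perm})$ and F-comparisons carry a 1e-12
slack so exact ties count; all-tied dispersion inputs return a zero
Kruskal-Wallis statistic with p = 1 rather than NaN; empty samples,
missing tree tips (listed by name), absent controls, zero-variance
groups and malformed input files raise structured errors naming the
offending column or taxon. Every stochastic routine takes an explicit
seed and restores the caller's RNG state.

## Problem sizes used in verification

The shipped tests and acceptance script run at the study's own scale:
16 libraries of 12-20k reads over ~120 ASVs, 15 medusae per isotope
element-fraction cell, and replicate counts of 100-500 for power and
bias estimates (200 replicates for allometric model selection, 500 for
respirometry bias, 100 for dispersion-test power and the regression
recoveries). These sizes make all checks reproducible on a laptop in
minutes while keeping Monte-Carlo error well below the decision
thresholds they feed.
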