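# holotracer

Quantitative tools for studying nutrient cycling in photosymbiotic
cnidarian holobionts — host animals (here, upside-down jellyfish of the
genus *Cassiopea*) together with their Symbiodiniaceae photosymbionts and
bacterial associates. The package is aimed at ecophysiologists and
microbiome researchers who run stable-isotope pulse-chase experiments,
closed-chamber respirometry, and 16S amplicon surveys on the same animals
and want one tested, reproducible analysis path from raw tables to test
statistics.

## What it computes

**Stable-isotope tracer processing.** Delta notation is converted to atom
percent via

    AP = 100 R / (1 + R),   R = R_std (1 + delta / 1000)

with R_PDB = 0.0112372 (13C/12C) and R_air = 0.0036765 (15N/14N).
Enrichment is expressed as atom percent excess against measured
natural-abundance controls (APE = AP_sample − AP_control), symbiont
enrichment as a percentage of host enrichment
((APE_algal / APE_host) × 100), and spiked samples are recovered through
the mass balance
AP_mix (m_s f_s + m_std f_std) = AP_s m_s f_s + AP_std m_std f_std.

**Respirometry.** Mass-specific oxygen flux from closed-chamber
incubations,

    rate = dO2 * (V_chamber − V_medusa) / (T * WW)

with the animal's volume derived from wet weight and seawater density
(1022.6 g/L at 35 PSS-78, 28 °C). Net primary production Pn, respiration
R, gross production Pg = Pn + R and the Pg:R ratio follow.

**Allometric calibration.** Wet weight ~ bell diameter polynomials
(degree 1 vs 2) fitted by OLS and selected by small-sample-corrected AIC.

**Microbiome analysis.** ASV tables are filtered against an extraction
control (an ASV is a contaminant when ≥ 10 % of its reads occur in the
control), summarised at family level, and profiled per sample: richness
and Hill numbers of order 1 and 2 at a common depth via analytic
rarefaction–extrapolation, Faith phylogenetic diversity on a supplied
tree, and Pielou evenness. Beta diversity uses Bray–Curtis
dissimilarities with NMDS ordination, one-way and pairwise PERMANOVA
(with an exhaustive-enumeration mode for small n), a within-treatment
dispersion test (Kruskal–Wallis over pooled within-group
dissimilarities), and core/symbiome/apobiome membership sets.

**Synthetic study generator.** `sim_config()` and the `simulate_*()`
functions emit every input the pipeline consumes — isotope trajectories
with instrument-level noise, DO incubation records, calibration pairs,
and a 16-library Dirichlet-multinomial ASV table with planted
contaminants, membership sets, a dominant pair of taxa and elevated
aposymbiotic dispersion — together with their ground truth, so every
stage is testable without any data download.

## Worked example

```r
library(holotracer)
res <- run_pipeline("demo_run", seed = 1)
str(res$report$microbiome)
```

    List of 10
     $ n_asvs_removed    : int 7
     $ n_control_only    : int 6
     $ core_size         : int 10
     $ symbiome_size     : int 12
     $ apobiome_size     : int 12
     $ nmds_stress       : num 8e-05
     $ permanova_F       : num 2.09
     $ permanova_p       : num 0.001
     $ dispersion_kw_chi2: num 20.7
     $ dispersion_kw_p   : num 3.17e-05

The contamination filter removed 7 of 121 simulated ASVs (6 of them found
only in the extraction control); 10 ASVs form the core microbiome, and
the symbiome and apobiome each hold 12. The within-treatment dispersion
test (chi² = 20.7, df = 2, p = 3e-5) picks up the planted compositional
heterogeneity of the bleached (aposymbiotic) group. Per-sample alpha
diversity lands in the magnitude range typical of these communities:

```r
head(res$microbiome$diversity[, c("sample_id", "richness", "hill1",
                                  "hill2", "faith_pd", "evenness")], 3)
```

      sample_id richness    hill1    hill2  faith_pd  evenness
    1  SymLPul1 41.63914 3.710504 2.121953 0.2423057 0.3486981
    2  SymLPul2 35.00000 3.403308 2.089507 0.2118027 0.3444804
    3  SymLPul3 47.34244 3.758729 2.139222 0.2771574 0.3386422

The same run writes all tables (APE values, enrichment tests, metabolic
rates, calibration models, filtered ASV table, diversity profiles,
distance matrix, ordination coordinates) plus `report.json` to the output
directory; rerunning with the same seed reproduces them byte for byte.

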