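# phaeotox

Dose-response ecotoxicology analysis for the model diatom *Phaeodactylum
tricornutum*, built around the endpoints of a standard 6-treatment × 3-replicate
exposure experiment (e.g. fluoxetine at 0, 0.3, 0.6, 20, 40, 80 µg/L):

* **Growth & IC50** — specific growth rates µ = (ln N_f − ln N_i)/Δt,
  relative cell-density reduction toward the control, and the two-parameter
  log-logistic fit I(d) = 100 / (1 + (IC50/d)^h), with a log-linear
  interpolation fallback and an explicit "not reached" result.
* **JIP test** — cardinal points (F0, F300, FJ, FI, FM) from OJIP
  chlorophyll-*a* fluorescence transients and the standard derived
  parameters: V_J, V_I, M0, Area, S_M, N, φ_P0 = F_V/F_M, ψ_E0, δ_R0, the
  per-cross-section energy fluxes (ABS, TR, ET, DI, RC), their ratios, and a
  control-referenced fraction of active oxygen-evolving complexes.
* **Pigments** — Gauss-peak-spectra (GPS) deconvolution of 350–750 nm
  whole-cell absorbance spectra into chlorophyll *a*/*c*, pheophytin *a*,
  β-carotene, fucoxanthin, diadinoxanthin and diatoxanthin by non-negative
  least squares over a fixed Gaussian template library.
* **Fatty acids** — FAME peak-table quantification against the C15:0
  internal standard, saturation classes, and the double bond index
  DBI = 2(%monoenes + 2 %dienes + 3 %trienes + 4 %tetraenes + 5 %pentaenes)/100.
* **Oxidative stress** — Beer–Lambert conversions for TBARS/MDA
  (ε = 155 mM⁻¹cm⁻¹), catalase (ε = 39.4), ascorbate peroxidase (ε = 2.8)
  and the pyrogallol-inhibition SOD assay (1 U = 50% inhibition).
* **Energy budget** — cellular energy allocation: Ea from combustion
  equivalents (17,500 / 24,000 / 39,500 mJ/mg for carbohydrate / protein /
  lipid), Ec from ETS INT-formazan kinetics (ε = 15,900; 2 formazan : 1 O₂;
  480 kJ/mol O₂), CEA = Ea/Ec, all per 10⁶ cells.
* **Statistics** — Kruskal–Wallis with Dunn/Holm compact letter displays,
  Spearman dose correlations (signed ρ² reported), and canonical analysis of
  principal coordinates (CAP) with true leave-one-out nearest-centroid
  classification and a permutation test of the canonical trace.
* **Synthetic data** — a ground-truth generator for the full design (growth
  series, transients, spectra, FAME tables, assay traces, biomolecule
  masses), so every stage of the chain is testable without instrument data.

The raw measurements of such studies are rarely deposited, so the package is
organised as an analysis workflow over synthetic-but-faithful data: the
numbered scripts under `analysis/` regenerate the whole experiment and every
results table from one seed.

## Worked example

The only desk-reproducible quantity of such an experiment is the IC50 from
the published inhibition anchors — 39% at 40 µg/L and 83% at 80 µg/L:

```r
library(phaeotox)
fit_ic50(c(0, 40, 80), c(0, 39, 83))
#> Dose-response fit (loglogistic)
#>   IC50 = 46.59 ug/L, hill slope = 2.93
fit_ic50(c(0, 40, 80), c(0, 39, 83), method = "interpolation")
#> Dose-response fit (interpolation)
#>   IC50 = 47.57 ug/L
```

The two estimates bracket the conventional "≈47.3 µg/L" for these anchors.
A full synthetic experiment runs end to end in a couple of seconds:

```r
res <- run_pipeline(NULL, "phaeotox_results")   # default design, seed 1
res$summary$ic50_ug_per_l
#> [1] 50.17463
res$summary$cap_fa_accuracy_pct
#> [1] 38.88889
```

Here the fitted IC50 (50.2 µg/L) recovers the generator's ground truth
(47.3 µg/L) within the replicate noise (CV 0.1, n = 3), and the fatty-acid
CAP classifies 38.9% of samples to their exposure group (chance is 16.7%;
the three low doses are nearly indistinguishable at this noise level, which
caps the attainable accuracy). The same stages can be driven step by step:

```sh
Rscript analysis/01_simulate.R        # instrument-level input tables
Rscript analysis/02_growth_ic50.R     # rates, inhibition, IC50
Rscript analysis/03_photochemistry.R  # JIP parameters + dose statistics
Rscript analysis/04_pigments.R        # GPS pigment deconvolution
Rscript analysis/05_fatty_acids.R     # profiles, classes, DBI
Rscript analysis/06_stress_energy.R   # MDA, enzymes, Ea/Ec/CEA
Rscript analysis/07_multivariate.R    # CAP classification
```

Each script reads the CSVs of the previous stages from `results/` and writes
its own tables there, each stamped with a provenance header (seed, config
hash, content hash).

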