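---
title: "Models and methods behind the phaeotox pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the phaeotox pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phaeotox)
```

phaeotox implements the computational chain of a single-stressor
dose-response experiment on the marine diatom *Phaeodactylum tricornutum*:
six exposure concentrations (0, 0.3, 0.6, 20, 40, 80 µg/L of a dissolved
stressor such as the antidepressant fluoxetine), three biological replicates
each, with growth, chlorophyll-*a* fluorescence, pigment, fatty-acid,
oxidative-stress and energy-budget endpoints followed by univariate
statistics and a multivariate classifier. This vignette describes each model,
its assumptions, the tunable parameters, and the design decisions that were
genuinely open.

## Growth and dose-response

The specific growth rate over a time window is
$\mu = (\ln N_f - \ln N_i)/\Delta t$ in d$^{-1}$. Growth inhibition is
expressed on *densities* — the relative cell-density reduction toward the
control at the exposure endpoint, $(1 - N_t/N_c)\times 100$ — not on rates.
Both readings are defensible; densities were chosen because the endpoint is
reported that way in the ecotoxicological literature this pipeline serves,
and rates remain available through `specific_growth_rate()`.

`fit_ic50()` fits the two-parameter log-logistic curve
$$I(d) = \frac{100}{1 + (\mathrm{IC}_{50}/d)^{h}}$$
to inhibition percent by Nelder–Mead least squares on $(\log \mathrm{IC}_{50},
\log h)$. The control cannot enter log-dose space; it anchors the 0%
asymptote, which the model satisfies by construction. The fallback method is
log-linear interpolation of inhibition against $\log_{10}$ dose between the
doses bracketing 50%. Both methods are always labelled in the output. When
50% is neither bracketed nor reached by a convergent fit inside the tested
range, the result is an explicit "IC50 not reached", never an extrapolation.
Negative inhibition (stimulation) is retained and flagged, not clipped.

Worked example: inhibition of 39% at 40 µg/L and 83% at 80 µg/L yields
46.6 µg/L by the exact two-point log-logistic solution ($h = 2.93$) and
47.6 µg/L by log-linear interpolation — the two estimates bracket the
customary "approximately 47.3 µg/L" for such data.

## OJIP transients and the JIP test

A dark-adapted chlorophyll-*a* fluorescence rise (Kautsky curve) is sampled
log-uniformly from tens of microseconds to seconds, with cardinal steps O
(origin, F0 at 50 µs), K-band region (300 µs), J (2 ms), I (30 ms) and P
(peak, FM). `extract_cardinal_points()` interpolates linearly in log-time at
exactly those times; FM is the maximum of the record. Curves whose maximum
does not exceed F0 are flagged degenerate and all derived quantities are NA.

`compute_jip()` applies the standard JIP-test definitions, each stated in its
documentation: relative variable fluorescence $V_J$, $V_I$, $V_K$; initial
slope $M_0 = 4(F_{300} - F_0)/F_V$ per ms; the area above the curve up to FM
(trapezoids on the raw, not log, time grid), its normalisation
$S_M = \mathrm{Area}/F_V$ and the turnover number $N = S_M M_0 / V_J$;
quantum yields $\varphi_{P0} = F_V/F_M$, $\psi_{E0} = 1 - V_J$,
$\delta_{R0} = (1 - V_I)/(1 - V_J)$ and their odds-ratio forms; and the
phenomenological fluxes per cross-section. Two conventions exist for the
cross-section proxy; `abs_cs_proxy = "f0"` (default) or `"fm"` selects one
and is recorded in every output. Energy conservation
$\mathrm{ABS/CS} = \mathrm{TR/CS} + \mathrm{DI/CS}$ holds exactly by
construction and is asserted to machine precision in the tests.

Two indices are deliberately marked experimental because the instrument
vendor's exact formulas are not published: the grouping (connectivity) index
`p_g`, computed as the mid-chord curvature of the 100–300 µs relative
variable fluorescence, and the fraction of active oxygen-evolving complexes,
$\mathrm{AOEC} = [1 - V_K/V_J]_{sample} / [1 - V_K/V_J]_{control}$. Both are
meaningful only within an experiment, against its own control.

## Gauss-peak-spectra pigment deconvolution

Whole-cell acetone-extract absorbance spectra (350–750 nm, 0.5 nm steps, 801
points) are modelled as a non-negative combination of fixed pigment
templates, each template a sum of Gaussians, plus a constant + linear
baseline. Only the per-pigment scales are fitted (the *linear* GPS variant):
peak positions are never refined, matching the fixed-library practice of the
spectrophotometric protocol. The solver is Lawson–Hanson non-negative least
squares; the sign-free baseline is represented as +/− column pairs so the
problem stays a pure NNLS. Scattering correction is out of scope; the
solvent context is fixed to 100% acetone.

The shipped template table (`inst/extdata/gps_library.csv`) is a *synthetic*
parameterisation — literature-typical acetone peak positions, widths and
vibronic amplitude patterns for chlorophyll *a* and *c*, pheophytin *a*,
β-carotene, fucoxanthin, diadinoxanthin and diatoxanthin — not a
transcription of a published library. The carotenoids overlap heavily in
420–490 nm; the library was designed so that each keeps a distinct vibronic
signature (sharp triple-banded diadinoxanthin, a broad fucoxanthin band,
offset diatoxanthin maxima), giving a normalized template Gram condition
number of about 750. With that conditioning, noiseless mixtures round-trip
to well below 1% and mixtures under 1% multiplicative noise to within 10%
(worst pigment, worst mixture). `fit_pigments()` reports the condition
number with every fit so a replacement library's resolvability is visible.

## Fatty acids

FAME peak tables are quantified by the peak-surface method against the
pentadecanoic acid (C15:0) internal standard:
$m_i = A_i/A_{IS} \times m_{IS}$, with relative percentages over identified
fatty acids (internal standard excluded). Saturation classes are defined by
double-bond count (SFA 0, MUFA 1, PUFA ≥ 2) and the double bond index is
$$\mathrm{DBI} = \frac{2(\%\mathrm{monoenes} + 2\,\%\mathrm{dienes} +
3\,\%\mathrm{trienes} + 4\,\%\mathrm{tetraenes} +
5\,\%\mathrm{pentaenes})}{100}.$$
The printed formula stops at pentaenes; acids with more double bonds (absent
in this diatom) extend the pattern with coefficient = bond count, under a
warning. Positional isomer suffixes (n-7, n-3) are carried in identifiers
but never affect a computed statistic.

## Oxidative-stress assay conversions

All conversions are Beer–Lambert arithmetic with the protocol's extinction
coefficients: MDA from the turbidity-corrected TBARS signal
$(A_{532} - A_{600})$ with ε = 155 mM⁻¹cm⁻¹; catalase from the 240 nm
H₂O₂ consumption slope with ε = 39.4 mM⁻¹cm⁻¹; ascorbate peroxidase from
the 290 nm slope with ε = 2.8 mM⁻¹cm⁻¹ (used as printed in the protocol,
although 290 nm is an unusual ascorbate wavelength). Kinetic slopes are
least-squares fits over a configurable window (default: the full trace).
Volume bookkeeping is explicit — reaction volume over extract aliquot
volume — because specific activities (nmol min⁻¹ mg protein⁻¹) depend on how
much extract entered the reaction, and protein is supplied as the Bradford
concentration of the extract (mg/mL). SOD has no extinction coefficient: its
activity is percent inhibition of pyrogallol autoxidation against a
substrate-only control, with the conventional Marklund unit (1 U = 50%
inhibition) per mg protein; that unit definition is a documented choice, as
assay write-ups often omit it.

## Cellular energy allocation

Available energy converts biomolecule masses with the combustion
equivalents 17,500 mJ/mg (carbohydrate), 24,000 mJ/mg (protein) and
39,500 mJ/mg (lipid), normalized to 10⁶ cells. Energy consumption converts
the ETS INT-reduction slope at 490 nm to a formazan production rate
(ε = 15,900), halves it through the 2 µmol formazan : 1 µmol O₂
stoichiometry, extrapolates the 3-minute read linearly to an hour, and
applies the oxyenthalpic equivalent 480 kJ/mol O₂. CEA = Ea/Ec, with Ec = 0
flagged undefined rather than returned as infinity.

One genuine ambiguity is preserved as a switch: the formazan coefficient is
printed as mM⁻¹cm⁻¹ in the protocol this pipeline follows, while the INT
literature typically reports ≈15,900 M⁻¹cm⁻¹. The default honours the
printed unit (`formazan_unit = "per_mM"`); `"per_M"` selects the literature
reading and scales Ec — and therefore CEA — by 10³. Because the choice
cancels nowhere, it is recorded in every pipeline log.

## Univariate statistics

Treatment differences use Kruskal–Wallis (tie-corrected), followed when
significant by pairwise Dunn z-tests with Holm adjustment and a compact
letter display computed from the maximal cliques of the
not-significantly-different graph. Dose-response monotonicity uses Spearman
rank correlation; outputs carry ρ, ρ² and the signed ρ² so either reporting
convention can be read directly.

## CAP: canonical analysis of principal coordinates

`cap()` follows the Anderson & Willis construction: principal-coordinate
analysis of the chosen distance (Euclidean by default, matching feature
matrices of raw Kautsky samples or fatty-acid percentages), canonical
discriminant analysis on the first *m* PCoA axes, and leave-one-out
allocation of each sample to the nearest group centroid in canonical space.
The leave-one-out is *true*: the held-out sample is projected (Gower's
add-a-point formula) onto axes recomputed without it, and the discriminant
is refitted without it, avoiding the optimism of re-used axes. *m* is chosen
to maximize LOO success (smallest *m* on ties) up to $n - g$ axes, unless
fixed by the caller; negative-eigenvalue axes are excluded with a warning
and a singular within-group covariance falls back to a flagged ridge. The
permutation test permutes group labels against the trace statistic
$\mathrm{tr}(Q_m' H Q_m)$ (the sum of squared canonical correlations), with
the seed recorded.

Two statistical properties of this construction deserve emphasis:

* **Selecting *m* by maximizing LOO success is optimistic under the null.**
  On structureless data the per-*m* LOO accuracies are chance-level
  estimates; taking their maximum over ~$n - g$ candidates is biased upward.
  Null-behaviour checks therefore fix *m*.
* **True-LOO nearest-centroid allocation is *conservative* under the null.**
  Holding a sample out moves its own group centroid away from it; with three
  replicates per group this depresses null allocation success visibly below
  $1/g$ (measured ≈13% against $1/6 \approx 16.7\%$, for every *m* from 1
  to 8). The classifier therefore never fabricates structure — its null
  accuracy sits at or below chance — but a two-sided "binomial band around
  $1/g$" check fails on the low side by this inherent bias, and the test
  suite documents exactly that. Resubstitution centroids or re-used axes
  would remove the conservative bias only by introducing an optimistic one.

## The synthetic-data generator

The generator emulates the study conditions so that every analysis stage has
a testable inverse. Its defaults are the design constants: doses
0–80 µg/L as above, 3 replicates, inoculation at 2.7 × 10⁵ cells/mL, 48 h
acclimation + 48 h exposure, a ground-truth IC50 of 47.3 µg/L and a
log-logistic slope of 2.93 — the exact two-parameter solution through the
39%/83% inhibition anchor points; steeper published paraphrases (h ≈ 3.9) do
not reproduce those anchors. Control cultures grow exponentially at
0.8 d⁻¹; exposed cultures grow at a reduced rate chosen so the endpoint
density deficit equals the log-logistic inhibition, which makes the IC50
identifiable from densities by construction.

Design choices a scientist should know:

* **Transient shape.** The Kautsky rise is a weighted sum of three log-time
  sigmoid phases (O–J, J–I, I–P) whose weights are solved from the requested
  $V_J$ and $V_I$, guaranteeing the cardinal points by construction. The
  representable envelope covers the physiological range
  ($V_J \in [0.3, 0.7]$, $V_I \lesssim 0.9$); extreme $V_I$ with low $V_J$
  has no monotone three-phase solution and is rejected explicitly.
* **Noise model.** Replicate noise is multiplicative lognormal with unit
  mean: cell counts and peak areas are positive and CV-stable. The default
  CV of 0.1 is an invented but typical biological replicate scatter — no
  variance model is available to emulate — and instrument-level noise
  (fluorescence, absorbance) is scaled down from it.
* **Dose trends.** Endpoint effects follow $\log(1+d)$ in dose (the gradient
  spans more than two decades), with signs mirroring the reported
  correlation directions and a default fractional effect of 0.4 at the top
  dose. Fatty-acid trends are mass-balanced so the total is dose-invariant:
  after closure to percentages, trending acids keep their exact signs
  (Spearman ±1 noiselessly) and untrended acids stay exactly flat.
* **Seeds.** One master seed; each (dose, replicate) stream derives its own
  seed from the dose *index* and replicate index, so streams do not shift
  when the dose list is extended.

What the generator does **not** emulate: mechanistic photosynthesis or
enzyme kinetics, chromatogram peak shapes (peak-area tables only),
dose-dependent variance heterogeneity, or any between-endpoint correlation
beyond the shared dose trend. Passing round-trip tests therefore demonstrate
that the analysis chain inverts its own forward models at the stated
tolerances — not that it would recover truth from real instrument
idiosyncrasies.

## Problem sizes and numerical choices

The test suite exercises 1,000 random transients for the JIP conservation
and round-trip properties, 100 random 7-pigment mixtures for GPS recovery,
100 seeds for noisy IC50 recovery (CV 0.1, n = 3, median error within 15%),
200 null datasets for the CAP chance-level and permutation-uniformity checks
(499 permutations each), and exhaustive enumeration for the two-group
Kruskal–Wallis oracle. Cardinal-point interpolation is linear in log-time;
area integration is trapezoidal on the raw grid; NNLS is the Lawson–Hanson
active-set method; CDA uses a symmetric $W^{-1/2} B W^{-1/2}$
eigen-decomposition with a flagged ridge fallback ($10^{-8}$ of the largest
within-group eigenvalue) for singular cases; ties in the *m* search resolve
to the smallest *m*.

## Known limitations

* The grouping index `p_g` and the AOEC fraction implement conventional
  JIP-test treatments of quantities whose instrument-specific formulas are
  unpublished; compare them only within an experiment.
* The GPS library is a synthetic stand-in; quantitative pigment
  concentrations from real extracts require the user's calibrated library,
  and the reported Gram condition number should be checked after any
  replacement.
* The energy model inherits the formazan unit ambiguity described above;
  absolute Ec and CEA values are only comparable under a stated
  `formazan_unit`.
* CAP leave-one-out accuracies with three replicates per group are
  conservative near the null and should be read together with the
  permutation p-value, not alone.
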