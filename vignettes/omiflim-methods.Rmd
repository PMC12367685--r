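---
title: "Single-cell optical metabolic imaging analysis with omiflim"
author: "omiflim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell optical metabolic imaging analysis with omiflim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

omiflim implements a complete single-cell optical metabolic imaging
(OMI) analysis chain for time-correlated single photon counting (TCSPC)
fluorescence-lifetime data of the metabolic coenzymes NAD(P)H and FAD:

1. per-pixel decay fitting — the biexponential model
   $I(t) = \alpha_1 e^{-t/\tau_1} + \alpha_2 e^{-t/\tau_2} + C$
   convolved with the instrument response function (IRF), fitted by
   weighted least squares;
2. per-cell feature extraction over label masks, including the optical
   redox ratio $\mathrm{NAD(P)H}/(\mathrm{NAD(P)H}+\mathrm{FAD})$;
3. a Gaussian-mixture heterogeneity index
   $H = \sum_i -w_i \ln w_i \, |\mu_i - \bar\mu|$ with a component
   weight-floor validity rule and BIC model selection;
4. group statistics (coefficient of variation, Glass's delta, log2
   fold changes, t/ANOVA+Tukey contracts); and
5. a random-forest activation classifier with a stratified 70/30
   split, evaluated by ROC/AUC, confusion matrix and feature
   importances.

Because raw neutrophil imaging data of this kind are rarely deposited,
the package ships a forward simulator (`scenario_config()`,
`sample_population()`, `render_field()`) that renders ground-truth cell
populations into Poisson-noisy decay cubes with label masks. Every
downstream stage is validated against this generator.

## The decay model and its numerical choices

**Time axis.** The default axis is 256 bins spanning a 12.5 ns window
(an 80 MHz repetition period), bin width ≈ 48.8 ps — a standard TCSPC
configuration. Decays are evaluated at bin centres.

**Incomplete decays.** A 2.5 ns bound-NAD(P)H component does not fully
decay within 12.5 ns. The model therefore uses the periodic steady
state, $e^{-t/\tau} / (1 - e^{-T/\tau})$, and convolves it
*circularly* with the IRF over the window. The acquisition window is
treated as the repetition period; with the default configuration the
two differ by less than 0.1%.

**IRF.** The default IRF is a Gaussian parameterized by FWHM and peak
position, normalized to unit sum — a standard surrogate for a measured
second-harmonic-generation response, which instruments record but
rarely parameterize. Measured IRFs load via `read_irf()` (JSON or
CSV). `make_irf()` degrades gracefully to a delta IRF as FWHM → 0,
which the identity tests exploit.

**Weighting.** Per-bin weights default to Neyman weighting
$w_i = 1/\max(O_i, 1)$, the convention of TCSPC least-squares software;
Pearson weighting ($1/\max(M_i,1)$, model-based, recomputed each
iteration) is available via `fit_config(weighting = "pearson")`.
Neyman weighting is known to bias parameters slightly at low counts —
we observe a ≈ 2–3% downward bias in $\tau_m$ at $10^4$ photons per
pixel, well inside the 5% accuracy regime this configuration targets.

**Optimizer.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) over
(amplitude, $\alpha_1$, $\tau_1$, $\tau_2$, $C$), with
$\tau \in [50, 10^4]$ ps, $\alpha_1 \in [0,1]$, $C \ge 0$.
Starting values are literature-typical free/bound lifetimes
($\alpha_1 = 0.7$, $\tau_1 = 300$ ps, $\tau_2 = 2000$ ps for NAD(P)H,
2500 ps for FAD); $C$ starts from the mean of the pre-rise bins. The
model is symmetric under exchange of the two components, so fits are
sorted post hoc to report $\tau_1 \le \tau_2$; the identifiability test
verifies that swapped initializations land on identical reported
parameters. Non-convergence and degenerate inputs (all-zero decays)
yield `converged = FALSE` with the parameters retained or `NA` — never
silent drops or `NaN` propagation.

**Reduced chi-squared.** $\chi^2_\nu = \chi^2/(n_\mathrm{bins} - 5)$
for the five free parameters. On correctly specified Poisson data the
median is calibrated to ≈ 1.0 (tested at [0.8, 1.2]). A
$\chi^2_\nu$ cut-off is available as a quality *flag*
(`fit_config(chi2_max = )`) but is off by default: with Poisson noise
roughly half of perfectly specified fits exceed 1.0, so a hard
"< 1.0" rejection would discard half the valid pixels and bias maps.

**Binning and thresholding.** 3×3 binning sums each pixel's
neighbourhood decay-wise; borders truncate the neighbourhood rather
than pad (no photons are invented). The peak-count threshold
(default 50 after binning, a free parameter that commercial TCSPC
software leaves to the operator) uses a ≥ comparison.

## Per-cell aggregation

Cell features are unweighted means of each parameter map over the
cell's valid pixels (threshold ∧ converged); reports in this field
rarely state whether per-cell values are pixel means or
intensity-weighted means, and the unweighted mean is the simpler
convention.
The cell redox ratio is likewise the mean of *per-pixel* redox values,
following the pixel-level definition of the ratio; the ratio of summed
intensities is an alternative the user can compute from the intensity
columns. Pixels with zero combined intensity are excluded, not coerced
to zero. The default morphology triple is area (µm²), second-moment
eccentricity and convex-hull solidity. Cells need ≥ 10 pixels valid in
both channels (stabilizes means; configurable).

**Boundary rule.** Cells touching the image border are excluded when
less than half of the cell lies inside the frame. For a convex cell
this is *equivalent* to its widest extent parallel to the touched
border lying on the border row/column itself (the width profile of a
convex shape is unimodal about its centre), which is what
`filter_cells()` tests — it is exact for the generator's ellipses and
robust on pixelated masks, where direct ellipse fits to short visible
arcs proved ill-conditioned. Size- and lifetime-range rules (proxies
for manual exclusion of other cell types) exist but default to off;
every removal is logged with its rule.

## Heterogeneity index

Single-cell NAD(P)H $\tau_m$ values (the variable is a parameter) are
fitted with univariate Gaussian mixtures, $k = 1 \ldots 3$, by EM on
the raw values with 10 seeded k-means restarts, tolerance $10^{-6}$ on
the log-likelihood, and a variance floor of $10^{-9}\times$ the sample
variance. Fits in which any component weight falls below 0.1 are
discarded as over-fitting; among the valid fits the lowest
$\mathrm{BIC} = p \ln n - 2 \ln \hat L$ (with $p = 3k - 1$) wins, ties
to smaller $k$. $k=1$ has weight 1 and is always valid, so selection
cannot fail. Natural logarithms are used in both the entropy term and
the BIC (conventions that write "log" without a base are read as
natural log).

$H$ carries the units of the input variable — $\tau_m$ in ps gives
values three orders of magnitude larger than the same data in ns — so
results record their units. $H = 0$ exactly when one component is
selected or all means coincide; $H$ is shift-invariant and scales with
$|c|$ under $x \mapsto cx$, both tested to $10^{-9}$.

A deliberately homogeneous population (one condition of the default
scenario) selects $k = 1$ and reports $H = 0$; pooling control and
activated cells produces genuine sub-population structure and a
positive $H$. Per-donor values measured on primary human cells cannot
be reproduced from simulation and are not targeted.

## Group statistics and classification

All SDs use the sample ($n-1$) denominator. The CoV heatmap matrix
z-scores each variable across groups (degenerate rows become 0 with a
warning) and exposes hierarchical-clustering orders as metadata rather
than plotting. Glass's delta normalizes by the *control* SD, the
appropriate effect size when treatment changes the variance. Metabolite
fold changes average replicates before taking log2(sample/control); the
LC-MS redox ratio supports both plausible cofactor conventions and
records which was used. `compare_groups()` delegates to `t.test`
(Student, pooled variance), `aov` and `TukeyHSD`, with 0.05/0.01/0.001
significance stars; its type-I error is verified at 3–7% over 1000
seeded null replicates. Mixed-effects modelling of in vivo data is out
of scope: the package emits tidy per-cell tables for external fitting.

The classifier is a 500-tree random forest on the ten OMI variables
(± the three morphology variables), a stratified 70/30 cell-level
split, AUC from out-of-sample class probabilities, confusion matrix at
0.5, and Gini importances normalized to sum to 1. Cell-level splitting
is the common design in this field but leaks donor structure when
donors are pooled; `split_data(stratify_by = "donor_id")` offers the
donor-aware alternative.

## What the simulator does and does not emulate

The generator draws per-cell biexponential parameters from truncated
Gaussians per condition, places non-overlapping axis-aligned ellipses
by rejection sampling (after 1000 failed attempts a cell is placed
anyway with a warning; overlaps resolve deterministically, later id
wins), renders each cell's expected decay — wrapped biexponential,
IRF-convolved, scaled to its photon budget, plus a flat background
offset — and applies bin-wise Poisson noise from per-cell random
substreams, so adding a cell never perturbs the noise of existing
cells. A noiseless mode supports exact identity tests.

Default conditions emulate quiescent vs activated neutrophils with the
established directions of activation: lower NAD(P)H $\tau_m$
(0.70→0.78 in $\alpha_1$, 400→380 ps in $\tau_1$, 2500→2300 ps in
$\tau_2$) and higher redox ratio (0.55→0.62, realized through the FAD
photon budget). The magnitudes are free simulation parameters, chosen
once at values typical for this instrument class. Between-cell SDs
(0.02 in $\alpha_1$, 15/80 ps in $\tau_1/\tau_2$, 0.03 in redox)
produce within-condition CoVs of a few percent, comparable to typical
single-cell OMI scatter. The
photon budget defaults to 1200 photons/pixel (≈ $1.1\times10^4$ after
3×3 binning), since instruments report count *rates*, not per-pixel
totals.

Not modelled: optical PSF blur, detector afterpulsing, dead time,
spectral bleed-through, cell shapes beyond ellipses, within-cell
parameter gradients, or donor-level random effects. Passing tests
therefore demonstrate correctness of the *analysis* under a known
forward model — not robustness to every artefact of real microscopy.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run, by choice, at desk
scale: parameter recovery on one 64×64 field (12 cells,
≈ 1000 fitted pixels); $\chi^2$ calibration on 400–2000 single-pixel
fits; mixture-selection rates over 50 seeded replicates at
$n = 500$; end-to-end classification on 5 fields/condition
(≈ 70 cells/condition) for the activation scenario and
20 fields/condition (≈ 280 cells/condition) for the null scenario,
with AUC averaged over 10–20 split seeds so its sampling noise is
small against the chance-level band. Larger fields change none of the
statistics, only their precision.

## Known limitations

- Equivalence with proprietary instrument-vendor fitting software is
  not claimed; weighting and convergence rules differ between vendors.
- Neyman weighting's small-sample bias (see above) is inherent to the
  convention; switch to Pearson weighting when photon budgets are low.
- The boundary rule is exact for convex cells only.
- `H` depends on the EM seed in principle; with the default 10
  restarts, selection and `H` are stable across seeds in all tested
  scenarios.
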