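# omiflim

Single-cell **optical metabolic imaging** (OMI) analysis from TCSPC
fluorescence-lifetime data, in R.

Immune cells such as neutrophils rewire their metabolism within minutes
of activation. Label-free OMI detects this at single-cell resolution by
imaging the autofluorescence of the metabolic coenzymes NAD(P)H and
FAD: activated cells show a shorter NAD(P)H mean lifetime, a larger
free-NAD(P)H fraction and a higher optical redox ratio. omiflim
implements the full analysis chain that turns raw photon-arrival
histograms into those per-cell readouts and their group-level
statistics — for microscopists and computational biologists who have
TCSPC decay cubes and cell masks and want a tested, scriptable pipeline.

## What it computes

**Per pixel** — the biexponential decay model

> I(t) = α₁·exp(−t/τ₁) + α₂·exp(−t/τ₂) + C,

wrapped over the laser repetition period, convolved with the
instrument response function (IRF), and fitted by bounded
Levenberg–Marquardt weighted least squares after 3×3 spatial binning
and intensity thresholding. Reported per pixel: α₁, τ₁, τ₂, C, the
mean lifetime τₘ = α₁τ₁ + α₂τ₂, integrated intensity, and reduced χ².

**Per cell** — means of the fitted maps over a label mask, the optical
redox ratio NAD(P)H/(NAD(P)H+FAD), morphology (area, eccentricity,
solidity), and the boundary-cell exclusion rule (<50% of the cell
inside the frame).

**Per group** —

- a heterogeneity index from a Gaussian mixture fit of single-cell
  NAD(P)H τₘ (k ≤ 3, every component weight ≥ 0.1, lowest BIC):
  **H = Σᵢ −wᵢ ln wᵢ |μᵢ − μ̄|**, zero for homogeneous populations;
- coefficient-of-variation matrices (z-scored across conditions),
  Glass's delta effect sizes, log2 fold changes, LC-MS redox ratios,
  t / ANOVA + Tukey tests;
- a 500-tree random-forest activation classifier with a stratified
  70/30 split, ROC/AUC, confusion matrix and feature importances.

A forward simulator (`scenario_config()` → `sample_population()` →
`render_field()`) renders ground-truth cell populations into
Poisson-noisy decay cubes plus label masks, so the entire pipeline is
testable without microscope data. Cubes, masks and truth tables
round-trip through multi-page TIFF + JSON sidecars and CSV.

## Worked example

Simulate one field of quiescent ("control") and one of PMA-activated
cells, run the pipeline, and analyse:

```r
library(omiflim)

irf <- make_irf(fwhm_ps = 250, bin_width_ps = 12500/256,
                n_bins = 256, t0_ps = 1200)
cfg <- scenario_config(n_cells = 10,
                       optics = optics_config(field = c(64, 64)))
tab <- simulate_and_extract(cfg, irf, seed = 7, n_fields = 1)

tab[1:4, c("cell_id", "nadph_tau_m", "nadph_alpha1_pct",
           "redox_ratio", "area_um2")]
#>   cell_id nadph_tau_m nadph_alpha1_pct redox_ratio area_um2
#> 1       1     927.335           74.053       0.551    15.25
#> 2       2    1103.740           66.555       0.554    21.25
#> 3       3    1082.418           66.445       0.565    12.50
#> 4       4     987.118           66.269       0.570    15.25

compare_groups(tab, "nadph_tau_m")
#> <omi_group_test> student_t: statistic = 9.486, p = 2e-08 ***

glass_delta(tab$nadph_tau_m[tab$condition == "PMA"],
            tab$nadph_tau_m[tab$condition == "control"])$delta
#> [1] -3.66

heterogeneity(tab$nadph_tau_m, seed = 1)
#> <omi_heterogeneity> H = 79.63 ps (k = 2, n = 20)
```

Each row is one cell. The activated cells sit ~230 ps below the
controls in NAD(P)H τₘ (hence the strongly negative Glass's delta) and
the *pooled* population is bimodal, so the mixture selects k = 2 and
the heterogeneity index is large; within a single condition the
populations are unimodal and H = 0. Lifetimes are in picoseconds, the
redox ratio is dimensionless in [0, 1], and H carries the units of the
input variable (here ps).

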