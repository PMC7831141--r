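---
title: "Luminescence-lifetime oximetry and dendrogram analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Luminescence-lifetime oximetry and dendrogram analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plimox)
```

## The measurement chain

Oxygen quenches the phosphorescence of [Ru(Phen)₃]²⁺, so the probe's
emission lifetime is an oxygen meter: around 1090 ns at zero oxygen,
dropping below 550 ns at 20 % O₂ in N₂. The package models the chain
from raw signal to biological conclusion in four stages:

1. **Decay fitting.** A gated acquisition yields time-binned photon
   counts. `fit_mono()` fits `I(t) = A·exp(−t/τ) + B` by
   Levenberg–Marquardt least squares; `fit_bi_fixed()` adds a second
   exponential with its lifetime *held fixed* (default 20,000 ns), the
   standard device for per-pixel phosphorescence maps in which a sparse,
   very-long-lived contribution (e.g. DNA-bound probe) would otherwise
   bias τ₁. The fraction `A₂/(A₁+A₂)` is reported but deliberately not
   thresholded — it is a diagnostic, not a decision rule.
2. **Calibration.** `tau_to_oxygen()` applies the Stern–Volmer relation
   `%O₂ = (1/τ − a)/b` with `a = 919,155.47 s⁻¹`, `b = 45,157.84 s⁻¹/%`
   (solution calibration of the probe in 0.9 % NaCl). Lifetimes are
   handled in nanoseconds at every public interface and converted to
   seconds internally, because the constants are meaningful only on the
   seconds scale.
3. **Distribution statistics.** Per condition (oxygen regime × minutes
   post administration × in/out of vessels), the lifetime sample is
   reduced to the six-number summary `(min, Q1, mean, median, Q3, max)`
   and the indicators `rel_Md` (median–mean asymmetry; zero for
   symmetric, Gaussian-like samples) and `rel_OI` (extravascular vs
   intravascular mean-lifetime contrast, stored on the `out` row of each
   pair).
4. **Clustering.** Conditions are compared by the Minkowski `p = 1`
   distance between their six-number vectors — with `p = 1` the heights
   stay interpretable as summed nanosecond differences — and
   agglomerated by Ward.D2 (`ward_d2_linkage()`), with cophenetic
   distances and Newick export for downstream tree analysis.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `intercept_a`, `slope_b` | 919155.47, 45157.84 | s⁻¹, s⁻¹/% | published solution calibration; configurable via JSON/YAML |
| `tau2_fixed` | 20000 | ns | fixed slow component for PLIM fits |
| `min_counts` (`fit_map`) | 50 | counts | pixels below threshold stay undefined ("dark areas"); instrument-dependent |
| `bin_width` (`map_histogram`) | 10 | ns | matches the 100–1000 ns display range of PLIM maps |
| `threshold` (`split_bimodal`) | 600 | ns | the boundary between quenched extracellular and intact intracellular populations in peroxide-treated cultures |
| `p` (`minkowski_distance_matrix`) | 1 | — | city-block distances in ns |
| `dispersion_cv` (synthetic) | 0.08 | — | see below |
| `n_samples` (synthetic) | 500 | per cell | see below |

## What the synthetic generator emulates — and what it does not

No raw per-decay lifetimes are published for the in vivo study; only
per-condition means, `rel_Md`, `rel_OI` and the derived %O₂ are printed.
`table1_specs()` transcribes those 18 cells as generation targets, and
`generate_condition_samples()` draws from a shifted-gamma family whose
population mean and population `rel_Md` equal the targets:

* the target `rel_Md` fixes the population median
  `Md = mean·(2+r)/(2−r)`;
* with the standard deviation pinned at `cv × mean`, the gamma shape `k`
  solves `(k − qgamma(0.5, k))/√k = |Md − mean|/sd` on the decreasing
  branch of that function (the less extreme of the two roots; the
  attainable maximum ≈ 0.414 makes some asymmetry/dispersion
  combinations impossible, reported as an explicit error);
* positive `rel_Md` (median above mean) uses the reflected gamma,
  symmetric targets the Gaussian limit.

**Defaults.** Dispersion is a coefficient of variation of 0.08. The
study measured ten eggs per condition but does not state decays per egg;
the default of 500 lifetimes per cell corresponds to ten eggs × ~50
repeated point acquisitions (realistic for a 10 Hz pulsed source) and is
sized jointly with the dispersion so that the regime-level structure the
clustering stage is meant to resolve — the 0 % regime separating from
{10 %, 20 %} at the top of the tree — holds robustly across seeds. At
materially smaller per-cell samples the quartile estimates are noisy
enough that the top split misassigns border conditions in a substantial
fraction of seeds.

The generator reproduces the *distributional* structure only. It does
not emulate between-egg heterogeneity (draws within a cell are i.i.d.),
temporal drift within an acquisition, instrument response, or any
spatial correlation in maps. Passing tests therefore demonstrate that
the analysis recovers the assumed structure, not that real CAM data are
shaped exactly this way.

Scenes (`scene_preset()`) place constant-lifetime regions on a grid:
`fig5_cells` (650 ns medium / 800 ns cell interiors), `fig8_h2o2`
(medium quenched to 400 ns by peroxide), `uniform`, and `cells_dark_bg`
(no background signal, exercising the undefined-pixel path). Pixel
decays come from the same mono-exponential machinery with optional
Poisson noise.

## Numerical choices

* **Optimizer.** Fits use `minpack.lm::nls.lm` directly with explicit
  residual functions. The higher-level `nlsLM` wrapper constructs an
  `nls` model object that fails on exactly-zero-residual (noiseless)
  traces and at box bounds; the low-level route is robust there.
  Estimates are validated afterwards (`τ > 0`, `A ≥ 0`); invalid or
  non-converged fits return an explicit failure object, never silent
  `NaN`s.
* **Initialisation.** Baseline from the trace tail, then τ and A from a
  log-linear regression of baseline-corrected counts — the closed form
  that is exact for clean mono-exponential data.
* **Goodness of fit.** Reduced χ² uses Poisson-variance weights
  `var = max(counts, 1)`, so a good photon-counting fit sits near 1.
* **Quartiles.** Linear interpolation between order statistics at
  positions `1 + (n−1)p` (R's default type 7, the convention of
  `summary()`).
* **Printed precision.** The published per-condition oxygenation values
  are reproduced exactly by *truncating* the computed %O₂ to the printed
  decimals, not by rounding (e.g. 16.0079 prints as 16.00, 4.2508 as
  4.2, and 16.55 as 16.5); `truncate_decimals()` implements this
  convention and the condition table exposes it as
  `percent_o2_printed`. Computations always carry full precision.
* **Ward.D2.** Lance–Williams recurrence on squared distances; heights
  are square roots, in the input units. Exact cost ties break toward the
  pair whose smallest original leaf indices are lexicographically least,
  making the tree deterministic. Heights are emitted unnormalised —
  any display normalisation is a plotting concern.
* **Degenerate inputs.** Empty samples, all-zero traces, fewer than five
  populated bins, non-symmetric distance matrices, empty ROIs and
  FLIM-channel oxygen conversion all raise immediate, specific errors.
  One-sided bimodal splits return an empty population rather than
  failing. Out-of-calibration lifetimes (τ above the zero-oxygen
  lifetime, as for nucleus-bound probe) yield negative %O₂ with a
  `below_calibration` flag — never clipped, since clipping would hide
  out-of-calibration physics.

## Design decisions on genuinely open points

* **Which split threshold for which scene.** 600 ns separates quenched
  extracellular medium (≈400 ns after H₂O₂) from intact cell interiors
  (≈800 ns). For the untreated two-population configuration
  (650 ns / 800 ns) a 600 ns threshold cannot discriminate — both modes
  lie above it — so its natural split point is the histogram valley near
  725 ns. The tests exercise both pairings.
* **Clustering features.** Full six-dimensional summary vectors are
  clustered; no per-panel reduction is attempted.
* **rel_OI pairing.** Computed from the `out` and `in` cells sharing
  regime and time, stored on the `out` row; a missing partner logs a
  warning and leaves the value absent.
* **Seeds.** Every stochastic public interface requires a seed; the
  pipeline derives per-stage seeds deterministically from one top-level
  seed, and identical configuration + seed reproduce byte-identical
  numeric outputs.

## Problem sizes used by the test suite

Parameter-recovery checks run 100 Poisson replicates at 10⁶ total counts
over τ ∈ [400, 900] ns (mono; |bias| < 1 %, RMSE < 2 %) and 30 fixed-τ₂
mixtures (τ₁ within 3 %). Clustering is verified against a brute-force
recompute-from-scratch Ward agglomerator on 100 random instances with
n ≤ 7 leaves, plus 100 random trees for monotonicity and cophenetic
ultrametricity. The regime-outlier property is evaluated over 20 seeds
of the full 18-cell synthetic study. Scenes use 24 × 24 grids with
64 time bins.

## Known limitations

* The printed dendrogram heights of the original in vivo trees
  (150/270 ns) are not reproducible because the underlying raw lifetime
  samples are unpublished; the package asserts the qualitative regime
  topology instead.
* Instrument-response deconvolution is not performed (pulse widths are
  two orders of magnitude shorter than the lifetimes of interest).
* FLIM maps are carried through the same machinery but have no oxygen
  conversion — the calibration belongs to the phosphorescent probe.
* ROIs are user-supplied masks; no segmentation is attempted.
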