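---
title: "Methods: simulating and analysing fluorescence thermal-shift ligand screens"
author: "ftsascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing fluorescence thermal-shift ligand screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftsascreen)
```

## Scope

`ftsascreen` models a genome-scale fluorescence thermal-shift (FTS/DSF)
ligand screen of ABC-transporter solute-binding proteins and implements its
analysis: melt-curve simulation with known ground truth, derivative-based
melting-midpoint (Tm) calling, ΔTm binding classification against matched
no-ligand controls, two-step pooled screening with deconvolution, and
evidence-based tiering of functional assignments. This vignette documents
the model, the defaults and why they were chosen, the numerical decisions,
and what the package's simulation-based validation does and does not
establish about real instrument data.

## The unfolding model

Unfolding is two-state with an apparent van 't Hoff enthalpy and no
heat-capacity increment:

$$f(T) = \frac{1}{1 + e^{\Delta G(T)/RT}}, \qquad
  \Delta G(T) = \Delta H_{vH}\left(1 - \frac{T}{T_m}\right),$$

temperatures in Kelvin inside the thermodynamics core, degrees Celsius
everywhere else. The two-state form is the simplest model that yields a
single cooperative sigmoidal melt — the regime in which derivative Tm
calling is meaningful — and keeps parameter recovery well posed. No ΔCp
means ΔG is linear in T; over the ±15 °C around the midpoint that the
analysis actually uses, curvature from a realistic ΔCp would be a
second-order effect on the extremum position.

A ligand present at concentration $L$ that binds only the folded state with
dissociation constant $K_d$ raises the unfolding free energy by
$RT\ln(1 + L/K_d)$ (ligand in excess, free ≈ total — at 100× ligand:protein
this is accurate to ~1%). The shifted midpoint solves

$$\Delta G(T) + RT\ln(1 + L/K_d) = 0$$

by bracketed root finding (`uniroot`) over the acquisition window; if the
stabilization pushes the root past the window's upper edge the edge is
returned with a `saturated` flag. `kdForShift()` inverts the relation in
closed form, which is how simulations plant binders with prescribed shifts.

Two consequences of this model worth knowing:

* **Same-ratio invariance is approximate, and enthalpy-dependent.** At
  saturation, doubling $L$ at fixed ratio adds $R T_m^2 \ln 2 / \Delta H_{vH}$
  to the shift. Duplicate-concentration screening (5 µM/500 µM vs
  10 µM/1000 µM) therefore agrees to ≤ 2 °C only when
  $\Delta H_{vH} \gtrsim 320$ kJ/mol at $T_m \approx 55$ °C. The default
  enthalpy (below) respects that observed assay property.
* **The exact form is slightly asymmetric.** Because $\Delta G/RT$ carries a
  $1/T$ term, the steepest-ascent temperature of a noiseless melt sits
  slightly *below* the thermodynamic midpoint, by roughly
  $2\pi^2R^2T_m^3/3\Delta H_{vH}^2$ — negligible at the default 450 kJ/mol
  (< 0.05 °C) but approaching 1 °C at 100 kJ/mol. ΔTm is unaffected (the
  displacement cancels between sample and control). Tests of the caller
  therefore use the model's own steepest-ascent point, computed by an
  independent fine-grid oracle, as the reference for absolute Tm.

## Curve rendering and instrument profiles

$$F(T) = (1-f)\,N(T) + f\,U(T)\,e^{-k\,\max(0,\,T-T_m')} + bg(T) + \varepsilon$$

* $N, U$: linear baselines, defaults 200 − 0.5·T and 2600 − 0.5·T
  fluorescence units — a low native signal and a high unfolded plateau, as
  SYPRO-orange reports hydrophobic surface exposure. Parallel slopes keep
  the transition amplitude constant across the window, so the derivative
  extremum is not displaced by a baseline-convergence gradient.
* $k$: post-transition decay, default 0.002 /°C. Real curves lose signal
  above the transition as dye dissociates; the decay begins at the apparent
  midpoint, so it skews the derivative peak slightly low. 0.002 keeps that
  systematic under ~0.1 °C while preserving the qualitative post-peak
  decline; heavier decay (supported via the parameter) biases derivative
  calls further and is a documented limitation of the extremum method, not
  of the simulator.
* $bg$: optional fatty-acid dye background, 20 units per µM of ligand with
  a mild temperature fade. At 100× concentrations it rivals or exceeds the
  protein transition amplitude — the behaviour that motivates the 10×
  fatty-acid rule — while at 40 µM it is a modest offset.
* $\varepsilon$: additive Gaussian noise, default SD 5 units (~0.2% of the
  transition amplitude). This is the one deliberately calibrated default:
  it is chosen so that the pipeline reproduces the assay's documented
  reproducibility — duplicate ΔTm spreads consistently below 2 °C and mean
  absolute midpoint recovery error below 0.2 °C at default settings.

Instrument profiles bundle the ramp and signal characteristics. The default
`"lightcycler480"` profile acquires 30 points per degree over a 70 °C ramp
(2101 points, 25–95 °C) and is the reference frame for midpoints; the
sparser `"mx4000"` profile reads apparent midpoints 3 °C lower, emulating
the systematic between-instrument difference observed when identical
reactions are run on both machines. The offset moves every Tm but cancels
in ΔTm — a property the test suite checks explicitly.

**Randomness contract.** One root seed per plate; each well draws from a
substream derived from (seed, plate:well key) by a polynomial hash, so
simulation is bit-reproducible and independent of well evaluation order.

## Tm calling

The caller mirrors instrument "Tm calling" software: smooth, differentiate,
take the extremum.

1. **Smoothing**: Savitzky–Golay, polynomial order 3, window ≈ 1 °C of
   points (forced odd). Local polynomial smoothing preserves derivative
   peak positions, which flat-kernel averaging does not.
2. **Derivative**: −dF/dT by central differences on the interior grid. At
   30 points/°C central differences re-amplify residual high-frequency
   noise, so the derivative trace — which varies over several degrees —
   receives a second local-polynomial pass with a ~2 °C window before
   extremum selection.
3. **Analysis window**: trim 10% of the temperature range at each extreme,
   then start the search at the minimum of smoothed fluorescence over the
   first half of the window. This excludes the initial dye-background
   descent that SYPRO curves show, so a steep early decay is never mistaken
   for the transition.
4. **Extremum**: global minimum of the smoothed derivative; ties break to
   the lowest temperature (determinism). A parabolic fit through the
   extremum and its neighbours refines the call to sub-grid resolution,
   confined to ±half a grid step.
5. **Quality control**: the transition amplitude is the peak depth over the
   median absolute deviation of the derivative sampled from the outer 15%
   of the window (true baseline whatever the peak width). Amplitude below
   k = 5 flags `no_clear_melt` with no midpoint — the fate of wells with
   denatured protein, near-flat traces, or protein-free controls. An
   extremum touching the window boundary flags `edge_of_window`. Secondary
   minima at least half as deep as the main one are counted as metadata;
   only the global extremum is reported, since the assay reports a single
   Tm per well.

Calling is exactly translation-equivariant in temperature and invariant to
positive affine transforms of fluorescence, both pinned by tests.

## ΔTm, controls and classification

Every plate carries negative controls: duplicate protein-only wells per
protein (their ok-flagged Tm values are averaged into the control
midpoint), a buffer-only and a dye-only well. Dye/buffer wells are sanity
checks only; no background subtraction is applied before Tm calling, since
a flat additive background does not move the derivative extremum.

Control matching prefers a same-plate control in the sample's solvent class
— a 2% DMSO reaction is compared against a 2% DMSO protein-only control,
because DMSO itself can shift the midpoint — then degrades to any-solvent
or off-plate controls with explicit annotations. A protein with no usable
control yields `qc_fail` for all its wells.

ΔTm = Tm(sample) − Tm(control), signed; duplicates are averaged
(arithmetic mean) and the spread (max − min) kept, flagged at ≥ 2 °C as
atypical variability. Classification is *binding* iff mean ΔTm ≥ 2.0 °C,
threshold inclusive; destabilization (negative ΔTm) is reported but never
classified as binding. Tm is called per well and ΔTm averaged afterwards —
the alternative (averaging curves before calling) is statistically close
but couples replicate noise, and per-well calling preserves per-replicate
QC.

Per-target summaries list at most the four strongest binding ligands
(highest mean ΔTm, ties broken by ligand id).

## Screen construction

* **Pools** partition the library by (chemical category, stock solvent),
  at most 10 members; oversized groups split into balanced, id-ordered
  pools (25 members → 9/8/8). Stocks at nonstandard pH (pH 10 / pH 1.5
  buffers) are never pooled and run as singletons, since they are dosed
  individually to keep the nonstandard buffer at 2% of the reaction.
* **Concentrations**: 100× ligand:protein for standard chemistry, 10× for
  fatty acids; permitted protein concentrations default to {4, 5, 10} µM.
* **Plate layout**: 96-well plates filled row-major; sample wells are
  packed greedily and each plate closes with its own control block.
  DMSO-stock pools are marked for 2% final DMSO and paired with
  DMSO-matched protein-only controls on the same plate.
* **Deconvolution**: every (protein, pool) with a binding verdict is
  re-tested against the pool and each member ligand. `deconvolute()`
  schedules each follow-up reaction once; the orchestrator (`runScreen`)
  requests two replicates, honouring the rule that every positive reaction
  is independently duplicated. Proteins without pooled hits get nothing.
* **Pool signal**: a simulated pooled well melts with the member ligand
  producing the largest individual shift — one stabilizer dominates. This
  is the design decision under which the two-step screen is provably
  equivalent to an exhaustive per-ligand screen on noise-free data, an
  equivalence the test suite checks end to end. Real pools can deviate
  (competing binders, additive weak stabilization); the deconvolution
  stage, not the pooled signal model, is what identifies the individual
  binder in either case.

## Evidence tiering and annotation comparison

Assignments are tiered by external validation: **High** = good-quality
assay data plus ≥ 2 external sources (literature, genome context,
annotation/description, PDB homology, other); **Moderate** = one source;
**Low** = good-quality assay data alone; marginal data with no sources gets
no tier. "Good quality" is operationalized as: all replicate spreads
< 2 °C and no QC flags — the assay's only quantitative quality statements.
Duplicate source entries never change a tier. Annotation consistency is
scored at the ligand-category level (predicted class among the categories
of observed binders), since functional predictions name ligand classes
rather than exact compounds.

## What the simulations do and do not establish

The generator emulates: single-transition SYPRO-style melts, ligand- and
concentration-dependent stabilization, replicate noise at the assay's
documented reproducibility, a systematic between-instrument midpoint
offset, and the high fatty-acid dye background. It does not model ΔCp,
aggregation or oligomerization, multi-domain/multi-transition melts,
scan-rate (kinetic) effects, dye-binding kinetics, compound insolubility or
precipitation, or pool-internal competition. Green tests therefore
establish that the analysis is correct *for data matching the assay's
stated behaviour*; they cannot certify performance on pathological real
curves, which is precisely what the `no_clear_melt` / `edge_of_window`
flags are for.

Validation problem sizes were chosen to exercise the statistics while
keeping the suite quick: 200 noisy curves for recovery error, 50 root
seeds for duplicate-spread and instrument-offset Monte-Carlo checks, a
48-reaction duplicated campaign (8 proteins × 6 ligands) for the
reproducibility figure in `scripts/acceptance.R`, and full-library
(33-category) pool construction for the partition properties.

## Known limitations

* The derivative extremum is a biased estimator of the thermodynamic
  midpoint when post-transition decay is strong or the transition shallow;
  this is inherent to the assay's Tm definition, and all binding decisions
  rest on ΔTm, where the bias cancels.
* `no_clear_melt` detection uses a fixed amplitude ratio (k = 5); very
  broad genuine transitions on top of strongly sloped backgrounds can in
  principle be flagged. k is configurable.
* Pool scheduling assumes all pools are compatible with all proteins;
  the assay's occasional category-specific exemptions are left to the
  caller by subsetting the pool table.
* Tm values at the acquisition-window edge saturate (flagged); shifts
  beyond the ramp cannot be quantified, only bounded.
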