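---
title: "From volt-ohm-meter readings to paracellular permeabilities: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From volt-ohm-meter readings to paracellular permeabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraperm)
```

## The measurement problem

A confluent epithelial monolayer on a permeable filter separates an apical
from a basal bath. When the two baths carry different NaCl concentrations,
a charge-selective paracellular barrier produces a *dilution potential*
whose sign and size encode the ratio of the apparent sodium and chloride
permeabilities, β = P_Na/P_Cl; together with the transepithelial
resistance (TER) this yields the absolute permeabilities. Both raw readings
are contaminated by the filter itself and by electrode junction potentials,
which is why every epithelium-bearing filter is paired with a cell-free
*blank* filter measured under identical solutions and subtracted time point
by time point.

`paraperm` implements this chain as composable steps —
`blank_correct()` → `ghk_invert_beta()` → `kk_split_permeabilities()`,
wrapped by `compute_permeability_series()` — plus the morphometric
companion (`zigzag_index()` and its sampling protocol) and a simulator
that generates raw series with known latent truth.

## Model and assumptions

### Two-ion constant-field electrodiffusion

Only Na⁺ and Cl⁻ enter the potential model. The other bath ions (K⁺,
Mg²⁺, Ca²⁺, the HEPES anion) are identical on both sides in every
condition, so they generate no diffusion potential; their conductance
contribution is absorbed into the measured G. With apical (a) and basal
(b) concentrations,

$$V = \frac{RT}{F}\,\ln\frac{\beta\,C_{Na,b} + C_{Cl,a}}
{\beta\,C_{Na,a} + C_{Cl,b}},$$

apical minus basal, so a dilute apical bath over a cation-selective
barrier gives a positive potential. The inversion is closed-form
(`ghk_invert_beta()`); it is defined only strictly between the Cl⁻ and
Na⁺ Nernst potentials, and the implementation refuses values at or beyond
those limits rather than returning a sign-flipped or infinite ratio. The
forward/inverse pair is verified to round-trip to 1e-9 relative error
across β ∈ [0.05, 100] and all NaCl pairs from {70, 140, 210} mM, and the
forward relation is cross-checked in the tests against an independent
zero-current root-finder on the GHK current equation.

Concentrations are used as molarities throughout — no activity
corrections. That matches how such measurements are conventionally
reduced; since both the forward construction and the inversion use the
same convention, selectivity ratios are unaffected and absolute
permeabilities shift only by a common factor.

Free-ion bookkeeping: Na⁺ counts NaCl + HEPES-NaOH; Cl⁻ counts
NaCl + KCl + 2·MgCl₂ + 2·CaCl₂. The shipped condition presets use this
full accounting; a pure-NaCl bath pair can be built directly when only
the nominal 70/140 mM gradient matters.

### Kimizuka–Koketsu conductance decomposition

The zero-current conductance of the constant-field model separates into
per-ion terms,

$$G = \frac{F^2}{RT}\left(P_{Na}\,\bar C_{Na} + P_{Cl}\,\bar C_{Cl}\right),$$

with concentrations in mol/cm³ so that P comes out in cm/s. Under a
standing gradient the "concentration" of each ion is not unique; the
constant-field-consistent choice is the *logarithmic mean* of the apical
and basal values, which is the default. Arithmetic-mean and basal-only
variants are selectable (`variant =`), because the literature is not
uniform here; for a two-fold gradient the arithmetic-mean variant shifts
P_Na by ~4% relative to the log mean, and the basal-only variant by ~28%,
so the choice must be explicit rather than silent. The decomposition is
tested against the conservation identity
(F²/RT)(P_Na·C̄_Na + P_Cl·C̄_Cl)·TER = 1 at 1e-12.

### Sign conventions and units

Potentials are handled in volts internally and reported in mV; they are
always apical-minus-basal. TER is area-normalised (Ω·cm²); raw meter ohms
can be converted with the filter growth area (1.12 cm² for a 12-mm
insert) at ingest. Temperature defaults to 310.15 K and enters only
through RT/F (≈ 26.73 mV).

## The condition presets

`condition_presets()` ships the eight osmotic-challenge bath combinations
(apical or basal NaCl at 70/140/210 mM, with or without 130 mM sucrose —
or mannitol — balancing the osmolarity) and the reversibility protocol, in
which the apical bath is replaced at 120 min by the sucrose-balanced
solution with *unchanged* NaCl: the osmotic gradient disappears while the
NaCl gradient, and therefore the measurement configuration and the liquid
junction potentials, stay constant. `osmotic_class()` classifies a bath
pair by nominal osmolarity difference with a ±20 mOsm/L isosmotic band:
130 mM sucrose replaces 140 osmotic units of NaCl, so "balanced"
conditions sit 10 mOsm/L off exact equality by design, and the band must
absorb that residual.

Nominal osmolarity is the ideal-dissociation sum (NaCl, KCl, HEPES-NaOH
→ 2 particles; MgCl₂, CaCl₂ → 3; sugars → 1) with no osmotic
coefficients; it is used only for classification, never in the
electrodiffusion math.

## The simulator

`monolayer_model()` describes the latent state as piecewise-exponential
relaxations of β and G per bath epoch,

$$\beta(t) = \beta_\infty + (\beta_{start} - \beta_\infty)\,
e^{-(t-t_0)/\tau},$$

continuous across epochs. This is the minimal monotone model consistent
with a gradual selectivity decline under a standing relative apical
hyposmotic gradient and a prompt (τ ≈ 1 min) recovery when the gradient is
removed; it is a phenomenological stand-in, not a mechanistic water-flux
model, and the preset parameters are documented as illustrative anchors.
The `wt_reversibility` preset solves its epoch parameters so the latent
trajectory passes exactly through the reported selectivity triple
(22.41 → 3.40 → 16.55) and the matching P_Na anchors; the relaxation time
constant (30 min) is a free choice, as the source measurements constrain
only the anchor points.

`simulate_run()` maps (β, G) through the forward GHK relation, adds the
blank filter's series resistance and potential offset, and applies
Gaussian meter noise to sample and blank readings alike. Defaults
(σ_V = 0.2 mV, σ_R = 2 Ω·cm², blank 10 Ω·cm² with a 0.5 mV offset) are
calibration choices of the generator: measurement noise magnitudes for
this protocol are not published, and these values give replicate SEMs of
the same order as typical reported values (±0.1 on β ≈ 3). All randomness
flows through one explicit seed; runs are bit-reproducible and the global
RNG stream is left untouched.

What the simulator does *not* emulate: biological replicate-to-replicate
variation in β₀ and G₀ (only meter noise), drift of the epithelium between
solution replacements, electrode polarisation, or any mechanistic coupling
of water flow to junction structure. Passing recovery tests therefore
demonstrates the correctness and calibration of the *pipeline*, not the
biological model.

### Parameter recovery

Recovered β(t) series can be fitted two ways. `fit_relaxation()` fits the
exponential to the inverted β values; `fit_relaxation_potential()` fits
the same model pushed through the forward GHK relation directly to the
blank-corrected potentials. The latter is the maximum-likelihood estimator
under the simulator's noise model and is markedly better conditioned at
high selectivity, where dV/dβ is small (≈ 0.35 mV per β unit at β = 9
under these baths) and inverting individual noisy potentials both
inflates variance and biases β upward (the inversion is convex in V).
Recovery is validated as an ensemble property: over 20 Monte-Carlo repeats
of 4 replicates at σ_V = 0.2 mV, the mean fitted (β₀, β_∞) must land
within 5% of the generator truth, and the replicate SEM of recovered
β(120 min) must scale as n^(−1/2). A single repeat's β₀ estimate has an
irreducible SD of 2–3% under these conditions, so per-repeat bounds are
tested at noise-level tolerances instead.

## Morphometry

The zigzag index is the pooled ratio L_TJ/L_St — sums over sides, not a
mean of per-side ratios, so long sides weigh more and the result lies
between the per-side extremes. The sampling protocol places five square
815-µm² windows uniformly at random (seeded); a side belongs to a window
iff *both* of its junction vertices fall inside. The alternative readings
(clipping sides at the window border, or including sides with one vertex
inside) are defensible too; whole-side inclusion was chosen because the
index is defined on sides as units and clipping would alter arc/chord
ratios near the border. Fewer than 80 pooled sides triggers a protocol
warning, not an error.

`generate_mesh()` builds the synthetic geometry: a seeded Voronoi
tessellation of uniform cell centres (hand-rolled half-plane clipping;
~150 cells in a 120 × 120 µm field ≈ 96 µm²/cell, a confluent-MDCK-like
density that comfortably exceeds 80 sides in five windows), with each
cell–cell edge replaced by a symmetric triangular wave. The wave uses an
integer number of periods per edge with the period rescaled to divide the
edge length and the amplitude rescaled by the same factor, so *every*
segment of every edge has perpendicular slope exactly 2a/p and the pooled
index equals √(1 + (2a/p)²) by construction (a = p/2 gives √2). An
optional `jag_jitter` scatters per-edge amplitudes to emulate the
side-to-side variability of real traced junctions; it defaults to 0 so
the analytic ground truth holds exactly.

`trace_boundaries()` replaces manual tracing for label masks: boundaries
are followed along the cracks between 4-adjacent pixels of differing
nonzero labels, chains are split at corners where ≥ 3 labels meet (the
junction vertices), and the emitted polylines use crack *midpoints*
(half-pixel coordinates). Pure corner-following would overestimate the
length of diagonal boundaries by up to √2; the midpoint polyline is exact
for 0°, 45° and 90° boundaries and keeps the worst-case length error of
other slopes to a few percent at fine pixel sizes. Background (label 0)
forms no boundaries; a two-label island comes back as a closed loop whose
coincident endpoints are excluded from the index with a warning.

## Statistics

Replicate summaries are mean ± SEM (sample SD, n − 1). Group comparisons
use the unpaired two-sided Student's t-test with pooled variance (Welch
selectable), treating conditions as independent filters; comparisons are
assumed unpaired because nothing in the protocol pairs filters across
conditions. Zero-variance degenerate inputs follow an explicit convention
(equal means → p = 1, unequal → p = 0) instead of erroring. The wrapper's
type-I error under the simulator's null is checked at 1000 repeats in the
acceptance suite. No multiple-testing correction is applied by design.

## Numerical choices

- Round-trip assertions at 1e-9 relative; conservation identities at
  1e-12.
- The GHK inversion rejects, rather than clamps, potentials outside the
  open Nernst interval, and names the violated limit.
- Blank pairing matches nearest time points within ±0.5 min; anchor
  matching for the 5/120-min deltas and recovery metrics uses ±2.5 min
  (the measurement grid of such experiments is coarse and not exactly
  reproducible).
- Non-positive corrected TER flags the record; flagged records propagate
  as NA rather than being dropped, so series lengths are preserved.
- Degenerate Voronoi draws (near-coincident centres) are resampled with a
  warning, up to 10 attempts.
- Log-mean concentration uses the (a + b)/2 limit when |a − b| is below
  1e-12 relative.

## Problem sizes used in the shipped analyses

The `analysis/` drivers simulate 4 replicates per condition on a 5-min
grid over 2 h (27 points for the reversibility protocol), 3–4 mesh
samples per morphometry condition, 20 Monte-Carlo repeats for parameter
recovery, and 1000 repeats for the type-I-error calibration. These sizes
mirror the scale of the underlying experimental design (n = 3–4 filters
per condition) while keeping the whole workflow fast on a laptop.

## Known limitations

- The two-ion model cannot separate transcellular from paracellular
  conductance; in tight (low-G) epithelia the permeability estimates
  conflate both routes, and the knockout preset's low-G regime should be
  interpreted accordingly.
- Liquid-junction-potential physics is not modelled (no Henderson
  equation); electrode drift is treated purely as a blank offset, which
  is exactly what the blank-subtraction protocol can remove.
- The exponential relaxation is descriptive. Fitted τ values have no
  mechanistic interpretation.
- `trace_boundaries()` assumes a clean label mask; it does not segment
  raw fluorescence images.
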