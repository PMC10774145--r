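---
title: "Methods: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(holofield)
```

This vignette is the package's own account of the science it implements:
the linearized neural-field model of L2/3 recurrent dynamics under
holographic ensemble photostimulation, the calcium-imaging analysis that
turns traces into distance- and tuning-resolved influence curves, and the
numerical and design choices made where the problem left them open. It
states no empirical result that the test suite and the worked examples do
not themselves compute.

## The model

We describe L2/3 as two coupled rate fields — excitatory `e` and a single
generic inhibitory population `i` — on a square periodic domain of
1400 × 1400 µm with an additional orientation-preference coordinate
θ ∈ [0°, 180°). Because the experiments are performed on a gray screen, the
network sits at a spatially uniform steady state with low gain, and the
perturbations delivered by photostimulation are weak. Both facts justify
working entirely with the *linearized* steady-state response: the full
nonlinear rate dynamics (gain functions, time constants, external drives)
are absorbed into effective connectivity operators `W = g·j` and never
appear separately. Time-dependent transients are out of scope.

Connectivity is separable in space and feature:

W(x₁,θ₁; x₂,θ₂) = w · g(r; σ, κ) · h(θ₁−θ₂) / z,

with the two-scale spatial kernel

g(r) = (1−κ)/(2πσ_b²)·e^{−r²/(2σ_b²)} + κ/(2πσ_n²)·e^{−r²/(2σ_n²)}

and the like-to-like feature kernel `h(Δθ) = r₀ + r_p·e^{−Δθ²/(2σ_θ²)}` on
the folded difference Δθ ∈ [0°, 90°]. `z` is the discrete normalization
that makes the kernel sum to one over the grid (space weighted by cell
area, orientation levels with unit weight), so each `w` is the *total
gain* of its operator — the convention that makes `w_ee` directly
comparable across grids. Stimulation of an ensemble enters as a point mass
of 10 rate units at each target's nearest grid node and orientation level.

Per 3D Fourier mode (two spatial, one orientation), the two-population
block is 2 × 2 with entries `a = Ŵ_ee`, `b = Ŵ_ei`, `c = Ŵ_ie` (and no
I→I coupling; only the product `b·c = −w_eie·(...)` is identifiable, so
the inhibitory weights are split symmetrically with the sign carried by
`W_ei`). The exact steady state is

Δr̃_e = (a + bc) / (1 − a − bc) · r̃_stim,

and the second-order pathway expansion is

Δr̃_e ≈ (a + a² + bc) · r̃_stim,

whose three terms are exactly the monosynaptic E→E, disynaptic E→E→E and
disynaptic E→I→E routes (`decompose_pathways()`). The expansion is the
default working mode — in the weak-coupling regime the truncation error is
first order in the weights (verified as a test property) — and the exact
resolvent serves as the in-package oracle. Exact mode checks the per-mode
spectral radius and refuses to invert an unstable parameterization,
reporting the offending mode; expansion mode only warns.

### Discretization

* Grid spacing 4 µm (350 × 350 nodes). The narrow spatial scale defaults
  to σ_n = 15 µm, and a spacing above σ_n/3 triggers a warning: the narrow
  Gaussian is the mechanism under study and must be resolved.
* Orientation uses 4 levels {0°, 45°, 90°, 135°}, matching the granularity
  of an 8-direction tuning protocol after folding. All operators are
  circulant in the θ index, so the solve is a single 3D FFT.
* Point stimuli snap to the nearest node with mass `amplitude/spacing²`
  (mass conservation is the invariant the tests assert; coincident targets
  accumulate).

### Parameter conventions and defaults

| Parameter | Default | Units | Meaning |
| --- | --- | --- | --- |
| `w_ee` | 0.45 | – | total recurrent E→E gain |
| `w_eie` | 0.5 | – | disynaptic inhibitory gain `w_ei·w_ie` |
| `sigma_e_broad` | 110 | µm | broad scale of E-outgoing projections |
| `sigma_i_broad` | 90 | µm | broad scale of I-outgoing projections |
| `sigma_e_narrow` | 15 | µm | narrow (sub-50 µm) E scale |
| `kappa_e` | 0.3 | – | weight of the narrow E scale |
| `kappa_i` | 0 | – | I projections have no narrow component |
| `feature_ee` | (0.5, 0.5, 30°) | – | E→E like-to-like rule |
| `feature_ei`, `feature_ie` | (0.1, 0.9, 30°) | – | inhibitory like-to-like rules |
| `stim_amplitude` | 10 | rate | added mass per target |

The broad scales and the E→E feature rule reflect published connectivity
measurements only qualitatively — the quantitative values were never
printed in a reusable form — so these are the package's reference choices,
exposed as configuration, not constants. The narrow-scale parameters and
the inhibitory feature rule are free parameters of the model by
construction (they exist to be fitted against the observed response
structure). Two calibration decisions deserve explanation:

* **Inhibitory like-to-like strength.** The inhibitory feature rule is
  deliberately strong (r₀ = 0.1, r_p = 0.9). With a weak rule the tuned
  and untuned E→I configurations barely differ: the iso-oriented
  suppression share of the E→I→E pathway scales with the θ-autocorrelation
  of `h`, which for a shallow kernel is within ~10% of the untuned value.
  Only a strongly concentrated rule produces the qualitative signature the
  package's tuning-contrast experiment is about — iso-oriented cells
  flipping from net activation (tuned E→E only) to surround suppression
  (full tuned model).
* **Default `w_ee` = 0.45 with κ = 0.3.** At this operating point the
  E→E-only-tuned model keeps iso cells net-activated across the 0–250 µm
  analysis range (the range over which distance curves are computed, set
  by the extent of an 800 µm field of view and by where responses fall to
  noise), while the full tuned model flips iso cells negative beyond
  ~50 µm. For the purely spatial experiments the package instead defaults
  to the *data-regime* parameterization `w_ee = 0.2, κ = 0.2` — the sweep
  point whose point-stimulation profile lands inside the observed
  (crossing, ratio) regime box — mirroring the logic of selecting the
  parameterization that passes through the data regime before asking
  further questions of the model.

A known limitation of this calibration: with inhibition so concentrated on
iso-oriented cells, *ortho*-oriented cells are left net activated near a
tuned ensemble, whereas recordings show them weakly suppressed. A single
inhibitory population cannot simultaneously produce deep iso-surround
suppression and ortho suppression under these kernels; the package asserts
only the iso-cell signs.

### The two Gaussian conventions

The connectivity kernel uses the Gaussian-density convention
`e^{−r²/(2σ²)}`; the center–surround *response* fit uses
`f(d) = A₁e^{−(d/σ₁)²} + A₂e^{−(d/σ₂)²}` with no factor ½. Both are kept
exactly as stated because the published fit parameters (A₁ = 0.196,
σ₁ = 22.1 µm, A₂ = −0.021, σ₂ = 147.3 µm) reproduce the reported ~35 µm
crossing only under the no-½ reading; the crossing is available in closed
form,

d\* = sqrt( ln(A₁/|A₂|) / (1/σ₁² − 1/σ₂²) ) ≈ 33.4 µm,

which rounds to 35 µm at the experiment's 5 µm granularity. (As printed,
the fit function carries *positive* exponents; those diverge, so the
negative-exponent reading is the only sensible one and is what the package
implements.)

## Model experiments

* `sweep_regime()` sweeps `w_ee` × κ (default 12 × 6 grid over
  (0.05–0.6) × (0–0.5)), computes each point-stimulation radial profile,
  and summarizes it by zero crossing and max-activation/max-suppression
  ratio against a supplied regime box. The box used in the tests is
  centered on the reference fit's summary (33.4 µm, ratio ≈ 9.8) with
  ±10 µm and ±30% extents — wide enough to absorb discretization, far
  tighter than the qualitative separation it tests, and fixed before the
  sweeps are run.
* `sweep_spread()` stimulates 10-target ensembles whose mean pairwise
  spread is set exactly (disc-uniform placement, rescaled), and reports
  the mean response 50–150 µm from the nearest target plus per-pathway
  magnitudes. Magnitude is the spatial L2 norm: the L1 mass of a convolved
  field is conserved regardless of target placement, so only a
  concentration-sensitive norm can express how compact ensembles
  super-activate shared inhibitory neurons.
* `tuning_contrast()` compares iso/ortho distance curves between the
  E→E-only-tuned and fully tuned models for a compact cotuned ensemble.

## Trace analysis

ΔF/F follows the standard two-photon pipeline: `F = F_cell − c·F_neu`
(c = 0.7), baseline `F₀` = moving average of the rolling 10th percentile
of a 1,000-frame window (~3 min at 6 Hz), ΔF/F = (F − F₀)/F₀. A cell whose
baseline is not strictly positive is flagged invalid, never clipped. The
rolling percentile is exact at stride 1; the analysis default evaluates it
every 25 frames and interpolates, which is indistinguishable for a
baseline that varies over thousands of frames and cuts the cost 25-fold.
The percentile is taken on a
lightly smoothed copy of the trace (5-frame running mean, `f0_smooth`):
without this the percentile of a noisy trace tracks the noise floor rather
than the baseline and inflates every amplitude by roughly 1.3 noise SDs —
the same reason source-extraction pipelines low-pass before their rolling
baselines. Even so, percentile baselines sit slightly below the true
quiescent level under drift, inflating response amplitudes by a few
percent; ratios and crossings are unaffected.

Per-trial evoked responses average ΔF/F over the stimulation frames plus
one trailing frame, minus the mean of the 3 preceding frames. The trailing
frame captures the indicator's decay tail; the pre-stimulus baseline
subtraction removes slow drift and the residual tail of the previous trial.

Tuning: per-direction means are folded (opposite directions averaged) to 4
orientations; OSI = (PO − OO)/(PO + OO) on rectified folded responses so
the index stays in [0, 1] even with negative ΔF/F; a vanishing denominator
defines OSI = 0. Visual responsiveness is a one-way ANOVA across the 8
directions plus the blank condition (the blank is included because the
response of interest is "different from gray screen", not merely
"different across gratings"). SEM is sample SD/√n with the n−1
denominator; single-observation bins report SEM as missing.

Distance curves use 15 µm bins with edges at 0, 15, 30, …; empty bins are
missing, not zero. Minimal target distance is 3D (plane index × 30 µm
depth), with a 2D option exposed. The registration-shift exclusion
threshold is stored in µm (4.7), not pixels.

Modulation significance: percentile bootstrap (2,000 resamples, seeded) of
each cell's mean across-trial response; a cell is called activated or
suppressed only if its 99% CI excludes zero *and* it survives
Benjamini–Hochberg FDR control at 1% applied to bootstrap two-sided
p-values across cells; fewer than 10 trials yields "neither" with an
insufficient-data flag. On 1,000 null cells the flagged fraction stays
within the binomial envelope of the 1% target (a test asserts ≤ 2%).

## Ensemble design

The optimizer selects ensembles from a candidate pool to minimize a
weighted cost: hinge-squared deviations from the requested spread,
ensemble-OSI and mean-OSI windows (zero inside the window — the window *is*
the goal, so sitting anywhere inside it should be free; penalizing
distance from the window center instead makes the window terms trade off
endlessly against the preference terms and scatters the local optima),
plus pairwise membership-overlap (Jaccard) and reuse penalties across
ensembles, low-power and visual-responsiveness preferences, and a
within-ensemble spacing reward. No two members may sit within 30 µm of
each other in 3D — a hard constraint enforced at every step.

Search: 8 random restarts of best-of-8 single-cell swaps (1,500-iteration
cap, 300-swap stall cutoff), then a deterministic coordinate-descent
polish of the best restarts (every slot against every candidate until no
swap improves). The accepted-cost sequence is monotone non-increasing and
the whole procedure is a pure function of the seed. The polish step is
what makes costs reproducible across seeds: without it, random swap
sequences strand runs in local optima differing by 15–20%.

## The synthetic generator

The generator emulates what the analysis consumes: three 800 × 800 µm
planes 30 µm apart; uniform cell positions; salt-and-pepper orientation
preferences (uniform over {0°, 45°, 90°, 135°}, independent of position);
Beta-distributed OSIs with tuning curves constructed to reproduce each
drawn OSI exactly after folding; opsin, matched, artifact and
visual-responsiveness flags at configurable rates; ensembles placed in
discs sized from the requested spread under the 30 µm rule; trial tables
with running speed, registration shift and per-target success flags drawn
at known rates (so every exclusion rule fires at a predictable frequency);
and F/Fneu trace matrices at 6 Hz.

Ground truth for nontargeted cells is a center–surround profile of minimal
3D target distance, optionally scaled by a relative-tuning weight; cells
inside the off-target zone receive a direct-activation surrogate with a
PPSF-shaped falloff (HWHM 8 µm radial, 18 µm axial) so the off-target
exclusion has real work to do. Evoked transients rise during the 1 s
stimulation and decay with a single-exponential GCaMP6s-like τ = 1.5 s
(rise kinetics are immaterial at 6 Hz because the analysis averages over a
window); the transient is scaled so that the *analysis-window mean* of the
noiseless response equals the specified amplitude — ground truth is
expressed in measured-response units, which is what makes "recover the
parameters within 10%" a well-posed round trip. Noise is additive Gaussian
per frame with SD = `noise_ref/snr` (reference 0.2 ΔF/F, a typical nearby
nontarget response; SNR 5 ⇒ 0.04 ΔF/F per frame); the neuropil channel is
a shared slow background with per-cell contamination.

What the generator does *not* emulate — shot-noise statistics, motion,
segmentation errors beyond a Bernoulli "unmatched" flag, spiking dynamics,
optical aberrations — bounds what passing tests show: they validate the
analysis logic and its statistical calibration, not robustness to every
imaging pathology.

Problem sizes: the end-to-end recovery test runs the full default
configuration (1,500 cells, 20 ensembles × 15 trials, ~9,000 frames,
SNR 5, plus a noiseless repeat), chosen as the smallest run in which all
four profile parameters are comfortably identifiable; module tests use
300-cell populations and 160 µm toy domains where the property under test
does not need scale.

## File formats

Datasets round-trip as plain CSV tables (`write_dataset()` /
`read_dataset()`): cells, ensembles, targets, trials, responses. Trace
matrices live in memory as plain R matrices; at the synthetic scales used
here a binary container buys nothing.
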