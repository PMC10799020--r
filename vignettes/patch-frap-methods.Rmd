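---
title: "Patch/FRAP analysis: model, simulator, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch/FRAP analysis: model, simulator, and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchfrap)
```

## The assay and its observables

Spot FRAP measures the lateral mobility of a fluorescently labelled membrane
receptor: a brief high-power pulse of a Gaussian-profile laser beam bleaches
the fluorophores inside a small spot, and the subsequent refill of
fluorescence by unbleached molecules is followed at low (monitoring) power
through the same spot. Fitting the recovery yields two parameters per cell:

* `D` — the lateral diffusion coefficient (µm²/s), setting the recovery
  *rate* through the characteristic time `tau_D = w^2 / (4 D)` for a spot of
  e⁻² radius `w`;
* `R_f` — the mobile fraction, setting the recovery *extent*: the fraction
  of labelled molecules free to diffuse on the measurement timescale.
  Transmembrane receptors typically show `R_f` of 60–70%, the remainder
  being transiently anchored to the cytoskeleton, matrix, or endocytic
  structures.

Patch/FRAP turns this into a pairwise interaction assay. One receptor is
clustered and laterally immobilized with bivalent IgG; a co-expressed
partner, labelled only with monovalent (non-crosslinking) Fab' fragments, is
then measured by FRAP. Complexes between the two receptors show up in the
partner's mobility, and the *lifetime* of the complex relative to the FRAP
timescale decides the signature:

* complexes outliving the measurement co-immobilize the labelled receptor:
  `R_f` drops, `D` is unchanged (**stable**);
* complexes turning over many times during the measurement let the receptor
  keep moving, but slower on average: `D` drops, `R_f` is unchanged
  (**transient**).

For stable complexes, the fraction of the labelled receptor bound to the
immobilized partner is the relative reduction of the mobile fraction,

\[
C = 100 \cdot \frac{R_{f,\mathrm{free}} - R_{f,\mathrm{CL}}}{R_{f,\mathrm{free}}} \;[\%],
\]

implemented in `complex_fraction()`. The statistic is scale invariant, so
group means may be entered as fractions or percentages.

## Forward model

For a Gaussian bleach-and-monitor profile `I(r) ∝ exp(-2 r^2 / w^2)` and a
brief bleach pulse of dimensionless depth `K`, the post-bleach concentration
profile of unbleached fluorophore is `c(r, 0) = exp[-K exp(-2 r^2 / w^2)]`.
For pure 2-D lateral diffusion the fractional fluorescence observed through
the same spot admits the series solution

\[
f(t) = \sum_{n=0}^{\infty} \frac{(-K)^n}{n!}\,
       \bigl[1 + n\,(1 + 2t/\tau_D)\bigr]^{-1},
\]

normalized so the pre-bleach level is 1. Its anchor points are exact:
`f(0) = (1 - e^{-K})/K` (the bleach-depth relation, by which `K = 3`
corresponds to ~68% bleach, inside the usual 60–75% operating range) and
`f(t) → 1` as `t → ∞`. Time enters only through `t/τ_D`.

An immobile subpopulation is pure bookkeeping: with mobile fraction `R_f`,

\[
F(t) = F_{pre}\left[(1 - R_f)\, f(0) + R_f\, f(t)\right],
\]

so `F(0)` is independent of `R_f` (both subpopulations bleach alike) and the
normalized recovery `(F_\infty - F(0))/(F_{pre} - F(0))` equals `R_f`
exactly.

Numerical choices: the alternating series is accumulated until the next
term's magnitude falls below `1e-9`, with a hard cap of 200 terms; reaching
the cap raises an error rather than returning a partial sum (relevant only
for unphysical `K` far above the detector-linearity limit). `D = 0` is
admitted via `tau_D = Inf`, giving the flat fully-immobile curve. The test
suite checks the series against an independent finite-difference integration
of the axisymmetric diffusion equation from the same post-bleach profile
(max-abs error below 5×10⁻³ over `t ∈ [0, 20 τ_D]` for `K ∈ {1, 3, 6}`;
observed agreement is ~3×10⁻⁵).

Modelling assumptions worth keeping in mind: a single Gaussian beam used for
both bleach and monitoring (the hardware uses one beam at two powers);
monitoring-induced bleaching neglected (the power ratio is ~5000×); no flow,
no anomalous diffusion, no 3-D exchange with the cytoplasm. Units are fixed
to µm, s, µm²/s throughout; the conventional display unit 10⁻² µm²/s is a
presentation choice.

## Synthetic data

`simulate_frap_curve()` draws a noiseless backbone from the forward model —
pre-bleach baseline, bleach event at `t = 0`, recovery on the acquisition
grid — and adds detector noise. The default noise model is signal-scaled
Gaussian with SD `sigma0 * sqrt(F)`, the Gaussian limit of photon shot
noise; a constant-SD variant covers read-noise-dominated detectors. The
default `sigma0 = 0.02` gives residuals of a few percent of the baseline,
matching what routine confocal FRAP traces look like. Protocols implying
bleach depths of 95% or more are rejected (outside detector linearity).

`simulate_frap_cohort()` generates per-condition cohorts from a design
table. Cell-to-cell variability is modelled by jittering the condition-level
ground truth per cell: lognormal on `D` (mean preserved) and logit-normal on
`R_f`, both at a stated coefficient of variation, default 15% — the spread
typical of per-cell mobility measurements in live-cell work. The logit scale
keeps `R_f` in (0, 1); the CV is mapped onto the logit SD by the delta
method, and the logit location is recentred numerically so condition-level
means equal the design targets (the naive location `qlogis(p)` would pull
means toward 0.5 by several points at CV 15%). Default cohorts use about 30
cells per condition, matching common practice of at least ~27 independent
cells per condition. Per-cell seeds are drawn from a stream scrambled by the
base seed, so cohorts are bit-reproducible and different base seeds share no
cell-level randomness (a plain `seed + cell index` rule would make nearby
base seeds reuse almost all of each other's per-cell draws).

### The binding simulator

`simulate_binding_frap()` generates patch/FRAP curves from first principles
instead of from the fitted-form model: `n_particles` receptors diffuse in a
periodic square box and exchange between a free state (2-D Brownian motion
at `D_free`) and a trap-bound state (immobile, modelling IgG-crosslinked
patches) with pseudo-first-order rates `k_on`, `k_off`. The bleach pulse
marks each particle bleached with probability
`1 − exp[−K exp(−2 r² / w²)]` at its position, and the recorded fluorescence
is the Gaussian-weighted sum of unbleached particles — the particle-level
transcription of the forward model's optics.

The underlying process is a discrete-time chain with step `dt`, validated to
resolve both the kinetics (`(k_on + k_off)·dt < 0.1`) and diffusion relative
to the box (`4 D dt < (box/100)²`). The implementation samples this chain
exactly but event-wise: state flips are drawn from the equivalent geometric
waiting-time distributions, and because bound particles are frozen and
positions are only read out at the recording times, the accumulated free
flight between readouts is drawn as a single Gaussian displacement with
variance `2 D dt × (steps spent free)`. The distribution of the recorded
trajectory is identical to the explicit per-step loop at a small fraction of
the cost, which is what makes regime sweeps with 10⁵ particles practical.
Random numbers come from an internal xoshiro256++ stream seeded from R's
RNG, so `set.seed()` still governs reproducibility. Before the bleach the
simulator both initializes states at the stationary bound fraction
`k_on/(k_on + k_off)` and runs an equilibration of at least
`5/(k_on + k_off)` of simulated time (capped, with a warning, at 10⁴ steps —
harmless given the stationary initialization).

The dimensionless product `k_off · tau_D` controls the regime. Sweeping it
at a fixed bound fraction moves the fitted signature continuously from
(ΔR_f < 0, ΔD ≈ 0) to (ΔR_f ≈ 0, ΔD < 0); in the fast-exchange limit the
fitted `D` approaches the reaction–diffusion prediction
`D_free · k_off/(k_on + k_off)`. The simulator does not hard-code any
boundary between "stable" and "transient" — that classification is the
inference layer's job.

What the simulator does *not* emulate: fluorophore blinking or reversible
dark states, 3-D geometry, crowding, or trap saturation (traps are a
pseudo-first-order field, not discrete saturable sites). Consequently,
passing tests demonstrate the internal consistency of the
model–simulator–fitter–classifier chain under these idealizations, not the
behaviour of any particular receptor in cells.

## Fitting

`fit_frap()` normalizes a curve to its mean pre-bleach level (making
estimates gain-invariant) and extracts `(R_f, D)` by bounded
Levenberg–Marquardt least squares against the forward model. Unweighted
least squares on the normalized data is the default loss — weighting is an
extension point, not a default, since the noise model of real detectors is
rarely known.

Choices that needed making:

* **Bleach parameter.** When `K` is not supplied it is estimated per curve
  from the observed bleach depth by inverting `(1 − e^{-K})/K = F(0)/F_pre`
  (monotone; bisection), reducing the regression to the two parameters of
  interest. Because the first post-bleach sample sits at `t₁ > 0` where
  recovery has already begun, the estimate is refined by re-solving `K` so
  the fitted model reproduces that sample at its actual time, alternating
  with refits (2–3 rounds suffice; on noiseless curves the procedure
  recovers the generating parameters to better than four significant
  figures). The `K` source (supplied vs estimated) is recorded in the
  output.
* **Initialization.** `D` starts from the empirical half-recovery time via
  `D₀ = w² · u₁ᵤ₂(K) / (4 t₁ᵤ₂)`, where the K-dependent factor `u₁ᵤ₂` is
  obtained by numerically inverting the forward model; `R_f` starts from the
  observed recovery percentage. On failure the fit restarts from three
  perturbed initializations before being flagged non-converged — flagged,
  never fabricated.
* **Quality control.** The recovery percentage uses the mean of the last 5%
  of post-bleach samples as the endpoint (robust to terminal noise). Curves
  recovering less than 20% constrain `D` too weakly: `d_reliable` is set
  `FALSE`, the `R_f` estimate is kept, and `compare_groups(..., "D")`
  excludes such cells — which is why D group sizes can be smaller than R_f
  group sizes.
* **Bound behaviour.** An optimizer terminating with `R_f` pinned at 1 is
  accepted (fully mobile species). Pinned at 0, it is accepted only when
  the recovery percentage is below 5 — a genuinely immobile curve, as for a
  directly crosslinked receptor — and otherwise flagged non-converged, to
  distinguish immobility from fit failure.
* **Uncertainties.** Standard errors come from the local curvature of the
  loss at the optimum and are reported as `NA` when the curvature matrix is
  singular.

## Inference

`compare_groups()` follows the reporting conventions of quantitative FRAP
studies: for more than two groups, a one-way ANOVA omnibus test followed by
all-pairs pooled-SD t contrasts with Bonferroni adjustment; for exactly two
groups, a Welch t test; summaries as mean ± SEM with per-group n.
Significance tiers map to the conventional star notation (0.05, 0.01, 10⁻³,
10⁻⁴). Degenerate zero-variance groups (possible with pinned fits on clean
synthetic data) are handled explicitly rather than erroring.

`classify_interaction()` applies the decision table to the crosslinked-vs-
free contrast of per-cell estimates: R_f significantly lower and D not —
**stable**; D significantly lower and R_f not — **transient**; both —
**mixed** (a case the underlying interpretive rule never needed; forcing it
into either class would discard information); neither — **none**. "No
effect" is operationalized as adjusted `p ≥ alpha`; a formal equivalence
test would be stronger but is out of scope. The complex fraction is computed
from the *group-mean* mobile fractions (cells differ between arms, so no
pairing exists); for transient calls the analogous statistic on mean `D`
estimates the bound fraction via the fast-exchange limit. An optional
bootstrap over cells provides a percentile CI on the complex fraction.
`ligand_effect()` runs the same two-group machinery for ± ligand contrasts
(e.g. VEGF-A), labelled as such.

## Problem sizes and calibration of the shipped tests

The test suite exercises the chain at chosen, fixed problem sizes: 200
noisy curves for parameter recovery (median relative error of `D` under
10%, median absolute error of `R_f` under 0.03 at `sigma0 = 0.02`); 1000
replicate null cohorts for the family-wise error of the Bonferroni
procedure; 200 replicates for power at the published effect size (0.64 vs
0.39, n = 30/group, CV 15%); and a 10-replicate regime sweep of the binding
simulator at bound fraction 0.4 with `k_off · tau_D` at 10⁻² and 10². For
the sweep, each replicate compares 6–8 simulated cells per arm at 1.2×10⁵
particles in a 16 µm box over a 30 s acquisition — chosen so that per-curve
Monte Carlo noise in the fitted `D` is comparable to the per-cell scatter of
real measurements. That matters beyond runtime: at the stable-regime
boundary (`k_off · tau_D = 10⁻²`, i.e. bound lifetimes of ~100 `tau_D`), a
small fraction of bound receptors releases *within* the acquisition window,
so an arbitrarily precise D contrast would eventually detect this genuine
leak and tip the p-below-alpha rule from "stable" to "mixed". The
classification rule is calibrated to experimental, not asymptotic,
precision — an inherent property of operationalizing "no effect" as a
failed significance test.

## Known limitations

* The forward model assumes an infinite membrane reservoir; the simulator's
  periodic box approximates it (box ≥ 10 spot radii), leaving a small
  depletion of the unbleached pool that shows up as a plateau slightly
  below the pre-bleach level.
* Single mobile population only: no two-component fits, no anomalous
  diffusion, no global multi-curve fitting.
* `K` estimation from the bleach depth assumes the acquisition's first
  post-bleach sample is early relative to `tau_D`; protocols that start
  sampling late should supply `K` explicitly.
* The complex fraction inherits the assay's identification limits: it is
  blind to complexes shorter-lived than the FRAP time (those move into the
  `D` signature) and to complexes with partners that are themselves mobile.
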