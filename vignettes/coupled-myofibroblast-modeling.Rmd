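---
title: "Methods: coupled myocyte-myofibroblast electrophysiology and optical-map analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled myocyte-myofibroblast electrophysiology and optical-map analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofib)
```

# The scientific question

After a myocardial infarction, activated cardiac fibroblasts
(myofibroblasts) populate the scar and the infarct border zone. A fraction
of them, especially in aged hearts, becomes senescent: proliferation-
arrested and, importantly for electrophysiology, much larger. When such
cells couple to surviving myocytes through connexin-43 gap junctions they
act as a passive electrical load. This package implements a computational
model of that interaction: a rabbit ventricular myocyte (the Mahajan 2008
ionic model) coupled through ohmic gap junctions to one or more passive
myofibroblasts, together with the supporting measurement pipeline — fitting
Boltzmann current-voltage curves to fibroblast voltage-clamp data,
extrapolating whole-cell capacitance from cell volumetry, pacing and S1S2
premature-stimulus protocols, and the analysis of fluorescence
voltage-mapping movies.

The central quantities are the action potential duration (APD90), the
L-type Ca current `I_CaL` and the gap-junctional current `I_gap` in two
conditions: *young* border-zone tissue (one myocyte + four proliferating,
18 pF fibroblasts) and *aged* tissue (one myocyte + one senescent 35 pF +
four proliferating fibroblasts), both with sodium conductance halved to
represent border-zone remodeling.

# The myocyte model

The ventricular cell is the Mahajan 2008 rabbit action potential model: a
26-variable system with Luo-Rudy-type sodium kinetics, a seven-state
Markov L-type Ca channel with Ca-dependent inactivation driven by a
dyadic-junction Ca pool, rapid and slow delayed rectifiers, fast and slow
transient outward currents, the inward rectifier, Na/Ca exchange, the
Na/K pump, and a phenomenological SR Ca cycling system. The equations
were transcribed from the published formulation; no machine-readable
encoding was available in this environment, so the transcription was
validated behaviorally:

* the published initial conditions are a quiescent operating point (the
  net membrane current balances to < 0.01 pA/pF and the membrane
  potential drifts < 1 mV over 10 s unstimulated);
* pacing at a 350 ms cycle length returns the state to those initial
  conditions (SR load 103 vs 104.5 uM, intracellular Na 11.58 vs
  11.44 mM), i.e. they are recovered as the model's own paced steady
  state;
* the action potential has the published morphology (peak ~ +39 mV,
  maximum upstroke velocity ~ 300 V/s, phase-1 notch, dome near +15 mV,
  APD90 ~ 188 ms at a 400 ms cycle length), and the voltage-clamp peak
  `I_CaL` is ~ -7.3 pA/pF near +10 mV, in the measured rabbit range.

One transcription ambiguity deserves record: the conversion between the
L-type channel's Ca flux and its membrane current. We resolved it by
requiring charge consistency — `I_CaL = 2 * wca * J_CaL`, i.e. valence 2
times the model's own flux-to-current constant (`wca = 8.0313` pA/pF per
uM/ms) times the GHK-shaped flux. The alternative (a unit conversion
inconsistent with the flux bookkeeping) produces a dome-less action
potential with APD90 ~ 80 ms, clearly not the published model.

A note on the resting state: the model's true quiescent equilibrium
involves very slow Na and SR redistribution (minutes of model time) and
lies away from the physiological operating point. The package therefore
treats the published paced-steady-state initial conditions as the
reference state, and tests quiescence as bounded drift rather than as an
exact fixed point.

## Units

Membrane currents are pA/pF (equivalently uA/uF), time is ms, voltage is
mV, Ca concentrations are uM (Na in mM), conductances mS/uF. Gap currents
are computed in pA (nS x mV) and divided by the myocyte capacitance
`Cm_myo` only at the coupling boundary and for reporting.

## The myocyte capacitance

`Cm_myo` enters only the conversion between absolute gap currents (pA)
and densities (pA/pF). No reference value is reported for it; we default to
180 pF. Two candidate conventions bracket it: a generic 100 pF textbook
myocyte, and the 310 pF cell implied by the Mahajan model's internal
flux-conversion constant. Neither is compatible with the reported
current densities: with 20 nS connections the reported gap-current
densities (7.4 and 8.1 pA/pF) and Ca-current ordering are jointly
consistent only with a normalization near 170-180 pF, which is also the
measured range for adult rabbit ventricular myocytes. We therefore adopt
180 pF as the default and expose the parameter in the configuration, since
every reported density scales with it.

# The fibroblast model

Myofibroblasts are modeled as passive, memoryless membranes:

```
I_f(V) = g_scale * 140 mV * B(V),
B(V) = A / (1 + exp((V_half - V)/k)) + C  (shifted so B(E_rev) = 0)
```

`B` is the normalized Boltzmann fit of the whole-cell I-V relation; the
140 mV factor is the span of the clamp protocol (-100 to +40 mV), so
`g_scale` in nS is the conductance of the linear resistor that would
carry the same current across the protocol span at unit amplitude. The
reversal shift is a horizontal translation when the unshifted sigmoid
attains zero, and a vertical offset otherwise; the mode used is recorded
in the object.

Defaults (shipped as a versioned configuration in
`inst/extdata/fibroblast_defaults.yaml`):

* **I-V shape**: fitted by the package's own pipeline (tail-referenced
  extraction, normalized Boltzmann fit) from the synthetic clamp
  generator's default myofibroblast-like curve (outwardly rectifying,
  half-activation -20 mV, slope 12 mV).
* **E_rev = -50 mV**: a typical cardiac fibroblast resting potential;
  resting potentials were measured with sharp electrodes in the source
  experiments but no value is reported.
* **g_scale (gPro = gSen) = 0.25 nS**: no fitted amplitudes are
  reported, but the reference results identify the operating regime — APD90
  decreases only slightly with fibroblast conductance and increases
  strongly with capacitance, and all young/aged differences are driven by
  capacitance. Conductance scales of 0.5 nS and above put the coupled
  model in a drain-dominated regime in which adding the senescent
  fibroblast *shortens* the APD, contradicting that description; 0.25 nS
  (a tissue-size fibroblast carrying ~ 2 pA/pF at +40 mV) reproduces it.
  The two phenotypes share the curve because the measured difference in
  peak current was not significant.
* **Capacitance**: 18 pF (proliferating) and 35 pF (senescent), the
  tissue-extrapolated values (below).

# Capacitance extrapolation

In-vitro whole-cell capacitances (128.7 pF proliferating, 138.4 pF
senescent) are scaled to tissue values by the tissue/culture surface-area
ratio of proliferating cells, assuming spherical cells
(`A = (36 pi)^(1/3) V^(2/3)`), and the senescent tissue value is the
proliferating one times the senescent/proliferating area ratio in tissue
(1.95). Rounding to whole pF happens only at the reporting layer
(`capacitance_report()`), yielding 18 and 35 pF. The extrapolation is
scale-equivariant (a global volume rescaling cancels), which the tests
assert.

# Coupling and integration

Each fibroblast connects only to the myocyte (star topology) with an
ohmic gap junction, 20 nS per connection by default (interpreted
per-connection; a total-conductance convention can be emulated by
dividing). The coupled system is

```
dVm/dt = -I_ion - sum_i g_gap (Vm - Vf_i) / Cm_myo + I_stim
Cm_CF,i dVf_i/dt = -I_f(Vf_i) + g_gap (Vm - Vf_i)
```

integrated by forward Euler with an adaptive step
`dt = clamp(theta / max|dV/dt|, 0.05 us, 5 us)` over all cells, with
`theta = 0.1 mV` by default. The controller is validated against a fixed
0.05 us reference run: APD90, peak |I_CaL| and peak gap-current density
agree within 0.2% (the acceptance tests require 1%). Halving `theta`
exhibits the expected first-order convergence. Fibroblasts start at
`E_rev`, the unstimulated fixed point of the passive membrane. Traces are
recorded on a uniform 0.1 ms grid.

Stimuli are rectangular, 1 ms, with amplitude 1.5x the diastolic
threshold found by bisection at the chosen cycle length (no in-silico stimulus
parameters are reported; the patch-clamp experiments used
threshold-relative stimulation).

# Protocols

**APD measurement.** APD is the time from the maximum upstroke slope to
50% or 90% repolarization referenced to the peak-minus-diastolic
amplitude, with linear interpolation at the crossing. A beat with maximum
slope below 10 V/s is a no-AP result (distinct from an error); a window
that ends before the level crossing yields a right-censored flag.

**Conditions.** `make_condition("young")` and `make_condition("aged")`
build the two border-zone configurations (gNa at 50%; gK1 at 100% for
trace simulations and 73% for the S1S2 analysis, both configurable; the
gK1 reduction is an experimentally observed border-zone remodeling
applied here only to the conduction-failure analysis). Pacing runs at a 350 ms cycle length (mirroring the ex vivo
optical mapping) to beat-to-beat APD90 convergence (< 0.5 ms change),
with a 25-beat budget; persistent period-2 alternation is flagged as
alternans and the final beat reported. At the default settings the young
condition shows ~ 1.8 ms APD alternans (a known behavior of this myocyte
model under load at short cycle lengths); the aged condition converges.

**S1S2.** Eight conditioning beats at 350 ms are followed by a single
premature stimulus; the S2 coupling interval is scanned downward and the
success/failure boundary refined by bisection to 1 ms. Success requires a
regenerative response within 50 ms of S2: peak Vm > 0 mV and maximum
dV/dt > 10 V/s. The returned onset is the largest failing interval, with
the confirming bracket attached. Conditioning is simulated once and
reused across candidate intervals, which keeps a full map cell at a few
seconds.

**Sweeps.** `sweep_apd_map()` (conductance x capacitance) and
`sweep_failure_map()` (gNa or gK1 scaling x capacitance) iterate the
protocols over grids; individual cell failures are recorded with their
reason without aborting the sweep. The package's reduced default grids
(6 x 6 for APD, 4 x 4 for failure onset) reproduce the reported trends:
APD90 non-decreasing in capacitance along every row and non-increasing in
conductance along every column; failure-onset cycle length increasing
with capacitance, decreasing with gNa and gK1, with the gK1 axis steeper
per normalized parameter step; and aged onset above young at 73% gK1.

# Optical-map analysis

Movies are frames x rows x cols fluorescence arrays with a frame interval
(1 ms default in the generator, the standard 1 kHz acquisition rate) and
a 200 um pixel pitch. The stages:

* **Temporal polynomial filter**: local least-squares cubic over a
  13-sample window (Savitzky-Golay with the stated order and length); it
  reproduces cubics exactly, including at the edges.
* **Activation**: time of maximum first derivative (central differences,
  parabolic sub-sample refinement), with a noise-floor gate; flat series
  give a no-activation marker and constant-slope ramps are flagged
  degenerate with the tie broken to the earliest sample.
* **Repolarization**: time of maximum second derivative after the AP
  peak. The second derivative is estimated from a local cubic fit
  spanning ~ 25 ms, and the search is confined to the repolarization
  limb — from the 50%-amplitude crossing until shortly after the signal
  first returns near baseline. The gating matters: filter ringing at the
  upstroke and baseline noise otherwise dominate the curvature maximum.
* **APD map**: repolarization minus activation per pixel, averaged over
  beats; failures become NA and masked pixels propagate (mask-closure is
  tested).
* **Conduction velocity**: least-squares plane fit of activation time
  over a centered 11 x 11 pixel window; speed = pitch / |gradient|,
  reported in m/s; pixels with < 60% valid neighbors or a vanishing
  gradient (simultaneous activation) are NA. Speeds are isotropic (90
  degree rotation changes speeds < 1%) and scale exactly with pitch.
* **Dominant frequency**: per-pixel segment-averaged periodogram (Hann
  window, 50% overlap, mean removed), peak within 5-40 Hz; a peak that
  does not stand five-fold above the median band power is flagged
  low-confidence (white-noise pixels are rejected by this rule). The
  study does not state its estimator; this conventional, deterministic
  choice is validated against the generator. Since the environment
  provides no Welch routine, the averaged periodogram is implemented
  directly on top of the FFT.

# Synthetic data generators

Every pipeline input can be generated with known ground truth; all
generators are pure functions of their specification and seed, and the
ground truth travels with the dataset (consumed only by tests).

* **Clamp traces** emulate the fibroblast protocol (holding -60 mV, 3 s
  steps from -100 to +40 mV): steady Boltzmann current plus capacitive
  transients (RC decay from the spec's access resistance and capacitance),
  optional linear leak, and Gaussian noise. The attached truth includes
  both the underlying curve and the amplitudes an ideal tail-referenced
  extraction would report.
* **Volume samples** are lognormal per group; the defaults reproduce the
  study conditions (tissue senescent/proliferating area ratio 1.95; the
  culture/tissue volume ratio that maps the measured 128.7 pF to the
  reported 18 pF). A target area ratio can be imposed exactly in
  expectation.
* **Wave movies** contain a planar wavefront of stylized APs translating
  at a set velocity and angle. The waveform is a sigmoid upstroke (max
  slope at the activation time), a plateau and a *linear* phase-3 ramp
  reaching baseline exactly at the nominal APD. The slope corner at
  baseline arrival is the curvature maximum, and because a corner's
  curvature spreads symmetrically under any symmetric smoothing kernel,
  the detector's target is unbiased under the analysis filters — making
  the recovery test a genuine end-to-end check rather than a calibration.
  In VF mode each pixel oscillates at a prescribed frequency field
  (periodic APs or a pure sinusoid). A wave crossing the grid in under
  one frame is rejected as temporally unresolvable.

The generators emulate geometry, kinetics and noise, not photophysics:
no bleaching, motion, dual-dye ratiometry or spatial blur. Passing
recovery tests therefore demonstrate correctness of the estimators on
well-posed inputs, not robustness to every artifact of real recordings.

# Problem sizes and runtime choices

The package's default analysis sizes are chosen for a desktop run: APD
sweeps on 6 x 6 grids (~ 15 beats per cell), failure-onset maps on 4 x 4
grids (eight conditioning beats, ~ 10 bisection evaluations per cell),
movies of 32-40 pixels square and 3 beats at 1 kHz. The full test suite
runs in ~ 2 minutes; the end-to-end driver (`reproduce_paper()`) in
~ 1 minute at its reduced defaults. All grids and movie sizes are
arguments, so larger reproductions only cost time.

# Known limitations

* The myocyte model is a transcription validated behaviorally, not
  against the original source code; residual constant-level differences
  cannot be fully excluded, though the paced steady state reproduces the
  published initial conditions closely.
* The fibroblast conductance scale and the myocyte normalization
  capacitance are inferred from the reported results (the original fits
  are unpublished); the young-condition peak gap-current density lands
  ~ 14% below the printed value at these defaults, a structural mismatch
  documented in the tests, because the model's senescent/proliferating
  peak-density ratio (~ 1.25) exceeds the printed pair's ratio (1.09).
* Single cells only: no tissue-level propagation, no fibroblast-
  fibroblast coupling, no stochastic channel gating.
* The quiescent fixed point is treated as an operating point (see above),
  not solved to machine precision.
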