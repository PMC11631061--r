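---
title: "Modelling and measuring the haemodynamics of accelerated atrial pacing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring the haemodynamics of accelerated atrial pacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrialpace)
```

# The question the package addresses

In heart failure with preserved ejection fraction (HFpEF), symptoms are
driven largely by an elevated left-heart filling pressure, summarised
clinically by the mean left atrial pressure (mLAP). Accelerated atrial
pacing — pacing the atrium faster than the intrinsic sinus rate — shortens
diastole and reduces per-beat filling, which in a stiff ventricle can
*lower* filling pressure while a homeostatically regulated circulation
holds cardiac output and arterial pressure constant. But pacing faster
also prolongs atrioventricular (AV) nodal conduction (the PR interval),
and a long PR pushes atrial contraction into early diastole, against a
closed or closing mitral valve — the cannon A-wave — which raises mLAP
again. The net effect is a U-shaped relationship between pacing rate and
mLAP whose optimum depends on AV coupling and atrial contractile function.

`atrialpace` implements both halves of the investigation:

1. a closed-loop lumped-parameter model of the heart and circulation with
   imposed pacing timing, a homeostatic pressure-flow regulation module,
   and an in-silico pacing trial sweeping rate and PR;
2. a clinical-style signal pipeline (ECG + LA pressure + coronary-sinus
   electrogram at 1 kHz) for the alternating 30-s sinus/paced protocol,
   validated end to end against a synthetic recording generator with
   exact ground truth.

# The circulation model

## Chambers

Each of the four chambers follows an activation-weighted linear-active /
exponential-passive pressure-volume law

$$p(V, a) = a\,c\,E_{act}\,(V - V_0) +
  P_{ref}\left(e^{k\,(V/V_0 - 1)} - 1\right) + p_{peri},$$

with activation $a(t)$ rising as $\sin^2$ to a single maximum of 1 over
the activation duration $d_{act}$ and then relaxing exponentially with
time constant $\tau$. Atrial activation onset defines time zero of the
cycle; ventricular onset lies the programmed PR interval later, and both
wrap modulo the cycle length (necessary at 140 bpm with PR 300 ms, where
PR exceeds diastole). Activation durations shorten with
$\sqrt{\text{cycle length}}$, mimicking the rate dependence of systole.
This chamber law deliberately replaces full one-fiber wall mechanics: it
retains every lever the study phenotype needs — relaxation time, passive
stiffness, wall mass, contractility — at a fraction of the cost, and no
value-level equality with the original wall-mechanics model is claimed.

The pericardium contributes a shared power-law pressure
$p_{peri} = P_{ref,peri}\,(V_{heart}/V_{0,peri})^{k_{peri}}$ on the total
heart volume, added to all four chambers (on by default).

## Valves and vessels

Valves are ideal diodes (no regurgitant leak); the mitral valve carries an
inertance so that early (E) and atrial (A) filling waves separate — the
E/A ratio is a calibration target, and without inertance the waves merge.
Systemic and pulmonary arteries and veins are linear windkessel
compartments; venous-return resistances are bidirectional so retrograde
pressure waves (cannon A-waves) transmit into the veins.

## Integration

The state (8 compartment volumes + mitral flow) is integrated by a
fixed-step RK4 scheme in compiled code, step 0.1 ms, output on a 1-ms
grid. Because every flow enters one compartment's derivative with `+` and
another's with `-`, the sum of volumes is an exact invariant of the
scheme; total blood volume is conserved to round-off (tested at 1e-6
relative over 50 beats). A fixed-step explicit scheme was chosen over an
adaptive stiff solver because the chosen resistances keep the fastest
time constant near 1 ms (well resolved at 0.1 ms), exact conservation
falls out of the antisymmetric flow structure, and the speed makes the
full regulated 9 × 31 pacing grid cheap. Steady state is declared when
consecutive beat-onset states differ by less than 0.1% (cap 200 beats).

Two diagnostic modes support closed-form verification: activation can be
frozen at a constant and all valves locked open, in which case the loop
must relax to the static equilibrium of an RC network — a single common
pressure determined by volume conservation, computed independently in
`static_equilibrium()` by inverting each compartment's volume-pressure
relation. The dynamic model matches it to better than 0.5% (in practice,
~1e-11).

## Homeostatic pressure-flow regulation

Between beats the regulation module adjusts systemic resistance and total
blood volume multiplicatively until beat-averaged systemic flow and mean
arterial pressure sit at 5.0 L/min and 92 mmHg (both within 0.5%, three
consecutive beats). The resistance update divides by the relative
deviation of the measured pressure-to-flow ratio from its target — the
measured MAP/CO *is* (up to units) the effective systemic resistance, so
multiplying by the deviation would amplify it; dividing is contractive.
The volume gain (0.08) is deliberately smaller than the resistance gain
(0.3): mean arterial pressure is roughly four times more log-sensitive to
circulating volume than volume itself (only the stressed fraction makes
pressure), and symmetric gains produce an under-damped limit cycle.
Measurements use three-beat windows so the venous and arterial relaxation
times (~1.8 s) are respected. Both updates are exactly the identity at
the set-points. Regulation is re-converged independently at every grid
cell, warm-started from the intrinsic reference solution, so grid cells
are order-independent and deterministic.

## The HFpEF phenotype and its calibration

The virtual patient is produced from a normal heart by four scalers: LV
passive stiffness (`lv_passive_stiffness_scale`, on $P_{ref}$), LV active
relaxation (`lv_relaxation_tau_scale`, on $\tau$), LV wall mass
(`lv_mass_scale`, jointly on $E_{act}$ and $P_{ref}$), and the LA
unstressed volume. Atrial myopathy reduces the atrial contractility scale
to 0.5. `calibrate_phenotype()` tunes the four levers by Nelder-Mead on
log-transformed parameters (positivity enforced by the transform, no
explicit bounds needed) to minimise the summed squared relative error on
three baseline targets at 54 bpm under regulation: mLAP 15.0 mmHg,
maximal LA volume 108 mL, E/A 1.1. The calibrated values shipped as
defaults are

| parameter | value |
|---|---|
| `lv_passive_stiffness_scale` | 3.2269 |
| `lv_relaxation_tau_scale` | 1.9468 |
| `lv_mass_scale` | 1.0762 |
| `la_v0` (mL) | 47.498 |

which reproduce all three targets to well inside their tolerances while
cardiac output and arterial pressure are pinned by regulation. Quantities
*not* calibrated land in plausible HFpEF territory (LVEDP ≈ 24 mmHg,
LVEDV ≈ 144 mL, SV ≈ 93 mL at 54 bpm).

## The in-silico trial and its conventions

`run_grid()` sweeps 60–140 bpm in 10-bpm steps × PR 0–300 ms in 10-ms
steps (279 regulated steady states) and reports each cell's beat metrics
plus ΔmLAP against the intrinsic reference (54 bpm). Per-rate optimal PR
uses grid resolution with ties broken toward the shorter PR. The
decremental-conduction trajectory reads the grid along a monotone
piecewise-linear PR(rate) law anchored at (55 bpm, 153 ms) and (100 bpm,
228 ms) — printed cohort values — interpolating mLAP linearly in PR.

Two conventions deserve note. First, the stroke volume metric is defined
volumetrically (LV volume at ventricular activation onset minus minimum
LV volume); at extreme PR settings where filling continues into early
contraction this differs from the beat-averaged aortic flow, so the
metrics report both (`co` and `co_flow`), and regulation targets the
flow. Second, ΔmLAP maps for phenotype variants (atrial myopathy) are
computed against the *shared* normal-atrium reference, not each
variant's own intrinsic simulation: the trial's Δ maps are all defined
relative to the one reference whose intrinsic mLAP is 15 mmHg. With that
convention, atrial myopathy attenuates the achievable unloading; with
per-variant references it would not, because myopathy itself raises the
intrinsic mLAP (to ≈ 19 mmHg here). `run_grid(reference_phenotype = ...)`
exposes the choice.

# The signal pipeline

Preprocessing follows the clinical analysis: 0.5–100 Hz band-pass
(4th-order Butterworth), 50 Hz notch (biquad, Q = 30), 800-sample moving
median subtraction — all zero-phase so onset timings are not shifted.
Zero-phase application uses linear-prediction (AR) padding: odd
reflection keeps a signal continuous but reverses its slope, and the
resulting kink makes the high-Q notch ring into the recording; an AR
extension continues narrowband content coherently, taking the residual
of a full-scale 50 Hz tone below −60 dB across the whole output (the
acceptance bound is −40 dB). The input mean is removed before filtering
(the band-pass rejects DC at steady state anyway), so a constant input
maps to exactly zero.

R peaks come from the classic Pan-Tompkins cascade (5–15 Hz emphasis,
five-point derivative, squaring, 150-ms integration, adaptive dual
thresholds, 200-ms refractory, search-back), with every threshold
relative to running peak estimates so detections are amplitude-invariant.
Pacing spikes are first-difference outliers (8 × rolling MAD, 100-ms
refractory) on the coronary-sinus channel. Contiguous spike stretches
become paced segments (rate = median interval rounded to the nearest
10 bpm); the clustering uses a greedy *local* interval estimate because a
global median gap threshold falsely splits slow-rate segments in
protocols dominated by fast ones. Analysis windows are the final 10 s of
each segment — nothing outside a window touches any mLAP — and per-rate
ΔmLAP subtracts the mean of the two flanking sinus windows (single flank
at protocol edges, flagged), exactly the carry-over control of the
clinical analysis.

QRS onset scans back (≤ 80 ms) from each R peak for the sample where the
10-ms slope of the smoothed signal-energy envelope drops below 5% of its
local peak; P-wave onset is the foot of the maximal positive slope in the
300–50 ms pre-QRS window. Both detectors are this package's own designs
(the clinical analysis verified onsets manually) and are validated only
against the synthetic generator's exact truth, where per-rate mean PR is
recovered within ~2 ms. Pacing spikes with no QRS within one pacing cycle
are emitted as dropped beats; the first paced segment containing a
dropped beat marks Wenckebach block, and the maximum rate is the
preceding tested rate. Optimal-rate ties break toward the lower rate.
Retained PR intervals outside (40, 400) ms are flagged and excluded from
averages, never silently used.

Paired cohort statistics follow the stated procedure: Shapiro-Wilk on
the paired differences at α = 0.05 selects between the paired Student
t-test and the Wilcoxon signed-rank test; output includes the two-sided
p, mean ± SD with t-based 95% CI, and medians [IQR]. (The normality gate
is applied to the differences — the quantity the paired tests act on.)

# The synthetic generator

`generate_recording()` builds the alternating protocol from analytic
Gaussian-bump morphology, because analytic placement yields *exact* onset
ground truth: the P-wave foot (2σ before its centre) is the atrial onset
for intrinsic beats, a 2-ms biphasic CS spike marks it for paced beats,
and the QRS foot sits exactly PR(rate) after the atrial onset. The LA
pressure is an a-wave + v-wave bump train riding on the programmed level,
normalised so each analysis-window mean equals the programmed
mLAP(rate) = m_sinus − depth·exp(−((rate − r_opt)/width)²) exactly before
noise. Defaults mirror the cohort's printed values: sinus 55 bpm, optimum
100 bpm, depth 2.3 mmHg, PR 153 ms prolonging 1.7 ms/bpm, Wenckebach at
140 bpm with a fixed 4:1 drop pattern (a deterministic surrogate for true
Wenckebach periodicity). Noise defaults — 0.02 mV ECG white noise,
0.05 mV mains, 0.3 mmHg LA-pressure noise and 0.3 mmHg slow drift — are
modest values typical of a calibrated fluid-filled catheter in a quiet
lab; the flanking-sinus differencing absorbs slow drift just as it does
clinically. What the generator does *not* emulate: realistic ECG
morphology beyond onset timing, ectopy, respiratory modulation, or AF
episodes — so pipeline validation here demonstrates correct *protocol
arithmetic* (segmentation, windowing, timing, differencing), not
robustness to every clinical artefact.

`model_driven_recording()` ties the halves together: the LA-pressure
channel is the tiled steady-beat waveform of the regulated model at each
segment's (rate, PR) while ECG/CS come from the same timing. One caveat
is inherent to windowed means of periodic signals: a 10-s window holds a
whole number of beats only at rates dividing 6000 ms (60, 75, 90,
120 bpm, ...); elsewhere the partial beat at the window edge biases the
window mean by up to a few tenths of a mmHg, so the cross-module
agreement check uses rates where the window is beat-aligned.

# Problem sizes and determinism

The shipped tests run the full 9 × 31 grid twice (normal and myopathic
atria), a 10-seed end-to-end pipeline recovery, a 75-patient synthetic
cohort truth table with a 3-patient full-pipeline subsample, and the
closed-form oracles; the whole suite completes in a few minutes on one
core. Everything downstream of a configuration and seed is deterministic:
the model contains no randomness at all, and the generator draws all
noise from the provided seed.

# Known limitations

* The chamber law is a reduced model: cell-level values of the original
  wall-mechanics cohort (e.g. specific ΔmLAP magnitudes at specific
  cells) are directional anchors only; this package's grids are larger in
  |ΔmLAP| than the published ones while reproducing every ordering and
  shape property.
* No baroreflex or adrenergic dynamics: regulation is a steady-state
  construct, matching the protocol's rationale (pacing lacks the
  adrenergic surge of exercise), not beat-to-beat autonomic control.
* AV conduction is imposed, not emergent: Wenckebach appears in the
  synthetic data by construction and in the model only as a programmed
  PR; the model cannot predict the rate at which block occurs.
* The P-onset detector assumes a monophasic P wave, adequate for the
  generator's morphology and for clean sinus rhythm, not for complex
  atrial signals.
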