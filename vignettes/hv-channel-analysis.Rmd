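---
title: "Models and methods for Hv channel recording analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for Hv channel recording analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hvgating)
```

## Scope

`hvgating` is built around four connected pieces: a generative model of
voltage-gated proton (Hv) channel currents, a plain-text episodic trace
format, the measurement pipeline that turns sweeps into biophysical
parameters, and a sequence-divergence mapping workflow used when designing
chimeric channels between two homologues. This vignette explains the models
and the numerical and design choices behind each piece; the README shows a
worked end-to-end example.

## The gating model

Channel gating is a linear kinetic scheme
$C_{n-1} \leftrightarrow \dots \leftrightarrow C_1 \leftrightarrow O$
with $n \ge 2$ states. Transition $i$ carries a gating charge $z_i$
(elementary charges) and has rate constants

$$\alpha_i(V) = k_i e^{+z_i (V - V_m)/2 V_T}, \qquad
  \beta_i(V)  = k_i e^{-z_i (V - V_m)/2 V_T},$$

where $V_T = k_B T / e_0$ is the thermal voltage (25.6 mV at 297 K) and the
charge is split symmetrically between the forward and backward barriers.
The common transition midpoint $V_m$ is not a free parameter: it is solved
(exactly for two states, numerically otherwise) so that the equilibrium
open probability is 0.5 at the model's effective half-activation voltage.
Three consequences matter for validation:

* **Two-state limit.** For $n = 2$ the equilibrium open probability is the
  Boltzmann function $1/(1 + e^{(V_{1/2}-V)/s})$ with
  $s = V_T / z$. Two-state presets therefore tie their single gating charge
  to the slope factor, and the limiting-slope estimator must return
  $V_T/s$ on them — an analytic identity the tests check to 2%.
* **Activation lag.** With $n > 2$, occupancy must traverse the closed
  states before reaching $O$, which produces the sigmoidal delay seen in
  real Hv activation without any ad-hoc delay term, and deactivation tails
  relax with more than one exponential component, again as observed.
* **Limiting slope.** At very low open probability,
  $\ln P_o \to \sum_i z_i (V - V_m)/V_T + \text{const}$, so the slope of
  $\ln P_o$ against $V$ recovers the total gating charge.

### pH coupling

The voltage dependence couples to the solutions phenomenologically and
linearly:

$$V_{1/2}(\mathrm{pH_i}, \mathrm{pH_o}) = V_{1/2}^{\mathrm{ref}}
  + c_{\mathrm{sym}} (\mathrm{pH_i} - 6)
  + c_{\Delta\mathrm{pH}} (\mathrm{pH_o} - \mathrm{pH_i}),$$

with the reference condition pH 6.0 on both sides. This is a description,
not a mechanism: the coefficients are preset per channel. Fungal-like
presets carry $c_{\Delta\mathrm{pH}}$ of $-85$ to $-90$ mV per pH unit and
the human-like preset $-40$ mV per pH unit (the canonical animal rule);
the SlHv1-background presets additionally carry
$c_{\mathrm{sym}} = +19$ mV per pH unit. Two sign conventions were left
open by the source data and are configurable in `hv_preset()`: we take
$c_{\Delta\mathrm{pH}} < 0$ (raising the gradient hyperpolarizes
activation, the direction the animal rule implies) and
$c_{\mathrm{sym}} > 0$. Whether gradient coupling is symmetric in
pH$_i$ and pH$_o$ changes is untested experimentally; the model assumes it
is, since only the difference enters.

Proton selectivity is built in rather than emergent: the open-channel
driving force is $V - E_H$ with
$E_H = -\ln(10)\,(RT/F)\,\Delta\mathrm{pH}$. The default temperature is
297 K so that the Nernst slope is the conventional 58.9 mV per pH unit
reference value; temperature is a field of `hv_solutions()`.

### Presets

`hv_preset()` carries Boltzmann parameters for SlHv1 (46.5 mV, 7.6 mV),
AoHv1 (−13.9 mV, 7.4 mV), a human-like reference (53 mV, 11.6 mV), and the
nine SlHv1/AoHv1 chimeras, all at the pH 6.0 reference condition. Kinetic
scales are stated as the relaxation time constant at $V_{1/2}$
($\tau = 1/2k$ for two states); no absolute time constants were published
for these channels, so the defaults — 600 ms for SlHv1-like channels,
100 ms for AoHv1-like (the reported roughly sixfold difference), chimeras
grouped fast or slow by their measured kinetics class — were chosen once as
realistic values and are not calibrated against any test. `SlHv1_seq` is a
three-state fixture with per-transition charges of 2.5 $e_0$ (total 5, the
reported gating-charge scale for these channels) and a 2 ms kinetic scale
so that slow ramps remain quasi-static; it exists for limiting-slope work.

### Artifacts

`hv_noise()` adds the three artifacts the preprocessing stages must remove:
additive Gaussian current noise (pA), an ohmic leak
$g_{\mathrm{leak}}(V - E_{\mathrm{leak}})$, and geometric rundown (each
sweep's channel conductance retains a factor $r \le 1$ of the previous
sweep's; default 0.98 in the fixture suite, strong enough to exercise the
correction while keeping reference currents measurable). Every stochastic
entry point takes an explicit integer seed; the same seed and configuration
give byte-identical trace files.

### What the generator does and does not emulate

Simulated recordings have Boltzmann-activated, perfectly proton-selective
currents with sigmoidal activation, multi-exponential deactivation,
pH-coupled voltage dependence, leak, rundown, noise, and the two blocker
mechanisms (open-channel occlusion scaling $g_{max}$ by $1/(1+c/K_d)$;
closed-state stabilization shifting $V_{1/2}$ by its saturable occupancy
term and slowing the kinetic prefactors). They do **not** emulate patch
instability or seal loss, capacitive transients (the pipeline's blanking
window exists for real data; simulated traces are clean at epoch
boundaries), channel noise (gating is deterministic mean-field),
inactivation, mechanosensitive facilitation (a facilitated state can only
be encoded as a preset change), or subunit cooperativity beyond the total
gating charge. Passing tests therefore demonstrate estimator correctness
under the stated statistical structure, not robustness to every pathology
of real patches.

## The measurement pipeline

The stages mirror standard Hv analysis practice:

* **Leak subtraction** fits $I = g(V - E)$ per sweep over user-designated
  subthreshold samples. The exact historical procedure behind published
  datasets is not restated in the literature we model; an ohmic fit over a
  declared window is the transparent stand-in, and the window is flagged if
  it reaches above a stated subthreshold ceiling.
* **Rundown correction** rescales each sweep by the ratio of the first
  sweep's isochronal reference-step current to that sweep's, failing
  loudly if a reference current is indistinguishable from zero.
* **G–V derivation** uses $G = I/(V - V_{\mathrm{rev}})$ with
  $V_{\mathrm{rev}} \approx E_H$ by default (the high-selectivity
  approximation) and masks points within 5 mV of $V_{\mathrm{rev}}$, where
  the quotient is numerically unstable. Tail-derived G–V curves use the
  instantaneous tail amplitude directly, optionally extrapolating an
  exponential fit back to the repolarization onset to undo decay during
  the blanking window.
* **Boltzmann fits** are unweighted nonlinear least squares
  (Levenberg–Marquardt) with self-starting values from the half-maximum
  crossing and the 10–90% rise width; uncertainties come from the
  covariance at the optimum. Monotonically decreasing data are rejected,
  not silently fitted with a negative slope.
* **Activation fits** exclude the sigmoidal lag by starting at the first
  crossing of 10% (configurable) of the steady rise, then fit a single
  exponential; multi-exponential activation fitting is deliberately out of
  scope. A 0.5 ms capacitive blanking window (configurable) is excluded
  after each voltage change.
* **Deactivation** is summarized by the model-free half-decay time
  $t_{1/2}$ because tails are multi-exponential.
* **Limiting slope** fits $\ln P_o$ against $V$ over a window
  $P_o \le 0.02$ by default. "Very low" is not a number; 0.02 keeps the
  relative bias of the finite window below the fit noise for charges near
  5 (the apparent slope at $P_o = 0.01$ underestimates the total charge by
  a few percent, visible in the acceptance numbers). A lower window bound
  is available because measured $P_o$ values near zero are dominated by
  additive current noise, and censoring their negative excursions at zero
  would otherwise bias the log-slope downward — the measurement windows in
  the packaged analyses keep $P_o \ge 10^{-3}$ for that reason.
* **Thresholds.** $V_{\mathrm{threshold}}$ ("first observable current") is
  noise-dependent in raw form; it is operationalized as the voltage where
  normalized conductance crosses 0.02.

Group comparisons use Welch's $t$ for two conditions and one-way ANOVA
with Tukey's post hoc correction otherwise, via the standard R
implementations (the studentized-range distribution in R is evaluated
numerically, not from tables), annotated with the conventional star
thresholds.

## Sequence divergence mapping

The chimera-design readout is a per-residue divergence scale between two
homologues. The pairwise global alignment uses BLOSUM62 with affine gap
penalties, opening 8 and extension 1, under the convention that a gap of
length $L$ costs $8 + (L-1)$ — the published penalty pair does not fix the
convention, so it is documented here and configurable. The aligner is
Needleman–Wunsch (via Biostrings, with the opening penalty shifted to map
conventions); its optimality is cross-checked in the tests against an
exhaustive enumeration oracle on small sequences. Because published
alignments of this kind often carry manual register edits (e.g. preserving
coiled-coil heptads), `hv_alignment()` accepts externally aligned rows
as-is.

Per-column scores (substitution value, $-8$ on the first column of a gap
run, $-1$ on subsequent ones) are converted to divergence as deviation
from the average, $d_i = \bar w - w_i$, indexed by the reference row's
residue numbering. Columns where the reference row is gapped are dropped
and their penalties folded into the preceding reference residue (the
following one at the N-terminus) — the treatment of such columns is not
specified anywhere authoritative, so this is a declared choice. The
profile is smoothed by a centered 5-residue moving average (truncated
symmetrically at the termini) and then min-max rescaled to $[0, 1]$; the
order deviation → smooth → rescale guarantees the scale actually attains 0
and 1 after smoothing, which the alternative order (rescale before
smoothing, available as a switch) does not. Constant profiles map to all
zeros rather than dividing by a zero range. The scale is written into the
B-factor column of a PDB model (×100, rounded to 2 decimals) for rendering
in any structure viewer; rendering itself is out of scope.

## Numerical choices

* Constant-voltage epochs are propagated by the matrix exponential of the
  generator, computed from its eigendecomposition with a `Matrix::expm`
  fallback when the eigenvector basis is ill-conditioned; occupancies are
  clipped at zero and renormalized each step, keeping their sum within
  $10^{-9}$ of one.
* Ramps are integrated piecewise-constant with sub-steps of at most 1 ms,
  bounded at 20000 sub-steps per epoch: beyond that, ramps are so slow
  relative to the kinetics that coarser steps are quasi-static and the
  discretization error is far below fit noise.
* Overflow guards: equilibrium weights are computed in log space;
  transition-rate exponents are capped at $e^{300}$.
* All fits are unweighted least squares; ties in interpolation use means.

## Problem sizes

The shipped tests and acceptance analyses run at deliberately small scale,
chosen as the smallest sizes at which the estimators' sampling error is
comfortably below the tolerances being asserted: step families of 7–10
sweeps at 1–2 ms sampling, 1.5–4 s depolarizations, a single 12 s ramp for
the limiting slope, 5 noisy G–V replicates per recovery analysis
(noise s.d. 0.03 on normalized conductance), 100 replicates for the
bias check, and 1000 for the test-size check.

## Known limitations

* The pH coupling is linear over the tested range (±1 pH unit); real
  channels may saturate outside it.
* The closed-state blocker model shifts $V_{1/2}$ and slows all
  transitions uniformly; state-dependent binding kinetics (use-dependence,
  relief at depolarized potentials) are not modelled.
* `estimate_reversal` requires a sign change in the tail family; it will
  not extrapolate beyond the measured voltages.
* The divergence scale treats the alignment as fixed truth; alignment
  uncertainty is not propagated.
* Master-equation integration assumes a time-homogeneous scheme within
  each sub-step; extremely fast ramps (mV per µs) would need finer
  sub-stepping than the defaults.
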