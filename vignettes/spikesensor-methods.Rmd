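---
title: "Modelling SAI afferent spiking from embedded force sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling SAI afferent spiking from embedded force sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikesensor)
```

## The model

Slowly adapting type I (SAI) mechanoreceptive afferents fire continuously
during sustained skin indentation and more vigorously while the stimulus
moves. `spikesensor` reproduces that behaviour from the force measured by
a sensor embedded in a skin-like elastic substrate, in three stages.

**Transduction.** Force and its rate of change are converted linearly
into transmembrane current,

$$I(t) = \beta + k_s\, f(t) + k_d\, f'(t),$$

with intercept $\beta$ (mA) absorbing per-sensor baseline, static gain
$k_s$ (mA/N), and dynamic gain $k_d$ (mA·s/N). The force rate is the
backward difference $f'(t) = (f(t) - f(t-h))/h$ in N/ms with $h = 10$ ms
(one sample at 100 Hz); it is defined as zero at the detected stimulus
onset, at all samples before onset, and wherever the look-back would
precede the trace. The product $k_d f'$ is treated as a plain numeric
product — the only convention under which published parameter values
combine into currents commensurate with $k_s f$; we document rather than
resolve the ambiguity in the printed unit of $k_d$.

**Membrane dynamics.** The current drives a leaky integrate-and-fire
membrane,

$$\frac{du}{dt} = -\frac{u}{\tau} + \frac{I(t)}{C}, \qquad R = \tau / C,$$

integrated by the classical fourth-order Runge–Kutta scheme at a fixed
step of $dt = 0.01$ ms. When $u$ reaches the threshold $\bar v$ at a step
boundary (equality counts), that boundary is recorded as a spike, $u$
resets to $u_0 = 0$ mV, and the membrane is clamped at $u_0$ for the 1 ms
absolute refractory period. With $u$ in mV, $t$ in ms, $I$ in mA and $C$
in mF, both terms of the current balance are in mA and no hidden
conversion factors appear anywhere.

Two consequences of these choices matter for testing. First, under a
constant suprathreshold current the interspike interval has the closed
form $t_{\mathrm{ref}} + \tau \ln\!\big(RI/(RI - \bar v)\big)$, which the
clamp makes exact up to $dt$-quantization; `lif_constant_current_isi()`
exposes it and the test suite holds the simulator to it within $2\,dt$
across 1.1–10× rheobase. Second, because the current is held constant
over each 10 ms sampling interval (zero-order hold; linear interpolation
is available as an option), the RK4 update inside an interval reduces
algebraically to an affine map, which the compiled integrator exploits —
it is the identical classical-RK4 step, evaluated in folded form.

**Metrics.** Spike trains are summarized by interspike intervals (ISIs)
windowed by stimulus phase: the *dynamic* window runs from stimulus onset
to the time of peak force (earliest maximum on ties), the *static* window
from 2 to 5 s after onset. Windows are closed; an ISI belongs to a window
only when both of its spikes do, so edge-straddling intervals count
nowhere. First-spike latency is the time from onset to the first spike at
or after it, and static-ISI irregularity is the coefficient of variation
using the sample (n−1) standard deviation. All of these conventions are
stated here because the verbal definitions they implement leave them
open.

## The six free parameters and their identifiability

Fitting adjusts $(\beta, k_s, k_d, \tau, C, \bar v)$. Scaling
$(\beta, k_s, k_d, C)$ jointly by any $\alpha > 0$ leaves $I(t)/C$ and
hence every spike time unchanged — an exact degeneracy the test suite
asserts bit-for-bit at $\alpha \in \{0.1, 10\}$. Only the five
combinations $(\beta/C,\; k_s/C,\; k_d/C,\; \tau,\; \bar v)$ are
identifiable from spike data, and parameter-recovery checks compare
those, never the raw six-vector.

Identifiability is graded even within the five. Because spike times are
quantized to $dt$ and phase means average a finite spike count, the
fitting objective is piecewise constant at fine scales, and it is nearly
blind to $\beta/C$: moving $\beta$ alone by ±20 % changes the objective
by about $10^{-4}$, and compensated combinations (a ~15 % shift in
$\beta/C$ absorbed by percent-level shifts in the other gains and
$\bar v$) lie within $10^{-6}$ of the optimum. A steepest-ascent fit
started 20 % off therefore recovers $k_s/C$, $k_d/C$, $\tau$ and $\bar v$
to within a few percent but can leave $\beta/C$ ten to twenty percent
off at a near-perfect objective value.

Worse, some ±20 % starts are themselves *compensated*: co-scaling
$\tau$, $\bar v$ and the gains produces predictions whose FSS deficit is
under $10^{-3}$ with every parameter 20 % off. Around such points the
FSS surface is a thin curved valley — steps of a few percent off the
valley floor cost $\sim 10^{-2}$, while 20 % of error along it costs
almost nothing — and neither steepest ascent nor the second-order ridge
phase can traverse the floor before hitting the quantization plateaus.
A recovery experiment started at a compensated perturbation will
therefore report a near-perfect FSS with several combinations still
15–30 % off. This is a property of the experiment — five force levels,
four replications, ISI-mean targets — not of the optimizer, and the
acceptance suite reports it honestly rather than tightening the
experiment until it disappears; the strong sensitivity of the original
fitting sessions to their starting values is the same phenomenon seen
from the bench.

## The fitting objective and optimizer

Predicted and observed phase ISI means are compared by the fractional
sum of squares,

$$\mathrm{FSS} = \omega_{dyn}\Big(1 - \tfrac{\sum_i \sum_j (\mathrm{obs}_i - \mathrm{pred}_{ij})^2}{J \sum_i \mathrm{obs}_i^2}\Big)_{dyn} + \omega_{stat}\big(\cdots\big)_{stat},$$

with equal weights $\omega = 0.5/0.5$ and $J$ replications per
indentation type ($J = 4$ for a two-thirds training split of six
blocks). A perfect fit scores 1, all-zero predictions score 0, and each
squared deviation strictly lowers its component. Predictions undefined
because no two spikes fell inside a window are scored with a penalty ISI
of ten times the largest observed mean and counted in the result, never
silently dropped.

`rsm_fit()` maximizes FSS by first-order response-surface methodology:
a $2^6$ factorial probe at ±5 % per parameter around the current point, a
least-squares first-order surface, a steepest-ascent line search with up
to eight step halvings, and — when no step improves — halving of the
probe radius (standard region-of-interest shrinkage) down to a floor.
Iteration stops when the FSS improvement drops below the tolerance
(default $10^{-3}$) or after 25 iterations; every accepted iterate is
logged, so the session log's FSS sequence is non-decreasing by
construction. Two optional escalations follow classical sequential RSM:
`restarts` re-centres the factorial with a fresh radius after a stall,
and `second_order` augments it into a central composite design, fits a
full quadratic, and takes ridge-analysis (trust-region) steps — useful
when the objective has a curved ridge. Probes whose predictions needed
the no-spike penalty are treated as infeasible when fitting either
surface: they are legitimate objective values but, at $\mathrm{FSS}
\approx -30$, they would destroy a local least-squares model. All knobs
live in `rsm_control()`. The recovery experiment in the acceptance
suite tightens the tolerance to $10^{-6}$, allows 40 iterations, a
radius floor of 0.05/256, two restarts and the second-order phase,
because it asks for parameter polish rather than a practical fit. Training/test splitting is stratified
by indentation type (`split_train_test()`, two-thirds by default), and
`validate()` recomputes FSS on held-out traces with the replication count
present there.

## What the synthetic generator emulates

No deposited sensor recordings exist, so the stimulus module generates
the five-type ramp-and-hold design synthetically: zero force during an
onset gap (default 100 ms — the time an indenter moving a few mm/s takes
to close the 0.6 mm start gap, plus substrate lag), a linear rise at the
protocol's peak dForce rate, and a sustained ~5 s hold with a
single-exponential relaxation (default 5 % amplitude, 800 ms time
constant) toward the plateau, emulating substrate creep. Types I–III
share a 1.2 mm hold depth and differ in ramp rate (coded dForce levels
1.43 < 1.78 < 2.19); types III–V share the top rate and hold at 1.2, 1.3
and 1.4 mm.

Two generator constants deserve their derivations:

* **Plateau forces.** The force at an embedded sensor during the hold is
  never published, so the defaults were derived from the closed-form
  constant-current ISI: plateau forces of 1.35, 1.92 and 2.37 N are the
  levels at which the published end-of-fit parameters produce hold-phase
  static ISIs in the characteristic tens-of-ms SAI regime (about 110, 59
  and 44 ms after relaxation), with the 1 N onset rule sitting just
  above the ≈0.99 N rheobase force.
* **dForce unit scale.** The printed dForce levels carry an ambiguous
  unit. Read as N/s they give ramps of 0.6–1.1 s in which the static
  term dominates the ramp current — contradicting both the sub-500 ms
  ramp the apparatus delivered and the transduction model's description
  of a dynamic-dominated ramp. The default scale of 4.6×10⁻³ N/ms per
  level unit is the value obtained by inverting the constant-current ISI
  against the dynamic-phase ISI regime (≈15–22 ms) the model reproduces;
  it yields ramps of 134–235 ms and a ramp current dominated by
  $k_d f'$. The scale remains configurable.

Sensor noise is added as i.i.d. Gaussian perturbations *after* the
deterministic profile and is then low-pass filtered in the default
pipeline. The default sd of 0.025 N is calibrated so the filtered
pipeline under the published parameters reproduces a static-ISI
coefficient of variation of ≈0.07, the value reported for filtered
sensor data; leaving the noise unfiltered raises the CV, reproducing the
reported direction of the filtering effect on ISI irregularity.

The filter itself mirrors the bench instrumentation: FFT, Gaussian taper
with unity DC gain and standard deviation fixed by a $10^{-3}$ gain at
the 15 Hz cutoff, hard zero above the cutoff, inverse FFT. Traces are
mirror-padded (edge-hold then reflection) to the next power of two to
keep the wrap-around transient out of the retained samples; the cost is
a trace of truncation leakage (~$10^{-5}$ relative stop-band power),
and `pad = FALSE` recovers exact circular stop-band zeroing. Because the
taper is below unity everywhere except DC, filtering twice attenuates
pass-band content further — the filter is deliberately not a projection.

What the generator does **not** emulate: skin or substrate continuum
mechanics, the sensor's electronics, displacement servo dynamics, or the
separate load-cell (applied-force) channel of the original apparatus.
The last omission matters for one metric, below.

## Onset rules and the latency reference

Two onset definitions are supported: force crossing (default 1 N, the
rule used for sensor-in-substrate data) and force-rate crossing (default
0.5 mN/ms, the rule used for afferent recordings). Onset is the first
*sample* past threshold, so it inherits the 10 ms sampling quantization;
"no onset" is a distinguishable `NA`, not time zero.

With the published parameters the rheobase force (0.992 N) lies just
below the 1 N onset threshold. On a single trace this means the membrane
is already charged to within ~1 mV of threshold when the trace crosses
1 N, so first-spike latencies measured from the 1 N onset collapse to a
few milliseconds of dynamics underneath the 10 ms onset quantization and
carry no usable rate ordering. The large, rate-ordered latencies seen in
the original apparatus arise from the delay between the *applied* force
(load cell, where onset was defined) and the slower force build-up at
the embedded sensor — two channels, of which this package's data model
carries only the second. Latency trend analyses here therefore measure
latency from the force-rate onset, which anchors the stimulus start on a
single trace (it fires at the first ramp sample, identically across
types) and makes the charge-up time to first spike cleanly rate-ordered.
The 1 N rule remains the default for windowing and fitting.

## Validation statistics

Treatment effects of indentation type on the phase ISI means are tested
by the classical randomized-complete-block decomposition (every type
once per replication block), computed through `stats::aov` with
`response ~ treatment + block`; only the treatment F (on
$(a-1), (a-1)(b-1)$ degrees of freedom) is tested, and the block effect
— which would speak to adaptation across repeated indentations — is
estimated but deliberately not tested. Tukey pairwise comparisons use
the critical difference $q_{\alpha, a, \nu}\sqrt{MS_E / b}$ with
quantiles from the studentized-range distribution (`qtukey`), never from
printed tables; the test suite checks the four printed critical values
(2.87, 2.78, 4.24, 4.17) at two-decimal precision. The design check
rejects incomplete tables naming the offending cell, and a
roundoff guard returns $F = 0$ for constant responses.

## Numerical and degenerate-input choices

* Integration runs from the first to the last current sample (stimulus
  offset); there is no retraction-phase special handling.
* Refractory bookkeeping is in integer steps, so spike times are exact
  multiples of $dt$; consecutive spikes can never be closer than the
  refractory period, which a fuzzed battery of step/ramp/noisy currents
  confirms.
* Halving $dt$ moves the first spike and every ISI by less than $dt$;
  absolute times late in long trains may accumulate several one-step
  roundings, which is why convergence is asserted on intervals.
* Fewer than two spikes in a window yield an `NA` mean with a zero
  count; a single spike yields an empty ISI list, not an error.
* Traces must be uniformly sampled to within $10^{-6}$ relative spacing;
  readers reject non-monotone or gapped time stamps with line numbers.
* Membrane overflow (non-finite $u$) aborts with the offending time.

## Problem sizes

The test suite and acceptance analyses run at the design's natural desk
scale: five indentation types by four or six replication blocks, ~5.5 s
traces at 100 Hz, membranes integrated at 0.01 ms (≈ 5×10⁵ steps per
trace), and a recovery fit of ≤ 40 response-surface iterations (≈ 70
objective evaluations each over 20 traces). The randomized-null Tukey
calibration uses 600 simulated 5×6 tables.

## Known limitations

* $\beta/C$ is only weakly identified by ISI-mean targets (see above);
  reported recovery bounds for it should be read accordingly.
* The generator's force profiles are phenomenological (piecewise-linear
  ramp, exponential relaxation), not mechanics-derived; absolute ISI
  levels track the plateau-force map, so only orderings and trends — not
  absolute milliseconds — transfer to any particular physical sensor.
* A single force channel means load-cell-referenced quantities (notably
  absolute first-spike latency) are not reproducible, only their
  directions under the force-rate reference.
* The membrane has no intrinsic adaptation, no relative refractory
  period, and a 0 mV rest by construction; the blocking/adaptation
  effect across repeated indentations is out of scope.
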