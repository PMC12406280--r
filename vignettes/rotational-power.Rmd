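---
title: "Rotational power from a thigh-worn accelerometer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rotational power from a thigh-worn accelerometer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotpower)
```

## The measurement model

During a 30-second chair stand test (30CST) the thigh rotates between
roughly horizontal (seated) and vertical (standing). A single thigh-worn
triaxial accelerometer, sampled at 250 Hz, measures the gravity reaction
plus movement acceleration in its own, arbitrarily mounted, frame. The
processing chain is:

1. **Sensor-to-segment alignment.** A quiet-standing (orthostatic)
   calibration gives the gravity direction in the sensor frame
   (`estimate_static_gravity()`). The Rodrigues rotation that maps this
   direction onto the anatomical reference (−1, 0, 0) — gravity along the
   negative cranial-caudal axis — is applied to every sample
   (`rodrigues_rotation()`, `align_recording()`).
2. **Pitch.** The cranial-caudal (a_X) and anterior-posterior (a_Z)
   channels are low-passed (4th-order Bessel, 2 Hz, zero phase) and the
   pitch of the thigh relative to the vertical is
   θ = atan2(a_Z, −a_X): 0 standing, +π/2 seated. This is a
   quasi-static estimate — it treats the filtered acceleration as pure
   gravity, which the 2 Hz cut-off is designed to make approximately true.
3. **Rotational power.** θ is low-passed once more (2.5 Hz), differentiated
   twice (ω, α), and RP = ω·α in rad²/s³. The positive peak per transition
   is the RPP.
4. **Reference branch.** The mean vertical trajectory z of the left and
   right PSIS markers (100 Hz motion capture) approximates the
   center-of-mass height; after the 2 Hz filter, v = dz/dt, a = dv/dt and
   p = a·v in W/kg. Its positive peak per transition is the VPP.
5. **Synchronization and segmentation.** The two systems run on independent
   clocks; the lag is estimated by cross-correlation (below). Transitions
   are delimited by the alternating extrema of filtered z (maxima =
   standing, minima = seated), labeled SI-ST on rising z and ST-SI on
   falling z; a valid repetition is an SI-ST whose following ST-SI
   completes within the 30 s task.
6. **Trial summaries and statistics.** Per-transition peaks are aggregated
   as 95th centiles (RP95c, VP95c), which are then related to clinical
   scores, compared across systems via ICC, and tracked over the three 10 s
   task windows for acute fatigue.

## Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| filter order | 4 | – | transient-preserving Bessel family, both branches |
| axis / displacement cut-off | 2 | Hz | retains ≥ 95% of sub-1.5 Hz chair-stand energy |
| pitch cut-off | 2.5 | Hz | second stage on θ before differentiation |
| peak prominence | 0.25 | fraction of z range | rejects bounce/settling oscillations |
| peak separation | 0.5 | s | maximum plausible cadence ≈ 1 transition/s |
| max lag | 5 | s | search bound of the clock-offset estimate |
| task duration / windows | 30, edges 10 and 20 | s | protocol constants; windows are [0,10), [10,20), [20,30] |
| centile | 0.95 | – | near-maximal capacity robust to outliers |
| alpha | 0.05 | – | a-priori significance level for every test |

## Numerical choices

**Bessel normalization.** "4th-order Bessel, cut-off 2 Hz" leaves open what
the cut-off means for a Bessel design. The package defaults to the
*delay-normalized* prototype (poles of the reverse Bessel polynomial used
directly), with −3 dB (`"mag"`) and phase-midpoint (`"phase"`)
normalizations available. The choice is driven by the design rule that
filtering must retain at least 95% of the signal energy: applied forward
and backward (zero phase squares the magnitude response), the −3 dB-normalized
design retains only ~92% of a 0.5 Hz tone and attenuates the peak of a 1 s
raised-cosine transition by over 10%, while the delay-normalized design
retains ≥ 99% of in-band energy and keeps the closed-form transition peaks
within a few percent. `energy_retention()` checks the rule on every run.

**Zero phase and padding.** Filters are applied forward–backward so that
RPP and VPP peak times are not lag-shifted against each other. Edges are
handled by 3 s reflective padding; the first/last ~1 s of a recording is
still the least trustworthy, which is why the lag estimator trims 2 s from
each end before correlating.

**Differentiation.** Second-order central differences with second-order
one-sided stencils at the endpoints. Interior error for a band-limited
signal is h²|f‴|/6; the endpoint formula doubles that.

**Synchronization.** The correlated pair is the negated pitch rate against
the vertical velocity (both zero-phase filtered, marker branch resampled to
250 Hz by polyphase FIR). Rate-level signals are used because the
displacement-level pair has an extremely flat correlation peak — the
signals are band-limited to ~1 Hz but sampled at 250 Hz — so sample-level
accuracy requires the sharper derivative correlation. The accelerometer
*norm*, an alternative one might consider, is useless under quasi-static
motion (it is ≈ 1 g throughout). The estimator correlates a fixed central
window of one stream against sliding windows of the other and normalizes
per lag; this keeps the number of products identical across lags (a
shrinking-overlap estimator tilts the correlation toward small lags and
biased the recovered offset by 2–3 samples before the fix).

**Segmentation.** Local extrema of filtered z are made strictly
alternating, then pruned by prominence (25% of the trial's z range) and
minimum separation (0.5 s), weakest pair first. Because a trial starts
seated, the first boundary is the signal start, not an interior extremum;
endpoints are added as pseudo-extrema when the excursion to their neighbor
passes the prominence threshold. Boundaries are the extrema themselves,
which under a postural hold between transitions land inside the hold — up
to half a hold away from the kinematic end of the transition. Peak values
are insensitive to this (the power peak lies mid-transition), but a hold
straddling the 30 s cutoff makes the valid-repetition count ambiguous by
±1; the tests therefore check counting on known-cadence sessions where no
boundary is near the cutoff.

**Percentile and standardization conventions.** The 95th centile uses
linear interpolation between order statistics (`quantile` type 7).
Standardization before ICC uses the population (divide-by-n) scale and is
pooled across all transitions of a type over all subjects; the agreement
analysis aggregates all transitions of a type into one table.

**ICC.** Two-way random effects, absolute agreement; ICC(2,1) for single
measures and ICC(2,k) for trial-level averages, with F-based 95% confidence
intervals (Satterthwaite degrees of freedom for the single-measure form,
Spearman–Brown transformed bounds for the average-measure form). The unit
tests verify the mean-squares computation against an independent `aov()`
oracle to 1e-9.

**Fatigue regression.** Per subject and 10 s window, the 95th centile of
RPP over transitions *completing* in that window; subjects lacking a
transition in any window are dropped (logged). The trend test is an OLS fit
of RP95c on the window index *with subject intercepts*: the slope is then
the within-subject change per window. A pooled fit without subject terms
estimates the same slope but inflates its standard error with
between-subject capacity variance, making the test badly conservative —
its null rejection rate collapses far below the nominal 5% under realistic
capacity spread — so the within-subject form is used. The slope is reported
in rad²/s³ per window. The complementary paired t-test compares windows 1
and 3 (two-sided, df = n − 1). No multiplicity adjustment is applied
anywhere: every association is tested once at the a-priori 0.05 level, and
this is deliberate and documented rather than hidden.

## The synthetic-data generator

`simulate_session()` emulates one instrumented 30CST:

- **Kinematics.** A standing fraction φ(t) alternates 0 → 1 → 0 through
  raised cosines x(t) = x₀ + Δx(1 − cos(πt/T))/2, C¹ at both ends. Pitch is
  θ = θ₀(1 − φ) and PSIS height z = z_sit + hφ, so both branches share
  timing exactly. The product of the first two derivatives of a raised
  cosine peaks at Δx²π³/(8T³) at t = T/4 — the closed-form oracle for both
  RPP (Δx = θ₀, rad) and VPP (Δx = h, m).
- **Defaults as study conditions.** 2.5 s cycle (12 repetitions at unit
  capacity), 0.9 s transitions, θ₀ = 1.48 rad and h = 0.30 m (standard
  0.432 m chair), 0.5 s reaction delay after the go signal, 0.02 g
  accelerometer noise, 2 mm marker noise, 0.2 rad mounting misalignment,
  0.8 s clock offset, 5%-per-repetition duration inflation (fatigue), and a
  17-subject cohort with log-normal capacity (σ = 0.25) whose ABC score
  rises and MFIS scores fall with capacity.
- **Quasi-static accelerometer model.** The accelerometer sees the gravity
  projection of θ only; the linear-acceleration term is available
  (`dynamic_accel = TRUE`) but off by default, because the 2 Hz filtering
  is designed to suppress it and the closed-form oracles require the
  quasi-static case.
- **Misalignment.** The default misalignment axis lies orthogonal to the
  cranial-caudal axis. This is deliberate: a single static calibration
  observes only the gravity direction, so the component of mounting error
  *about* gravity (heading) is unobservable and cannot be corrected by any
  single-vector alignment; the simulator's default represents the
  correctable error, and the residual-heading limitation is inherited from
  the measurement protocol itself, not from this implementation.
- **Determinism.** All draws flow from one master seed with per-subject
  substreams derived from (seed, subject index); identical configurations
  produce identical streams.

`simulate_cohort()` by default emits per-transition peak tables directly
(closed-form peaks under log-normal measurement noise, CV 10–12%), which
exercises every statistical stage in milliseconds; `level = "signals"`
generates the full sensor streams for end-to-end runs.

**What the simulator does not emulate.** Real thigh accelerometry contains
impact transients at seat-on/seat-off, tremor and spasticity, non-raised-
cosine asymmetric kinematics, soft-tissue artifact, marker occlusion
beyond simple dropout, and time-varying sensor mounting. Passing the
closed-loop tests therefore demonstrates the internal consistency and
statistical calibration of the pipeline under its stated model — not
field accuracy on clinical recordings, which would require real
validation data.

## Problem sizes used by the tests

The suite and the acceptance script run simulations at the scale a laptop
handles in a couple of minutes: single sessions of 32 s at native rates
(8000 × 3 accelerometer samples), 100-session batches for repetition
counting, 200 cohort replicates per arm for fatigue power and null size,
and 100 replicates for the clinical sign pattern — sizes at which the
binomial uncertainty of the reported rates is a few percent.

## Known limitations

- Heading misalignment (rotation about gravity) is unobservable from a
  static calibration, as discussed above; strongly tilted mountings mix
  medial-lateral signal into the pitch plane.
- Boundary placement inside postural holds makes repetition counts near
  the 30 s cutoff ambiguous by one repetition.
- The fatigue trend uses a fixed-effects OLS; a mixed-effects model would
  be the natural extension but is out of scope.
- Absolute (non-normalized) power in watts is out of scope; both branches
  are body-mass normalized by construction.
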