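# rotpower

Rotational power from a single thigh-worn accelerometer during the
30-second chair stand test (30CST), with the motion-capture vertical-power
reference branch and the statistical machinery used to validate the metric.

## The problem

The 30CST — stand up and sit down as many times as possible in 30 seconds,
arms crossed — is a standard functional test in populations such as people
with multiple sclerosis. Its usual outcome, the repetition count, is coarse.
Mechanical power generated during each postural transition is far more
informative, but the laboratory reference (vertical power of the body's
center of mass) needs optical motion capture. This package implements an
accelerometer-only surrogate:

- **Rotational power (RP)**: from the thigh pitch angle
  θ = atan2(a_Z, −a_X) (anterior–posterior and cranial–caudal
  components of the gravity-aligned acceleration), compute the angular
  velocity ω = dθ/dt and acceleration α = dω/dt; then **RP = ω · α**
  (rad²/s³). The positive peak within a transition is the **RPP**.
- **Vertical power (VP)**: from the averaged vertical trajectory z of the
  two posterior-superior-iliac-spine (PSIS) markers, v = dz/dt, a = dv/dt,
  and **p = a · v** (W/kg, body-mass normalized). Its positive peak is the
  **VPP**.

Both branches use zero-phase 4th-order Bessel low-pass filters (2 Hz on the
axes and displacement, 2.5 Hz on the pitch), transitions are segmented from
the alternating extrema of z and labeled sit-to-stand (SI-ST) or
stand-to-sit (ST-SI), the two recording systems are synchronized by
cross-correlation, and trials are summarized by the 95th centile of the
per-transition peaks (**RP95c**, **VP95c**).

The validation layer reproduces the analysis pipeline end to end:
Shapiro–Wilk-gated Pearson/Spearman correlations with Evans strength
labels, two-way random-effects absolute-agreement ICC(2,1)/ICC(2,k) on
standardized peaks, confounder-screened regression, and an acute-fatigue
analysis over the three 10-second task windows (within-subject slope and a
paired t-test of window 1 versus window 3).

Because no raw study data are deposited anywhere, the package ships a
ground-truthed simulator: raised-cosine sit-stand kinematics with known
per-transition closed-form peak powers (dx²·π³ / 8T³), configurable sensor
misalignment, clock lag, noise, per-repetition fatigue slowing, and a
cohort model that couples capacity to ABC/MFIS clinical scores.

## Worked example

```r
library(rotpower)

ses <- simulate_session(sim_config(seed = 1), subject = 1)
res <- process_session(ses$accel, ses$markers, ses$calib, subject_id = 1)

res$sync
#> <sync_result> lag = 0.8000 s (200 samples), peak xcorr = 0.999
res$n_reps
#> [1] 11
head(res$transitions[, c("label", "t_i", "t_f", "rpp", "vpp", "window")], 4)
#>   label  t_i  t_f  rpp   vpp window
#> 1 SI-ST 0.42 1.30 19.1 0.869      1
#> 2 ST-SI 1.30 2.32 19.0 0.926      1
#> 3 SI-ST 2.32 3.49 20.1 0.702      1
#> 4 ST-SI 3.49 4.47 17.5 0.726      1
res$summary
#>   subject_id n_reps rp95c_sist rp95c_stsi vp95c_sist vp95c_stsi
#> 1          1     11      19.54      18.25     0.7773     0.8259
```

The estimated lag recovers the configured 0.8 s clock offset exactly; `rpp`
is in rad²/s³ and `vpp` in W/kg. At cohort level:

```r
co <- simulate_cohort(sim_config(seed = 1))          # 17 subjects
vr <- validate_trial_set(co$transitions, co$scores)

vr$analytical        # per-transition RPP-VPP association, per type
#>       label   method coefficient   p_value    strength   n
#> SI-ST SI-ST spearman       0.969 1.05e-101 very strong 167
#> ST-SI ST-SI spearman       0.964  3.27e-93 very strong 160
vr$fatigue[["SI-ST"]]
#> fatigue trend: slope -4.101 per window (p = 5.537e-08);
#> paired t(16) = 5.268, p = 7.652e-05; 17 subjects
```

With the default 5%-per-repetition slowing, the within-task decline in
SI-ST RP95c is strongly negative, and the clinical table
(`vr$clinical`) shows RP95c positively correlated with the repetition
count and the ABC balance-confidence score and negatively with the MFIS
fatigue scores, the sign structure the capacity coupling is built to
produce.

A command-line interface wraps the same stages:

```sh
exec/rotpower simulate --config sim.yaml --out data/
exec/rotpower process  --accel data/sub01_accel.csv \
    --markers data/sub01_markers.csv --calib data/sub01_calib.csv --out proc/
exec/rotpower validate --transitions transitions.csv --scores scores.csv --out stats/
exec/rotpower all --out run/       # simulate -> process -> validate + manifest
```

## Package layout

- `R/uniform-signal.R`, `R/bessel.R` — signal container, calculus, filters
- `R/io.R`, `R/sync.R` — delimited-text I/O, resampling, lag estimation
- `R/align.R`, `R/power.R`, `R/segment.R` — alignment, both power branches,
  transition segmentation and repetition counting
- `R/stats.R` — validation statistics
- `R/synthetic.R` — ground-truthed session and cohort simulator
- `R/pipeline.R`, `exec/rotpower` — orchestration, configuration, CLI
- `vignettes/rotational-power.Rmd` — methods and design notes
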