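---
title: "Thermal death time curves from knock-down assays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal death time curves from knock-down assays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heattol)
```

## The scientific problem

Heat tolerance of small aquatic ectotherms is often summarised by a single
number — a critical temperature from a ramping assay, or a survival time at
one fixed temperature. Both collapse a two-dimensional phenomenon: the
physiological challenge of heat depends on intensity *and* duration. Thermal
death time curves (TDTCs) keep both axes. An individual held at constant
temperature $T$ (°C) loses locomotory function ("knock-down") after a time
$t$ (minutes) that shortens roughly exponentially with temperature:

$$\log_{10} t = \frac{\mathrm{CTmax} - T}{z}$$

Two parameters summarise a group's tolerance. The temperature sensitivity
coefficient $z$ is $-1/\text{slope}$ of the semi-log regression of
knock-down time on temperature; a *high* $z$ means *low* sensitivity (each
extra degree costs proportionally less time). CTmax is the $x$-intercept —
the temperature at which the fitted $\log_{10} t$ reaches 0, i.e. knock-down
in one minute. Because the intercept is unit-dependent, this package fixes
minutes as the time unit throughout; CTmax would shift if times were
expressed in, say, seconds. The *elevation* of the curve (its height over
the assay range) measures the overall magnitude of tolerance: two groups
with equal $z$ but different elevation differ by a constant factor in
knock-down time at every temperature.

The package implements the full analysis for a multi-temperature,
multi-run knock-down assay of *Daphnia*-like zooplankton in which two
body-size groups are compared: detection of the knock-down time from
velocity tracking exports, TDTC estimation per size group, and
maximum-likelihood mixed-model comparison of how body size enters the
relationship.

## The knock-down detector

Tracking software exports a velocity series per subject at a fixed rate
(default 3 Hz) on the *recording* clock, which starts only after the last
subject of a run has been introduced into its well. The time to
immobilisation $T_\mathrm{imm}$ is defined operationally: the time from the
subject's *own introduction* until its swimming velocity is last observed
above a threshold. `estimate_timm()` therefore finds the last sample that
begins a run of at least `min_bout_samples` consecutive samples with
velocity strictly above `velocity_threshold_mm_s`, and adds the subject's
introduction offset:

```{r detector}
trace <- data.frame(sample_time_s = seq(0, 400, by = 1/3))
trace$velocity_mm_s <- ifelse(trace$sample_time_s <= 300, 5, 0)
estimate_timm(trace, intro_offset_s = 120)
```

Defaults are a 1.0 mm/s threshold and `min_bout_samples = 1` (the literal
"last sample above threshold"). The original assay's exact threshold and
any smoothing are configuration, not constants, and both knobs are exposed;
lowering the threshold can only move the estimate later, never earlier, a
monotonicity the tests verify. Omitting the introduction offset would bias
every estimate low by the 3–6 minute introduction stagger, which is why the
offset lives in the subject table and is always added back.

Three failure modes are flagged rather than silently estimated.
`never_moved`: no qualifying sample — the subject was already immobile when
recording began (or tracking failed); it gets no estimate and is excluded
from model input. `right_censored`: the trace ends while the subject still
qualifies, so knock-down is only bounded below; excluded by default since a
faithfully filmed assay ends when all subjects are motionless.
`gap_warning`: a sampling gap above `max_gap_s` (default 2 s); the estimate
is kept but marked.

## The synthetic assay generator

`synthetic_config()` / `generate_experiment()` emulate the design the
analysis assumes: 6 exposure temperatures (35–40 °C in 1 °C steps), 14
measuring runs allocated 3,2,2,2,2,3 across temperatures (any allocation
with at most three runs per temperature totalling 14 is admissible; this
one is symmetric and puts the extra replication at the extremes), 20
subjects per run — one small and one large individual from each of 10
culture beakers — and a total introduction span drawn uniformly from 3–6
minutes, with the last subject entering at recording start.

Latent knock-down times follow the TDTC model with crossed random
intercepts on the $\log_{10}$-minutes scale:

$$\log_{10} t_{ijk} = \beta_0 + \beta_T T + \beta_S S + \beta_{TS} T S +
u_{\mathrm{beaker}(j)} + u_{\mathrm{run}(k)} + \varepsilon_{ijk}$$

Defaults: $\beta_T = -0.45$ (so $z = -1/\beta_T \approx 2.2$ °C),
$\beta_0$ chosen so a mean-size small subject (1.14 mm) sits at
$\log_{10} t = 0.7$ at 40 °C — about 5 minutes at the hottest exposure and
about 15 hours at 35 °C, the intense-and-brief to moderate-and-prolonged
span the assay is meant to cover; $\beta_S = -0.12$ per mm (larger
individuals knock down sooner, at every temperature); $\beta_{TS} = 0$
(no size-by-temperature interaction unless asked for);
$\sigma_\mathrm{beaker} = \sigma_\mathrm{run} = 0.05$ and
$\sigma_\mathrm{resid} = 0.10$ log10-minutes. Body sizes are truncated
normals matching the two visually selected groups (1.14 ± 0.12 mm on
0.92–1.51; 2.70 ± 0.12 mm on 2.37–3.17).

One deliberate consequence of this calibration: large subjects at 40 °C
(~3.3 min latent knock-down) can fall below the 3–6 min introduction
stagger, so a handful of subjects per experiment are already immobile at
recording start and are flagged `never_moved` — the synthetic analogue of
assay individuals whose $T_\mathrm{imm}$ cannot be estimated. The pipeline
excludes them, and the usable count of a default experiment lands within a
few subjects of the full 280.

Velocity traces are generated only when needed (a 35 °C run records for
many hours at 3 Hz) and streamed run by run. The active-swimming process is
a two-state bout model: exponential move bouts (mean 3 s) with lognormal
speeds (median 5 mm/s, well above threshold) alternating with exponential
pauses (mean 0.4 s) at tracking-jitter level; after the knock-down instant
only jitter below 0.3× the threshold remains. The final 2 s before
knock-down are always a move bout — terminal agitation — so the last
supra-threshold sample falls within one sampling interval (1/3 s) of the
latent truth, which is what makes detection fidelity testable against the
generator. Features of real data the generator does *not* emulate: gradual
decline of swimming speed before failure, well-edge effects and partial
occlusion, tracking dropouts, water-temperature drift, and any distinction
between immobilisation and death. Passing tests therefore certify the
statistical machinery at the assumed data-generating structure, not the
behaviour of any particular tracking rig.

All randomness derives from one master seed through deterministic
per-run/per-subject sub-streams (a Lehmer-style mix), so identical
configurations reproduce byte-identical tables, and adding runs or
replicates never perturbs earlier draws.

## TDTC estimation

`fit_tdtc()` is ordinary least squares of $\log_{10} t$ on $T$; $z$ and
CTmax follow algebraically, and the invariants $z \cdot \text{slope} = -1$
and `predict_time(fit, ctmax_C) = 1` minute hold exactly. CTmax is almost
always an extrapolation beyond the assay range (here ~41–41.5 °C from a
35–40 °C design) and the fit records that. A slope within $10^{-12}$ of
zero or positive marks $z$ and CTmax invalid rather than returning an
astronomical extrapolation. `fit_tdtc_by_group()` adds the comparison the
assay is for: per-group curves, plus a common-slope fit
`log10 t ~ temperature + group` whose group coefficient is the elevation
difference (log10 minutes) — the cleaner quantity when slopes are shared,
since per-group intercepts at $T = 0$ amplify slope noise ~37 °C away from
the data.

## Candidate mixed models and AICc

Whether body size changes *sensitivity* ($z$) or only *elevation* is a
model-selection question. Three candidates share the response
$\log_{10}(T_\mathrm{imm})$ and crossed random intercepts for beaker (10
levels) and run (14 levels), and differ in fixed effects: `temperature`
only; `temperature + size` (elevation shift); `temperature × size` with
main effects (size-specific slope, hence size-specific $z$). Modelling
choices, each deliberate:

* **Log response.** The TDTC framework is semi-logarithmic and knock-down
  times span two orders of magnitude; residual structure on the raw scale
  would be wildly heteroscedastic.
* **Size as continuous mm,** not a two-level factor: the assay measures a
  length for every subject, group predictions are made at the group mean
  sizes, and the parameter counts (4/3/2 fixed coefficients) then match the
  7/6/5 totals with two variance components and a residual variance.
* **ML, not REML,** because AICc compares fixed-effect structures;
  REML likelihoods are not comparable across them.
* **Crossed, not nested,** random intercepts: every beaker contributes
  subjects to many runs.
* **Temperature centred internally** at its sample mean for optimizer
  conditioning; coefficients are reported back-transformed, and the tests
  verify the two parameterisations give identical predictions.

Support is summarised by
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ and Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$ (computed after
subtracting the minimum, so huge $\Delta$s cannot overflow). Rows are
sorted by AICc with exact ties broken by smaller $k$; when the top two
models sit within $\Delta < 2$ the table carries a near-tie note, since the
extra term then buys roughly what its penalty costs. $R^2$ is reported as
the squared correlation between conditional predictions (fixed plus
predicted random effects) and observations; no single $R^2$ definition is
canonical for mixed models, a marginal variant is selectable, and no
analysis decision in this package rests on $R^2$.

Numerical policy: `lme4::lmer` with default optimizer settings; on a
convergence warning the fit is retried with `bobyqa` before failing hard
with the diagnostics. A variance component estimated at zero is a
legitimate boundary fit and is flagged, not rejected — with only 10 and 14
levels, boundary estimates are expected behaviour under weak grouping.

## What the simulation studies check

`recovery_experiment()` replicates generation + analysis and compares
estimates with the generating truth. At the default conditions (100
replicates in the acceptance checks; the bundled analysis scripts use 50):
the pooled $z$ is recovered with ~1% median relative error; the negative
elevation shift for large subjects is recovered in sign essentially always;
±2 SE intervals for the temperature effect cover the truth at close to
nominal rate; with $\beta_{TS} = 0$ the additive model stays within
$\Delta\mathrm{AICc} < 2$ of the top model in ≳90% of replicates (the
interaction model sometimes noses ahead, exactly the near-tie pattern such
data produce), and with a strong generated interaction
($\beta_{TS} = -0.05$: $z$ of 1.97 vs 1.71 °C between mean-size small and
large subjects) the interaction model ranks first essentially always.

Replicated recovery fits models to the generated knock-down times rather
than re-running trace simulation each time: the detector's error is bounded
by one 1/3-s sampling interval (verified separately on a full 280-subject
assay, and `use_detection = TRUE` runs the full route on small designs),
which is below $10^{-4}$ on the log10-minutes scale for all but
near-instant knock-downs. Problem sizes used by the bundled checks — one
full 280-subject trace-level experiment, 100-replicate recovery runs at the
default design, and a 48-observation balanced dataset for the dense
likelihood oracle — were chosen as the smallest sizes at which the
corresponding statistical property is stable.

## Known limitations

* The detector assumes essentially complete traces; it flags but does not
  model gaps, and censored subjects are excluded rather than analysed with
  survival methods.
* The TDTC is strictly linear in $T$; curvilinear death-time models and
  survival-analysis formulations are out of scope.
* CTmax is an extrapolation and inherits the linearity assumption; it
  should be read as a curve summary, not a measured limit.
* $R^2$ for mixed models is definition-dependent; values are reported for
  completeness, not inference.
* The generator's bout process is stylised; detector performance on real
  exports with smeared sub-threshold decline near failure will depend on
  the threshold choice in a way the synthetic tests cannot certify.
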