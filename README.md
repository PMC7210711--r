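# heattol

Analysis of static heat-tolerance ("knock-down") assays of small aquatic
ectotherms such as *Daphnia magna*, organised as an R package plus a
numbered analysis workflow.

Warm-acclimated individuals are held at a constant water temperature and
filmed until they stop swimming. The time to immobilisation
T<sub>imm</sub> (minutes, from the individual's introduction into its well
until its swimming velocity is last observed above a threshold) shortens
with exposure temperature following a thermal death time curve (TDTC):

    log10 t = (CTmax − T) / z

where *z* is the temperature sensitivity coefficient (−1/slope of the
semi-log regression; high *z* = low sensitivity) and CTmax is the
extrapolated temperature at which log10 t = 0 (knock-down in one minute).
The scientific question the workflow answers is how body size (and hence
age) enters this relationship: does size change the curve's *elevation*
(overall tolerance), its *slope* (sensitivity, *z*), or neither? That is
cast as an AICc comparison of three maximum-likelihood linear mixed models
of log10 T<sub>imm</sub> — `temperature × size`, `temperature + size`,
`temperature` — sharing crossed random intercepts for culture beaker and
measuring run.

The package provides:

* `synthetic_config()`, `generate_experiment()`, `simulate_trace()` — a
  seeded generator reproducing the assay's statistical structure (6
  temperatures 35–40 °C, 14 runs, 280 subjects in two size groups from 10
  beakers, staggered 3–6 min introduction, 3 Hz velocity traces with
  move/pause bouts, TDTC-distributed latent knock-down times with
  beaker/run random effects);
* `read_dataset()` / `write_dataset()` / `validate_dataset()` — a fixed
  CSV dialect for runs, subjects and velocity traces with referential
  integrity checks;
* `estimate_timm()` / `detect_batch()` / `detect_experiment()` — the
  knock-down detector with QC flags (`never_moved`, `right_censored`,
  `gap_warning`);
* `fit_tdtc()` / `fit_tdtc_by_group()` / `predict_time()` — TDTC fits with
  derived *z*, CTmax and elevation differences;
* `fit_lmm()` / `aicc()` / `akaike_weights()` / `compare_models()` — the
  candidate mixed models and the comparison table;
* `run_pipeline()` / `recovery_experiment()` — the end-to-end pipeline and
  a replicated parameter-recovery study.

## Worked example

The numbered scripts under `analysis/` run the whole study; each is a thin
driver over the package. `Rscript analysis/01_simulate.R` through
`05_recovery.R` writes its tables under `results/`. Steps 2–4 print, for
the default seeded assay:

```
Knock-down detection: 280 subjects, 270 usable estimates
           flag   n
             ok 270
    gap_warning   0
 right_censored   0
    never_moved  10
Detection fidelity: 100.0% of estimable subjects within one sample interval (median |error| 0.17 s)
```

Ten subjects — large individuals at 40 °C, where knock-down can outpace
the 3–6 min introduction stagger — were already immobile at recording
start and are excluded, the synthetic analogue of assay individuals whose
T<sub>imm</sub> cannot be estimated.

```
Thermal death time curve [small], n = 133
  log10 t(min) = 18.8628 -0.4548 * T
  z = 2.199 C, CTmax = 41.47 C (extrapolated beyond 35-40 C)
Thermal death time curve [large], n = 137
  log10 t(min) = 18.6579 -0.4545 * T
  z = 2.200 C, CTmax = 41.05 C (extrapolated beyond 35-40 C)
Pooled (common-slope) z = 2.199 C
  elevation shift large - small: -0.1909 log10 min
```

Both size groups lose about one decade of tolerance time per 2.2 °C
(equal *z*), but the large group's curve sits 0.19 log10 units lower:
small subjects last ~55% longer at every assay temperature.

```
Model comparison (AICc, ML fits, n = 270)
       model      fixed_effects k    AICc  dAICc    w acc_w   R2
    additive temperature + size 6 -438.09   0.00 0.74  0.74 0.99
 interaction temperature x size 7 -435.99   2.11 0.26  1.00 0.99
 temperature        temperature 5 -260.15 177.94 0.00  1.00 0.97
```

Dropping size costs ~178 AICc units, while letting size change the slope
(the interaction) buys essentially nothing over the additive elevation
shift — size affects the magnitude of heat tolerance, not its temperature
sensitivity. Step 5 replicates the analysis on fresh synthetic assays and
reports that the pooled *z* is recovered with ~1% median relative error
and the negative elevation shift for large subjects in every replicate.

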