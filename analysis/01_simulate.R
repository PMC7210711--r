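#!/usr/bin/env Rscript
## Step 1: generate the synthetic heat-tolerance assay at the study
## conditions: 6 exposure temperatures (35-40 C), 14 measuring runs, 20
## subjects per run (10 small + 10 large) drawn from 10 culture beakers,
## staggered 3-6 min introduction, latent knock-down times from the thermal
## death time model with beaker/run random intercepts.
##
## Writes the dataset tables (runs.csv, subjects.csv, an empty traces.csv --
## traces are streamed in step 2) plus the latent truth sidecar to
## results/dataset/.

library(heattol)

cfg <- synthetic_config(seed = 1L)
exp <- generate_experiment(cfg)

dir.create("results/dataset", recursive = TRUE, showWarnings = FALSE)
write_dataset(list(runs = exp$runs, subjects = exp$subjects, traces = NULL),
              "results/dataset")
jsonlite::write_json(
  list(config = unclass(cfg), knockdown = exp$knockdown),
  "results/dataset/true_parameters.json", auto_unbox = TRUE, digits = NA)

print(cfg)
print(exp)
cat(sprintf("Latent knock-down spans %.1f min (40 C) to %.0f min (35 C) on average.\n",
            mean(exp$knockdown$t_true_min[
              exp$subjects$run_id %in%
                exp$runs$run_id[exp$runs$temperature_C == 40]]),
            mean(exp$knockdown$t_true_min[
              exp$subjects$run_id %in%
                exp$runs$run_id[exp$runs$temperature_C == 35]])))
cat("Dataset written to results/dataset/\n")
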