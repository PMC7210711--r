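## End-to-end pipeline: simulate -> detect -> fit TDTCs -> compare mixed
## models, plus a replicated parameter-recovery experiment. Traces are
## streamed run by run so the full default assay (35 C runs record for many
## hours at 3 Hz) never has to be held in memory at once.

#' Simulate traces and detect knock-down for a whole experiment
#'
#' For each run, simulates the velocity traces of its subjects (from
#' deterministic per-subject RNG sub-streams) and applies the knock-down
#' detector, without materialising more than one run's traces at a time.
#'
#' @param experiment a [generate_experiment()] result.
#' @param detection a [detection_config()].
#' @param margin_s recording margin beyond the run's last knock-down (s).
#' @param trace_sink optional function called with each run's trace
#'   data.frame (e.g. to append to a CSV); `NULL` to discard traces after
#'   detection.
#' @return a `timm_batch` (see [detect_batch()]) whose `estimates` carry an
#'   extra column `t_true_min` for convenience in recovery studies.
#' @export
detect_experiment <- function(experiment, detection = detection_config(),
                              margin_s = 10, trace_sink = NULL) {
  est <- vector("list", nrow(experiment$runs))
  for (i in seq_len(nrow(experiment$runs))) {
    rid <- experiment$runs$run_id[i]
    tr <- simulate_run_traces(experiment, rid, margin_s = margin_s)
    if (!is.null(trace_sink)) trace_sink(tr)
    subj <- experiment$subjects[experiment$subjects$run_id == rid, ,
                                drop = FALSE]
    ds <- list(runs = experiment$runs, subjects = subj, traces = tr)
    est[[i]] <- detect_batch(ds, detection)$estimates
  }
  estimates <- do.call(rbind, est)
  estimates$t_true_min <- experiment$knockdown$t_true_min[
    match(estimates$subject_id, experiment$knockdown$subject_id)]
  qc <- as.data.frame(table(flag = factor(
    estimates$flag,
    levels = c("ok", "gap_warning", "right_censored", "never_moved"))),
    responseName = "n")
  structure(list(estimates = estimates, qc = qc), class = "timm_batch")
}

#' Merge estimates with metadata into the modelling table
#'
#' @param estimates data.frame with `subject_id` and `timm_min` (unusable
#'   rows dropped when a `usable` column is present).
#' @param subjects,runs metadata tables.
#' @return data.frame with one row per usable subject: `timm_min`,
#'   `temperature_C`, `body_length_mm`, `size_group`, `beaker_id`, `run_id`.
#' @export
modeling_table <- function(estimates, subjects, runs) {
  keep <- intersect(c("subject_id", "timm_min", "usable"), names(estimates))
  d <- merge(estimates[, keep, drop = FALSE], subjects, by = "subject_id")
  d <- merge(d, runs, by = "run_id")
  if ("usable" %in% names(d)) d <- d[d$usable, ]
  d <- d[is.finite(d$timm_min) & d$timm_min > 0, ]
  d[, c("subject_id", "timm_min", "temperature_C", "body_length_mm",
        "size_group", "beaker_id", "run_id")]
}

#' Run the full knock-down analysis pipeline
#'
#' Simulates an experiment (or accepts one), streams trace simulation and
#' knock-down detection, fits thermal death time curves by size group, fits
#' and compares the three candidate mixed models, and writes all outputs to
#' a directory: `runs.csv`, `subjects.csv`, `estimates.csv`,
#' `tdtc_fits.csv`, `model_comparison.csv`, `true_parameters.json` (latent
#' truth, for testing only), `manifest.json` and `run_log.txt`. Every
#' artefact records the seed and a hash of the configuration, so a rerun
#' with the same seed is byte-identical.
#'
#' @param synthetic a [synthetic_config()].
#' @param detection a [detection_config()].
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param experiment optionally, a pre-generated [generate_experiment()]
#'   result (its config must match `synthetic`).
#' @param write_traces if `TRUE`, also stream the full trace table to
#'   `traces.csv` (large for the default assay).
#' @param margin_s recording margin (s).
#' @param verbose print stage progress.
#' @return invisibly, list of class `heattol_pipeline`: `experiment`,
#'   `detection` (`timm_batch`), `tdtc` (`tdtc_by_group`), `fits`,
#'   `comparison`, `config_hash`, `out_dir`.
#' @export
run_pipeline <- function(synthetic = synthetic_config(),
                         detection = detection_config(),
                         out_dir = NULL,
                         experiment = NULL,
                         write_traces = FALSE,
                         margin_s = 10,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(format(Sys.time(),
                                                   "%Y-%m-%dT%H:%M:%S "),
                                            sprintf(...))
  hash <- config_hash(list(synthetic = unclass(synthetic),
                           detection = unclass(detection)))
  stage <- "simulate"
  result <- tryCatch({
    say("[simulate] generating experiment (seed %d)", synthetic$seed)
    if (is.null(experiment)) experiment <- generate_experiment(synthetic)

    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_dataset(list(runs = experiment$runs,
                         subjects = experiment$subjects, traces = NULL),
                    out_dir)
      jsonlite::write_json(
        list(config = unclass(synthetic), config_hash = hash,
             knockdown = experiment$knockdown),
        file.path(out_dir, "true_parameters.json"),
        auto_unbox = TRUE, digits = NA)
    }

    stage <- "detect"
    say("[detect] simulating traces and detecting knock-down (%d subjects)",
        nrow(experiment$subjects))
    sink_fun <- NULL
    if (!is.null(out_dir) && write_traces) {
      trace_path <- file.path(out_dir, "traces.csv")
      cat("subject_id,run_id,well_id,sample_time_s,velocity_mm_s\n",
          file = trace_path)
      sink_fun <- function(tr) {
        tr$sample_time_s <- sprintf("%.6f", tr$sample_time_s)
        tr$velocity_mm_s <- sprintf("%.7g", tr$velocity_mm_s)
        write.table(tr, trace_path, sep = ",", row.names = FALSE,
                    col.names = FALSE, quote = FALSE, append = TRUE)
      }
    }
    det <- detect_experiment(experiment, detection, margin_s = margin_s,
                             trace_sink = sink_fun)
    say("[detect] %d usable of %d estimates", sum(det$estimates$usable),
        nrow(det$estimates))

    stage <- "fit"
    say("[fit] thermal death time curves by size group")
    curves <- fit_tdtc_by_group(det$estimates, experiment$subjects,
                                experiment$runs)

    stage <- "compare"
    say("[compare] fitting candidate mixed models (ML)")
    mtab <- modeling_table(det$estimates, experiment$subjects,
                           experiment$runs)
    fits <- lapply(c("interaction", "additive", "temperature"),
                   function(m) fit_lmm(mtab, lmm_spec(m)))
    names(fits) <- vapply(fits, function(f) f$spec$fixed, character(1))
    comparison <- compare_models(fits)

    if (!is.null(out_dir)) {
      est <- det$estimates
      est$timm_min <- ifelse(is.na(est$timm_min), "",
                             sprintf("%.6f", est$timm_min))
      write.csv(est[, c("subject_id", "run_id", "timm_min", "flag",
                        "usable")],
                file.path(out_dir, "estimates.csv"), row.names = FALSE,
                quote = FALSE)
      write.csv(tdtc_table(curves), file.path(out_dir, "tdtc_fits.csv"),
                row.names = FALSE, quote = FALSE)
      write.csv(as.data.frame(comparison),
                file.path(out_dir, "model_comparison.csv"),
                row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(config_hash = hash, seed = synthetic$seed,
             package_version = as.character(packageVersion("heattol")),
             files = c("runs.csv", "subjects.csv", "estimates.csv",
                       "tdtc_fits.csv", "model_comparison.csv")),
        file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
      qc_lines <- sprintf("  %-14s %d", det$qc$flag, det$qc$n)
      writeLines(c(
        sprintf("heattol pipeline run"),
        sprintf("seed: %d", synthetic$seed),
        sprintf("config_hash: %s", hash),
        sprintf("package_version: %s",
                as.character(packageVersion("heattol"))),
        sprintf("subjects: %d", nrow(experiment$subjects)),
        "qc flag counts:", qc_lines,
        sprintf("modeled observations: %d", nrow(mtab))),
        file.path(out_dir, "run_log.txt"))
    }
    say("[done] top model: %s (w = %.2f)", comparison$fixed_effects[1],
        comparison$w[1])
    list(experiment = experiment, detection = det, tdtc = curves,
         fits = fits, comparison = comparison, modeled_n = nrow(mtab),
         config_hash = hash, out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  class(result) <- "heattol_pipeline"
  invisible(result)
}

#' Check that a dataset directory matches a configuration
#'
#' Compares the `config_hash` recorded in a pipeline output directory's
#' `manifest.json` with the hash of the supplied configuration; refuses
#' mismatched inputs.
#'
#' @param out_dir a directory written by [run_pipeline()].
#' @param synthetic,detection the configurations expected to have produced
#'   it.
#' @return invisibly `TRUE`, or an error naming both hashes.
#' @export
check_manifest <- function(out_dir, synthetic, detection = detection_config()) {
  path <- file.path(out_dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", out_dir)
  manifest <- jsonlite::read_json(path)
  expected <- config_hash(list(synthetic = unclass(synthetic),
                               detection = unclass(detection)))
  if (!identical(manifest$config_hash, expected))
    stop(sprintf(
      "configuration mismatch: directory written under %s, supplied config hashes to %s",
      manifest$config_hash, expected))
  invisible(TRUE)
}

#' Replicated parameter-recovery experiment
#'
#' Repeats the analysis on independently generated synthetic experiments and
#' compares estimates with the generating truth: the pooled temperature
#' sensitivity coefficient z (common-slope TDTC), the elevation difference
#' between size groups, the mixed-model fixed effects (with +/- 2 SE
#' coverage of the temperature effect), and which candidate model AICc
#' ranks first. By default models are fitted to the generated knock-down
#' times directly; `use_detection = TRUE` runs trace simulation and the
#' detector per replicate instead (the detector's error is bounded by one
#' sampling interval, but traces of a full default assay are long, so this
#' is intended for reduced configurations).
#'
#' @param synthetic a [synthetic_config()]; replicate r uses a seed derived
#'   deterministically from `synthetic$seed` and r.
#' @param n_replicates number of replicate experiments (>= 2).
#' @param models which candidate models to fit each replicate.
#' @param use_detection run the trace/detection stage per replicate.
#' @param detection a [detection_config()] (only used with detection).
#' @return list of class `recovery_report`: `replicates` (one row per
#'   replicate) and `summary` (bias, RMSE, median relative error of z,
#'   coverage, sign-recovery and model-ranking proportions).
#' @export
recovery_experiment <- function(synthetic = synthetic_config(),
                                n_replicates = 100,
                                models = c("interaction", "additive",
                                           "temperature"),
                                use_detection = FALSE,
                                detection = detection_config()) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  models <- match.arg(models, several.ok = TRUE)
  s_bar <- (synthetic$size_small$mean + synthetic$size_large$mean) / 2
  slope_true <- synthetic$beta_T + synthetic$beta_TS * s_bar
  z_true <- -1 / slope_true
  elev_true <- (synthetic$beta_S + synthetic$beta_TS *
                  mean(synthetic$temperatures)) *
    (synthetic$size_large$mean - synthetic$size_small$mean)

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- synthetic
    cfg$seed <- substream_seed(synthetic$seed, 3L, r)
    exp_r <- generate_experiment(cfg)
    if (use_detection) {
      est <- detect_experiment(exp_r, detection)$estimates
    } else {
      est <- data.frame(subject_id = exp_r$knockdown$subject_id,
                        timm_min = exp_r$knockdown$t_true_min,
                        stringsAsFactors = FALSE)
    }
    curves <- fit_tdtc_by_group(est, exp_r$subjects, exp_r$runs)
    mtab <- modeling_table(est, exp_r$subjects, exp_r$runs)
    fits <- lapply(models, function(m) fit_lmm(mtab, lmm_spec(m)))
    names(fits) <- models
    cmp <- if (length(fits) > 1L) compare_models(fits) else NULL

    ref <- if ("additive" %in% models) fits[["additive"]] else fits[[1]]
    bT <- unname(ref$beta_centered["Tc"])
    seT <- unname(ref$se_centered[which(names(ref$beta_centered) == "Tc")])
    bS <- if ("S" %in% names(ref$beta_centered))
      unname(ref$beta_centered["S"]) else NA_real_

    rows[[r]] <- data.frame(
      replicate = r,
      z_hat = curves$pooled_z_C,
      elev_diff_hat = if (!is.null(curves$elevation_diff))
        unname(curves$elevation_diff[1]) else NA_real_,
      beta_T_hat = bT, beta_T_se = seT, beta_S_hat = bS,
      beta_T_covered = abs(bT - slope_true) <= 2 * seT,
      top_model = if (!is.null(cmp)) cmp$model[1] else models[1],
      dAICc_additive = if (!is.null(cmp) && "additive" %in% cmp$model)
        cmp$dAICc[cmp$model == "additive"] else NA_real_,
      dAICc_interaction = if (!is.null(cmp) && "interaction" %in% cmp$model)
        cmp$dAICc[cmp$model == "interaction"] else NA_real_,
      n_modeled = nrow(mtab))
  }
  reps <- do.call(rbind, rows)
  z_rel_err <- abs(reps$z_hat - z_true) / z_true
  summary <- data.frame(
    n_replicates = n_replicates,
    z_true = z_true,
    z_median_rel_err = stats::median(z_rel_err),
    z_bias = mean(reps$z_hat) - z_true,
    z_rmse = sqrt(mean((reps$z_hat - z_true)^2)),
    beta_T_bias = mean(reps$beta_T_hat) - slope_true,
    beta_T_rmse = sqrt(mean((reps$beta_T_hat - slope_true)^2)),
    beta_T_coverage = mean(reps$beta_T_covered),
    elev_true = elev_true,
    elev_sign_recovered = mean(sign(reps$elev_diff_hat) == sign(elev_true)),
    prop_top_interaction = mean(reps$top_model == "interaction"),
    prop_top_additive = mean(reps$top_model == "additive"),
    prop_additive_within_2 = mean(reps$dAICc_additive < 2, na.rm = TRUE))
  structure(list(replicates = reps, summary = summary,
                 config = synthetic),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Parameter recovery over %d replicate experiments\n",
              s$n_replicates))
  cat(sprintf("  z: true %.3f, median rel. error %.3f, bias %+.4f, RMSE %.4f\n",
              s$z_true, s$z_median_rel_err, s$z_bias, s$z_rmse))
  cat(sprintf("  beta_T: bias %+.5f, RMSE %.5f, +/-2SE coverage %.2f\n",
              s$beta_T_bias, s$beta_T_rmse, s$beta_T_coverage))
  cat(sprintf("  elevation shift (large - small): true %+.4f, sign recovered %.2f\n",
              s$elev_true, s$elev_sign_recovered))
  cat(sprintf("  top-ranked: interaction %.2f, additive %.2f; additive within dAICc<2: %.2f\n",
              s$prop_top_interaction, s$prop_top_additive,
              s$prop_additive_within_2))
  invisible(x)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Builds the synthetic and detection configurations from a plain config
#' file; unknown keys are rejected.
#'
#' @param path a `.yaml`/`.yml` or `.json` file with optional top-level
#'   sections `synthetic` and `detection`.
#' @return list with elements `synthetic` ([synthetic_config()]) and
#'   `detection` ([detection_config()]).
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  syn_args <- raw$synthetic
  det_args <- raw$detection
  bad <- setdiff(names(syn_args), names(formals(synthetic_config)))
  if (length(bad)) stop("unknown synthetic config key(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(names(det_args), names(formals(detection_config)))
  if (length(bad)) stop("unknown detection config key(s): ",
                        paste(bad, collapse = ", "))
  list(synthetic = do.call(synthetic_config, as.list(syn_args)),
       detection = do.call(detection_config, as.list(det_args)))
}
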