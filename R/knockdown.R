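#' Detection settings for time to immobilisation
#'
#' @param velocity_threshold_mm_s swimming-velocity threshold (mm/s); the
#'   knock-down time is the last time the subject is observed above it.
#' @param min_bout_samples number of consecutive supra-threshold samples
#'   required for a crossing to count as movement (1 = a single sample).
#' @param max_gap_s sampling gap (s) above which the estimate is flagged
#'   `gap_warning`.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(velocity_threshold_mm_s = 1.0,
                             min_bout_samples = 1L,
                             max_gap_s = 2.0) {
  if (velocity_threshold_mm_s <= 0) stop("velocity threshold must be > 0")
  if (min_bout_samples < 1L) stop("min_bout_samples must be >= 1")
  structure(list(velocity_threshold_mm_s = velocity_threshold_mm_s,
                 min_bout_samples = as.integer(min_bout_samples),
                 max_gap_s = max_gap_s),
            class = "detection_config")
}

#' Estimate time to immobilisation from a velocity trace
#'
#' Implements the knock-down detector: the time from a subject's introduction
#' into its well until its swimming velocity is last observed above a
#' threshold. On the trace (recording clock) the detector finds the last
#' sample that begins a run of at least `min_bout_samples` consecutive
#' samples with velocity strictly above the threshold; the estimate is
#' `(intro_offset_s + that sample's time) / 60` minutes.
#'
#' Flags: `never_moved` when no sample qualifies (no estimate is returned,
#' mirroring subjects whose knock-down time cannot be estimated);
#' `right_censored` when the trace ends while the subject still qualifies
#' (movement may continue past recording end); `gap_warning` when any
#' inter-sample gap exceeds `max_gap_s`; `ok` otherwise.
#'
#' @param trace data.frame with `sample_time_s` and `velocity_mm_s`; rows are
#'   sorted by time internally.
#' @param intro_offset_s seconds before recording start at which the subject
#'   was introduced.
#' @param config a [detection_config()].
#' @return list of class `timm_estimate`: `timm_min` (NA when `never_moved`),
#'   `flag`, `last_supra_time_s`, `n_samples`.
#' @export
estimate_timm <- function(trace, intro_offset_s,
                          config = detection_config()) {
  if (is.null(trace) || nrow(trace) == 0L)
    stop("empty trace: no samples to analyse")
  if (intro_offset_s < 0) stop("intro_offset_s must be >= 0")
  ord <- order(trace$sample_time_s)
  times <- trace$sample_time_s[ord]
  vel <- trace$velocity_mm_s[ord]
  if (any(diff(times) <= 0))
    stop("sample times must be strictly increasing")
  n <- length(times)
  m <- config$min_bout_samples
  supra <- vel > config$velocity_threshold_mm_s

  flag <- "ok"
  gap <- n > 1L && any(diff(times) > config$max_gap_s)

  if (m == 1L) {
    qual_last <- if (any(supra)) max(which(supra)) else NA_integer_
  } else if (n < m) {
    qual_last <- NA_integer_
  } else {
    cs <- cumsum(c(0L, as.integer(supra)))
    starts <- which((cs[(m + 1L):(n + 1L)] - cs[1:(n - m + 1L)]) == m)
    qual_last <- if (length(starts)) max(starts) else NA_integer_
  }

  if (is.na(qual_last)) {
    return(structure(list(timm_min = NA_real_, flag = "never_moved",
                          last_supra_time_s = NA_real_, n_samples = n),
                     class = "timm_estimate"))
  }
  if (n >= m && all(supra[(n - m + 1L):n])) {
    flag <- "right_censored"
  } else if (gap) {
    flag <- "gap_warning"
  }
  t_last <- times[qual_last]
  structure(list(timm_min = (intro_offset_s + t_last) / 60,
                 flag = flag,
                 last_supra_time_s = t_last,
                 n_samples = n),
            class = "timm_estimate")
}

#' @export
print.timm_estimate <- function(x, ...) {
  if (is.na(x$timm_min)) {
    cat(sprintf("T_imm: not estimable (%s; %d samples)\n", x$flag,
                x$n_samples))
  } else {
    cat(sprintf("T_imm = %.3f min [%s] (last supra-threshold sample at %.3f s, %d samples)\n",
                x$timm_min, x$flag, x$last_supra_time_s, x$n_samples))
  }
  invisible(x)
}

#' Detect knock-down times for every subject of a dataset
#'
#' Applies [estimate_timm()] per subject of a validated dataset and returns
#' the estimate table together with a QC report. Subjects flagged
#' `never_moved` carry no estimate and are excluded from downstream model
#' input; `right_censored` estimates are reported but marked unusable by
#' default (a faithfully filmed assay ends only when all subjects are
#' motionless).
#'
#' @param dataset list with `runs`, `subjects`, `traces` (see
#'   [read_dataset()]).
#' @param config a [detection_config()].
#' @return list of class `timm_batch`: `estimates` (data.frame `subject_id`,
#'   `run_id`, `timm_min`, `flag`, `usable`) and `qc` (data.frame of counts
#'   per flag).
#' @export
detect_batch <- function(dataset, config = detection_config()) {
  subj <- dataset$subjects
  tr <- dataset$traces
  missing_traces <- setdiff(subj$subject_id, unique(tr$subject_id))
  if (length(missing_traces))
    stop("no trace data for subject(s): ",
         paste(utils::head(missing_traces, 5L), collapse = ", "))
  pieces <- split(seq_len(nrow(tr)), tr$subject_id)
  est <- lapply(seq_len(nrow(subj)), function(i) {
    rows <- pieces[[subj$subject_id[i]]]
    e <- estimate_timm(tr[rows, c("sample_time_s", "velocity_mm_s")],
                       subj$intro_offset_s[i], config)
    data.frame(subject_id = subj$subject_id[i],
               run_id = subj$run_id[i],
               timm_min = e$timm_min,
               flag = e$flag,
               stringsAsFactors = FALSE)
  })
  estimates <- do.call(rbind, est)
  estimates$usable <- estimates$flag %in% c("ok", "gap_warning")
  qc <- as.data.frame(table(flag = factor(
    estimates$flag,
    levels = c("ok", "gap_warning", "right_censored", "never_moved"))),
    responseName = "n")
  structure(list(estimates = estimates, qc = qc), class = "timm_batch")
}

#' @export
print.timm_batch <- function(x, ...) {
  cat(sprintf("Knock-down detection: %d subjects, %d usable estimates\n",
              nrow(x$estimates), sum(x$estimates$usable)))
  print(x$qc, row.names = FALSE)
  invisible(x)
}
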