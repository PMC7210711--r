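## Dataset I/O: a fixed three-file CSV dialect emulating tracking-software
## exports. Times are on the recording clock; the introduction offset lives
## only in the subject table.

.heattol_cols <- list(
  runs = c("run_id", "temperature_C", "label"),
  subjects = c("subject_id", "run_id", "beaker_id", "size_group",
               "body_length_mm", "intro_offset_s"),
  traces = c("subject_id", "run_id", "well_id", "sample_time_s",
             "velocity_mm_s")
)

.heattol_classes <- list(
  runs = c(run_id = "character", temperature_C = "numeric",
           label = "character"),
  subjects = c(subject_id = "character", run_id = "character",
               beaker_id = "character", size_group = "character",
               body_length_mm = "numeric", intro_offset_s = "numeric"),
  traces = c(subject_id = "character", run_id = "character",
             well_id = "character", sample_time_s = "numeric",
             velocity_mm_s = "numeric")
)

#' Write a knock-down dataset to CSV files
#'
#' Writes `runs.csv`, `subjects.csv` and `traces.csv` in the package's fixed
#' dialect: UTF-8, header row, `.` decimal separator. Sample times are printed
#' with 6 decimals (preserving 1/3-s sampling) and velocities with 7
#' significant digits; row order is deterministic (`run_id`, `subject_id`,
#' `sample_time_s`).
#'
#' @param dataset list with data.frames `runs`, `subjects`, `traces` (the
#'   latter may be `NULL` to write an empty trace table).
#' @param dir output directory, created if needed.
#' @return invisibly, a named character vector of the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  runs <- dataset$runs[order(dataset$runs$run_id), .heattol_cols$runs,
                       drop = FALSE]
  subj <- dataset$subjects
  subj <- subj[order(subj$run_id, subj$subject_id), .heattol_cols$subjects,
               drop = FALSE]
  tr <- dataset$traces
  if (is.null(tr))
    tr <- data.frame(subject_id = character(), run_id = character(),
                     well_id = character(), sample_time_s = numeric(),
                     velocity_mm_s = numeric())
  tr <- tr[order(tr$run_id, tr$subject_id, tr$sample_time_s),
           .heattol_cols$traces, drop = FALSE]

  fmt <- function(df, numfmt) {
    for (nm in names(numfmt)) df[[nm]] <- sprintf(numfmt[[nm]], df[[nm]])
    df
  }
  runs_out <- fmt(runs, c(temperature_C = "%.6g"))
  subj_out <- fmt(subj, c(body_length_mm = "%.7g", intro_offset_s = "%.6f"))
  tr_out <- fmt(tr, c(sample_time_s = "%.6f", velocity_mm_s = "%.7g"))

  paths <- c(runs = file.path(dir, "runs.csv"),
             subjects = file.path(dir, "subjects.csv"),
             traces = file.path(dir, "traces.csv"))
  tryCatch({
    write.csv(runs_out, paths[["runs"]], row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
    write.csv(subj_out, paths[["subjects"]], row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
    write.csv(tr_out, paths[["traces"]], row.names = FALSE, quote = FALSE,
              fileEncoding = "UTF-8")
  }, error = function(e) stop("I/O error writing dataset: ",
                              conditionMessage(e)))
  invisible(paths)
}

read_table_checked <- function(path, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- names(read.csv(path, nrows = 0, check.names = FALSE))
  expected <- .heattol_cols[[what]]
  missing <- setdiff(expected, header)
  if (length(missing))
    stop(sprintf("format error in %s: missing column(s): %s",
                 basename(path), paste(missing, collapse = ", ")))
  df <- read.csv(path, colClasses = .heattol_classes[[what]][header],
                 check.names = FALSE, fileEncoding = "UTF-8")
  df[, expected, drop = FALSE]
}

#' Read a knock-down dataset from CSV files
#'
#' Reads the three tables of the dialect (see [write_dataset()]), types the
#' columns and validates cross-references and invariants via
#' [validate_dataset()].
#'
#' @param dir directory containing `runs.csv`, `subjects.csv`, `traces.csv`,
#'   or a named character vector of paths with names `runs`, `subjects`,
#'   `traces`.
#' @param temperature_range declared assay temperature range (degrees C) used
#'   by validation.
#' @return list with data.frames `runs`, `subjects`, `traces`.
#' @export
read_dataset <- function(dir, temperature_range = c(35, 40)) {
  if (length(dir) == 1L && is.null(names(dir))) {
    paths <- c(runs = file.path(dir, "runs.csv"),
               subjects = file.path(dir, "subjects.csv"),
               traces = file.path(dir, "traces.csv"))
  } else paths <- dir
  ds <- list(runs = read_table_checked(paths[["runs"]], "runs"),
             subjects = read_table_checked(paths[["subjects"]], "subjects"),
             traces = read_table_checked(paths[["traces"]], "traces"))
  validate_dataset(ds, temperature_range = temperature_range)
  ds
}

#' Validate a knock-down dataset
#'
#' Checks referential integrity (every trace subject exists in the subject
#' table, every subject's run exists in the run table, trace/subject run ids
#' agree) and the type invariants: finite nonnegative velocities, strictly
#' increasing sample times per subject, positive body lengths, nonnegative
#' introduction offsets, temperatures within the declared assay range, and
#' size-group labels in `{small, large}`. Optionally checks body lengths
#' against declared per-group ranges.
#'
#' @param dataset list with `runs`, `subjects`, `traces`.
#' @param temperature_range numeric length-2 declared range, or `NULL` to
#'   skip.
#' @param size_ranges optional list with elements `small` and `large`, each a
#'   length-2 range in mm, for strict size-group validation.
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_dataset <- function(dataset, temperature_range = c(35, 40),
                             size_ranges = NULL) {
  runs <- dataset$runs; subj <- dataset$subjects; tr <- dataset$traces
  name_some <- function(x) paste(utils::head(unique(x), 5L), collapse = ", ")

  orphan_subj <- setdiff(tr$subject_id, subj$subject_id)
  if (length(orphan_subj))
    stop("integrity error: trace rows reference unknown subject(s): ",
         name_some(orphan_subj))
  orphan_run <- setdiff(subj$run_id, runs$run_id)
  if (length(orphan_run))
    stop("integrity error: subjects reference unknown run(s): ",
         name_some(orphan_run))
  if (nrow(tr)) {
    sr <- subj$run_id[match(tr$subject_id, subj$subject_id)]
    bad <- tr$subject_id[sr != tr$run_id]
    if (length(bad))
      stop("integrity error: trace run_id disagrees with subject table for: ",
           name_some(bad))
    if (any(!is.finite(tr$velocity_mm_s) | tr$velocity_mm_s < 0)) {
      row <- which(!is.finite(tr$velocity_mm_s) | tr$velocity_mm_s < 0)[1]
      stop(sprintf("invalid velocity at traces row %d (subject %s): %s",
                   row, tr$subject_id[row], tr$velocity_mm_s[row]))
    }
    ord <- order(tr$subject_id, tr$sample_time_s)
    ts <- tr$sample_time_s[ord]; ss <- tr$subject_id[ord]
    dup <- which(diff(ts) <= 0 & ss[-length(ss)] == ss[-1])
    if (length(dup))
      stop("invalid trace: sample times not strictly increasing for subject ",
           ss[dup[1]])
    if (any(tr$sample_time_s < 0)) {
      row <- which(tr$sample_time_s < 0)[1]
      stop(sprintf("invalid sample time at traces row %d (subject %s)",
                   row, tr$subject_id[row]))
    }
  }
  if (any(subj$body_length_mm <= 0))
    stop("invalid body length for subject(s): ",
         name_some(subj$subject_id[subj$body_length_mm <= 0]))
  if (any(subj$intro_offset_s < 0))
    stop("invalid introduction offset for subject(s): ",
         name_some(subj$subject_id[subj$intro_offset_s < 0]))
  if (!all(subj$size_group %in% c("small", "large")))
    stop("invalid size_group for subject(s): ",
         name_some(subj$subject_id[!subj$size_group %in% c("small", "large")]))
  if (!is.null(temperature_range)) {
    bad <- runs$temperature_C < temperature_range[1] |
      runs$temperature_C > temperature_range[2]
    if (any(bad))
      stop("temperature outside declared assay range for run(s): ",
           name_some(runs$run_id[bad]))
  }
  if (!is.null(size_ranges)) {
    for (g in c("small", "large")) {
      s <- subj[subj$size_group == g, ]
      bad <- s$body_length_mm < size_ranges[[g]][1] |
        s$body_length_mm > size_ranges[[g]][2]
      if (any(bad))
        stop(sprintf("body length outside the %s-group range for subject(s): %s",
                     g, name_some(s$subject_id[bad])))
    }
  }
  invisible(TRUE)
}
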