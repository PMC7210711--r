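#' Fit a thermal death time curve
#'
#' Ordinary least-squares regression of `log10(knock-down time, min)` on
#' exposure temperature. The fitted line is summarised by the temperature
#' sensitivity coefficient `z = -1/slope` (degrees C; a high `z` means low
#' sensitivity) and the extrapolated upper thermal limit
#' `CTmax = -intercept/slope`, the temperature at which `log10 t = 0`
#' (knock-down in 1 minute). A nonnegative slope yields a fit with `z` and
#' `CTmax` marked invalid (`NA`).
#'
#' @param temperature_C exposure temperatures (degrees C), at least two
#'   distinct values.
#' @param timm_min knock-down times in minutes, all > 0.
#' @param group_label label carried on the fit (e.g. a size group).
#' @return object of class `tdtc_fit`: `slope`, `intercept`, `z_C`,
#'   `ctmax_C`, `valid`, `n_points`, `group_label`, `temperature_range`,
#'   `ctmax_extrapolated` (TRUE when CTmax lies outside the observed
#'   temperature range).
#' @export
fit_tdtc <- function(temperature_C, timm_min, group_label = "all") {
  if (length(temperature_C) != length(timm_min))
    stop("temperature_C and timm_min must have equal length")
  if (any(!is.finite(timm_min)) || any(timm_min <= 0))
    stop("all knock-down times must be finite and > 0")
  if (length(unique(temperature_C)) < 2L)
    stop("at least two distinct temperatures are required")
  fit <- lm(y ~ x, data = data.frame(x = temperature_C, y = log10(timm_min)))
  b <- unname(coef(fit))
  intercept <- b[1]; slope <- b[2]
  # a slope within rounding error of zero is treated as flat, not negative
  valid <- is.finite(slope) && slope < -1e-12
  z <- if (valid) -1 / slope else NA_real_
  ctmax <- if (valid) -intercept / slope else NA_real_
  rng <- range(temperature_C)
  structure(list(slope = slope, intercept = intercept,
                 z_C = z, ctmax_C = ctmax, valid = valid,
                 n_points = length(timm_min), group_label = group_label,
                 temperature_range = rng,
                 ctmax_extrapolated = valid &&
                   (ctmax < rng[1] || ctmax > rng[2])),
            class = "tdtc_fit")
}

#' @export
print.tdtc_fit <- function(x, ...) {
  cat(sprintf("Thermal death time curve [%s], n = %d\n", x$group_label,
              x$n_points))
  cat(sprintf("  log10 t(min) = %.4f %+.4f * T\n", x$intercept, x$slope))
  if (x$valid) {
    cat(sprintf("  z = %.3f C, CTmax = %.2f C%s\n", x$z_C, x$ctmax_C,
                if (x$ctmax_extrapolated)
                  sprintf(" (extrapolated beyond %g-%g C)",
                          x$temperature_range[1], x$temperature_range[2])
                else ""))
  } else {
    cat("  slope is not negative: z and CTmax invalid\n")
  }
  invisible(x)
}

#' Predict knock-down time from a thermal death time curve
#'
#' Evaluates `t = 10^((CTmax - T)/z)` minutes, identical to
#' `10^(intercept + slope * T)`.
#'
#' @param fit a valid [fit_tdtc()] result.
#' @param temperature_C temperatures (degrees C) at which to predict.
#' @return predicted knock-down times in minutes.
#' @export
predict_time <- function(fit, temperature_C) {
  if (!inherits(fit, "tdtc_fit")) stop("fit must be a tdtc_fit")
  if (!fit$valid)
    stop("cannot predict from an invalid fit (nonnegative slope)")
  10^((fit$ctmax_C - temperature_C) / fit$z_C)
}

#' Fit thermal death time curves by group
#'
#' Merges knock-down estimates with subject and run metadata, fits one curve
#' per level of a grouping column (skipping, with a warning, groups observed
#' at fewer than two temperatures), and additionally fits a common-slope
#' model `log10 t ~ temperature + group` from which the elevation difference
#' between groups (vertical shift of the curve, log10 minutes) and a pooled
#' `z` are derived.
#'
#' @param estimates data.frame with `subject_id`, `timm_min` (e.g. the
#'   `estimates` element of [detect_batch()]; rows with `usable == FALSE` or
#'   missing `timm_min` are dropped).
#' @param subjects,runs metadata tables as in [read_dataset()].
#' @param group name of the grouping column in `subjects` (default
#'   `"size_group"`).
#' @return list of class `tdtc_by_group`: `fits` (named list of `tdtc_fit`),
#'   `pooled` (common-slope `tdtc_fit` ignoring group), `pooled_z_C`,
#'   `elevation_diff` (named vector of intercept shifts relative to the first
#'   group level), `data` (the merged modelling table).
#' @export
fit_tdtc_by_group <- function(estimates, subjects, runs,
                              group = "size_group") {
  if (!group %in% names(subjects))
    stop("grouping column not found in subjects: ", group)
  d <- merge(estimates, subjects, by = "subject_id",
             suffixes = c("", ".subj"))
  d <- merge(d, runs, by = "run_id")
  if ("usable" %in% names(d)) d <- d[d$usable, ]
  d <- d[is.finite(d$timm_min) & d$timm_min > 0, ]
  if (!nrow(d)) stop("no usable knock-down estimates to fit")

  levels_g <- sort(unique(d[[group]]))
  # put "small" first when grouping by size so the elevation shift reads
  # "large minus small"
  if (identical(group, "size_group"))
    levels_g <- intersect(c("small", "large"), levels_g)
  fits <- list()
  for (g in levels_g) {
    dg <- d[d[[group]] == g, ]
    if (length(unique(dg$temperature_C)) < 2L) {
      warning("group '", g, "' observed at fewer than two temperatures; ",
              "skipped")
      next
    }
    fits[[g]] <- fit_tdtc(dg$temperature_C, dg$timm_min, group_label = g)
  }

  pooled <- fit_tdtc(d$temperature_C, d$timm_min, group_label = "pooled")
  elevation <- NULL
  if (length(levels_g) > 1L) {
    gf <- factor(d[[group]], levels = levels_g)
    cs <- lm(log10(timm_min) ~ temperature_C + gf, data = d)
    b <- coef(cs)
    elevation <- setNames(unname(b[-(1:2)]),
                          paste0(levels_g[-1], " - ", levels_g[1]))
    pooled_slope <- unname(b["temperature_C"])
    pooled_z <- if (pooled_slope < 0) -1 / pooled_slope else NA_real_
  } else {
    pooled_z <- pooled$z_C
  }
  structure(list(fits = fits, pooled = pooled,
                 pooled_z_C = if (length(levels_g) > 1L) pooled_z
                              else pooled$z_C,
                 elevation_diff = elevation, data = d),
            class = "tdtc_by_group")
}

#' @export
print.tdtc_by_group <- function(x, ...) {
  for (f in x$fits) print(f)
  cat(sprintf("Pooled (common-slope) z = %.3f C\n", x$pooled_z_C))
  if (!is.null(x$elevation_diff)) {
    for (nm in names(x$elevation_diff))
      cat(sprintf("  elevation shift %s: %+.4f log10 min\n", nm,
                  x$elevation_diff[[nm]]))
  }
  invisible(x)
}

#' Tidy a set of group-wise TDTC fits
#'
#' @param x a [fit_tdtc_by_group()] result.
#' @return data.frame with one row per fit (groups plus pooled).
#' @export
tdtc_table <- function(x) {
  rows <- c(x$fits, list(pooled = x$pooled))
  do.call(rbind, lapply(rows, function(f)
    data.frame(group = f$group_label, n = f$n_points, slope = f$slope,
               intercept = f$intercept, z_C = f$z_C, ctmax_C = f$ctmax_C,
               stringsAsFactors = FALSE)))
}
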