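#' Configuration for a synthetic knock-down experiment
#'
#' Defines the design and generating parameters of a simulated static
#' heat-tolerance assay: a set of exposure temperatures with one or more
#' measuring runs each, a fixed number of subjects per run drawn from two
#' visually distinct body-size groups and from a pool of culture beakers,
#' staggered introduction into the filming wells, and latent knock-down
#' times following the thermal death time model
#' `log10 t = beta0 + beta_T*T + beta_S*S + beta_TS*T*S + u_beaker + u_run + eps`
#' with `t` in minutes, `T` in degrees C and body size `S` in mm.
#'
#' Defaults reproduce the structure of a 6-temperature (35-40 C), 14-run,
#' 280-subject assay with 10 source beakers, 20 subjects per run (10 small +
#' 10 large), a 3-6 minute introduction window and 3 Hz velocity sampling.
#' `beta_T = -0.45` gives a temperature sensitivity coefficient
#' `z = -1/beta_T ~ 2.2` C, and `beta0` places a mean-size small subject at
#' `log10 t = 0.7` (about 5 min) at 40 C and about 15 h at 35 C.
#'
#' @param temperatures exposure temperatures in degrees C.
#' @param runs_per_temperature number of measuring runs at each temperature
#'   (same length as `temperatures`).
#' @param subjects_per_run subjects recorded simultaneously in one run; must
#'   be even (half per size group).
#' @param n_beakers number of source culture beakers.
#' @param beta0 intercept of the latent model, log10 minutes at `T = 0`,
#'   `S = 0`.
#' @param beta_T temperature effect, log10 minutes per degree C; must be
#'   negative (knock-down is faster when hotter).
#' @param beta_S body-size effect, log10 minutes per mm.
#' @param beta_TS temperature-by-size interaction, log10 minutes per (C mm).
#' @param sigma_beaker,sigma_run,sigma_resid standard deviations of the
#'   beaker random intercept, run random intercept and residual, on the
#'   log10-minutes scale.
#' @param size_small,size_large lists with elements `mean`, `sd`, `range`
#'   (mm) describing the truncated-normal body-size distribution of each
#'   group; the two ranges must not overlap.
#' @param intro_window_s range (seconds) of the total time taken to introduce
#'   all subjects of a run; recording starts when the last subject is in.
#' @param sample_rate_hz velocity sampling rate of the tracking export.
#' @param active_speed_meanlog,active_speed_sdlog lognormal parameters of
#'   swimming speed (mm/s) during move bouts; the default median is 5 mm/s.
#' @param move_bout_mean_s,pause_bout_mean_s mean durations (s) of the
#'   exponential move and pause bouts of the active-swimming process.
#' @param final_active_s length (s) of the guaranteed move bout immediately
#'   before the knock-down instant (terminal agitation), so the last
#'   supra-threshold sample falls within one sampling interval of the latent
#'   knock-down time.
#' @param jitter_max_frac post-knock-down (and pause-bout) tracking jitter is
#'   uniform on `[0, jitter_max_frac * velocity_threshold_mm_s]`.
#' @param velocity_threshold_mm_s detection threshold context the trace
#'   process is calibrated around (mm/s).
#' @param seed master integer seed; all randomness derives from it.
#' @return an object of class `synthetic_config` (a validated list).
#' @seealso [generate_experiment()], [simulate_trace()]
#' @export
synthetic_config <- function(temperatures = 35:40,
                             runs_per_temperature = c(3, 2, 2, 2, 2, 3),
                             subjects_per_run = 20L,
                             n_beakers = 10L,
                             beta0 = 18.8368,
                             beta_T = -0.45,
                             beta_S = -0.12,
                             beta_TS = 0,
                             sigma_beaker = 0.05,
                             sigma_run = 0.05,
                             sigma_resid = 0.10,
                             size_small = list(mean = 1.14, sd = 0.12,
                                               range = c(0.92, 1.51)),
                             size_large = list(mean = 2.70, sd = 0.12,
                                               range = c(2.37, 3.17)),
                             intro_window_s = c(180, 360),
                             sample_rate_hz = 3,
                             active_speed_meanlog = log(5),
                             active_speed_sdlog = 0.35,
                             move_bout_mean_s = 3,
                             pause_bout_mean_s = 0.4,
                             final_active_s = 2,
                             jitter_max_frac = 0.3,
                             velocity_threshold_mm_s = 1.0,
                             seed = 1L) {
  cfg <- list(temperatures = as.numeric(temperatures),
              runs_per_temperature = as.integer(runs_per_temperature),
              subjects_per_run = as.integer(subjects_per_run),
              n_beakers = as.integer(n_beakers),
              beta0 = beta0, beta_T = beta_T, beta_S = beta_S,
              beta_TS = beta_TS,
              sigma_beaker = sigma_beaker, sigma_run = sigma_run,
              sigma_resid = sigma_resid,
              size_small = size_small, size_large = size_large,
              intro_window_s = as.numeric(intro_window_s),
              sample_rate_hz = sample_rate_hz,
              active_speed_meanlog = active_speed_meanlog,
              active_speed_sdlog = active_speed_sdlog,
              move_bout_mean_s = move_bout_mean_s,
              pause_bout_mean_s = pause_bout_mean_s,
              final_active_s = final_active_s,
              jitter_max_frac = jitter_max_frac,
              velocity_threshold_mm_s = velocity_threshold_mm_s,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (length(cfg$temperatures) < 1L)
    stop("configuration error: at least one temperature is required")
  if (length(cfg$runs_per_temperature) != length(cfg$temperatures))
    stop("configuration error: runs_per_temperature must match temperatures ",
         "in length")
  if (any(cfg$runs_per_temperature < 1L))
    stop("configuration error: runs_per_temperature must be >= 1")
  if (cfg$beta_T >= 0)
    stop("configuration error: beta_T must be negative ",
         "(knock-down time decreases with temperature)")
  if (any(c(cfg$sigma_beaker, cfg$sigma_run, cfg$sigma_resid) < 0))
    stop("configuration error: sigmas must be >= 0")
  if (cfg$sample_rate_hz <= 0)
    stop("configuration error: sample_rate_hz must be > 0")
  if (cfg$intro_window_s[1] >= cfg$intro_window_s[2])
    stop("configuration error: intro_window_s must be an increasing pair")
  if (cfg$subjects_per_run %% 2L != 0L)
    stop("configuration error: subjects_per_run must be even ",
         "(two equal size groups)")
  rs <- cfg$size_small$range
  rl <- cfg$size_large$range
  if (max(rs[1], rl[1]) < min(rs[2], rl[2]) &&
      !(rs[2] <= rl[1] || rl[2] <= rs[1]))
    stop("configuration error: small and large size ranges must not overlap")
  invisible(TRUE)
}

#' @export
print.synthetic_config <- function(x, ...) {
  n_runs <- sum(x$runs_per_temperature)
  cat("Synthetic knock-down assay configuration\n")
  cat(sprintf("  temperatures : %s C (%d runs total)\n",
              paste(x$temperatures, collapse = ", "), n_runs))
  cat(sprintf("  subjects     : %d per run (%d total), %d beakers\n",
              x$subjects_per_run, n_runs * x$subjects_per_run, x$n_beakers))
  cat(sprintf("  latent model : log10 t = %.4f %+.3f*T %+.3f*S %+.3f*T*S\n",
              x$beta0, x$beta_T, x$beta_S, x$beta_TS))
  cat(sprintf("  sigmas       : beaker %.3f, run %.3f, resid %.3f (log10 min)\n",
              x$sigma_beaker, x$sigma_run, x$sigma_resid))
  cat(sprintf("  seed         : %d\n", x$seed))
  invisible(x)
}

#' Generate a complete synthetic knock-down experiment
#'
#' Draws run metadata, subject metadata and latent knock-down times under the
#' configured thermal death time model with crossed beaker and run random
#' intercepts. Velocity traces are not materialised here (they can be large);
#' see [simulate_run_traces()] or [detect_experiment()] which stream them
#' per run from the same seeded sub-streams.
#'
#' Each run draws one small and one large subject per beaker (when
#' `subjects_per_run == 2 * n_beakers`; otherwise beakers are cycled), body
#' sizes from the group's truncated normal, and introduction offsets spanning
#' a total introduction time drawn uniformly from `intro_window_s`; the last
#' subject is introduced at recording start (offset 0) and the first at the
#' full span. All draws are deterministic given `config$seed`, with per-run
#' sub-streams so the experiment is reproducible run by run.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `heattol_experiment` with elements
#'   \describe{
#'     \item{runs}{data.frame: `run_id`, `temperature_C`, `label`}
#'     \item{subjects}{data.frame: `subject_id`, `run_id`, `beaker_id`,
#'       `size_group`, `body_length_mm`, `intro_offset_s`}
#'     \item{knockdown}{data.frame: `subject_id`, `t_true_min` - the latent
#'       truth, used for testing and recovery experiments only}
#'     \item{config}{the configuration used}
#'   }
#' @export
generate_experiment <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  n_runs <- sum(config$runs_per_temperature)
  n_per <- config$subjects_per_run

  set.seed(substream_seed(config$seed, 0L))
  u_beaker <- rnorm(config$n_beakers, 0, config$sigma_beaker)
  beaker_ids <- sprintf("B%02d", seq_len(config$n_beakers))

  temps <- rep(config$temperatures, config$runs_per_temperature)
  runs <- data.frame(run_id = sprintf("R%02d", seq_len(n_runs)),
                     temperature_C = temps,
                     label = sprintf("order_%02d", seq_len(n_runs)),
                     stringsAsFactors = FALSE)

  subj_list <- vector("list", n_runs)
  kd_list <- vector("list", n_runs)
  half <- n_per %/% 2L
  for (i in seq_len(n_runs)) {
    set.seed(substream_seed(config$seed, 1L, i))
    u_run <- rnorm(1, 0, config$sigma_run)
    beaker <- c(rep_len(beaker_ids, half), rep_len(beaker_ids, half))
    size_group <- rep(c("small", "large"), each = half)
    sz_s <- config$size_small
    sz_l <- config$size_large
    body <- c(rtrunc_norm(half, sz_s$mean, sz_s$sd, sz_s$range[1], sz_s$range[2]),
              rtrunc_norm(half, sz_l$mean, sz_l$sd, sz_l$range[1], sz_l$range[2]))
    # introduction: total span D in the window; first subject at D seconds
    # before recording start, last at 0 (recording begins after the last)
    D <- runif(1, config$intro_window_s[1], config$intro_window_s[2])
    u <- sort(runif(n_per, 0, D))
    u[1] <- 0
    u[n_per] <- D
    intro_offset <- D - u  # decreasing: subject 1 introduced first
    eps <- rnorm(n_per, 0, config$sigma_resid)
    temp <- temps[i]
    lp <- config$beta0 + config$beta_T * temp + config$beta_S * body +
      config$beta_TS * temp * body +
      u_beaker[match(beaker, beaker_ids)] + u_run + eps
    sid <- sprintf("%s_S%02d", runs$run_id[i], seq_len(n_per))
    subj_list[[i]] <- data.frame(subject_id = sid,
                                 run_id = runs$run_id[i],
                                 beaker_id = beaker,
                                 size_group = size_group,
                                 body_length_mm = body,
                                 intro_offset_s = intro_offset,
                                 stringsAsFactors = FALSE)
    kd_list[[i]] <- data.frame(subject_id = sid,
                               t_true_min = 10^lp,
                               stringsAsFactors = FALSE)
  }
  structure(list(runs = runs,
                 subjects = do.call(rbind, subj_list),
                 knockdown = do.call(rbind, kd_list),
                 config = config),
            class = "heattol_experiment")
}

#' @export
print.heattol_experiment <- function(x, ...) {
  cat(sprintf("Synthetic knock-down experiment: %d runs, %d subjects, %d temperatures (%g-%g C)\n",
              nrow(x$runs), nrow(x$subjects),
              length(unique(x$runs$temperature_C)),
              min(x$runs$temperature_C), max(x$runs$temperature_C)))
  cat(sprintf("  knock-down times: %.2f-%.1f min (median %.1f)\n",
              min(x$knockdown$t_true_min), max(x$knockdown$t_true_min),
              stats::median(x$knockdown$t_true_min)))
  invisible(x)
}

#' Simulate one subject's velocity trace
#'
#' Produces a 3 Hz (by default) velocity series on the recording clock for a
#' subject with latent knock-down time `t_true_min` (minutes from its own
#' introduction). The knock-down instant maps to recording time
#' `t_true_min * 60 - intro_offset_s`. Before it the subject swims in
#' alternating move/pause bouts (move speeds lognormal, well above the
#' detection threshold; pauses at tracking-jitter level), with the final
#' `config$final_active_s` seconds always a move bout; after it only
#' sub-threshold jitter remains. If the knock-down instant precedes recording
#' start the whole trace is jitter (the subject is never seen moving).
#'
#' Uses the current RNG state; callers seed it (see [simulate_run_traces()]).
#'
#' @param t_true_min latent knock-down time, minutes from introduction (> 0).
#' @param intro_offset_s seconds before recording start at which the subject
#'   entered its well (>= 0).
#' @param recording_duration_s length of the recording in seconds (> 0).
#' @param config a [synthetic_config()] supplying the trace process
#'   parameters.
#' @return data.frame with `sample_time_s` (recording clock) and
#'   `velocity_mm_s`.
#' @export
simulate_trace <- function(t_true_min, intro_offset_s, recording_duration_s,
                           config = synthetic_config()) {
  if (recording_duration_s <= 0) stop("recording_duration_s must be > 0")
  if (intro_offset_s < 0) stop("intro_offset_s must be >= 0")
  if (t_true_min <= 0) stop("t_true_min must be > 0")
  rate <- config$sample_rate_hz
  n <- floor(recording_duration_s * rate) + 1L
  times <- (seq_len(n) - 1L) / rate
  t_k <- t_true_min * 60 - intro_offset_s  # knock-down on the recording clock

  jitter_max <- config$jitter_max_frac * config$velocity_threshold_mm_s
  vel <- runif(n, 0, jitter_max)  # default: sub-threshold jitter

  active <- times < t_k
  if (any(active)) {
    # alternating move/pause bouts over the active span
    span <- min(t_k, times[n] + 1 / rate)
    n_bouts <- max(16L, 4L + 2L * ceiling(
      span / (config$move_bout_mean_s + config$pause_bout_mean_s)))
    repeat {
      durs <- numeric(n_bouts)
      odd <- seq(1L, n_bouts, by = 2L)
      durs[odd] <- rexp(length(odd), 1 / config$move_bout_mean_s)
      durs[-odd] <- rexp(n_bouts - length(odd), 1 / config$pause_bout_mean_s)
      if (sum(durs) >= span) break
      n_bouts <- n_bouts * 2L
    }
    bout_end <- cumsum(durs)
    idx <- findInterval(times[active], bout_end) + 1L
    moving <- idx %% 2L == 1L  # odd bouts are move bouts
    # terminal agitation: always moving just before knock-down
    moving[times[active] >= t_k - config$final_active_s] <- TRUE
    n_mov <- sum(moving)
    v_act <- vel[active]
    if (n_mov > 0)
      v_act[moving] <- rlnorm(n_mov, config$active_speed_meanlog,
                              config$active_speed_sdlog)
    vel[active] <- v_act
  }
  data.frame(sample_time_s = times, velocity_mm_s = vel)
}

#' Simulate velocity traces for one run of an experiment
#'
#' Streams the traces of all subjects of a run from deterministic per-subject
#' RNG sub-streams. The recording length covers the run's latest knock-down
#' plus a margin, mirroring an assay filmed until all subjects are motionless.
#'
#' @param experiment a [generate_experiment()] result.
#' @param run_id which run to simulate.
#' @param margin_s extra recording time beyond the last knock-down (s).
#' @return data.frame with columns `subject_id`, `run_id`, `well_id`,
#'   `sample_time_s`, `velocity_mm_s`.
#' @export
simulate_run_traces <- function(experiment, run_id, margin_s = 10) {
  if (margin_s < 0) stop("margin_s must be >= 0")
  cfg <- experiment$config
  i <- match(run_id, experiment$runs$run_id)
  if (is.na(i)) stop("unknown run_id: ", run_id)
  subj <- experiment$subjects[experiment$subjects$run_id == run_id, ,
                              drop = FALSE]
  kd <- experiment$knockdown$t_true_min[
    match(subj$subject_id, experiment$knockdown$subject_id)]
  t_k <- kd * 60 - subj$intro_offset_s
  duration <- max(max(t_k), 0) + margin_s
  out <- vector("list", nrow(subj))
  for (j in seq_len(nrow(subj))) {
    set.seed(substream_seed(cfg$seed, 2L, i, j))
    tr <- simulate_trace(kd[j], subj$intro_offset_s[j], duration, cfg)
    out[[j]] <- data.frame(subject_id = subj$subject_id[j],
                           run_id = run_id,
                           well_id = sprintf("W%02d", j),
                           sample_time_s = tr$sample_time_s,
                           velocity_mm_s = tr$velocity_mm_s,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
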