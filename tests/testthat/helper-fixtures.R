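## Fixtures built in code: small assay configurations and a balanced
## crossed-design dataset for the mixed-model oracle comparison.

# two-temperature, two-run assay: fast to trace-simulate end to end
small_assay_config <- function(seed = 3L, ...) {
  synthetic_config(temperatures = c(39, 40), runs_per_temperature = c(1, 1),
                   seed = seed, ...)
}

# step-function trace: constant velocity up to t_stop_s, zero afterwards
step_trace <- function(v_active = 5, t_stop_s = 300, t_end_s = 400,
                       rate = 3) {
  times <- seq(0, t_end_s, by = 1 / rate)
  data.frame(sample_time_s = times,
             velocity_mm_s = ifelse(times <= t_stop_s, v_active, 0))
}

# balanced crossed design: n_beaker x n_run cells, n_per_cell obs each,
# known fixed effects and variance components on the log10-minutes scale
balanced_lmm_data <- function(seed, sigma_beaker = 0.15, sigma_run = 0.12,
                              sigma_resid = 0.20, n_beaker = 4, n_run = 2,
                              n_per_cell = 6) {
  set.seed(seed)
  g <- expand.grid(cell = seq_len(n_per_cell),
                   beaker = seq_len(n_beaker), run = seq_len(n_run))
  temp <- c(37, 39)[g$run]
  size <- rep_len(c(1.1, 1.3, 2.5, 2.7), nrow(g)) + runif(nrow(g), -0.05, 0.05)
  u_b <- rnorm(n_beaker, 0, sigma_beaker)
  u_r <- rnorm(n_run, 0, sigma_run)
  y <- 19 - 0.45 * temp - 0.1 * size + u_b[g$beaker] + u_r[g$run] +
    rnorm(nrow(g), 0, sigma_resid)
  data.frame(timm_min = 10^y,
             temperature_C = temp,
             body_length_mm = size,
             beaker_id = sprintf("B%d", g$beaker),
             run_id = sprintf("R%d", g$run))
}

# design matrix matching fit_lmm's internal centring, additive spec
additive_design <- function(d) {
  cbind(1, d$temperature_C - mean(d$temperature_C), d$body_length_mm)
}
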