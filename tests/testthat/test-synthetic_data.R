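test_that("default configuration reproduces the assay design", {
  e <- generate_experiment(synthetic_config(seed = 101))
  expect_equal(nrow(e$runs), 14L)
  expect_equal(nrow(e$subjects), 280L)
  expect_equal(sort(unique(e$runs$temperature_C)), 35:40)
  expect_equal(length(unique(e$subjects$beaker_id)), 10L)
  expect_equal(unname(table(e$subjects$size_group)), c(140L, 140L),
               ignore_attr = TRUE)
  # one small and one large subject per beaker per run
  per_run <- split(e$subjects, e$subjects$run_id)
  for (s in per_run) {
    expect_equal(unname(table(s$beaker_id, s$size_group)),
                 matrix(1L, 10, 2), ignore_attr = TRUE)
  }
  # introduction spans within the window, last subject at recording start
  for (s in per_run) {
    expect_true(min(s$intro_offset_s) == 0)
    expect_gte(max(s$intro_offset_s), 180)
    expect_lte(max(s$intro_offset_s), 360)
  }
  expect_true(all(e$knockdown$t_true_min > 0))
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(beta_T = 0.1), "beta_T must be negative")
  expect_error(synthetic_config(sigma_run = -1), "sigmas")
  expect_error(synthetic_config(intro_window_s = c(360, 180)), "intro_window")
  expect_error(synthetic_config(subjects_per_run = 19), "even")
  expect_error(synthetic_config(
    size_small = list(mean = 1.5, sd = 0.1, range = c(1.0, 2.6)),
    size_large = list(mean = 2.7, sd = 0.1, range = c(2.4, 3.2))),
    "must not overlap")
  expect_error(synthetic_config(runs_per_temperature = c(2, 2)),
               "must match temperatures")
})

test_that("the generator is deterministic given the seed", {
  cfg <- small_assay_config(seed = 55)
  e1 <- generate_experiment(cfg)
  e2 <- generate_experiment(cfg)
  expect_identical(e1$runs, e2$runs)
  expect_identical(e1$subjects, e2$subjects)
  expect_identical(e1$knockdown, e2$knockdown)
  tr1 <- simulate_run_traces(e1, "R01")
  tr2 <- simulate_run_traces(e2, "R01")
  expect_identical(tr1, tr2)
  e3 <- generate_experiment(small_assay_config(seed = 56))
  expect_false(identical(e1$knockdown$t_true_min, e3$knockdown$t_true_min))
})

test_that("adding runs does not perturb earlier runs' draws", {
  cfg2 <- synthetic_config(temperatures = c(39, 40),
                           runs_per_temperature = c(1, 1), seed = 9)
  cfg3 <- synthetic_config(temperatures = c(39, 40),
                           runs_per_temperature = c(1, 2), seed = 9)
  e2 <- generate_experiment(cfg2)
  e3 <- generate_experiment(cfg3)
  ids <- e2$subjects$subject_id
  expect_identical(e2$subjects, e3$subjects[e3$subjects$subject_id %in% ids, ])
  expect_identical(e2$knockdown$t_true_min,
                   e3$knockdown$t_true_min[match(ids, e3$knockdown$subject_id)])
})

test_that("the noise-free limit reproduces the linear predictor exactly", {
  cfg <- synthetic_config(sigma_beaker = 0, sigma_run = 0, sigma_resid = 0,
                          beta_TS = 0, seed = 17)
  e <- generate_experiment(cfg)
  temp <- e$runs$temperature_C[match(e$subjects$run_id, e$runs$run_id)]
  lp <- cfg$beta0 + cfg$beta_T * temp + cfg$beta_S * e$subjects$body_length_mm
  expect_equal(log10(e$knockdown$t_true_min), lp, tolerance = 1e-12)
})

test_that("replicate means match the linear predictor within MC error", {
  # Monte-Carlo oracle: mean of log10 t_true at each temperature for
  # mean-size subjects, over replicate experiments
  cfg <- synthetic_config(seed = 300)
  n_rep <- 200
  s_ref <- cfg$size_small$mean
  devs <- matrix(NA_real_, n_rep, length(cfg$temperatures))
  for (r in seq_len(n_rep)) {
    cfg_r <- cfg
    cfg_r$seed <- 300 + r
    e <- generate_experiment(cfg_r)
    temp <- e$runs$temperature_C[match(e$subjects$run_id, e$runs$run_id)]
    small <- e$subjects$size_group == "small"
    # remove the size term so every subject is referenced to mean size
    adj <- log10(e$knockdown$t_true_min) -
      cfg$beta_S * (e$subjects$body_length_mm - s_ref)
    devs[r, ] <- vapply(seq_along(cfg$temperatures), function(j)
      mean(adj[small & temp == cfg$temperatures[j]]), numeric(1))
  }
  expected <- cfg$beta0 + cfg$beta_T * cfg$temperatures + cfg$beta_S * s_ref
  mc_mean <- colMeans(devs)
  mc_se <- apply(devs, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(mc_mean - expected) <= 3 * mc_se))
})

test_that("variance components decompose as configured, within MC error", {
  cfg <- synthetic_config(seed = 900)
  n_rep <- 120
  vb <- vr <- vt <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg_r <- cfg
    cfg_r$seed <- 900 + r
    e <- generate_experiment(cfg_r)
    temp <- e$runs$temperature_C[match(e$subjects$run_id, e$runs$run_id)]
    w <- log10(e$knockdown$t_true_min) -
      (cfg$beta0 + cfg$beta_T * temp + cfg$beta_S * e$subjects$body_length_mm)
    # cross-products of subjects sharing a beaker across different runs
    # estimate sigma_beaker^2; sharing a run across beakers, sigma_run^2
    bk <- e$subjects$beaker_id; rn <- e$subjects$run_id
    same_beaker <- outer(bk, bk, "==") & outer(rn, rn, "!=")
    same_run <- outer(rn, rn, "==") & outer(bk, bk, "!=")
    cp <- tcrossprod(w)
    vb[r] <- mean(cp[same_beaker])
    vr[r] <- mean(cp[same_run])
    vt[r] <- mean(w^2)
  }
  ck <- function(est, truth) {
    se <- sd(est) / sqrt(n_rep)
    expect_lte(abs(mean(est) - truth), 3 * se + 1e-8)
  }
  ck(vb, cfg$sigma_beaker^2)
  ck(vr, cfg$sigma_run^2)
  ck(vt, cfg$sigma_beaker^2 + cfg$sigma_run^2 + cfg$sigma_resid^2)
})

test_that("group body sizes converge to truncation-corrected means", {
  cfg <- synthetic_config(seed = 501)
  n_rep <- 60
  ms <- ml <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg_r <- cfg
    cfg_r$seed <- 501 + r
    e <- generate_experiment(cfg_r)
    ms[r] <- mean(e$subjects$body_length_mm[e$subjects$size_group == "small"])
    ml[r] <- mean(e$subjects$body_length_mm[e$subjects$size_group == "large"])
  }
  for (g in c("small", "large")) {
    p <- cfg[[paste0("size_", g)]]
    expected <- oracle_truncnorm_mean(p$mean, p$sd, p$range[1], p$range[2])
    est <- if (g == "small") ms else ml
    expect_lte(abs(mean(est) - expected), 3 * sd(est) / sqrt(n_rep))
  }
})

test_that("default calibration anchors brief and prolonged knock-down", {
  cfg <- synthetic_config()
  lp40 <- cfg$beta0 + cfg$beta_T * 40 + cfg$beta_S * cfg$size_small$mean
  lp35 <- cfg$beta0 + cfg$beta_T * 35 + cfg$beta_S * cfg$size_small$mean
  expect_equal(10^lp40, 5, tolerance = 0.1)  # ~5 min at 40 C
  # arithmetic mean over the lognormal noise exceeds 15 h at 35 C
  s_tot2 <- cfg$sigma_beaker^2 + cfg$sigma_run^2 + cfg$sigma_resid^2
  mean35 <- 10^lp35 * exp((log(10))^2 * s_tot2 / 2)
  expect_gt(mean35, 900)
})

test_that("simulated traces respect the knock-down instant and clocks", {
  cfg <- small_assay_config(seed = 8)
  thr <- cfg$velocity_threshold_mm_s
  set.seed(1)
  # knock-down before recording start: never seen moving
  tr <- simulate_trace(t_true_min = 2, intro_offset_s = 180,
                       recording_duration_s = 120, config = cfg)
  expect_true(all(tr$velocity_mm_s < thr))
  # knock-down beyond recording end: active throughout, mostly supra
  tr2 <- simulate_trace(t_true_min = 60, intro_offset_s = 0,
                        recording_duration_s = 300, config = cfg)
  expect_gt(mean(tr2$velocity_mm_s > thr), 0.5)
  # sampling grid
  expect_equal(diff(tr2$sample_time_s), rep(1 / 3, nrow(tr2) - 1),
               tolerance = 1e-12)
  expect_error(simulate_trace(5, 0, -10, cfg), "> 0")
  # after the knock-down instant everything is sub-threshold jitter
  tr3 <- simulate_trace(t_true_min = 3, intro_offset_s = 60,
                        recording_duration_s = 300, config = cfg)
  post <- tr3$sample_time_s >= 3 * 60 - 60
  expect_true(all(tr3$velocity_mm_s[post] < thr))
  expect_true(any(tr3$velocity_mm_s[!post] > thr))
})

test_that("simulate/detect round trip recovers the latent knock-down", {
  cfg <- small_assay_config(seed = 31)
  e <- generate_experiment(cfg)
  det <- detect_experiment(e)
  ok <- det$estimates$flag == "ok"
  err_s <- abs(det$estimates$timm_min[ok] - det$estimates$t_true_min[ok]) * 60
  expect_gte(mean(err_s <= 1 / 3 + 1e-9), 0.95)
})
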