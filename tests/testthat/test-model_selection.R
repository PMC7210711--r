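test_that("parameter counts follow fixed effects + 2 variances + residual", {
  expect_equal(count_parameters(lmm_spec("interaction")), 7L)
  expect_equal(count_parameters(lmm_spec("additive")), 6L)
  expect_equal(count_parameters(lmm_spec("temperature")), 5L)
  expect_equal(count_parameters("additive"), 6L)
})

test_that("AICc follows its definition and limits", {
  # direct arithmetic
  expect_equal(aicc(-184.0, 7, 277), 368 + 14 + 112 / 269, tolerance = 1e-12)
  # large-n limit approaches AIC
  expect_equal(aicc(-100, 3, 1e6), 206, tolerance = 1e-4)
  # equal-k difference reduces to -2 * delta loglik
  expect_equal(aicc(-100, 4, 50) - aicc(-97.3, 4, 50), -2 * (-100 + 97.3),
               tolerance = 1e-12)
  expect_error(aicc(-10, 5, 6), "n must exceed k")
})

test_that("Akaike weights normalise, symmetrise and resist overflow", {
  w <- akaike_weights(c(0, 1.46, 81.74))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(round(w, 2), c(0.67, 0.33, 0.00))
  expect_equal(akaike_weights(rep(123.4, 4)), rep(0.25, 4))
  set.seed(31)
  for (i in 1:1000) {
    x <- runif(sample(2:6, 1), -1e5, 1e5)
    wi <- akaike_weights(x)
    expect_equal(sum(wi), 1, tolerance = 1e-9)
    expect_true(all(wi >= 0))
  }
  expect_error(akaike_weights(c(1, NA)), "finite")
})

test_that("ML fit matches the dense-covariance brute-force oracle", {
  d <- balanced_lmm_data(seed = 5150)
  fit <- fit_lmm(d, lmm_spec("additive"))
  oracle <- oracle_lmm_ml(log10(d$timm_min), additive_design(d),
                          indicator_matrix(d$beaker_id),
                          indicator_matrix(d$run_id))
  expect_equal(fit$loglik, oracle, tolerance = 1e-5)
})

test_that("zero-variance grouping reduces the ML fit to OLS", {
  cfg <- synthetic_config(sigma_beaker = 0, sigma_run = 0,
                          sigma_resid = 0.001, seed = 1234)
  e <- generate_experiment(cfg)
  d <- modeling_table(
    data.frame(subject_id = e$knockdown$subject_id,
               timm_min = e$knockdown$t_true_min),
    e$subjects, e$runs)
  fit <- fit_lmm(d, lmm_spec("additive"))
  expect_true(all(fit$vc <= 1e-4))
  expect_true(fit$boundary)
  ols <- lm(log10(timm_min) ~ I(temperature_C - mean(temperature_C)) +
              body_length_mm, data = d)
  expect_equal(unname(fit$beta_centered), unname(coef(ols)),
               tolerance = 1e-6)
})

test_that("centred and natural-scale coefficients describe the same model", {
  d <- balanced_lmm_data(seed = 99)
  for (m in c("temperature", "additive", "interaction")) {
    fit <- fit_lmm(d, lmm_spec(m))
    b <- fit$beta
    pred_nat <- switch(m,
      temperature = b[1] + b["temperature_C"] * d$temperature_C,
      additive = b[1] + b["temperature_C"] * d$temperature_C +
        b["body_length_mm"] * d$body_length_mm,
      interaction = b[1] + b["temperature_C"] * d$temperature_C +
        b["body_length_mm"] * d$body_length_mm +
        b["temperature_C:body_length_mm"] * d$temperature_C *
          d$body_length_mm)
    pred_mod <- predict(fit$model, re.form = NA)
    expect_equal(unname(pred_nat), unname(pred_mod), tolerance = 1e-9)
  }
})

test_that("nested candidates have ordered likelihoods", {
  for (seed in c(11, 12)) {
    e <- generate_experiment(synthetic_config(seed = seed))
    d <- modeling_table(
      data.frame(subject_id = e$knockdown$subject_id,
                 timm_min = e$knockdown$t_true_min),
      e$subjects, e$runs)
    ll <- vapply(c("interaction", "additive", "temperature"),
                 function(m) fit_lmm(d, lmm_spec(m))$loglik, numeric(1))
    expect_gte(ll["interaction"], ll["additive"] - 1e-6)
    expect_gte(ll["additive"], ll["temperature"] - 1e-6)
  }
})

test_that("duplicating the dataset changes loglik but not effect ordering", {
  d <- balanced_lmm_data(seed = 314)
  f1 <- fit_lmm(d, lmm_spec("additive"))
  f2 <- fit_lmm(rbind(d, d), lmm_spec("additive"))
  expect_false(isTRUE(all.equal(f1$loglik, f2$loglik)))
  expect_equal(sign(f1$beta_centered), sign(f2$beta_centered))
  expect_equal(order(abs(f1$beta_centered)), order(abs(f2$beta_centered)))
})

test_that("comparison table is sorted, normalised and order-invariant", {
  e <- generate_experiment(synthetic_config(seed = 21))
  d <- modeling_table(
    data.frame(subject_id = e$knockdown$subject_id,
               timm_min = e$knockdown$t_true_min),
    e$subjects, e$runs)
  fits <- lapply(c("interaction", "additive", "temperature"),
                 function(m) fit_lmm(d, lmm_spec(m)))
  tab <- compare_models(fits)
  expect_false(is.unsorted(tab$AICc))
  expect_equal(tab$dAICc[1], 0)
  expect_equal(sum(tab$w), 1, tolerance = 1e-9)
  expect_false(is.unsorted(tab$acc_w))
  expect_equal(tab$acc_w[nrow(tab)], 1, tolerance = 1e-9)
  # permuting the input leaves the table identical
  tab2 <- compare_models(fits[c(3, 1, 2)])
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
  # single model
  tab1 <- compare_models(fits[2])
  expect_equal(tab1$dAICc, 0)
  expect_equal(tab1$w, 1)
  # mismatched data are refused
  fits_small <- fit_lmm(d[1:100, ], lmm_spec("additive"))
  expect_error(compare_models(list(fits[[1]], fits_small)),
               "identical data")
})

test_that("R-squared behaves at its reference points", {
  # near-noise-free saturated model explains everything
  cfg <- synthetic_config(sigma_beaker = 0, sigma_run = 0,
                          sigma_resid = 1e-6, seed = 404)
  e <- generate_experiment(cfg)
  d <- modeling_table(
    data.frame(subject_id = e$knockdown$subject_id,
               timm_min = e$knockdown$t_true_min),
    e$subjects, e$runs)
  fit <- fit_lmm(d, lmm_spec("interaction"))
  expect_equal(r_squared(fit), 1.0, tolerance = 1e-6)

  # shuffled response carries no signal
  e2 <- generate_experiment(synthetic_config(seed = 405))
  d2 <- modeling_table(
    data.frame(subject_id = e2$knockdown$subject_id,
               timm_min = e2$knockdown$t_true_min),
    e2$subjects, e2$runs)
  set.seed(1)
  d2$timm_min <- sample(d2$timm_min)
  fit2 <- fit_lmm(d2, lmm_spec("interaction"))
  expect_lt(r_squared(fit2), 0.05)

  # nesting: interaction explains at least as much as temperature-only
  fit_full <- fit_lmm(d, lmm_spec("interaction"))
  fit_temp <- fit_lmm(d, lmm_spec("temperature"))
  expect_gte(r_squared(fit_full), r_squared(fit_temp))
  expect_gte(r_squared(fit_full, "marginal"),
             r_squared(fit_temp, "marginal") - 1e-9)
})

test_that("model input problems raise informative errors", {
  d <- balanced_lmm_data(seed = 4)
  expect_error(fit_lmm(d[, -1], lmm_spec("additive")), "timm_min")
  d2 <- d; d2$timm_min[3] <- NA
  expect_error(fit_lmm(d2, lmm_spec("additive")), "missing values")
  d3 <- d; d3$beaker_id <- "B1"
  expect_error(fit_lmm(d3, lmm_spec("additive")), "at least 2 levels")
})
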