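## Candidate linear mixed models for knock-down time and AICc-based
## comparison. All models share the response log10(T_imm, min) and crossed
## random intercepts for culture beaker and measuring run, and are fitted by
## maximum likelihood (not REML) because the candidates differ in their
## fixed-effect structure.

.lmm_fixed_terms <- c(interaction = "temperature x size",
                      additive = "temperature + size",
                      temperature = "temperature")
.lmm_n_fixed <- c(interaction = 4L, additive = 3L, temperature = 2L)

#' Specify a candidate mixed model for knock-down time
#'
#' The three candidates share the response `log10(timm_min)` and crossed
#' random intercepts for beaker and run, and differ only in fixed effects:
#' temperature only; temperature + body size (size shifts the elevation of
#' the thermal death time curve); or temperature x size with main effects
#' (size may also change the slope, i.e. the temperature sensitivity z).
#' Body size enters as a continuous covariate in mm.
#'
#' @param fixed one of `"interaction"`, `"additive"`, `"temperature"`.
#' @return object of class `lmm_spec`.
#' @export
lmm_spec <- function(fixed = c("interaction", "additive", "temperature")) {
  fixed <- match.arg(fixed)
  structure(list(fixed = fixed,
                 label = .lmm_fixed_terms[[fixed]],
                 response = "log10(timm_min)",
                 random_intercepts = c("beaker_id", "run_id"),
                 method = "ML"),
            class = "lmm_spec")
}

#' Count estimated parameters of a candidate model
#'
#' Fixed-effect coefficients plus two random-intercept variances plus the
#' residual variance: 7 for the interaction model, 6 additive, 5
#' temperature-only.
#'
#' @param spec an [lmm_spec()] or one of its `fixed` strings.
#' @return integer parameter count `k`.
#' @export
count_parameters <- function(spec) {
  fixed <- if (inherits(spec, "lmm_spec")) spec$fixed else
    match.arg(spec, names(.lmm_n_fixed))
  .lmm_n_fixed[[fixed]] + 2L + 1L
}

#' Fit a candidate mixed model by maximum likelihood
#'
#' Fits `log10(timm_min)` with the spec's fixed effects and crossed random
#' intercepts for `beaker_id` and `run_id` using [lme4::lmer()] with
#' `REML = FALSE`. Temperature is centred at its sample mean internally for
#' optimizer stability; coefficients are reported back-transformed to the
#' natural scale. A fit with a variance component estimated at the boundary
#' (zero) is returned with `boundary = TRUE`; optimizer non-convergence is an
#' error carrying the diagnostics.
#'
#' @param data data.frame with columns `timm_min`, `temperature_C`,
#'   `body_length_mm`, `beaker_id`, `run_id`; no missing values.
#' @param spec an [lmm_spec()].
#' @return object of class `lmm_fit`: `spec`, `label`, `model` (the merMod),
#'   `beta` (natural-scale fixed effects), `beta_centered`, `se_centered`,
#'   `vc` (beaker and run variances), `sigma2_resid`, `loglik`, `k`, `n`,
#'   `boundary`, `t_center`.
#' @export
fit_lmm <- function(data, spec) {
  if (!inherits(spec, "lmm_spec")) spec <- lmm_spec(spec)
  need <- c("timm_min", "temperature_C", "body_length_mm", "beaker_id",
            "run_id")
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop("model input is missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyNA(data[need]))
    stop("model input contains missing values")
  if (any(data$timm_min <= 0))
    stop("all knock-down times must be > 0")
  for (rf in c("beaker_id", "run_id"))
    if (length(unique(data[[rf]])) < 2L)
      stop("random factor ", rf, " needs at least 2 levels")

  t_bar <- mean(data$temperature_C)
  d <- data.frame(y = log10(data$timm_min),
                  Tc = data$temperature_C - t_bar,
                  S = data$body_length_mm,
                  beaker_id = factor(data$beaker_id),
                  run_id = factor(data$run_id))
  form <- switch(spec$fixed,
                 temperature = y ~ Tc + (1 | beaker_id) + (1 | run_id),
                 additive = y ~ Tc + S + (1 | beaker_id) + (1 | run_id),
                 interaction = y ~ Tc * S + (1 | beaker_id) + (1 | run_id))

  fit_once <- function(control) {
    warnings <- character()
    fit <- withCallingHandlers(
      suppressMessages(lme4::lmer(form, data = d, REML = FALSE,
                                  control = control)),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(fit = fit, warnings = warnings)
  }
  res <- fit_once(lme4::lmerControl())
  if (any(grepl("failed to converge|convergence", res$warnings,
                ignore.case = TRUE))) {
    # retry with a derivative-free optimizer before giving up
    res <- fit_once(lme4::lmerControl(
      optimizer = "bobyqa", optCtrl = list(maxfun = 1e5)))
    if (any(grepl("failed to converge|convergence", res$warnings,
                  ignore.case = TRUE)))
      stop("mixed-model optimizer did not converge: ",
           paste(res$warnings, collapse = "; "))
  }
  fit <- res$fit

  bc <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  beta <- back_transform_beta(bc, spec$fixed, t_bar)
  vcdf <- as.data.frame(lme4::VarCorr(fit))
  vc <- setNames(vcdf$vcov[match(c("beaker_id", "run_id"), vcdf$grp)],
                 c("beaker", "run"))
  sigma2 <- vcdf$vcov[vcdf$grp == "Residual"]
  ll <- logLik(fit)
  k <- count_parameters(spec)
  stopifnot(attr(ll, "df") == k)
  structure(list(spec = spec, label = spec$label, model = fit,
                 beta = beta, beta_centered = bc, se_centered = se,
                 vc = vc, sigma2_resid = sigma2,
                 loglik = as.numeric(ll), k = k, n = nrow(d),
                 boundary = lme4::isSingular(fit), t_center = t_bar),
            class = "lmm_fit")
}

## Undo the internal temperature centring Tc = T - t_bar:
## y = b0 + bT*Tc + bS*S + bTS*Tc*S
##   = (b0 - bT*t_bar) + bT*T + (bS - bTS*t_bar)*S + bTS*T*S
back_transform_beta <- function(bc, fixed, t_bar) {
  switch(fixed,
         temperature = c("(Intercept)" = unname(bc[1] - bc["Tc"] * t_bar),
                         temperature_C = unname(bc["Tc"])),
         additive = c("(Intercept)" = unname(bc[1] - bc["Tc"] * t_bar),
                      temperature_C = unname(bc["Tc"]),
                      body_length_mm = unname(bc["S"])),
         interaction = c(
           "(Intercept)" = unname(bc[1] - bc["Tc"] * t_bar),
           temperature_C = unname(bc["Tc"]),
           body_length_mm = unname(bc["S"] - bc["Tc:S"] * t_bar),
           "temperature_C:body_length_mm" = unname(bc["Tc:S"])))
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("ML mixed model [%s]: loglik = %.3f, k = %d, n = %d%s\n",
              x$label, x$loglik, x$k, x$n,
              if (x$boundary) " (variance component at boundary)" else ""))
  cat("  fixed effects (natural scale):\n")
  print(round(x$beta, 5))
  cat(sprintf("  variance components: beaker %.5f, run %.5f, residual %.5f\n",
              x$vc[["beaker"]], x$vc[["run"]], x$sigma2_resid))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*loglik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1)
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = AICc_i - min(AICc)`; subtracting the minimum keeps the
#' exponentials in range.
#'
#' @param aicc_values finite AICc values, one per candidate model.
#' @return weights summing to one.
#' @export
akaike_weights <- function(aicc_values) {
  if (!length(aicc_values) || any(!is.finite(aicc_values)))
    stop("aicc_values must be a non-empty finite vector")
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Compare candidate mixed models by AICc
#'
#' Builds the model-comparison table: one row per fit, sorted by AICc
#' ascending (exact ties broken by smaller `k`), with Delta AICc, Akaike
#' weights, accumulated weights and R-squared (squared correlation between
#' conditional predictions and observations). When the top two models are
#' within Delta < 2 the table carries a near-tie note: the simpler model has
#' essentially equal support.
#'
#' @param fits list of [fit_lmm()] results on identical data.
#' @return data.frame of class `model_comparison` with columns `model`,
#'   `fixed_effects`, `k`, `AICc`, `dAICc`, `w`, `acc_w`, `R2`, plus
#'   attributes `note` and `n`.
#' @export
compare_models <- function(fits) {
  if (!length(fits)) stop("no fits to compare")
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("all fits must be on identical data (observation counts differ: ",
         paste(unique(ns), collapse = ", "), ")")
  if (length(fits) > 1L) {
    y0 <- sort(fits[[1]]$model@frame$y)
    for (f in fits[-1])
      if (!isTRUE(all.equal(sort(f$model@frame$y), y0)))
        stop("all fits must share the same response values")
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$fixed, character(1)),
    fixed_effects = vapply(fits, function(f) f$label, character(1)),
    k = vapply(fits, function(f) f$k, integer(1)),
    AICc = vapply(fits, function(f) aicc(f$loglik, f$k, f$n), numeric(1)),
    R2 = vapply(fits, r_squared, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$AICc, tab$k)
  tab <- tab[ord, ]
  tab$dAICc <- tab$AICc - tab$AICc[1]
  tab$w <- akaike_weights(tab$AICc)
  tab$acc_w <- cumsum(tab$w)
  tab <- tab[, c("model", "fixed_effects", "k", "AICc", "dAICc", "w",
                 "acc_w", "R2")]
  rownames(tab) <- NULL
  note <- if (nrow(tab) > 1L && tab$dAICc[2] < 2.0)
    sprintf("near-tie: dAICc between the top two models is %.2f (< 2.0)",
            tab$dAICc[2]) else NULL
  structure(tab, class = c("model_comparison", "data.frame"),
            note = note, n = ns[1])
}

#' @export
print.model_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("Model comparison (AICc, ML fits, n = %d)\n", attr(x, "n")))
  out <- as.data.frame(x)
  for (nm in c("AICc", "dAICc", "w", "acc_w", "R2"))
    out[[nm]] <- round(out[[nm]], digits)
  print(out, row.names = FALSE)
  if (!is.null(attr(x, "note"))) cat("Note:", attr(x, "note"), "\n")
  invisible(x)
}

#' R-squared of a fitted mixed model
#'
#' Default (`"conditional"`): squared Pearson correlation between conditional
#' predictions (fixed effects plus predicted random effects) and the observed
#' response. `"marginal"` uses fixed-effect predictions only.
#'
#' @param fit an [fit_lmm()] result.
#' @param type `"conditional"` or `"marginal"`.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(fit, type = c("conditional", "marginal")) {
  type <- match.arg(type)
  y <- fit$model@frame$y
  if (var(y) == 0) stop("response has zero variance; R-squared undefined")
  pred <- if (type == "conditional") fitted(fit$model)
          else predict(fit$model, re.form = NA)
  if (var(pred) == 0) return(0)
  cor(pred, y)^2
}
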