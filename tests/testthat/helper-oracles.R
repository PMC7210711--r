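## Independent oracles used by the tests. These deliberately avoid the
## package's own code paths: the detector oracle is a literal scan, the OLS
## oracle uses the closed-form normal equations, and the mixed-model oracle
## builds the full marginal covariance matrix and maximises the exact
## Gaussian log-density numerically.

# literal "last sample above threshold" scan (min_bout_samples = 1)
oracle_last_supra <- function(times, vel, threshold) {
  last <- NA_real_
  for (i in seq_along(times)) {
    if (vel[i] > threshold) last <- times[i]
  }
  last
}

# closed-form simple linear regression of y on x
oracle_ols_line <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x * x) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# exact marginal Gaussian log-likelihood of a crossed random-intercept model,
# with the fixed effects profiled out by GLS
oracle_lmm_loglik <- function(pars, y, X, Zb, Zr) {
  sb <- exp(pars[1]); sr <- exp(pars[2]); se <- exp(pars[3])
  n <- length(y)
  V <- sb^2 * tcrossprod(Zb) + sr^2 * tcrossprod(Zr) + diag(se^2, n)
  ch <- chol(V)
  solve_V <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  Vi_X <- solve_V(X)
  beta <- solve(crossprod(X, Vi_X), crossprod(X, solve_V(y)))
  r <- as.numeric(y - X %*% beta)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(r * solve_V(r)))
}

# brute-force ML: multi-start Nelder-Mead + BFGS over log standard deviations
oracle_lmm_ml <- function(y, X, Zb, Zr) {
  nll <- function(p) -oracle_lmm_loglik(p, y, X, Zb, Zr)
  starts <- list(log(c(0.2, 0.2, 0.2)), log(c(0.05, 0.05, 0.3)),
                 log(c(0.4, 0.1, 0.15)))
  best <- -Inf
  for (s in starts) {
    o1 <- optim(s, nll, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    o2 <- optim(o1$par, nll, method = "BFGS",
                control = list(maxit = 2000, reltol = 1e-14))
    best <- max(best, -o1$value, -o2$value)
  }
  best
}

# indicator matrix of a factor
indicator_matrix <- function(f) {
  f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

# mean of a normal truncated to [a, b]
oracle_truncnorm_mean <- function(mean, sd, a, b) {
  al <- (a - mean) / sd; be <- (b - mean) / sd
  mean + sd * (dnorm(al) - dnorm(be)) / (pnorm(be) - pnorm(al))
}
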