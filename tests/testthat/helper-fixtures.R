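# Shared fixtures, built in code at test time.

# noise-free assessment table: every patient follows `params` exactly
noise_free_cohort <- function(n = 10, params = kinetic_params(8, 0.07, 0.02),
                              times = seq(0, 48, by = 8)) {
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(patient_id = sprintf("NF%02d", i), time_weeks = times,
               sld_cm = sld_at(params, times))))
}

# independent R-side evaluation of the per-patient penalised objective used
# by the population fit (kept deliberately separate from the package's
# compiled implementation)
penalised_objective <- function(lp, t, y, mu, om2, s2) {
  th <- exp(lp)
  pred <- th[1] * (exp(-th[2] * t) + exp(th[3] * t) - 1)
  sum((y - pred)^2) / (2 * s2) + sum((lp - mu)^2 / (2 * om2))
}

# brute-force minimiser of the penalised objective: coarse grid of starts,
# Nelder-Mead polish
brute_force_eb <- function(t, y, mu, om2, s2) {
  grid <- expand.grid(a = mu[1] + c(-0.5, 0, 0.5),
                      b = mu[2] + seq(-1.5, 1.5, by = 0.75),
                      c = mu[3] + seq(-1.5, 1.5, by = 0.75))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    r <- optim(as.numeric(grid[i, ]), penalised_objective, t = t, y = y,
               mu = mu, om2 = om2, s2 = s2, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-14))
    if (is.null(best) || r$value < best$value) best <- r
  }
  list(params = exp(best$par), value = best$value)
}

# numerical-minimisation oracle for the turning point: locates the curve's
# minimum as the root of a central finite-difference slope (robust where
# the curve is too flat for direct golden-section search); the minimiser
# location is invariant to positive scaling, so the search runs on the
# unit-baseline curve for full floating-point resolution
num_tp <- function(p, h = 1e-3) {
  p1 <- kinetic_params(1, p$B, p$C)
  uniroot(function(t) (sld_at(p1, t + h) - sld_at(p1, t - h)) / (2 * h),
          interval = c(-400, 400), tol = 1e-10)$root
}

# O(n^2) double-loop oracle for the signed model-based concordance
# probability (independent of the vectorised implementation)
cp_oracle <- function(beta, x, direction) {
  n <- length(x)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      np <- np + 1
      if (x[i] == x[j]) { tot <- tot + 0.5; next }
      better <- if (direction == "higher") max(x[i], x[j]) else min(x[i], x[j])
      other <- if (better == x[i]) x[j] else x[i]
      tot <- tot + 1 / (1 + exp(beta * better - beta * other))
    }
  }
  tot / np
}

# small survival table generator for CP/bootstrap tests
exp_surv_cohort <- function(n, beta = 0.4, cens_rate = 0) {
  x <- rnorm(n)
  t <- rexp(n, rate = exp(beta * x))
  if (cens_rate > 0) {
    cc <- rexp(n, cens_rate)
    data.frame(x = x, time = pmin(t, cc) + 1e-9, event = as.integer(t <= cc))
  } else {
    data.frame(x = x, time = t + 1e-9, event = 1L)
  }
}
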