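#' Univariate Cox proportional-hazards fit
#'
#' Thin wrapper around [survival::coxph()] (Efron tie handling) for a single
#' continuous or binary covariate, as needed by the model-based concordance
#' probability. A covariate that is constant across patients is a degenerate
#' design: the fit is flagged and returned with `beta = 0`, `se = Inf`
#' rather than failing inside resampling loops.
#'
#' @param x covariate values, one per patient.
#' @param time_weeks,event survival times (weeks, > 0) and event indicators
#'   (1 observed, 0 censored).
#' @return a list of class `cox_fit`: `beta`, `se`, `n`, `n_events`,
#'   `degenerate`.
#' @export
fit_cox <- function(x, time_weeks, event) {
  n <- length(x)
  if (n != length(time_weeks) || n != length(event))
    stop("x, time_weeks and event must have equal length", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("covariate must be finite", call. = FALSE)
  if (any(time_weeks <= 0)) stop("survival times must be positive", call. = FALSE)
  if (sum(event) == 0) stop("no events: Cox model cannot be fitted", call. = FALSE)
  if (length(unique(time_weeks[event == 1])) < 2L)
    stop("need at least 2 distinct event times", call. = FALSE)
  if (var(x) == 0) {
    return(structure(list(beta = 0, se = Inf, n = n, n_events = sum(event),
                          degenerate = TRUE), class = "cox_fit"))
  }
  fit <- coxph(Surv(time_weeks, event) ~ x, ties = "efron")
  if (!is.finite(coef(fit)))
    stop("Cox fit did not converge: ", paste(capture_diag(fit), collapse = "; "),
         call. = FALSE)
  structure(list(beta = unname(coef(fit)), se = sqrt(unname(vcov(fit)[1, 1])),
                 n = n, n_events = sum(event), degenerate = FALSE),
            class = "cox_fit")
}

capture_diag <- function(fit) {
  c(sprintf("iterations = %s", fit$iter), sprintf("loglik = %s", fit$loglik[2]))
}

# formula-free univariate Cox coefficient (survival's fitting engine called
# directly); used inside resampling loops where coxph()'s model-frame
# machinery would dominate the runtime
fast_cox_beta <- function(x, time, event) {
  if (sum(event) == 0) stop("no events", call. = FALSE)
  if (var(x) == 0) return(0)
  f <- survival::coxph.fit(matrix(x, ncol = 1L), Surv(time, event),
                           strata = NULL, offset = NULL, init = 0,
                           control = survival::coxph.control(),
                           weights = NULL, method = "efron", rownames = NULL)
  b <- unname(f$coefficients)
  if (!is.finite(b)) stop("Cox fit did not converge", call. = FALSE)
  b
}

#' Signed model-based concordance probability
#'
#' Pairwise concordance probability in the style of Gonen & Heller (2005),
#' with a pre-specified benefit direction. With linear predictor
#' \eqn{\eta_i = \beta x_i}, each unordered pair of patients with different
#' covariate values contributes the model-based probability that the patient
#' with the better covariate value outlives the other,
#' \eqn{1 / (1 + \exp(\eta_{better} - \eta_{other}))}; tied covariate values
#' contribute 1/2, and the estimate is the mean over all pairs. Censoring
#' enters only through the Cox fit that produced `beta`.
#'
#' Because the benefit direction is pre-specified per metric (higher TTG is
#' better, lower GR is better), a fitted coefficient whose sign contradicts
#' expectation yields an estimate below 0.5 — a covariate anti-concordant
#' with its assumed direction — which the unsigned estimator cannot express.
#' A value of 0.5 means no consistent covariate-survival relationship; in
#' particular `beta = 0` gives exactly 0.5 for any cohort.
#'
#' @param beta Cox proportional-hazards coefficient for `x` (from
#'   [fit_cox()] on the same data).
#' @param x covariate values.
#' @param direction `"higher"` if larger covariate values are expected to be
#'   beneficial (e.g. TTG), `"lower"` if smaller values are (e.g. GR).
#' @return the concordance probability, a number in \[0, 1\].
#' @export
#' @examples
#' concordance_probability(0, rnorm(20), "higher") # exactly 0.5
concordance_probability <- function(beta, x, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (length(x) < 2L) stop("need at least 2 patients", call. = FALSE)
  if (anyNA(x) || !is.finite(beta)) stop("inputs must be finite", call. = FALSE)
  s <- if (direction == "lower") 1 else -1
  .cp_pairwise_cpp(s * beta, as.numeric(x))
}

#' Percentile bootstrap for a cohort-level statistic
#'
#' Resamples patients (rows) with replacement at the original cohort size,
#' recomputes `statistic` on each replicate, and returns the percentile
#' interval. Significance against the null concordance value is declared
#' when the interval excludes 0.5.
#'
#' @param statistic function mapping a resampled cohort `data.frame` to a
#'   scalar.
#' @param data cohort `data.frame`, one row per patient.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param level confidence level of the percentile interval.
#' @param seed optional integer seed for reproducibility.
#' @return a list of class `concordance_result`: `cp` (statistic on the full
#'   cohort), `ci_low`, `ci_high`, `n_boot`, `significant` (interval
#'   excludes 0.5), `boot_values`.
#' @export
bootstrap_ci <- function(statistic, data, n_boot = 1000L, level = 0.95,
                         seed = NULL) {
  stopifnot(is.function(statistic), is.data.frame(data), n_boot >= 2,
            level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  vals <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    tryCatch(as.numeric(statistic(data[idx, , drop = FALSE])),
             error = function(e) NA_real_)
  }, numeric(1))
  n_fail <- sum(is.na(vals))
  if (n_fail > 0.10 * n_boot)
    stop(sprintf("statistic failed on %d of %d bootstrap replicates",
                 n_fail, n_boot), call. = FALSE)
  alpha <- (1 - level) / 2
  ci <- unname(quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE))
  point <- as.numeric(statistic(data))
  structure(list(cp = point, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot),
                 significant = ci[1] > 0.5 || ci[2] < 0.5,
                 level = level, boot_values = vals),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("CP = %.3f (%.0f%% CI %.3f-%.3f, %d bootstrap samples)%s\n",
              x$cp, 100 * x$level, x$ci_low, x$ci_high, x$n_boot,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Concordance-probability analysis of one metric
#'
#' Convenience composition used for each cell of a forward/reverse
#' concordance table: fit the univariate Cox model, evaluate the signed
#' model-based concordance probability, and attach a patient-level
#' percentile bootstrap interval (Cox fit and CP re-evaluated on each
#' replicate).
#'
#' @inheritParams concordance_probability
#' @inheritParams fit_cox
#' @inheritParams bootstrap_ci
#' @return a `concordance_result` (see [bootstrap_ci()]), with the fitted
#'   `beta` attached.
#' @export
cp_analysis <- function(x, time_weeks, event, direction = c("higher", "lower"),
                        n_boot = 1000L, level = 0.95, seed = NULL) {
  direction <- match.arg(direction)
  df <- data.frame(x = x, time = time_weeks, event = event)
  stat <- function(d) {
    concordance_probability(fast_cox_beta(d$x, d$time, d$event), d$x,
                            direction)
  }
  res <- bootstrap_ci(stat, df, n_boot = n_boot, level = level, seed = seed)
  res$beta <- fast_cox_beta(x, time_weeks, event)
  res$direction <- direction
  res
}

#' Kaplan-Meier median with log-log confidence interval
#'
#' @inheritParams fit_cox
#' @param level confidence level.
#' @return a list `median`, `ci_low`, `ci_high` in weeks; all `NA` when the
#'   survival curve never reaches 0.5 (median not estimable).
#' @export
km_median <- function(time_weeks, event, level = 0.95) {
  if (sum(event) == 0) stop("no events: Kaplan-Meier median undefined", call. = FALSE)
  fit <- survfit(Surv(time_weeks, event) ~ 1, conf.type = "log-log",
                 conf.int = level)
  q <- quantile(fit, probs = 0.5)
  list(median = unname(q$quantile), ci_low = unname(q$lower),
       ci_high = unname(q$upper))
}

#' Hazard ratio between two arms
#'
#' `exp(beta)` from a Cox fit (Efron ties) on the arm indicator, test versus
#' reference, with a Wald confidence interval. Values below 1 favour the
#' test arm.
#'
#' @param time_test,event_test survival records of the test arm (weeks).
#' @param time_ref,event_ref survival records of the reference arm.
#' @param level confidence level.
#' @return a list `hr`, `ci_low`, `ci_high`, `beta`, `se`.
#' @export
hazard_ratio <- function(time_test, event_test, time_ref, event_ref,
                         level = 0.95) {
  if (sum(event_test) == 0 || sum(event_ref) == 0)
    stop("both arms must have events", call. = FALSE)
  time <- c(time_test, time_ref)
  event <- c(event_test, event_ref)
  arm <- rep(c(1, 0), c(length(time_test), length(time_ref)))
  fit <- coxph(Surv(time, event) ~ arm, ties = "efron")
  beta <- unname(coef(fit)); se <- sqrt(unname(vcov(fit)[1, 1]))
  z <- qnorm(1 - (1 - level) / 2)
  list(hr = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       beta = beta, se = se)
}
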