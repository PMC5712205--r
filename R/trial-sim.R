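#' Resample one head-to-head test trial
#'
#' Draws patients with replacement from two historical arms — the exact arm
#' sizes of the emulated head-to-head trial — carrying each patient's full
#' record (survival times and model-derived metrics) intact.
#'
#' @param arm_test,arm_ref per-patient `data.frame`s (test and reference
#'   arm) with at least `pfs_weeks`, `pfs_event`, `GR`, `TTG` columns.
#' @param n_test,n_ref numbers of patients to draw; the defaults 110 and 112
#'   are the arm sizes of the emulated second-line NSCLC head-to-head trial
#'   (docetaxel test arm versus erlotinib reference arm).
#' @return a list with resampled `test` and `ref` `data.frame`s.
#' @export
resample_trial <- function(arm_test, arm_ref, n_test = 110L, n_ref = 112L) {
  if (nrow(arm_test) == 0L || nrow(arm_ref) == 0L)
    stop("arms must be non-empty", call. = FALSE)
  if (n_test < 2L || n_ref < 2L) stop("arm sizes must be at least 2", call. = FALSE)
  list(test = arm_test[sample.int(nrow(arm_test), n_test, replace = TRUE), ,
                       drop = FALSE],
       ref = arm_ref[sample.int(nrow(arm_ref), n_ref, replace = TRUE), ,
                     drop = FALSE])
}

#' Ratio of arm-level mean metrics, HR-oriented
#'
#' Ratio of the mean metric values between the two arms of a test trial,
#' oriented so that values below 1 read like a hazard ratio favouring the
#' test arm: for GR (growth is harmful) the ratio is
#' `mean(test) / mean(ref)`; for TTG (longer time to re-growth is
#' beneficial) it is `mean(ref) / mean(test)`.
#'
#' @param metric_test,metric_ref per-patient metric values in each arm.
#' @param orientation `"gr"` or `"ttg"`.
#' @return the oriented ratio (> 0).
#' @export
ratio_of_means <- function(metric_test, metric_ref,
                           orientation = c("gr", "ttg")) {
  orientation <- match.arg(orientation)
  mt <- mean(metric_test); mr <- mean(metric_ref)
  if (!is.finite(mt) || !is.finite(mr) || mt <= 0 || mr <= 0)
    stop("arm means must be positive", call. = FALSE)
  if (orientation == "gr") mt / mr else mr / mt
}

#' Simulate resampled head-to-head test trials
#'
#' Group-risk analysis: generates `replicates` test-trial datasets by
#' resampling each historical arm with replacement at the head-to-head arm
#' sizes, and for each replicate computes the PFS hazard ratio
#' ([hazard_ratio()]) and the oriented ratios of mean GR and mean TTG
#' ([ratio_of_means()]). The three per-replicate distributions are the
#' trial-level predictions of the OS hazard ratio; they are proxies — ratios
#' of kinetic means are reported on the HR scale without any formal
#' surrogacy mapping. Per-patient GR/TTG entering the resampler come from a
#' single population fit per arm (fit once, resample patients).
#'
#' @inheritParams resample_trial
#' @param replicates number of resampled trials.
#' @param seed optional integer seed.
#' @param observed_os_hr optional list (`hr`, `ci_low`, `ci_high`) with the
#'   observed head-to-head OS hazard ratio, stored for overlay/reporting.
#' @return an object of class `trial_sim_result`: `replicates`
#'   (`data.frame` with `replicate`, `pfs_hr`, `gr_ratio`, `ttg_ratio`),
#'   `summary` (median and 2.5/97.5 percentiles per metric), `r2_ttg_gr`
#'   (squared Pearson correlation between the TTG and GR ratios across
#'   replicates), `observed_os_hr`, `n_test`, `n_ref`.
#' @export
simulate_test_trials <- function(arm_test, arm_ref, n_test = 110L,
                                 n_ref = 112L, replicates = 1000L,
                                 seed = NULL, observed_os_hr = NULL) {
  need <- c("pfs_weeks", "pfs_event", "GR", "TTG")
  for (nm in need) {
    if (!nm %in% names(arm_test) || !nm %in% names(arm_ref))
      stop("arms need column '", nm, "'", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, replicates, 3L,
                dimnames = list(NULL, c("pfs_hr", "gr_ratio", "ttg_ratio")))
  for (b in seq_len(replicates)) {
    res <- tryCatch({
      tr <- resample_trial(arm_test, arm_ref, n_test, n_ref)
      if (sum(tr$test$pfs_event) == 0 || sum(tr$ref$pfs_event) == 0)
        stop("no events in a resampled arm")
      beta <- fast_cox_beta(rep(c(1, 0), c(n_test, n_ref)),
                            c(tr$test$pfs_weeks, tr$ref$pfs_weeks),
                            c(tr$test$pfs_event, tr$ref$pfs_event))
      c(exp(beta),
        ratio_of_means(tr$test$GR, tr$ref$GR, "gr"),
        ratio_of_means(tr$test$TTG, tr$ref$TTG, "ttg"))
    }, error = function(e) rep(NA_real_, 3L))
    out[b, ] <- res
  }
  n_fail <- sum(!stats::complete.cases(out))
  if (n_fail > 0.05 * replicates)
    stop(sprintf("%d of %d resampled trials failed", n_fail, replicates),
         call. = FALSE)
  reps <- data.frame(replicate = seq_len(replicates), out)
  summ <- t(apply(out, 2L, quantile, probs = c(0.5, 0.025, 0.975),
                  na.rm = TRUE))
  colnames(summ) <- c("median", "q2.5", "q97.5")
  ok <- stats::complete.cases(out)
  r2 <- cor(out[ok, "ttg_ratio"], out[ok, "gr_ratio"])^2
  structure(list(replicates = reps, summary = as.data.frame(summ),
                 r2_ttg_gr = r2, observed_os_hr = observed_os_hr,
                 n_test = as.integer(n_test), n_ref = as.integer(n_ref),
                 n_failed = n_fail),
            class = "trial_sim_result")
}

#' @export
print.trial_sim_result <- function(x, ...) {
  cat(sprintf("Resampled test trials: %d replicates (arm sizes %d test / %d ref)\n",
              nrow(x$replicates), x$n_test, x$n_ref))
  cat("Predicted OS-HR distributions (median [95% prediction interval]):\n")
  for (m in rownames(x$summary)) {
    s <- x$summary[m, ]
    cat(sprintf("  %-9s %.2f [%.2f-%.2f]\n", m, s$median, s$q2.5, s$q97.5))
  }
  cat(sprintf("r^2 between TTG and GR ratios: %.3f\n", x$r2_ttg_gr))
  if (!is.null(x$observed_os_hr))
    cat(sprintf("Observed OS HR: %.2f (%.2f-%.2f)\n", x$observed_os_hr$hr,
                x$observed_os_hr$ci_low, x$observed_os_hr$ci_high))
  invisible(x)
}
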