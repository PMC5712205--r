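#' Specification of a synthetic trial arm
#'
#' Describes one simulated comparator arm: biexponential SLD kinetics with
#' log-normal inter-individual variability, a fixed scan schedule with
#' optional uniform jitter, additive Gaussian measurement noise on the cm
#' scale, a RECIST-like progression rule (SLD at least
#' `1 + progression_threshold` times the running nadir), progression- or
#' death-triggered end of imaging, and a configurable post-progression
#' survival model.
#'
#' `post_progression` is either
#' \describe{
#'   \item{null}{`list(model = "null", rate = r)` — post-progression
#'     survival is exponential with rate `r` per week, independent of the
#'     patient's kinetics (the mechanism under which tumour dynamics up to
#'     progression carry no information about survival beyond it);}
#'   \item{linked}{`list(model = "linked", base_rate = r, gamma_gr = g1,
#'     gamma_ttg = g2)` — log-hazard `log(r) + g1 * GR_true + g2 *
#'     TTG_true`, linking post-progression survival to the true kinetics.}
#' }
#'
#' @param n_patients number of patients in the arm.
#' @param scan_interval weeks between scheduled scans (6 or 8 in the
#'   emulated phase III protocols).
#' @param max_followup last scheduled scan time (weeks).
#' @param mu log-scale population means of (A, B, C).
#' @param omega2 log-scale population variances of (A, B, C); diagonal.
#' @param sigma additive measurement noise SD (cm).
#' @param progression_threshold fractional rise over the running nadir that
#'   triggers progressive disease (default 0.20, RECIST-1.0-like on SLD).
#' @param post_progression post-progression survival model, see Details.
#' @param death_during_imaging_prob per-interval probability of death while
#'   still on imaging; these deaths are the small "progression by death"
#'   subset.
#' @param censoring_time administrative censoring time (weeks) for both PFS
#'   and OS.
#' @param scan_jitter half-width (weeks) of the uniform jitter applied to
#'   scheduled on-treatment scan times (0 = exact schedule).
#' @param seed optional integer seed recorded in the spec and applied by
#'   [generate_cohort()].
#' @return a list of class `cohort_spec`.
#' @seealso [nsclc_arm_spec()] for presets emulating the three NSCLC
#'   comparator arms.
#' @export
cohort_spec <- function(n_patients, scan_interval, max_followup, mu, omega2,
                        sigma, progression_threshold = 0.20,
                        post_progression = list(model = "null",
                                                rate = log(2) / 22.6),
                        death_during_imaging_prob = 0.02,
                        censoring_time = 130, scan_jitter = 0, seed = NULL) {
  stopifnot(n_patients >= 1, scan_interval > 0,
            max_followup >= scan_interval, length(mu) == 3L,
            length(omega2) == 3L, all(omega2 >= 0), sigma >= 0,
            progression_threshold > 0,
            death_during_imaging_prob >= 0, death_during_imaging_prob < 1,
            censoring_time > 0, scan_jitter >= 0,
            scan_jitter < scan_interval / 2)
  if (!is.list(post_progression) ||
      !post_progression$model %in% c("null", "linked"))
    stop("post_progression$model must be 'null' or 'linked'", call. = FALSE)
  if (post_progression$model == "null") {
    if (!is.numeric(post_progression$rate) || post_progression$rate <= 0)
      stop("null post-progression model needs a positive rate", call. = FALSE)
  } else {
    if (!is.numeric(post_progression$base_rate) ||
        post_progression$base_rate <= 0)
      stop("linked post-progression model needs a positive base_rate",
           call. = FALSE)
    post_progression$gamma_gr <- post_progression$gamma_gr %||% 0
    post_progression$gamma_ttg <- post_progression$gamma_ttg %||% 0
  }
  structure(list(n_patients = as.integer(n_patients),
                 scan_interval = scan_interval, max_followup = max_followup,
                 mu = unname(mu), omega2 = unname(omega2), sigma = sigma,
                 progression_threshold = progression_threshold,
                 post_progression = post_progression,
                 death_during_imaging_prob = death_during_imaging_prob,
                 censoring_time = censoring_time, scan_jitter = scan_jitter,
                 seed = seed),
            class = "cohort_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preset cohort specifications emulating three NSCLC comparator arms
#'
#' Returns a [cohort_spec()] calibrated so that simulated arms land near the
#' published imaging and survival summaries of the three phase III NSCLC
#' comparator arms: a second-line docetaxel-like arm (8-weekly scans, median
#' baseline SLD about 8.3 cm, median PFS about 4 months), a second-line
#' erlotinib-like arm (6-weekly scans, short survival follow-up so the OS
#' median is typically not estimable), and a first-line
#' paclitaxel/carboplatin-like arm (8-weekly scans, larger baseline burden,
#' deeper response, longer PFS). All presets use the null (kinetics-
#' independent) post-progression model by default.
#'
#' @param arm one of `"docetaxel"`, `"erlotinib"`,
#'   `"paclitaxel_carboplatin"`.
#' @param n_patients arm size; defaults to the published arm totals (399,
#'   369, 413).
#' @param seed optional integer seed stored in the spec.
#' @param ... overrides passed on to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
nsclc_arm_spec <- function(arm = c("docetaxel", "erlotinib",
                                   "paclitaxel_carboplatin"),
                           n_patients = NULL, seed = NULL, ...) {
  arm <- match.arg(arm)
  base <- switch(arm,
    docetaxel = list(n_patients = 399L, scan_interval = 8, max_followup = 96,
                     mu = log(c(8.3, 0.06, 0.04)),
                     omega2 = c(0.4, 0.5, 0.5)^2, sigma = 0.3,
                     post_progression = list(model = "null",
                                             rate = log(2) / 22.6),
                     death_during_imaging_prob = 0.02, censoring_time = 130),
    erlotinib = list(n_patients = 369L, scan_interval = 6, max_followup = 96,
                     mu = log(c(8, 0.05, 0.035)),
                     omega2 = c(0.45, 0.5, 0.5)^2, sigma = 0.3,
                     post_progression = list(model = "null",
                                             rate = log(2) / 22.6),
                     death_during_imaging_prob = 0.03, censoring_time = 30),
    paclitaxel_carboplatin = list(n_patients = 413L, scan_interval = 8,
                     max_followup = 96, mu = log(c(10.7, 0.05, 0.02)),
                     omega2 = c(0.4, 0.5, 0.5)^2, sigma = 0.3,
                     post_progression = list(model = "null",
                                             rate = log(2) / 17.8),
                     death_during_imaging_prob = 0.005, censoring_time = 130))
  if (!is.null(n_patients)) base$n_patients <- n_patients
  over <- list(...)
  base[names(over)] <- over
  base$seed <- seed
  do.call(cohort_spec, base)
}

#' First scan triggering RECIST-like progression
#'
#' Returns the 1-based index of the first scan whose SLD is at least
#' `(1 + threshold)` times the running nadir of all earlier scans, or
#' `NA_integer_` if no scan qualifies. The baseline scan can never trigger
#' progression. With `threshold = 0` this degenerates to the first uptick
#' from the running nadir.
#'
#' @param sld_cm SLD values in scan order.
#' @param threshold fractional rise over the nadir (default 0.20).
#' @return integer index or `NA_integer_`.
#' @export
#' @examples
#' apply_progression(c(5.0, 4.0, 4.9), threshold = 0.2) # 3
apply_progression <- function(sld_cm, threshold = 0.20) {
  n <- length(sld_cm)
  if (n == 0L) stop("empty series", call. = FALSE)
  if (n == 1L) return(NA_integer_)
  nadir <- cummin(sld_cm)[-n]
  hit <- which(sld_cm[-1L] >= (1 + threshold) * nadir)
  if (length(hit) == 0L) NA_integer_ else hit[1L] + 1L
}

#' Generate a synthetic trial arm
#'
#' Simulates one arm according to a [cohort_spec()]: draws each patient's
#' (A, B, C) log-normally, evaluates the biexponential model on the scan
#' grid, adds N(0, sigma^2) noise floored at 0.1 cm, calls progression with
#' [apply_progression()], truncates imaging at progression (or at a death
#' occurring during imaging), sets PFS to the progression scan time or death
#' time, draws post-progression survival from the specified model, and
#' applies administrative censoring to both endpoints. For patients with no
#' progression within follow-up, PFS is censored at the last scan.
#'
#' @param spec a `cohort_spec`.
#' @param seed optional integer seed; overrides `spec$seed` when given.
#' @return a list of class `synthetic_cohort`:
#'   \describe{
#'     \item{assessments}{long-format table `patient_id`, `time_weeks`,
#'       `sld_cm` (imaging up to and including the progression scan);}
#'     \item{survival}{`patient_id`, `pfs_weeks`, `pfs_event`, `os_weeks`,
#'       `os_event`, `progression_is_death`;}
#'     \item{params_true}{per-patient ground truth `A`, `B`, `C`,
#'       `tp_true` (unclamped turning point), `gr_true`, `dr_true`,
#'       `ttg_true` (clamped to the scheduled follow-up);}
#'     \item{spec}{the generating spec, with the seed actually used.}
#'   }
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)
  spec$seed <- seed
  n <- spec$n_patients
  grid <- seq(0, spec$max_followup, by = spec$scan_interval)

  eta <- matrix(rnorm(3L * n, mean = spec$mu, sd = sqrt(spec$omega2)), 3L, n)
  th <- exp(eta)

  ids <- sprintf("P%04d", seq_len(n))
  arows <- vector("list", n)
  pfs <- os <- numeric(n)
  pfs_e <- os_e <- integer(n)
  isdeath <- logical(n)

  for (i in seq_len(n)) {
    p <- kinetic_params(th[1L, i], th[2L, i], th[3L, i])
    tt <- grid
    if (spec$scan_jitter > 0 && length(tt) > 1L) {
      tt[-1L] <- tt[-1L] + runif(length(tt) - 1L, -spec$scan_jitter,
                                 spec$scan_jitter)
      tt <- sort(tt)
    }
    y <- pmax(sld_at(p, tt) + rnorm(length(tt), 0, spec$sigma), 0.1)

    # death while still on imaging: small per-interval hazard
    d_int <- which(runif(length(tt) - 1L) < spec$death_during_imaging_prob)
    death_time <- if (length(d_int)) tt[d_int[1L]] +
        runif(1) * (tt[d_int[1L] + 1L] - tt[d_int[1L]]) else Inf

    prog_idx <- apply_progression(y, spec$progression_threshold)
    prog_time <- if (is.na(prog_idx)) Inf else tt[prog_idx]

    if (death_time < prog_time) {           # progression event is death
      keep <- tt < death_time
      pfs[i] <- death_time; pfs_e[i] <- 1L; isdeath[i] <- TRUE
      os_raw <- death_time
    } else if (is.finite(prog_time)) {      # radiological progression
      keep <- seq_along(tt) <= prog_idx
      pfs[i] <- prog_time; pfs_e[i] <- 1L
      os_raw <- prog_time + post_progression_draw(spec, th[3L, i],
                                                  ttg_true(p, spec$max_followup))
    } else {                                # no progression within follow-up
      keep <- rep(TRUE, length(tt))
      pfs[i] <- tt[length(tt)]; pfs_e[i] <- 0L
      os_raw <- tt[length(tt)] + post_progression_draw(spec, th[3L, i],
                                                  ttg_true(p, spec$max_followup))
    }
    arows[[i]] <- data.frame(patient_id = ids[i], time_weeks = tt[keep],
                             sld_cm = y[keep], stringsAsFactors = FALSE)

    os_e[i] <- as.integer(os_raw <= spec$censoring_time)
    os[i] <- min(os_raw, spec$censoring_time)
    if (pfs[i] > spec$censoring_time) {
      pfs[i] <- spec$censoring_time; pfs_e[i] <- 0L; isdeath[i] <- FALSE
    }
  }

  assessments <- do.call(rbind, arows)
  survival <- data.frame(patient_id = ids, pfs_weeks = pfs,
                         pfs_event = pfs_e, os_weeks = os, os_event = os_e,
                         progression_is_death = isdeath,
                         stringsAsFactors = FALSE)
  tp <- (eta[2L, ] - eta[3L, ]) / (th[2L, ] + th[3L, ])
  params_true <- data.frame(patient_id = ids, A = th[1L, ], B = th[2L, ],
                            C = th[3L, ], tp_true = tp,
                            dr_true = th[2L, ], gr_true = th[3L, ],
                            ttg_true = pmin(pmax(tp, 0), spec$max_followup),
                            stringsAsFactors = FALSE)
  structure(list(assessments = assessments, survival = survival,
                 params_true = params_true, spec = spec),
            class = "synthetic_cohort")
}

ttg_true <- function(p, span) min(max(turning_point(p), 0), span)

post_progression_draw <- function(spec, gr, ttg) {
  pp <- spec$post_progression
  rate <- if (pp$model == "null") pp$rate
          else exp(log(pp$base_rate) + pp$gamma_gr * gr + pp$gamma_ttg * ttg)
  rexp(1L, rate)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d assessments (seed %s)\n",
              nrow(x$survival), nrow(x$assessments),
              x$spec$seed %||% "unset"))
  cat(sprintf("  progressions: %d (of which deaths: %d), OS events: %d\n",
              sum(x$survival$pfs_event),
              sum(x$survival$progression_is_death),
              sum(x$survival$os_event)))
  invisible(x)
}
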