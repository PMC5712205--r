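#' Reverse-align one SLD time series
#'
#' Reflects a forward-aligned series about its last included scan, so that
#' the progression scan becomes time 0 and the series runs backwards toward
#' baseline on a non-negative clock: each observation time \eqn{t_i} maps to
#' \eqn{t_{last} - t_i} and the observations are re-ordered so times ascend
#' from 0. SLD values are unchanged and stay paired with their scans, and
#' the observation span is preserved. Applying the transform twice returns
#' the original series.
#'
#' The reflected clock runs forward from progression into the past rather
#' than along a negative time axis; the two are equivalent up to reflection,
#' and a non-negative clock lets the same model code fit both alignments.
#' "Time of progression" for imaging is the last scan of the series, since
#' scan collection stops at progression under the trial protocols emulated
#' here.
#'
#' @param time_weeks scan times in weeks, ascending from 0 (at least 2).
#' @param sld_cm SLD values (cm) paired with `time_weeks`.
#' @return a list with elements `time` (reversed clock, ascending from 0),
#'   `sld`, and `observation_span` (weeks).
#' @export
#' @examples
#' reverse_align_series(c(0, 6, 12, 18), c(8, 6.5, 6.8, 8.4))
reverse_align_series <- function(time_weeks, sld_cm) {
  if (length(time_weeks) < 2L)
    stop("reverse alignment needs at least 2 observations", call. = FALSE)
  if (length(time_weeks) != length(sld_cm))
    stop("time and SLD vectors must have equal length", call. = FALSE)
  if (anyNA(time_weeks) || anyNA(sld_cm))
    stop("missing values in series", call. = FALSE)
  o <- order(time_weeks)
  t <- time_weeks[o]; y <- sld_cm[o]
  if (any(diff(t) <= 0)) stop("scan times must be strictly increasing", call. = FALSE)
  rt <- t[length(t)] - t
  o2 <- order(rt)
  list(time = rt[o2], sld = y[o2], observation_span = t[length(t)] - t[1L])
}

#' Post-progression survival records
#'
#' Builds the reverse-alignment outcome, overall survival minus
#' progression-free survival (OS - PFS), for every patient with an observed
#' progression. The OS event indicator is carried over. Patients whose
#' progression event was itself death (zero post-progression time with no
#' imaging beyond progression) are flagged for exclusion from
#' reverse-alignment survival analysis rather than silently dropped; the
#' returned attribute `n_excluded` counts them.
#'
#' @param survival a survival table with columns `patient_id`, `pfs_weeks`,
#'   `pfs_event`, `os_weeks`, `os_event` and (optionally)
#'   `progression_is_death` (see [read_survival()]).
#' @return a `data.frame` with columns `patient_id`, `time_weeks`
#'   (OS - PFS), `event`, and `excluded` (progression-by-death flag); only
#'   patients with `pfs_event == 1` appear. Attribute `n_excluded` gives the
#'   number of flagged rows.
#' @export
post_progression_survival <- function(survival) {
  survival <- validate_survival(survival)
  s <- survival[survival$pfs_event == 1, , drop = FALSE]
  if (any(s$os_weeks < s$pfs_weeks))
    stop("data integrity error: OS time earlier than PFS time for patient(s) ",
         paste(head(s$patient_id[s$os_weeks < s$pfs_weeks], 5L), collapse = ", "),
         call. = FALSE)
  out <- data.frame(patient_id = s$patient_id,
                    time_weeks = s$os_weeks - s$pfs_weeks,
                    event = s$os_event,
                    excluded = s$progression_is_death,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(out$excluded)
  out
}

# table-level reverse alignment helper used by analysis drivers: reflects
# every patient's series in a long-format assessment table; single-scan
# patients cannot be reflected and are dropped with a warning
reverse_align_assessments <- function(assessments) {
  assessments <- validate_assessments(assessments)
  series <- split_series(assessments)
  single <- names(series)[vapply(series, function(s) length(s$time) < 2L,
                                 logical(1))]
  if (length(single)) {
    warning(sprintf("%d single-scan patient(s) dropped in reverse alignment",
                    length(single)), call. = FALSE)
    series <- series[setdiff(names(series), single)]
  }
  rows <- lapply(names(series), function(id) {
    r <- reverse_align_series(series[[id]]$time, series[[id]]$sld)
    data.frame(patient_id = id, time_weeks = r$time, sld_cm = r$sld,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
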