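# Tabular I/O: RFC-4180 CSVs with a "#" comment header carrying version,
# seed and config hash, so that identical inputs give byte-identical files.

validate_assessments <- function(x) {
  if (!is.data.frame(x)) stop("assessments must be a data.frame", call. = FALSE)
  need <- c("patient_id", "time_weeks", "sld_cm")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("assessment table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$patient_id <- as.character(x$patient_id)
  bad <- which(!is.finite(x$time_weeks) | x$time_weeks < 0)
  if (length(bad))
    stop("negative or non-finite time_weeks in row(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(x$sld_cm) | x$sld_cm <= 0)
  if (length(bad))
    stop("non-positive or non-finite sld_cm in row(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  key <- paste(x$patient_id, x$time_weeks)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (patient_id, time_weeks) in row(s): ",
         paste(head(dup, 10L), collapse = ", "), call. = FALSE)
  x[need]
}

validate_survival <- function(x) {
  if (!is.data.frame(x)) stop("survival must be a data.frame", call. = FALSE)
  need <- c("patient_id", "pfs_weeks", "pfs_event", "os_weeks", "os_event")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("survival table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$patient_id <- as.character(x$patient_id)
  if (!"progression_is_death" %in% names(x)) x$progression_is_death <- FALSE
  x$progression_is_death <- as.logical(x$progression_is_death)
  bad <- which(!is.finite(x$pfs_weeks) | x$pfs_weeks <= 0 |
               !is.finite(x$os_weeks) | x$os_weeks <= 0)
  if (length(bad))
    stop("non-positive survival time in row(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  bad <- which(!(x$pfs_event %in% c(0, 1)) | !(x$os_event %in% c(0, 1)))
  if (length(bad))
    stop("event indicators must be 0/1; offending row(s): ",
         paste(head(bad, 10L), collapse = ", "), call. = FALSE)
  dup <- which(duplicated(x$patient_id))
  if (length(dup))
    stop("duplicate patient_id in row(s): ",
         paste(head(dup, 10L), collapse = ", "), call. = FALSE)
  x[c(need, "progression_is_death")]
}

file_header <- function(seed = NULL, config = NULL) {
  h <- sprintf("# tgmetrics %s",
               as.character(utils::packageVersion("tgmetrics")))
  h <- c(h, sprintf("# seed: %s", if (is.null(seed)) "unset" else seed))
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(paste(deparse(config), collapse = ""), tf)
    h <- c(h, sprintf("# config: md5 %s", unname(tools::md5sum(tf))))
  }
  h
}

write_table_commented <- function(x, path, seed, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(file_header(seed, config), con)
  write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write assessment and survival tables
#'
#' Long-format CSVs: assessments carry `patient_id,time_weeks,sld_cm` (one
#' scan per row, times in weeks with 4-decimal precision, SLD in cm);
#' survival tables carry
#' `patient_id,pfs_weeks,pfs_event,os_weeks,os_event,progression_is_death`
#' (one patient per row). Lines starting with `#` are metadata comments
#' written by the `write_*` functions (package version, seed, config hash)
#' and are skipped on read. Rows violating the table invariants
#' (non-positive SLD, negative times, duplicate keys, non-0/1 events) are
#' rejected with row-numbered messages.
#'
#' @param path CSV file path.
#' @return validated `data.frame`.
#' @export
read_assessments <- function(path) {
  validate_assessments(read.csv(path, comment.char = "#",
                                stringsAsFactors = FALSE))
}

#' @rdname read_assessments
#' @export
read_survival <- function(path) {
  validate_survival(read.csv(path, comment.char = "#",
                             stringsAsFactors = FALSE))
}

#' @rdname read_assessments
#' @param x table to write.
#' @param seed,config optional provenance recorded in the comment header.
#' @export
write_assessments <- function(x, path, seed = NULL, config = NULL) {
  x <- validate_assessments(x)
  x$time_weeks <- round(x$time_weeks, 4L)
  x$sld_cm <- round(x$sld_cm, 4L)
  write_table_commented(x, path, seed, config)
}

#' @rdname read_assessments
#' @export
write_survival <- function(x, path, seed = NULL, config = NULL) {
  x <- validate_survival(x)
  num <- c("pfs_weeks", "os_weeks")
  x[num] <- lapply(x[num], round, 4L)
  write_table_commented(x, path, seed, config)
}

#' Cohort summary in the style of a trial characteristics table
#'
#' Computes, for one arm, the event counts, median baseline SLD with IQR,
#' the observed percent change between baseline and the first on-treatment
#' scan falling in weeks 6-10 (median and IQR), and Kaplan-Meier medians
#' with log-log confidence intervals (reported in months) for PFS, OS and
#' post-progression survival (OS - PFS, progression-by-death patients
#' excluded). Fields whose inputs do not exist (no scan in the week 6-10
#' window, survival curve never reaching 0.5) are `NA`, not zero.
#'
#' @param assessments assessment table (see [read_assessments()]).
#' @param survival survival table sharing the same patient ids.
#' @return a list of class `cohort_summary`.
#' @export
summarize_cohort <- function(assessments, survival) {
  assessments <- validate_assessments(assessments)
  survival <- validate_survival(survival)
  ids <- intersect(unique(assessments$patient_id), survival$patient_id)
  if (length(ids) == 0L)
    stop("assessment and survival tables share no patient ids", call. = FALSE)

  series <- split_series(assessments[assessments$patient_id %in% ids, ])
  base <- vapply(series, function(s) s$sld[1L], numeric(1))
  pc <- vapply(series, function(s) {
    k <- which(s$time >= 6 & s$time <= 10)[1L]
    if (is.na(k)) NA_real_ else 100 * (s$sld[k] - s$sld[1L]) / s$sld[1L]
  }, numeric(1))

  sv <- survival[survival$patient_id %in% ids, ]
  km_m <- function(t, e) {
    if (sum(e) == 0) return(list(median = NA_real_, ci_low = NA_real_,
                                 ci_high = NA_real_))
    r <- km_median(t, e)
    lapply(r, weeks_to_months)
  }
  pps <- post_progression_survival(sv)
  pps_ok <- pps[!pps$excluded & pps$time_weeks > 0, , drop = FALSE]

  structure(list(
    n_total = nrow(sv),
    n_death_events = sum(sv$os_event),
    n_progression_events = sum(sv$pfs_event),
    n_progressions_by_death = sum(sv$progression_is_death & sv$pfs_event == 1),
    median_baseline_sld = median(base),
    iqr_baseline_sld = unname(quantile(base, c(0.25, 0.75))),
    median_pct_change_w6_10 = if (all(is.na(pc))) NA_real_
                              else median(pc, na.rm = TRUE),
    iqr_pct_change_w6_10 = if (all(is.na(pc))) c(NA_real_, NA_real_)
                           else unname(quantile(pc, c(0.25, 0.75), na.rm = TRUE)),
    km_pfs_months = km_m(sv$pfs_weeks, sv$pfs_event),
    km_os_months = km_m(sv$os_weeks, sv$os_event),
    km_os_minus_pfs_months = if (nrow(pps_ok))
        km_m(pps_ok$time_weeks, pps_ok$event)
      else list(median = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt_km <- function(k) {
    if (is.na(k$median)) return("NA")
    sprintf("%.1f (%.1f-%.1f)", k$median,
            ifelse(is.na(k$ci_low), NA, k$ci_low),
            ifelse(is.na(k$ci_high), NA, k$ci_high))
  }
  cat(sprintf("Patients: %d | deaths: %d | progressions: %d (by death: %d)\n",
              x$n_total, x$n_death_events, x$n_progression_events,
              x$n_progressions_by_death))
  cat(sprintf("Baseline SLD: %.1f cm (IQR %.1f-%.1f)\n",
              x$median_baseline_sld, x$iqr_baseline_sld[1],
              x$iqr_baseline_sld[2]))
  if (!is.na(x$median_pct_change_w6_10))
    cat(sprintf("%% change weeks 6-10: %.1f (IQR %.1f-%.1f)\n",
                x$median_pct_change_w6_10, x$iqr_pct_change_w6_10[1],
                x$iqr_pct_change_w6_10[2]))
  cat(sprintf("Median PFS: %s months | OS: %s | OS-PFS: %s\n",
              fmt_km(x$km_pfs_months), fmt_km(x$km_os_months),
              fmt_km(x$km_os_minus_pfs_months)))
  invisible(x)
}

#' Proportion of progression events that are deaths
#'
#' Imaging stops at progression under the emulated protocols, so the
#' time-series drop-out mechanism is informative of survival only if
#' progression events are predominantly deaths. This check computes the
#' proportion of observed progression events that were deaths, with an exact
#' (Clopper-Pearson) binomial confidence interval; a small proportion
#' justifies analysing the longitudinal and survival data separately rather
#' than jointly.
#'
#' @param survival survival table with the `progression_is_death` flag.
#' @param level confidence level.
#' @return a list: `proportion`, `ci_low`, `ci_high`, `n_progressions`,
#'   `n_deaths`.
#' @export
dropout_assessment <- function(survival, level = 0.95) {
  survival <- validate_survival(survival)
  n_prog <- sum(survival$pfs_event == 1)
  if (n_prog == 0L) stop("no progression events", call. = FALSE)
  n_death <- sum(survival$progression_is_death & survival$pfs_event == 1)
  ci <- binom.test(n_death, n_prog, conf.level = level)$conf.int
  list(proportion = n_death / n_prog, ci_low = ci[1], ci_high = ci[2],
       n_progressions = n_prog, n_deaths = n_death)
}
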