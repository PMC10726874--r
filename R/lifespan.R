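# Organismal lifespan assays: pooling of biological repeats, Kaplan-Meier
# curves, logrank tests and the percent change in median lifespan.

check_survival_records <- function(records) {
  needed <- c("animal_id", "arm", "repeat_id", "day", "event")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("survival records lack column(s): ", paste(missing, collapse = ", "))
  if (any(records$day <= 0)) stop("death/censor days must be positive")
  bad <- setdiff(unique(records$event), c("death", "censored"))
  if (length(bad)) stop("unknown event label(s): ", paste(bad, collapse = ", "))
  invisible(records)
}

#' Pool biological repeats into one survival dataset
#'
#' Concatenates per-repeat record tables, preserving repeat labels.  Animal
#' identifiers that collide across repeats are re-keyed with a repeat prefix.
#'
#' @param datasets List of survival record data frames (columns `animal_id`,
#'   `arm`, `repeat_id`, `day`, `event`).
#' @return One pooled data frame.
#' @export
pool_repeats <- function(datasets) {
  if (!length(datasets)) stop("need at least one dataset")
  lapply(datasets, check_survival_records)
  pooled <- do.call(rbind, datasets)
  rownames(pooled) <- NULL
  if (anyDuplicated(pooled$animal_id)) {
    pooled$animal_id <- sprintf("r%s_%s", pooled$repeat_id, pooled$animal_id)
    if (anyDuplicated(pooled$animal_id))
      stop("conflicting animal ids within a repeat")
  }
  pooled
}

#' Kaplan-Meier curve and median for one arm
#'
#' Product-limit estimate over distinct death days; censored animals leave the
#' risk set after their day.  The median is the smallest observed day with
#' survival at or below one half (step-function convention); when the curve
#' never falls to 0.5 the median is `NA` and flagged.
#'
#' @param records Survival records (see [pool_repeats()]).
#' @param arm Arm label to estimate.
#' @return List with `arm`, `km_curve` (data frame `day`, `surv`),
#'   `median_day`, `median_defined`, `n`.
#' @export
km_curve <- function(records, arm) {
  check_survival_records(records)
  d <- records[records$arm == arm, , drop = FALSE]
  if (!nrow(d)) stop("no records for arm ", arm)
  if (!any(d$event == "death")) stop("no death event in arm ", arm)
  sf <- survival::survfit(
    survival::Surv(d$day, d$event == "death") ~ 1)
  step <- sf$n.event > 0   # the curve steps only at death days
  curve <- data.frame(day = sf$time[step], surv = sf$surv[step])
  below <- curve$day[curve$surv <= 0.5]
  median_day <- if (length(below)) min(below) else NA_real_
  list(arm = arm, km_curve = curve, median_day = median_day,
       median_defined = length(below) > 0, n = nrow(d))
}

#' Two-sample logrank test
#'
#' Standard (unstratified) logrank comparison of the two arms; a
#' repeat-stratified variant is available behind `stratify_repeats`.
#'
#' @param records Survival records with exactly two arms, each with at least
#'   one death.
#' @param stratify_repeats Stratify the test by `repeat_id`.
#' @return List with `chi2`, `df = 1`, `p_value`.
#' @export
logrank_test <- function(records, stratify_repeats = FALSE) {
  check_survival_records(records)
  arms <- unique(records$arm)
  if (length(arms) != 2)
    stop("logrank test needs exactly two arms, got ", length(arms))
  for (a in arms)
    if (!any(records$event[records$arm == a] == "death"))
      stop("no death event in arm ", a)
  records$.status <- as.numeric(records$event == "death")
  sd <- if (stratify_repeats)
    survival::survdiff(survival::Surv(day, .status) ~ arm +
                         survival::strata(repeat_id), data = records)
  else
    survival::survdiff(survival::Surv(day, .status) ~ arm, data = records)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, df = 1,
       p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Percent change in median lifespan
#'
#' @param treated_median,control_median Median lifespans in days;
#'   `control_median` must be positive.
#' @return `100 * (treated - control) / control`, rounded to one decimal.
#' @export
median_change_percent <- function(treated_median, control_median) {
  if (is.na(control_median) || control_median <= 0)
    stop("control median must be positive")
  round(100 * (treated_median - control_median) / control_median, 1)
}

#' Summarize a two-arm lifespan assay
#'
#' Pooled Kaplan-Meier medians per arm, the percent change of the treated
#' median, and the logrank test.  Optional bootstrap confidence intervals for
#' the medians (percentile method over animal resamples within arm).
#'
#' @param records Survival records with arms `control` and `treatment`.
#' @param n_boot Number of bootstrap resamples (0 to skip).
#' @param conf_level Confidence level of the bootstrap interval.
#' @return List with `control_median`, `treatment_median`, `change_percent`,
#'   `logrank` and (when `n_boot > 0`) `median_ci` (per-arm percentile
#'   intervals, clearly bootstrap-based).
#' @export
lifespan_summary <- function(records, n_boot = 0, conf_level = 0.95) {
  km_c <- km_curve(records, "control")
  km_t <- km_curve(records, "treatment")
  out <- list(control_median = km_c$median_day,
              treatment_median = km_t$median_day,
              change_percent = median_change_percent(km_t$median_day,
                                                     km_c$median_day),
              logrank = logrank_test(records))
  if (n_boot > 0) {
    boot_medians <- function(arm) {
      d <- records[records$arm == arm, , drop = FALSE]
      replicate(n_boot, {
        i <- sample.int(nrow(d), replace = TRUE)
        b <- d[i, , drop = FALSE]
        b$animal_id <- seq_len(nrow(b))
        km_curve(b, arm)$median_day
      })
    }
    qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
    out$median_ci <- list(
      method = "bootstrap percentile",
      control = quantile(boot_medians("control"), qs, na.rm = TRUE),
      treatment = quantile(boot_medians("treatment"), qs, na.rm = TRUE))
  }
  out
}
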