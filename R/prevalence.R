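#' Prevalence of positive scores per timepoint and group
#'
#' For each timepoint and group, the percentage of alive animals in a
#' SIRS state, flagged by the SOFA sepsis rule, and NEWS2-positive.
#' Denominators are the animals alive at the timepoint (dead animals are
#' censored), so they can only shrink over time. Percentages are rounded
#' to the nearest integer.
#'
#' @param timecourse A `cohort_timecourse` from [score_cohort()].
#' @return Object of class `prevalence_table`: data frame with columns
#'   `time_h`, `group`, `n_alive`, `sirs_pct`, `sofa_pct`, `news2_pct`.
#' @export
prevalence_table <- function(timecourse) {
  stopifnot(inherits(timecourse, "cohort_timecourse") ||
              is.data.frame(timecourse))
  if (nrow(timecourse) == 0L) stop("empty timecourse", call. = FALSE)
  pct <- function(x) round_half_away(100 * mean(x), 0)
  groups <- split(timecourse,
                  list(time = timecourse$time_h, group = timecourse$group),
                  drop = TRUE)
  rows <- lapply(groups, function(d) data.frame(
    time_h = d$time_h[1], group = d$group[1], n_alive = nrow(d),
    sirs_pct = pct(d$sirs_state), sofa_pct = pct(d$sofa_flag),
    news2_pct = pct(d$news2_positive), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$time_h, out$group), ]
  rownames(out) <- NULL
  structure(out, class = c("prevalence_table", "data.frame"))
}

#' Survival rate and mean survival time
#'
#' The two published cohort summaries: the survival rate (percent of
#' animals alive at protocol end) and the mean survival time, where
#' survivors contribute the protocol duration (e.g. deaths at 18 and 18 h
#' among 8 animals observed for 72 h give 75% and
#' (2 x 18 + 6 x 72) / 8 = 58.5 h).
#'
#' @param death_times Numeric vector, one element per animal: death time
#'   in hours or `NA` for survivors. Alternatively a `swine_cohort`, in
#'   which case the PAT group's death times are used.
#' @param end_h Protocol end in hours (default 72).
#' @param group For a cohort input, which group to summarize.
#' @return List with `survival_rate_pct` and `mean_survival_h`.
#' @examples
#' survival_summary(c(18, 18, NA, NA, NA, NA, NA, NA)) # 75%, 58.5 h
#' @export
survival_summary <- function(death_times, end_h = 72, group = "pat") {
  if (inherits(death_times, "swine_cohort")) {
    cohort <- death_times
    end_h <- cohort$config$duration_h
    keep <- vapply(cohort$animals, `[[`, "", "group") == group
    death_times <- vapply(cohort$animals[keep], `[[`, NA_real_,
                          "death_time_h")
  }
  if (length(death_times) == 0L) stop("empty cohort", call. = FALSE)
  surv <- is.na(death_times)
  list(survival_rate_pct = 100 * mean(surv),
       mean_survival_h = mean(pmin(ifelse(surv, end_h, death_times),
                                   end_h)))
}
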