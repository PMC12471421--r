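#' Score a cohort over the 8-h timepoint grid
#'
#' End-to-end aggregation and scoring: for each animal and each timepoint
#' (default 0, 8, ..., 72 h post-injury, matching the blood draws),
#' telemetry channels are averaged over the trailing 8-h window
#' ([window_average()]), lab analytes and the SNORT score are taken at the
#' draw, and the snapshot is scored with SIRS, SOFA and NEWS2. The SOFA
#' sepsis rule uses each animal's pre-injury (time 0) total as baseline.
#' Timepoints at or after an animal's death are censored (no rows).
#'
#' @param cohort A `swine_cohort` from [simulate_cohort()] or
#'   [read_cohort()].
#' @param sirs_table A `sirs_table`.
#' @param news2_table A `news2_table`.
#' @param timepoints Scoring grid in hours post-injury.
#' @return Object of class `cohort_timecourse`: data frame with one row
#'   per animal x alive timepoint, holding the snapshot values, the
#'   diurnal phase, SIRS (`sirs_n_met`, `sirs_state`), SOFA
#'   (`sofa_total`, `sofa_baseline`, `sofa_flag`) and NEWS2
#'   (`news2_total`, `news2_extreme`, `news2_positive`) results, with
#'   attributes `end_h` and `death_times`.
#' @export
score_cohort <- function(cohort, sirs_table, news2_table,
                         timepoints = seq(0, 72, by = 8)) {
  stopifnot(inherits(cohort, "swine_cohort"))
  cfg <- cohort$config
  rows <- list()
  for (animal in cohort$animals) {
    alive <- if (is.na(animal$death_time_h)) timepoints else
      timepoints[timepoints < animal$death_time_h]
    if (length(alive) == 0L) next
    tel <- window_average(animal$telemetry, alive,
                          window_h = cfg$blooddraw_interval_h)
    get_tel <- function(ch, t) {
      v <- tel$value[tel$channel == ch & tel$time_h == t]
      if (length(v) == 1L) v else NA_real_
    }
    get_lab <- function(an, t) {
      v <- animal$labs$value[animal$labs$analyte == an &
                               abs(animal$labs$time_h - t) < 1e-9]
      if (length(v) == 1L) v else NA_real_
    }
    get_snort <- function(t) {
      v <- animal$snort$score[abs(animal$snort$time_h - t) < 1e-9]
      if (length(v) == 1L) v else NA_real_
    }
    baseline_sofa <- NA_integer_
    for (t in alive) {
      clock <- (cfg$injury_clock_hour + t) %% 24
      snap <- vitals_snapshot(
        animal_id = animal$animal_id, time_h = t,
        phase = diurnal_phase(clock, cfg$lights_on_hour,
                              cfg$lights_off_hour),
        hr = get_tel("hr", t), rr = get_tel("rr", t),
        temp = get_tel("temp", t), map = get_tel("map", t),
        sbp = get_tel("sbp", t),
        wbc = get_lab("wbc", t), platelets = get_lab("platelets", t),
        creatinine = get_lab("creatinine", t),
        bilirubin = get_lab("bilirubin", t),
        pf_ratio = get_lab("pf_ratio", t), spo2 = get_lab("spo2", t),
        snort = get_snort(t))
      sirs <- evaluate_sirs(snap, sirs_table)
      sofa0 <- sofa_total(snap, baseline_total = 0)
      if (t == min(timepoints) && is.na(baseline_sofa)) {
        baseline_sofa <- sofa0$total
      }
      base <- if (is.na(baseline_sofa)) 0L else baseline_sofa
      sofa <- sofa_total(snap, baseline_total = base)
      news2 <- news2_total(snap, news2_table)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = animal$animal_id, group = animal$group, time_h = t,
        phase = snap$phase,
        hr = snap$hr, rr = snap$rr, temp = snap$temp, wbc = snap$wbc,
        platelets = snap$platelets, creatinine = snap$creatinine,
        bilirubin = snap$bilirubin, map = snap$map,
        pf_ratio = snap$pf_ratio, spo2 = snap$spo2, snort = snap$snort,
        sirs_n_met = sirs$n_met, sirs_state = sirs$sirs_state,
        sofa_total = sofa$total, sofa_baseline = base,
        sofa_flag = isTRUE(sofa$sepsis_flag),
        news2_total = news2$total, news2_extreme = news2$extreme_flag,
        news2_positive = news2$positive,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  deaths <- stats::setNames(
    vapply(cohort$animals, `[[`, NA_real_, "death_time_h"),
    vapply(cohort$animals, `[[`, "", "animal_id"))
  structure(out, class = c("cohort_timecourse", "data.frame"),
            end_h = max(timepoints), death_times = deaths)
}
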