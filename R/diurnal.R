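#' Assign clock times to the day or night phase
#'
#' @param clock_hour Numeric clock hours in `[0, 24)` (fractions allowed).
#' @param lights_on_hour,lights_off_hour Clock hours delimiting the 12-h
#'   day phase; a sample is "day" when
#'   `lights_on_hour <= clock < lights_off_hour`.
#' @return Character vector `"day"`/`"night"`.
#' @export
diurnal_phase <- function(clock_hour, lights_on_hour = 6,
                          lights_off_hour = 18) {
  if (anyNA(clock_hour)) stop("clock_hour contains missing values",
                              call. = FALSE)
  h <- clock_hour %% 24
  on <- lights_on_hour %% 24
  off <- lights_off_hour %% 24
  day <- if (on < off) h >= on & h < off else h >= on | h < off
  ifelse(day, "day", "night")
}

#' Split a timestamped series into day and night samples
#'
#' Every sample is assigned to exactly one phase of the facility light
#' cycle; counts are conserved (`nrow(day) + nrow(night) == nrow(series)`).
#'
#' @param series Data frame with a `clock_hour` column (clock time of each
#'   sample) and any value columns.
#' @param lights_on_hour,lights_off_hour The 12-h light cycle.
#' @return List with elements `day` and `night` (subsets of `series`).
#' @export
partition_diurnal <- function(series, lights_on_hour = 6,
                              lights_off_hour = 18) {
  if (!is.data.frame(series) || is.null(series$clock_hour)) {
    stop("series must be a data frame with a 'clock_hour' column",
         call. = FALSE)
  }
  if (anyNA(series$clock_hour)) {
    stop("samples without a timestamp cannot be assigned a phase",
         call. = FALSE)
  }
  phase <- diurnal_phase(series$clock_hour, lights_on_hour, lights_off_hour)
  list(day = series[phase == "day", , drop = FALSE],
       night = series[phase == "night", , drop = FALSE])
}

#' Diurnal baseline statistics of a healthy cohort
#'
#' Computes, per parameter and 12-h phase, the mean and sample SD of all
#' telemetry recorded in the pre-injury baseline window (by default the
#' 48 h immediately before the morning baseline blood draw at `t = 0`).
#' Blood analytes listed in `pooled_analytes` are pooled across all
#' baseline draws in the window (including the `t = 0` draw) with no
#' diurnal split, since blood-draw data carry no day/night structure.
#'
#' @param cohort A `swine_cohort` from [simulate_cohort()], or a list with
#'   the same structure (each animal holding `telemetry` and `labs`).
#' @param window_start,window_end Baseline window in hours relative to
#'   injury (telemetry in `[window_start, window_end)`; lab draws in
#'   `[window_start, window_end]` so the baseline draw itself is included).
#' @param pooled_analytes Analytes given pooled (phase-free) statistics;
#'   default `"wbc"`.
#' @return Object of class `diurnal_stats`: a data frame with columns
#'   `parameter`, `phase` (`"day"`, `"night"` or `"pooled"`), `mean`, `sd`,
#'   `n`, plus a `source` attribute.
#' @export
compute_diurnal_stats <- function(cohort, window_start = -48,
                                  window_end = 0,
                                  pooled_analytes = "wbc") {
  animals <- if (inherits(cohort, "swine_cohort")) cohort$animals else cohort
  tel <- do.call(rbind, lapply(animals, `[[`, "telemetry"))
  labs <- do.call(rbind, lapply(animals, `[[`, "labs"))
  tel <- tel[tel$time_h >= window_start & tel$time_h < window_end, ,
             drop = FALSE]
  rows <- list()
  for (ch in unique(tel$channel)) {
    for (ph in c("day", "night")) {
      v <- tel$value[tel$channel == ch & tel$phase == ph]
      if (length(v) < 2) {
        stop("insufficient baseline data for parameter '", ch,
             "', phase '", ph, "' (need >= 2 samples, have ",
             length(v), ")", call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = ch, phase = ph, mean = mean(v), sd = stats::sd(v),
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  for (an in pooled_analytes) {
    v <- labs$value[labs$analyte == an & labs$time_h >= window_start &
                      labs$time_h <= window_end]
    if (length(v) < 2) {
      stop("insufficient baseline data for parameter '", an,
           "', phase 'pooled'", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = an, phase = "pooled", mean = mean(v),
      sd = stats::sd(v), n = length(v), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("diurnal_stats", "data.frame"),
            source = "derived",
            window = c(start = window_start, end = window_end))
}

#' Construct a diurnal-statistics table by hand
#'
#' Convenience constructor for a `diurnal_stats` object from explicit
#' means and SDs (e.g. the published healthy-cohort values), for use with
#' [derive_sirs_table()] and [derive_news2_table()].
#'
#' @param parameter,phase,mean,sd,n Equal-length vectors (`n` may be a
#'   scalar).
#' @param source Provenance label stored on the object.
#' @return A `diurnal_stats` data frame.
#' @export
diurnal_stats <- function(parameter, phase, mean, sd, n = NA_integer_,
                          source = "manual") {
  stopifnot(all(sd >= 0), all(phase %in% c("day", "night", "pooled")))
  out <- data.frame(parameter = parameter, phase = phase, mean = mean,
                    sd = sd, n = n, stringsAsFactors = FALSE)
  structure(out, class = c("diurnal_stats", "data.frame"), source = source)
}
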