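#' NEWS2 points for one parameter
#'
#' For the derived parameters (`rr`, `sbp`, `hr`, `temp`) the rounded band
#' edges at `mean +/- {1..4} SD` of the snapshot's diurnal phase are looked
#' up in the band table: the closed 0-point band is `[-1 SD, +1 SD]` and
#' values between the 0-band and the `+/-2 SD` edge also score 0; the
#' `+/-2`, `+/-3` and `+/-4` SD edges are inclusive outer boundaries of the
#' 1-, 2- and 3-point bands (`v >= +2SD edge -> 1`, `>= +3SD -> 2`,
#' `>= +4SD -> 3`, mirrored below the mean). Two rows are fixed absolute
#' cut-offs rather than derived: oxygen saturation (`>=96 -> 0`,
#' `94-95 -> 1`, `92-93 -> 2`, `<=91 -> 3`) and SNORT (`>=10 -> 0`,
#' `<10 -> 3`). A parameter in a 3-point band raises the extreme flag.
#'
#' @param parameter One of `"rr"`, `"spo2"`, `"sbp"`, `"hr"`, `"snort"`,
#'   `"temp"`.
#' @param value Measured value (channel units).
#' @param phase `"day"` or `"night"`; ignored for the fixed rows.
#' @param bands A `news2_table` from [derive_news2_table()] or
#'   [printed_news2_table()].
#' @return List with `points` (0-3) and `extreme` (logical).
#' @examples
#' bands <- derive_news2_table(printed_baseline_stats())
#' news2_points("hr", 92, "night", bands)   # 0 points
#' news2_points("hr", 201, "day", bands)    # 3 points, extreme
#' news2_points("snort", 6.6, "day", bands) # 3 points, extreme
#' @export
news2_points <- function(parameter, value, phase = c("day", "night"),
                         bands) {
  phase <- match.arg(phase)
  stopifnot(length(value) == 1L, is.numeric(value))
  if (is.na(value)) stop("value is missing; missing parameters are handled ",
                         "by news2_total()", call. = FALSE)
  if (parameter == "spo2") {
    points <- if (value >= 96) 0L else if (value >= 94) 1L else
      if (value >= 92) 2L else 3L
    return(list(points = points, extreme = points == 3L))
  }
  if (parameter == "snort") {
    points <- if (value >= 10) 0L else 3L
    return(list(points = points, extreme = points == 3L))
  }
  rows <- bands[bands$parameter == parameter & bands$phase == phase, ,
                drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("NEWS2 band table has no rows for parameter '", parameter,
         "', phase '", phase, "'", call. = FALSE)
  }
  edge <- stats::setNames(rows$edge, rows$band)
  upper_of <- function(band) if (is.na(edge[band])) Inf else edge[band]
  lower_of <- function(band) if (is.na(edge[band])) -Inf else edge[band]
  points <- if (value >= upper_of("p4")) 3L else
    if (value >= upper_of("p3")) 2L else
    if (value >= upper_of("p2")) 1L else
    if (value <= lower_of("m4")) 3L else
    if (value <= lower_of("m3")) 2L else
    if (value <= lower_of("m2")) 1L else 0L
  list(points = points, extreme = points == 3L)
}

#' Total NEWS2 score of one snapshot
#'
#' Sums the per-parameter points over respiration rate, oxygen saturation,
#' systolic blood pressure, heart rate, SNORT and temperature. Missing
#' parameters (SpO2 and systolic pressure are often unavailable from
#' telemetry-only snapshots) contribute 0 points and are recorded in the
#' completeness fields rather than penalized, since fabricating points for
#' missingness would manufacture signal. The score is positive when the
#' total reaches 5 or any single parameter sits in a 3-point (extreme)
#' band.
#'
#' @param snapshot A [vitals_snapshot()].
#' @param bands A `news2_table`.
#' @return Object of class `news2_result`: list with `points` (named
#'   integer, `NA` for missing parameters), `total`, `extreme_flag`,
#'   `positive`, `complete` and `missing`.
#' @export
news2_total <- function(snapshot, bands) {
  stopifnot(inherits(snapshot, "vitals_snapshot"))
  params <- c("rr", "spo2", "sbp", "hr", "snort", "temp")
  present <- !vapply(params, function(p) is.na(snapshot[[p]]), TRUE)
  if (!any(present[c("rr", "hr", "temp")])) {
    stop("cannot score NEWS2: all core parameters (rr, hr, temp) missing",
         call. = FALSE)
  }
  points <- stats::setNames(rep(NA_integer_, length(params)), params)
  extreme <- FALSE
  for (p in params[present]) {
    res <- news2_points(p, snapshot[[p]], snapshot$phase, bands)
    points[p] <- res$points
    extreme <- extreme || res$extreme
  }
  total <- sum(points, na.rm = TRUE)
  structure(list(points = points, total = total, extreme_flag = extreme,
                 positive = total >= 5 || extreme,
                 complete = all(present),
                 missing = params[!present]),
            class = "news2_result")
}

#' @export
print.news2_result <- function(x, ...) {
  cat(sprintf("<news2_result> total %d%s -> positive: %s%s\n",
              x$total, if (x$extreme_flag) " (extreme)" else "",
              x$positive,
              if (x$complete) "" else
                paste0(" (missing: ", paste(x$missing, collapse = ", "), ")")))
  shown <- x$points[!is.na(x$points)]
  cat("  ", paste(names(shown), shown, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
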