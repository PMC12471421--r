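#' Trailing-window telemetry averages at blood-draw times
#'
#' For each draw time `t` and channel, the mean of all telemetry samples
#' with time in `(t - window_h, t]`. Empty windows yield `NA`, which
#' propagates as missingness through the scorers.
#'
#' @param telemetry Data frame with columns `time_h`, `channel`, `value`
#'   (the `telemetry` element of an `animal_course`).
#' @param draw_times Sorted numeric vector of draw times (hours).
#' @param window_h Window length in hours (default 8, the blood-draw
#'   interval).
#' @return Data frame with columns `time_h`, `channel`, `value`.
#' @export
window_average <- function(telemetry, draw_times, window_h = 8) {
  stopifnot(is.data.frame(telemetry), window_h > 0,
            !is.unsorted(draw_times))
  channels <- unique(telemetry$channel)
  out <- expand.grid(time_h = draw_times, channel = channels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- NA_real_
  for (i in seq_len(nrow(out))) {
    t <- out$time_h[i]
    sel <- telemetry$channel == out$channel[i] &
      telemetry$time_h > t - window_h & telemetry$time_h <= t
    if (any(sel)) out$value[i] <- mean(telemetry$value[sel])
  }
  out
}

#' Per-phase (12-h block) telemetry means
#'
#' Averages each channel over consecutive 12-h light-cycle blocks (the
#' day/night averaging used to display diurnal cycling of activity and
#' vitals).
#'
#' @param telemetry Data frame with columns `time_h`, `clock_hour`,
#'   `channel`, `value`.
#' @param lights_on_hour,lights_off_hour The 12-h light cycle.
#' @return Data frame with columns `block` (integer index of the 12-h
#'   block, 0 containing `time_h = 0`), `phase`, `start_h`, `channel`,
#'   `value` (mean).
#' @export
diurnal_average <- function(telemetry, lights_on_hour = 6,
                            lights_off_hour = 18) {
  stopifnot(is.data.frame(telemetry), nrow(telemetry) > 0)
  phase <- diurnal_phase(telemetry$clock_hour, lights_on_hour,
                         lights_off_hour)
  # phase boundaries fall where clock_hour crosses lights_on/lights_off;
  # anchor block 0 at the boundary at or before time_h = 0
  offset <- (telemetry$clock_hour - lights_on_hour) %% 12
  block_start <- telemetry$time_h - offset
  block <- floor((block_start - min(block_start)) / 12 + 0.5)
  anchor <- block[which.min(abs(telemetry$time_h))]
  block <- as.integer(block - anchor)
  agg <- stats::aggregate(
    telemetry$value,
    by = list(block = block, phase = phase, channel = telemetry$channel),
    FUN = mean)
  names(agg)[4] <- "value"
  starts <- stats::aggregate(block_start, by = list(block = block),
                             FUN = min)
  agg$start_h <- starts$x[match(agg$block, starts$block)]
  agg[order(agg$channel, agg$block), c("block", "phase", "start_h",
                                       "channel", "value")]
}
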