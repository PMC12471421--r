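#' Per-parameter channel specification for the cohort simulator
#'
#' A channel bundles the diurnal baseline statistics of one physiological
#' parameter (telemetry channel or blood analyte) with its injury-response
#' kinetics. Baselines are phase-specific (12-h day / night); the injury
#' response is a normalized gamma-kernel impulse added to the baseline of
#' injured animals from the moment of injury.
#'
#' @param name Parameter identifier, e.g. `"hr"`, `"wbc"`.
#' @param day_mean,day_sd Daytime baseline mean and SD, channel units.
#' @param night_mean,night_sd Nighttime baseline mean and SD; default to the
#'   day values for channels without a diurnal split (all blood analytes).
#' @param amplitude Peak deviation from baseline after injury (channel
#'   units; may be negative). `0` means the channel does not respond.
#' @param peak_time_h Hours post-injury at which the impulse peaks.
#' @param recovery_shape Positive shape of the gamma kernel; larger values
#'   give a sharper peak and faster return to baseline.
#' @param amplitude2,peak_time2_h,recovery_shape2 Optional second kernel for
#'   biphasic channels (e.g. glucose: early hyperglycemia then
#'   hypoglycemia); `amplitude2 = 0` disables it.
#' @param noise_sd Stationary SD of the simulation noise. `NA` (default)
#'   uses the phase baseline SDs, so a simulated healthy cohort reproduces
#'   the configured diurnal statistics.
#' @param noise_autocorr Lag-one autocorrelation of the telemetry noise per
#'   minute, in `[0, 1)`. Ignored for blood analytes (independent draws).
#' @param floor,ceiling Physical bounds; simulated values are clipped and
#'   the clipping is logged on the animal course.
#' @param kind `"telemetry"` (continuous, AR(1) noise) or `"lab"`
#'   (per-blood-draw, independent noise).
#'
#' @return An object of class `channel_spec`.
#' @seealso [default_channels()], [injury_response()]
#' @export
channel_spec <- function(name, day_mean, day_sd,
                         night_mean = day_mean, night_sd = day_sd,
                         amplitude = 0, peak_time_h = 8, recovery_shape = 1,
                         amplitude2 = 0, peak_time2_h = NA_real_,
                         recovery_shape2 = 1,
                         noise_sd = NA_real_, noise_autocorr = 0,
                         floor = -Inf, ceiling = Inf,
                         kind = c("telemetry", "lab")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (day_sd < 0 || night_sd < 0) {
    stop("channel '", name, "': baseline SDs must be >= 0", call. = FALSE)
  }
  if (!is.na(noise_sd) && noise_sd < 0) {
    stop("channel '", name, "': noise_sd must be >= 0", call. = FALSE)
  }
  if (peak_time_h <= 0) {
    stop("channel '", name, "': peak_time_h must be > 0", call. = FALSE)
  }
  if (amplitude2 != 0 && (is.na(peak_time2_h) || peak_time2_h <= 0)) {
    stop("channel '", name, "': peak_time2_h must be > 0 when amplitude2 != 0",
         call. = FALSE)
  }
  if (recovery_shape <= 0 || recovery_shape2 <= 0) {
    stop("channel '", name, "': recovery shapes must be > 0", call. = FALSE)
  }
  if (noise_autocorr < 0 || noise_autocorr >= 1) {
    stop("channel '", name, "': noise_autocorr must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(name = name, day_mean = day_mean, day_sd = day_sd,
         night_mean = night_mean, night_sd = night_sd,
         amplitude = amplitude, peak_time_h = peak_time_h,
         recovery_shape = recovery_shape,
         amplitude2 = amplitude2, peak_time2_h = peak_time2_h,
         recovery_shape2 = recovery_shape2,
         noise_sd = noise_sd, noise_autocorr = noise_autocorr,
         floor = floor, ceiling = ceiling, kind = kind),
    class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf("<channel_spec> %s (%s)\n", x$name, x$kind))
  cat(sprintf("  baseline day %g (sd %g), night %g (sd %g)\n",
              x$day_mean, x$day_sd, x$night_mean, x$night_sd))
  if (x$amplitude != 0 || x$amplitude2 != 0) {
    cat(sprintf("  injury response: amplitude %g peaking at %g h (shape %g)",
                x$amplitude, x$peak_time_h, x$recovery_shape))
    if (x$amplitude2 != 0) {
      cat(sprintf(" + %g at %g h (shape %g)",
                  x$amplitude2, x$peak_time2_h, x$recovery_shape2))
    }
    cat("\n")
  }
  invisible(x)
}

# Normalized gamma-shaped impulse: 0 at t <= 0, exactly 1 at t = peak,
# -> 0 as t -> Inf. shape controls sharpness.
gamma_impulse <- function(t, peak, shape) {
  stopifnot(peak > 0, shape > 0)
  out <- numeric(length(t))
  pos <- which(t > 0)
  u <- t[pos] / peak
  out[pos] <- u^shape * exp(shape * (1 - u))
  out
}

#' Deterministic injury-response kinetic of one channel
#'
#' Returns the noise-free expected value of a channel at `t` hours
#' post-injury: `baseline + amplitude * g(t)` where `g` is a normalized
#' gamma kernel with `g(0) = 0`, `g(peak_time_h) = 1` and `g(t) -> 0` as
#' `t -> Inf`. Biphasic channels add a second kernel of (typically)
#' opposite sign.
#'
#' @param t Hours post-injury (vectorized); must be `>= 0`.
#' @param spec A [channel_spec()].
#' @param baseline Baseline value the impulse is superposed on (channel
#'   units); typically the diurnal phase mean.
#' @return Numeric vector of expected channel values.
#' @examples
#' hr <- channel_spec("hr", day_mean = 100, day_sd = 15.1,
#'                    amplitude = 101, peak_time_h = 8)
#' injury_response(c(0, 8), hr, baseline = 100) # 100 at injury, 201 at peak
#' @export
injury_response <- function(t, spec, baseline) {
  stopifnot(inherits(spec, "channel_spec"), all(t >= 0))
  out <- baseline + spec$amplitude *
    gamma_impulse(t, spec$peak_time_h, spec$recovery_shape)
  if (spec$amplitude2 != 0) {
    out <- out + spec$amplitude2 *
      gamma_impulse(t, spec$peak_time2_h, spec$recovery_shape2)
  }
  out
}

#' Default channel set for the 72-h porcine fecal-peritonitis model
#'
#' Baseline means/SDs are the healthy-cohort diurnal statistics the
#' threshold tables are derived from (heart rate, respiration rate,
#' temperature, WBC); injury kinetics are anchored to the injured-group
#' extrema of the model: tachycardia peaking near 201 bpm at 8 h,
#' biphasic leukopenia with a nadir of ~3.9 x 10^3/uL at 8 h recovering by
#' ~40 h, thrombocytopenia bottoming near 132 x 10^3/uL at 32 h, creatinine
#' peaking at ~2.0 mg/dL at 24 h, a delayed bilirubin peak (~0.53 mg/dL),
#' acute hyperlactatemia (~6.3 mM), early hyperglycemia (~174 mg/dL)
#' followed by hypoglycemia, a mild P/F-ratio depression that stays above
#' 400 on average, and cytokine impulses peaking at 8 h (16 h for
#' TNF-alpha). Baselines that no threshold table constrains (platelets,
#' creatinine, glucose, cytokines) are set to typical healthy-pig values.
#'
#' @return Named list of [channel_spec()] objects.
#' @export
default_channels <- function() {
  specs <- list(
    # -- telemetry -----------------------------------------------------
    channel_spec("hr", 100, 15.1, 92, 12.0,
                 amplitude = 101, peak_time_h = 8, recovery_shape = 0.4,
                 noise_autocorr = 0.98, floor = 30, kind = "telemetry"),
    channel_spec("rr", 22, 3.9, 16, 3.1,
                 noise_autocorr = 0.98, floor = 4, kind = "telemetry"),
    channel_spec("temp", 38.5, 0.69, 38.8, 0.47,
                 amplitude = 0.6, peak_time_h = 16, recovery_shape = 0.3,
                 noise_autocorr = 0.98, floor = 35, kind = "telemetry"),
    channel_spec("map", 107, 6, 104, 6,
                 amplitude = -7, peak_time_h = 24, recovery_shape = 0.5,
                 noise_autocorr = 0.98, floor = 20, kind = "telemetry"),
    channel_spec("sbp", 140, 14, 132.5, 12.5,
                 amplitude = -10, peak_time_h = 24, recovery_shape = 0.5,
                 noise_autocorr = 0.98, floor = 40, kind = "telemetry"),
    channel_spec("activity", 8, 2.5, 2, 1,
                 amplitude = -6, peak_time_h = 8, recovery_shape = 0.2,
                 noise_autocorr = 0.98, floor = 0, kind = "telemetry"),
    # -- blood analytes (one draw every 8 h) ---------------------------
    channel_spec("wbc", 19.1, 3.5,
                 amplitude = -15.2, peak_time_h = 8, recovery_shape = 1.2,
                 floor = 0.2, kind = "lab"),
    channel_spec("platelets", 350, 60,
                 amplitude = -218, peak_time_h = 32, recovery_shape = 1.5,
                 floor = 5, kind = "lab"),
    channel_spec("creatinine", 1.0, 0.2,
                 amplitude = 1.0, peak_time_h = 24, recovery_shape = 6,
                 floor = 0.1, kind = "lab"),
    channel_spec("bilirubin", 0.11, 0.03,
                 amplitude = 0.42, peak_time_h = 48, recovery_shape = 2,
                 floor = 0.01, kind = "lab"),
    channel_spec("lactate", 1.4, 0.3,
                 amplitude = 4.9, peak_time_h = 8, recovery_shape = 3,
                 floor = 0.1, kind = "lab"),
    channel_spec("glucose", 100, 15,
                 amplitude = 74, peak_time_h = 8, recovery_shape = 3,
                 amplitude2 = -45, peak_time2_h = 28, recovery_shape2 = 3,
                 floor = 10, kind = "lab"),
    channel_spec("pf_ratio", 448.61, 18.04,
                 amplitude = -30.5, peak_time_h = 16, recovery_shape = 0.5,
                 floor = 40, kind = "lab"),
    channel_spec("spo2", 97, 1,
                 amplitude = -1.5, peak_time_h = 16, recovery_shape = 0.5,
                 floor = 50, ceiling = 100, kind = "lab"),
    channel_spec("il6", 40, 15,
                 amplitude = 1800, peak_time_h = 8, recovery_shape = 1.5,
                 floor = 0, kind = "lab"),
    channel_spec("il10", 30, 10,
                 amplitude = 500, peak_time_h = 8, recovery_shape = 1.5,
                 floor = 0, kind = "lab"),
    channel_spec("il1b", 25, 10,
                 amplitude = 300, peak_time_h = 8, recovery_shape = 0.6,
                 floor = 0, kind = "lab"),
    channel_spec("tnfa", 60, 20,
                 amplitude = 250, peak_time_h = 16, recovery_shape = 0.5,
                 floor = 0, kind = "lab")
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}
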