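#' One animal x one timepoint bundle of scoreable parameters
#'
#' Validated container for everything the three scoring systems consume.
#' Missing measurements are passed as `NA` and handled explicitly by the
#' scorers (per-criterion "unknown" for SIRS, partial totals for SOFA,
#' zero points plus a completeness flag for NEWS2).
#'
#' @param animal_id Animal identifier.
#' @param time_h Hours relative to injury.
#' @param phase `"day"` or `"night"` (light cycle at the timepoint).
#' @param hr Heart rate, bpm.
#' @param rr Respiration rate, breaths/min.
#' @param temp Core temperature, degC.
#' @param wbc White blood cells, 10^3 cells/uL.
#' @param platelets Platelet count, 10^3 cells/uL.
#' @param creatinine mg/dL.
#' @param bilirubin Total bilirubin, mg/dL.
#' @param map Mean arterial pressure, mmHg.
#' @param pf_ratio PaO2/FiO2 ratio (dimensionless).
#' @param snort SNORT neurological score, 2-11 (fractional medians
#'   accepted).
#' @param spo2 Oxygen saturation, percent (optional).
#' @param sbp Systolic blood pressure, mmHg (optional).
#' @return Object of class `vitals_snapshot` (named list).
#' @export
vitals_snapshot <- function(animal_id = NA_character_, time_h = NA_real_,
                            phase = c("day", "night"),
                            hr = NA_real_, rr = NA_real_, temp = NA_real_,
                            wbc = NA_real_, platelets = NA_real_,
                            creatinine = NA_real_, bilirubin = NA_real_,
                            map = NA_real_, pf_ratio = NA_real_,
                            snort = NA_real_, spo2 = NA_real_,
                            sbp = NA_real_) {
  phase <- match.arg(phase)
  chk <- function(value, what, lo, hi = Inf) {
    if (!is.na(value) && (value < lo || value > hi)) {
      stop("snapshot ", what, " = ", value, " outside physical range [",
           lo, ", ", hi, "]", call. = FALSE)
    }
  }
  chk(hr, "hr", 0 + 1e-12); chk(rr, "rr", 0); chk(temp, "temp", 20, 45)
  chk(wbc, "wbc", 0); chk(platelets, "platelets", 0)
  chk(creatinine, "creatinine", 0); chk(bilirubin, "bilirubin", 0)
  chk(map, "map", 0); chk(pf_ratio, "pf_ratio", 0 + 1e-12)
  chk(snort, "snort", 2, 11); chk(spo2, "spo2", 0 + 1e-12, 100)
  chk(sbp, "sbp", 0)
  structure(list(animal_id = animal_id, time_h = time_h, phase = phase,
                 hr = hr, rr = rr, temp = temp, wbc = wbc,
                 platelets = platelets, creatinine = creatinine,
                 bilirubin = bilirubin, map = map, pf_ratio = pf_ratio,
                 snort = snort, spo2 = spo2, sbp = sbp),
            class = "vitals_snapshot")
}

#' @export
print.vitals_snapshot <- function(x, ...) {
  cat(sprintf("<vitals_snapshot> %s at %g h (%s)\n",
              x$animal_id, x$time_h, x$phase))
  vals <- unlist(x[c("hr", "rr", "temp", "wbc", "platelets", "creatinine",
                     "bilirubin", "map", "pf_ratio", "snort", "spo2",
                     "sbp")])
  cat("  ", paste(names(vals), signif(vals, 4), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}
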