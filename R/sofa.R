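#' Score one organ system of the adapted porcine SOFA
#'
#' Band lookup per the adapted six-system table. Respiratory uses a
#' descending `>=400 -> 0, <400 -> 1, <300 -> 2, <200 -> 3, <100 -> 4`
#' chain on the P/F ratio; hematological uses closed upper edges on the
#' platelet count (`>150 -> 0, <=150 -> 1, <=100 -> 2, <=50 -> 3,
#' <=20 -> 4`); renal (creatinine) and hepatic (bilirubin) values are
#' rounded to one decimal before closed-interval lookup so the printed
#' interval gaps cannot be hit; cardiovascular rounds MAP to an integer
#' (`>70 -> 0`, `60-70 -> 1`, `50-59 -> 2`, `40-49 -> 3`, `<40 -> 4`);
#' neurological maps SNORT ranges (`[10,11] -> 0`, `[8,10) -> 1`,
#' `[6,8) -> 2`, `[4,6) -> 3`, `[2,4) -> 4`). Values below the lowest
#' defined renal/hepatic band (e.g. creatinine < 0.3) score 0 and carry an
#' out-of-table note.
#'
#' @param system One of `"respiratory"`, `"renal"`, `"hepatic"`,
#'   `"hematological"`, `"cardiovascular"`, `"neurological"`.
#' @param value The system's input (P/F ratio, creatinine mg/dL, total
#'   bilirubin mg/dL, platelets 10^3/uL, MAP mmHg, SNORT).
#' @return Integer score 0-4, with attribute `note` set to
#'   `"below lowest defined band"` when applicable.
#' @examples
#' sofa_component("respiratory", 418.15) # 0
#' sofa_component("hematological", 132.2) # 1
#' sofa_component("neurological", 6.6)    # 2
#' @export
sofa_component <- function(system = c("respiratory", "renal", "hepatic",
                                      "hematological", "cardiovascular",
                                      "neurological"),
                           value) {
  system <- match.arg(system)
  stopifnot(length(value) == 1L, is.numeric(value))
  if (is.na(value)) return(NA_integer_)
  note <- NULL
  score <- switch(system,
    respiratory = {
      if (value < 0) stop("P/F ratio must be positive", call. = FALSE)
      if (value >= 400) 0L else if (value >= 300) 1L else
        if (value >= 200) 2L else if (value >= 100) 3L else 4L
    },
    renal = {
      v <- round_half_away(value, 1)
      if (v < 0.3) { note <- "below lowest defined band"; 0L }
      else if (v <= 1.4) 0L else if (v <= 2.4) 1L else if (v <= 3.4) 2L
      else if (v <= 4.9) 3L else 4L
    },
    hepatic = {
      v <- round_half_away(value, 1)
      if (v < 0.3) { note <- "below lowest defined band"; 0L }
      else if (v <= 0.6) 0L else if (v <= 2.0) 1L else if (v <= 5.0) 2L
      else if (v <= 10.0) 3L else 4L
    },
    hematological = {
      if (value > 150) 0L else if (value > 100) 1L else if (value > 50) 2L
      else if (value > 20) 3L else 4L
    },
    cardiovascular = {
      v <- round_half_away(value, 0)
      if (v > 70) 0L else if (v >= 60) 1L else if (v >= 50) 2L
      else if (v >= 40) 3L else 4L
    },
    neurological = {
      if (value < 2 || value > 11) {
        stop("SNORT must lie in [2, 11]", call. = FALSE)
      }
      if (value >= 10) 0L else if (value >= 8) 1L else if (value >= 6) 2L
      else if (value >= 4) 3L else 4L
    })
  if (!is.null(note)) attr(score, "note") <- note
  score
}

#' Total adapted SOFA score of one snapshot
#'
#' Sums the six organ-system components and applies the sepsis rule: an
#' increase of at least 2 over the animal's baseline total indicates organ
#' dysfunction. With missing components the total is marked partial;
#' `sepsis_flag` is then `NA` unless the partial total already clears
#' `baseline_total + 2`.
#'
#' @param snapshot A [vitals_snapshot()] (uses `pf_ratio`, `creatinine`,
#'   `bilirubin`, `platelets`, `map`, `snort`).
#' @param baseline_total The animal's pre-injury SOFA total (default 0).
#' @return Object of class `sofa_result`: list with `components` (named
#'   integer, `NA` for missing), `total`, `complete`, `baseline_total`,
#'   `sepsis_flag` and `notes`.
#' @examples
#' snap <- vitals_snapshot(phase = "day", pf_ratio = 418.15,
#'                         creatinine = 2.0, bilirubin = 0.53,
#'                         platelets = 132.2, map = 100, snort = 11)
#' sofa_total(snap, baseline_total = 0) # total 2 -> sepsis flag
#' @export
sofa_total <- function(snapshot, baseline_total = 0) {
  stopifnot(inherits(snapshot, "vitals_snapshot"),
            baseline_total >= 0, baseline_total <= 24)
  inputs <- c(respiratory = "pf_ratio", renal = "creatinine",
              hepatic = "bilirubin", hematological = "platelets",
              cardiovascular = "map", neurological = "snort")
  components <- stats::setNames(rep(NA_integer_, length(inputs)),
                                names(inputs))
  notes <- character(0)
  for (sys in names(inputs)) {
    sc <- sofa_component(sys, snapshot[[inputs[[sys]]]])
    if (!is.null(attr(sc, "note"))) {
      notes <- c(notes, paste0(sys, ": ", attr(sc, "note")))
    }
    components[sys] <- as.integer(sc)
  }
  complete <- !anyNA(components)
  total <- sum(components, na.rm = TRUE)
  sepsis_flag <- if (complete) {
    total - baseline_total >= 2
  } else if (total - baseline_total >= 2) TRUE else NA
  structure(list(components = components, total = total,
                 complete = complete, baseline_total = baseline_total,
                 sepsis_flag = sepsis_flag, notes = notes),
            class = "sofa_result")
}

#' @export
print.sofa_result <- function(x, ...) {
  cat(sprintf("<sofa_result> total %d (baseline %d) -> sepsis flag: %s%s\n",
              x$total, x$baseline_total, x$sepsis_flag,
              if (x$complete) "" else " (partial)"))
  cat("  ", paste(names(x$components), x$components, sep = "=",
                  collapse = "  "), "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
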