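# Display precision per parameter: integer bpm/mmHg, 0.1 degC, 0.1 10^3/uL.
display_digits <- function(parameter) {
  d <- c(hr = 0, rr = 0, sbp = 0, map = 0, temp = 1, wbc = 1)
  out <- unname(d[parameter])
  out[is.na(out)] <- 1
  out
}

#' Round half away from zero
#'
#' Commercial rounding at a fixed number of decimals (`0.5` always moves
#' away from zero), the convention the published threshold tables follow
#' (e.g. 130.2 -> 130, 69.8 -> 70, 39.88 -> 39.9, 84.9 -> 85), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.stats_row <- function(stats, parameter, phase) {
  i <- which(stats$parameter == parameter & stats$phase == phase)
  if (length(i) != 1L) {
    stop("baseline statistics missing for parameter '", parameter,
         "', phase '", phase, "'", call. = FALSE)
  }
  stats[i, , drop = FALSE]
}

#' Derive the pig-specific SIRS threshold table
#'
#' SIRS thresholds are the healthy-baseline `mean +/- 2 SD` per parameter
#' and diurnal phase, rounded to each parameter's display precision. Heart
#' rate, respiration rate and temperature are phase-specific; WBC uses a
#' single pooled row (blood draws carry no diurnal split).
#'
#' @param stats A `diurnal_stats` object ([compute_diurnal_stats()],
#'   [diurnal_stats()] or [printed_baseline_stats()]) containing `hr`,
#'   `rr`, `temp` (day + night) and `wbc` (pooled).
#' @param k SD multiplier (default 2).
#' @return Object of class `sirs_table`: data frame with columns
#'   `parameter`, `phase`, `mean`, `sd`, `lower`, `upper`.
#' @examples
#' derive_sirs_table(printed_baseline_stats())
#' @export
derive_sirs_table <- function(stats, k = 2) {
  stopifnot(inherits(stats, "diurnal_stats") || is.data.frame(stats))
  need <- list(hr = c("day", "night"), rr = c("day", "night"),
               temp = c("day", "night"), wbc = "pooled")
  rows <- list()
  for (p in names(need)) {
    for (ph in need[[p]]) {
      s <- .stats_row(stats, p, ph)
      dg <- display_digits(p)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, phase = ph, mean = s$mean, sd = s$sd,
        lower = round_half_away(s$mean - k * s$sd, dg),
        upper = round_half_away(s$mean + k * s$sd, dg),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("sirs_table", "data.frame"), k = k,
            source = attr(stats, "source"))
}

#' Derive the pig-specific NEWS2 band table
#'
#' For each derived parameter (respiration rate, systolic blood pressure,
#' heart rate, temperature) and diurnal phase, band boundaries are placed
#' at the healthy-baseline `mean +/- {1, 2, 3, 4} SD`, rounded to display
#' precision. The closed 0-point band is `[mean - 1 SD, mean + 1 SD]`; the
#' `+/-2`, `+/-3` and `+/-4` SD edges are the inclusive outer boundaries of
#' the 1-, 2- and 3-point bands on each side (see [news2_points()]).
#' Oxygen saturation and SNORT rows are fixed absolute cut-offs, not
#' derived (see [news2_points()]).
#'
#' @param stats A `diurnal_stats` object with `rr`, `sbp`, `hr` and `temp`
#'   rows for both phases.
#' @return Object of class `news2_table`: long data frame with columns
#'   `parameter`, `phase`, `band` (`"m4"`, `"m3"`, `"m2"`, `"m1"`, `"p1"`,
#'   `"p2"`, `"p3"`, `"p4"`; `m` = mean minus k SD, `p` = mean plus k SD)
#'   and `edge`.
#' @examples
#' t3 <- derive_news2_table(printed_baseline_stats())
#' subset(t3, parameter == "hr" & phase == "night")
#' @export
derive_news2_table <- function(stats) {
  stopifnot(inherits(stats, "diurnal_stats") || is.data.frame(stats))
  params <- c("rr", "sbp", "hr", "temp")
  ks <- c(m4 = -4, m3 = -3, m2 = -2, m1 = -1, p1 = 1, p2 = 2, p3 = 3, p4 = 4)
  rows <- list()
  for (p in params) {
    for (ph in c("day", "night")) {
      s <- .stats_row(stats, p, ph)
      dg <- display_digits(p)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, phase = ph, band = names(ks),
        edge = round_half_away(s$mean + ks * s$sd, dg),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  bad <- vapply(split(out, paste(out$parameter, out$phase)),
                function(d) any(diff(d$edge[match(names(ks), d$band)]) < 0),
                TRUE)
  if (any(bad)) {
    stop("NEWS2 band boundaries are not non-decreasing for: ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  structure(out, class = c("news2_table", "data.frame"),
            source = attr(stats, "source"))
}

#' Published healthy-baseline diurnal statistics
#'
#' The printed means and SDs of the 48-animal healthy reference cohort the
#' pig-specific thresholds were built from: heart rate (day 100 +/- 15.1,
#' night 92 +/- 12.0 bpm), respiration rate (22 +/- 3.9 / 16 +/- 3.1 bpm),
#' temperature (38.5 +/- 0.69 / 38.8 +/- 0.47 degC) and pooled WBC
#' (19.1 +/- 3.5 x 10^3/uL). Systolic blood pressure statistics are not
#' published; they are reconstructed from the published NEWS2 0-point bands
#' (day 126-154 -> mean 140, SD 14; night 120-145 -> mean 132.5, SD 12.5)
#' and marked as such in the `source` attribute.
#'
#' @return A `diurnal_stats` data frame.
#' @export
printed_baseline_stats <- function() {
  diurnal_stats(
    parameter = c("hr", "hr", "rr", "rr", "temp", "temp", "wbc",
                  "sbp", "sbp"),
    phase = c("day", "night", "day", "night", "day", "night", "pooled",
              "day", "night"),
    mean = c(100, 92, 22, 16, 38.5, 38.8, 19.1, 140, 132.5),
    sd = c(15.1, 12.0, 3.9, 3.1, 0.69, 0.47, 3.5, 14, 12.5),
    n = 48L,
    source = "published (sbp reconstructed from 0-point bands)")
}

#' Published SIRS threshold table
#'
#' The printed pig-specific SIRS thresholds, kept verbatim for auditing the
#' derivation (see [audit_sirs_table()]). A few printed cells differ from
#' the `mean +/- 2 SD` arithmetic on the printed means by one display unit
#' (respiration-rate upper bounds, WBC upper bound, nighttime temperature
#' lower bound), presumably because the published means are themselves
#' rounded.
#'
#' @return A `sirs_table` data frame.
#' @export
printed_sirs_table <- function() {
  out <- data.frame(
    parameter = c("hr", "hr", "rr", "rr", "temp", "temp", "wbc"),
    phase = c("day", "night", "day", "night", "day", "night", "pooled"),
    mean = c(100, 92, 22, 16, 38.5, 38.8, 19.1),
    sd = c(15.1, 12.0, 3.9, 3.1, 0.69, 0.47, 3.5),
    lower = c(70, 68, 14, 10, 37.1, 37.8, 12.1),
    upper = c(130, 116, 29, 23, 39.9, 39.7, 26.2),
    stringsAsFactors = FALSE)
  structure(out, class = c("sirs_table", "data.frame"), k = 2,
            source = "published")
}

#' Published NEWS2 band table
#'
#' The printed pig-specific NEWS2 band boundaries in the same long format
#' as [derive_news2_table()]. Cells left blank in the published table are
#' `NA`.
#'
#' @return A `news2_table` data frame.
#' @export
printed_news2_table <- function() {
  cell <- function(parameter, phase, m4, m3, m2, m1, p1, p2, p3, p4) {
    data.frame(parameter = parameter, phase = phase,
               band = c("m4", "m3", "m2", "m1", "p1", "p2", "p3", "p4"),
               edge = c(m4, m3, m2, m1, p1, p2, p3, p4),
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    cell("rr", "day", 6, NA, 14, 18, 26, NA, 33, 37),
    cell("rr", "night", 4, NA, 10, 13, 20, NA, 26, 29),
    cell("sbp", "day", 85, 99, 113, 126, 154, NA, NA, 196),
    cell("sbp", "night", 83, 95, 108, 120, 145, NA, NA, 183),
    cell("hr", "day", 40, NA, 70, 85, 115, 130, 145, 161),
    cell("hr", "night", 45, NA, 68, 80, 104, 116, 128, 140),
    cell("temp", "day", 35.7, NA, 37.1, 37.8, 39.2, 39.9, 40.5, NA),
    cell("temp", "night", 36.9, NA, 37.8, 38.3, 39.2, 39.7, 40.2, NA))
  rownames(out) <- NULL
  structure(out, class = c("news2_table", "data.frame"),
            source = "published")
}

.audit_frame <- function(merged) {
  merged$match <- ifelse(is.na(merged$printed), NA,
                         abs(merged$derived - merged$printed) < 1e-9)
  merged
}

#' Audit a derived SIRS table against the published thresholds
#'
#' Compares each derived threshold cell with the published value and flags
#' mismatches rather than silently matching them; the published table
#' contains a handful of cells that are off by one display unit from the
#' printed-mean arithmetic.
#'
#' @param derived A `sirs_table`, typically
#'   `derive_sirs_table(printed_baseline_stats())`.
#' @param printed The published table; default [printed_sirs_table()].
#' @return Data frame with one row per parameter/phase/bound holding
#'   `derived`, `printed` and a logical `match`.
#' @export
audit_sirs_table <- function(derived, printed = printed_sirs_table()) {
  long <- function(tab, col) {
    rbind(data.frame(parameter = tab$parameter, phase = tab$phase,
                     bound = "lower", value = tab$lower),
          data.frame(parameter = tab$parameter, phase = tab$phase,
                     bound = "upper", value = tab$upper))
  }
  d <- long(derived); names(d)[4] <- "derived"
  p <- long(printed); names(p)[4] <- "printed"
  out <- merge(d, p, by = c("parameter", "phase", "bound"), all.x = TRUE)
  .audit_frame(out)
}

#' Audit a derived NEWS2 table against the published bands
#'
#' @param derived A `news2_table`, typically
#'   `derive_news2_table(printed_baseline_stats())`.
#' @param printed The published table; default [printed_news2_table()].
#' @return Data frame with `derived`, `printed` and `match` per band edge;
#'   `match` is `NA` where the published cell is blank.
#' @export
audit_news2_table <- function(derived, printed = printed_news2_table()) {
  d <- derived[, c("parameter", "phase", "band", "edge")]
  names(d)[4] <- "derived"
  p <- printed[, c("parameter", "phase", "band", "edge")]
  names(p)[4] <- "printed"
  out <- merge(d, p, by = c("parameter", "phase", "band"), all.x = TRUE)
  .audit_frame(out)
}

#' Serialize threshold tables to YAML with provenance
#'
#' @param sirs_table,news2_table Derived tables.
#' @param stats The `diurnal_stats` they were derived from.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_thresholds_yaml <- function(sirs_table, news2_table, stats, path) {
  obj <- list(
    provenance = list(
      source = attr(stats, "source"),
      window_h = as.list(attr(stats, "window")),
      rounding = "half away from zero at per-parameter display precision",
      sd_convention = "sample SD (n - 1)",
      k_sirs = attr(sirs_table, "k"),
      n = stats$n[1]),
    baseline_stats = lapply(seq_len(nrow(stats)), function(i)
      as.list(stats[i, , drop = FALSE])),
    sirs = lapply(seq_len(nrow(sirs_table)), function(i)
      as.list(sirs_table[i, , drop = FALSE])),
    news2 = lapply(seq_len(nrow(news2_table)), function(i)
      as.list(news2_table[i, , drop = FALSE])))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read threshold tables back from YAML
#'
#' @param path File written by [write_thresholds_yaml()].
#' @return List with `sirs` (`sirs_table`), `news2` (`news2_table`) and
#'   `provenance`.
#' @export
read_thresholds_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  bind <- function(rows) {
    out <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    rownames(out) <- NULL
    out
  }
  sirs <- structure(bind(obj$sirs), class = c("sirs_table", "data.frame"),
                    k = obj$provenance$k_sirs)
  news2 <- structure(bind(obj$news2), class = c("news2_table", "data.frame"))
  list(sirs = sirs, news2 = news2, provenance = obj$provenance)
}
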