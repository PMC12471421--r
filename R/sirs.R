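#' Evaluate the pig-specific SIRS criteria on one snapshot
#'
#' A criterion is met when the measured value lies strictly above the
#' upper or strictly below the lower phase-specific threshold (heart rate,
#' respiration rate, temperature use the snapshot's diurnal phase; WBC
#' uses the pooled row). The SIRS state is declared when at least two of
#' the four criteria are met. Missing parameters yield `NA` criterion
#' flags; `n_met` is then computed over the known criteria and the result
#' is marked incomplete.
#'
#' @param snapshot A [vitals_snapshot()].
#' @param table A `sirs_table` from [derive_sirs_table()] or
#'   [printed_sirs_table()].
#' @return Object of class `sirs_result`: list with `criteria` (named
#'   logical, `NA` for unknown), `n_met`, `n_known`, `complete` and
#'   `sirs_state` (`n_met >= 2`).
#' @examples
#' tab <- printed_sirs_table()
#' snap <- vitals_snapshot(phase = "day", hr = 201, rr = 20, temp = 39.2,
#'                         wbc = 3.9)
#' evaluate_sirs(snap, tab) # hr and wbc criteria met -> SIRS state
#' @export
evaluate_sirs <- function(snapshot, table) {
  stopifnot(inherits(snapshot, "vitals_snapshot"),
            is.data.frame(table))
  row_for <- function(parameter, phase) {
    i <- which(table$parameter == parameter & table$phase == phase)
    if (length(i) != 1L) {
      stop("SIRS table has no row for parameter '", parameter,
           "', phase '", phase, "'", call. = FALSE)
    }
    table[i, , drop = FALSE]
  }
  params <- c(hr = snapshot$phase, rr = snapshot$phase,
              temp = snapshot$phase, wbc = "pooled")
  criteria <- stats::setNames(rep(NA, length(params)), names(params))
  for (p in names(params)) {
    v <- snapshot[[p]]
    if (is.na(v)) next
    r <- row_for(p, params[[p]])
    criteria[p] <- v > r$upper || v < r$lower
  }
  n_known <- sum(!is.na(criteria))
  n_met <- sum(criteria, na.rm = TRUE)
  structure(list(criteria = criteria,
                 n_met = n_met,
                 n_known = n_known,
                 complete = n_known == length(criteria),
                 sirs_state = n_met >= 2),
            class = "sirs_result")
}

#' @export
print.sirs_result <- function(x, ...) {
  flag <- function(v) if (is.na(v)) "?" else if (v) "MET" else "-"
  cat(sprintf("<sirs_result> %d/%d criteria met -> SIRS state: %s%s\n",
              x$n_met, x$n_known, x$sirs_state,
              if (x$complete) "" else " (incomplete)"))
  cat("  ", paste(names(x$criteria), vapply(x$criteria, flag, ""),
                  sep = ":", collapse = "  "), "\n")
  invisible(x)
}
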