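#' Rule-based group classification of one scored trajectory
#'
#' Computational analog of a blinded reviewer sorting animals into the
#' injured or control group from their score trajectories. The default
#' rule labels an animal `"pat"` when its NEWS2 score is positive at two
#' or more timepoints, or a SIRS state occurs within the first 16 h after
#' injury; otherwise `"control"`. The rule parameters are configurable and
#' the triggering criteria are returned as justification.
#'
#' @param trajectory Rows of a `cohort_timecourse` for a single animal
#'   (at least two scored timepoints).
#' @param news2_min_positive Number of NEWS2-positive timepoints that
#'   triggers a `"pat"` label.
#' @param sirs_within_h SIRS state at any timepoint `<=` this many hours
#'   post-injury triggers a `"pat"` label.
#' @return List with `label` (`"pat"` or `"control"`), `justification`
#'   (character) and the trigger counts.
#' @export
classify_animal <- function(trajectory, news2_min_positive = 2,
                            sirs_within_h = 16) {
  need <- c("time_h", "sirs_state", "news2_positive")
  if (!is.data.frame(trajectory) || !all(need %in% names(trajectory))) {
    stop("trajectory must contain scored timepoints (columns ",
         paste(need, collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(trajectory) < 2L) {
    stop("need at least two scored timepoints to classify", call. = FALSE)
  }
  n_news2 <- sum(trajectory$news2_positive, na.rm = TRUE)
  early_sirs <- any(trajectory$sirs_state &
                      trajectory$time_h <= sirs_within_h, na.rm = TRUE)
  justification <- character(0)
  if (n_news2 >= news2_min_positive) {
    justification <- c(justification,
                       sprintf("NEWS2 positive at %d timepoints (>= %d)",
                               n_news2, news2_min_positive))
  }
  if (early_sirs) {
    justification <- c(justification,
                       sprintf("SIRS state within the first %g h",
                               sirs_within_h))
  }
  label <- if (length(justification)) "pat" else "control"
  list(label = label, justification = justification,
       n_news2_positive = n_news2, early_sirs = early_sirs)
}

#' Classify every animal of a scored cohort
#'
#' Applies [classify_animal()] per animal and, when the timecourse carries
#' true group labels, reports the classification accuracy.
#'
#' @param timecourse A `cohort_timecourse`.
#' @param ... Rule parameters passed to [classify_animal()].
#' @return Data frame with `animal_id`, `truth`, `label`, `correct`, and
#'   an `accuracy` attribute.
#' @export
classify_cohort <- function(timecourse, ...) {
  ids <- unique(timecourse$animal_id)
  rows <- lapply(ids, function(id) {
    d <- timecourse[timecourse$animal_id == id, , drop = FALSE]
    cl <- classify_animal(d, ...)
    data.frame(animal_id = id, truth = d$group[1], label = cl$label,
               correct = d$group[1] == cl$label,
               justification = paste(cl$justification, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "accuracy") <- mean(out$correct)
  out
}

#' Flag robust outliers by median absolute deviation
#'
#' Annotates values whose absolute deviation from the median exceeds
#' `k * 1.4826 * MAD` (MAD = raw median absolute deviation; the 1.4826
#' factor scales it to a Gaussian SD). Data are never removed, only
#' flagged. A degenerate `MAD = 0` (at least half the values identical)
#' triggers a warning; the strict inequality then flags exactly the
#' values that differ from the median.
#'
#' @param values Numeric vector, length at least 4.
#' @param k Threshold in scaled-MAD units (default 5).
#' @return Logical vector of flags, same length as `values`.
#' @examples
#' robust_outlier_flag(c(0, 0, 0, 100)) # last value flagged
#' @export
robust_outlier_flag <- function(values, k = 5) {
  stopifnot(is.numeric(values), !anyNA(values))
  if (length(values) < 4L) {
    stop("need at least 4 values to flag outliers", call. = FALSE)
  }
  med <- stats::median(values)
  mad_raw <- stats::median(abs(values - med))
  if (mad_raw == 0) {
    warning("MAD is zero; flagging all values differing from the median",
            call. = FALSE)
  }
  abs(values - med) > k * 1.4826 * mad_raw
}
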