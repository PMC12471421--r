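#' Default SNORT rubric
#'
#' The swine neurological observed response test (SNORT) is an observer
#' rubric of ordered sub-items whose maxima sum to 11 and minima to 2, so
#' the total ranges over `[2, 11]` (11 = fully normal). The default item
#' set used here covers alertness, posture and gait, response to approach,
#' response to offered food and treat, and vocalization/demeanor; item
#' ranges are configurable because rubric wording varies between
#' facilities.
#'
#' @return Data frame with columns `item`, `min`, `max`.
#' @export
snort_rubric <- function() {
  data.frame(
    item = c("alertness", "posture_gait", "response_to_approach",
             "response_to_offered_food_and_treat", "vocalization_demeanor"),
    min = c(1L, 1L, 0L, 0L, 0L),
    max = c(3L, 2L, 2L, 2L, 2L),
    stringsAsFactors = FALSE)
}

#' Total SNORT score from sub-item scores
#'
#' Validates each sub-score against its rubric item range, sums them, and
#' clips the total to `[2, 11]`.
#'
#' @param subscores Named numeric vector of per-item scores; names must
#'   match `rubric$item`.
#' @param rubric Rubric definition; default [snort_rubric()].
#' @return Integer SNORT total in `[2, 11]`.
#' @examples
#' r <- snort_rubric()
#' snort_score(setNames(r$max, r$item)) # 11, fully normal
#' @export
snort_score <- function(subscores, rubric = snort_rubric()) {
  stopifnot(is.numeric(subscores))
  if (is.null(names(subscores)) ||
      !setequal(names(subscores), rubric$item)) {
    stop("subscores must be named after the rubric items: ",
         paste(rubric$item, collapse = ", "), call. = FALSE)
  }
  subscores <- subscores[rubric$item]
  bad <- subscores < rubric$min | subscores > rubric$max
  if (any(bad)) {
    stop("sub-score out of range for item(s): ",
         paste(rubric$item[bad], collapse = ", "), call. = FALSE)
  }
  total <- sum(subscores)
  as.integer(min(max(total, 2), 11))
}
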