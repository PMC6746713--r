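#' Score the PHQ-9 questionnaire
#'
#' Compound score = sum of the nine item responses, each in 0..3; range
#' 0..27.
#'
#' @param items Integer vector of exactly 9 responses in `[0, 3]`.
#' @return Integer compound score.
#' @export
score_phq9 <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 9) {
    stop("PHQ-9 requires exactly 9 items (got ", length(items), ")",
         call. = FALSE)
  }
  bad <- which(is.na(items) | items < 0 | items > 3 | items != round(items))
  if (length(bad) > 0) {
    stop("PHQ-9 item ", bad[1], " out of range [0, 3]: ", items[bad[1]],
         call. = FALSE)
  }
  as.integer(sum(items))
}

#' Assign depressive-tendency group labels
#'
#' Subjects with PHQ-9 compound score at or above the cutoff are labelled
#' `DT` (depressive tendency), below it `HC` (healthy control). The study
#' presets are cutoff 5 (mild or worse symptoms) and 10 (moderate/major
#' depression).
#'
#' @param score Integer PHQ-9 score(s) in `[0, 27]`.
#' @param cutoff Integer cutoff (default 5).
#' @return Factor with levels `HC`, `DT`; attribute `cutoff` records the
#'   cutoff used.
#' @export
assign_group <- function(score, cutoff = 5) {
  if (any(score < 0 | score > 27)) {
    stop("PHQ-9 score out of range [0, 27]", call. = FALSE)
  }
  out <- factor(ifelse(score >= cutoff, "DT", "HC"), levels = c("HC", "DT"))
  attr(out, "cutoff") <- cutoff
  out
}

#' Label table for a cohort
#'
#' @param cohort Tibble from [read_cohort()] or [generate_cohort()]'s
#'   `subjects` (needs `subject_id` and `phq9_score`).
#' @param cutoff PHQ-9 cutoff (5 or 10 presets; any integer allowed).
#' @return Tibble `subject_id`, `phq9`, `label`, `cutoff`.
#' @export
cohort_labels <- function(cohort, cutoff = 5) {
  tibble::tibble(
    subject_id = as.character(cohort$subject_id),
    phq9 = as.integer(cohort$phq9_score),
    label = assign_group(cohort$phq9_score, cutoff),
    cutoff = as.integer(cutoff))
}
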