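#' Convergence session count
#'
#' Smallest number of chronological sessions n such that every cumulative
#' mean probability over the first m sessions, for all m >= n, lies within
#' `tolerance` of the full-sequence mean (the final estimation). A constant
#' probability stream converges at n = 1.
#'
#' @param session_probs Chronological session probabilities (length >= 1).
#' @param tolerance Absolute deviation tolerance (default 0.05).
#' @return Integer session count >= 1.
#' @export
convergence_session_count <- function(session_probs, tolerance = 0.05) {
  stopifnot(length(session_probs) >= 1)
  cm <- cumsum(session_probs) / seq_along(session_probs)
  final <- cm[length(cm)]
  ok <- abs(cm - final) <= tolerance + 1e-12
  bad <- which(!ok)
  if (length(bad) == 0) 1L else as.integer(max(bad) + 1L)
}

#' Per-subject daily prediction trajectories
#'
#' Daily mean prediction probability and session count per subject; days
#' with zero sessions are omitted.
#'
#' @param session_probs Tibble with `subject_id`, `day_index`, `prob` (e.g.
#'   from [loso_session_probs()]).
#' @return Tibble `subject_id`, `day_index`, `daily_mean`, `n_sessions`.
#' @export
daily_trajectories <- function(session_probs) {
  session_probs |>
    dplyr::group_by(.data$subject_id, .data$day_index) |>
    dplyr::summarise(daily_mean = mean(.data$prob),
                     n_sessions = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$subject_id, .data$day_index)
}

#' Daily-variability correlation
#'
#' For each subject, the standard deviation of the daily mean prediction
#' probabilities and the average number of sessions per active day; across
#' subjects, the Spearman correlation between the two (in the study's
#' framing, a negative correlation indicates that sparse typing days drive
#' probability fluctuation). Subjects with fewer than two active days are
#' excluded (counted in the `n_excluded` field).
#'
#' @param daily Tibble from [daily_trajectories()].
#' @return List `rho`, `p`, `n`, `n_excluded`, `per_subject` (tibble with
#'   `daily_sd` and `mean_daily_sessions`), `degenerate` flag.
#' @export
daily_variability_correlation <- function(daily) {
  per_subject <- daily |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_days = dplyr::n(),
                     daily_sd = sd(.data$daily_mean),
                     mean_daily_sessions = mean(.data$n_sessions),
                     .groups = "drop")
  excluded <- per_subject$n_days < 2
  kept <- per_subject[!excluded, , drop = FALSE]
  if (nrow(kept) < 3) {
    stop("daily-variability correlation needs at least 3 subjects with >= 2 active days",
         call. = FALSE)
  }
  ct <- correlation_with_phq9(kept$daily_sd, kept$mean_daily_sessions)
  list(rho = ct$rho, p = ct$p, n = nrow(kept),
       n_excluded = sum(excluded), per_subject = kept,
       degenerate = isTRUE(ct$degenerate))
}

#' Convergence records for a LOSO result
#'
#' @param result A `loso_result`.
#' @param tolerance Convergence tolerance (default 0.05).
#' @return Tibble `subject_id`, `n_converge`, `final_mean`, `n_sessions`.
#' @export
convergence_report <- function(result, tolerance = 0.05) {
  dplyr::bind_rows(lapply(result$iterations, function(it) {
    tibble::tibble(subject_id = it$subject_id,
                   n_converge = convergence_session_count(it$session_probs,
                                                          tolerance),
                   final_mean = it$mean_prob,
                   n_sessions = length(it$session_probs))
  }))
}
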