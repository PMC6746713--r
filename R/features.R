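#' Canonical feature names
#'
#' The fixed order of the 20 session features: four summary statistics
#' (median, std, skewness, kurtosis) for each of HT, FT, SP, PFR, followed by
#' the typing metadata (session duration `t_s` in seconds, characters typed
#' `l_chars`, delete rate `dr`, characters per minute `cpm`).
#'
#' @return Character vector of length 20.
#' @export
feature_names <- function() {
  vars <- c("ht", "ft", "sp", "pfr")
  stats <- c("median", "std", "skew", "kurt")
  c(as.vector(t(outer(vars, stats, paste, sep = "_"))),
    "t_s", "l_chars", "dr", "cpm")
}

#' Summary statistics of a dynamics sequence
#'
#' Median, standard deviation, skewness and kurtosis of one filtered
#' keystroke-dynamics sequence. The median uses the ceiling/floor midpoint
#' rule on the ascending-sorted sequence (equivalent to the usual midpoint
#' median); the standard deviation is the population form
#' sqrt(sum((a_k - mu)^2) / N); skewness and kurtosis are sums of third and
#' fourth powers of z-scores divided by N + 1 by default
#' (`standard_moments = TRUE` divides by N instead).
#'
#' @param x Numeric sequence of length >= 4.
#' @param standard_moments Use the conventional N denominator for skewness
#'   and kurtosis instead of N + 1?
#' @return Named list `median`, `std`, `skew`, `kurt`, plus a logical
#'   `degenerate` flag set when the sequence has zero dispersion (skewness
#'   and kurtosis are then reported as 0).
#' @export
summary_statistics <- function(x, standard_moments = FALSE) {
  n <- length(x)
  if (n < 4) {
    stop("summary_statistics needs at least 4 values (got ", n, ")",
         call. = FALSE)
  }
  s <- sort(x)
  med <- (s[ceiling(n / 2)] + s[floor(n / 2 + 1)]) / 2
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / n)
  if (sigma == 0) {
    return(list(median = med, std = 0, skew = 0, kurt = 0, degenerate = TRUE))
  }
  z <- (x - mu) / sigma
  denom <- if (standard_moments) n else n + 1
  list(median = med, std = sigma,
       skew = sum(z^3) / denom, kurt = sum(z^4) / denom,
       degenerate = FALSE)
}

#' Typing metadata of a session
#'
#' Session duration T (seconds, keyboard launch to last key release),
#' characters typed L (non-delete key registrations), delete rate DR
#' (delete presses over all key presses) and characters per minute
#' CPM = L / (T / 60).
#'
#' @param session A `raw_typing_session`.
#' @return Named list `t_s`, `l_chars`, `dr`, `cpm`.
#' @export
session_metadata <- function(session) {
  ev <- session$events
  n <- nrow(ev)
  t_s <- (max(ev$release) - session$start_time) / 1000
  if (t_s <= 0) {
    stop("session '", session$session_id,
         "': non-positive duration, CPM undefined", call. = FALSE)
  }
  l <- sum(!ev$is_delete)
  dr <- sum(ev$is_delete) / n
  list(t_s = t_s, l_chars = as.numeric(l), dr = dr, cpm = l / (t_s / 60))
}

#' Assemble the 20-dimensional session feature vector
#'
#' Combines the four summary statistics of each dynamics variable with the
#' four metadata values into the canonical 20-feature order.
#'
#' @param stats Named list with elements `ht`, `ft`, `sp`, `pfr`, each a
#'   result of [summary_statistics()] (or `NULL` when that sequence was too
#'   short / excluded, which raises an incomplete-session error).
#' @param meta Result of [session_metadata()].
#' @return Named numeric vector of length 20 in [feature_names()] order.
#' @export
assemble_feature_vector <- function(stats, meta) {
  vars <- c("ht", "ft", "sp", "pfr")
  missing_var <- vars[vapply(vars, function(v) is.null(stats[[v]]), logical(1))]
  if (length(missing_var) > 0 || is.null(meta)) {
    stop(structure(
      class = c("keydyn_incomplete_session", "error", "condition"),
      list(message = paste0("incomplete session: missing ",
                            paste(c(missing_var,
                                    if (is.null(meta)) "metadata"),
                                  collapse = ", ")),
           call = NULL)))
  }
  v <- c(unlist(lapply(vars, function(a) {
    st <- stats[[a]]
    c(st$median, st$std, st$skew, st$kurt)
  })), meta$t_s, meta$l_chars, meta$dr, meta$cpm)
  names(v) <- feature_names()
  v
}

#' Extract the session feature table of a cohort
#'
#' Runs the full per-session extraction: validity check (minimum 8 keys),
#' timing filters, per-user flight-time outlier flagging, summary statistics
#' and metadata. Sessions that end up with any dynamics sequence shorter than
#' `min_stat_len` (or outlier-flagged, which removes FT/SP/PFR) are skipped
#' and counted.
#'
#' @param sessions List of `raw_typing_session` (any subject mix).
#' @param cfg A [filter_config()].
#' @param standard_moments Passed to [summary_statistics()].
#' @param min_stat_len Minimum sequence length for the summary statistics
#'   (default 4; kurtosis needs spread).
#' @return Tibble with `subject_id`, `session_id`, `day_index` (calendar day
#'   offset from the subject's first session, UTC) and the 20 features.
#'   Attribute `counts` records sessions read / invalid / outlier-flagged /
#'   incomplete / emitted.
#' @export
extract_features <- function(sessions, cfg = filter_config(),
                             standard_moments = FALSE, min_stat_len = 4) {
  subj_ids <- vapply(sessions, function(s) s$subject_id, character(1))
  counts <- c(read = length(sessions), invalid = 0L, outlier = 0L,
              incomplete = 0L, emitted = 0L)
  rows <- list()
  for (sid in unique(subj_ids)) {
    subj_sessions <- sessions[subj_ids == sid]
    valid <- vapply(subj_sessions, is_valid_session, logical(1),
                    min_keys = cfg$min_keys)
    counts["invalid"] <- counts["invalid"] + sum(!valid)
    subj_sessions <- subj_sessions[valid]
    if (length(subj_sessions) == 0) next
    dyn <- lapply(subj_sessions, session_dynamics, cfg = cfg)
    flags <- flag_outlier_sessions(dyn, sigma = cfg$outlier_sigma)
    counts["outlier"] <- counts["outlier"] + sum(flags)
    starts <- vapply(subj_sessions, function(s) s$start_time, numeric(1))
    day0 <- floor(min(starts) / 86400000)
    for (j in seq_along(subj_sessions)) {
      s <- subj_sessions[[j]]
      d <- dyn[[j]]
      seqs <- list(ht = d$ht, ft = d$ft, sp = d$sp, pfr = d$pfr)
      if (flags[j]) seqs[c("ft", "sp", "pfr")] <- list(NULL, NULL, NULL)
      stats <- lapply(seqs, function(a) {
        if (is.null(a) || length(a) < min_stat_len) NULL
        else summary_statistics(a, standard_moments = standard_moments)
      })
      row <- tryCatch({
        meta <- session_metadata(s)
        fv <- assemble_feature_vector(stats, meta)
        dplyr::bind_cols(
          tibble::tibble(subject_id = s$subject_id,
                         session_id = s$session_id,
                         day_index = as.integer(floor(s$start_time / 86400000) - day0)),
          tibble::as_tibble_row(fv))
      }, keydyn_incomplete_session = function(e) NULL,
         error = function(e) NULL)
      if (is.null(row)) {
        counts["incomplete"] <- counts["incomplete"] + 1L
      } else {
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- if (length(rows) == 0) {
    tibble::as_tibble(c(list(subject_id = character(0),
                             session_id = character(0),
                             day_index = integer(0)),
                        setNames(rep(list(numeric(0)), 20), feature_names())))
  } else {
    dplyr::bind_rows(rows)
  }
  counts["emitted"] <- nrow(out)
  attr(out, "counts") <- counts
  out
}

#' Write a feature table to CSV
#'
#' @param features Tibble from [extract_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}
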