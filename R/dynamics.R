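#' Timing-filter configuration
#'
#' Thresholds for the conditional filtering of keystroke dynamics sequences:
#' flight times above `ft_max_ms` (keyboard left idle on screen) or at/below
#' `ft_min_exclusive_ms` (two-handed overlap) are removed; hold times above
#' `long_press_ms` are deliberate long presses and are removed; sessions with
#' fewer than `min_keys` keys are invalid; per-user sessions whose flight-time
#' median deviates from the user's mean of session medians by more than
#' `outlier_sigma` standard deviations are excluded from flight-time-derived
#' features.
#'
#' @param ft_max_ms Maximum flight time kept, ms (default 3000 = 3 s).
#' @param ft_min_exclusive_ms Exclusive lower bound on flight time, ms.
#' @param long_press_ms Long-press hold-time threshold, ms (default 300).
#' @param min_keys Minimum keys for a valid session (default 8).
#' @param outlier_sigma Per-user session outlier threshold in standard
#'   deviations of session flight-time medians (default 3).
#' @return A `filter_config` list.
#' @export
filter_config <- function(ft_max_ms = 3000, ft_min_exclusive_ms = 0,
                          long_press_ms = 300, min_keys = 8,
                          outlier_sigma = 3) {
  stopifnot(ft_max_ms > ft_min_exclusive_ms, long_press_ms > 0,
            min_keys >= 1, outlier_sigma > 0)
  structure(list(ft_max_ms = ft_max_ms,
                 ft_min_exclusive_ms = ft_min_exclusive_ms,
                 long_press_ms = long_press_ms, min_keys = min_keys,
                 outlier_sigma = outlier_sigma),
            class = "filter_config")
}

#' Hold times of a session
#'
#' HT_n = release_n - press_n for every key n = 1..N, in milliseconds.
#'
#' @param session A `raw_typing_session`.
#' @return Numeric vector of length N.
#' @export
compute_hold_times <- function(session) {
  ev <- session$events
  if (nrow(ev) == 0) stop("empty session: no events", call. = FALSE)
  as.numeric(ev$release - ev$press)
}

#' Flight times of a session
#'
#' FT_n = press_{n+1} - release_n for n = 1..N-1, in milliseconds. Negative
#' values are legal at this stage: they occur when the next key is pressed
#' before the previous one is released (two-handed typing).
#'
#' @param session A `raw_typing_session`.
#' @return Numeric vector of length N-1 (empty when N < 2).
#' @export
compute_flight_times <- function(session) {
  ev <- session$events
  n <- nrow(ev)
  if (n < 2) return(numeric(0))
  as.numeric(ev$press[-1] - ev$release[-n])
}

#' Inter-key distances of a session
#'
#' Euclidean distance between successive key centres in millimetres,
#' converting pixel offsets through the screen densities:
#' D_n = sqrt( (dX/densityX * 25.4)^2 + (dY/densityY * 25.4)^2 ).
#' Privacy-mode sessions pass through their precomputed `distances_mm`.
#'
#' @param session A `raw_typing_session`.
#' @return Numeric vector of length N-1 (empty when N < 2).
#' @export
compute_distances <- function(session) {
  if (!session_has_coords(session)) return(as.numeric(session$distances_mm))
  if (session$screen_density_x <= 0 || session$screen_density_y <= 0) {
    stop("screen densities must be > 0", call. = FALSE)
  }
  ev <- session$events
  if (nrow(ev) < 2) return(numeric(0))
  dx <- diff(ev$x) / session$screen_density_x * 25.4
  dy <- diff(ev$y) / session$screen_density_y * 25.4
  sqrt(dx^2 + dy^2)
}

#' Speed and press-flight-rate sequences
#'
#' SP_n = D_n / FT_n (mm/ms) and PFR_n = HT_n / FT_n (dimensionless) over the
#' aligned index n = 1..length(ft), pairing each key's hold time with the
#' flight to the next key. Flight times must already be filtered to strictly
#' positive values. Entries whose hold time was removed as a long press
#' (encoded as `NA` in `ht`) are dropped from PFR only.
#'
#' @param ht Hold times aligned with `ft` (HT of the key starting flight n);
#'   `NA` marks a long-press-removed hold.
#' @param ft Strictly positive filtered flight times.
#' @param dist Inter-key distances aligned with `ft`.
#' @return List with components `sp` and `pfr`.
#' @export
compute_speed_and_pfr <- function(ht, ft, dist) {
  if (length(ft) != length(dist) || length(ht) != length(ft)) {
    stop("ht, ft and dist must be index-aligned", call. = FALSE)
  }
  if (any(ft <= 0)) {
    stop("contract violation: non-positive flight time reached speed/PFR computation",
         call. = FALSE)
  }
  sp <- dist / ft
  pfr <- (ht / ft)[!is.na(ht)]
  list(sp = as.numeric(sp), pfr = as.numeric(pfr))
}

#' Raw aligned dynamics of a session
#'
#' Computes the unfiltered, index-aligned HT/FT/D sequences of one session,
#' ready for [apply_timing_filters()].
#'
#' @param session A `raw_typing_session`.
#' @return A `dynamics_sequences` object with `filtered = FALSE`.
#' @export
raw_dynamics <- function(session) {
  ht <- compute_hold_times(session)
  structure(
    list(ht = ht, ft = compute_flight_times(session),
         dist = compute_distances(session),
         sp = NULL, pfr = NULL,
         n_raw = length(ht), long_press_count = 0L, filtered = FALSE),
    class = "dynamics_sequences")
}

#' Apply the conditional timing filters
#'
#' Removes flight times above 3 s (idle keyboard) and at/below 0 ms
#' (two-handed overlap), removes hold times above the long-press threshold,
#' and computes the speed and press-flight-rate sequences with cascade
#' semantics: removing FT_n removes SP_n and PFR_n; removing HT_n (long
#' press) removes PFR_n only. Filtering is idempotent: applying it to an
#' already-filtered object returns it unchanged.
#'
#' @param dyn A `dynamics_sequences` object (from [raw_dynamics()]).
#' @param cfg A [filter_config()].
#' @return A filtered `dynamics_sequences` with components `ht`, `ft`,
#'   `dist`, `sp`, `pfr`, `n_raw`, `long_press_count`.
#' @export
apply_timing_filters <- function(dyn, cfg = filter_config()) {
  stopifnot(inherits(dyn, "dynamics_sequences"))
  if (isTRUE(dyn$filtered)) {
    # already-filtered sequences satisfy all bounds; re-filtering is a no-op
    out <- dyn
    out$ht <- dyn$ht[dyn$ht <= cfg$long_press_ms]
    keep <- dyn$ft > cfg$ft_min_exclusive_ms & dyn$ft <= cfg$ft_max_ms
    out$ft <- dyn$ft[keep]
    out$dist <- dyn$dist[keep]
    return(out)
  }
  ht <- dyn$ht
  ft <- dyn$ft
  dist <- dyn$dist
  n <- length(ht)
  ht_keep <- ht <= cfg$long_press_ms
  long_press_count <- sum(!ht_keep)
  ft_keep <- ft > cfg$ft_min_exclusive_ms & ft <= cfg$ft_max_ms
  # flight n runs from key n; pair HT_n with FT_n, NA-marking removed holds
  ht_for_ft <- ht[seq_along(ft)]
  ht_for_ft[!ht_keep[seq_along(ft)]] <- NA_real_
  sp <- numeric(0)
  pfr <- numeric(0)
  if (any(ft_keep)) {
    ratios <- compute_speed_and_pfr(ht_for_ft[ft_keep], ft[ft_keep],
                                    dist[ft_keep])
    sp <- ratios$sp
    pfr <- ratios$pfr
  }
  structure(
    list(ht = ht[ht_keep], ft = ft[ft_keep], dist = dist[ft_keep],
         sp = sp, pfr = pfr, n_raw = dyn$n_raw,
         long_press_count = as.integer(long_press_count), filtered = TRUE),
    class = "dynamics_sequences")
}

#' Session dynamics, end to end
#'
#' Convenience wrapper: raw sequences then conditional filters.
#'
#' @inheritParams raw_dynamics
#' @param cfg A [filter_config()].
#' @return A filtered `dynamics_sequences`.
#' @export
session_dynamics <- function(session, cfg = filter_config()) {
  apply_timing_filters(raw_dynamics(session), cfg)
}

#' Session validity
#'
#' A session is valid only if at least `min_keys` characters were typed
#' (default 8).
#'
#' @param session A `raw_typing_session`.
#' @param min_keys Minimum keystroke count.
#' @return Logical.
#' @export
is_valid_session <- function(session, min_keys = 8) {
  nrow(session$events) >= min_keys
}

#' Per-user session outlier flags
#'
#' For one user's sessions, computes each session's flight-time median
#' (after timing filters) and flags sessions whose median deviates from the
#' mean of the user's session medians by more than `sigma` standard
#' deviations. Flagged sessions have their FT-derived sequences (FT, SP, PFR)
#' excluded from feature extraction. With fewer than two usable sessions, or
#' zero dispersion of the medians, nothing is flagged.
#'
#' @param user_dynamics List of filtered `dynamics_sequences` for one user.
#' @param sigma Threshold in standard deviations (default 3).
#' @return Logical mask, `TRUE` = outlier session.
#' @export
flag_outlier_sessions <- function(user_dynamics, sigma = 3) {
  meds <- vapply(user_dynamics, function(d) {
    if (length(d$ft) == 0) NA_real_ else median(d$ft)
  }, numeric(1))
  ok <- !is.na(meds)
  flags <- rep(FALSE, length(meds))
  if (sum(ok) < 2) return(flags)
  mu <- mean(meds[ok])
  s <- sd_pop(meds[ok])
  if (s == 0) return(flags)
  flags[ok] <- abs(meds[ok] - mu) > sigma * s
  flags
}

# population standard deviation: sqrt(mean squared deviation)
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
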