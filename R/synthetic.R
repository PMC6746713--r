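#' Synthetic typing-cohort specification
#'
#' Parameters of the seeded two-group typing-cohort generator. Group scale
#' anchors default to the study conditions this package targets: 11 DT / 14
#' HC subjects, 55.14 / 66.46 sessions per day, PHQ-9 group means 10.64 /
#' 2.29 with DT scores in 5..15 and HC in 0..4. Psychomotor effects default
#' to a higher DT hold-time median and more dispersed DT speed /
#' press-flight-rate sequences, the directions seen in depressed typing.
#'
#' @param n_dt,n_hc Subject counts per group.
#' @param days Study length in days.
#' @param sessions_per_day_mean Named vector `c(dt = , hc = )` of Poisson
#'   means for daily session counts.
#' @param keys_mean,keys_min Session keystroke count: `keys_min` plus a
#'   Poisson draw with mean `keys_mean - keys_min`.
#' @param ht_median_hc,ht_median_dt Group hold-time medians, ms.
#' @param ht_sdlog Within-session log-sd of hold times.
#' @param ft_median_ms,ft_sdlog Flight-time median (ms) and within-session
#'   log-sd (both groups).
#' @param pfr_dispersion_multiplier DT-vs-HC within-session dispersion ratio
#'   (>= 1) applied to hold- and flight-time deviations, inflating DT speed
#'   and press-flight-rate spread.
#' @param p_overlap Probability of a two-handed-overlap event (negative
#'   flight time).
#' @param p_pause Probability of a pause event (flight time > 3 s).
#' @param p_longpress Probability of a deliberate long press (> 300 ms hold).
#' @param delete_rate Mean delete-key rate.
#' @param phq9_mean_hc,phq9_sd_hc,phq9_range_hc HC PHQ-9 score distribution
#'   (truncated normal, rounded).
#' @param phq9_mean_dt,phq9_sd_dt,phq9_range_dt DT PHQ-9 score distribution.
#' @param subject_sdlog_ht,subject_sdlog_ft Between-subject log-sd of the
#'   per-subject hold/flight-time medians (random effects).
#' @param screen_ppi_x,screen_ppi_y Virtual screen densities, pixels/inch.
#' @param key_pitch_mm Key pitch of the virtual 10x4 QWERTY grid, mm.
#' @param seed Default generator seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_dt = 11, n_hc = 14, days = 60,
                        sessions_per_day_mean = c(dt = 55.14, hc = 66.46),
                        keys_mean = 20, keys_min = 2,
                        ht_median_hc = 100, ht_median_dt = 140,
                        ht_sdlog = 0.2,
                        ft_median_ms = 250, ft_sdlog = 0.25,
                        pfr_dispersion_multiplier = 1.5,
                        p_overlap = 0.05, p_pause = 0.02,
                        p_longpress = 0.01, delete_rate = 0.07,
                        phq9_mean_hc = 2.29, phq9_sd_hc = 1.73,
                        phq9_range_hc = c(0, 4),
                        phq9_mean_dt = 10.64, phq9_sd_dt = 3.47,
                        phq9_range_dt = c(5, 15),
                        subject_sdlog_ht = 0.12, subject_sdlog_ft = 0.15,
                        screen_ppi_x = 420, screen_ppi_y = 420,
                        key_pitch_mm = 6, seed = 1) {
  spec <- structure(as.list(environment()), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    stopifnot(n_dt >= 1, n_hc >= 1, days >= 1,
              all(sessions_per_day_mean > 0),
              keys_min >= 2, keys_mean >= keys_min,
              ht_median_hc > 0, ht_median_dt > 0, ht_sdlog > 0,
              ft_median_ms > 0, ft_sdlog > 0,
              pfr_dispersion_multiplier >= 1,
              p_overlap >= 0, p_overlap <= 1, p_pause >= 0, p_pause <= 1,
              p_longpress >= 0, p_longpress <= 1,
              delete_rate >= 0, delete_rate <= 1,
              subject_sdlog_ht > 0, subject_sdlog_ft > 0,
              screen_ppi_x > 0, screen_ppi_y > 0, key_pitch_mm > 0)
    if (phq9_range_dt[1] < 5) {
      stop("contradictory spec: DT PHQ-9 range must start at or above the cutoff of 5",
           call. = FALSE)
    }
    if (phq9_range_hc[2] >= 5) {
      stop("contradictory spec: HC PHQ-9 range must stay below the cutoff of 5",
           call. = FALSE)
    }
  })
  invisible(spec)
}

#' Plant a psychomotor effect into a cohort spec
#'
#' Raises the DT group's hold-time median by `ht_shift_ms` (ms) and scales
#' the DT within-session dispersion (hence speed and press-flight-rate
#' spread) by `dispersion_multiplier`, relative to the spec's current
#' values; the HC group is untouched. `plant_effect(spec, 0, 1)` is the
#' identity.
#'
#' @param spec A [cohort_spec()].
#' @param ht_shift_ms Additional DT hold-time median shift, ms (>= 0).
#' @param dispersion_multiplier Multiplier on the DT dispersion ratio
#'   (>= 1).
#' @return The modified `cohort_spec`.
#' @export
plant_effect <- function(spec, ht_shift_ms, dispersion_multiplier = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (ht_shift_ms < 0) stop("ht_shift_ms must be >= 0", call. = FALSE)
  if (dispersion_multiplier < 1) {
    stop("dispersion_multiplier must be >= 1", call. = FALSE)
  }
  spec$ht_median_dt <- spec$ht_median_dt + ht_shift_ms
  spec$pfr_dispersion_multiplier <-
    spec$pfr_dispersion_multiplier * dispersion_multiplier
  validate_cohort_spec(spec)
  spec
}

# truncated-normal integer draw within [lo, hi]
rtrunc_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# distribute a compound score over 9 items, each capped at 3
allocate_phq9_items <- function(score) {
  items <- integer(9)
  for (k in seq_len(score)) {
    open <- which(items < 3)
    j <- open[sample.int(length(open), 1)]
    items[j] <- items[j] + 1L
  }
  items
}

# linear-deviation dispersion scaling about the median: std scales by m.
# The floor keeps scaled draws away from the implausible near-zero range
# (flight times have a physiological lower bound for sequential taps); it
# also keeps the 1/FT tail of speed and press-flight rate from exploding,
# so per-session SP/PFR spread scales about linearly with m.
scale_dispersion <- function(x, med, m, floor_at) {
  pmax(med + (x - med) * m, floor_at)
}

generate_session_events <- function(n_keys, med_ht, med_ft, spec, disp_m) {
  ht <- med_ht * exp(rnorm(n_keys, 0, spec$ht_sdlog))
  ht <- scale_dispersion(ht, med_ht, disp_m, floor_at = 5)
  lp <- runif(n_keys) < spec$p_longpress
  ht[lp] <- runif(sum(lp), 320, 900)
  ft <- med_ft * exp(rnorm(n_keys - 1, 0, spec$ft_sdlog))
  ft <- scale_dispersion(ft, med_ft, disp_m, floor_at = 0.6 * med_ft)
  pause <- runif(n_keys - 1) < spec$p_pause
  ft[pause] <- runif(sum(pause), 3050, 20000)
  overlap <- runif(n_keys - 1) < spec$p_overlap & !pause
  if (any(overlap)) {
    io <- which(overlap)
    ft[io] <- -runif(length(io), 0.1, 0.8) * pmin(ht[io], ht[io + 1])
  }
  # virtual 10x4 QWERTY grid, uniform content-free key choice
  pitch_x <- spec$key_pitch_mm / 25.4 * spec$screen_ppi_x
  pitch_y <- spec$key_pitch_mm / 25.4 * spec$screen_ppi_y
  col <- sample.int(10, n_keys, replace = TRUE) - 1
  row <- sample.int(4, n_keys, replace = TRUE) - 1
  x <- round((col + 0.5) * pitch_x)
  y <- round((row + 0.5) * pitch_y + 4 * pitch_y) # keyboard at screen bottom
  press <- cumsum(c(0, ht[-n_keys] + ft))
  release <- press + ht
  press <- round(press)
  release <- round(release)
  for (i in seq_len(n_keys - 1)) { # integer-ms strict monotonicity fix-up
    if (press[i + 1] <= press[i]) press[i + 1] <- press[i] + 1
  }
  release <- pmax(release, press)
  for (i in seq_len(n_keys - 1)) {
    if (release[i + 1] <= release[i]) release[i + 1] <- release[i] + 1
  }
  tibble::tibble(press = press, release = release, x = x, y = y,
                 is_delete = runif(n_keys) < spec$delete_rate)
}

#' Generate a synthetic typing cohort
#'
#' Draws a two-group cohort of subjects with PHQ-9 items, demographics and
#' raw typing sessions. Per subject, hold- and flight-time medians carry
#' log-normal random effects around the group parameters; per session, key
#' counts, per-key hold/flight times (with injected two-handed overlaps,
#' pauses > 3 s and deliberate long presses), content-free QWERTY key
#' coordinates and delete flags are drawn. Fully reproducible under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @return List with `subjects` (tibble: ids, PHQ-9 items and score, group,
#'   demographics) and `sessions` (list of `raw_typing_session`).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed) {
  validate_cohort_spec(spec)
  withr::with_seed(as.integer(seed), {
    groups <- c(rep("DT", spec$n_dt), rep("HC", spec$n_hc))
    n_subj <- length(groups)
    ids <- sprintf("S%02d", seq_len(n_subj))
    scores <- integer(n_subj)
    items_mat <- matrix(0L, n_subj, 9)
    for (i in seq_len(n_subj)) {
      scores[i] <- if (groups[i] == "DT") {
        rtrunc_int(1, spec$phq9_mean_dt, spec$phq9_sd_dt,
                   spec$phq9_range_dt[1], spec$phq9_range_dt[2])
      } else {
        rtrunc_int(1, spec$phq9_mean_hc, spec$phq9_sd_hc,
                   spec$phq9_range_hc[1], spec$phq9_range_hc[2])
      }
      items_mat[i, ] <- allocate_phq9_items(scores[i])
    }
    subjects <- tibble::tibble(
      subject_id = ids, group = groups,
      age = rtrunc_int(n_subj, 23.7, 3.9, 18, 39),
      gender = sample(c("F", "M"), n_subj, replace = TRUE,
                      prob = c(0.4, 0.6)),
      education = sample(c("high-school", "university"), n_subj,
                         replace = TRUE, prob = c(0.76, 0.24)))
    for (j in 1:9) subjects[[paste0("phq", j)]] <- items_mat[, j]
    subjects$phq9_score <- scores

    epoch0 <- 1541721600000 # study-scale anchor date (ms)
    sessions <- list()
    for (i in seq_len(n_subj)) {
      g <- tolower(groups[i])
      med_ht <- (if (g == "dt") spec$ht_median_dt else spec$ht_median_hc) *
        exp(rnorm(1, 0, spec$subject_sdlog_ht))
      med_ft <- spec$ft_median_ms * exp(rnorm(1, 0, spec$subject_sdlog_ft))
      disp_m <- if (g == "dt") spec$pfr_dispersion_multiplier else 1
      rate <- spec$sessions_per_day_mean[[g]]
      k <- 0L
      for (day in seq_len(spec$days)) {
        n_d <- rpois(1, rate)
        if (n_d == 0) next
        starts <- sort(runif(n_d, 0, 86400000 - 60000))
        for (s in seq_len(n_d)) {
          k <- k + 1L
          n_keys <- spec$keys_min + rpois(1, spec$keys_mean - spec$keys_min)
          ev <- generate_session_events(n_keys, med_ht, med_ft, spec, disp_m)
          t0 <- epoch0 + (day - 1) * 86400000 + round(starts[s])
          ev$press <- ev$press + t0
          ev$release <- ev$release + t0
          sessions[[length(sessions) + 1L]] <- typing_session(
            subject_id = ids[i],
            session_id = sprintf("%s-%05d", ids[i], k),
            start_time = t0 - round(runif(1, 100, 1500)),
            events = ev,
            screen_density_x = spec$screen_ppi_x,
            screen_density_y = spec$screen_ppi_y,
            app_name = "messenger")
        }
      }
    }
    list(subjects = subjects, sessions = sessions)
  })
}
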