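# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# Build a session from explicit press/release vectors (ms, relative to start).
make_session <- function(press, release, x = NULL, y = NULL,
                         deletes = NULL, subject = "S01", session = "sess1",
                         start = 0, ppi_x = 420, ppi_y = 420,
                         distances_mm = NULL) {
  n <- length(press)
  if (is.null(x) && is.null(distances_mm)) {
    x <- seq(100, by = 37, length.out = n)
    y <- rep(1700, n)
  }
  typing_session(
    subject_id = subject, session_id = session, start_time = start,
    events = tibble::tibble(
      press = press, release = release,
      x = if (is.null(x)) NA_real_ else x,
      y = if (is.null(y)) NA_real_ else y,
      is_delete = if (is.null(deletes)) rep(FALSE, n) else deletes),
    screen_density_x = ppi_x, screen_density_y = ppi_y,
    distances_mm = distances_mm)
}

# Build a session from hold-time / flight-time sequences.
session_from_timing <- function(ht, ft, start = 0, ...) {
  n <- length(ht)
  stopifnot(length(ft) == n - 1)
  press <- start + cumsum(c(1000, ht[-n] + ft))
  make_session(press = press, release = press + ht, start = start, ...)
}

# A random valid session (integer-ms timings, no overlaps).
random_session <- function(n = 12, subject = "S01", session = "sess1",
                           start = 0) {
  ht <- sample(40:280, n, replace = TRUE)
  ft <- sample(20:900, n - 1, replace = TRUE)
  session_from_timing(ht, ft, subject = subject, session = session,
                      start = start)
}

# A small, fast two-group cohort for pipeline tests: 20 subjects at a
# desk-scale session count, default psychomotor effect sizes.
test_cohort_spec <- function(...) {
  defaults <- list(n_dt = 10, n_hc = 10, days = 2,
                   sessions_per_day_mean = c(dt = 5, hc = 6))
  do.call(cohort_spec, utils::modifyList(defaults, list(...)))
}

# Reduced single-combination random-forest grid for fast LOSO runs.
fast_rf_config <- function(seed = 1, ...) {
  pipeline_config(classifier = "random_forest",
                  grid = data.frame(num_trees = 100, max_depth = 5),
                  seed = seed, ...)
}

# Feature table + labels for a synthetic cohort, in one call.
cohort_feature_fixture <- function(seed = 42, spec = test_cohort_spec(),
                                   cutoff = 5) {
  co <- generate_cohort(spec, seed = seed)
  list(features = extract_features(co$sessions),
       labels = cohort_labels(co$subjects, cutoff),
       cohort = co)
}

# Directly constructed session-level feature table (bypasses extraction) for
# classifier-behaviour tests: one separating feature, the rest noise.
separable_feature_table <- function(n_subjects = 12, sessions_each = 5,
                                    noise_sd = 0.05, seed = 1) {
  withr::with_seed(seed, {
    subj <- sprintf("S%02d", seq_len(n_subjects))
    lab <- rep(c("DT", "HC"), length.out = n_subjects)
    rows <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      v <- matrix(rnorm(sessions_each * 20), sessions_each, 20)
      colnames(v) <- feature_names()
      v[, "ht_median"] <- (lab[i] == "DT") + rnorm(sessions_each, 0, noise_sd)
      data.frame(subject_id = subj[i],
                 session_id = sprintf("%s-%02d", subj[i], seq_len(sessions_each)),
                 day_index = 0L, v, check.names = FALSE)
    }))
    list(features = tibble::as_tibble(rows),
         labels = tibble::tibble(subject_id = subj,
                                 phq9 = ifelse(lab == "DT", 10L, 2L),
                                 label = factor(lab, levels = c("HC", "DT")),
                                 cutoff = 5L))
  })
}
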