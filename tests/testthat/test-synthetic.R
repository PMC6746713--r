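test_that("generated sessions always satisfy the raw-session invariants", {
  spec <- cohort_spec(n_dt = 3, n_hc = 3, days = 2,
                      sessions_per_day_mean = c(dt = 6, hc = 6),
                      p_overlap = 0.2, p_pause = 0.1, p_longpress = 0.05)
  co <- generate_cohort(spec, seed = 71)
  expect_gt(length(co$sessions), 30)
  for (s in co$sessions) {
    expect_silent(validate_session(s)) # strict monotonicity even with overlaps
    expect_gte(min(s$events$press), s$start_time)
  }
  scores <- co$subjects$phq9_score
  expect_true(all(scores[co$subjects$group == "DT"] >= 5))
  expect_true(all(scores[co$subjects$group == "HC"] <= 4))
  # items sum to the compound score
  items <- as.matrix(co$subjects[, paste0("phq", 1:9)])
  expect_equal(unname(rowSums(items)), as.numeric(scores))
  expect_true(all(items >= 0 & items <= 3))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- test_cohort_spec()
  c1 <- generate_cohort(spec, seed = 72)
  c2 <- generate_cohort(spec, seed = 72)
  expect_identical(c1, c2)
  f1 <- tempfile(); f2 <- tempfile()
  write_sessions(c1$sessions[1:20], f1)
  write_sessions(c2$sessions[1:20], f2)
  expect_identical(readLines(f1), readLines(f2))
  c3 <- generate_cohort(spec, seed = 73)
  expect_false(identical(c1$sessions[[1]], c3$sessions[[1]]))
})

test_that("the pre-filter negative flight-time fraction tracks p_overlap", {
  for (p in c(0.03, 0.12)) {
    spec <- cohort_spec(n_dt = 2, n_hc = 2, days = 3,
                        sessions_per_day_mean = c(dt = 25, hc = 25),
                        p_overlap = p, p_pause = 0)
    co <- generate_cohort(spec, seed = 74)
    ft <- unlist(lapply(co$sessions, compute_flight_times))
    expect_lt(abs(mean(ft < 0) - p), 0.02 + 3 * sqrt(p * (1 - p) / length(ft)))
  }
})

test_that("plant_effect is the identity at (0, 1) and shifts the DT hold-time median", {
  spec <- test_cohort_spec(ht_median_dt = 100, pfr_dispersion_multiplier = 1)
  expect_identical(plant_effect(spec, 0, 1), spec)
  expect_error(plant_effect(spec, -5), ">= 0")
  shifted <- plant_effect(spec, 40, 1)
  expect_equal(shifted$ht_median_dt, 140)
  expect_equal(shifted$ht_median_hc, 100)
  # generation-then-measure: group HT medians differ by about the shift
  big <- cohort_spec(n_dt = 12, n_hc = 12, days = 2,
                     sessions_per_day_mean = c(dt = 8, hc = 8),
                     ht_median_dt = 100, pfr_dispersion_multiplier = 1,
                     subject_sdlog_ht = 0.02, p_longpress = 0)
  big <- plant_effect(big, 40, 1)
  co <- generate_cohort(big, seed = 75)
  f <- extract_features(co$sessions)
  lab <- cohort_labels(co$subjects)
  subj_med <- tapply(f$ht_median, f$subject_id, mean)
  grp <- as.character(lab$label[match(names(subj_med), lab$subject_id)])
  gap <- mean(subj_med[grp == "DT"]) - mean(subj_med[grp == "HC"])
  expect_lt(abs(gap - 40), 12)
})

test_that("the dispersion multiplier scales per-session PFR spread about linearly", {
  base <- cohort_spec(n_dt = 6, n_hc = 6, days = 2,
                      sessions_per_day_mean = c(dt = 10, hc = 10),
                      ht_median_dt = 100, pfr_dispersion_multiplier = 1,
                      subject_sdlog_ht = 0.02, subject_sdlog_ft = 0.02,
                      p_longpress = 0, p_pause = 0, p_overlap = 0)
  doubled <- plant_effect(base, 0, 2)
  expect_equal(doubled$pfr_dispersion_multiplier, 2)
  co <- generate_cohort(doubled, seed = 76)
  f <- extract_features(co$sessions)
  lab <- cohort_labels(co$subjects)
  grp <- as.character(lab$label[match(f$subject_id, lab$subject_id)])
  ratio <- mean(f$pfr_std[grp == "DT"]) / mean(f$pfr_std[grp == "HC"])
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})

test_that("zero-effect cohorts show no systematic group difference; default effects do", {
  null_sig <- 0L
  effect_ordered <- 0L
  n_seeds <- 50
  for (seed in seq_len(n_seeds)) {
    spec0 <- cohort_spec(n_dt = 6, n_hc = 6, days = 1,
                         sessions_per_day_mean = c(dt = 5, hc = 5),
                         ht_median_dt = 100, pfr_dispersion_multiplier = 1)
    co <- generate_cohort(spec0, seed = 700 + seed)
    f <- extract_features(co$sessions)
    lab <- cohort_labels(co$subjects)
    subj_med <- tapply(f$ht_median, f$subject_id, mean)
    grp <- as.character(lab$label[match(names(subj_med), lab$subject_id)])
    p <- suppressWarnings(
      wilcox.test(subj_med[grp == "DT"], subj_med[grp == "HC"])$p.value)
    if (p >= 0.05) null_sig <- null_sig + 1L
  }
  expect_gte(null_sig / n_seeds, 0.9) # non-significant in >= 90% of seeds
  for (seed in 1:20) {
    co <- generate_cohort(test_cohort_spec(days = 1,
                                           sessions_per_day_mean = c(dt = 4, hc = 4)),
                          seed = 800 + seed)
    f <- extract_features(co$sessions)
    lab <- cohort_labels(co$subjects)
    subj_med <- tapply(f$ht_median, f$subject_id, mean)
    grp <- as.character(lab$label[match(names(subj_med), lab$subject_id)])
    if (mean(subj_med[grp == "DT"]) > mean(subj_med[grp == "HC"])) {
      effect_ordered <- effect_ordered + 1L
    }
  }
  expect_gte(effect_ordered / 20, 0.95) # DT above HC in >= 95% of seeds
})
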