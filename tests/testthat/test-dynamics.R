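test_that("hold times are the press-to-release intervals", {
  s <- make_session(press = c(0, 500), release = c(120, 650))
  expect_equal(compute_hold_times(s), c(120, 150))
  z <- make_session(press = c(0, 300, 700), release = c(0, 300, 700))
  expect_equal(compute_hold_times(z), c(0, 0, 0))
  set.seed(21)
  for (i in 1:50) { # element-wise subtraction oracle on random sessions
    s <- random_session(sample(2:30, 1))
    expect_equal(compute_hold_times(s), s$events$release - s$events$press)
  }
})

test_that("flight times span release to next press; negatives legal; N<2 empty", {
  s <- make_session(press = c(0, 400), release = c(100, 500))
  expect_equal(compute_flight_times(s), 300)
  # overlapped typing: next key pressed before previous released
  ov <- make_session(press = c(0, 450), release = c(500, 600))
  expect_equal(compute_flight_times(ov), -50)
  single <- make_session(press = 0, release = 80)
  expect_identical(compute_flight_times(single), numeric(0))
})

test_that("distances convert pixel offsets through densities to millimetres", {
  s <- make_session(press = c(0, 500), release = c(100, 600),
                    x = c(0, 254), y = c(10, 10), ppi_x = 254, ppi_y = 254)
  expect_equal(compute_distances(s), 25.4) # 254 px at 254 ppi = 1 inch
  same <- make_session(press = c(0, 500), release = c(100, 600),
                       x = c(30, 30), y = c(40, 40))
  expect_equal(compute_distances(same), 0)
  set.seed(22)
  for (i in 1:100) { # independent Euclidean oracle
    n <- sample(2:10, 1)
    x <- sample(0:1080, n, replace = TRUE)
    y <- sample(0:1920, n, replace = TRUE)
    px <- runif(1, 200, 500); py <- runif(1, 200, 500)
    s <- make_session(press = seq(0, by = 300, length.out = n),
                      release = seq(100, by = 300, length.out = n),
                      x = x, y = y, ppi_x = px, ppi_y = py)
    oracle <- sqrt((diff(x) / px * 25.4)^2 + (diff(y) / py * 25.4)^2)
    expect_equal(compute_distances(s), oracle)
  }
})

test_that("distances are isotropic under axis swap at equal densities", {
  set.seed(23)
  n <- 9
  x <- sample(0:1000, n); y <- sample(0:1000, n)
  s1 <- make_session(seq(0, by = 300, length.out = n),
                     seq(100, by = 300, length.out = n), x = x, y = y)
  s2 <- make_session(seq(0, by = 300, length.out = n),
                     seq(100, by = 300, length.out = n), x = y, y = x)
  expect_equal(compute_distances(s1), compute_distances(s2))
})

test_that("speed and press-flight-rate are the element-wise ratios", {
  r <- compute_speed_and_pfr(ht = 150, ft = 300, dist = 10)
  expect_equal(r$pfr, 0.5)
  r <- compute_speed_and_pfr(ht = 100, ft = 100, dist = 10)
  expect_equal(r$sp, 0.1)
  expect_error(compute_speed_and_pfr(ht = 100, ft = -5, dist = 10),
               "contract violation")
  set.seed(24)
  for (i in 1:100) { # element-wise division oracle on filtered triples
    n <- sample(1:20, 1)
    ht <- runif(n, 30, 280); ft <- runif(n, 1, 2900); d <- runif(n, 0, 40)
    drop_ht <- runif(n) < 0.2
    ht_in <- replace(ht, drop_ht, NA)
    r <- compute_speed_and_pfr(ht_in, ft, d)
    expect_equal(r$sp, d / ft)
    expect_equal(r$pfr, (ht / ft)[!drop_ht])
  }
})

test_that("timing filters enforce the 3 s / non-positive FT and 300 ms long-press rules", {
  dyn <- structure(list(ht = c(100, 100, 100, 100, 100),
                        ft = c(100, 3500, -20, 2999),
                        dist = c(1, 2, 3, 4), sp = NULL, pfr = NULL,
                        n_raw = 5L, long_press_count = 0L, filtered = FALSE),
                   class = "dynamics_sequences")
  out <- apply_timing_filters(dyn)
  expect_equal(out$ft, c(100, 2999))
  expect_equal(out$dist, c(1, 4))
  dyn2 <- structure(list(ht = c(120, 310), ft = 200, dist = 5,
                         sp = NULL, pfr = NULL, n_raw = 2L,
                         long_press_count = 0L, filtered = FALSE),
                    class = "dynamics_sequences")
  out2 <- apply_timing_filters(dyn2)
  expect_equal(out2$ht, 120)
  expect_identical(out2$long_press_count, 1L)
  # all entries in bounds: no-op
  dyn3 <- structure(list(ht = c(100, 200, 90), ft = c(150, 250),
                         dist = c(5, 6), sp = NULL, pfr = NULL, n_raw = 3L,
                         long_press_count = 0L, filtered = FALSE),
                    class = "dynamics_sequences")
  out3 <- apply_timing_filters(dyn3)
  expect_equal(out3$ht, c(100, 200, 90))
  expect_equal(out3$ft, c(150, 250))
})

test_that("FT removal cascades to SP and PFR; long-press removal only to PFR", {
  # key 2 long-pressed (ht 400); flight 3 too slow (4000)
  s <- session_from_timing(ht = c(100, 400, 120, 150),
                           ft = c(200, 300, 250))
  d <- session_dynamics(s)
  expect_equal(d$ht, c(100, 120, 150))
  expect_equal(d$ft, c(200, 300, 250))
  # PFR loses flight 2 (its hold was a long press); SP keeps all three
  expect_length(d$sp, 3)
  expect_equal(d$pfr, c(100 / 200, 120 / 250))
})

test_that("filtering is idempotent and outputs order-preserving subsequences", {
  set.seed(25)
  for (i in 1:30) {
    n <- sample(8:25, 1)
    ht <- runif(n, 10, 500)          # some above the 300 ms threshold
    ft <- runif(n - 1, -200, 4000)   # some negative / above 3 s
    dyn <- structure(list(ht = ht, ft = ft, dist = runif(n - 1, 0, 40),
                          sp = NULL, pfr = NULL, n_raw = as.integer(n),
                          long_press_count = 0L, filtered = FALSE),
                     class = "dynamics_sequences")
    once <- apply_timing_filters(dyn)
    twice <- apply_timing_filters(once)
    expect_identical(once, twice)
    expect_true(all(once$ht %in% ht) && !is.unsorted(match(once$ht, ht)))
    expect_true(all(once$ft %in% ft) && !is.unsorted(match(once$ft, ft)))
    expect_true(all(once$ft > 0 & once$ft <= 3000))
    expect_true(all(once$ht <= 300))
  }
})

test_that("session validity needs at least eight keys", {
  expect_true(is_valid_session(random_session(8)))
  expect_false(is_valid_session(random_session(7)))
  expect_false(is_valid_session(make_session(0, 80), min_keys = 8))
})

test_that("the 3-sigma rule flags sessions by flight-time median, per user", {
  set.seed(26)
  mk_dyn <- function(med) {
    s <- session_from_timing(ht = rep(100, 10),
                             ft = pmax(round(rnorm(9, med, 5)), 10))
    session_dynamics(s)
  }
  normal <- lapply(rnorm(20, 200, 10), mk_dyn)
  outlier <- mk_dyn(2000)
  flags <- flag_outlier_sessions(c(normal, list(outlier)))
  expect_identical(which(flags), 21L)
  # direct |x - mu| > 3 sigma oracle
  meds <- vapply(c(normal, list(outlier)), function(d) median(d$ft), 0)
  mu <- mean(meds); s3 <- 3 * sqrt(mean((meds - mu)^2))
  expect_identical(flags, abs(meds - mu) > s3)
  # degenerate cases: identical medians, single session
  same <- lapply(lapply(1:5, function(i) mk_dyn(200)),
                 function(d) { d$ft <- rep(200, 9); d })
  expect_false(any(flag_outlier_sessions(same)))
  expect_false(any(flag_outlier_sessions(list(mk_dyn(200)))))
})
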