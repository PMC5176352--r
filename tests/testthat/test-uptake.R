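# Initial-rate extraction and per-plate normalization.

test_that("initial_rate recovers exact and degenerate slopes", {
  exact <- data.frame(time_s = c(0, 60, 120, 180, 240),
                      fluorescence_au = c(100, 160, 220, 280, 340))
  expect_equal(initial_rate(exact, 5L), 1.0, tolerance = 1e-12)
  flat <- data.frame(time_s = c(0, 60, 120, 180),
                     fluorescence_au = rep(42, 4))
  expect_equal(initial_rate(flat, 4L), 0.0, tolerance = 1e-12)
})

test_that("initial_rate equals the closed-form OLS oracle on noisy data", {
  t <- c(0, 60, 120, 180, 240)
  f <- c(101.3, 158.2, 221.9, 275.4, 344.8)
  # textbook sums-based least-squares slope on baseline-subtracted values
  y <- f - f[1]
  oracle <- (sum(t * y) - length(t) * mean(t) * mean(y)) /
    (sum(t^2) - length(t) * mean(t)^2)
  d <- data.frame(time_s = t, fluorescence_au = f)
  expect_equal(initial_rate(d, 5L), oracle, tolerance = 1e-10)
})

test_that("initial_rate is shift-invariant and gain-equivariant", {
  d <- simulate_uptake_timeseries(1.4, duration_s = 600,
                                  noise_sd_au = 3, seed = 11)
  r0 <- initial_rate(d)
  d2 <- d; d2$fluorescence_au <- d$fluorescence_au + 500
  expect_equal(initial_rate(d2), r0, tolerance = 1e-12)
  d3 <- d; d3$fluorescence_au <- d$fluorescence_au * 2.5
  expect_equal(initial_rate(d3), 2.5 * r0, tolerance = 1e-12)
})

test_that("initial_rate input validation", {
  d <- data.frame(time_s = c(0, 60, 120, 180, 240),
                  fluorescence_au = 1:5)
  expect_error(initial_rate(d, 1L), "window_points")
  expect_error(initial_rate(d, 6L), "window_points")
  expect_error(initial_rate(d[1:2, ], 2L), "at least 3")
  bad <- d; bad$time_s[3] <- 60
  expect_error(initial_rate(bad), "strictly increasing")
})

test_that("truncate_decline drops late samples only", {
  d <- simulate_uptake_timeseries(1, duration_s = 15 * 60)
  expect_equal(nrow(truncate_decline(d)), 11L)  # t = 0..600 s at 60 s
  short <- simulate_uptake_timeseries(1, duration_s = 300)
  expect_identical(truncate_decline(short), short)
  five <- data.frame(time_s = c(0, 60, 120, 180, 240),
                     fluorescence_au = 1:5)
  expect_equal(nrow(truncate_decline(five, 240)), 5L)
})

test_that("normalize_rates maps the control mean to 1 per plate", {
  tab <- data.frame(
    agonist_conc_M = rep(c(1e-3, 1e-3, 1e-5), 2),
    antagonist_conc_M = rep(c(0, 0, 0), 2),
    rate_au_per_s = c(2, 2, 1, 4, 4, 1),
    replicate = rep(1:3, 2),
    plate_id = rep(c("p1", "p2"), each = 3))
  out <- normalize_rates(tab)
  expect_equal(out$response[1:2], c(1, 1))
  expect_equal(out$response[3], 0.5)
  expect_equal(out$response[4:5], c(1, 1))   # per-plate control
  expect_equal(out$response[6], 0.25)
  # brute-force group-by oracle over a larger mixed-plate table
  withr::with_seed(3, {
    big <- expand.grid(agonist_conc_M = c(1e-6, 1e-4, 1e-3),
                       antagonist_conc_M = c(0, 1e-8),
                       replicate = 1:4,
                       plate_id = c("p1", "p2", "p3"))
    big$rate_au_per_s <- stats::runif(nrow(big), 0.1, 3)
  })
  got <- normalize_rates(big)
  for (i in seq_len(nrow(big))) {
    sel <- big$plate_id == big$plate_id[i]
    ctrl <- sel & big$agonist_conc_M == 1e-3 & big$antagonist_conc_M == 0
    expect_equal(got$response[i],
                 big$rate_au_per_s[i] / mean(big$rate_au_per_s[ctrl]),
                 tolerance = 1e-12)
  }
  # a plate with antagonist everywhere has no control condition
  noctrl <- tab
  noctrl$antagonist_conc_M <- 1e-8
  expect_error(normalize_rates(noctrl), "control")
})

test_that("timeseries reduction round-trips the generating rate", {
  # noiseless series: rate recovered essentially exactly
  d <- simulate_uptake_timeseries(0.8, duration_s = 900, noise_sd_au = 0)
  expect_equal(initial_rate(truncate_decline(d)), 0.8, tolerance = 1e-9)
  # untruncated series including the decline underestimates the true rate
  expect_lt(initial_rate(d, window_points = nrow(d)), 0.8)
  # linear-then-plateau with decline after the window: within 5%
  noisy <- simulate_uptake_timeseries(0.8, duration_s = 900,
                                      noise_sd_au = 0.5, seed = 5)
  expect_rel(initial_rate(truncate_decline(noisy)), 0.8, 0.05)
})

test_that("rates_from_timeseries assembles a normalized table", {
  mk <- function(rate, A, B, rep)
    simulate_uptake_timeseries(rate, duration_s = 900, noise_sd_au = 0,
                               agonist_conc_M = A, antagonist_id = "JNJ",
                               antagonist_conc_M = B, replicate = rep)
  ts <- rbind(mk(2, 1e-3, 0, 1), mk(2, 1e-3, 0, 2),
              mk(1, 1e-3, 1e-7, 1), mk(0.5, 1e-4, 0, 1))
  out <- rates_from_timeseries(ts)
  expect_equal(nrow(out), 4L)
  ctrl <- out$agonist_conc_M == 1e-3 & out$antagonist_conc_M == 0
  expect_equal(out$response[ctrl], c(1, 1), tolerance = 1e-9)
  expect_equal(out$response[out$antagonist_conc_M > 0], 0.5,
               tolerance = 1e-9)
  expect_equal(attr(out, "window_points"), 5L)
})
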