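make_trace <- function(n = 5000, dt = 0.05, noise = 1, seed = 71) {
  set.seed(seed)
  flow_trace(seq(0, by = dt, length.out = n),
             rnorm(n, 0, noise), rnorm(n, 0, noise), rnorm(n, 0, noise))
}

inject_pulse <- function(trace, t0, amp, sigma = 0.15,
                         channels = "ssc") {
  shape <- amp * exp(-(trace$time_ms - t0)^2 / (2 * sigma^2))
  for (ch in channels) trace[[ch]] <- trace[[ch]] + shape
  trace
}

test_that("event detection finds injected pulses and respects excursions", {
  tr <- make_trace()
  t0s <- seq(20, 200, by = 20)
  for (t0 in t0s) tr <- inject_pulse(tr, t0, amp = 10)
  ev <- detect_events(tr, k_sigma = 5)
  expect_identical(nrow(ev), length(t0s))
  expect_equal(ev$time_ms, t0s, tolerance = 0.01)
  expect_true(all(ev$ssc_height > 5))

  # all-zero / flat trace: warning, no events
  flat <- flow_trace(1:200, rep(0, 200), rep(0, 200), rep(0, 200))
  expect_warning(ev0 <- detect_events(flat), "flat")
  expect_identical(nrow(ev0), 0L)

  expect_error(detect_events(make_trace(n = 50)), "100 samples")

  # two pulses with a sub-threshold gap are two events; without a gap, one
  # (low noise so the excursion boundaries are unambiguous)
  quiet <- make_trace(seed = 72, noise = 0.05)
  tr2 <- inject_pulse(inject_pulse(quiet, 50, 10), 51, 10)
  expect_identical(nrow(detect_events(tr2)), 2L)
  tr1 <- inject_pulse(inject_pulse(quiet, 50, 10), 50.2, 10)
  expect_identical(nrow(detect_events(tr1)), 1L)
})

test_that("event count is non-increasing in k_sigma", {
  set.seed(73)
  sim <- simulate_flow(flow_sim_config(seed = 8, duration_ms = 2000))
  counts <- vapply(c(3, 5, 8, 12), function(k)
    nrow(detect_events(sim$trace, k_sigma = k)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("flow phenotype percentages cover all events and sum to 100", {
  ev <- data.frame(time_ms = 1:2000, ssc_height = 10,
                   fl1_height = 0, fl2_height = 0)
  pct <- call_flow_phenotypes(ev, 5, 5)
  expect_equal(as.numeric(pct), c(100, 0, 0, 0))

  # thresholds at 0 with strictly positive fluorescence: all double positive
  ev2 <- transform(ev, fl1_height = 1, fl2_height = 1)
  pct2 <- call_flow_phenotypes(ev2, 0, 0)
  expect_equal(as.numeric(pct2[["double_positive"]]), 100)
  expect_equal(sum(pct2), 100, tolerance = 1e-9)

  expect_warning(call_flow_phenotypes(ev[1:10, ], 5, 5), "unreliable")
})

test_that("double-negative removal is exact, scale-invariant, idempotent", {
  expect_equal(unname(recalc_without_double_negatives(c(80, 10, 5, 5))),
               c(50, 25, 25))
  p0 <- c(double_negative = 0, CD9_only = 20, CD81_only = 30,
          double_positive = 50)
  expect_equal(unname(recalc_without_double_negatives(p0)), c(20, 30, 50))
  expect_error(recalc_without_double_negatives(c(100, 0, 0, 0)),
               "undefined")

  set.seed(74)
  for (rep in 1:10) {
    p <- runif(4); p <- 100 * p / sum(p)
    r1 <- recalc_without_double_negatives(p)
    expect_equal(sum(r1), 100, tolerance = 1e-9)
    # scale invariance
    r2 <- recalc_without_double_negatives(p / 5)
    expect_equal(r1, r2, tolerance = 1e-9)
    # idempotence: recalculating with a zero DN share changes nothing
    r3 <- recalc_without_double_negatives(c(0, r1))
    expect_equal(unname(r3), unname(r1), tolerance = 1e-9)
  }
})

test_that("SSC size calibration interpolates log-log and flags extrapolation", {
  beads <- data.frame(diameter_nm = c(68, 91, 113, 155),
                      ssc = c(200, 800, 2400, 9000))
  cal <- fit_ssc_calibration(beads)
  ev <- data.frame(time_ms = 1:4,
                   ssc_height = c(800, sqrt(800 * 2400), 100, 20000),
                   fl1_height = 0, fl2_height = 0)
  out <- calibrate_size(cal, ev)
  expect_equal(out$est_diameter[1], 91)                    # at a node
  expect_equal(out$est_diameter[2], sqrt(91 * 113))        # geometric mean
  expect_identical(out$extrapolated, c(FALSE, FALSE, TRUE, TRUE))
  expect_lt(out$est_diameter[3], 68)
  expect_gt(out$est_diameter[4], 155)

  bad <- beads; bad$ssc[2] <- 5
  expect_error(fit_ssc_calibration(bad), "increasing")
  expect_error(fit_ssc_calibration(beads[1, , drop = FALSE]))
})

test_that("recovery-rate arithmetic", {
  expect_equal(recovery_rate(2e10, 1.9e10), 95)
  expect_equal(recovery_rate(1e10, 1e10), 100)
  expect_equal(recovery_rate(1e10, 1e8), 1)     # ~100-fold column loss
  expect_equal(recovery_rate(1e10, 5e9, dilution_factor = 2), 100)
  expect_error(recovery_rate(0, 1), "> 0")
})
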