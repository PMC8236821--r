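flat_trace_with_epsp <- function(amp = 8, latency_ms = 11, ttp_ms = 10,
                                 fs = 1e5, noise = 0) {
  vm <- rep(-70, fs %/% 2)
  if (noise > 0) {
    set.seed(2)
    vm <- vm + rnorm(length(vm), 0, noise)
  }
  kern <- amp * vmtypes:::epsp_kernel(ttp_ms, 15, fs, 60)
  i0 <- floor((0.2 + latency_ms / 1000) * fs) + 1L
  vm[i0:(i0 + length(kern) - 1L)] <- vm[i0:(i0 + length(kern) - 1L)] + kern
  vm
}

test_that("a planted EPSP is measured to specification", {
  vm <- flat_trace_with_epsp(amp = 8, latency_ms = 11, noise = 0.02)
  m <- measure_pulse_response(vm, 0.2, 1e5)
  expect_false(is.null(m))
  expect_lt(abs(m$amplitude_mv - 8) / 8, 0.10)
  expect_lt(abs(m$latency_ms - 11), 1)
  expect_lt(abs(m$ttp_ms - 10), 2)
})

test_that("flat or truncated traces yield no measurement", {
  expect_null(measure_pulse_response(rep(-70, 5e4), 0.2, 1e5))
  vm <- flat_trace_with_epsp()
  expect_null(measure_pulse_response(vm, 0.499, 1e5))  # < 40 ms left
})

test_that("measured amplitudes reproduce the single-pulse variability", {
  sp <- cached("sp400", simulate_single_pulse_trials(400, seed = 7))
  vm <- smooth_trace(blank_artifacts(sp$vm, sp$pulse_times, sp$fs), sp$fs)
  meas <- lapply(sp$pulse_times, function(t_)
    measure_pulse_response(vm, t_, sp$fs))
  ok <- !vapply(meas, is.null, logical(1))
  expect_gt(mean(ok), 0.9)
  amp <- vapply(meas[ok], `[[`, numeric(1), "amplitude_mv")
  cv <- sd(amp) / mean(amp)
  expect_lt(abs(cv - 0.43), 0.08)
  # planted parameters recovered within 3 standard errors
  expect_lt(abs(mean(amp) - mean(sp$truth$amplitude_mv)),
            3 * sd(amp) / sqrt(sum(ok)) + 0.2)
})

test_that("template building clamps checkpoints and reflects event spread", {
  fs <- 1e5
  vm <- rep(-70, fs * 20)
  kern <- 8 * vmtypes:::epsp_kernel(10, 15, fs, 60)
  onsets <- seq(0.1, by = 0.15, length.out = 120)  # non-overlapping
  for (t_ in onsets) {
    i0 <- floor(t_ * fs) + 1L
    vm[i0:(i0 + length(kern) - 1L)] <- vm[i0:(i0 + length(kern) - 1L)] + kern
  }
  expect_error(build_epsp_template(vm, onsets[1:50], fs), "100")
  tm <- build_epsp_template(vm, onsets, fs, n_checkpoints = 50)
  expect_lte(nrow(tm$checkpoints), 20)
  tm2 <- build_epsp_template(vm, onsets, fs, n_checkpoints = 2)
  expect_gte(nrow(tm2$checkpoints), 5)
  # identical events: tolerance collapses to the floor
  expect_true(all(tm$checkpoints$tol_mv <= 0.2 + 1e-9))
  expect_equal(max(tm$checkpoints$value_mv), 8, tolerance = 0.2)
})

test_that("template matching finds planted events and rejects noise", {
  fs <- 1e5
  set.seed(11)
  vm <- rep(-70, fs * 40) + rnorm(fs * 40, 0, 0.15)
  kern <- 8 * vmtypes:::epsp_kernel(10, 15, fs, 60)
  train <- seq(0.1, by = 0.15, length.out = 120)
  test_ev <- seq(20, 38, by = 0.15)
  for (t_ in c(train, test_ev)) {
    i0 <- floor(t_ * fs) + 1L
    vm[i0:(i0 + length(kern) - 1L)] <- vm[i0:(i0 + length(kern) - 1L)] + kern
  }
  # align on detected onsets, exactly as the pipeline does
  det <- (vmtypes:::candidate_onsets(vm, fs) - 1) / fs
  det_train <- det[det < 19]
  tm <- build_epsp_template(vm, det_train, fs)
  hits <- match_template(vm, tm, fs)
  # held-out events recovered
  rec <- vapply(test_ev, function(t_) any(abs(hits - t_) < 0.005), logical(1))
  expect_gte(mean(rec), 0.95)
  # event-free background: less than 1 false positive per 10 s
  set.seed(12)
  quiet <- rep(-70, fs * 10) + rnorm(fs * 10, 0, 0.15)
  expect_lte(length(match_template(quiet, tm, fs)), 1)
})

test_that("the response-fraction gate passes real responses only", {
  pulses <- seq(1, 20, by = 2)
  onsets <- seq(0.5, 19.5, by = 2)
  # a matched event after every pulse, silent baseline
  g <- response_fraction_and_gate(pulses + 0.010, pulses, onsets)
  expect_equal(g$fraction, 1)
  expect_true(g$significant)
  # four events cannot pass the minimum-count rule
  g4 <- response_fraction_and_gate(pulses[1:4] + 0.010, pulses, onsets)
  expect_identical(g4$n_events, 4L)
  expect_false(g4$significant)
  # no pattern onsets: the gate fails closed
  g0 <- response_fraction_and_gate(pulses + 0.010, pulses, numeric(0))
  expect_false(g0$significant)
})

test_that("baseline-only activity rarely passes the gate", {
  set.seed(13)
  fails <- 0L
  for (run in 1:40) {
    onsets <- seq(2, 120, by = 2)
    matches <- sort(runif(150, 0, 122))   # spontaneous events only
    pulses <- onsets + runif(length(onsets), 0.3, 0.5)
    g <- response_fraction_and_gate(matches, pulses, onsets)
    if (!g$significant) fails <- fails + 1L
  }
  expect_gte(fails, 38L)   # >= 95%
})

test_that("chunk-order tests calibrate and detect depression", {
  # identical amplitude lists for the two ranks: no order effect, p = 1
  expect_equal(order_effect_test(rep(1:5, 2), rep(1:2, each = 5))[1, 2], 1)
  set.seed(15)
  amps <- rnorm(100, 8, 2)
  ranks <- rep(1:5, 20)
  p <- order_effect_test(amps, ranks)
  expect_true(all(is.na(diag(p))))
  expect_gt(min(p, na.rm = TRUE), 0.001)  # no spurious strong effect
  # 50% depression on ranks 2-5
  amps2 <- ifelse(ranks == 1, rnorm(100, 8, 1), rnorm(100, 4, 1))
  p2 <- order_effect_test(amps2, ranks)
  expect_true(all(p2[1, 2:5] < 0.01))
  skip <- order_effect_test(c(1, 2, 1, 2), c(1, 1, 2, 2))
  expect_true(all(is.na(skip)))           # groups below the minimum size
})

test_that("between-neuron comparisons detect planted differences", {
  set.seed(16)
  same <- replicate(6, rnorm(40, 6, 2), simplify = FALSE)
  r <- pairwise_neuron_tests(same)
  expect_lt(r$frac_significant, 0.3)
  diffd <- list(a = rnorm(40, 4, 1), b = rnorm(40, 8, 1))
  r2 <- pairwise_neuron_tests(diffd)
  expect_lt(r2$p["a", "b"], 0.01)
  r1 <- pairwise_neuron_tests(list(a = rnorm(10)))
  expect_identical(r1$n_comparisons, 0L)
})
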