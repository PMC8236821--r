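test_that("the 50-us moving average behaves like a 5-sample boxcar", {
  x <- numeric(101); x[51] <- 1
  sm <- smooth_trace(x, fs = 1e5)
  expect_equal(sm[49:53], rep(0.2, 5))
  expect_equal(smooth_trace(rep(-70, 50), 1e5), rep(-70, 50))
  set.seed(1)
  z <- rnorm(2e5)
  expect_equal(var(smooth_trace(z, 1e5)[100:(2e5 - 100)]), 1 / 5,
               tolerance = 0.05)
})

test_that("artifact blanking removes planted transients and merges spans", {
  fs <- 1e5
  vm <- rep(-70, 5e4)
  art <- vmtypes:::artifact_kernel(30, 1, fs)
  i0 <- 2e4
  vm[i0:(i0 + length(art) - 1L)] <- vm[i0:(i0 + length(art) - 1L)] + art
  out <- blank_artifacts(vm, (i0 - 1) / fs, fs, blank_ms = 1)
  expect_lt(max(abs(out + 70)), 1)
  expect_identical(blank_artifacts(vm, numeric(0), fs), vm)
  # two pulses 0.5 ms apart: one merged span, interior fully replaced
  vm2 <- rep(0, 1e4); vm2[3001:3150] <- 25
  out2 <- blank_artifacts(vm2, c(0.03, 0.0305), fs, blank_ms = 1)
  expect_lt(max(abs(out2)), 1e-9)
})

test_that("recursive spike fitting subtracts stereotyped spikes", {
  fs <- 1e5
  vm <- rep(-70, 6e5)
  spk <- vmtypes:::spike_kernel(40, fs)
  at <- seq(3e4, 5.5e5, length.out = 10)
  for (i in at) vm[i:(i + length(spk) - 1L)] <- vm[i:(i + length(spk) - 1L)] + spk
  res <- remove_spikes(vm, fs)
  expect_length(res$spike_times, 10)
  expect_lt(max(abs(res$vm + 70)), 0.05 * 40)

  clean <- rep(-70, 1e5)
  res0 <- remove_spikes(clean, fs)
  expect_identical(res0$vm, clean)
  expect_length(res0$spike_times, 0)

  vm2 <- rep(-70, 2e5)
  for (i in c(3e4, 1.2e5)) {
    vm2[i:(i + length(spk) - 1L)] <- vm2[i:(i + length(spk) - 1L)] + spk
  }
  res2 <- remove_spikes(vm2, fs)
  expect_length(res2$spike_times, 2)
  expect_identical(res2$vm, vm2)   # below the minimum count: not subtracted
})

test_that("window extraction aligns to onsets and drops truncated windows", {
  fs <- 1e5
  vm <- seq_len(fs * 3)  # 3 s ramp, value = sample index
  ev <- data.frame(onset_s = c(0.5, 1.5, 2.9), label = "X",
                   repetition = 1:3)
  expect_message(w <- extract_windows(vm, ev, duration_ms = 350, fs = fs),
                 "dropping 1")
  expect_identical(nrow(w$windows), 2L)
  expect_equal(w$windows[1, 1], floor(0.5 * fs) + 1)
  expect_identical(w$n_dropped, 1L)
})

test_that("long statistics windows never overlap the next presentation", {
  s <- tiny_session()
  ev <- s$recording$events
  pev <- ev[ev$kind == "pattern", ]
  gaps <- diff(sort(ev$onset_s))
  expect_true(all(gaps > 1.2))   # 1200 ms windows fit in the 1.8-s spacing
})

test_that("window normalisation scales shape to [0,1] and flags flat input", {
  set.seed(2)
  x <- rnorm(35000) + 5 * sin(seq_len(35000) / 2000)
  nx <- normalize_window(x, fs = 1e5)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), 1)
  expect_false(attr(nx, "degenerate"))

  flat <- normalize_window(rep(-70, 35000), fs = 1e5)
  expect_true(attr(flat, "degenerate"))
  expect_true(all(flat == 0.5))
})

test_that("normalisation removes offsets and preserves sinusoid phase", {
  fs <- 1000
  t <- seq_len(400)
  x <- 2 * sin(2 * pi * 5 * t / 1000)       # 200-ms period
  n1 <- as.numeric(normalize_window(x, fs = fs))
  n2 <- as.numeric(normalize_window(x + 33.3, fs = fs))
  expect_equal(n1, n2, tolerance = 1e-9)    # constant offset is irrelevant
  expect_equal(min(n1), 0)
  expect_equal(max(n1), 1)
  mid <- 100:300
  expect_gt(cor(n1[mid], x[mid]), 0.99)     # phase preserved
  # re-application is stable away from the shrinking-window edges
  n3 <- as.numeric(normalize_window(n1, fs = fs))
  expect_gt(cor(n3[mid], n1[mid]), 0.999)
})

test_that("quality control applies the inclusion criteria", {
  qc_flat <- qc_check(rep(-70, 2e5), fs = 1e5)
  expect_equal(qc_flat$down_state_mode, -70, tolerance = 0.5)
  expect_false(qc_flat$passes$peak_to_peak)
  expect_false(qc_flat$passes$overall)

  s <- tiny_session()
  vm <- blank_artifacts(s$recording$vm,
                        stimulus_pulse_times(s$recording)$time_s,
                        s$recording$fs_vm)
  qc <- qc_check(vm, fs = s$recording$fs_vm)
  expect_true(qc$passes$overall)
  # shifting the whole trace up by 20 mV breaks the Down-state criterion
  qc_up <- qc_check(vm + 20, fs = s$recording$fs_vm)
  expect_false(qc_up$passes$down_state)
  expect_false(qc_up$passes$overall)
})
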