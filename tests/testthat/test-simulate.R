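test_that("session simulation is bit-identical under a fixed seed", {
  cfg <- session_config(n_patterns = 1, reps_per_pattern = 8,
                        single_pulse_chunks = 1, seed = 9)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$recording$vm, b$recording$vm)
  expect_identical(a$recording$ecog, b$recording$ecog)
  expect_identical(a$truth$types, b$truth$types)
  expect_identical(a$truth$epsp, b$truth$epsp)
})

test_that("the event table is consistent with the configuration", {
  s <- tiny_session()
  ev <- s$recording$events
  expect_true(all(diff(ev$onset_s) > 0))
  pat <- ev[ev$kind == "pattern", ]
  expect_true(all(table(pat$label) == 20))
  # repetition index counts presentations chronologically
  for (lb in unique(pat$label)) {
    expect_identical(pat$repetition[pat$label == lb],
                     seq_len(sum(pat$label == lb)))
  }
  # every repetition has exactly one planted label
  tt <- s$truth$types
  expect_identical(nrow(tt), nrow(pat))
  expect_false(any(is.na(tt$type_id)))
})

test_that("config validation rejects out-of-range settings", {
  expect_error(session_config(down_mv = -50), "-55")
  expect_error(session_config(down_mv = -64, up_mv = -56), "separation")
  expect_error(session_config(reps_per_pattern = 0), "reps")
  expect_error(session_config(ungrouped_fraction = 1.2), "ungrouped")
})

test_that("ECoG ground-truth states tile the session and hit the target", {
  cfg <- session_config(n_patterns = 2, reps_per_pattern = 40,
                        single_pulse_chunks = 0, seed = 31)
  s <- simulate_session(cfg)
  st <- s$truth$states
  expect_true(all(abs(utils::head(st$end_s, -1) -
                        utils::tail(st$start_s, -1)) < 1e-9))
  de <- st$state == "desynchronized"
  frac <- sum(st$end_s[de] - st$start_s[de]) / max(st$end_s)
  expect_lt(abs(frac - 0.2), 0.05)
})

test_that("planted single-pulse statistics follow the population values", {
  # pooled across neurons: mean 7.7 mV, SD 4.8 mV (within 3 SE at n >= 400)
  cfg <- session_config()
  set.seed(40)
  draws <- do.call(rbind, lapply(1:13, function(i) {
    nr <- vmtypes:::draw_neuron_params(cfg, 1)
    vmtypes:::draw_epsp_events(40, nr, cfg)
  }))
  n <- nrow(draws)
  se_mean <- sd(draws$amplitude_mv) / sqrt(n)
  expect_lt(abs(mean(draws$amplitude_mv) - 7.7), 3 * se_mean + 0.3)
  expect_lt(abs(sd(draws$amplitude_mv) - 4.8), 1.2)
  expect_lt(abs(mean(draws$latency_ms) - 11.1), 0.6)
  expect_lt(abs(mean(draws$ttp_ms) - 9.8), 1.6)
})

test_that("isolated single-pulse trials plant the configured amplitudes", {
  sp <- cached("sp400", simulate_single_pulse_trials(400, seed = 7))
  expect_lt(abs(mean(sp$truth$amplitude_mv) - 7.7), 0.5)
  cv <- sd(sp$truth$amplitude_mv) / mean(sp$truth$amplitude_mv)
  expect_lt(abs(cv - 0.43), 0.06)
})

test_that("window sets carry coherent ground truth", {
  ws <- simulate_window_set(2, 3, reps = 30, duration_ms = 500, seed = 4)
  for (cl in ws$cells) {
    expect_identical(length(cl$truth), 30L)
    expect_true(all(cl$truth %in% 0:3))
    expect_identical(dim(cl$windows), c(30L, 500L))
  }
  ws2 <- simulate_window_set(2, 3, reps = 30, duration_ms = 500, seed = 4)
  expect_identical(ws$cells[[1]]$windows, ws2$cells[[1]]$windows)
  # ungrouped_fraction = 0 plants a type for every repetition
  cfg0 <- session_config(ungrouped_fraction = 0)
  ws0 <- simulate_window_set(1, 3, reps = 25, config = cfg0,
                             duration_ms = 400, seed = 4)
  expect_true(all(ws0$cells[[1]]$truth > 0))
})

test_that("generated sessions pass quality control after blanking", {
  for (seed in c(6, 23, 57)) {
    cfg <- session_config(n_patterns = 1, reps_per_pattern = 10,
                          single_pulse_chunks = 1, seed = seed)
    s <- simulate_session(cfg)
    vm <- blank_artifacts(s$recording$vm,
                          stimulus_pulse_times(s$recording)$time_s,
                          s$recording$fs_vm)
    expect_true(qc_check(vm, fs = s$recording$fs_vm)$passes$overall)
  }
})

test_that("mean normalized window of a planted type matches its template", {
  cells <- clustered_cells()
  ws <- simulate_window_set(4, 4, reps = 80, duration_ms = 1200, seed = 11)
  for (ci in 1:2) {
    cl <- ws$cells[[ci]]
    tpl <- cl$templates$templates
    n350 <- normalize_windows(cl$windows[, 1:350], fs = 1000)$normalized
    for (t_ in 1:2) {
      m <- colMeans(n350[cl$truth == t_, , drop = FALSE])
      expect_gt(cor(m, tpl[t_, ]), 0.9)
    }
  }
})
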