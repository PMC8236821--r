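# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but complete session (two patterns, quick to simulate).
tiny_session <- function(seed = 6) {
  cached(paste0("session", seed), {
    cfg <- session_config(n_patterns = 2, reps_per_pattern = 20,
                          single_pulse_chunks = 3, seed = seed)
    simulate_session(cfg)
  })
}

# Window-level set with clustering applied; used by the statistics tests.
clustered_cells <- function(n_cells = 4, k = 4, reps = 80, seed = 11,
                            duration_ms = 1200) {
  cached(sprintf("cells.%d.%d.%d.%d.%d", n_cells, k, reps, seed, duration_ms), {
    ws <- simulate_window_set(n_cells, k, reps = reps,
                              duration_ms = duration_ms, seed = seed)
    lapply(ws$cells, function(cl) {
      ts <- response_types(normalize_windows(cl$windows[, 1:350, drop = FALSE],
                                             fs = 1000))
      nl <- normalize_windows(cl$windows, fs = 1000)
      list(windows = nl$normalized, assignment = ts$assignment,
           typeset = ts, truth = cl$truth, windows350 =
             normalize_windows(cl$windows[, 1:350, drop = FALSE],
                               fs = 1000)$normalized,
           neuron = cl$neuron, label = cl$label)
    })
  })
}

# Normalised windows with three well-separated planted blocks, built by
# hand; used by the clustering unit tests.
block_windows <- function(n_per = 30, len = 350) {
  base <- rep(0.2, len)
  curves <- rbind(base, base + 0.3, base + 0.6)
  w <- curves[rep(1:3, each = n_per), ]
  list(windows = w, truth = rep(1:3, each = n_per))
}
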