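test_that("median ties and single-segment dips are synchronized", {
  # constant-power signal: repeating one 125-sample block (125 divides both
  # the segment length and the hop) makes every segment bitwise identical,
  # so all powers tie exactly at the median
  x <- rep(sin(2 * pi * 8 * (0:124) / 1000), 240)
  tr <- segment_ecog(x)
  expect_true(all(tr$segments$state == "synchronized"))

  # power alternating every segment: below-median runs have length 1
  t <- seq_len(40000) / 1000
  am <- ifelse(floor(t / 0.875) %% 2 == 0, 2, 0.5)
  y <- am * sin(2 * pi * 6 * t)
  tr2 <- segment_ecog(y)
  r <- rle(tr2$segments$below)
  expect_true(all(r$lengths[r$values] <= 1))
  expect_true(all(tr2$segments$state == "synchronized"))
})

test_that("segmentation recovers planted state intervals", {
  s <- cached("ecog_session", {
    cfg <- session_config(n_patterns = 2, reps_per_pattern = 40,
                          single_pulse_chunks = 2, seed = 9)
    simulate_session(cfg)
  })
  tr <- segment_ecog(s$recording$ecog)
  st <- s$truth$states
  truth_state <- vapply(tr$segments$start_s + 0.5, function(t_) {
    st$state[findInterval(t_, st$start_s)]
  }, "")
  expect_gt(mean(tr$segments$state == truth_state), 0.8)
})

test_that("state lookup uses the latest containing segment", {
  x <- rnorm(5000)
  tr <- segment_ecog(x)
  tr$segments$state <- c("synchronized", "desynchronized",
                         "desynchronized", "synchronized",
                         "synchronized")[seq_len(nrow(tr$segments))]
  # time in the overlap of segments 1 and 2 belongs to segment 2
  t_overlap <- tr$segments$start_s[2] + 0.05
  expect_identical(state_at_times(tr, t_overlap), tr$segments$state[2])
  expect_error(state_at_times(tr, -1), "before")
  s <- tiny_session()
  tr2 <- segment_ecog(s$recording$ecog)
  onsets <- s$recording$events$onset_s
  expect_length(state_at_times(tr2, onsets), length(onsets))
})

test_that("random type-state assignment is not declared significant", {
  set.seed(44)
  hits <- 0L
  for (run in 1:50) {
    cells <- lapply(1:4, function(i) {
      n <- 80
      list(assignment = sample(c(0:3), n, replace = TRUE),
           onset_states = sample(c("synchronized", "desynchronized"), n,
                                 replace = TRUE, prob = c(0.8, 0.2)))
    })
    a <- type_state_association(cells)
    if (a$p_all > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 45L)   # >= 90% of runs
})

test_that("a genuine state preference is detected", {
  set.seed(45)
  cells <- lapply(1:6, function(i) {
    # three small types occurring only in the desynchronized state, while
    # the cell's overall desynchronized fraction stays near 0.2
    n <- 90
    assignment <- c(rep(1:3, each = 6), rep(0L, n - 18))
    st <- ifelse(assignment > 0, "desynchronized",
                 sample(c("synchronized", "desynchronized"), n,
                        replace = TRUE, prob = c(0.95, 0.05)))
    list(assignment = assignment, onset_states = st)
  })
  a <- type_state_association(cells)
  expect_lt(a$p_all, 0.01)
})

test_that("member-weighted type fractions conserve the cell fraction", {
  set.seed(46)
  n <- 60
  assignment <- sample(0:2, n, replace = TRUE)
  st <- sample(c("synchronized", "desynchronized"), n, replace = TRUE)
  de <- st == "desynchronized"
  cell_frac <- mean(de)
  groups <- split(seq_len(n), assignment)
  weighted <- sum(vapply(groups, function(ix) {
    length(ix) * mean(de[ix])
  }, numeric(1))) / n
  expect_equal(weighted, cell_frac)
})
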