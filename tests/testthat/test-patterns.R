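test_that("generated patterns satisfy the protocol constraints", {
  pats <- generate_patterns(8, 4, seed = 1)
  expect_length(pats, 8)
  for (p in pats) {
    k <- nrow(p$pulses)
    expect_gte(k, 5)
    expect_lte(k, 33)
    expect_lt(max(p$pulses$offset_ms), 340)
    ipi <- diff(p$pulses$offset_ms)
    expect_true(all(ipi >= 1 - 1e-9 & ipi <= 123 + 1e-9))
    expect_true(all(p$pulses$channel %in% 1:4))
    expect_true(all(diff(p$pulses$offset_ms) >= 0))
  }
  total <- sum(vapply(pats, function(p) nrow(p$pulses), integer(1)))
  expect_gt(total, 120)
  expect_lt(total, 190)
  # some pulses must be >= 10 ms from both neighbours
  el <- select_in_pattern_pulses(pats)
  expect_gt(sum(el$eligible), 0)
})

test_that("pattern generation is seeded and handles degenerate inputs", {
  a <- generate_patterns(8, 4, seed = 1)
  b <- generate_patterns(8, 4, seed = 1)
  expect_identical(a, b)
  one <- generate_patterns(1, 1, seed = 0)
  expect_length(one, 1)
  expect_true(all(one[[1]]$pulses$channel == 1))
  expect_error(generate_patterns(8, 0), "n_channels")
})

test_that("in-pattern pulse eligibility follows the 10-ms separation rule", {
  p <- structure(list(label = "X", pulses = data.frame(
    offset_ms = c(0, 5, 30, 45), channel = 1L)), class = "stim_pattern")
  el <- select_in_pattern_pulses(p)
  expect_identical(which(el$eligible), c(3L, 4L))

  p$pulses <- data.frame(offset_ms = seq(0, 100, by = 20), channel = 1L)
  expect_true(all(select_in_pattern_pulses(p)$eligible))

  p$pulses <- data.frame(offset_ms = seq(0, 100, by = 5), channel = 1L)
  expect_false(any(select_in_pattern_pulses(p)$eligible))
})

test_that("raising the separation requirement never adds eligible pulses", {
  pats <- generate_patterns(4, 4, seed = 3)
  for (sep in list(c(5, 10), c(10, 20), c(20, 40))) {
    lo <- select_in_pattern_pulses(pats, min_sep_ms = sep[1])$eligible
    hi <- select_in_pattern_pulses(pats, min_sep_ms = sep[2])$eligible
    expect_true(all(lo | !hi))  # eligible at hi => eligible at lo
  }
})
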