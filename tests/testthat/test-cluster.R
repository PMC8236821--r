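test_that("the pairwise same-type rule matches the worked thresholds", {
  a <- rep(0.5, 350)
  expect_true(pair_same_type(a, a)$same)
  expect_equal(pair_same_type(a, a)$mean_overshoot, 0)

  b <- a + 0.20   # overshoot 0.07 everywhere: same type
  r <- pair_same_type(a, b)
  expect_equal(r$mean_overshoot, 0.07)
  expect_true(r$same)

  c <- a + 0.25   # overshoot 0.12: different types
  r2 <- pair_same_type(a, c)
  expect_equal(r2$mean_overshoot, 0.12)
  expect_false(r2$same)
  expect_equal(r2$mean_overshoot, pair_same_type(c, a)$mean_overshoot)
  expect_error(pair_same_type(a, a[-1]), "length")
})

test_that("well-separated planted blocks are recovered exactly", {
  bw <- block_windows()
  ts <- response_types(bw$windows)
  expect_identical(ts$n_types, 3L)
  expect_identical(sort(ts$sizes), rep(30L, 3))
  expect_identical(ts$prop_ungrouped, 0)
  expect_equal(adjusted_rand_index(ts$assignment, bw$truth), 1)
})

test_that("undersized groups dissolve into the ungrouped class", {
  set.seed(8)
  len <- 350
  # 4 identical curves plus mutually dissimilar ones
  same4 <- matrix(rep(0.5, 4 * len), 4, len)
  distinct <- t(sapply(seq_len(20), function(i) {
    lv <- (i - 1) / 19
    0.5 * lv + c(rep(0, len / 2), rep(0.9, len / 2)) * (i %% 2) +
      seq(0, 1, length.out = len) * lv
  }))
  distinct <- distinct / max(distinct)
  w <- rbind(same4, distinct)
  ts <- response_types(w)
  # the 4-member group is below min_members and must dissolve
  expect_true(all(ts$assignment[1:4] == 0L) || all(ts$sizes >= 5))
  expect_true(all(ts$sizes >= 5))
})

test_that("single windows and degenerate windows are ungrouped", {
  one <- response_types(matrix(runif(350), 1))
  expect_identical(one$n_types, 0L)
  expect_identical(one$assignment, 0L)

  bw <- block_windows(n_per = 10)
  deg <- rep(FALSE, 30); deg[1:3] <- TRUE
  ts <- response_types(bw$windows, degenerate = deg)
  expect_true(all(ts$assignment[1:3] == 0L))
})

test_that("greedy extraction always removes a maximum-size candidate group", {
  # exhaustive oracle for small n: at every step, every remaining window's
  # candidate group is enumerated and the extracted group must be maximal
  params <- cluster_params(min_members = 1)
  set.seed(33)
  for (case in 1:25) {
    n <- sample(4:12, 1)
    w <- matrix(runif(n * 40, 0, 1), n, 40)
    w <- w * sample(c(0.2, 1), n, replace = TRUE)  # mixed similarity scales
    ov <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j) {
      pair_same_type(w[i, ], w[j, ], params)$mean_overshoot
    }))
    same <- ov < params$overshoot_thresh
    diag(same) <- TRUE
    ts <- response_types(w, params)
    # replay the extraction
    remaining <- seq_len(n)
    for (t_ in seq_len(max(ts$assignment))) {
      grp <- which(ts$assignment == t_)
      grp <- intersect(grp, remaining)
      if (length(grp) == 0) next
      best <- max(vapply(remaining, function(r) {
        sum(same[r, remaining])
      }, numeric(1)))
      expect_identical(length(grp), as.integer(best))
      remaining <- setdiff(remaining, grp)
    }
  }
})

test_that("permuting the windows permutes the assignment accordingly", {
  bw <- block_windows(n_per = 12)
  set.seed(5)
  perm <- sample(nrow(bw$windows))
  ts1 <- response_types(bw$windows)
  ts2 <- response_types(bw$windows[perm, ])
  expect_identical(sort(ts1$sizes), sort(ts2$sizes))
  expect_equal(adjusted_rand_index(ts1$assignment[perm], ts2$assignment), 1)
})

test_that("the adjusted Rand index agrees with the reference implementation", {
  set.seed(91)
  for (i in 1:5) {
    a <- sample(0:3, 60, replace = TRUE)
    b <- sample(0:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("predict assigns new windows to the fitted types", {
  bw <- block_windows()
  ts <- response_types(bw$windows)
  pred <- predict(ts, bw$windows[c(1, 31, 61), ])
  expect_identical(pred, ts$assignment[c(1, 31, 61)])
  far <- matrix(c(rep(0, 175), rep(1, 175)), 1)
  expect_identical(predict(ts, far), 0L)
})
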