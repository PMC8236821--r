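test_that("the vectorised two-group test matches kruskal.test exactly", {
  set.seed(14)
  for (rep_ in 1:5) {
    n <- 40
    x <- matrix(round(rnorm(n * 6), 1), n, 6)   # rounding forces ties
    g <- sample(c(1, 1, 2, 2, 0), n, replace = TRUE)
    tc <- type_specificity_timecourse(x, g)
    for (ti in seq_along(tc$type_ids)) {
      t_ <- tc$type_ids[ti]
      for (col in 1:6) {
        ref <- kruskal.test(x[, col],
                            factor(g == t_, c(TRUE, FALSE)))$p.value
        expect_equal(tc$p[ti, col], ref, tolerance = 1e-12)
      }
    }
    # omnibus against kruskal.test over all classes
    for (col in 1:6) {
      ref <- kruskal.test(x[, col], factor(g))$p.value
      expect_equal(tc$omnibus_p[col], ref, tolerance = 1e-12)
    }
  }
})

test_that("completely tied samples give p = 1", {
  x <- cbind(rep(1, 10), c(rnorm(5, 0), rnorm(5, 10)))
  g <- rep(c(1, 2), each = 5)
  tc <- type_specificity_timecourse(x, g)
  expect_equal(tc$p[, 1], rep(1, 2))
  expect_true(all(tc$p[, 2] < 0.05))
})

test_that("types with fewer than two members are skipped", {
  x <- matrix(rnorm(50), 10, 5)
  g <- c(1, rep(2, 5), rep(0, 4))
  tc <- type_specificity_timecourse(x, g)
  expect_identical(tc$type_ids, 2L)
  one_type <- type_specificity_timecourse(x, rep(1, 10))
  expect_identical(nrow(one_type$p), 0L)
})

test_that("arbitrary labels on one distribution give uniform p-values", {
  set.seed(21)
  x <- matrix(rnorm(60 * 300), 60, 300)
  g <- rep(c(1, 2, 0), each = 20)
  tc <- type_specificity_timecourse(x, g)
  ks <- suppressWarnings(ks.test(as.vector(tc$p), "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("significant fraction summarises p-value matrices", {
  tc <- structure(list(p = matrix(0.001, 3, 10), alpha = 0.05),
                  class = "kw_timecourse")
  expect_equal(as.numeric(significant_fraction(tc)), rep(1, 10))
  tc$p[] <- 0.5
  expect_equal(as.numeric(significant_fraction(tc)), rep(0, 10))
})

test_that("separability holds during stimulation and collapses after", {
  cells <- clustered_cells()    # 4 cells x 4 types x 80 reps, seed 11
  tcs <- lapply(cells, function(cl)
    type_specificity_timecourse(cl$windows, cl$assignment))
  fr <- significant_fraction(tcs)
  expect_gt(mean(fr[1:341]), 0.6)
  # after stimulation offset (+150 ms) the fraction returns to near chance
  expect_lt(mean(fr[500:1200]), 0.15)
})

test_that("label shuffling calibrates the type-I error to alpha", {
  cells <- clustered_cells()
  sh <- shuffle_control(cells, n_shuffles = 50, seed = 3)
  expect_lt(abs(sh$time_avg - 0.05), 0.02)
  expect_identical(sh$n_shuffles, 50)
  # deterministic under the seed
  sh2 <- shuffle_control(cells, n_shuffles = 5, seed = 3)
  sh3 <- shuffle_control(cells, n_shuffles = 5, seed = 3)
  expect_identical(sh2$fraction, sh3$fraction)
})
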