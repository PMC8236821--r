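test_that("chance level is the reciprocal class count", {
  expect_equal(chance_level(7), 1 / 7)
  expect_equal(chance_level(34), 1 / 34)
  expect_equal(chance_level(48), 1 / 48)
  expect_error(chance_level(0))
})

test_that("the PC basis respects rank bounds and recovers known subspaces", {
  set.seed(3)
  two <- matrix(rnorm(2 * 50), 2, 50)
  b2 <- fit_pc_basis(two)
  expect_identical(b2$n_components, 1L)

  five <- matrix(rnorm(5 * 50), 5, 50)
  expect_lte(fit_pc_basis(five)$n_components, 4L)
  expect_error(fit_pc_basis(five[1, , drop = FALSE]), "two")

  # mean curves built from 3 orthogonal basis functions
  t <- seq_len(120)
  basis <- rbind(sin(2 * pi * t / 40), cos(2 * pi * t / 40),
                 sin(2 * pi * t / 15))
  mix <- matrix(rnorm(18), 6, 3) %*% basis
  bf <- fit_pc_basis(mix, var_frac = 0.999)
  expect_identical(bf$n_components, 3L)
  # recovered subspace spans the construction basis
  proj <- basis %*% bf$rotation %*% t(bf$rotation)
  expect_lt(max(abs(proj - basis %*% diag(120) %*% diag(120))), 1e-6)
})

test_that("projection is centred and near-lossless for fitted curves", {
  set.seed(4)
  curves <- matrix(rnorm(4 * 80), 4, 80)
  b <- fit_pc_basis(curves, var_frac = 0.95)
  expect_equal(as.numeric(project_responses(rbind(b$center), b)),
               rep(0, b$n_components))
  co <- project_responses(curves, b)
  recon <- sweep(co %*% t(b$rotation), 2, b$center, `+`)
  rel_err <- sqrt(sum((recon - curves)^2)) /
    sqrt(sum(sweep(curves, 2, b$center)^2))
  expect_lte(rel_err, 0.05 + 1e-6)
  expect_error(project_responses(curves[, -1], b), "length")
})

test_that("kNN decoding is near-perfect for separated clusters", {
  set.seed(5)
  co <- rbind(matrix(rnorm(40 * 2, 0, 0.1), 40, 2),
              matrix(rnorm(40 * 2, 10, 0.1), 40, 2))
  lab <- rep(c("a", "b"), each = 40)
  d <- knn_decode(co, lab, k = 4, n_iter = 10, seed = 1)
  expect_gt(d$accuracy, 0.99)
  expect_equal(unname(rowSums(d$confusion)), c(1, 1))
})

test_that("shuffled labels decode at chance level", {
  set.seed(6)
  co <- matrix(rnorm(120 * 3), 120, 3)
  lab <- rep(c("a", "b", "c"), 40)
  d <- knn_decode(co, lab, k = 4, n_iter = 40, seed = 2)
  se <- sqrt(d$chance * (1 - d$chance) / 60)
  expect_lt(abs(d$accuracy - 1 / 3), 4 * se)
})

test_that("a 2-2 neighbour tie falls back to the nearest neighbour", {
  # training points arranged so the 4 nearest neighbours of the test point
  # split 2-2 and the single nearest belongs to class b
  train <- rbind(c(0.9, 0), c(1.1, 0), c(-1, 0.1), c(-1, -0.1),
                 c(5, 5), c(-5, 5))
  lab <- factor(c("b", "b", "a", "a", "a", "b"))
  d2 <- as.numeric(sqrt(rowSums(sweep(train, 2, c(0.15, 0))^2)))
  expect_identical(order(d2)[1], 1L)  # class b is nearest
  pred <- vmtypes:::knn_predict(train, lab, rbind(c(0.15, 0)), k = 4)
  expect_identical(as.character(pred), "b")
})

test_that("decoding tasks assemble the documented class structures", {
  cells <- clustered_cells()
  one <- cells[[1]]
  task <- assemble_decoding_task(
    list(list(windows = one$windows350, typeset = one$typeset,
              neuron = 1, label = "F5")), "within_pattern")
  expect_identical(task$k, 4L)
  expect_identical(nlevels(task$labels), one$typeset$n_types + 1L)
  expect_true("ungrouped" %in% levels(task$labels))

  cl <- lapply(cells, function(c_) list(windows = c_$windows350,
                                        typeset = c_$typeset,
                                        neuron = c_$neuron,
                                        label = c_$label))
  cp <- assemble_decoding_task(cl, "cross_pattern")
  expect_identical(cp$k, 9L)
  expect_false(any(grepl("ungrouped", levels(cp$labels))))
  expect_identical(nlevels(cp$labels),
                   sum(vapply(cells, function(c_) c_$typeset$n_types,
                              integer(1))))
})

test_that("planted types decode accurately and ungrouped confuses most", {
  cells <- clustered_cells()
  one <- cells[[1]]
  task <- assemble_decoding_task(
    list(list(windows = one$windows350, typeset = one$typeset,
              neuron = 1, label = "F5")), "within_pattern")
  d <- decode_task(task, n_iter = 20, seed = 3)
  expect_gt(d$accuracy, 0.8)
  expect_identical(names(which.min(d$f1)), "ungrouped")
  expect_equal(unname(rowSums(d$confusion)),
               rep(1, nrow(d$confusion)), tolerance = 1e-9)
})

test_that("shuffling labels degrades cross-pattern decoding strongly", {
  cells <- clustered_cells()
  cl <- lapply(cells, function(c_) list(windows = c_$windows350,
                                        typeset = c_$typeset,
                                        neuron = c_$neuron,
                                        label = c_$label))
  task <- assemble_decoding_task(cl, "cross_pattern")
  d <- decode_task(task, n_iter = 10, seed = 4)
  set.seed(9)
  shuf <- task
  shuf$labels <- sample(task$labels)
  shuf$mean_curves <- t(vapply(levels(shuf$labels), function(l) {
    colMeans(shuf$windows[shuf$labels == l, , drop = FALSE])
  }, numeric(ncol(shuf$windows))))
  ds <- decode_task(shuf, n_iter = 10, seed = 4)
  expect_lt(ds$accuracy, 0.5 * d$accuracy)
})
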