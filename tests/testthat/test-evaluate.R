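test_that("a perfect reconstruction scores TP only", {
  ph <- generate_phantom(phantom_spec(n_neurons = 3, n_crossings = 1,
                                      seed = 23))
  pred <- truth_as_trees(ph$truth)
  m <- match_neurites(pred, ph$truth)
  n_true <- sum(vapply(ph$truth$trees, function(t) length(t$neurites),
                       integer(1)))
  expect_equal(m$TP, n_true)
  expect_equal(m$FN, 0L)
  expect_equal(m$FP, 0L)
  expect_equal(as.numeric(trace_metrics(m)), c(1, 1, 1))
  # deleting one neurite creates exactly one false negative
  pred2 <- pred
  pred2[[1]]$neurites <- pred2[[1]]$neurites[-1]
  m2 <- match_neurites(pred2, ph$truth)
  expect_equal(m2$FN, 1L)
  expect_equal(m2$FP, 0L)
  # moving a neurite to the wrong soma: one FP and one FN
  pred3 <- pred
  moved <- pred3[[1]]$neurites[[1]]
  pred3[[1]]$neurites <- pred3[[1]]$neurites[-1]
  pred3[[2]]$neurites <- c(pred3[[2]]$neurites, list(moved))
  m3 <- match_neurites(pred3, ph$truth)
  expect_equal(m3$FN, 1L)
  expect_equal(m3$FP, 1L)
  # soma matching failure is an error
  far <- pred
  for (i in seq_along(far)) far[[i]]$soma$centroid <- far[[i]]$soma$centroid + 300
  expect_error(match_neurites(far, ph$truth), "soma matching")
})

test_that("metric formulas and their algebraic identity hold", {
  m <- trace_metrics(list(TP = 172, FN = 19, FP = 0))
  expect_equal(round(as.numeric(m), 4), c(0.9005, 1.0000, 0.9477))
  expect_equal(as.numeric(trace_metrics(list(TP = 1, FN = 0, FP = 0))), c(1, 1, 1))
  expect_equal(as.numeric(trace_metrics(list(TP = 0, FN = 5, FP = 3))), c(0, 0, 0))
  degen <- trace_metrics(list(TP = 0, FN = 0, FP = 0))
  expect_false(attr(degen, "defined"))
  withr::with_seed(99, {
    for (i in 1:200) {
      tp <- sample(0:50, 1); fn <- sample(0:50, 1); fp <- sample(0:50, 1)
      if (tp + fn == 0 || tp + fp == 0 || tp == 0) next
      v <- trace_metrics(list(TP = tp, FN = fn, FP = fp))
      expect_equal(unname(v["dice"]),
                   2 * v[["precision"]] * v[["sensitivity"]] /
                     (v[["precision"]] + v[["sensitivity"]]),
                   tolerance = 1e-12)
      expect_true(all(v >= 0 & v <= 1))
    }
  })
  # converting an FN into a TP never decreases any metric
  v1 <- trace_metrics(list(TP = 10, FN = 5, FP = 3))
  v2 <- trace_metrics(list(TP = 11, FN = 4, FP = 3))
  expect_true(all(v2 >= v1))
})

test_that("crossing resolution rate counts solved crossings and is label-invariant", {
  ph <- generate_phantom(phantom_spec(n_neurons = 4, n_crossings = 2,
                                      seed = 29))
  pred <- truth_as_trees(ph$truth)
  expect_equal(as.numeric(crossing_resolution_rate(pred, ph$truth)), 1)
  # permuting prediction order leaves the rate unchanged
  perm <- rev(pred)
  expect_equal(as.numeric(crossing_resolution_rate(perm, ph$truth)), 1)
  # severing a crossing neurite beyond the crossing breaks that crossing
  cr <- ph$truth$crossings[1, ]
  cut <- pred
  nn <- cut[[cr$neuron_b]]$neurites[[cr$neurite_b]]
  keep <- nn$nodes[, "arclength"] <= cr$s_b - 5
  cut[[cr$neuron_b]]$neurites[[cr$neurite_b]]$nodes <-
    nn$nodes[keep, , drop = FALSE]
  rate <- as.numeric(crossing_resolution_rate(cut, ph$truth))
  expect_lt(rate, 1)
  # no crossings: undefined flag
  ph0 <- generate_phantom(phantom_spec(n_neurons = 2, n_crossings = 0,
                                       seed = 30))
  r0 <- crossing_resolution_rate(truth_as_trees(ph0$truth), ph0$truth)
  expect_true(is.na(r0))
  expect_false(attr(r0, "defined"))
})
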