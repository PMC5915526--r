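test_that("feature bank has documented structure and filter behaviour", {
  m <- matrix(5, 40, 40)
  fb <- compute_features(m, scales = c(1, 2), n_orient = 4)
  expect_equal(ncol(fb$features), 2 * (1 + 4))
  expect_lt(max(abs(fb$features[, "log_s1"])), 1e-8)
  expect_error(compute_features(m, scales = c(0, 1)), "positive")

  # isotropy of the LoG response around a point source
  pt <- matrix(0, 41, 41); pt[21, 21] <- 1
  fb2 <- compute_features(pt, scales = 2, n_orient = 4)
  log_resp <- matrix(fb2$features[, "log_s2"], 41, 41)
  expect_lt(max(abs(log_resp - rot90_mat(log_resp))), 1e-6)

  # a horizontal bar excites the 0-degree ridge filter most
  bar <- matrix(0, 41, 41); bar[20:22, 5:37] <- 1
  fb3 <- compute_features(bar, scales = 1.5, n_orient = 8)
  r0 <- matrix(fb3$features[, 2], 41, 41)       # orientation 0
  r90 <- matrix(fb3$features[, 2 + 4], 41, 41)  # orientation pi/2
  expect_gt(r0[21, 21], r90[21, 21])
})

test_that("classifier separates phantom foreground and predicts deterministically", {
  spec <- phantom_spec(shape = c(256, 256), n_neurons = 2, poisson = FALSE,
                       background = 0, background_gradient = 0,
                       min_separation = 60, seed = 4)
  ph <- generate_phantom(spec)
  img <- ph$channels$structural$voxels[1, , ]
  truth <- ph$truth$label > 0
  fb <- compute_features(img, scales = c(1, 2, 4), n_orient = 8)
  expect_error(train_classifier(fb, truth & FALSE), "classes")
  model <- train_classifier(fb, truth)
  m1 <- segment_image(img, model = model, features = fb)
  m2 <- segment_image(img, model = model, features = fb)
  expect_identical(m1, m2)
  acc <- mean(m1 == truth)
  expect_gt(acc, 0.99)
  # perfectly separable two-intensity image
  simple <- matrix(0, 64, 64); simple[20:40, 20:40] <- 100
  fbs <- compute_features(simple, scales = c(1, 2), n_orient = 4)
  ms <- train_classifier(fbs, simple > 0, n_per_class = 400)
  pred <- segment_image(simple, model = ms, features = fbs, min_size = 1,
                        max_hole = 0)
  dice <- 2 * sum(pred & simple > 0) / (sum(pred) + sum(simple > 0))
  expect_equal(dice, 1)
})

test_that("threshold fallback recovers phantom masks", {
  expect_true(all(segment_image(matrix(0, 32, 32)) == FALSE))
  # noiseless, zero background: exact recovery
  spec <- phantom_spec(n_neurons = 2, poisson = FALSE, background = 0,
                       background_gradient = 0, seed = 15)
  ph <- generate_phantom(spec)
  img <- ph$channels$structural$voxels[1, , ]
  mask <- segment_image(img)
  expect_true(all(mask == (ph$truth$label > 0)))
  # high-SNR Poisson phantom: Dice >= 0.95 and idempotent cleaning
  ph2 <- generate_phantom(phantom_spec(n_neurons = 3, seed = 16))
  img2 <- project_mip(ph2$channels$structural)
  m2 <- segment_image(img2)
  truth2 <- ph2$truth$label > 0
  expect_gt(2 * sum(m2 & truth2) / (sum(m2) + sum(truth2)), 0.95)
  expect_true(all(segment_image(img2) == m2))
})
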