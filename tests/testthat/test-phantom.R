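test_that("degenerate and deterministic phantom generation", {
  spec <- phantom_spec(n_neurons = 1, neurites_per_soma = c(0, 0),
                       poisson = FALSE, background = 0,
                       background_gradient = 0, seed = 9)
  ph <- generate_phantom(spec)
  expect_length(ph$truth$trees, 1)
  expect_length(ph$truth$trees[[1]]$neurites, 0)
  expect_true(sum(ph$truth$label > 0) == ph$truth$trees[[1]]$soma$area)

  # bit-identical regeneration under the same seed
  spec2 <- phantom_spec(n_neurons = 3, n_crossings = 1, seed = 77)
  a <- generate_phantom(spec2)
  b <- generate_phantom(spec2)
  expect_identical(a$channels$structural$voxels, b$channels$structural$voxels)
  expect_identical(a$truth$label, b$truth$label)
})

test_that("noise-free zero-background phantom has label support equal to image support", {
  spec <- phantom_spec(n_neurons = 2, poisson = FALSE, background = 0,
                       background_gradient = 0, seed = 21)
  ph <- generate_phantom(spec)
  img <- ph$channels$structural$voxels[1, , ]
  expect_identical(ph$truth$label > 0, img > 0)
})

test_that("forced crossings overlap rendered masks but not true centerlines", {
  spec <- phantom_spec(n_neurons = 2, n_crossings = 1,
                       crossing_angles = c(pi / 2, pi / 2),
                       poisson = FALSE, seed = 5)
  ph <- generate_phantom(spec)
  cr <- ph$truth$crossings
  expect_equal(nrow(cr), 1)
  expect_equal(cr$angle, pi / 2, tolerance = 1e-9)
  ma <- ph$truth$neuron_masks[[cr$neuron_a]]
  mb <- ph$truth$neuron_masks[[cr$neuron_b]]
  expect_gt(sum(ma & mb), 0)
  # centerlines of the two neurons are disjoint point sets
  pa <- do.call(rbind, lapply(ph$truth$trees[[cr$neuron_a]]$neurites,
                              function(n) n$pts))
  pb <- do.call(rbind, lapply(ph$truth$trees[[cr$neuron_b]]$neurites,
                              function(n) n$pts))
  expect_equal(nrow(merge(as.data.frame(pa), as.data.frame(pb))), 0)
  # the recorded crossing location lies on both true neurites
  na <- ph$truth$trees[[cr$neuron_a]]$neurites[[cr$neurite_a]]
  expect_lt(min(sqrt((na$pts[, 1] - cr$y)^2 + (na$pts[, 2] - cr$x)^2)), 1)
})

test_that("adding a crossing neuron leaves the host trees unchanged", {
  base <- phantom_spec(n_neurons = 2, n_crossings = 0, seed = 31)
  plus <- phantom_spec(n_neurons = 3, n_crossings = 1, seed = 31)
  a <- generate_phantom(base)
  b <- generate_phantom(plus)
  for (i in 1:2) {
    expect_equal(a$truth$trees[[i]]$soma$centroid,
                 b$truth$trees[[i]]$soma$centroid)
    expect_equal(lapply(a$truth$trees[[i]]$neurites, `[[`, "pts"),
                 lapply(b$truth$trees[[i]]$neurites, `[[`, "pts"))
  }
})

test_that("ground-truth trees respect smoothness and label membership", {
  ph <- generate_phantom(phantom_spec(n_neurons = 3, n_crossings = 1,
                                      seed = 13))
  for (tr in ph$truth$trees) {
    for (nn in tr$neurites) {
      d <- diff(nn$pts)
      ang <- atan2(d[, 1], d[, 2])
      turns <- abs(neurotracer:::wrap_angle(diff(ang)))
      expect_lt(max(turns), 0.05)   # curvature bound (0.03) + rounding
      expect_true(all(diff(nn$arclength) > 0))
      inside <- ph$truth$neuron_masks[[tr$id]][round(nn$pts)]
      expect_true(all(inside))
    }
  }
})

test_that("painted bell signal equals the Gaussian along the centerline", {
  spec <- phantom_spec(n_neurons = 1, poisson = FALSE, background = 0,
                       background_gradient = 0, seed = 5)
  ph <- generate_phantom(spec)
  expect_error(render_bell_signal(ph$truth, 1, 99, 10, 5, 5), "unknown")
  blank <- render_bell_signal(ph$truth, 1, 1, H = 0, mu = 35, sigma = 10)
  expect_true(all(blank$pixels == 0))
  bell <- render_bell_signal(ph$truth, 1, 1, H = 100, mu = 35, sigma = 10)
  ne <- ph$truth$trees[[1]]$neurites[[1]]
  k <- which.min(abs(ne$arclength - 35))
  val <- bell$pixels[round(ne$pts[k, 1]), round(ne$pts[k, 2])]
  expect_equal(val, 100, tolerance = 0.01)
})
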