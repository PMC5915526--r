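test_that("directional ratio scores isotropic and tubular geometry correctly", {
  # large filled disk: interior pixels fully covered at every orientation
  disk <- disk_mask(c(61, 61), 31, 31, 25)
  dr <- directional_ratio(disk, length = 15, n_orient = 8)
  expect_equal(dr$score[31, 31], 1)
  expect_true(all(dr$score >= 0 & dr$score <= 1))
  expect_true(all(dr$score[!disk] == 0))
  # 1-px bar: min response is 1/length of the max
  bar <- matrix(FALSE, 41, 41); bar[21, 5:37] <- TRUE
  drb <- directional_ratio(bar, length = 9, n_orient = 8)
  expect_equal(drb$score[21, 21], 1 / 9, tolerance = 1e-6)
  # empty mask
  dre <- directional_ratio(matrix(FALSE, 16, 16))
  expect_true(all(dre$score == 0))
  # score map is 90-degree rotation invariant within discretization
  m <- disk_mask(c(80, 80), 30, 35, 12)
  m <- tube_mask(m, c(30, 47), c(30, 75), hw = 2)
  d1 <- directional_ratio(m, length = 15, n_orient = 16)$score
  d2 <- directional_ratio(rot90_mat(m), length = 15, n_orient = 16)$score
  expect_lt(max(abs(rot90_mat(d1) - d2)), 0.1)
})

test_that("soma detection finds blobs, rejects bars, localizes centroids", {
  # one disk, no neurites
  disk <- disk_mask(c(90, 90), 45, 45, 14)
  regs <- detect_somas(disk)
  expect_length(regs, 1)
  expect_gt(sum(regs[[1]]$mask & disk) / sum(disk), 0.9)
  # bars only: no isotropic region
  bars <- matrix(FALSE, 90, 90)
  bars <- tube_mask(bars, c(20, 5), c(20, 85), hw = 2)
  bars <- tube_mask(bars, c(10, 40), c(80, 40), hw = 2)
  expect_length(detect_somas(bars), 0)
  # phantom with five separated somas
  ph <- generate_phantom(phantom_spec(n_neurons = 5, seed = 19))
  mask <- segment_image(project_mip(ph$channels$structural))
  regs5 <- detect_somas(mask)
  expect_length(regs5, 5)
  true_ctr <- t(vapply(ph$truth$trees, function(t) t$soma$centroid, numeric(2)))
  for (r in regs5) {
    d <- sqrt((true_ctr[, 1] - r$centroid[1])^2 +
                (true_ctr[, 2] - r$centroid[2])^2)
    expect_lt(min(d), 3)
  }
  # refinement never includes weakly isotropic pixels
  dr <- directional_ratio(mask, 15, 16)
  for (r in regs5) expect_true(all(dr$score[r$mask] >= 0.3))
})

test_that("clustered somas split along the distance-transform valley", {
  # a single convex disk is returned unchanged
  disk <- disk_mask(c(70, 70), 35, 35, 15)
  r0 <- neurotracer:::new_soma_region(1L, disk)
  expect_length(split_clustered_somas(r0), 1)
  # two overlapping disks, centres 1.5 radii apart
  m <- disk_mask(c(70, 90), 35, 30, 14) | disk_mask(c(70, 90), 35, 51, 14)
  r1 <- neurotracer:::new_soma_region(1L, m)
  parts <- split_clustered_somas(r1)
  expect_length(parts, 2)
  union <- Reduce(`|`, lapply(parts, function(p) p$mask))
  expect_identical(union, m)
  overlap <- parts[[1]]$mask & parts[[2]]$mask
  expect_false(any(overlap))
  centers <- rbind(c(35, 30), c(35, 51))
  for (ct in seq_len(2)) {
    holds <- vapply(parts, function(p) p$mask[centers[ct, 1], centers[ct, 2]],
                    logical(1))
    expect_equal(sum(holds), 1L)
  }
})

test_that("detected soma count equals phantom neuron count on the suite", {
  runs <- standard_suite_runs()
  specs <- phantom_suite(12, seed = 1)
  for (k in seq_along(runs)) {
    expect_length(runs[[k]]$somas, specs[[k]]$n_neurons)
  }
})
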