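test_that("background subtraction cancels a constant field exactly", {
  m <- matrix(FALSE, 40, 120)
  m <- tube_mask(m, c(20, 10), c(20, 110), hw = 2)
  img <- matrix(37, 40, 120)
  nodes <- cbind(y = rep(20, 6), x = seq(10, 110, length.out = 6))
  prof <- sample_profile(img, m, nodes)
  expect_true(all(abs(prof$corrected) < 1e-9))
  expect_equal(prof$arclength_um, prof$arclength_px * 0.28)
  expect_true(all(diff(prof$arclength_px) > 0))
})

test_that("painted Gaussian profile is recovered through the full pipeline", {
  spec <- phantom_spec(n_neurons = 1, poisson = FALSE, background = 0,
                       background_gradient = 0, seed = 5)
  ph <- generate_phantom(spec)
  ni_bell <- which.max(vapply(ph$truth$trees[[1]]$neurites,
                              function(n) max(n$arclength), numeric(1)))
  bell <- render_bell_signal(ph$truth, 1, ni_bell, H = 100, mu = 35, sigma = 10)
  shape <- dim(bell$pixels)
  gx <- outer(rep(1, shape[1]), seq(0, 1, length.out = shape[2]))
  target <- image2d(bell$pixels + 20 + 10 * gx)
  mask <- segment_image(project_mip(ph$channels$structural))
  somas <- detect_somas(mask)
  trees <- suppressMessages(extract_trees(somas, mask))
  profs <- lapply(trees[[1]]$neurites, function(nn)
    sample_profile(target, mask, nn$nodes))
  ax <- identify_axon(profs)
  met <- ais_metrics(profs[[ax]], profs[setdiff(seq_along(profs), ax)][1:2])
  expect_true(met$fit_ok)
  expect_lt(abs(met$H - 100) / 100, 0.05)
  # corrected profile near the bell centre is close to the painted peak
  near <- which(abs(profs[[ax]]$arclength_px - met$mu) < 1)
  expect_lt(abs(max(profs[[ax]]$corrected[near]) - 100) / 100, 0.06)
  # background-gradient run matches a background-free run within 10% RMS
  prof0 <- sample_profile(image2d(bell$pixels), mask,
                          trees[[1]]$neurites[[ax]]$nodes)
  both <- seq_len(min(length(prof0$corrected),
                      length(profs[[ax]]$corrected)))
  rms <- sqrt(mean((prof0$corrected[both] - profs[[ax]]$corrected[both])^2))
  expect_lt(rms / max(prof0$corrected), 0.10)
})

test_that("AIS metrics match closed forms on analytic profiles", {
  g <- function(x, H, mu, s) H * exp(-(x - mu)^2 / (2 * s^2))
  mkprof <- function(y) {
    x <- 0:80
    structure(list(neuron_id = 1L, neurite_id = 1L, arclength_px = x,
                   arclength_um = x * 0.28, raw = y, background = 0 * x,
                   corrected = y), class = "intensity_profile")
  }
  ax <- mkprof(g(0:80, 50, 35, 12))
  den <- mkprof(rep(0.5, 81))
  met <- ais_metrics(ax, list(den, den))
  expect_lt(abs(met$H - 50), 1e-3)
  a_closed <- 50 * 12 * sqrt(2 * pi) * (pnorm((70 - 35) / 12) - pnorm(-35 / 12))
  expect_lt(abs(met$A_AIS - a_closed) / a_closed, 1e-3)
  expect_equal(met$A_den, 0.5 * 70, tolerance = 1e-9)
  expect_equal(met$R_AD, met$A_AIS / 35, tolerance = 1e-9)
  # all-zero profiles: degenerate flags
  z <- mkprof(rep(0, 81))
  mz <- ais_metrics(z, list(z, z))
  expect_equal(mz$A_AIS, 0)
  expect_equal(mz$V_AIS, 0)
  expect_false(mz$rad_defined)
  expect_true(is.na(mz$R_AD))
  # 5% multiplicative noise still recovers H within 10%
  withr::with_seed(31, {
    noisy <- mkprof(g(0:80, 80, 30, 10) * (1 + 0.05 * rnorm(81)))
    mn <- ais_metrics(noisy, list(den, den))
    expect_lt(abs(mn$H - 80) / 80, 0.1)
  })
})

test_that("group comparisons behave under null, separation and relabeling", {
  mk <- function(vals) lapply(vals, function(v)
    structure(list(A_AIS = v, V_AIS = v / 2, H = v / 3, R_AD = v / 10),
              class = "ais_metrics"))
  a <- mk(c(10, 11, 12, 13, 9, 10.5))
  expect_error(compare_groups(mk(10), mk(10)), "at least 2")
  # identical groups: no difference
  cmp0 <- compare_groups(a, a)
  expect_true(all(cmp0$p > 0.99))
  # strongly separated groups at n = 12
  withr::with_seed(4, {
    g1 <- mk(rnorm(12, 100, 1))
    g2 <- mk(rnorm(12, 110, 1))
  })
  cmp1 <- compare_groups(g1, g2)
  expect_true(all(cmp1$p < 1e-3))
  cmp2 <- compare_groups(g2, g1)
  expect_equal(cmp2$p, cmp1$p, tolerance = 1e-12)
  expect_equal(cmp2$t, -cmp1$t, tolerance = 1e-12)
})

test_that("axon identification and dendrite pairing follow the stated rules", {
  mkprof <- function(level, len = 100) {
    x <- 0:len
    structure(list(neuron_id = 1L, neurite_id = 1L, arclength_px = x,
                   arclength_um = x * 0.28, raw = x * 0 + level,
                   background = 0 * x, corrected = x * 0 + level),
              class = "intensity_profile")
  }
  profs <- list(mkprof(1), mkprof(10), mkprof(2), mkprof(3, len = 40))
  expect_equal(identify_axon(profs), 2L)
  dd <- select_dendrites(profs, radii = c(2.0, 2.5, 2.4, 2.5), axon = 2L)
  expect_equal(sort(dd), c(1L, 3L))   # the short profile is excluded
  expect_true(is.na(identify_axon(list(mkprof(5, len = 30)))))
})
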