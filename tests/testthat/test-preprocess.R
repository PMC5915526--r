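test_that("denoising preserves constants, shape and non-negativity", {
  m <- matrix(50, 64, 64)
  out <- denoise(m, denoise_config())
  expect_equal(dim(out), dim(m))
  expect_lt(max(abs(out - 50)), 1e-6 * 50)
  expect_true(all(out >= 0))
  # deterministic
  set.seed(8)
  noisy <- matrix(rpois(64 * 64, 30), 64, 64)
  expect_identical(denoise(noisy), denoise(noisy))
})

test_that("denoising reduces RMSE of a Poisson-corrupted bar", {
  clean <- matrix(10, 96, 96)
  clean[40:56, 10:86] <- 120
  set.seed(42)
  noisy <- matrix(rpois(length(clean), clean), nrow(clean), ncol(clean))
  den <- denoise(noisy)
  rmse <- function(a) sqrt(mean((a - clean)^2))
  expect_lt(rmse(den), rmse(noisy))
})

test_that("total variation decreases monotonically with the threshold multiplier", {
  set.seed(7)
  clean <- matrix(15, 96, 96)
  clean[30:40, 5:90] <- 100
  noisy <- matrix(rpois(length(clean), clean), nrow(clean), ncol(clean))
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  tvs <- vapply(c(1, 2, 4, 8), function(k)
    tv(denoise(noisy, denoise_config(k = k))), numeric(1))
  expect_true(all(diff(tvs) <= 0))
})

test_that("denoising does not degrade downstream segmentation", {
  specs <- phantom_suite(12, seed = 1)
  for (k in 1:2) {
    ph <- generate_phantom(specs[[k]])
    img <- project_mip(ph$channels$structural)
    truth <- ph$truth$label > 0
    dice <- function(mk) {
      tp <- sum(mk & truth)
      2 * tp / (sum(mk) + sum(truth))
    }
    d_noisy <- dice(segment_image(img))
    d_den <- dice(segment_image(denoise(img)))
    expect_gte(d_den, d_noisy - 1e-6)
  }
})
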