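test_that("Otsu separates two balanced classes and rejects constants", {
  m <- matrix(rep(c(0, 255), each = 32), 8, 8)
  ot <- otsu_threshold(m)
  expect_gt(ot$threshold, 0)
  expect_lt(ot$threshold, 255)
  expect_identical(ot$mask, m == 255)

  m4 <- matrix(c(10, 10, 200, 200), 2, 2)
  expect_equal(sum(otsu_threshold(m4)$mask), 2)

  expect_error(otsu_threshold(matrix(5, 3, 3)), "degenerate")
})

test_that("Otsu matches exhaustive between-class-variance search on 8-bit images", {
  set.seed(42)
  for (rep in 1:12) {
    img <- matrix(sample(0:255, 400, replace = TRUE,
                         prob = runif(256)^2), 20, 20)
    if (length(unique(as.vector(img))) < 2) next
    ot <- otsu_threshold(img)
    oracle <- brute_otsu_split(as.vector(img))
    expect_identical(ot$mask, img > oracle$threshold)
  }
})

test_that("skull stripping yields one filled component containing the tumor", {
  ps <- small_phantom_slice()
  ss <- skull_strip(ps$slice)
  expect_false(ss$empty)
  # tumor entirely inside the mask
  expect_true(all(ss$mask[ps$truth]))
  # single connected component, no interior holes
  lab <- qdaseg:::eb_label(ss$mask)
  expect_equal(max(lab), 1L)
  expect_identical(qdaseg:::eb_fill_holes(ss$mask), ss$mask)
  # outside zeroed
  expect_true(all(ss$brain$data[!ss$mask] == 0))
})

test_that("skull stripping flags slices without brain instead of failing", {
  z <- skull_strip(matrix(0, 32, 32))
  expect_true(z$empty)
  expect_equal(sum(z$mask), 0)
  set.seed(8)
  noise <- matrix(rnorm(64 * 64, 0, 6), 64, 64)
  expect_true(skull_strip(noise)$empty)
})

test_that("skull stripping is a fixed point on a solid disk", {
  m <- matrix(0, 64, 64)
  d <- disk_mask(64, 20)
  m[d] <- 200
  ss <- skull_strip(m)
  expect_false(ss$empty)
  expect_identical(ss$mask, d)
  expect_identical(ss$brain$data, m)
})

test_that("diffusion is the identity on constants and obeys the max principle", {
  cfg <- preprocess_config(diffusion_iters = 25)
  const <- matrix(7.5, 16, 16)
  expect_equal(anisotropic_diffusion(const, cfg), const)
  set.seed(5)
  for (rep in 1:10) {
    img <- matrix(runif(256, 0, 255), 16, 16)
    out <- anisotropic_diffusion(img, cfg)
    expect_gte(min(out), min(img) - 1e-12)
    expect_lte(max(out), max(img) + 1e-12)
  }
})

test_that("diffusion keeps step edges while flattening flat-region noise", {
  set.seed(9)
  img <- matrix(0, 40, 40)
  img[, 21:40] <- 120
  noisy <- img + matrix(rnorm(1600, 0, 8), 40, 40)
  cfg <- preprocess_config(diffusion_iters = 10, kappa = 30, lam = 0.14)
  out <- anisotropic_diffusion(noisy, cfg)
  # edge contrast retained within 5%
  edge_in <- mean(noisy[, 25:40]) - mean(noisy[, 1:16])
  edge_out <- mean(out[, 25:40]) - mean(out[, 1:16])
  expect_lt(abs(edge_out - edge_in) / edge_in, 0.05)
  # flat-region variance drops
  expect_lt(var(as.vector(out[5:36, 1:16])), var(as.vector(noisy[5:36, 1:16])))
})

test_that("diffusion rejects unstable step weights", {
  expect_error(preprocess_config(lam = 0.3), "stability")
})

test_that("histogram equalization maps a balanced two-level image to the extremes", {
  m <- matrix(rep(c(60, 80), each = 18), 6, 6)
  mask <- matrix(TRUE, 6, 6)
  out <- hist_equalize(m, mask)
  # direct CDF computation: cdf(60) = 0.5 -> lo, cdf(80) = 1 -> hi
  expect_true(all(out[m == 60] == 60))
  expect_true(all(out[m == 80] == 80))
  expect_lt(unique(out[m == 60]), unique(out[m == 80]))
})

test_that("equalization is monotone, mask-restricted, and ~affine on uniform data", {
  set.seed(13)
  m <- matrix(runif(900, 50, 150), 30, 30)
  mask <- matrix(FALSE, 30, 30)
  mask[5:26, 5:26] <- TRUE
  out <- hist_equalize(m, mask, preprocess_config(histeq_bins = 64))
  # out-of-mask bit-identical
  expect_identical(out[!mask], m[!mask])
  # monotone non-decreasing in the input ordering
  ord <- order(m[mask])
  expect_true(all(diff(out[mask][ord]) >= -1e-9))
  # uniform input stays close to the identity (affine, same range); the
  # deviation is bounded by a few bin widths of quantization plus the
  # cdf_min edge correction
  expect_lt(max(abs(out[mask] - m[mask])), (150 - 50) / 64 * 5)
  expect_error(hist_equalize(m, mask & FALSE), "empty mask")
})

test_that("full preprocessing preserves the tumor's intensity rank and flags empties", {
  ps <- small_phantom_slice()
  pp <- preprocess_slice(ps$slice)
  expect_false(pp$empty)
  lab <- ps$labels
  ranks_raw <- rank(c(csf = mean(ps$slice$data[lab == 1]),
                      grey = mean(ps$slice$data[lab == 2]),
                      white = mean(ps$slice$data[lab == 3]),
                      tumor = mean(ps$slice$data[lab == 5])))
  ranks_clean <- rank(c(csf = mean(pp$clean$data[lab == 1]),
                        grey = mean(pp$clean$data[lab == 2]),
                        white = mean(pp$clean$data[lab == 3]),
                        tumor = mean(pp$clean$data[lab == 5])))
  expect_identical(ranks_clean, ranks_raw)

  z <- preprocess_slice(matrix(0, 16, 16))
  expect_true(z$empty)
  expect_equal(sum(z$brain_mask), 0)
  expect_true(all(z$clean$data == 0))
})

test_that("preprocessing is close to idempotent on a phantom slice", {
  ps <- small_phantom_slice()
  pp1 <- preprocess_slice(ps$slice)
  pp2 <- preprocess_slice(pp1$clean)
  d01 <- mean(abs(pp1$clean$data - ps$slice$data))
  d12 <- mean(abs(pp2$clean$data - pp1$clean$data))
  expect_lt(d12, d01)
})
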