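test_that("edge indicator is 1 on constants and dips at edges", {
  const <- matrix(42, 20, 20)
  expect_true(all(edge_indicator(const) == 1))
  step <- matrix(0, 30, 30); step[, 16:30] <- 100
  g <- edge_indicator(step, sigma = 1.5)
  expect_lt(min(g[, 14:17]), 0.01)
  expect_gt(min(g[, c(1:5, 26:30)]), 0.9)
  expect_true(all(g > 0 & g <= 1))
})

test_that("edge indicator matches pointwise evaluation on a random slice", {
  set.seed(44)
  img <- matrix(runif(400, 0, 50), 20, 20)
  sig <- 1.2
  size <- 2 * ceiling(3 * sig) + 1
  brush <- EBImage::makeBrush(size, "Gaussian", sigma = sig)
  sm <- EBImage::imageData(EBImage::filter2(img, brush, boundary = "replicate"))
  shift <- function(m, dr, dc) qdaseg:::shift_mat(m, dr, dc)
  gx <- (shift(sm, 1, 0) - shift(sm, -1, 0)) / 2
  gy <- (shift(sm, 0, 1) - shift(sm, 0, -1)) / 2
  oracle <- 1 / (1 + gx^2 + gy^2)
  expect_equal(unname(edge_indicator(img, sig)[3:18, 3:18]),
               unname(oracle[3:18, 3:18]), tolerance = 1e-10)
})

test_that("the stability step is inversely proportional to the weights", {
  expect_equal(stability_dt(level_set_params(Wa = 1, Wc = 1)), 1 / 6)
  expect_equal(stability_dt(level_set_params(Wa = 2, Wc = 1)), 1 / 12)
  p1 <- stability_dt(level_set_params(Wa = 1, Wc = 2))
  p2 <- stability_dt(level_set_params(Wa = 2, Wc = 2))
  expect_equal(p2, p1 / 2)
  expect_equal(stability_dt(level_set_params(dt = 0.05)), 0.05)
})

test_that("zero iterations return phi unchanged; evolution is deterministic", {
  m <- disk_mask(41, 12)
  phi <- signed_distance_init(m)
  g <- matrix(1, 41, 41)
  z <- evolve_level_set(phi, g, level_set_params(max_iters = 0))
  expect_identical(z$phi, phi)
  expect_equal(z$iters, 0L)
  p <- level_set_params(max_iters = 40, convergence_tol = 0)
  a <- evolve_level_set(phi, g, p)
  b <- evolve_level_set(phi, g, p)
  expect_identical(a$phi, b$phi)
  expect_error(evolve_level_set(phi, matrix(1, 5, 5), p), "dimensions")
})

test_that("pure curvature flow follows the shrinking-circle law", {
  m <- disk_mask(61, 20)
  phi <- signed_distance_init(m)
  g <- matrix(1, 61, 61)
  # evolve to t = 50: r = sqrt(400 - 100) = sqrt(300)
  p <- level_set_params(nu = 0, max_iters = 300, convergence_tol = 0,
                        include_advection = FALSE)
  ev <- evolve_level_set(phi, g, p)
  r <- sqrt(sum(ev$phi < 0) / pi)
  expect_lt(abs(r - sqrt(300)) / sqrt(300), 0.02)
})

test_that("a contour resting on a deep edge minimum stays put", {
  img <- matrix(0, 61, 61)
  img[disk_mask(61, 15)] <- 200
  g <- edge_indicator(img, sigma = 1.5, scale = 4)
  m <- disk_mask(61, 15)
  phi <- signed_distance_init(m)
  p <- level_set_params(nu = 0, max_iters = 100, convergence_tol = 0)
  ev <- evolve_level_set(phi, g, p)
  before <- sqrt(sum(phi < 0) / pi)
  after <- sqrt(sum(ev$phi < 0) / pi)
  expect_lt(abs(after - before), 0.5)
})

test_that("two seeds over one lump merge into a single component", {
  img <- matrix(0, 81, 81)
  lump <- disk_mask(81, 22)
  img[lump] <- 180
  g <- edge_indicator(img, sigma = 1.5, scale = 4)
  init <- matrix(FALSE, 81, 81)
  init[(row(init) - 31)^2 + (col(init) - 41)^2 <= 64] <- TRUE
  init[(row(init) - 51)^2 + (col(init) - 41)^2 <= 64] <- TRUE
  expect_equal(max(qdaseg:::eb_label(init)), 2L)
  # inflate outward (nu > 0) until both fronts hit the lump edge and merge
  p <- level_set_params(nu = 0.8, Wc = 0.2, max_iters = 400,
                        convergence_tol = 0)
  ev <- evolve_level_set(signed_distance_init(init), g, p)
  final <- phi_to_mask(ev$phi)
  expect_equal(max(qdaseg:::eb_label(final)), 1L)
})

test_that("phi stays finite and masks respond monotonically to shifts", {
  ps <- small_phantom_slice()
  pp <- preprocess_slice(ps$slice)
  g <- edge_indicator(pp$diffused, 1.5,
                      scale = 0.02 * diff(range(pp$diffused$data[pp$brain_mask])))
  phi <- signed_distance_init(disk_mask(120, 25))
  p <- level_set_params(max_iters = 1000, convergence_tol = 0)
  ev <- evolve_level_set(phi, g, p)
  expect_true(all(is.finite(ev$phi)))
  areas <- vapply(c(-2, -1, 0, 1, 2),
                  function(s) sum(phi_to_mask(ev$phi + s)), numeric(1))
  expect_true(all(diff(areas) <= 0))   # raising phi shrinks the region
})

test_that("slice segmentation refines the cluster mask and short-circuits empties", {
  ps <- small_phantom_slice()
  pp <- preprocess_slice(ps$slice)
  pix <- pp$diffused$data[pp$brain_mask]
  fit <- kmeans_fit(pix, K = 4)
  tm <- tumor_mask(fit$labels, identify_tumor_cluster(fit),
                   shape = c(120, 120), mask_index = which(pp$brain_mask),
                   brain_mask = pp$brain_mask)
  init <- qdaseg:::eb_dilate(tm, qdaseg:::disc_brush(2)) & pp$brain_mask
  seg <- segment_slice(pp$diffused, init, level_set_params(), 1.5,
                       edge_scale = 0.02 * diff(range(pix)))
  dice_init <- seg_rates(confusion_counts(init, ps$truth))$dice
  dice_seg <- seg_rates(confusion_counts(seg, ps$truth))$dice
  expect_gte(dice_seg, dice_init)
  expect_gt(dice_seg, 0.9)
  # determinism and the empty short-circuit
  seg2 <- segment_slice(pp$diffused, init, level_set_params(), 1.5,
                        edge_scale = 0.02 * diff(range(pix)))
  expect_identical(unclass(seg), unclass(seg2))
  empty <- segment_slice(pp$diffused, init & FALSE, level_set_params())
  expect_equal(sum(empty), 0)
})
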