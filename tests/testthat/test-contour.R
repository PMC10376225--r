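test_that("tumor mask extraction keeps lumps and filters speckle", {
  lab <- matrix(1L, 30, 30)
  lab[5:14, 5:14] <- 2L         # 100-px blob
  lab[18:27, 18:27] <- 2L       # second 100-px blob
  m <- tumor_mask(lab, 2L, min_area = 20)
  expect_equal(sum(m), 200)
  expect_equal(max(qdaseg:::eb_label(m)), 2L)   # both lumps retained

  sp <- matrix(1L, 30, 30)
  sp[10, 10:14] <- 2L           # 5-px speckle
  expect_equal(sum(tumor_mask(sp, 2L, min_area = 20)), 0)
  expect_true(isTRUE(attr(tumor_mask(sp, 2L, min_area = 20), "empty")))

  all2 <- matrix(2L, 12, 12)
  expect_true(all(tumor_mask(all2, 2L, cleanup = FALSE)))
})

test_that("vector labels with mask indices reconstruct the slice mask", {
  shape <- c(20, 20)
  brain <- disk_mask(20, 8)
  labs <- rep(1L, sum(brain))
  labs[1:30] <- 4L
  m <- tumor_mask(labs, 4L, shape = shape, mask_index = which(brain),
                  cleanup = FALSE)
  expect_equal(sum(m), 30)
  expect_true(all(brain[m]))
  expect_error(tumor_mask(labs, 4L), "shape")
})

test_that("border-touching components are excluded when asked", {
  brain <- disk_mask(40, 15)
  lab <- matrix(0L, 40, 40)
  lab[brain] <- 1L
  rim <- brain & qdaseg:::boundary_voxels(brain)
  lab[rim] <- 2L                         # skull-like rim in the top cluster
  lab[18:23, 18:23] <- 2L                # interior lump
  m <- tumor_mask(lab, 2L, min_area = 10, brain_mask = brain,
                  exclude_border = TRUE)
  expect_equal(sum(m), 36)
  expect_true(all(which(m, arr.ind = TRUE)[, 1] %in% 18:23))
})

test_that("contours enumerate the 4-connected boundary in order", {
  m <- matrix(FALSE, 5, 5)
  m[2:4, 2:4] <- TRUE
  ct <- mask_to_contour(m)
  expect_equal(nrow(ct$points), 8)       # 3x3 square: all but the center
  # consecutive points are Moore neighbors
  d <- abs(diff(ct$points))
  expect_true(all(pmax(d[, 1], d[, 2]) <= 1))

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(nrow(mask_to_contour(single)$points), 1)
  expect_error(mask_to_contour(matrix(FALSE, 3, 3)), "empty")
})

test_that("contour points are exactly the pixels with an outside 4-neighbour", {
  for (s in 1:5) {
    m <- random_blob(24, s)
    if (!any(m)) next
    ct <- mask_to_contour(m)
    oracle <- which(qdaseg:::boundary_voxels(m), arr.ind = TRUE)
    got <- ct$points[order(ct$points[, 1], ct$points[, 2]), , drop = FALSE]
    oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(oracle))
    # every contour point touches the outside
    for (k in seq_len(nrow(got))) {
      r <- got[k, 1]; c <- got[k, 2]
      nbs <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
      inb <- nbs[, 1] >= 1 & nbs[, 1] <= 24 & nbs[, 2] >= 1 & nbs[, 2] <= 24
      outside <- any(!inb) || any(!m[nbs[inb, , drop = FALSE]])
      expect_true(outside)
    }
  }
})

test_that("signed distance has the right sign, magnitude and round trip", {
  m <- disk_mask(41, 10)
  phi <- signed_distance_init(m)
  expect_lt(phi[21, 21], -9)
  expect_gt(phi[21, 21], -11.5)
  edge <- which(qdaseg:::boundary_voxels(m), arr.ind = TRUE)[1, ]
  expect_gte(phi[edge[1], edge[2]], -1.5)
  expect_lte(phi[edge[1], edge[2]], 0)
  # round trip through the zero level set
  expect_identical(phi_to_mask(phi), m)
  # complement symmetry: boundary pixel sets shift by one pixel, so compare
  # away from the interface
  phic <- signed_distance_init(!m)
  far <- abs(phi) > 2
  expect_true(all(sign(phic[far]) == -sign(phi[far])))
  # gradient magnitude ~ 1 on a band near the zero set
  gx <- (qdaseg:::shift_mat(phi, 1, 0) - qdaseg:::shift_mat(phi, -1, 0)) / 2
  gy <- (qdaseg:::shift_mat(phi, 0, 1) - qdaseg:::shift_mat(phi, 0, -1)) / 2
  band <- abs(phi) <= 3 & abs(phi) >= 1
  gm <- sqrt(gx^2 + gy^2)[band]
  expect_gte(mean(gm), 0.8)
  expect_lte(mean(gm), 1.2)

  empty <- signed_distance_init(matrix(FALSE, 8, 8))
  expect_true(all(empty > 0))
})

test_that("signed distance round trips arbitrary blobs", {
  for (s in 6:10) {
    m <- random_blob(20, s)
    expect_identical(phi_to_mask(signed_distance_init(m)), m)
  }
})
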