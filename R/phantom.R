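# Synthetic head phantom with ground-truth labels. The phantom models one
# fixed physical head (240 x 240 x 155 mm field of view, concentric
# ellipsoidal tissue shells) sampled at whatever grid is requested, so a
# 20-slice volume is simply the same head at 7.75 mm slice thickness.

PHANTOM_TISSUES <- c("background", "csf", "grey", "white", "skull", "tumor")
PHANTOM_FOV <- c(240, 240, 155)          # mm
PHANTOM_HEAD_AXES <- c(90, 95, 65)       # ellipsoid semi-axes, mm
# normalized-radius shells: white core, grey shell, CSF moat, skull annulus
PHANTOM_RHO <- c(white = 0.62, grey = 0.82, csf = 0.92, skull = 1.0)

#' Phantom specification
#'
#' @param shape Grid size `(rows, cols, slices)`; default `c(240, 240, 155)`.
#' @param spacing Voxel size in mm; default `240/rows, 240/cols, 155/slices`
#'   so every grid samples the same physical head.
#' @param means Named tissue mean intensities (8-bit scale):
#'   background/CSF/grey/white/skull/tumor. The tumor is hyperintense
#'   (contrast-enhanced appearance) by default.
#' @param sds Per-tissue intensity standard deviations.
#' @param n_tumors Number of tumor lumps (>= 0), default 1.
#' @param tumor_radius Radius range in mm, default `c(10, 25)`.
#' @param tumor_irregularity Relative amplitude of the star-convex boundary
#'   perturbation in `[0, 1)`, default 0.25.
#' @param bias_amplitude Multiplicative low-frequency intensity
#'   inhomogeneity strength, default 0.1.
#' @param noise_sd Additive Gaussian noise, default 6.
#' @param seed RNG seed; generation is fully deterministic given it.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(240, 240, 155), spacing = NULL,
                         means = c(background = 0, csf = 40, grey = 100,
                                   white = 150, skull = 230, tumor = 210),
                         sds = c(background = 3, csf = 6, grey = 7,
                                 white = 7, skull = 5, tumor = 8),
                         n_tumors = 1, tumor_radius = c(10, 25),
                         tumor_irregularity = 0.25, bias_amplitude = 0.1,
                         noise_sd = 6, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive sizes")
  if (is.null(spacing)) spacing <- PHANTOM_FOV / shape
  means <- means[PHANTOM_TISSUES]; sds <- sds[PHANTOM_TISSUES]
  if (any(is.na(means)) || any(is.na(sds)))
    stop("means and sds must name all tissues: ",
         paste(PHANTOM_TISSUES, collapse = ", "))
  if (anyDuplicated(means)) stop("tissue means must be distinct")
  others <- setdiff(PHANTOM_TISSUES, "tumor")
  sep <- abs(means[others] - means[["tumor"]]) > 2 * sds[others]
  if (!all(sep))
    stop("tumor mean must lie outside +/- 2 sd of every other tissue mean; ",
         "violated by: ", paste(others[!sep], collapse = ", "))
  if (n_tumors < 0) stop("n_tumors must be >= 0")
  if (length(tumor_radius) == 1L) tumor_radius <- rep(tumor_radius, 2L)
  if (tumor_irregularity < 0 || tumor_irregularity >= 1)
    stop("tumor_irregularity in [0, 1)")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 means = means, sds = sds, n_tumors = as.integer(n_tumors),
                 tumor_radius = as.numeric(tumor_radius),
                 tumor_irregularity = tumor_irregularity,
                 bias_amplitude = bias_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth directional perturbation field in [-1, 1] for star-convex lumps
make_lump_shape <- function(irregularity) {
  dirs <- matrix(stats::rnorm(9), 3L)
  dirs <- sweep(dirs, 2L, sqrt(colSums(dirs^2)), "/")
  ks <- sample(2:3, 3L, replace = TRUE)
  phs <- stats::runif(3L, 0, 2 * pi)
  ws <- stats::runif(3L, 0.2, 1)
  ws <- ws / sum(ws)
  function(u) {
    # u: n x 3 unit directions
    p <- 0
    for (j in 1:3) p <- p + ws[j] * cos(pi * ks[j] * (u %*% dirs[, j]) + phs[j])
    as.vector(p)
  }
}

#' Generate a phantom head volume with ground truth
#'
#' Builds the concentric-ellipsoid head (skull annulus enclosing CSF, grey
#' and white shells), places `n_tumors` star-convex hyperintense lumps
#' inside the white matter without mutual overlap (bounded rejection
#' sampling; failure raises a placement error), and renders intensities as
#' `(tissue mean + N(0, tissue sd)) * (1 + bias_amplitude * B) +
#' N(0, noise_sd)` with `B` a normalized low-frequency smooth field in
#' `[-1, 1]`. Fully deterministic given the spec seed.
#'
#' @param spec [phantom_spec].
#' @return List with `volume` ([mri_volume]), `labels` ([mri_volume] of
#'   integer tissue codes 0..5: background, CSF, grey, white, skull, tumor),
#'   `tumor_voxels` (count) and `tumors` (data.frame of centers/radii in mm).
#' @export
phantom_generate <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$shape[1L]; ny <- spec$shape[2L]; nz <- spec$shape[3L]
  sp <- spec$spacing
  fov <- spec$shape * sp
  cx <- fov / 2
  xs <- (seq_len(nx) - 0.5) * sp[1L] - cx[1L]
  ys <- (seq_len(ny) - 0.5) * sp[2L] - cx[2L]
  zs <- (seq_len(nz) - 0.5) * sp[3L] - cx[3L]
  ax <- PHANTOM_HEAD_AXES
  rho2 <- outer(outer((xs / ax[1L])^2, (ys / ax[2L])^2, "+"),
                (zs / ax[3L])^2, "+")
  rho <- sqrt(rho2)
  labels <- array(0L, dim = spec$shape)
  labels[rho <= PHANTOM_RHO[["skull"]]] <- 4L
  labels[rho <= PHANTOM_RHO[["csf"]]] <- 1L
  labels[rho <= PHANTOM_RHO[["grey"]]] <- 2L
  labels[rho <= PHANTOM_RHO[["white"]]] <- 3L

  with_seed(spec$seed, {
    tumors <- NULL
    if (spec$n_tumors > 0L) {
      centers <- matrix(0, 0L, 3L)
      radii <- numeric(0)
      shapes <- list()
      tries <- 0L
      while (length(radii) < spec$n_tumors) {
        tries <- tries + 1L
        if (tries > 200L)
          stop("placement error: could not fit ", spec$n_tumors,
               " non-overlapping tumors after 200 tries")
        r <- stats::runif(1L, spec$tumor_radius[1L], spec$tumor_radius[2L])
        r_eff <- r * (1 + spec$tumor_irregularity)
        margin <- r_eff / min(ax)
        rho_max <- PHANTOM_RHO[["white"]] - margin
        if (rho_max <= 0) next
        cand <- stats::runif(3L, -1, 1) * rho_max * ax
        if (sqrt(sum((cand / ax)^2)) > rho_max) next
        if (length(radii) > 0L) {
          gap <- sqrt(rowSums((centers - matrix(cand, nrow(centers), 3L,
                                                byrow = TRUE))^2))
          if (any(gap < radii * (1 + spec$tumor_irregularity) + r_eff +
                    2 * max(sp))) next
        }
        centers <- rbind(centers, cand)
        radii <- c(radii, r)
        shapes[[length(radii)]] <- make_lump_shape(spec$tumor_irregularity)
      }
      for (k in seq_along(radii)) {
        c_k <- centers[k, ]; r_k <- radii[k]
        r_out <- r_k * (1 + spec$tumor_irregularity)
        ix <- which(abs(xs - c_k[1L]) <= r_out)
        iy <- which(abs(ys - c_k[2L]) <= r_out)
        iz <- which(abs(zs - c_k[3L]) <= r_out)
        if (!length(ix) || !length(iy) || !length(iz)) next
        grid <- expand.grid(x = xs[ix], y = ys[iy], z = zs[iz])
        rel <- cbind(grid$x - c_k[1L], grid$y - c_k[2L], grid$z - c_k[3L])
        dist <- sqrt(rowSums(rel^2))
        u <- rel / pmax(dist, 1e-9)
        rdir <- r_k * (1 + spec$tumor_irregularity * shapes[[k]](u))
        inside <- dist <= rdir
        if (any(inside)) {
          idx <- as.matrix(expand.grid(ix, iy, iz))[inside, , drop = FALSE]
          sel <- labels[idx] == 3L   # only carve tumor out of white matter
          labels[idx[sel, , drop = FALSE]] <- 5L
        }
      }
      tumors <- data.frame(x = centers[, 1L], y = centers[, 2L],
                           z = centers[, 3L], radius = radii)
    }

    base <- spec$means[labels + 1L]
    if (any(spec$sds > 0))
      base <- base + stats::rnorm(length(labels), 0, spec$sds[labels + 1L])
    if (spec$bias_amplitude > 0) {
      fx <- stats::runif(3L, -1, 1); fy <- stats::runif(3L, -1, 1)
      fz <- stats::runif(3L, -1, 1)
      amp <- stats::runif(3L, 0.5, 1); ph <- stats::runif(3L, 0, 2 * pi)
      B <- 0
      for (m in 1:3) {
        arg <- outer(outer(2 * pi * fx[m] * (xs / fov[1L]),
                           2 * pi * fy[m] * (ys / fov[2L]), "+"),
                     2 * pi * fz[m] * (zs / fov[3L]), "+")
        B <- B + amp[m] * cos(arg + ph[m])
      }
      B <- B / max(abs(B))
      base <- base * (1 + spec$bias_amplitude * B)
    }
    if (spec$noise_sd > 0)
      base <- base + stats::rnorm(length(labels), 0, spec$noise_sd)
    vol <- array(base, dim = spec$shape)
  })

  list(volume = mri_volume(vol, spacing = sp),
       labels = mri_volume(array(as.double(labels), dim = spec$shape),
                           spacing = sp),
       tumor_voxels = sum(labels == 5L),
       tumors = tumors)
}

#' Ground-truth tumor mask
#'
#' @param labels Label volume (or array) from [phantom_generate].
#' @return Logical array of tumor voxels.
#' @export
tumor_truth <- function(labels) {
  arr <- if (inherits(labels, "mri_volume")) labels$data else labels
  arr == 5
}

#' Convenience: one phantom slice with its label map
#'
#' Generates the phantom volume and extracts an axial slice (the middle one
#' by default) together with its tissue label matrix.
#'
#' @param spec [phantom_spec].
#' @param index Axial slice index; default the middle slice.
#' @return List with `slice` ([mri_slice]), `labels` (integer matrix),
#'   `truth` (logical tumor mask matrix).
#' @export
phantom_slice <- function(spec = phantom_spec(), index = NULL) {
  ph <- phantom_generate(spec)
  if (is.null(index)) index <- ceiling(spec$shape[3L] / 2)
  lab <- ph$labels$data[, , index]
  list(slice = mri_slice(ph$volume$data[, , index],
                         spacing = spec$spacing[1:2], index = index),
       labels = lab,
       truth = lab == 5)
}
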