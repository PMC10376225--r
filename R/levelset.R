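# Geodesic level-set evolution: the contour is the zero set of a signed
# field phi (negative inside) advected by a curvature term, an edge-gated
# balloon force, and an edge-attraction term, all discretized explicitly.

#' Level-set evolution parameters
#'
#' @param Wa Advection (balloon) weight, > 0. Default 1.
#' @param Wc Curvature weight, > 0. Default 1.
#' @param nu Balloon speed along the outward normal, dimensionless: positive
#'   inflates the contour, negative deflates it. Default -0.3, shrinking a
#'   slightly dilated initialization onto the tumor edge.
#' @param dt Explicit time step; `NULL` (default) uses the stability value
#'   `1/(6 Wa Wc)` from [stability_dt].
#' @param max_iters Maximum iterations (default 300).
#' @param reinit_every Reinitialize phi to an exact signed distance of its
#'   current zero-sublevel set every this many iterations (default 20).
#' @param convergence_tol Stop when the fraction of zero-sublevel pixels
#'   changing between checks falls below this (default 1e-3).
#' @param check_every Convergence check cadence in iterations (default 10).
#' @param min_iters No convergence stop before this many iterations
#'   (default 50); slow contours can need several dozen iterations before
#'   the first pixel flips.
#' @param include_advection Include the `grad g . grad phi` edge-attraction
#'   term (default TRUE); without it contours overshoot weak edges.
#' @return List of class `level_set_params`.
#' @export
level_set_params <- function(Wa = 1, Wc = 1, nu = -0.3, dt = NULL,
                             max_iters = 300, reinit_every = 20,
                             convergence_tol = 1e-3, check_every = 10,
                             min_iters = 50, include_advection = TRUE) {
  if (Wa <= 0 || Wc <= 0) stop("Wa and Wc must be > 0")
  if (max_iters < 0) stop("max_iters must be >= 0")
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0")
  structure(list(Wa = Wa, Wc = Wc, nu = nu, dt = dt,
                 max_iters = as.integer(max_iters),
                 reinit_every = as.integer(reinit_every),
                 convergence_tol = convergence_tol,
                 check_every = as.integer(check_every),
                 min_iters = as.integer(min_iters),
                 include_advection = isTRUE(include_advection)),
            class = "level_set_params")
}

#' Stability time step
#'
#' `dt = 1 / (6 Wa Wc)`: the step shrinks as either weight grows, keeping
#' the explicit scheme stable; an explicit `dt` in the parameters overrides
#' it.
#'
#' @param p [level_set_params].
#' @return Time step.
#' @export
stability_dt <- function(p) {
  if (!is.null(p$dt)) return(p$dt)
  1 / (6 * p$Wa * p$Wc)
}

#' Geodesic edge-stopping map
#'
#' `g = 1 / (1 + (|grad(G_sigma * I)| / scale)^2)` with Gaussian
#' pre-smoothing at scale `sigma` and central-difference gradients: close to
#' 0 at strong edges, 1 in flat regions. `scale` sets the gradient magnitude
#' treated as a unit edge; the default 1 reproduces the plain
#' `1/(1 + |grad|^2)` form, while callers working on arbitrary intensity
#' scales (e.g. 8-bit MRI) should pass a few percent of the dynamic range so
#' that genuine edges give small `g` without freezing the whole edge
#' neighbourhood.
#'
#' @param s [mri_slice] or matrix.
#' @param sigma Gaussian scale in pixels (> 0). Default 1.5.
#' @param scale Gradient normalization (> 0). Default 1.
#' @return Matrix `g` in (0, 1] with attribute `sigma`.
#' @export
edge_indicator <- function(s, sigma = 1.5, scale = 1) {
  if (scale <= 0) stop("scale must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  m <- slice_data(s)
  size <- 2L * ceiling(3 * sigma) + 1L
  size <- min(size, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (size >= 3L) {
    brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
    m <- EBImage::imageData(EBImage::filter2(m, brush, boundary = "replicate"))
  }
  gx <- (shift_mat(m, 1L, 0L) - shift_mat(m, -1L, 0L)) / 2
  gy <- (shift_mat(m, 0L, 1L) - shift_mat(m, 0L, -1L)) / 2
  g <- 1 / (1 + (gx^2 + gy^2) / scale^2)
  attr(g, "sigma") <- sigma
  g
}

# Sussman reinitialization with the Russo-Smereka subcell fix: a few
# explicit iterations of phi_t = sign(phi0) (1 - |grad phi|) with Godunov
# upwinding away from the interface, while cells whose phi0 changes sign
# against a 4-neighbour are anchored to the local distance estimate
# phi0 / |grad phi0|. Unlike a distance transform of the zero-sublevel mask,
# this preserves the sub-pixel position of the interface, which long
# evolutions depend on.
reinit_phi <- function(phi, iters = 5L, dtau = 0.5) {
  phi0 <- phi
  sgn <- sign(phi0)
  band <- (phi0 * shift_mat(phi0, 1L, 0L) < 0) |
    (phi0 * shift_mat(phi0, -1L, 0L) < 0) |
    (phi0 * shift_mat(phi0, 0L, 1L) < 0) |
    (phi0 * shift_mat(phi0, 0L, -1L) < 0)
  gx0 <- (shift_mat(phi0, 1L, 0L) - shift_mat(phi0, -1L, 0L)) / 2
  gy0 <- (shift_mat(phi0, 0L, 1L) - shift_mat(phi0, 0L, -1L)) / 2
  D <- phi0 / pmax(sqrt(gx0^2 + gy0^2), 1e-8)
  s <- phi0 / sqrt(phi0^2 + 1)
  for (it in seq_len(iters)) {
    a <- phi - shift_mat(phi, -1L, 0L)   # backward x
    b <- shift_mat(phi, 1L, 0L) - phi    # forward x
    cc <- phi - shift_mat(phi, 0L, -1L)  # backward y
    d <- shift_mat(phi, 0L, 1L) - phi    # forward y
    gp <- sqrt(pmax(pmax(a, 0)^2, pmin(b, 0)^2) +
                 pmax(pmax(cc, 0)^2, pmin(d, 0)^2))
    gm <- sqrt(pmax(pmin(a, 0)^2, pmax(b, 0)^2) +
                 pmax(pmin(cc, 0)^2, pmax(d, 0)^2))
    grad <- ifelse(s > 0, gp, ifelse(s < 0, gm, 0))
    upd <- phi - dtau * s * (grad - 1)
    upd[band] <- phi[band] - dtau * (sgn[band] * abs(phi[band]) - D[band])
    phi <- upd
  }
  phi
}

#' Evolve the level-set field
#'
#' Explicit update
#' `phi <- phi + dt * [ g Wc kappa |grad phi| - g Wa nu |grad phi| +
#' grad g . grad phi ]` with curvature `kappa = div(grad phi / |grad phi|)`
#' by central differences (1e-8 norm guard), Godunov upwinding of the
#' balloon term on the sign of `g Wa nu`, and upwinding of the advection
#' term on the sign of the `g` gradient components. The field is
#' reinitialized to an exact signed distance every `reinit_every` iterations
#' and evolution stops at `max_iters` or when the zero-sublevel change
#' fraction drops below `convergence_tol`.
#'
#' @param phi Signed field (negative inside), same shape as `g`.
#' @param g Edge-stopping map from [edge_indicator].
#' @param p [level_set_params].
#' @return List with `phi` (evolved field) and `iters` (iterations used).
#' @export
evolve_level_set <- function(phi, g, p = level_set_params()) {
  if (!identical(dim(phi), dim(g)))
    stop("phi and g dimensions differ")
  dt <- stability_dt(p)
  gx <- (shift_mat(g, 1L, 0L) - shift_mat(g, -1L, 0L)) / 2
  gy <- (shift_mat(g, 0L, 1L) - shift_mat(g, 0L, -1L)) / 2
  eps <- 1e-8
  prev_mask <- phi < 0
  iters <- 0L
  for (it in seq_len(p$max_iters)) {
    px_f <- shift_mat(phi, 1L, 0L) - phi    # forward diff, rows
    px_b <- phi - shift_mat(phi, -1L, 0L)   # backward diff
    py_f <- shift_mat(phi, 0L, 1L) - phi
    py_b <- phi - shift_mat(phi, 0L, -1L)
    px_c <- (px_f + px_b) / 2
    py_c <- (py_f + py_b) / 2
    grad_c <- sqrt(px_c^2 + py_c^2)

    # curvature by central second differences
    pxx <- px_f - px_b
    pyy <- py_f - py_b
    pxy <- (shift_mat(phi, 1L, 1L) - shift_mat(phi, 1L, -1L) -
              shift_mat(phi, -1L, 1L) + shift_mat(phi, -1L, -1L)) / 4
    kappa <- (pxx * py_c^2 - 2 * px_c * py_c * pxy + pyy * px_c^2) /
      ((px_c^2 + py_c^2)^1.5 + eps)

    upd <- g * p$Wc * kappa * grad_c

    # balloon: phi_t += -F |grad phi| with outward speed F = g Wa nu
    F <- g * p$Wa * p$nu
    grad_plus <- sqrt(pmax(px_b, 0)^2 + pmin(px_f, 0)^2 +
                        pmax(py_b, 0)^2 + pmin(py_f, 0)^2)
    grad_minus <- sqrt(pmin(px_b, 0)^2 + pmax(px_f, 0)^2 +
                         pmin(py_b, 0)^2 + pmax(py_f, 0)^2)
    upd <- upd - (pmax(F, 0) * grad_plus + pmin(F, 0) * grad_minus)

    if (p$include_advection) {
      upd <- upd + pmax(gx, 0) * px_b + pmin(gx, 0) * px_f +
        pmax(gy, 0) * py_b + pmin(gy, 0) * py_f
    }

    phi <- phi + dt * upd
    iters <- it
    if (!all(is.finite(phi)))
      stop("numerical instability: non-finite phi at iteration ", it)
    if (p$reinit_every > 0L && it %% p$reinit_every == 0L)
      phi <- reinit_phi(phi)
    if (p$check_every > 0L && it %% p$check_every == 0L) {
      mask <- phi < 0
      changed <- sum(mask != prev_mask)
      denom <- max(1L, sum(mask))
      prev_mask <- mask
      if (it >= p$min_iters && changed / denom < p$convergence_tol) break
    }
  }
  list(phi = phi, iters = iters)
}

#' Extract the enclosed region of a level-set field
#'
#' @param phi Finite signed field.
#' @return Logical mask `phi < 0`.
#' @export
phi_to_mask <- function(phi) {
  if (!all(is.finite(phi))) stop("phi must be finite")
  phi < 0
}

#' Segment one slice by level-set refinement
#'
#' Composes [edge_indicator], [signed_distance_init], [evolve_level_set] and
#' [phi_to_mask]; an empty initial mask short-circuits to an empty output.
#' The evolution is fully deterministic.
#'
#' @param clean Preprocessed [mri_slice] or matrix supplying the edge map.
#' @param init_mask Initial contour mask (from the clustering stage).
#' @param p [level_set_params].
#' @param sigma Edge-map smoothing scale.
#' @param edge_scale Gradient normalization for [edge_indicator]; `NULL`
#'   (default) uses 1.
#' @return Logical mask with attribute `iters`.
#' @export
segment_slice <- function(clean, init_mask, p = level_set_params(),
                          sigma = 1.5, edge_scale = NULL) {
  if (!any(init_mask)) {
    out <- init_mask & FALSE
    attr(out, "iters") <- 0L
    return(out)
  }
  g <- edge_indicator(clean, sigma, scale = edge_scale %||% 1)
  phi <- signed_distance_init(init_mask)
  ev <- evolve_level_set(phi, g, p)
  out <- phi_to_mask(ev$phi)
  attr(out, "iters") <- ev$iters
  out
}
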