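# Quantum computing mechanism (QCM): scalar values in [lo, hi] are encoded as
# a qubit -- a scalar q in [-1, 1] plus a unit-norm amplitude pair (alpha,
# beta) -- updated by a rotation gate and decoded back to a real value. The
# QCM replaces the dragonfly algorithm's inertia and Levy-flight behaviors.

#' Search bounds
#'
#' @param lo,hi Finite bounds with `lo < hi` (intensity units).
#' @return List of class `qda_bounds`.
#' @export
qda_bounds <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("bounds must be finite with lo < hi")
  structure(list(lo = lo, hi = hi), class = "qda_bounds")
}

# Bijection between the quantized scalar and the amplitude pair: q in [-1, 1]
# maps to beta = sin(pi (q + 1) / 4) in [0, 1], alpha = sqrt(1 - beta^2). The
# map is smooth and monotone, so rotating the amplitudes toward larger beta
# moves q upward.
q_to_amplitudes <- function(q) {
  beta <- sin(pi * (q + 1) / 4)
  list(alpha = sqrt(pmax(1 - beta^2, 0)), beta = beta)
}

amplitude_to_q <- function(beta) {
  4 / pi * asin(clamp(beta, 0, 1)) - 1
}

#' Quantize a real value into qubit format
#'
#' `q = (2 dx - (hi + lo)) / (hi - lo)` after clamping `dx` into
#' `[lo, hi]`; the amplitude pair satisfies `alpha^2 + beta^2 = 1`.
#' Vectorized over `dx`.
#'
#' @param dx Numeric value(s).
#' @param b [qda_bounds].
#' @return List of class `qubit` with fields `q`, `alpha`, `beta`.
#' @export
quantize <- function(dx, b) {
  dx <- clamp(dx, b$lo, b$hi)
  q <- (2 * dx - (b$hi + b$lo)) / (b$hi - b$lo)
  amp <- q_to_amplitudes(q)
  structure(list(q = q, alpha = amp$alpha, beta = amp$beta), class = "qubit")
}

#' Apply the quantum rotation gate
#'
#' Multiplies the amplitude pair by the rotation matrix
#' `[[cos t, -sin t], [sin t, cos t]]` (norm preserved exactly) and recovers
#' `q` from the rotated beta amplitude. `theta` may be a vector matching `q`.
#'
#' @param qb A `qubit`.
#' @param theta Rotation angle(s) in radians.
#' @return Rotated `qubit`.
#' @export
rotate_qubit <- function(qb, theta) {
  a <- cos(theta) * qb$alpha - sin(theta) * qb$beta
  b <- sin(theta) * qb$alpha + cos(theta) * qb$beta
  structure(list(q = amplitude_to_q(b), alpha = a, beta = b), class = "qubit")
}

#' Dequantize a qubit back to a real value
#'
#' `dx = (hi (1 + q) + lo (1 - q)) / 2`; exact inverse of [quantize] on
#' `[lo, hi]`.
#'
#' @param qb A `qubit`.
#' @param b [qda_bounds].
#' @return Numeric value(s).
#' @export
dequantize <- function(qb, b) {
  (b$hi * (1 + qb$q) + b$lo * (1 - qb$q)) / 2
}

# Full QCM pass: clamp -> quantize -> rotate (sign pointing q toward
# target_q) -> dequantize. theta_mag >= 0; target_q NULL means rotate by
# +theta_mag unconditionally.
qcm_transform <- function(dx, b, theta_mag, target_q = NULL) {
  qb <- quantize(dx, b)
  th <- if (is.null(target_q)) rep(theta_mag, length(qb$q))
        else theta_mag * sign(target_q - qb$q)
  dequantize(rotate_qubit(qb, th), b)
}

#' Mantegna Levy step draws
#'
#' Heavy-tailed step lengths `0.01 * u / |v|^(1/beta)` with
#' `u ~ N(0, sigma_u^2)`, `v ~ N(0, 1)` and the Mantegna scale
#' `sigma_u = [Gamma(1+b) sin(pi b/2) / (Gamma((1+b)/2) b 2^((b-1)/2))]^(1/b)`;
#' the 0.01 prefactor follows the reference dragonfly implementation.
#'
#' @param n Number of draws.
#' @param beta Stability exponent in (1, 2].
#' @return Numeric vector of signed step lengths.
#' @export
levy_mantegna <- function(n, beta = 1.5) {
  if (!(beta > 1 && beta <= 2)) stop("levy_beta must lie in (1, 2]")
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(n, sd = sigma_u)
  v <- stats::rnorm(n)
  0.01 * u / abs(v)^(1 / beta)
}

#' Levy flight position update through the QCM
#'
#' For a neighborless dragonfly: quantize the position, rotate toward the
#' food target (unsigned rotation when no target is supplied), dequantize,
#' then add a Mantegna Levy perturbation scaled by the current position and
#' clamp into bounds. Draws from the current RNG stream.
#'
#' @param x Position scalar(s) within bounds.
#' @param b [qda_bounds].
#' @param theta Rotation magnitude (radians).
#' @param cfg [qda_config] supplying `levy_beta`.
#' @param target_q Optional quantized food value steering the rotation sign.
#' @return Updated position(s), always within `[lo, hi]`.
#' @export
levy_qcm_update <- function(x, b, theta, cfg, target_q = NULL) {
  xr <- qcm_transform(x, b, theta, target_q)
  clamp(xr + levy_mantegna(length(xr), cfg$levy_beta) * x, b$lo, b$hi)
}
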