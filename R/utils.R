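# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a per-slice RNG seed from a global seed
#'
#' One global seed deterministically derives every module seed: the slice with
#' index `i` (1-based) gets `(seed * 48271 + i * 9973) mod 2147483629`, which
#' stays inside the 32-bit integer range R requires.
#'
#' @param seed Integer global seed.
#' @param index Integer stream index (e.g. slice number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483629 * 48271 + as.double(index) * 9973) %%
               2147483629)
}

# Evaluate `expr` with the global RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so library calls never perturb user streams.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Shift a matrix by (dr, dc) with replicated (Neumann) boundaries.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- clamp(seq_len(nr) + dr, 1L, nr)
  ci <- clamp(seq_len(nc) + dc, 1L, nc)
  m[ri, ci, drop = FALSE]
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

as_binary <- function(m) {
  storage.mode(m) <- "double"
  m
}

# EBImage wrappers returning plain matrices.
eb_dilate <- function(mask, brush) {
  EBImage::imageData(EBImage::dilate(as_binary(mask), brush)) > 0.5
}
eb_erode <- function(mask, brush) {
  EBImage::imageData(EBImage::erode(as_binary(mask), brush)) > 0.5
}
eb_opening <- function(mask, brush) {
  EBImage::imageData(EBImage::opening(as_binary(mask), brush)) > 0.5
}
eb_fill_holes <- function(mask) {
  EBImage::imageData(EBImage::fillHull(as_binary(mask))) > 0.5
}
eb_label <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(as_binary(mask)))
  storage.mode(lab) <- "integer"
  lab
}

largest_component <- function(mask) {
  lab <- eb_label(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  lab == which.max(sizes)
}

# Pixels of `mask` with at least one 4-neighbour outside the mask (2D) or
# 6-neighbour outside (3D). Works on logical matrices and 3D arrays.
boundary_voxels <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) {
    inner <- shift_mat(mask, 1L, 0L) & shift_mat(mask, -1L, 0L) &
      shift_mat(mask, 0L, 1L) & shift_mat(mask, 0L, -1L)
    # border pixels of the array count as boundary when set
    inner[1L, ] <- FALSE; inner[d[1L], ] <- FALSE
    inner[, 1L] <- FALSE; inner[, d[2L]] <- FALSE
    mask & !inner
  } else if (length(d) == 3L) {
    shift3 <- function(a, dr, dc, ds) {
      ri <- clamp(seq_len(d[1L]) + dr, 1L, d[1L])
      ci <- clamp(seq_len(d[2L]) + dc, 1L, d[2L])
      si <- clamp(seq_len(d[3L]) + ds, 1L, d[3L])
      a[ri, ci, si, drop = FALSE]
    }
    inner <- shift3(mask, 1L, 0L, 0L) & shift3(mask, -1L, 0L, 0L) &
      shift3(mask, 0L, 1L, 0L) & shift3(mask, 0L, -1L, 0L) &
      shift3(mask, 0L, 0L, 1L) & shift3(mask, 0L, 0L, -1L)
    inner[c(1L, d[1L]), , ] <- FALSE
    inner[, c(1L, d[2L]), ] <- FALSE
    inner[, , c(1L, d[3L])] <- FALSE
    mask & !inner
  } else {
    stop("boundary_voxels() expects a 2D or 3D mask")
  }
}

slice_data <- function(s) {
  if (inherits(s, "mri_slice")) s$data else s
}
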