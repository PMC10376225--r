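# Initial contour extraction: turn the tumor-cluster assignment into a
# cleaned binary mask, an ordered boundary point set, and a signed-distance
# level-set field (negative inside).

#' Tumor mask from cluster labels
#'
#' Builds the binary mask of pixels labeled `tumor_idx` and cleans it:
#' morphological opening with a disc of radius 1 removes speckle, connected
#' components below `min_area` pixels are dropped, and (optionally)
#' components touching the brain-mask border are discarded -- when skull
#' stripping retains the bright skull remnant it lands in the brightest
#' cluster as a band hugging the mask boundary, whereas genuine tumor lumps
#' are interior. Multiple lumps are retained.
#'
#' @param labels Integer label matrix covering the slice (0 allowed outside
#'   the brain), or a label vector paired with `mask_index`.
#' @param tumor_idx Cluster index to extract.
#' @param shape Slice dimensions, required when `labels` is a vector.
#' @param mask_index Linear pixel indices of `labels` within the slice grid
#'   (used when clustering ran on brain pixels only).
#' @param min_area Minimum component area in pixels (default 20).
#' @param cleanup Apply opening + area filtering (default TRUE).
#' @param brain_mask Logical matrix enabling border-component exclusion.
#' @param exclude_border Drop components 4-adjacent to the outside of
#'   `brain_mask` (default TRUE; ignored without a brain mask).
#' @return Logical matrix (possibly empty, with attribute `empty = TRUE` and
#'   a warning flag when nothing survives cleaning).
#' @export
tumor_mask <- function(labels, tumor_idx, shape = NULL, mask_index = NULL,
                       min_area = 20, cleanup = TRUE, brain_mask = NULL,
                       exclude_border = TRUE) {
  if (is.matrix(labels)) {
    m <- labels == tumor_idx
  } else {
    if (is.null(shape) || is.null(mask_index))
      stop("vector labels need `shape` and `mask_index`")
    m <- matrix(FALSE, shape[1L], shape[2L])
    m[mask_index[labels == tumor_idx]] <- TRUE
  }
  if (cleanup && any(m)) {
    m <- eb_opening(m, disc_brush(1L))
    if (any(m)) {
      lab <- eb_label(m)
      sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
      keep <- which(sizes >= min_area)
      if (exclude_border && !is.null(brain_mask) && length(keep) > 0L) {
        rim <- brain_mask & boundary_voxels(brain_mask)
        rim <- eb_dilate(rim, disc_brush(1L))
        touching <- unique(lab[rim & lab > 0L])
        keep <- setdiff(keep, touching)
      }
      m <- matrix(lab %in% keep, nrow(m), ncol(m))
    }
  }
  if (!any(m)) attr(m, "empty") <- TRUE
  m
}

# 8-neighbour offsets in clockwise Moore order.
moore_offsets <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                        ncol = 2L, byrow = TRUE)

trace_boundary <- function(pts) {
  # Order a set of boundary pixels (n x 2 matrix) into closed chains by
  # Moore-neighbor walking; disjoint loops are concatenated in discovery
  # order.
  n <- nrow(pts)
  key <- paste(pts[, 1L], pts[, 2L])
  remaining <- stats::setNames(seq_len(n), key)
  out <- matrix(0L, n, 2L)
  filled <- 0L
  while (length(remaining) > 0L) {
    # start at topmost-leftmost remaining point
    idx <- remaining[order(pts[remaining, 1L], pts[remaining, 2L])][1L]
    cur <- pts[idx, ]
    remaining <- remaining[names(remaining) != paste(cur[1L], cur[2L])]
    filled <- filled + 1L
    out[filled, ] <- cur
    repeat {
      nb_keys <- paste(cur[1L] + moore_offsets[, 1L],
                       cur[2L] + moore_offsets[, 2L])
      hit <- nb_keys[nb_keys %in% names(remaining)]
      if (length(hit) == 0L) break
      idx <- remaining[[hit[1L]]]
      cur <- pts[idx, ]
      remaining <- remaining[names(remaining) != hit[1L]]
      filled <- filled + 1L
      out[filled, ] <- cur
    }
  }
  out
}

#' Boundary contour of a binary mask
#'
#' The contour point set is exactly the mask's 4-connected boundary (pixels
#' with at least one non-mask 4-neighbour); points are ordered along each
#' closed boundary by Moore-neighbour walking, one chain per connected
#' component (hole boundaries form their own chains).
#'
#' @param m Nonempty logical matrix.
#' @return Object of class `contour_points`: list with `points` (ordered
#'   n x 2 matrix of (row, col)) and `components` (per-point component id).
#' @export
mask_to_contour <- function(m) {
  if (!any(m)) stop("degenerate input: empty mask has no contour")
  b <- boundary_voxels(m)
  lab <- eb_label(m)
  comp_ids <- sort(unique(lab[b & lab > 0L]))
  pts_all <- NULL
  comps <- integer(0)
  for (cid in comp_ids) {
    sel <- which(b & lab == cid, arr.ind = TRUE)
    ordered <- trace_boundary(sel)
    pts_all <- rbind(pts_all, ordered)
    comps <- c(comps, rep(cid, nrow(ordered)))
  }
  structure(list(points = pts_all, components = comps),
            class = "contour_points")
}

#' @export
print.contour_points <- function(x, ...) {
  cat("<contour_points>", nrow(x$points), "boundary points,",
      length(unique(x$components)), "component(s)\n")
  invisible(x)
}

#' Signed-distance level-set initialization
#'
#' Exact Euclidean signed distance: positive outside the mask (distance to
#' the mask), negative inside (distance to the complement); the zero level
#' set lies on the mask boundary, and `|grad phi|` is approximately 1 near
#' it. An empty mask yields a uniformly positive field at a large constant.
#'
#' @param m Logical matrix (or 3D array).
#' @return Numeric field `phi` of the same shape.
#' @export
signed_distance_init <- function(m) {
  if (!any(m)) return(array(max(dim(m)) + 0, dim = dim(m)))
  if (all(m)) return(array(-(max(dim(m)) + 0), dim = dim(m)))
  outside <- EBImage::imageData(EBImage::distmap(as_binary(!m)))
  inside <- EBImage::imageData(EBImage::distmap(as_binary(m)))
  outside - inside
}
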