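# End-to-end pipeline: preprocess -> k-means -> QDA refinement -> initial
# contour -> level-set segmentation, slice by slice, restacked to a volume.

#' Pipeline configuration
#'
#' Nested configuration mirroring each stage; unknown keys in the overrides
#' are rejected before any computation starts.
#'
#' @param preprocess [preprocess_config].
#' @param K Number of intensity clusters (default 4).
#' @param tumor_strategy Tumor-cluster selection rule (see
#'   [identify_tumor_cluster]).
#' @param qda [qda_config]; its seed is overridden per slice, derived from
#'   the global seed.
#' @param min_area,cleanup,exclude_border Contour cleanup (see [tumor_mask]).
#' @param comp_contrast_frac Tumor-presence filter: each candidate component
#'   must be locally hyperintense, i.e. its mean intensity must exceed the
#'   mean of its surrounding ring (3 px dilation within the brain) by this
#'   fraction of the brain dynamic range (default 0.1; 0 disables). Slices
#'   holding fewer tissue classes than `K` otherwise split a bulk tissue and
#'   misread its brighter half -- a bias-field bump -- as tumor.
#' @param init_dilate Dilation radius (pixels) applied to the cluster mask
#'   before level-set evolution so the contour approaches the tumor edge
#'   from outside (default 2).
#' @param levelset [level_set_params].
#' @param sigma Edge-map smoothing scale (default 1.5 px).
#' @param edge_scale_frac Gradient normalization for the edge map as a
#'   fraction of the brain-pixel dynamic range (default 0.02): a gradient of
#'   2% of the range per pixel counts as a unit edge, so tissue boundaries
#'   produce small `g` without freezing their whole smoothed neighbourhood.
#' @param cluster_source `"diffused"` (default) or `"equalized"`: which
#'   preprocessed image feeds clustering and the edge map. Equalization is a
#'   rank transform that flattens the intensity modes clustering relies on,
#'   so the diffused image is the default; the equalized slice is still
#'   computed for contrast inspection.
#' @param plane Slicing plane (default axial).
#' @param seed Global seed; per-slice seeds derive from it via
#'   [derive_seed].
#' @param verbose Print per-slice progress.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(), K = 4,
                            tumor_strategy = "brightest",
                            qda = qda_config(), min_area = 20,
                            cleanup = TRUE, exclude_border = TRUE,
                            comp_contrast_frac = 0.1,
                            init_dilate = 2, levelset = level_set_params(),
                            sigma = 1.5, edge_scale_frac = 0.02,
                            cluster_source = c("diffused", "equalized"),
                            plane = "axial", seed = 1L, verbose = FALSE) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(qda, "qda_config"),
            inherits(levelset, "level_set_params"))
  structure(list(preprocess = preprocess, K = as.integer(K),
                 tumor_strategy = tumor_strategy, qda = qda,
                 min_area = min_area, cleanup = isTRUE(cleanup),
                 exclude_border = isTRUE(exclude_border),
                 comp_contrast_frac = comp_contrast_frac,
                 init_dilate = as.integer(init_dilate), levelset = levelset,
                 sigma = sigma, edge_scale_frac = edge_scale_frac,
                 cluster_source = match.arg(cluster_source),
                 plane = match.arg(plane, c("axial", "coronal", "sagittal")),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

segment_one_slice <- function(sl, cfg, slice_seed) {
  t0 <- proc.time()[["elapsed"]]
  pp <- preprocess_slice(sl, cfg$preprocess)
  empty_out <- function(reason) {
    list(mask = matrix(FALSE, nrow(sl$data), ncol(sl$data)),
         brain_mask = pp$brain_mask, empty = TRUE, reason = reason,
         fitness = NA_real_, kmeans_fitness = NA_real_,
         history_len = 0L, ls_iters = 0L,
         time = proc.time()[["elapsed"]] - t0)
  }
  if (pp$empty) return(empty_out("no brain"))
  src <- if (cfg$cluster_source == "diffused") pp$diffused else pp$clean
  pix <- src$data[pp$brain_mask]
  if (length(unique(pix)) < cfg$K) return(empty_out("too few intensities"))
  km <- kmeans_fit(pix, K = cfg$K)
  qcfg <- cfg$qda
  qcfg$seed <- slice_seed
  opt <- qda_optimize(pix, km, cfg = qcfg)
  tumor_idx <- identify_tumor_cluster(opt$best, strategy = cfg$tumor_strategy)
  tm <- tumor_mask(opt$best$labels, tumor_idx,
                   shape = dim(sl$data), mask_index = which(pp$brain_mask),
                   min_area = cfg$min_area, cleanup = cfg$cleanup,
                   brain_mask = pp$brain_mask,
                   exclude_border = cfg$exclude_border)
  if (!any(tm)) return(empty_out("no tumor cluster"))
  if (cfg$comp_contrast_frac > 0) {
    lab <- eb_label(tm)
    rng <- diff(range(pix))
    for (cid in seq_len(max(lab))) {
      comp <- lab == cid
      ring <- eb_dilate(comp, disc_brush(3L)) & pp$brain_mask & !comp
      if (!any(ring)) next
      if (stats::median(src$data[comp]) - stats::median(src$data[ring]) <
            cfg$comp_contrast_frac * rng)
        tm[comp] <- FALSE
    }
    if (!any(tm)) return(empty_out("no tumor cluster"))
  }
  init <- if (cfg$init_dilate > 0L) eb_dilate(tm, disc_brush(cfg$init_dilate))
          else tm
  init <- init & pp$brain_mask
  escale <- max(cfg$edge_scale_frac * diff(range(pix)), 1e-8)
  seg <- segment_slice(src, init, cfg$levelset, cfg$sigma,
                       edge_scale = escale)
  list(mask = seg & TRUE, brain_mask = pp$brain_mask, empty = FALSE,
       reason = "", fitness = opt$fitness,
       kmeans_fitness = qda_fitness(km$centroids, pix),
       history_len = length(opt$history),
       ls_iters = attr(seg, "iters") %||% 0L,
       time = proc.time()[["elapsed"]] - t0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full segmentation pipeline on a volume
#'
#' Per slice: preprocessing, k-means-seeded QDA clustering, tumor-cluster
#' contour initialization, and level-set refinement; per-slice masks are
#' restacked into a volume. Slices without brain (or without a surviving
#' tumor component) yield empty masks with a warning flag rather than
#' errors. Identical config + seed produces a bit-identical output volume.
#'
#' @param input Path to a NIfTI volume, or an [mri_volume].
#' @param cfg [pipeline_config].
#' @param output Optional path; the segmentation is written there as a 0/1
#'   NIfTI mask.
#' @return Object of class `qda_segmentation`: `mask` ([mri_volume] of 0/1),
#'   `brain_mask` ([mri_volume]), `report` (per-slice data.frame), `config`,
#'   `n_components` (3D 6-connected component count of the mask).
#' @export
run_pipeline <- function(input, cfg = pipeline_config(), output = NULL) {
  vol <- if (inherits(input, "mri_volume")) input else load_volume(input)
  slices <- volume_to_slices(vol, cfg$plane)
  n <- length(slices)
  masks <- vector("list", n)
  brain <- vector("list", n)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    res <- segment_one_slice(slices[[k]], cfg, derive_seed(cfg$seed, k))
    masks[[k]] <- res$mask
    brain[[k]] <- res$brain_mask
    rows[[k]] <- data.frame(slice = k, empty = res$empty, reason = res$reason,
                            fitness = res$fitness,
                            kmeans_fitness = res$kmeans_fitness,
                            history_len = res$history_len,
                            ls_iters = res$ls_iters, time = res$time)
    if (cfg$verbose)
      message(sprintf("slice %d/%d: %s (%.2fs)", k, n,
                      if (res$empty) res$reason else "segmented",
                      res$time))
  }
  mask_vol <- slices_to_volume(lapply(masks, function(m) m * 1), vol,
                               cfg$plane)
  brain_vol <- slices_to_volume(lapply(brain, function(m) m * 1), vol,
                                cfg$plane)
  if (!is.null(output)) save_mask(output, mask_vol$data != 0, vol)
  structure(list(mask = mask_vol, brain_mask = brain_vol,
                 report = do.call(rbind, rows), config = cfg,
                 n_components = count_components_3d(mask_vol$data != 0)),
            class = "qda_segmentation")
}

# 6-connected 3D component count via union of per-slice labels
count_components_3d <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) return(max(eb_label(mask)))
  labs <- vector("list", d[3L])
  offset <- 0L
  for (k in seq_len(d[3L])) {
    l <- eb_label(mask[, , k])
    l[l > 0L] <- l[l > 0L] + offset
    offset <- max(offset, max(l))
    labs[[k]] <- l
  }
  if (offset == 0L) return(0L)
  parent <- seq_len(offset)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(d[3L] - 1L)) {
    a <- labs[[k]]; b <- labs[[k + 1L]]
    both <- a > 0L & b > 0L
    if (any(both)) {
      pairs <- unique(cbind(a[both], b[both]))
      for (r in seq_len(nrow(pairs))) {
        ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  used <- unique(unlist(lapply(labs, function(l) unique(l[l > 0L]))))
  length(unique(vapply(used, find, integer(1L))))
}

#' @export
print.qda_segmentation <- function(x, ...) {
  nseg <- sum(!x$report$empty)
  cat("<qda_segmentation>", nrow(x$report), "slices,", nseg,
      "segmented,", x$n_components, "tumor component(s)\n")
  cat("  mask voxels:", sum(x$mask$data != 0), "\n")
  invisible(x)
}

#' @export
summary.qda_segmentation <- function(object, ...) {
  rep <- object$report
  cat("Pipeline run over", nrow(rep), "slices\n")
  cat("  segmented:", sum(!rep$empty), "  empty:", sum(rep$empty), "\n")
  if (any(!rep$empty)) {
    cat("  median QDA fitness:",
        signif(stats::median(rep$fitness[!rep$empty]), 5), "\n")
    cat("  median level-set iterations:",
        stats::median(rep$ls_iters[!rep$empty]), "\n")
  }
  cat("  total time:", signif(sum(rep$time), 4), "s\n")
  invisible(object)
}

#' Evaluate a segmentation against ground truth
#'
#' Loads both volumes (paths or [mri_volume]s), checks shapes, and reports
#' the full metric suite; optionally writes a JSON or CSV report.
#'
#' @param pred,truth NIfTI paths or [mri_volume]s (nonzero = mask).
#' @param region Optional region mask restricting the rate domain.
#' @param spacing Optional spacing override for HD95 (default: pixels).
#' @param out Optional report path ending in `.json` or `.csv`.
#' @return Metric list from [evaluate_segmentation].
#' @export
run_evaluate <- function(pred, truth, region = NULL, spacing = NULL,
                         out = NULL) {
  pv <- if (inherits(pred, "mri_volume")) pred else load_volume(pred)
  tv <- if (inherits(truth, "mri_volume")) truth else load_volume(truth)
  if (!identical(dim(pv$data), dim(tv$data)))
    stop("prediction and truth volume shapes differ")
  res <- evaluate_segmentation(pv$data != 0, tv$data != 0,
                               spacing = spacing, region = region)
  if (!is.null(out)) {
    flat <- res[c("accuracy", "recall", "precision", "specificity",
                  "dice", "hd95", "accuracy_whole")]
    if (grepl("\\.json$", out)) {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("jsonlite required for JSON reports")
      jsonlite::write_json(flat, out, auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.csv(data.frame(metric = names(flat),
                                  value = unlist(flat)),
                       out, row.names = FALSE)
    }
  }
  res
}
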