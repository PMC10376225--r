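# Intensity clustering: deterministic 1D k-means used to seed the dragonfly
# swarm with tissue-centroid "food sources".

# Compress an intensity vector into (values, weights); exact when the data
# are discrete, 512-bin otherwise. Used for the DP seed and swarm fitness.
compress_pixels <- function(pixels, max_levels = 512L) {
  vals <- sort(unique(pixels))
  if (length(vals) <= max_levels) {
    w <- tabulate(match(pixels, vals), nbins = length(vals))
    return(list(values = vals, weights = as.double(w)))
  }
  rng <- range(pixels)
  bin <- pmin(max_levels, 1L + floor((pixels - rng[1L]) / diff(rng) * max_levels))
  w <- tabulate(bin, nbins = max_levels)
  keep <- w > 0L
  centers <- vapply(which(keep), function(b) mean(pixels[bin == b]), numeric(1))
  list(values = centers, weights = as.double(w[keep]))
}

# Exact weighted 1D K-partition minimizing SSE (dynamic programming over
# sorted values; optimal 1D clusters are contiguous). Returns centroids.
dp_seed_centroids <- function(values, weights, K) {
  U <- length(values)
  stopifnot(U >= K)
  W <- cumsum(weights)
  S1 <- cumsum(weights * values)
  S2 <- cumsum(weights * values^2)
  seg_cost <- function(i, j) {
    # weighted SSE of values[i..j]; i may be a vector
    w <- W[j] - ifelse(i > 1L, W[i - 1L], 0)
    s1 <- S1[j] - ifelse(i > 1L, S1[i - 1L], 0)
    s2 <- S2[j] - ifelse(i > 1L, S2[i - 1L], 0)
    pmax(s2 - s1^2 / w, 0)
  }
  cost <- matrix(Inf, nrow = K, ncol = U)
  back <- matrix(1L, nrow = K, ncol = U)
  cost[1L, ] <- seg_cost(1L, seq_len(U))
  if (K > 1L) {
    for (k in 2:K) {
      for (j in k:U) {
        i <- k:j                      # last segment starts at i
        tot <- cost[k - 1L, i - 1L] + seg_cost(i, j)
        b <- which.min(tot)
        cost[k, j] <- tot[b]
        back[k, j] <- i[b]
      }
    }
  }
  cuts <- integer(K + 1L)
  cuts[K + 1L] <- U
  j <- U
  for (k in K:1L) {
    i <- back[k, j]
    cuts[k] <- i - 1L
    j <- i - 1L
  }
  vapply(seq_len(K), function(k) {
    idx <- (cuts[k] + 1L):cuts[k + 1L]
    sum(weights[idx] * values[idx]) / sum(weights[idx])
  }, numeric(1))
}

#' Assign pixels to their nearest centroid
#'
#' Euclidean (absolute) distance on intensity; ties go to the lowest centroid
#' index.
#'
#' @param pixels Numeric vector of intensities.
#' @param centroids Nonempty numeric vector.
#' @return Integer labels in `1..length(centroids)`.
#' @export
assign_clusters <- function(pixels, centroids) {
  if (length(centroids) < 1L) stop("centroids must be nonempty")
  D <- abs(outer(pixels, centroids, "-"))
  max.col(-D, ties.method = "first")
}

cluster_model <- function(centroids, labels, pixels, K, sse_trace = numeric(0),
                          iterations = NA_integer_, converged = NA) {
  ord <- order(centroids)
  centroids <- centroids[ord]
  relab <- match(seq_along(centroids), ord)
  labels <- relab[labels]
  resid <- pixels - centroids[labels]
  structure(list(centroids = centroids,
                 labels = labels,
                 objective = sum(abs(resid)),
                 sse = sum(resid^2),
                 K = as.integer(K),
                 n = length(pixels),
                 pixel_mean = mean(pixels),
                 sse_trace = sse_trace,
                 iterations = iterations,
                 converged = converged),
            class = "tissue_clusters")
}

#' @export
print.tissue_clusters <- function(x, ...) {
  cat("<tissue_clusters> K =", x$K, "on", x$n, "pixels\n")
  cat("  centroids:", paste(signif(x$centroids, 5), collapse = ", "), "\n")
  cat("  objective (sum |d|):", signif(x$objective, 6),
      " SSE:", signif(x$sse, 6), "\n")
  invisible(x)
}

#' K-means over pixel intensities
#'
#' Lloyd iteration on 1D intensities: assign each pixel to the nearest
#' centroid, recompute centroids as cluster means, stop when the largest
#' centroid shift drops below `tol` or after `max_iter` sweeps. Seeding is
#' deterministic: the exact weighted 1D dynamic-programming optimum of the
#' intensity histogram (exact for discrete data, 512-bin otherwise), from
#' which Lloyd cannot increase the within-cluster sum of squares. Empty
#' clusters are repaired by relocating the centroid to the pixel farthest
#' from its current centroid, keeping K constant.
#'
#' @param pixels Numeric intensities with at least `K` distinct values.
#' @param K Number of clusters (>= 2); 4 matches the CSF-or-background /
#'   grey / white / tumor tissue model.
#' @param tol Convergence tolerance on centroid movement; default `1e-4`
#'   of the intensity dynamic range.
#' @param max_iter Maximum Lloyd sweeps (default 100).
#' @param seed Unused by the deterministic seeding; kept so callers can treat
#'   all clustering entry points uniformly.
#' @return A `tissue_clusters` object: ascending `centroids`, per-pixel
#'   `labels`, `objective` (sum of absolute deviations), `sse`, and the
#'   per-iteration `sse_trace` (monotone non-increasing).
#' @export
kmeans_fit <- function(pixels, K = 4, tol = NULL, max_iter = 100, seed = NULL) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  nuniq <- length(unique(pixels))
  if (nuniq < K)
    stop("degenerate input: only ", nuniq, " distinct values for K = ", K)
  rng <- range(pixels)
  if (is.null(tol)) tol <- 1e-4 * max(diff(rng), .Machine$double.eps)
  comp <- compress_pixels(pixels)
  cents <- sort(dp_seed_centroids(comp$values, comp$weights, K))
  sse_trace <- numeric(0)
  labels <- assign_clusters(pixels, cents)
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    newc <- cents
    for (k in seq_len(K)) {
      xk <- pixels[labels == k]
      if (length(xk) == 0L) {
        # farthest-point repair keeps K constant
        d <- abs(pixels - cents[labels])
        newc[k] <- pixels[which.max(d)]
      } else newc[k] <- mean(xk)
    }
    shift <- max(abs(newc - cents))
    cents <- newc
    labels <- assign_clusters(pixels, cents)
    sse_trace <- c(sse_trace, sum((pixels - cents[labels])^2))
    if (shift < tol) { converged <- TRUE; break }
  }
  cluster_model(cents, labels, pixels, K, sse_trace = sse_trace,
                iterations = iterations, converged = converged)
}

#' Pick the tumor cluster
#'
#' `"brightest"` selects the cluster with the largest centroid (the default:
#' contrast-enhancing tumor is hyperintense); `"outlier"` selects the
#' centroid farthest from the brain mean intensity.
#'
#' @param cm A `tissue_clusters` (or [qda_cluster] fit).
#' @param strategy `"brightest"` or `"outlier"`.
#' @param reference_mean Brain mean intensity for the outlier rule; defaults
#'   to the model's stored pixel mean.
#' @return Cluster index (1-based).
#' @export
identify_tumor_cluster <- function(cm, strategy = c("brightest", "outlier"),
                                   reference_mean = NULL) {
  strategy <- match.arg(strategy)
  cents <- cm$centroids
  if (strategy == "brightest") return(which.max(cents))
  if (is.null(reference_mean)) reference_mean <- cm$pixel_mean
  which.max(abs(cents - reference_mean))
}
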