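# Shared fixtures, built in code. The small phantom keeps unit tests fast;
# its middle slice has all six tissues and a single hyperintense tumor.

small_phantom_spec <- function(seed = 3, ...) {
  phantom_spec(shape = c(120, 120, 9), seed = seed, ...)
}

# memoised mid-slice fixture (generation costs ~0.5 s)
local({
  cache <- new.env(parent = emptyenv())
  small_phantom_slice <<- function(seed = 3) {
    key <- as.character(seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- phantom_slice(small_phantom_spec(seed))
    cache[[key]]
  }
})

# centered disk mask
disk_mask <- function(n, r, center = (n + 1) / 2) {
  m <- matrix(FALSE, n, n)
  m[(row(m) - center)^2 + (col(m) - center)^2 <= r^2] <- TRUE
  m
}

random_blob <- function(n, seed, density = 0.4, grow = 2) {
  set.seed(seed)
  m <- matrix(runif(n * n) < density, n, n)
  m <- qdaseg:::eb_dilate(m, qdaseg:::disc_brush(1))
  qdaseg:::largest_component(m)
}

# brute-force oracles -------------------------------------------------------

# exhaustive Otsu: try all integer thresholds, maximize between-class
# variance computed directly from the two classes
brute_otsu_split <- function(x, candidates = 0:255) {
  best_t <- NA
  best_v <- -Inf
  for (t in candidates) {
    lo <- x[x <= t]; hi <- x[x > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  list(threshold = best_t, variance = best_v)
}

# exhaustive optimal 1D k-means over contiguous partitions of sorted data
brute_kmeans_sse <- function(x, K) {
  xs <- sort(x)
  n <- length(xs)
  best <- Inf
  for (cc in utils::combn(n - 1L, K - 1L, simplify = FALSE)) {
    grp <- cut(seq_len(n), breaks = c(0, cc, n))
    s <- 0
    for (lv in levels(grp)) {
      g <- xs[grp == lv]
      s <- s + sum((g - mean(g))^2)
    }
    if (s < best) best <- s
  }
  best
}

brute_hausdorff <- function(a, b, prob = 0.95) {
  pa <- which(qdaseg:::boundary_voxels(a), arr.ind = TRUE)
  pb <- which(qdaseg:::boundary_voxels(b), arr.ind = TRUE)
  dab <- apply(pa, 1, function(p) min(sqrt((pb[, 1] - p[1])^2 + (pb[, 2] - p[2])^2)))
  dba <- apply(pb, 1, function(p) min(sqrt((pa[, 1] - p[1])^2 + (pa[, 2] - p[2])^2)))
  max(quantile(dab, prob, type = 7), quantile(dba, prob, type = 7))
}
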