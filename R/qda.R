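# Quantum Dragonfly (QDA) clustering optimizer. Each dragonfly carries the
# full K-vector of candidate tissue centroids; the scalar swarm equations
# apply coordinate-wise. The swarm is seeded by the k-means solution and
# refines it under elitism, so the best-so-far fitness never worsens.

#' QDA configuration
#'
#' @param N Swarm size (>= 2). Default 20.
#' @param T Maximum iterations (default 100).
#' @param theta Rotation-angle magnitude in radians, within
#'   `(0.001*pi, 0.05*pi)`; default `0.02*pi`. The sign of each applied
#'   rotation points the qubit toward the food solution's quantized value.
#' @param mutation_prob Per-individual Gaussian mutation probability
#'   (default 0.1).
#' @param mutation_k Mutation weight `k` in `x (1 + k r)` (default 1).
#' @param levy_beta Levy stability exponent in (1, 2] (default 1.5).
#' @param stagnation_window,stagnation_tol Early stop when the best fitness
#'   improves by less than `stagnation_tol` over `stagnation_window`
#'   iterations (defaults 15 and 1e-6).
#' @param seed RNG seed; identical config + seed gives bit-identical runs.
#' @param init_spread Initial swarm spread as a fraction of the search range
#'   (default 0.1); 0 collapses every individual onto the k-means seed.
#' @param fitness_mode `"unsupervised"` (quantization error, the operational
#'   default) or `"mape"` (requires ground-truth labels; validation only).
#' @param literal_cohesion Use the repelling cohesion sign `Xi - mean(Xj)`
#'   that appears in some transcriptions of the dragonfly equations instead
#'   of the standard attracting `mean(Xj) - Xi` (default FALSE).
#' @return List of class `qda_config`.
#' @export
qda_config <- function(N = 20, T = 100, theta = 0.02 * pi,
                       mutation_prob = 0.1, mutation_k = 1,
                       levy_beta = 1.5, stagnation_window = 15,
                       stagnation_tol = 1e-6, seed = 1L,
                       init_spread = 0.1,
                       fitness_mode = c("unsupervised", "mape"),
                       literal_cohesion = FALSE) {
  if (N < 2) stop("swarm size N must be >= 2")
  if (T < 0) stop("T must be >= 0")
  if (!(theta > 0 && theta < pi / 2)) stop("theta must lie in (0, pi/2)")
  if (mutation_prob < 0 || mutation_prob > 1) stop("mutation_prob in [0, 1]")
  if (!(levy_beta > 1 && levy_beta <= 2)) stop("levy_beta in (1, 2]")
  structure(list(N = as.integer(N), T = as.integer(T), theta = theta,
                 mutation_prob = mutation_prob, mutation_k = mutation_k,
                 levy_beta = levy_beta,
                 stagnation_window = as.integer(stagnation_window),
                 stagnation_tol = stagnation_tol, seed = as.integer(seed),
                 init_spread = init_spread,
                 fitness_mode = match.arg(fitness_mode),
                 literal_cohesion = isTRUE(literal_cohesion)),
            class = "qda_config")
}

#' Clustering fitness of a centroid vector
#'
#' Unsupervised mode (default): the mean absolute quantization error -- each
#' pixel's distance to its nearest candidate centroid -- normalized by the
#' bounds range, a rate in [0, 1] where lower is better. Supervised mode
#' (`truth_labels` given): the mean absolute percentage error between true
#' classes and the predicted cluster index under the canonical
#' ascending-centroid labeling, `100/N * sum(|y - f| / y)`, computed over
#' pixels with `y != 0` (the number excluded is attached as attribute
#' `"excluded"`).
#'
#' @param position Candidate centroid vector (sorted ascending internally).
#' @param pixels Numeric intensities, or a list with `values`/`weights` for
#'   histogram-compressed data.
#' @param truth_labels Optional integer classes enabling MAPE mode.
#' @param bounds Optional [qda_bounds] for normalization; defaults to the
#'   pixel range.
#' @return Scalar fitness (lower is better).
#' @export
qda_fitness <- function(position, pixels, truth_labels = NULL, bounds = NULL) {
  position <- sort(position)
  compressed <- is.list(pixels) && !is.null(pixels$values)
  vals <- if (compressed) pixels$values else pixels
  if (length(vals) == 0L) stop("pixels must be nonempty")
  if (!is.null(truth_labels)) {
    if (compressed) stop("MAPE mode needs uncompressed pixels")
    f <- assign_clusters(vals, position)
    y <- as.numeric(truth_labels)
    keep <- y != 0
    mape <- 100 * mean(abs(y[keep] - f[keep]) / y[keep])
    attr(mape, "excluded") <- sum(!keep)
    return(mape)
  }
  w <- if (compressed) pixels$weights else rep(1, length(vals))
  if (is.null(bounds)) bounds <- qda_bounds(min(vals), max(vals) + 1e-12)
  D <- abs(outer(vals, position, "-"))
  dmin <- do.call(pmin, as.data.frame(D))
  sum(w * dmin) / sum(w) / (bounds$hi - bounds$lo)
}

#' Adaptive dragonfly operator weights
#'
#' The canonical adaptive schedule: separation/alignment/cohesion weights are
#' random fractions of a ramp `my_c = max(0, 0.1 - 0.2 t / T)` that decays to
#' zero at mid-run, the food factor is `2 * runif(1)`, the enemy factor is
#' `my_c`, and the inertia weight `xi` ramps linearly 0.9 -> 0.4 over the
#' run. Draws from the current RNG stream.
#'
#' @param t Current iteration (1-based).
#' @param T Total iterations.
#' @return List with `s`, `a`, `c`, `f`, `e`, `xi`.
#' @export
da_weights <- function(t, T) {
  frac <- if (T > 0) t / T else 1
  my_c <- max(0, 0.1 - 0.2 * frac)
  list(s = 2 * stats::runif(1) * my_c,
       a = 2 * stats::runif(1) * my_c,
       c = 2 * stats::runif(1) * my_c,
       f = 2 * stats::runif(1),
       e = my_c,
       xi = 0.9 - 0.5 * frac)
}

neighbor_radius <- function(t, T, b) {
  frac <- if (T > 0) min(t / T, 1) else 1
  (b$hi - b$lo) * (0.25 + 0.75 * frac)
}

#' Initialize the dragonfly swarm from k-means centroids
#'
#' One individual is set exactly to the k-means centroid vector; the
#' remaining `N - 1` are that vector plus seeded uniform perturbations of
#' amplitude `init_spread * (hi - lo)`, clamped into bounds. Step vectors
#' start at zero; fitness is evaluated and food (best) / enemy (worst)
#' positions set. Draws from the current RNG stream.
#'
#' @param cfg [qda_config].
#' @param bounds [qda_bounds].
#' @param seed_centroids K-vector of k-means centroids within bounds.
#' @param pixels Intensities (or compressed histogram) for fitness.
#' @return A `qda_swarm` state list.
#' @export
init_swarm <- function(cfg, bounds, seed_centroids, pixels) {
  if (any(seed_centroids < bounds$lo | seed_centroids > bounds$hi))
    stop("seed centroids violate bounds")
  d <- length(seed_centroids)
  X <- matrix(rep(seed_centroids, each = cfg$N), nrow = cfg$N)
  if (cfg$N > 1L && cfg$init_spread > 0) {
    pert <- matrix(stats::runif((cfg$N - 1L) * d, -1, 1), ncol = d) *
      cfg$init_spread * (bounds$hi - bounds$lo)
    X[-1L, ] <- clamp(X[-1L, , drop = FALSE] + pert, bounds$lo, bounds$hi)
  }
  fit <- apply(X, 1L, qda_fitness, pixels = pixels, bounds = bounds)
  best <- which.min(fit); worst <- which.max(fit)
  structure(list(X = X, dX = matrix(0, cfg$N, d), fit = fit,
                 food_pos = X[best, ], food_fit = fit[best],
                 enemy_pos = X[worst, ], enemy_fit = fit[worst],
                 bounds = bounds, pixels = pixels, t = 0L,
                 radius = neighbor_radius(0L, cfg$T, bounds)),
            class = "qda_swarm")
}

#' Neighbors of a dragonfly
#'
#' All other individuals within the current neighbor radius (Euclidean
#' distance over the centroid vector); the radius grows with the iteration
#' count so the swarm coalesces late in the run.
#'
#' @param st A `qda_swarm`.
#' @param i Individual index.
#' @return Integer vector of neighbor indices (possibly empty).
#' @export
neighbor_set <- function(st, i) {
  d2 <- rowSums((st$X - matrix(st$X[i, ], nrow(st$X), ncol(st$X),
                               byrow = TRUE))^2)
  js <- which(sqrt(d2) <= st$radius)
  js[js != i]
}

#' The five dragonfly swarm operators
#'
#' Separation `S = -sum_j (Xi - Xj)`, alignment `A = mean_j Vj` (the step
#' vectors double as velocities), cohesion `C = mean_j(Xj) - Xi` (attraction
#' to the neighborhood center; `literal = TRUE` uses the repelling sign
#' `Xi - mean(Xj)` instead), food attraction `F = X_food - Xi`, and
#' enemy distraction `E = X_enemy + Xi` (the sum, as in the original
#' dragonfly formulation). With zero neighbors S, A and C are zero vectors.
#'
#' @param st A `qda_swarm`.
#' @param i Individual index.
#' @param literal Use the repelling cohesion sign.
#' @return List with `S`, `A`, `C`, `F`, `E` (d-vectors).
#' @export
swarm_operators <- function(st, i, literal = FALSE) {
  xi <- st$X[i, ]
  nb <- neighbor_set(st, i)
  d <- ncol(st$X)
  if (length(nb) == 0L) {
    S <- A <- C <- rep(0, d)
  } else {
    Xn <- st$X[nb, , drop = FALSE]
    S <- -colSums(matrix(xi, length(nb), d, byrow = TRUE) - Xn)
    A <- colMeans(st$dX[nb, , drop = FALSE])
    C <- if (literal) xi - colMeans(Xn) else colMeans(Xn) - xi
  }
  list(S = S, A = A, C = C,
       F = st$food_pos - xi,
       E = st$enemy_pos + xi)
}

#' One synchronous dragonfly iteration
#'
#' For each individual with at least one neighbor the step becomes
#' `dX <- s S + a A + c C + f F + e E + xi * QCM(dX)`, where the inertia
#' term passes through the quantum computing mechanism
#' (quantize -> rotation gate toward the food qubit -> dequantize) instead of
#' plain multiplication, and the position is `clamp(X + dX)`. Neighborless
#' individuals take a QCM Levy flight instead and their step resets to zero.
#' Fitness is re-evaluated; the food position is elitist (never worsens) and
#' the enemy is the worst of the current population.
#'
#' @param st A `qda_swarm`.
#' @param w Operator weights (see [da_weights]).
#' @param cfg [qda_config].
#' @return Updated `qda_swarm`.
#' @export
da_step <- function(st, w, cfg) {
  N <- nrow(st$X); d <- ncol(st$X)
  b <- st$bounds
  newX <- st$X; newdX <- st$dX
  food_q <- quantize(st$food_pos, b)$q
  for (i in seq_len(N)) {
    nb <- neighbor_set(st, i)
    if (length(nb) >= 1L) {
      op <- swarm_operators(st, i, cfg$literal_cohesion)
      target_q <- quantize(clamp(st$food_pos - st$X[i, ], b$lo, b$hi), b)$q
      inertia <- w$xi * qcm_transform(st$dX[i, ], b, cfg$theta, target_q)
      step <- w$s * op$S + w$a * op$A + w$c * op$C +
        w$f * op$F + w$e * op$E + inertia
      newdX[i, ] <- step
      newX[i, ] <- clamp(st$X[i, ] + step, b$lo, b$hi)
    } else {
      newX[i, ] <- levy_qcm_update(st$X[i, ], b, cfg$theta, cfg,
                                   target_q = food_q)
      newdX[i, ] <- 0
    }
  }
  st$X <- newX; st$dX <- newdX
  st$fit <- apply(newX, 1L, qda_fitness, pixels = st$pixels, bounds = b)
  best <- which.min(st$fit)
  if (st$fit[best] < st$food_fit) {
    st$food_fit <- st$fit[best]
    st$food_pos <- newX[best, ]
  }
  worst <- which.max(st$fit)
  st$enemy_fit <- st$fit[worst]
  st$enemy_pos <- newX[worst, ]
  st$t <- st$t + 1L
  st$radius <- neighbor_radius(st$t, cfg$T, b)
  st
}

#' Gaussian mutation candidate
#'
#' With probability `mutation_prob` returns `clamp(x (1 + k r))` with `r` a
#' standard-normal draw (`r` can be forced for testing), otherwise returns
#' `x` unchanged. Acceptance is greedy in the optimizer: the mutant replaces
#' the original only when its fitness improves, preserving elitism.
#'
#' @param x Position vector within bounds.
#' @param cfg [qda_config] supplying `mutation_prob` and `mutation_k`.
#' @param bounds [qda_bounds].
#' @param r Optional forced normal draw.
#' @return Candidate position vector.
#' @export
gaussian_mutation <- function(x, cfg, bounds, r = NULL) {
  if (cfg$mutation_prob <= 0) return(x)
  if (cfg$mutation_prob < 1 && stats::runif(1) >= cfg$mutation_prob) return(x)
  if (is.null(r)) r <- stats::rnorm(1)
  clamp(x * (1 + cfg$mutation_k * r), bounds$lo, bounds$hi)
}

#' Run the QDA optimization loop
#'
#' Seeds the swarm from a k-means model and iterates [da_step] plus greedy
#' Gaussian mutation until `T` iterations or until the best fitness has not
#' improved by `stagnation_tol` within `stagnation_window` iterations.
#' `T = 0` returns the k-means solution unchanged. Fully deterministic given
#' the config seed.
#'
#' @param pixels Numeric intensities.
#' @param kmeans_model A `tissue_clusters` seed (see [kmeans_fit]).
#' @param cfg [qda_config].
#' @param bounds Optional [qda_bounds]; defaults to the pixel range.
#' @return List with `best` (a `tissue_clusters` built from the refined
#'   centroids), `history` (per-iteration best fitness, monotone
#'   non-increasing), `fitness` (final best fitness), `iterations`.
#' @export
qda_optimize <- function(pixels, kmeans_model, cfg = qda_config(),
                         bounds = NULL) {
  stopifnot(inherits(kmeans_model, "tissue_clusters"))
  if (is.null(bounds)) {
    rng <- range(pixels)
    bounds <- qda_bounds(rng[1L], rng[2L] + max(diff(rng), 1) * 1e-9)
  }
  comp <- compress_pixels(pixels)
  seed_fit <- qda_fitness(kmeans_model$centroids, comp, bounds = bounds)
  if (cfg$T == 0L) {
    return(list(best = kmeans_model, history = numeric(0),
                fitness = seed_fit, iterations = 0L))
  }
  with_seed(cfg$seed, {
    st <- init_swarm(cfg, bounds, kmeans_model$centroids, comp)
    history <- numeric(cfg$T)
    used <- 0L
    for (t in seq_len(cfg$T)) {
      w <- da_weights(t, cfg$T)
      st <- da_step(st, w, cfg)
      if (cfg$mutation_prob > 0) {
        for (i in seq_len(cfg$N)) {
          cand <- gaussian_mutation(st$X[i, ], cfg, bounds)
          if (!identical(cand, st$X[i, ])) {
            cf <- qda_fitness(cand, comp, bounds = bounds)
            if (cf < st$fit[i]) {
              st$X[i, ] <- cand
              st$fit[i] <- cf
              if (cf < st$food_fit) {
                st$food_fit <- cf
                st$food_pos <- cand
              }
            }
          }
        }
      }
      history[t] <- st$food_fit
      used <- t
      if (t > cfg$stagnation_window &&
          history[t - cfg$stagnation_window] - history[t] < cfg$stagnation_tol)
        break
    }
    history <- history[seq_len(used)]
    best_cent <- sort(st$food_pos)
    best <- cluster_model(best_cent, assign_clusters(pixels, best_cent),
                          pixels, kmeans_model$K)
    list(best = best, history = history, fitness = st$food_fit,
         iterations = used)
  })
}

#' Fit the quantum-dragonfly clustering model
#'
#' The main model-fitting entry point: deterministic k-means over the pixel
#' intensities provides the seed centroids ("food sources"), which the
#' quantum-inspired dragonfly swarm then refines under elitism. The returned
#' fit supports `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`
#' and `plot`.
#'
#' @param pixels Numeric intensities (e.g. brain-mask pixels of one slice).
#' @param K Number of tissue clusters (default 4: CSF-or-background, grey
#'   matter, white matter, tumor).
#' @param config [qda_config].
#' @param bounds Optional [qda_bounds].
#' @return Object of class `qda_fit`.
#' @examples
#' set.seed(7)
#' px <- c(rnorm(300, 20, 8), rnorm(300, 80, 8),
#'         rnorm(300, 140, 8), rnorm(300, 220, 8))
#' fit <- qda_cluster(px, K = 4, config = qda_config(T = 30, seed = 1))
#' coef(fit)
#' @export
qda_cluster <- function(pixels, K = 4, config = qda_config(), bounds = NULL) {
  km <- kmeans_fit(pixels, K = K)
  opt <- qda_optimize(pixels, km, cfg = config, bounds = bounds)
  structure(list(centroids = opt$best$centroids,
                 labels = opt$best$labels,
                 objective = opt$best$objective,
                 sse = opt$best$sse,
                 K = as.integer(K),
                 n = length(pixels),
                 pixel_mean = mean(pixels),
                 pixels = as.numeric(pixels),
                 fitness = opt$fitness,
                 history = opt$history,
                 iterations = opt$iterations,
                 seed_model = km,
                 config = config,
                 call = match.call()),
            class = c("qda_fit", "tissue_clusters"))
}

#' @export
print.qda_fit <- function(x, ...) {
  cat("Quantum dragonfly clustering fit\n")
  cat("  K =", x$K, "clusters over", x$n, "pixels;",
      x$iterations, "swarm iterations\n")
  cat("  centroids:", paste(signif(x$centroids, 5), collapse = ", "), "\n")
  cat("  fitness (quantization error rate):", signif(x$fitness, 6), "\n")
  invisible(x)
}

#' @export
summary.qda_fit <- function(object, ...) {
  sizes <- tabulate(object$labels, nbins = object$K)
  km_fit <- qda_fitness(object$seed_model$centroids, object$pixels)
  structure(list(centroids = object$centroids, sizes = sizes,
                 fitness = object$fitness, kmeans_fitness = km_fit,
                 objective = object$objective, sse = object$sse,
                 iterations = object$iterations, n = object$n,
                 K = object$K),
            class = "summary.qda_fit")
}

#' @export
print.summary.qda_fit <- function(x, ...) {
  cat("Quantum dragonfly clustering fit (K =", x$K, ", n =", x$n, ")\n\n")
  tab <- data.frame(centroid = signif(x$centroids, 6), size = x$sizes)
  rownames(tab) <- paste0("cluster", seq_len(x$K))
  print(tab)
  cat("\nFinal fitness:", signif(x$fitness, 6),
      " (k-means seed:", signif(x$kmeans_fitness, 6), ")\n")
  cat("Swarm iterations:", x$iterations, "\n")
  invisible(x)
}

#' @export
coef.qda_fit <- function(object, ...) object$centroids

#' @export
predict.qda_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$labels)
  assign_clusters(as.numeric(newdata), object$centroids)
}

#' @export
fitted.qda_fit <- function(object, ...) object$centroids[object$labels]

#' @export
residuals.qda_fit <- function(object, ...) object$pixels - fitted(object)

#' @export
plot.qda_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  if (length(x$history) > 0) {
    graphics::plot(seq_along(x$history), x$history, type = "l",
                   xlab = "iteration", ylab = "best fitness",
                   main = "Swarm convergence", ...)
  }
  graphics::hist(x$pixels, breaks = 64, main = "Intensity clusters",
                 xlab = "intensity", col = "grey85", border = NA)
  graphics::abline(v = x$centroids, col = "red3", lwd = 2)
  invisible(x)
}
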