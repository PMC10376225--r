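mixture_pixels <- function(seed = 1, n = 500, mus = c(20, 80, 140, 220), sd = 8) {
  set.seed(seed)
  rnorm(4 * n, rep(mus, each = n), sd)
}

test_that("fitness is zero at perfect centroids and matches the MAPE formula", {
  expect_equal(qda_fitness(c(10, 30), c(10, 10, 30, 30)), 0)
  # predicted classes under ascending labeling: f = (1, 2)
  m <- qda_fitness(c(10, 30), c(10, 30), truth_labels = c(2, 2))
  expect_equal(as.numeric(m), 25)
  expect_equal(as.numeric(qda_fitness(c(10, 30), c(10, 30),
                                      truth_labels = c(1, 2))), 0)
  # y = 0 instances are excluded and counted
  m0 <- qda_fitness(c(10, 30), c(10, 30, 30), truth_labels = c(0, 2, 2))
  expect_equal(attr(m0, "excluded"), 1L)
  expect_error(qda_fitness(c(1, 2), numeric(0)), "nonempty")
})

test_that("swarm initialization honors the seed centroids, spread and determinism", {
  b <- qda_bounds(0, 255)
  seeds <- c(40, 100, 150, 210)
  cfg0 <- qda_config(N = 2, init_spread = 0)
  px <- mixture_pixels(3, n = 100)
  set.seed(1)
  st <- init_swarm(cfg0, b, seeds, px)
  expect_equal(st$X[1, ], seeds)
  expect_equal(st$X[2, ], seeds)
  expect_equal(st$food_pos, seeds)
  expect_true(all(is.finite(st$fit)))
  expect_true(all(st$food_fit <= st$fit))

  cfg <- qda_config(N = 6)
  set.seed(9); a <- init_swarm(cfg, b, seeds, px)
  set.seed(9); b2 <- init_swarm(cfg, b, seeds, px)
  expect_identical(a, b2)
  expect_error(init_swarm(cfg, b, c(-5, 100, 150, 210), px), "bounds")
})

test_that("neighbor sets follow the radius and match a brute-force scan", {
  b <- qda_bounds(0, 100)
  st <- structure(list(X = rbind(c(10, 10), c(10, 10), c(90, 90)),
                       radius = 5), class = "qda_swarm")
  expect_equal(neighbor_set(st, 1), 2L)   # coincident points are neighbors
  expect_equal(neighbor_set(st, 3), integer(0))
  st$radius <- 0
  expect_equal(neighbor_set(st, 1), 2L)   # distance 0 <= radius 0
  st$X <- rbind(c(1, 1), c(2, 2), c(3, 3))
  expect_equal(neighbor_set(st, 1), integer(0))
  set.seed(12)
  st$X <- matrix(runif(20, 0, 100), 10)
  st$radius <- 30
  for (i in 1:10) {
    d <- sqrt(rowSums((st$X - matrix(st$X[i, ], 10, 2, byrow = TRUE))^2))
    expect_equal(neighbor_set(st, i), setdiff(which(d <= 30), i))
  }
})

test_that("swarm operators match direct evaluation of their formulas", {
  X <- rbind(c(10, 20), c(30, 40), c(50, 90))
  dX <- rbind(c(1, 2), c(3, 4), c(5, 6))
  st <- structure(list(X = X, dX = dX, radius = 1e6,
                       food_pos = c(5, 5), enemy_pos = c(100, 100)),
                  class = "qda_swarm")
  for (i in 1:3) {
    nb <- setdiff(1:3, i)
    op <- swarm_operators(st, i)
    expect_equal(op$S, -colSums(matrix(X[i, ], 2, 2, byrow = TRUE) -
                                  X[nb, ]))
    expect_equal(op$A, colMeans(dX[nb, ]))
    expect_equal(op$C, colMeans(X[nb, ]) - X[i, ])
    expect_equal(op$F, c(5, 5) - X[i, ])
    expect_equal(op$E, c(100, 100) + X[i, ])
    lit <- swarm_operators(st, i, literal = TRUE)
    expect_equal(lit$C, X[i, ] - colMeans(X[nb, ]))
  }
  # symmetric neighborhood: separation and cohesion vanish at the center
  st$X <- rbind(c(50, 50), c(40, 50), c(60, 50))
  op <- swarm_operators(st, 1)
  expect_equal(op$S, c(0, 0))
  expect_equal(op$C, c(0, 0))
  # at the food position the attraction vanishes
  st$food_pos <- st$X[1, ]
  expect_equal(swarm_operators(st, 1)$F, c(0, 0))
})

test_that("a step with zero weights and zero prior step leaves the swarm unchanged", {
  b <- qda_bounds(0, 255)
  px <- mixture_pixels(5, n = 50)
  cfg <- qda_config(N = 3, init_spread = 0.05)
  set.seed(2)
  st <- init_swarm(cfg, b, c(40, 100, 150, 210), px)
  st$dX[] <- 0
  w0 <- list(s = 0, a = 0, c = 0, f = 0, e = 0, xi = 0)
  st2 <- da_step(st, w0, cfg)
  expect_equal(st2$X, st$X)
})

test_that("a step with zero rotation reproduces the update equations exactly", {
  b <- qda_bounds(0, 255)
  px <- c(10, 60, 120, 200)
  cfg <- qda_config(N = 3, init_spread = 0)
  cfg$theta <- 0                       # QCM becomes a pass-through
  X <- rbind(c(40, 100), c(60, 120), c(45, 105))
  dX <- rbind(c(5, 10), c(20, 8), c(1, 2))      # within [lo, hi]: clamp no-op
  st <- structure(list(X = X, dX = dX,
                       fit = apply(X, 1, qda_fitness, pixels = px, bounds = b),
                       food_pos = c(50, 110), food_fit = 0,
                       enemy_pos = c(200, 220), enemy_fit = 1,
                       bounds = b, pixels = px, t = 0L, radius = 1e6),
                  class = "qda_swarm")
  w <- list(s = 0.1, a = 0.2, c = 0.3, f = 0.5, e = 0.05, xi = 0.7)
  st2 <- da_step(st, w, cfg)
  for (i in 1:3) {
    nb <- setdiff(1:3, i)
    S <- -colSums(matrix(X[i, ], 2, 2, byrow = TRUE) - X[nb, ])
    A <- colMeans(dX[nb, ])
    C <- colMeans(X[nb, ]) - X[i, ]
    F <- c(50, 110) - X[i, ]
    E <- c(200, 220) + X[i, ]
    step <- w$s * S + w$a * A + w$c * C + w$f * F + w$e * E + w$xi * dX[i, ]
    expect_equal(st2$dX[i, ], step)
    expect_equal(st2$X[i, ], pmin(pmax(X[i, ] + step, 0), 255))
  }
})

test_that("stepping preserves elitism and the bounds clamp", {
  b <- qda_bounds(0, 255)
  px <- mixture_pixels(6, n = 100)
  cfg <- qda_config(N = 8)
  set.seed(31)
  st <- init_swarm(cfg, b, kmeans_fit(px, 4)$centroids, px)
  for (t in 1:15) {
    before <- st$food_fit
    st <- da_step(st, da_weights(t, 15), cfg)
    expect_lte(st$food_fit, before)
    expect_true(all(st$X >= 0 & st$X <= 255))
    expect_equal(st$enemy_fit, max(st$fit))
  }
})

test_that("Gaussian mutation follows x(1 + k r) with clamping and probability", {
  cfg <- qda_config(mutation_prob = 1, mutation_k = 1)
  b <- qda_bounds(0, 255)
  expect_equal(gaussian_mutation(100, cfg, b, r = 0.5), 150)
  expect_equal(gaussian_mutation(100, cfg, b, r = 0), 100)
  expect_equal(gaussian_mutation(200, cfg, b, r = 1), 255)   # clamped
  cfg0 <- qda_config(mutation_prob = 0)
  expect_equal(gaussian_mutation(c(10, 20), cfg0, b), c(10, 20))
})

test_that("optimization history is monotone, elitist over the seed, and deterministic", {
  px <- mixture_pixels(8, n = 400)
  km <- kmeans_fit(px, 4)
  cfg <- qda_config(N = 12, T = 40, seed = 5)
  opt <- qda_optimize(px, km, cfg)
  expect_true(all(diff(opt$history) <= 1e-12))
  expect_lte(opt$fitness, qda_fitness(km$centroids, px) + 1e-12)
  opt2 <- qda_optimize(px, km, cfg)
  expect_identical(opt$best$centroids, opt2$best$centroids)
  expect_identical(opt$history, opt2$history)
  # T = 0 returns the k-means solution unchanged
  z <- qda_optimize(px, km, qda_config(T = 0))
  expect_identical(z$best, km)
  expect_length(z$history, 0)
})

test_that("the refined centroids recover a well-separated mixture", {
  mus <- c(20, 80, 140, 220)
  px <- mixture_pixels(15, n = 1000)
  fit <- qda_cluster(px, K = 4, config = qda_config(T = 60, seed = 2))
  expect_lt(max(abs(coef(fit) - mus)), 0.02 * diff(range(px)))
  expect_s3_class(fit, "qda_fit")
  expect_equal(predict(fit, c(19, 81, 141, 219)), 1:4)
  expect_equal(length(residuals(fit)), length(px))
  s <- summary(fit)
  expect_lte(s$fitness, s$kmeans_fitness + 1e-12)
})

test_that("the swarm beats random search at an equal evaluation budget", {
  mus <- c(20, 80, 140, 220)
  wins <- 0
  for (s in 1:10) {
    px <- mixture_pixels(100 + s, n = 400)
    km <- kmeans_fit(px, 4)
    cfg <- qda_config(N = 10, T = 30, seed = s)
    opt <- qda_optimize(px, km, cfg)
    budget <- cfg$N * (2 * cfg$T + 1)
    set.seed(200 + s)
    comp <- qdaseg:::compress_pixels(px)
    rb <- min(vapply(seq_len(budget), function(i)
      qda_fitness(runif(4, min(px), max(px)), comp), numeric(1)))
    if (opt$fitness <= rb) wins <- wins + 1
  }
  expect_gte(wins, 8)
})
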