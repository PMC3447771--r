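test_that("grid_to_points places nests at cell centers", {
  g <- lattice_geometry()
  st <- init_state(g, init_spec(p_ant = 0), seed = 1)
  pp <- grid_to_points(st)
  expect_equal(length(pp$x), 0L)
  expect_equal(pp$window, c(800, 600))
  expect_true(pp$toroidal)

  st$ants[1, 1] <- 1  # (col 1, row 1)
  pp <- grid_to_points(st)
  expect_equal(pp$x, 0.5 * 800 / 120, tolerance = 1e-12)
  expect_equal(pp$y, 0.5 * 600 / 90, tolerance = 1e-12)
  expect_equal(pp$x, 10 / 3, tolerance = 1e-9)

  st$ants[] <- 1
  expect_equal(length(grid_to_points(st)$x), 10800L)
})

test_that("point_pattern validates its window", {
  expect_error(point_pattern(c(1, 900), c(1, 2), window = c(800, 600)),
               "inside")
  expect_error(point_pattern(1, c(1, 2)), "equal length")
  expect_error(point_pattern(NaN, 0), "finite")
  pp <- point_pattern(numeric(0), numeric(0))
  expect_equal(length(pp$x), 0L)
})

test_that("single-linkage clusters use an inclusive 20 m threshold", {
  g <- lattice_geometry()
  cs <- g$cell_size
  st <- init_state(g, init_spec(p_ant = 0), seed = 1)
  # three cells apart axially = 20.0 m: joined
  st$ants[10, 10] <- 1; st$ants[10, 13] <- 1
  cl <- find_clusters(grid_to_points(st), threshold = 20)
  expect_equal(sort(cl$sizes), 2L)

  # (3,3) cells diagonal = 28.3 m: two singletons
  st <- init_state(g, init_spec(p_ant = 0), seed = 1)
  st$ants[10, 10] <- 1; st$ants[13, 13] <- 1
  cl <- find_clusters(grid_to_points(st), threshold = 20)
  expect_equal(cl$sizes, c(1L, 1L))

  # empty pattern: no clusters
  cl <- find_clusters(point_pattern(numeric(0), numeric(0)), 20)
  expect_equal(length(cl$sizes), 0L)
  expect_error(find_clusters(point_pattern(1, 1), threshold = 0), "threshold")
})

test_that("cluster labels match a brute-force union-find", {
  for (cfg in list(list(n = 50, seed = 1), list(n = 200, seed = 2),
                   list(n = 500, seed = 3))) {
    pp <- csr_pattern(cfg$n, window = c(800, 600), seed = cfg$seed)
    cl <- find_clusters(pp, threshold = 25)
    ref <- ref_clusters(pp, threshold = 25)
    # same partition up to label renaming
    expect_equal(length(unique(cl$labels)), length(unique(ref)))
    tab <- table(cl$labels, ref)
    expect_equal(sum(tab > 0), length(unique(ref)))
    expect_equal(sum(cl$sizes), cfg$n)
  }
  # and on a toroidal pattern, where wrap-around joins edge points
  pp <- csr_pattern(150, seed = 4, toroidal = TRUE)
  cl <- find_clusters(pp, threshold = 30)
  ref <- ref_clusters(pp, threshold = 30)
  expect_equal(length(unique(cl$labels)), length(unique(ref)))
})

test_that("cumulative cluster-size frequencies count sizes >= s", {
  cdf <- cluster_size_cdf(c(1L, 1L, 2L))
  expect_equal(cdf$size, c(1L, 2L))
  expect_equal(cdf$cum_freq, c(3, 1))

  cdf <- cluster_size_cdf(rep(1L, 7))
  expect_equal(cdf$size, 1L)
  expect_equal(cdf$cum_freq, 7)

  set.seed(5)
  sizes <- sample(1:30, 100, replace = TRUE)
  cdf <- cluster_size_cdf(sizes)
  expect_true(all(diff(cdf$cum_freq) <= 0))
  expect_equal(cdf$cum_freq[1], 100)
  expect_error(cluster_size_cdf(integer(0)), "empty")
})

test_that("power-law fit recovers an exact synthetic slope", {
  s <- 1:20
  cdf <- data.frame(size = s, cum_freq = 100 * s^(-1.5))
  fit <- fit_power_law(cdf)
  expect_equal(fit$slope, -1.5, tolerance = 1e-9)
  expect_equal(fit$intercept, 2, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  expect_equal(fit_power_law(data.frame(size = c(2, 5, 9),
                                        cum_freq = c(4, 4, 4)))$slope, 0,
               tolerance = 1e-12)
  expect_error(fit_power_law(data.frame(size = c(3, 3), cum_freq = c(2, 2))),
               "two distinct")
})

test_that("ripley_K matches the O(n^2) brute force on both geometries", {
  radii <- c(10, 25, 50, 100, 150, 250)
  for (toroidal in c(TRUE, FALSE)) {
    pp <- csr_pattern(50, window = c(800, 600), toroidal = toroidal, seed = 11)
    expect_equal(ripley_K(pp, radii), ref_ripley_K(pp, radii),
                 tolerance = 1e-12)
  }
})

test_that("centered L function behaves under CSR and degenerate input", {
  # two points farther apart than r: no pairs, L - r = -r
  pp <- point_pattern(c(100, 500), c(100, 500), window = c(800, 600))
  L <- ripley_L(pp, c(10, 50))
  expect_equal(L$L_minus_r, c(-10, -50))

  expect_error(ripley_K(point_pattern(1, 1), 10), "2 points")
  pp2 <- csr_pattern(30, seed = 1)
  expect_error(ripley_K(pp2, c(50, 400)), "half the shorter")
  expect_error(ripley_K(pp2, c(50, 20)), "ascending")

  # toroidal translation invariance
  pp3 <- csr_pattern(40, toroidal = TRUE, seed = 12)
  sh <- point_pattern((pp3$x + 333) %% 800, (pp3$y + 123) %% 600,
                      window = c(800, 600), toroidal = TRUE)
  radii <- seq(10, 100, by = 10)
  expect_equal(ripley_L(pp3, radii), ripley_L(sh, radii), tolerance = 1e-9)
})

test_that("csr_pattern has Poisson nearest-neighbor spacing", {
  # toroidal distances avoid edge bias; mean NN distance ~ 0.5 / sqrt(n/A)
  n <- 282; area <- 800 * 600
  expected <- 0.5 / sqrt(n / area)
  set.seed(13)
  nn <- replicate(200, {
    pp <- csr_pattern(n, toroidal = TRUE)
    D <- antscape:::pattern_dist(pp)
    diag(D) <- Inf
    mean(apply(D, 1, min))
  })
  expect_lt(abs(mean(nn) - expected) / expected, 0.05)
})

test_that("envelopes are pointwise quantile bands", {
  radii <- seq(10, 100, by = 10)
  # constant statistic collapses the band
  pp_fix <- csr_pattern(60, seed = 14)
  env <- ripley_envelope(radii, function() pp_fix, n_sims = 25)
  expect_equal(env$lo, env$hi, tolerance = 1e-12)
  expect_equal(env$n_sims, 25)

  # a CSR pattern stays inside the CSR band at most radii (aggregate)
  env <- csr_envelope(100, radii, n_sims = 99, seed = 15)
  expect_true(all(env$lo <= env$hi))
  set.seed(16)
  inside <- replicate(50, {
    L <- ripley_L(csr_pattern(100), radii)$L_minus_r
    mean(L >= env$lo & L <= env$hi)
  })
  expect_gte(mean(inside), 0.9)
})

test_that("Thomas-like clustered patterns exceed the CSR envelope", {
  radii <- seq(10, 50, by = 10)
  env <- csr_envelope(300, radii, n_sims = 99, toroidal = TRUE, seed = 17)
  set.seed(18)
  hits <- replicate(20, {
    pp <- thomas_pattern(30, 10, sigma = 10)
    length(pp$x) >= 2 && exceeds_envelope(pp, env, band = c(10, 50))
  })
  expect_gte(mean(hits), 0.9)
  # degenerate sigma: offspring sit on their parents
  pp0 <- thomas_pattern(5, 10, sigma = 0, seed = 19)
  expect_lte(nrow(unique(cbind(pp0$x, pp0$y))), 5)
})
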