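#' Planar point pattern of nest locations
#'
#' Coordinates in metres inside a rectangular observation window. Field
#' surveys of the plot recorded 282 nests (rainy season 2004) and 384
#' nests (dry season 2004) in the 800 m x 600 m window; simulated patterns
#' come from [grid_to_points()].
#'
#' @param x,y numeric coordinate vectors of equal length (metres).
#' @param window `c(width, height)` in metres.
#' @param toroidal logical; if `TRUE`, distances between points wrap around
#'   the window edges (appropriate for model output, which is periodic).
#' @return an object of class `"point_pattern"`.
#' @export
point_pattern <- function(x, y, window = c(800, 600), toroidal = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  window <- as.numeric(window)
  if (length(window) != 2L || any(!is.finite(window)) || any(window <= 0))
    stop("window must be c(width, height), both > 0", call. = FALSE)
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("coordinates must be finite", call. = FALSE)
  if (length(x) && (any(x < 0 | x > window[1L]) || any(y < 0 | y > window[2L])))
    stop("all points must lie inside the window", call. = FALSE)
  structure(list(x = x, y = y, window = window, toroidal = isTRUE(toroidal)),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point_pattern: %d points in %g m x %g m window%s\n",
              length(x$x), x$window[1L], x$window[2L],
              if (x$toroidal) " (toroidal)" else ""))
  invisible(x)
}

#' @export
plot.point_pattern <- function(x, ...) {
  plot(x$x, x$y, asp = 1, xlim = c(0, x$window[1L]), ylim = c(0, x$window[2L]),
       pch = 16, cex = 0.6, xlab = "x (m)", ylab = "y (m)", ...)
  graphics::rect(0, 0, x$window[1L], x$window[2L], border = "grey")
  invisible(x)
}

# pairwise Euclidean (or toroidal) distance matrix
pattern_dist <- function(pp) {
  dx <- abs(outer(pp$x, pp$x, "-"))
  dy <- abs(outer(pp$y, pp$y, "-"))
  if (pp$toroidal) {
    dx <- pmin(dx, pp$window[1L] - dx)
    dy <- pmin(dy, pp$window[2L] - dy)
  }
  sqrt(dx^2 + dy^2)
}

#' Nest coordinates of an occupancy grid
#'
#' One point per occupied cell, at the cell center
#' `((col - 0.5) * cell_size, (row - 0.5) * cell_size)`; the window is the
#' lattice extent and the toroidal flag is copied from the geometry.
#'
#' @param x a `"ca_state"`, or a binary occupancy matrix (then `geometry`
#'   is required).
#' @param geometry a [lattice_geometry()]; defaults to the state's.
#' @return a [point_pattern()].
#' @export
grid_to_points <- function(x, geometry = NULL) {
  if (inherits(x, "ca_state")) {
    if (is.null(geometry)) geometry <- x$geometry
    M <- x$ants
  } else M <- x
  stopifnot(inherits(geometry, "lattice_geometry"))
  occ <- which(M == 1, arr.ind = TRUE)  # (row, col)
  cs <- geometry$cell_size
  point_pattern(x = (occ[, 2L] - 0.5) * cs, y = (occ[, 1L] - 0.5) * cs,
                window = c(geometry$n_cols, geometry$n_rows) * cs,
                toroidal = geometry$toroidal)
}

#' Single-linkage nest clusters
#'
#' Groups points into connected components of the graph joining all pairs
#' at distance <= `threshold` (inclusive: two nests exactly 20 m apart --
#' three cells axially -- share a cluster). The default 20 m threshold is
#' the field definition of nests belonging to the same cluster.
#'
#' @param pattern a [point_pattern()].
#' @param threshold linkage distance in metres (> 0).
#' @param tol absolute slack added to `threshold` so that distances equal
#'   to it up to floating-point error still join.
#' @return an object of class `"cluster_set"`: list with integer `labels`
#'   (one per point), `sizes` (one per cluster), and `threshold`.
#' @export
find_clusters <- function(pattern, threshold = 20, tol = 1e-8) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!is.finite(threshold) || threshold <= 0)
    stop("threshold must be > 0", call. = FALSE)
  n <- length(pattern$x)
  if (n == 0L)
    return(structure(list(labels = integer(0), sizes = integer(0),
                          threshold = threshold), class = "cluster_set"))
  if (n == 1L)
    return(structure(list(labels = 1L, sizes = 1L, threshold = threshold),
                     class = "cluster_set"))
  D <- pattern_dist(pattern)
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  labels <- as.integer(stats::cutree(hc, h = threshold + tol))
  structure(list(labels = labels,
                 sizes = as.integer(unname(table(labels))),
                 threshold = threshold),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d points in %d clusters (linkage <= %g m)\n",
              sum(x$sizes), length(x$sizes), x$threshold))
  if (length(x$sizes))
    cat("  sizes:", paste(sort(x$sizes, decreasing = TRUE), collapse = " "),
        "\n")
  invisible(x)
}

#' Cumulative cluster-size distribution
#'
#' For every observed cluster size `s`, the number of clusters of size
#' `>= s` -- the quantity plotted on log-log axes against size when
#' comparing nest clustering to a power law.
#'
#' @param clusters a `"cluster_set"` from [find_clusters()].
#' @return data frame with columns `size` (ascending) and `cum_freq`
#'   (non-increasing).
#' @export
cluster_size_cdf <- function(clusters) {
  sizes <- if (inherits(clusters, "cluster_set")) clusters$sizes
           else as.integer(clusters)
  if (!length(sizes)) stop("empty cluster set", call. = FALSE)
  s <- sort(unique(sizes))
  data.frame(size = s,
             cum_freq = vapply(s, function(z) sum(sizes >= z), numeric(1)))
}

#' Power-law fit to a cumulative cluster-size distribution
#'
#' Ordinary least squares of `log10(cum_freq)` on `log10(size)`, using all
#' observed sizes, unweighted. The fit is comparative -- a common yardstick
#' for model and field cluster-size distributions -- not a claim that the
#' power law is the best-fitting size distribution.
#'
#' @param cdf data frame with columns `size` and `cum_freq` (from
#'   [cluster_size_cdf()]), with at least two distinct sizes.
#' @return list of class `"power_law_fit"` with `slope` (expected < 0 for
#'   clustered data), `intercept`, and `r_squared` (`NA` when the response
#'   is constant).
#' @export
fit_power_law <- function(cdf) {
  if (inherits(cdf, "cluster_set")) cdf <- cluster_size_cdf(cdf)
  if (!all(c("size", "cum_freq") %in% names(cdf)))
    stop("cdf must have columns size and cum_freq", call. = FALSE)
  if (length(unique(cdf$size)) < 2L)
    stop("power-law fit needs at least two distinct sizes", call. = FALSE)
  lx <- log10(cdf$size); ly <- log10(cdf$cum_freq)
  fit <- stats::lm(ly ~ lx)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot
        else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit: log10(cum freq) = %.4f %+.4f log10(size)  (R^2 = %.4f)\n",
    x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Ripley's K function
#'
#' `K(r) = (Area / n^2) * sum_i sum_{j != i} w_ij 1[d_ij <= r]`. For a
#' toroidal pattern distances wrap and no edge correction is needed
#' (`w = 1`); for a bounded window the translation edge correction
#' `w_ij = Area / ((W - |dx|) (H - |dy|))` is applied. Under complete
#' spatial randomness `K(r)` is close to `pi r^2`.
#'
#' @param pattern a [point_pattern()] with at least 2 points.
#' @param radii positive, strictly ascending radii (m); the largest must
#'   not exceed half the shorter window side.
#' @return numeric vector of K values, one per radius.
#' @export
ripley_K <- function(pattern, radii) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- length(pattern$x)
  if (n < 2L) stop("Ripley's K needs at least 2 points", call. = FALSE)
  radii <- as.numeric(radii)
  if (!length(radii) || any(!is.finite(radii)) || any(radii <= 0) ||
      is.unsorted(radii, strictly = TRUE))
    stop("radii must be positive and strictly ascending", call. = FALSE)
  W <- pattern$window[1L]; H <- pattern$window[2L]
  if (max(radii) > min(W, H) / 2)
    stop("largest radius exceeds half the shorter window side",
         call. = FALSE)
  area <- W * H
  D <- pattern_dist(pattern)
  diag(D) <- Inf
  if (pattern$toroidal) {
    wt <- 1
  } else {
    adx <- abs(outer(pattern$x, pattern$x, "-"))
    ady <- abs(outer(pattern$y, pattern$y, "-"))
    wt <- area / ((W - adx) * (H - ady))
    diag(wt) <- 0
  }
  vapply(radii, function(r) sum(wt * (D <= r)) * area / n^2, numeric(1))
}

#' Centered L function
#'
#' `L(r) - r` with `L(r) = sqrt(K(r) / pi)`: zero in expectation for a
#' random (Poisson) pattern, positive where the pattern is clustered.
#'
#' @inheritParams ripley_K
#' @return data frame with columns `r` and `L_minus_r`.
#' @export
ripley_L <- function(pattern, radii) {
  K <- ripley_K(pattern, radii)
  data.frame(r = as.numeric(radii), L_minus_r = sqrt(K / pi) - radii)
}

#' Completely spatially random pattern
#'
#' `n` i.i.d. uniform points in the window -- the null model against which
#' nest clustering is judged.
#'
#' @param n number of points (>= 0).
#' @param window `c(width, height)` in metres.
#' @param toroidal passed to [point_pattern()].
#' @param seed optional integer seed.
#' @return a [point_pattern()].
#' @export
csr_pattern <- function(n, window = c(800, 600), toroidal = FALSE,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  stopifnot(n >= 0L)
  point_pattern(runif(n, 0, window[1L]), runif(n, 0, window[2L]),
                window = window, toroidal = toroidal)
}

#' Clustered (Thomas-like) pattern
#'
#' Parent points scattered uniformly; each parent gets a Poisson number of
#' offspring displaced by isotropic Gaussian noise, wrapped into the
#' window. Emulates the aggregated nest maps seen in the field and is the
#' package's synthetic stand-in for survey data.
#'
#' @param n_parents number of cluster centers.
#' @param mean_offspring mean offspring per parent (Poisson).
#' @param sigma Gaussian displacement standard deviation (m).
#' @param window `c(width, height)` in metres.
#' @param toroidal passed to [point_pattern()].
#' @param seed optional integer seed.
#' @return a [point_pattern()] of the offspring only.
#' @export
thomas_pattern <- function(n_parents = 30, mean_offspring = 10, sigma = 10,
                           window = c(800, 600), toroidal = TRUE,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_parents >= 0, mean_offspring >= 0, sigma >= 0)
  px <- runif(n_parents, 0, window[1L])
  py <- runif(n_parents, 0, window[2L])
  n_off <- stats::rpois(n_parents, mean_offspring)
  x <- rep(px, n_off); y <- rep(py, n_off)
  m <- length(x)
  x <- (x + stats::rnorm(m, 0, sigma)) %% window[1L]
  y <- (y + stats::rnorm(m, 0, sigma)) %% window[2L]
  point_pattern(x, y, window = window, toroidal = toroidal)
}

#' Monte Carlo envelope of the centered L function
#'
#' Pointwise lower/upper quantile bounds (95% by default) of `L(r) - r`
#' across `n_sims` simulated patterns. With the default generator the null
#' is complete spatial randomness with fixed `n`; any function returning a
#' [point_pattern()] (e.g. model end states) can be supplied instead.
#'
#' @param radii radii (m) at which to evaluate the statistic.
#' @param generator function of no arguments returning a
#'   [point_pattern()] with at least 2 points.
#' @param n_sims number of simulated patterns (>= 2; the field comparison
#'   used 200).
#' @param level central coverage of the pointwise band.
#' @param seed optional integer seed.
#' @return object of class `"ripley_envelope"`: data frame-like list with
#'   `r`, `lo`, `hi`, `mean`, plus `n_sims` and `level`.
#' @export
ripley_envelope <- function(radii, generator, n_sims = 200, level = 0.95,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.function(generator), n_sims >= 2)
  sims <- vapply(seq_len(n_sims),
                 function(i) ripley_L(generator(), radii)$L_minus_r,
                 numeric(length(radii)))
  sims <- matrix(sims, nrow = length(radii))
  a <- (1 - level) / 2
  structure(list(r = as.numeric(radii),
                 lo = apply(sims, 1L, stats::quantile, probs = a,
                            names = FALSE),
                 hi = apply(sims, 1L, stats::quantile, probs = 1 - a,
                            names = FALSE),
                 mean = rowMeans(sims),
                 n_sims = n_sims, level = level),
            class = "ripley_envelope")
}

#' CSR envelope for a given point count
#'
#' Convenience wrapper around [ripley_envelope()] with a complete spatial
#' randomness generator of fixed `n`.
#'
#' @inheritParams ripley_envelope
#' @inheritParams csr_pattern
#' @return a `"ripley_envelope"`.
#' @export
csr_envelope <- function(n, radii, window = c(800, 600), n_sims = 200,
                         level = 0.95, toroidal = FALSE, seed = NULL) {
  ripley_envelope(radii,
                  function() csr_pattern(n, window, toroidal = toroidal),
                  n_sims = n_sims, level = level, seed = seed)
}

#' @export
print.ripley_envelope <- function(x, ...) {
  cat(sprintf(
    "ripley_envelope: %d radii in [%g, %g] m, %d sims, %g%% pointwise band\n",
    length(x$r), min(x$r), max(x$r), x$n_sims, 100 * x$level))
  invisible(x)
}

#' Does a pattern exceed an envelope?
#'
#' `TRUE` if the pattern's `L(r) - r` lies above the envelope's upper bound
#' for at least one radius inside `band` -- the operational definition of
#' "cluster-positive" used for scenario end states.
#'
#' @param pattern a [point_pattern()] with >= 2 points.
#' @param envelope a `"ripley_envelope"`.
#' @param band `c(lo, hi)` radius band (m) within which exceedance counts;
#'   `NULL` for all radii.
#' @return logical scalar.
#' @export
exceeds_envelope <- function(pattern, envelope, band = NULL) {
  L <- ripley_L(pattern, envelope$r)$L_minus_r
  keep <- if (is.null(band)) rep(TRUE, length(envelope$r))
          else envelope$r >= band[1L] & envelope$r <= band[2L]
  any(L[keep] > envelope$hi[keep])
}
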