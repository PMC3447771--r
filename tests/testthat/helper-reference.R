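# Independent straight-line (loop-based) reference implementations used as
# oracles. These deliberately avoid the package's vectorized code paths:
# everything is computed cell by cell with explicit neighbor enumeration.

ref_wrap <- function(i, n) ((i - 1L) %% n) + 1L

ref_moore <- function(row, col, nr, nc) {
  out <- matrix(0L, 8L, 2L)
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    k <- k + 1L
    out[k, ] <- c(ref_wrap(row + dr, nr), ref_wrap(col + dc, nc))
  }
  out
}

ref_clamp01 <- function(x) min(max(x, 0), 1)

# One full model step, cell by cell. Consumes the global RNG in the same
# documented order as model_step (seven column-major runif(n) draws), but
# every update rule is recomputed with scalar arithmetic in loops.
ref_step <- function(state, params) {
  p <- params
  nr <- nrow(state$ants); nc <- ncol(state$ants); n <- nr * nc
  ants <- state$ants; N <- state$scales; L <- state$larvae; A <- state$adults

  f2 <- function(c, Nv) c * Nv / (1 + p$g * c * Nv)

  # step 1: beetle growth (synchronous, no RNG)
  A1 <- matrix(0, nr, nc); L1 <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    cA <- if (ants[i, j] == 1) p$c_A_ant else p$c_A_noant
    A1[i, j] <- p$e * f2(p$c_L, N[i, j]) * L[i, j]
    L1[i, j] <- p$b * f2(cA, N[i, j]) * A[i, j]
  }

  # step 2a: mortality
  u <- matrix(runif(n), nr, nc)
  ants1 <- ants
  for (i in 1:nr) for (j in 1:nc) {
    if (ants[i, j] == 1) {
      pd <- ref_clamp01(p$d0 - p$d1 * N[i, j])
      if (u[i, j] < pd) ants1[i, j] <- 0
    }
  }
  # step 2b: expansion (neighbor counts from the post-mortality grid)
  u <- matrix(runif(n), nr, nc)
  ants2 <- ants1
  for (i in 1:nr) for (j in 1:nc) {
    if (ants1[i, j] == 0) {
      nb <- ref_moore(i, j, nr, nc)
      nocc <- 0
      for (k in 1:8) nocc <- nocc + ants1[nb[k, 1L], nb[k, 2L]]
      if (u[i, j] < ref_clamp01(p$a0 + p$a1 * nocc)) ants2[i, j] <- 1
    }
  }
  # step 2c: propagule rain
  u <- matrix(runif(n), nr, nc)
  ants3 <- ants2
  for (i in 1:nr) for (j in 1:nc)
    if (ants2[i, j] == 0 && u[i, j] < p$m_ant) ants3[i, j] <- 1

  # step 3: adult local then global migration, then the same for scales
  A2 <- ref_local_migration(A1, p$k_loc_A, p$mu_loc_A, nr, nc)
  A3 <- ref_global_migration(A2, ants3, p$p_glob_A_ant, p$p_glob_A_noant,
                             p$mu_glob_A, nr, nc)
  N1 <- ref_local_migration(N, p$k_loc_N, p$mu_loc_N, nr, nc)
  N2 <- ref_global_migration(N1, ants3, p$p_glob_N, p$p_glob_N,
                             p$mu_glob_N, nr, nc)

  # step 4: scale growth at post-migration values
  N3 <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    a <- ants3[i, j] == 1
    r <- if (a) p$r_ant else p$r_noant
    cA <- if (a) p$c_A_ant else p$c_A_noant
    v <- N2[i, j] + r * N2[i, j] * (1 - N2[i, j] / p$K) -
      f2(p$c_L, N2[i, j]) * L1[i, j] - f2(cA, N2[i, j]) * A3[i, j]
    N3[i, j] <- max(v, 0)
  }

  # step 5: survival
  A4 <- matrix(0, nr, nc); L2 <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    a <- ants3[i, j] == 1
    A4[i, j] <- (if (a) p$s_A_ant else p$s_A_noant) * A3[i, j]
    L2[i, j] <- (if (a) p$s_L_ant else p$s_L_noant) * L1[i, j]
  }

  list(ants = ants3, scales = N3, larvae = L2, adults = A4)
}

ref_local_migration <- function(pop, k_loc, mu_loc, nr, nc) {
  n <- nr * nc
  u <- matrix(runif(n), nr, nc)
  recv <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    nb <- ref_moore(i, j, nr, nc)
    S <- 0
    for (k in 1:8) S <- S + pop[nb[k, 1L], nb[k, 2L]]
    if (u[i, j] < ref_clamp01(k_loc * S)) recv[i, j] <- 1
  }
  nrecv <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    nb <- ref_moore(i, j, nr, nc)
    for (k in 1:8) nrecv[i, j] <- nrecv[i, j] + recv[nb[k, 1L], nb[k, 2L]]
  }
  res <- pop
  for (i in 1:nr) for (j in 1:nc) {
    demand <- mu_loc * nrecv[i, j]
    sc <- if (demand > 1) 1 / demand else 1
    res[i, j] <- res[i, j] - pop[i, j] * mu_loc * sc * nrecv[i, j]
  }
  for (i in 1:nr) for (j in 1:nc) {
    if (recv[i, j] == 1) {
      nb <- ref_moore(i, j, nr, nc)
      for (k in 1:8) {
        src <- pop[nb[k, 1L], nb[k, 2L]]
        dem <- mu_loc * nrecv[nb[k, 1L], nb[k, 2L]]
        sc <- if (dem > 1) 1 / dem else 1
        res[i, j] <- res[i, j] + src * mu_loc * sc
      }
    }
  }
  res
}

ref_global_migration <- function(pop, ants, p_ant, p_noant, mu, nr, nc) {
  n <- nr * nc
  u <- matrix(runif(n), nr, nc)
  chosen <- matrix(FALSE, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    pr <- if (ants[i, j] == 1) p_ant else p_noant
    chosen[i, j] <- u[i, j] < pr
  }
  k <- sum(chosen)
  pool <- mu * sum(pop)
  if (k == 0 || pool == 0) return(pop)
  res <- pop
  for (i in 1:nr) for (j in 1:nc) {
    res[i, j] <- pop[i, j] * (1 - mu)
    if (chosen[i, j]) res[i, j] <- res[i, j] + pool / k
  }
  res
}

# O(n^2) brute-force Ripley K
ref_ripley_K <- function(pp, radii) {
  n <- length(pp$x); W <- pp$window[1]; H <- pp$window[2]; area <- W * H
  K <- numeric(length(radii))
  for (ri in seq_along(radii)) {
    s <- 0
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      dx <- abs(pp$x[i] - pp$x[j]); dy <- abs(pp$y[i] - pp$y[j])
      if (pp$toroidal) {
        dx <- min(dx, W - dx); dy <- min(dy, H - dy)
        w <- 1
      } else {
        w <- area / ((W - dx) * (H - dy))
      }
      if (sqrt(dx^2 + dy^2) <= radii[ri]) s <- s + w
    }
    K[ri] <- s * area / n^2
  }
  K
}

# brute-force union-find single-linkage clustering
ref_clusters <- function(pp, threshold, tol = 1e-8) {
  n <- length(pp$x)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  W <- pp$window[1]; H <- pp$window[2]
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dx <- abs(pp$x[i] - pp$x[j]); dy <- abs(pp$y[i] - pp$y[j])
      if (pp$toroidal) { dx <- min(dx, W - dx); dy <- min(dy, H - dy) }
      if (sqrt(dx^2 + dy^2) <= threshold + tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# small random state for oracle comparisons
random_state <- function(nr = 4, nc = 4, seed = 1) {
  g <- lattice_geometry(nc, nr)
  init_state(g, init_spec(p_ant = 0.4, scale_max = 1,
                          larva_max = 0.8, adult_max = 0.8), seed = seed)
}

random_params <- function(seed = 1) {
  set.seed(seed)
  model_params(
    e = runif(1, 0.5, 1), b = runif(1, 2, 12),
    c_L = runif(1, 0.5, 6), c_A_ant = 0.5, c_A_noant = runif(1, 2, 5),
    g = runif(1, 0.4, 2), r_ant = runif(1, 0.3, 1.2),
    r_noant = runif(1, 0.1, 0.29),
    s_A_ant = 0.2, s_A_noant = runif(1, 0.5, 1),
    s_L_ant = runif(1, 0.6, 1), s_L_noant = 0.1,
    d0 = runif(1, 0, 0.9), d1 = runif(1, 0, 0.9),
    a0 = runif(1, 0, 0.1), a1 = runif(1, 0, 0.1),
    m_ant = runif(1, 0, 0.05),
    k_loc_A = runif(1, 0, 1), mu_loc_A = runif(1, 0, 1),
    p_glob_A_ant = 0.8, p_glob_A_noant = runif(1, 0, 0.5),
    mu_glob_A = runif(1, 0, 1),
    k_loc_N = runif(1, 0, 1), mu_loc_N = runif(1, 0, 1),
    p_glob_N = runif(1, 0, 1), mu_glob_N = runif(1, 0, 1))
}
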