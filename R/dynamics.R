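#' Holling type II functional response
#'
#' Per-capita consumption `f = c * N / (1 + g * c * N)`: linear in prey
#' density `N` when prey are scarce, saturating at the maximum predation
#' rate `1/g` when prey are abundant.
#'
#' @param c consumption (attack) rate, >= 0; may be a matrix for
#'   habitat-dependent rates.
#' @param g saturation term, > 0.
#' @param N prey (scale) density, >= 0; scalar or matrix.
#' @return consumption per predator per step, in `[0, 1/g)`.
#' @examples
#' holling2(1, 1, 1) # 0.5
#' @export
holling2 <- function(c, g, N) {
  if (!all(is.finite(g)) || any(g <= 0))
    stop("g must be > 0", call. = FALSE)
  if (any(c < 0)) stop("c must be >= 0", call. = FALSE)
  c * N / (1 + g * c * N)
}

# habitat-dependent scalar field: value v_ant where ants==1, else v_noant
hab_field <- function(ants, v_ant, v_noant) v_noant + (v_ant - v_noant) * ants

clamp01 <- function(x) pmin(pmax(x, 0), 1)

rand_mat <- function(state) {
  g <- state$geometry
  matrix(runif(g$n_rows * g$n_cols), g$n_rows, g$n_cols)
}

#' Beetle reproduction and predation (step 1)
#'
#' Synchronously replaces both beetle stages from time-t values: every
#' larva ecloses or dies within the step and every adult lives a single
#' step, so there are no carry-over terms. With `f(c) = holling2(c, g, N)`:
#' `adults' = e * f(c_L) * larvae` (eclosion fueled by larval feeding) and
#' `larvae' = b * f(c_A_h) * adults` (births fueled by adult feeding, at
#' the habitat-dependent adult consumption rate).
#'
#' @param state a `"ca_state"`.
#' @param params a [model_params()] object.
#' @return the state with `larvae` and `adults` replaced.
#' @export
beetle_growth <- function(state, params) {
  N <- state$scales
  fL <- holling2(params$c_L, params$g, N)
  cA <- hab_field(state$ants, params$c_A_ant, params$c_A_noant)
  fA <- holling2(cA, params$g, N)
  new_A <- params$e * fL * state$larvae
  new_L <- params$b * fA * state$adults
  state$adults <- new_A
  state$larvae <- new_L
  state
}

ant_death_prob <- function(params, N) clamp01(params$d0 - params$d1 * N)
ant_birth_prob <- function(params, n_occ) clamp01(params$a0 + params$a1 * n_occ)

#' Ant nest mortality (step 2a)
#'
#' Each occupied cell dies independently with probability
#' `clamp(d0 - d1 * N, 0, 1)`, a decreasing linear function of the local
#' scale density: nests starved of honeydew are the ones that die. One
#' uniform draw per cell is consumed (whole lattice, column-major).
#'
#' @inheritParams beetle_growth
#' @return the state with `ants` updated.
#' @export
ant_mortality <- function(state, params) {
  u <- rand_mat(state)
  p <- ant_death_prob(params, state$scales)
  state$ants[state$ants == 1 & u < p] <- 0
  state
}

#' Ant nest expansion by satellite nests (step 2b)
#'
#' Each empty cell is colonized with probability
#' `clamp(a0 + a1 * n_occ, 0, 1)` where `n_occ` is the number of occupied
#' Moore neighbors in the input grid (synchronous: colonizations this step
#' do not enable further colonizations this step).
#'
#' @inheritParams beetle_growth
#' @return the state with `ants` updated.
#' @export
ant_expansion <- function(state, params) {
  u <- rand_mat(state)
  n_occ <- moore_sum(state$ants)
  p <- ant_birth_prob(params, n_occ)
  state$ants[state$ants == 0 & u < p] <- 1
  state
}

#' Ant long-distance colonization as propagule rain (step 2c)
#'
#' Queens on nuptial flights found nests anywhere: each empty cell becomes
#' occupied independently with probability `m_ant`.
#'
#' @inheritParams beetle_growth
#' @return the state with `ants` updated.
#' @export
ant_propagule_rain <- function(state, params) {
  u <- rand_mat(state)
  state$ants[state$ants == 0 & u < params$m_ant] <- 1
  state
}

#' Density-dependent local migration (step 3, local part)
#'
#' Each cell fires a receive event with probability
#' `clamp(k_loc * S, 0, 1)`, where `S` is the summed density over its 8
#' Moore neighbors in the input lattice: crowded neighborhoods attract
#' migrants. A firing cell receives a fraction `mu_loc` of each neighbor's
#' (input) density, debited from that neighbor. Debits are computed against
#' the input snapshot; when a cell owes more than it holds (several
#' receiving neighbors), its outflows are scaled down proportionally so it
#' never goes negative. Total population is conserved exactly.
#'
#' @param pop non-negative numeric matrix of densities.
#' @param k_loc receive-probability sensitivity, >= 0.
#' @param mu_loc emigrant fraction per firing neighbor, in \[0, 1\].
#' @return the migrated matrix, with attribute `"moved"` holding the total
#'   mass transferred.
#' @export
local_migration <- function(pop, k_loc, mu_loc) {
  if (k_loc < 0) stop("k_loc must be >= 0", call. = FALSE)
  if (mu_loc < 0 || mu_loc > 1) stop("mu_loc must be in [0, 1]", call. = FALSE)
  u <- matrix(runif(length(pop)), nrow(pop), ncol(pop))
  S <- moore_sum(pop)
  recv <- (u < clamp01(k_loc * S)) + 0
  n_recv_nb <- moore_sum(recv)
  scale_f <- 1 / pmax(mu_loc * n_recv_nb, 1)  # proportional rescale if oversubscribed
  give <- pop * mu_loc * scale_f              # per receiving neighbor
  gains <- recv * moore_sum(give)
  # multiplicative form: the retained fraction is clamped at 0 so rounding
  # in the drain-everything case cannot produce a negative density
  retain <- pmax(1 - mu_loc * scale_f * n_recv_nb, 0)
  res <- pop * retain + gains
  attr(res, "moved") <- sum(pop * (1 - retain))
  res
}

#' Global migration as preferential propagule rain (step 3, global part)
#'
#' A pool of `mu_glob` times the total lattice population is debited from
#' all cells proportionally; each cell is independently "chosen" with its
#' habitat-dependent probability, and the pool is divided equally among
#' chosen cells. If no cell is chosen the pool stays where it was.
#' Conservation is exact. Adult beetles orient to ant pheromones
#' (`p_recv_ant > p_recv_noant`); wind-dispersed scales use equal
#' probabilities.
#'
#' @param pop non-negative numeric matrix of densities.
#' @param ants binary ant grid of the same dimension.
#' @param p_recv_ant,p_recv_noant per-cell receive probabilities in
#'   \[0, 1\] for cells with / without ants.
#' @param mu_glob emigrant fraction of the total population, in \[0, 1\].
#' @return the migrated matrix, with attribute `"pool"` holding the pool
#'   size actually redistributed.
#' @export
global_migration <- function(pop, ants, p_recv_ant, p_recv_noant, mu_glob) {
  for (v in c(p_recv_ant, p_recv_noant, mu_glob))
    if (!is.finite(v) || v < 0 || v > 1)
      stop("global migration probabilities must be in [0, 1]", call. = FALSE)
  u <- matrix(runif(length(pop)), nrow(pop), ncol(pop))
  chosen <- u < hab_field(ants, p_recv_ant, p_recv_noant)
  k <- sum(chosen)
  pool <- mu_glob * sum(pop)
  if (k == 0L || pool == 0) {
    attr(pop, "pool") <- 0
    return(pop)
  }
  res <- pop * (1 - mu_glob)
  res[chosen] <- res[chosen] + pool / k
  attr(res, "pool") <- pool
  res
}

#' Scale-insect local dynamics (step 4)
#'
#' Rosenzweig-MacArthur form with K = 1: logistic growth at the
#' habitat-dependent rate minus the same Holling II predation terms used in
#' step 1, evaluated at the current (post-migration) lattice values:
#' `N' = N + r_h N (1 - N/K) - f(c_L) L - f(c_A_h) A`, floored at 0.
#' No ceiling at K is imposed (transient logistic overshoot is allowed).
#'
#' @inheritParams beetle_growth
#' @return the state with `scales` updated.
#' @export
scale_growth <- function(state, params) {
  N <- state$scales
  r <- hab_field(state$ants, params$r_ant, params$r_noant)
  fL <- holling2(params$c_L, params$g, N)
  cA <- hab_field(state$ants, params$c_A_ant, params$c_A_noant)
  fA <- holling2(cA, params$g, N)
  state$scales <- pmax(N + r * N * (1 - N / params$K) -
                         fL * state$larvae - fA * state$adults, 0)
  state
}

#' Habitat-dependent beetle survival (step 5)
#'
#' Deterministic thinning: `adults <- s_A_h * adults`,
#' `larvae <- s_L_h * larvae`. Adults survive worse where ants patrol;
#' larvae survive better there.
#'
#' @inheritParams beetle_growth
#' @return the state with both beetle lattices thinned.
#' @export
beetle_survival <- function(state, params) {
  sA <- hab_field(state$ants, params$s_A_ant, params$s_A_noant)
  sL <- hab_field(state$ants, params$s_L_ant, params$s_L_noant)
  state$adults <- sA * state$adults
  state$larvae <- sL * state$larvae
  state
}

#' One synchronous model step
#'
#' Applies, in order: (1) [beetle_growth()]; (2) [ant_mortality()],
#' [ant_expansion()], [ant_propagule_rain()]; (3) [local_migration()] then
#' [global_migration()] for adults, then for scales; (4) [scale_growth()];
#' (5) [beetle_survival()]. Each numbered step reads the lattices produced
#' by the previous one, and `t` advances by one six-month period.
#'
#' Randomness: exactly seven `runif(n_cells)` vectors are consumed per
#' step (ant mortality, expansion, propagule rain; adult local and global
#' migration; scale local and global migration), each filling the lattice
#' in column-major order, so a seeded run is exactly reproducible. When
#' `frozen_ants = TRUE` step 2 is skipped entirely (no draws), which is how
#' the calibration fitness pins ants at 0% or 100% occupancy.
#'
#' @inheritParams beetle_growth
#' @param frozen_ants logical; skip all ant-nest dynamics.
#' @return a list with elements `state` (the successor `"ca_state"`) and
#'   `events` (named numeric: nest deaths, local/rain nest births, mass
#'   moved by each migration operation).
#' @export
model_step <- function(state, params, frozen_ants = FALSE) {
  state <- beetle_growth(state, params)
  ev <- c(nest_deaths = 0, nest_births_local = 0, nest_births_rain = 0,
          adult_moved_local = 0, adult_pool_global = 0,
          scale_moved_local = 0, scale_pool_global = 0)
  if (!frozen_ants) {
    n0 <- sum(state$ants)
    state <- ant_mortality(state, params)
    n1 <- sum(state$ants)
    state <- ant_expansion(state, params)
    n2 <- sum(state$ants)
    state <- ant_propagule_rain(state, params)
    n3 <- sum(state$ants)
    ev[["nest_deaths"]] <- n0 - n1
    ev[["nest_births_local"]] <- n2 - n1
    ev[["nest_births_rain"]] <- n3 - n2
  }
  A <- local_migration(state$adults, params$k_loc_A, params$mu_loc_A)
  ev[["adult_moved_local"]] <- attr(A, "moved")
  A <- global_migration(A, state$ants, params$p_glob_A_ant,
                        params$p_glob_A_noant, params$mu_glob_A)
  ev[["adult_pool_global"]] <- attr(A, "pool")
  attributes(A) <- attributes(A)["dim"]
  state$adults <- A
  N <- local_migration(state$scales, params$k_loc_N, params$mu_loc_N)
  ev[["scale_moved_local"]] <- attr(N, "moved")
  N <- global_migration(N, state$ants, params$p_glob_N, params$p_glob_N,
                        params$mu_glob_N)
  ev[["scale_pool_global"]] <- attr(N, "pool")
  attributes(N) <- attributes(N)["dim"]
  state$scales <- N
  state <- scale_growth(state, params)
  state <- beetle_survival(state, params)
  state$t <- state$t + 1L
  list(state = state, events = ev)
}

#' Run the model for many steps
#'
#' Repeated application of [model_step()], recording lattice totals and
#' event counts along the way.
#'
#' @inheritParams beetle_growth
#' @param n_steps number of steps (>= 0).
#' @param record_every record the trace every this many steps (the initial
#'   and final states are always recorded).
#' @param seed optional integer; seeds the global RNG before the run.
#' @param frozen_ants passed to [model_step()].
#' @param extinct_floor quasi-extinction floor: after any step in which the
#'   combined beetle total (larvae + adults) or the scale total falls below
#'   this value, that population is set to exactly zero. Multiplicative
#'   dynamics never reach zero on their own, and without a floor a
#'   population can dwindle to ~1e-30 per cell and later rebound, which has
#'   no biological reading. `0` disables the floor (the default here;
#'   [run_scenario()] enables it at its extinction threshold).
#' @return an object of class `"ca_run"`: list with `state` (final state)
#'   and `trace` (data frame with columns `t`, `n_nests`, `total_scales`,
#'   `total_larvae`, `total_adults` and the per-step event counts of the
#'   recorded step).
#' @examples
#' run <- run_model(init_state(lattice_geometry(30, 30), seed = 1),
#'                  model_params(), n_steps = 10, seed = 1)
#' run$trace[1:3, 1:5]
#' @export
run_model <- function(state, params, n_steps, record_every = 1L,
                      seed = NULL, frozen_ants = FALSE, extinct_floor = 0) {
  stopifnot(n_steps >= 0, record_every >= 1)
  if (!is.null(seed)) set.seed(seed)
  validate_state(state)
  n_steps <- as.integer(n_steps)
  rec_t <- unique(c(0L, seq_len(n_steps)[seq_len(n_steps) %% record_every == 0L],
                    n_steps))
  trace <- matrix(NA_real_, length(rec_t), 12L)
  colnames(trace) <- c("t", "n_nests", "total_scales", "total_larvae",
                       "total_adults", "nest_deaths", "nest_births_local",
                       "nest_births_rain", "adult_moved_local",
                       "adult_pool_global", "scale_moved_local",
                       "scale_pool_global")
  row <- 1L
  trace[row, ] <- c(state$t, state_totals(state), rep(0, 7))
  for (i in seq_len(n_steps)) {
    out <- model_step(state, params, frozen_ants = frozen_ants)
    state <- out$state
    if (extinct_floor > 0) {
      if (sum(state$larvae) + sum(state$adults) < extinct_floor) {
        state$larvae[] <- 0
        state$adults[] <- 0
      }
      if (sum(state$scales) < extinct_floor) state$scales[] <- 0
    }
    if (i %% record_every == 0L || i == n_steps) {
      row <- row + 1L
      trace[row, ] <- c(state$t, state_totals(state), out$events)
    }
  }
  structure(list(state = state, trace = as.data.frame(trace[seq_len(row), ,
                                                            drop = FALSE]),
                 params = params),
            class = "ca_run")
}

#' @export
print.ca_run <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf(
    "ca_run: %d recorded steps, final t = %d\n  nests %d | scales %.2f | larvae %.4f | adults %.4f\n",
    nrow(x$trace) - 1L, as.integer(last$t), as.integer(last$n_nests),
    last$total_scales, last$total_larvae, last$total_adults))
  invisible(x)
}

#' Plot population trajectories of a run
#'
#' Lattice totals of the four populations against time on a log(1 + x)
#' scale.
#'
#' @param x a `"ca_run"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ca_run <- function(x, ...) {
  tr <- x$trace
  y <- log1p(as.matrix(tr[, c("n_nests", "total_scales", "total_larvae",
                              "total_adults")]))
  graphics::matplot(tr$t, y, type = "l", lty = 1, lwd = 2,
                    col = c("black", "forestgreen", "orange", "red"),
                    xlab = "time (6-month steps)",
                    ylab = "log(1 + lattice total)", ...)
  graphics::legend("topright", c("ant nests", "scales", "larvae", "adults"),
                   col = c("black", "forestgreen", "orange", "red"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}
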