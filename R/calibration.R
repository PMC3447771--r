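#' Gene bounds for parameter calibration
#'
#' The free parameters searched by the genetic algorithm, as a named list
#' of `c(lower, upper)` bounds. Biologically ordered pairs are encoded as
#' a free larger member plus a ratio gene in (0, 1), so every decoded
#' chromosome automatically satisfies `c_A_ant < c_A_noant`,
#' `r_noant < r_ant`, `s_A_ant < s_A_noant`, `s_L_ant > s_L_noant` and
#' `p_glob_A_ant >= p_glob_A_noant`.
#'
#' @return named list of length-2 numeric vectors.
#' @export
param_bounds <- function() {
  list(e = c(0.1, 1), b = c(0.5, 10), c_L = c(0.1, 8),
       c_A_noant = c(0.1, 8), ratio_cA = c(0.005, 0.9),
       g = c(0.3, 3),
       r_ant = c(0.1, 1.5), ratio_r = c(0.5, 0.99),
       s_A_noant = c(0.1, 1), ratio_sA = c(0.02, 0.9),
       s_L_ant = c(0.1, 1), ratio_sL = c(0, 0.9),
       d0 = c(0, 1), d1 = c(0, 1),
       a0 = c(0, 0.05), a1 = c(0, 0.12), m_ant = c(0, 0.002),
       k_loc_A = c(0, 2), mu_loc_A = c(0, 1),
       p_glob_A_ant = c(0, 1), ratio_pglobA = c(0.005, 1),
       mu_glob_A = c(0, 1),
       k_loc_N = c(0, 2), mu_loc_N = c(0, 1),
       p_glob_N = c(0, 1), mu_glob_N = c(0, 1))
}

#' Decode a chromosome into model parameters
#'
#' Maps the gene vector (see [param_bounds()]) to a full [model_params()]
#' object, materializing the ratio genes into the constrained pair
#' members.
#'
#' @param x named numeric vector of genes within [param_bounds()].
#' @return a `"ca_params"` object (validated, so the ordering constraints
#'   are guaranteed to hold).
#' @export
decode_chromosome <- function(x) {
  x <- as.list(x)
  model_params(
    e = x$e, b = x$b, c_L = x$c_L,
    c_A_ant = x$ratio_cA * x$c_A_noant, c_A_noant = x$c_A_noant,
    g = x$g,
    r_ant = x$r_ant, r_noant = x$ratio_r * x$r_ant,
    s_A_ant = x$ratio_sA * x$s_A_noant, s_A_noant = x$s_A_noant,
    s_L_ant = x$s_L_ant, s_L_noant = x$ratio_sL * x$s_L_ant,
    d0 = x$d0, d1 = x$d1, a0 = x$a0, a1 = x$a1, m_ant = x$m_ant,
    k_loc_A = x$k_loc_A, mu_loc_A = x$mu_loc_A,
    p_glob_A_ant = x$p_glob_A_ant,
    p_glob_A_noant = x$ratio_pglobA * x$p_glob_A_ant,
    mu_glob_A = x$mu_glob_A,
    k_loc_N = x$k_loc_N, mu_loc_N = x$mu_loc_N,
    p_glob_N = x$p_glob_N, mu_glob_N = x$mu_glob_N)
}

#' Calibration fitness criteria
#'
#' Targets and weights for [evaluate_fitness()]. The criteria mirror the
#' calibration goals: a nest count near the ~3% field occupancy, complete
#' beetle extinction when ants are frozen at 0% and at 100% occupancy, and
#' per-cell beetle stage abundances by habitat near the field values (3.8
#' larvae per bush in ant areas, 5.8 adults at their peripheries; in model
#' units of ~10 individuals these become 0.38 and 0.58). Weights are
#' scaled so each deviation term is O(1) at total failure.
#'
#' @param target_nests target ant-nest count at the evaluation horizon.
#' @param target_larva_ant,target_adult_ant target per-cell larva / adult
#'   density in ant cells.
#' @param target_larva_noant,target_adult_noant targets in ant-free cells.
#' @param w_nests,w_stages,w_extinct penalty weights (>= 0, at least one
#'   positive).
#' @param horizon evaluation run length in steps.
#' @param n_replicates replicates averaged per condition.
#' @param geometry lattice used for fitness runs.
#' @param init an [init_spec()].
#' @param extinct_tol extinction threshold for the frozen-ant runs.
#' @return an object of class `"fitness_spec"`.
#' @export
fitness_spec <- function(target_nests = 324,
                         target_larva_ant = 0.38, target_adult_ant = 0.58,
                         target_larva_noant = 0.05,
                         target_adult_noant = 0.1,
                         w_nests = 1, w_stages = 1, w_extinct = 5,
                         horizon = 100, n_replicates = 1,
                         geometry = lattice_geometry(),
                         init = init_spec(), extinct_tol = 1e-6) {
  if (w_nests < 0 || w_stages < 0 || w_extinct < 0 ||
      (w_nests + w_stages + w_extinct) <= 0)
    stop("weights must be >= 0 with at least one positive", call. = FALSE)
  structure(list(target_nests = target_nests,
                 target_larva_ant = target_larva_ant,
                 target_adult_ant = target_adult_ant,
                 target_larva_noant = target_larva_noant,
                 target_adult_noant = target_adult_noant,
                 w_nests = w_nests, w_stages = w_stages,
                 w_extinct = w_extinct, horizon = horizon,
                 n_replicates = n_replicates, geometry = geometry,
                 init = init, extinct_tol = extinct_tol),
            class = "fitness_spec")
}

#' Fitness of a parameter combination
#'
#' Runs (a) the full model, (b) the model with ants frozen at 0%
#' occupancy, and (c) frozen at 100%, each for `spec$horizon` steps and
#' `spec$n_replicates` replicates, then scores
#' `-(w_nests * |nests - target| / target
#'    + w_stages * sum over stages/habitats of |mean - target| / target
#'    + w_extinct * (beetles alive in (b)) + w_extinct * (alive in (c)))`.
#' Higher is better; zero is perfect. A run that produces non-finite
#' densities scores `-Inf` rather than crashing. Deterministic for a given
#' `seed`.
#'
#' @param x a named gene vector (decoded via [decode_chromosome()]) or a
#'   `"ca_params"` object.
#' @param spec a [fitness_spec()].
#' @param seed integer seed for the replicate runs.
#' @return scalar fitness (<= 0).
#' @export
evaluate_fitness <- function(x, spec = fitness_spec(), seed = 1) {
  params <- if (inherits(x, "ca_params")) x else decode_chromosome(x)
  g <- spec$geometry
  dev <- 0
  alive0 <- alive1 <- FALSE
  nests <- 0
  stage_dev <- 0
  ok <- TRUE
  for (i in seq_len(spec$n_replicates)) {
    s <- as.integer(seed + 7919L * (i - 1L))
    # (a) full model
    st <- init_state(g, spec$init, seed = s)
    run <- tryCatch(run_model(st, params, spec$horizon,
                              record_every = spec$horizon),
                    error = function(e) NULL)
    if (is.null(run) || !all(is.finite(unlist(state_totals(run$state))))) {
      ok <- FALSE; break
    }
    fin <- run$state
    nests <- nests + sum(fin$ants)
    occ <- fin$ants == 1
    m <- function(M, cells) if (any(cells)) mean(M[cells]) else 0
    stage_dev <- stage_dev +
      abs(m(fin$larvae, occ) - spec$target_larva_ant) / spec$target_larva_ant +
      abs(m(fin$adults, occ) - spec$target_adult_ant) / spec$target_adult_ant +
      abs(m(fin$larvae, !occ) - spec$target_larva_noant) / spec$target_larva_noant +
      abs(m(fin$adults, !occ) - spec$target_adult_noant) / spec$target_adult_noant
    # (b) ants frozen at 0% occupancy
    st0 <- init_state(g, spec$init, seed = s)
    st0$ants[] <- 0
    run0 <- run_model(st0, params, spec$horizon,
                      record_every = spec$horizon, frozen_ants = TRUE)
    b0 <- sum(run0$state$larvae) + sum(run0$state$adults)
    # (c) ants frozen at 100% occupancy
    st1 <- init_state(g, spec$init, seed = s)
    st1$ants[] <- 1
    run1 <- run_model(st1, params, spec$horizon,
                      record_every = spec$horizon, frozen_ants = TRUE)
    b1 <- sum(run1$state$larvae) + sum(run1$state$adults)
    if (!is.finite(b0) || !is.finite(b1)) { ok <- FALSE; break }
    alive0 <- alive0 || b0 >= spec$extinct_tol
    alive1 <- alive1 || b1 >= spec$extinct_tol
  }
  if (!ok) return(-Inf)
  nr <- spec$n_replicates
  -(spec$w_nests * abs(nests / nr - spec$target_nests) / spec$target_nests +
      spec$w_stages * stage_dev / nr +
      spec$w_extinct * alive0 + spec$w_extinct * alive1)
}

#' Generational genetic algorithm
#'
#' Real-coded GA with tournament selection, uniform crossover, per-gene
#' Gaussian mutation and single-individual elitism, the search strategy
#' used to calibrate the model in place of unavailable fitted values.
#' `n_restarts` independent instantiations mirror running the search on
#' several machines at once; each restart starts from a fresh random
#' population.
#'
#' @param fitness function mapping a named gene vector to a scalar
#'   (higher is better). For model calibration use
#'   `function(x) evaluate_fitness(x, spec, seed)`.
#' @param bounds named list of `c(lower, upper)` per gene (e.g.
#'   [param_bounds()]).
#' @param pop_size population size (>= 2; the calibration runs used 100).
#' @param n_generations generations per restart.
#' @param n_restarts independent GA instantiations.
#' @param seed optional integer seed.
#' @param tournament_k tournament size.
#' @param p_crossover probability a child is produced by uniform crossover
#'   (otherwise it is a copy of one parent).
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_sd_frac mutation standard deviation as a fraction of the
#'   gene range.
#' @param verbose print per-generation best fitness.
#' @return object of class `"ga_result"`: `best_par` (named gene vector),
#'   `best_fitness`, `history` (list per restart of per-generation max
#'   fitness), `restart_best` (final best fitness per restart).
#' @export
run_ga <- function(fitness, bounds, pop_size = 100, n_generations = 50,
                   n_restarts = 1, seed = NULL, tournament_k = 3,
                   p_crossover = 0.9, mutation_rate = 0.1,
                   mutation_sd_frac = 0.05, verbose = FALSE) {
  if (!length(bounds)) stop("empty bounds", call. = FALSE)
  stopifnot(pop_size >= 2, n_generations >= 1, n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hi <- vapply(bounds, `[`, numeric(1), 2L)
  if (any(hi < lo)) stop("bounds must satisfy lower <= upper", call. = FALSE)
  ng <- length(bounds)
  gene_names <- names(bounds)
  rng <- hi - lo
  best_par <- NULL; best_fit <- -Inf
  history <- vector("list", n_restarts)
  restart_best <- numeric(n_restarts)
  for (rs in seq_len(n_restarts)) {
    pop <- matrix(runif(pop_size * ng, rep(lo, each = pop_size),
                        rep(hi, each = pop_size)), pop_size, ng)
    colnames(pop) <- gene_names
    fit <- apply(pop, 1L, function(v) fitness(stats::setNames(v, gene_names)))
    hist_rs <- numeric(n_generations)
    rs_best <- max(fit)
    rs_best_par <- stats::setNames(pop[which.max(fit), ], gene_names)
    for (gen in seq_len(n_generations)) {
      elite <- which.max(fit)
      newpop <- matrix(NA_real_, pop_size, ng, dimnames = list(NULL, gene_names))
      newpop[1L, ] <- pop[elite, ]
      for (k in seq.int(2L, pop_size)) {
        i1 <- tournament(fit, tournament_k)
        if (runif(1) < p_crossover) {
          i2 <- tournament(fit, tournament_k)
          mask <- runif(ng) < 0.5
          child <- ifelse(mask, pop[i1, ], pop[i2, ])
        } else child <- pop[i1, ]
        mut <- runif(ng) < mutation_rate
        if (any(mut))
          child[mut] <- child[mut] +
            stats::rnorm(sum(mut), 0, mutation_sd_frac * rng[mut])
        newpop[k, ] <- pmin(pmax(child, lo), hi)
      }
      pop <- newpop
      fit <- apply(pop, 1L, function(v) fitness(stats::setNames(v, gene_names)))
      # elitism: the previous best is carried over unchanged, so with a
      # deterministic fitness the per-generation max cannot decrease
      hist_rs[gen] <- max(fit)
      if (hist_rs[gen] > rs_best) {
        rs_best <- hist_rs[gen]
        rs_best_par <- stats::setNames(pop[which.max(fit), ], gene_names)
      }
      if (verbose)
        message(sprintf("restart %d gen %d: max fitness %.6g", rs, gen,
                        hist_rs[gen]))
    }
    history[[rs]] <- hist_rs
    restart_best[rs] <- rs_best
    if (rs_best > best_fit) {
      best_fit <- rs_best
      best_par <- rs_best_par
    }
  }
  structure(list(best_par = best_par, best_fitness = best_fit,
                 history = history, restart_best = restart_best),
            class = "ga_result")
}

tournament <- function(fit, k) {
  cand <- sample.int(length(fit), k, replace = TRUE)
  cand[which.max(fit[cand])]
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("ga_result: best fitness %.6g over %d restart(s)\n",
              x$best_fitness, length(x$history)))
  cat("best genes:\n")
  print(round(x$best_par, 5))
  invisible(x)
}
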