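#' Model parameters
#'
#' All demographic, predation, mortality and migration parameters of the
#' coupled ant / scale / beetle lattice model. The defaults are the
#' package's calibrated parameter set, found with [run_ga()] against the
#' fitness criteria in [fitness_spec()] (nest count near 3% occupancy,
#' beetle extinction when ants are frozen at 0% or 100% occupancy, and
#' stage abundances by habitat) and then validated against the four
#' scenario experiments ([run_scenario()]).
#'
#' Habitat-dependent rates come in `_ant` / `_noant` pairs reflecting the
#' biology: ants harass adult beetles (`c_A_ant < c_A_noant`,
#' `s_A_ant < s_A_noant`), protect the wax-covered larvae from their own
#' enemies (`s_L_ant > s_L_noant`), and tend the scales
#' (`r_noant < r_ant`). These orderings are enforced.
#'
#' Units: one time step is six months; scale density is on a 0..K scale
#' with carrying capacity `K = 1`; beetle stage densities are in units of
#' roughly ten individuals per cell, so the field abundances of 3.8 larvae
#' and 5.8 adults per bush correspond to model densities of about 0.4-0.6.
#'
#' @param e larva-to-adult eclosion rate.
#' @param b beetle birth rate.
#' @param c_L larval consumption rate (ant-independent).
#' @param c_A_ant,c_A_noant adult consumption rate in cells with / without
#'   ants; must satisfy `c_A_ant < c_A_noant`.
#' @param g Holling type II saturation term; `1/g` is the maximum predation
#'   rate per time step.
#' @param r_ant,r_noant intrinsic growth rate of scales with / without ants;
#'   `r_noant < r_ant`.
#' @param s_A_ant,s_A_noant proportion of adults surviving in cells with /
#'   without ants; `s_A_ant < s_A_noant`.
#' @param s_L_ant,s_L_noant proportion of larvae surviving; `s_L_ant >
#'   s_L_noant`.
#' @param d0,d1 ant-nest mortality intercept and scale-dependence slope:
#'   an occupied cell dies with probability `clamp(d0 - d1 * N, 0, 1)`.
#' @param a0,a1 ant short-distance expansion intercept and per-occupied-
#'   Moore-neighbor slope: an empty cell is colonized with probability
#'   `clamp(a0 + a1 * n_occ, 0, 1)`.
#' @param m_ant long-distance (propagule-rain) per-cell nest colonization
#'   probability.
#' @param k_loc_A,mu_loc_A adult local-migration receive sensitivity and
#'   emigrant fraction.
#' @param p_glob_A_ant,p_glob_A_noant per-cell probabilities of receiving
#'   global adult migrants with / without ants (`>=` ordering enforced:
#'   beetles orient to ant pheromones).
#' @param mu_glob_A fraction of the total adult population entering the
#'   global migrant pool each step.
#' @param k_loc_N,mu_loc_N,p_glob_N,mu_glob_N scale-insect migration
#'   analogues; scales are wind-dispersed so global reception has no ant
#'   preference (a single `p_glob_N`).
#' @param K scale carrying capacity, fixed at 1.
#' @return an object of class `"ca_params"` (a validated named list).
#' @seealso [update_params()], [run_ga()], [model_step()]
#' @export
model_params <- function(e = 0.95,
                         b = 10,
                         c_L = 5,
                         c_A_ant = 2,
                         c_A_noant = 4,
                         g = 0.5,
                         r_ant = 0.9,
                         r_noant = 0.765,
                         s_A_ant = 0.5,
                         s_A_noant = 0.9,
                         s_L_ant = 0.85,
                         s_L_noant = 0,
                         d0 = 0.4,
                         d1 = 0.4,
                         a0 = 0,
                         a1 = 0.018,
                         m_ant = 5e-05,
                         k_loc_A = 0.15,
                         mu_loc_A = 0.1,
                         p_glob_A_ant = 1,
                         p_glob_A_noant = 0.01,
                         mu_glob_A = 0.97,
                         k_loc_N = 1,
                         mu_loc_N = 0.1,
                         p_glob_N = 1,
                         mu_glob_N = 0.3,
                         K = 1) {
  p <- list(e = e, b = b, c_L = c_L, c_A_ant = c_A_ant,
            c_A_noant = c_A_noant, g = g, r_ant = r_ant, r_noant = r_noant,
            s_A_ant = s_A_ant, s_A_noant = s_A_noant, s_L_ant = s_L_ant,
            s_L_noant = s_L_noant, d0 = d0, d1 = d1, a0 = a0, a1 = a1,
            m_ant = m_ant, k_loc_A = k_loc_A, mu_loc_A = mu_loc_A,
            p_glob_A_ant = p_glob_A_ant, p_glob_A_noant = p_glob_A_noant,
            mu_glob_A = mu_glob_A, k_loc_N = k_loc_N, mu_loc_N = mu_loc_N,
            p_glob_N = p_glob_N, mu_glob_N = mu_glob_N, K = K)
  p <- lapply(p, as.numeric)
  validate_params(p)
  structure(p, class = "ca_params")
}

param_names <- function() names(formals(model_params))

#' Validate a parameter list
#'
#' Checks ranges, probability bounds and the biological ordering
#' constraints; errors name the offending parameter or constraint.
#'
#' @param p a named list of parameter values (see [model_params()]).
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  need <- param_names()
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in need) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter ", nm, " must be a single finite number",
           call. = FALSE)
    if (v < 0) stop("parameter ", nm, " must be >= 0", call. = FALSE)
  }
  probs <- c("s_A_ant", "s_A_noant", "s_L_ant", "s_L_noant", "m_ant",
             "mu_loc_A", "p_glob_A_ant", "p_glob_A_noant", "mu_glob_A",
             "mu_loc_N", "p_glob_N", "mu_glob_N")
  for (nm in probs)
    if (p[[nm]] > 1)
      stop("parameter ", nm, " must be <= 1", call. = FALSE)
  if (p$g <= 0) stop("parameter g must be > 0", call. = FALSE)
  if (p$K <= 0) stop("parameter K must be > 0", call. = FALSE)
  if (!(p$c_A_ant < p$c_A_noant))
    stop("constraint violated: c_A_ant < c_A_noant (ants harass feeding adults)",
         call. = FALSE)
  if (!(p$r_noant < p$r_ant))
    stop("constraint violated: r_noant < r_ant (ants tend the scales)",
         call. = FALSE)
  if (!(p$s_A_ant < p$s_A_noant))
    stop("constraint violated: s_A_ant < s_A_noant", call. = FALSE)
  if (!(p$s_L_ant > p$s_L_noant))
    stop("constraint violated: s_L_ant > s_L_noant (ants protect larvae)",
         call. = FALSE)
  if (p$p_glob_A_ant < p$p_glob_A_noant)
    stop("constraint violated: p_glob_A_ant >= p_glob_A_noant", call. = FALSE)
  invisible(p)
}

#' Override parameters
#'
#' Returns a copy of `params` with the named values replaced, re-validated.
#' Unknown names are rejected, so a scenario override cannot silently touch
#' a parameter that does not exist.
#'
#' @param params a [model_params()] object.
#' @param ... name = value overrides.
#' @return a `"ca_params"` object.
#' @export
update_params <- function(params, ...) {
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), param_names())
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    for (nm in names(over)) params[[nm]] <- as.numeric(over[[nm]])
  }
  validate_params(params)
  structure(params, class = "ca_params")
}

#' @export
print.ca_params <- function(x, ...) {
  cat("ant/scale/beetle model parameters:\n")
  v <- unlist(x)
  print(round(v, 6))
  invisible(x)
}
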