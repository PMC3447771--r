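#' Initialization specification
#'
#' How to randomize the starting lattices. Ant nests are scattered i.i.d.
#' Bernoulli(`p_ant`); each population density is drawn i.i.d.
#' Uniform(0, max) per cell (a max of 0 gives an all-zero lattice). The
#' defaults place nests at the ~3% tree occupancy observed in the field and
#' start scales well below carrying capacity with sparse beetles.
#'
#' @param p_ant probability that a cell starts with a nest, in \[0, 1\].
#' @param scale_max,larva_max,adult_max upper ends of the uniform initial
#'   density ranges (>= 0, finite).
#' @return an object of class `"init_spec"`.
#' @export
init_spec <- function(p_ant = 0.03, scale_max = 0.5,
                      larva_max = 0.2, adult_max = 0.2) {
  spec <- list(p_ant = as.numeric(p_ant), scale_max = as.numeric(scale_max),
               larva_max = as.numeric(larva_max),
               adult_max = as.numeric(adult_max))
  if (!is.finite(spec$p_ant) || spec$p_ant < 0 || spec$p_ant > 1)
    stop("p_ant must be a probability in [0, 1]", call. = FALSE)
  for (nm in c("scale_max", "larva_max", "adult_max"))
    if (!is.finite(spec[[nm]]) || spec[[nm]] < 0)
      stop(nm, " must be a finite non-negative density", call. = FALSE)
  structure(spec, class = "init_spec")
}

#' Random initial model state
#'
#' Scatters ant nests, scales and beetles at random over the lattice.
#' Draw order is fixed (ants, scales, larvae, adults; one column-major
#' `runif` vector each), so the same seed reproduces the state bit for bit.
#'
#' @param geometry a [lattice_geometry()].
#' @param init an [init_spec()].
#' @param seed optional integer seed; if given, the global RNG is seeded
#'   before drawing.
#' @return an object of class `"ca_state"`: a list with the four lattices
#'   (`ants` binary, `scales`, `larvae`, `adults` non-negative numeric
#'   matrices of dimension n_rows x n_cols), the `geometry`, and the time
#'   index `t` (in six-month steps, starting at 0).
#' @examples
#' st <- init_state(lattice_geometry(), seed = 1)
#' sum(st$ants) # about 3% of 10800
#' @export
init_state <- function(geometry = lattice_geometry(), init = init_spec(),
                       seed = NULL) {
  stopifnot(inherits(geometry, "lattice_geometry"))
  if (!inherits(init, "init_spec")) init <- do.call(init_spec, init)
  if (!is.null(seed)) set.seed(seed)
  nr <- geometry$n_rows; nc <- geometry$n_cols; n <- nr * nc
  ants <- matrix(as.numeric(runif(n) < init$p_ant), nr, nc)
  scales <- matrix(runif(n, 0, init$scale_max), nr, nc)
  larvae <- matrix(runif(n, 0, init$larva_max), nr, nc)
  adults <- matrix(runif(n, 0, init$adult_max), nr, nc)
  new_state(geometry, ants, scales, larvae, adults, t = 0L)
}

new_state <- function(geometry, ants, scales, larvae, adults, t = 0L) {
  structure(list(geometry = geometry, ants = ants, scales = scales,
                 larvae = larvae, adults = adults, t = as.integer(t)),
            class = "ca_state")
}

#' Validate a model state
#'
#' Checks that the four lattices share the geometry's dimensions, that the
#' ant grid is binary, and that all densities are finite and non-negative.
#'
#' @param state a `"ca_state"` object.
#' @return `state`, invisibly.
#' @export
validate_state <- function(state) {
  stopifnot(inherits(state, "ca_state"))
  g <- state$geometry
  for (nm in c("ants", "scales", "larvae", "adults")) {
    M <- state[[nm]]
    if (!is.matrix(M) || nrow(M) != g$n_rows || ncol(M) != g$n_cols)
      stop("lattice ", nm, " does not match geometry dimensions",
           call. = FALSE)
    if (!all(is.finite(M)))
      stop("lattice ", nm, " contains non-finite values", call. = FALSE)
    if (any(M < 0))
      stop("lattice ", nm, " contains negative values", call. = FALSE)
  }
  if (!all(state$ants %in% c(0, 1)))
    stop("ant grid must contain only zeros and ones", call. = FALSE)
  if (state$t < 0L) stop("t must be >= 0", call. = FALSE)
  invisible(state)
}

#' Translate a model state on the torus
#'
#' Shifts all four lattices by the same `(dx, dy)`; with periodic
#' boundaries the model dynamics commute with this operation.
#'
#' @param state a `"ca_state"`.
#' @param dx,dy integer shifts in columns / rows.
#' @return the translated `"ca_state"`.
#' @export
translate_state <- function(state, dx = 0L, dy = 0L) {
  for (nm in c("ants", "scales", "larvae", "adults"))
    state[[nm]] <- translate_grid(state[[nm]], dx, dy)
  state
}

state_totals <- function(state) {
  c(n_nests = sum(state$ants), total_scales = sum(state$scales),
    total_larvae = sum(state$larvae), total_adults = sum(state$adults))
}

#' @export
print.ca_state <- function(x, ...) {
  tot <- state_totals(x)
  cat(sprintf(
    "ca_state: %d x %d lattice at t = %d\n  nests %d | scales %.2f | larvae %.2f | adults %.2f (lattice totals)\n",
    x$geometry$n_cols, x$geometry$n_rows, x$t,
    as.integer(tot[["n_nests"]]), tot[["total_scales"]],
    tot[["total_larvae"]], tot[["total_adults"]]))
  invisible(x)
}

#' @export
summary.ca_state <- function(object, ...) {
  ants <- object$ants == 1
  hab <- function(M) c(mean_ant = if (any(ants)) mean(M[ants]) else NA_real_,
                       mean_noant = if (any(!ants)) mean(M[!ants]) else NA_real_)
  out <- list(t = object$t, n_nests = sum(ants),
              occupancy = mean(ants),
              scales = hab(object$scales), larvae = hab(object$larvae),
              adults = hab(object$adults))
  class(out) <- "summary.ca_state"
  out
}

#' @export
print.summary.ca_state <- function(x, ...) {
  cat(sprintf("t = %d: %d nests (%.2f%% occupancy)\n", x$t, x$n_nests,
              100 * x$occupancy))
  cat("per-cell means (ant cells | ant-free cells):\n")
  for (nm in c("scales", "larvae", "adults"))
    cat(sprintf("  %-7s %.4f | %.4f\n", nm, x[[nm]][["mean_ant"]],
                x[[nm]][["mean_noant"]]))
  invisible(x)
}
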