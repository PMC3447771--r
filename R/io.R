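#' Run configuration
#'
#' A validated bundle of geometry, parameters, initialization, scenario
#' and statistics settings plus a seed, serializable to JSON (the
#' package's configuration dialect) via [save_config()] /
#' [load_config()].
#'
#' @param geometry a [lattice_geometry()] or a named list of its fields.
#' @param params a [model_params()] or a named list of overrides applied
#'   to the calibrated defaults.
#' @param init an [init_spec()] or a named list of its fields.
#' @param scenario list with any of `id`, `n_steps`, `n_replicates`.
#' @param stats list with any of `cluster_threshold`, `radii` (numeric
#'   vector, m), `n_sims`, `level`.
#' @param seed integer seed recorded with the run.
#' @param out_dir output directory for CLI runs.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(geometry = list(), params = list(), init = list(),
                       scenario = list(), stats = list(), seed = 1,
                       out_dir = ".") {
  as_block <- function(x, fields, builder) {
    if (!is.list(x)) stop("config block must be a list", call. = FALSE)
    x <- unclass(x)
    bad <- setdiff(names(x), fields)
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    do.call(builder, x)
  }
  geometry <- as_block(geometry, names(formals(lattice_geometry)),
                       lattice_geometry)
  params <- if (inherits(params, "ca_params")) params
            else do.call(update_params, c(list(model_params()),
                                          unclass(params)))
  init <- as_block(init, names(formals(init_spec)), init_spec)
  scen_def <- list(id = "D", n_steps = 500, n_replicates = 20)
  stats_def <- list(cluster_threshold = 20, radii = seq(5, 150, by = 5),
                    n_sims = 200, level = 0.95)
  fill <- function(given, def, block) {
    given <- unclass(given)
    bad <- setdiff(names(given), names(def))
    if (length(bad))
      stop("unknown config key(s) in ", block, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    def[names(given)] <- given
    def
  }
  scenario <- fill(scenario, scen_def, "scenario")
  if (!scenario$id %in% c("A", "B", "C", "D"))
    stop("scenario id must be one of A, B, C, D", call. = FALSE)
  stats <- fill(stats, stats_def, "stats")
  structure(list(geometry = geometry, params = params, init = init,
                 scenario = scenario, stats = stats,
                 seed = as.integer(seed), out_dir = as.character(out_dir)),
            class = "run_config")
}

#' Write a configuration to JSON
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(geometry = unclass(config$geometry),
              params = unclass(config$params),
              init = unclass(config$init),
              scenario = config$scenario, stats = config$stats,
              seed = config$seed, out_dir = config$out_dir)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load and validate a JSON configuration
#'
#' Unknown keys (at the top level or inside any block) are rejected, and
#' every block is rebuilt through its constructor, so constraint
#' violations surface with the offending key named. Omitted values fall
#' back to the package defaults.
#'
#' @param path file path to a JSON configuration.
#' @return a [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("geometry", "params", "init", "scenario", "stats", "seed",
             "out_dir")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- raw[intersect(known, names(raw))]
  do.call(run_config, args)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "run_config: scenario %s, %d steps x %d replicates, seed %d\n",
    x$scenario$id, x$scenario$n_steps, x$scenario$n_replicates, x$seed))
  print(x$geometry)
  invisible(x)
}

#' Write / read nest coordinates as CSV
#'
#' Plain CSV with header `x_m,y_m`, coordinates in metres at full
#' precision (round-trips are exact).
#'
#' @param pattern a [point_pattern()].
#' @param path file path.
#' @return `write_pattern_csv`: `path` invisibly. `read_pattern_csv`: a
#'   [point_pattern()].
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  lines <- c("x_m,y_m",
             sprintf("%.17g,%.17g", pattern$x, pattern$y))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @param window,toroidal window metadata for the pattern being read (CSV
#'   stores coordinates only).
#' @export
read_pattern_csv <- function(path, window = c(800, 600), toroidal = FALSE) {
  df <- utils::read.csv(path)
  if (!all(c("x_m", "y_m") %in% names(df)))
    stop("pattern CSV must have columns x_m and y_m", call. = FALSE)
  point_pattern(df$x_m, df$y_m, window = window, toroidal = toroidal)
}

#' Write / read a dense lattice as CSV
#'
#' One CSV row per lattice row, values at full precision; round-trips are
#' bit-identical.
#'
#' @param M a numeric matrix.
#' @param path file path.
#' @return `write_grid_csv`: `path` invisibly; `read_grid_csv`: a matrix.
#' @export
write_grid_csv <- function(M, path) {
  writeLines(apply(M, 1L, function(r) paste(sprintf("%.17g", r),
                                            collapse = ",")), path)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  rows <- strsplit(readLines(path), ",", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

#' Write a run's time series as CSV
#'
#' Columns `t`, `n_nests`, `total_scales`, `total_larvae`, `total_adults`
#' plus the event counts, one row per recorded step (population totals
#' are raw; plot on a log(1+x) scale downstream).
#'
#' @param run a `"ca_run"` from [run_model()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(run, path) {
  tr <- if (inherits(run, "ca_run")) run$trace else run
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}

#' Snapshot a model state to a directory
#'
#' Writes the four lattices as dense CSV grids, the nest coordinates as a
#' pattern CSV, and a JSON metadata record (time index, geometry).
#' [read_state()] restores the identical state.
#'
#' @param state a `"ca_state"`.
#' @param dir directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_state <- function(state, dir) {
  validate_state(state)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("ants", "scales", "larvae", "adults"))
    write_grid_csv(state[[nm]], file.path(dir, paste0(nm, ".csv")))
  write_pattern_csv(grid_to_points(state), file.path(dir, "nests.csv"))
  jsonlite::write_json(list(t = state$t,
                            geometry = unclass(state$geometry)),
                       file.path(dir, "state.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_state
#' @export
read_state <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "state.json"),
                              simplifyVector = TRUE)
  geometry <- do.call(lattice_geometry, meta$geometry)
  grids <- lapply(c("ants", "scales", "larvae", "adults"),
                  function(nm) read_grid_csv(file.path(dir,
                                                       paste0(nm, ".csv"))))
  st <- new_state(geometry, grids[[1L]], grids[[2L]], grids[[3L]],
                  grids[[4L]], t = meta$t)
  validate_state(st)
  st
}

# 32-bit FNV-1a over a string; cheap content fingerprint for provenance.
# The multiply is split into 16-bit halves so it stays exact in doubles.
fnv1a <- function(s) {
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(s)) {
    low8 <- h %% 256
    h <- h - low8 + bitwXor(as.integer(low8), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Write a machine-readable provenance record
#'
#' JSON with the package version, R version, seed, and a fingerprint of
#' the configuration, written alongside any CLI output so a run can be
#' reproduced exactly.
#'
#' @param dir output directory.
#' @param seed the seed the run used.
#' @param config optional [run_config()] echoed into the record.
#' @return the file path, invisibly.
#' @export
write_provenance <- function(dir, seed, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- if (is.null(config)) "" else
    as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                  digits = NA, force = TRUE))
  rec <- list(package = "antscape",
              version = as.character(utils::packageVersion("antscape")),
              r_version = as.character(getRversion()),
              timestamp = format(Sys.time(), tz = "UTC"),
              seed = seed,
              config_hash = fnv1a(cfg_json))
  if (!is.null(config)) rec$config <- unclass(config)
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Generate a synthetic fixture
#'
#' Synthetic stand-ins for the field nest surveys (which are not shipped):
#' `"csr"` gives complete spatial randomness, `"clustered"` a Thomas-like
#' parent-offspring pattern whose L function exceeds CSR envelopes the way
#' the field data do, and `"grid-snapshot"` a Bernoulli occupancy grid.
#' Deterministic under `seed`.
#'
#' @param kind one of `"csr"`, `"clustered"`, `"grid-snapshot"`.
#' @param n point count (`csr`).
#' @param window `c(width, height)` in metres.
#' @param n_parents,mean_offspring,sigma clustered-pattern settings (see
#'   [thomas_pattern()]).
#' @param p_occupy occupancy probability (`grid-snapshot`).
#' @param geometry lattice for `grid-snapshot`.
#' @param seed optional integer seed.
#' @param path optional file path; patterns are written with
#'   [write_pattern_csv()], grids with [write_grid_csv()].
#' @return the generated [point_pattern()] or occupancy matrix.
#' @export
make_fixture <- function(kind = c("csr", "clustered", "grid-snapshot"),
                         n = 282, window = c(800, 600), n_parents = 30,
                         mean_offspring = 10, sigma = 10, p_occupy = 0.03,
                         geometry = lattice_geometry(), seed = NULL,
                         path = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  out <- switch(kind,
    "csr" = csr_pattern(n, window),
    "clustered" = thomas_pattern(n_parents, mean_offspring, sigma, window),
    "grid-snapshot" = matrix(as.numeric(
      runif(geometry$n_rows * geometry$n_cols) < p_occupy),
      geometry$n_rows, geometry$n_cols))
  if (!is.null(path)) {
    if (inherits(out, "point_pattern")) write_pattern_csv(out, path)
    else write_grid_csv(out, path)
  }
  out
}
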