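#' Lattice geometry of the study plot
#'
#' Defines the rectangular grid on which all four populations live. The
#' default is the 120 x 90 cell grid with periodic (toroidal) boundaries
#' representing an 800 m x 600 m coffee plot, so each cell -- one shade tree
#' plus its surrounding coffee bushes -- is 800/120 = 600/90 = 6.667 m on a
#' side.
#'
#' Cells are addressed 1-based as (col, row); the metric center of cell
#' (col, row) is ((col - 0.5) * cell_size, (row - 0.5) * cell_size), which
#' is the mapping used when converting an occupancy grid to a point pattern.
#'
#' @param n_cols,n_rows integer number of columns / rows (each >= 3).
#' @param cell_size edge length of a cell in metres (> 0).
#' @param toroidal logical; periodic boundaries. The simulation model always
#'   uses `TRUE`; the flag is carried so that point patterns derived from a
#'   grid know which distance to use.
#' @return an object of class `"lattice_geometry"`.
#' @examples
#' g <- lattice_geometry()
#' g$n_cols * g$n_rows # 10800 potential nest sites
#' @export
lattice_geometry <- function(n_cols = 120L, n_rows = 90L,
                             cell_size = 800 / 120, toroidal = TRUE) {
  n_cols <- as.integer(n_cols)
  n_rows <- as.integer(n_rows)
  if (is.na(n_cols) || is.na(n_rows) || n_cols < 3L || n_rows < 3L)
    stop("n_cols and n_rows must be integers >= 3", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L ||
      !is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive finite number", call. = FALSE)
  structure(
    list(n_cols = n_cols, n_rows = n_rows,
         cell_size = as.numeric(cell_size), toroidal = isTRUE(toroidal)),
    class = "lattice_geometry"
  )
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat(sprintf("lattice_geometry: %d x %d cells, %.4g m/cell (%g m x %g m)%s\n",
              x$n_cols, x$n_rows, x$cell_size,
              x$n_cols * x$cell_size, x$n_rows * x$cell_size,
              if (x$toroidal) ", periodic boundaries" else ""))
  invisible(x)
}

#' Moore neighborhood of a cell
#'
#' The 8 cells surrounding `cell`, with toroidal wrap-around at the lattice
#' edges. Short-distance ant-nest expansion and local migration both read
#' this neighborhood.
#'
#' @param cell integer vector `c(col, row)`, 1-based.
#' @param geometry a [lattice_geometry()].
#' @return an 8 x 2 integer matrix with columns `col`, `row`.
#' @export
moore_neighbors <- function(cell, geometry) {
  col <- as.integer(cell[[1L]]); row <- as.integer(cell[[2L]])
  if (col < 1L || col > geometry$n_cols || row < 1L || row > geometry$n_rows)
    stop("cell outside lattice bounds", call. = FALSE)
  off <- cbind(col = rep(-1:1, times = 3L), row = rep(-1:1, each = 3L))
  off <- off[!(off[, 1L] == 0L & off[, 2L] == 0L), , drop = FALSE]
  nb <- cbind(col = (col - 1L + off[, 1L]) %% geometry$n_cols + 1L,
              row = (row - 1L + off[, 2L]) %% geometry$n_rows + 1L)
  storage.mode(nb) <- "integer"
  nb
}

# Sum of the 8 Moore neighbors for every cell at once, on the torus.
# Two separable passes (rows then columns) over shifted copies; the center
# cell is subtracted from the 3x3 box sum.
moore_sum <- function(M) {
  nr <- nrow(M); nc <- ncol(M)
  rup <- c(nr, seq_len(nr - 1L)); rdn <- c(seq.int(2L, nr), 1L)
  R <- M[rup, , drop = FALSE] + M + M[rdn, , drop = FALSE]
  cl <- c(nc, seq_len(nc - 1L)); cr <- c(seq.int(2L, nc), 1L)
  R[, cl, drop = FALSE] + R + R[, cr, drop = FALSE] - M
}

#' Translate a lattice toroidally
#'
#' Shifts a matrix by `dx` columns and `dy` rows with wrap-around. Used to
#' verify that neighborhood queries commute with translation on the torus.
#'
#' @param M a matrix.
#' @param dx,dy integer shifts (any sign).
#' @return the shifted matrix: cell (col, row) of the result holds what cell
#'   (col - dx, row - dy) (mod lattice) held in `M`.
#' @export
translate_grid <- function(M, dx = 0L, dy = 0L) {
  nr <- nrow(M); nc <- ncol(M)
  rows <- (seq_len(nr) - 1L - as.integer(dy)) %% nr + 1L
  cols <- (seq_len(nc) - 1L - as.integer(dx)) %% nc + 1L
  M[rows, cols, drop = FALSE]
}
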