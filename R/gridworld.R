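#' Movement and target-identification class labels
#'
#' Movement actions fall into four classes: `TT` (towards the target without
#' reaching it), `TR` (target reached), `FA` (further away from an off-target
#' location) and `SO` (stepped off the target).  Target-identification
#' actions are `CTI` (correct target identification) or `FTI` (false target
#' identification).  The orderings are fixed throughout the package: they
#' index the rows and columns of every likelihood matrix and the entries of
#' one-hot observation vectors.
#'
#' @format Character vectors of class labels in canonical order.
#' @name action-classes
NULL

#' @rdname action-classes
#' @export
MOVEMENT_CLASSES <- c("TT", "TR", "FA", "SO")

#' @rdname action-classes
#' @export
TI_CLASSES <- c("CTI", "FTI")

#' Construct a rectangular grid world
#'
#' The robot navigates a grid of `n_rows` by `n_cols` cells with
#' 4-connectivity (no diagonal moves).  Cells are addressed either as
#' `c(row, col)` pairs (1-based, as in all user-facing output) or internally
#' as single cell indices in column-major order.
#'
#' @param n_rows,n_cols Positive integers; the grid must contain at least
#'   two cells.
#' @return An object of class `grid_world`: a list with `n_rows`, `n_cols`,
#'   `n_cells`, per-cell `row` and `col` lookup vectors, and a precomputed
#'   neighbour list `nbrs` (cell index -> integer vector of adjacent cell
#'   indices).
#' @examples
#' g <- grid_world(9, 1)
#' g$n_cells
#' @export
grid_world <- function(n_rows, n_cols) {
  stopifnot(length(n_rows) == 1, length(n_cols) == 1)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1)
    stop("grid dimensions must be positive integers")
  if (n_rows * n_cols < 2)
    stop("grid must contain at least 2 cells")
  n_cells <- n_rows * n_cols
  idx <- seq_len(n_cells)
  row <- ((idx - 1L) %% n_rows) + 1L
  col <- ((idx - 1L) %/% n_rows) + 1L
  nbrs <- vector("list", n_cells)
  for (k in idx) {
    out <- integer(0)
    if (row[k] > 1L)      out <- c(out, k - 1L)
    if (row[k] < n_rows)  out <- c(out, k + 1L)
    if (col[k] > 1L)      out <- c(out, k - n_rows)
    if (col[k] < n_cols)  out <- c(out, k + n_rows)
    nbrs[[k]] <- out
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, n_cells = n_cells,
         row = row, col = col, nbrs = nbrs),
    class = "grid_world")
}

#' @export
print.grid_world <- function(x, ...) {
  cat(sprintf("<grid_world %d x %d (%d cells)>\n", x$n_rows, x$n_cols,
              x$n_cells))
  invisible(x)
}

# ---- position helpers -------------------------------------------------

#' Convert between (row, col) positions and cell indices
#'
#' @param grid A [grid_world()].
#' @param p A position `c(row, col)` (1-based) or, for `cell_to_pos`, a cell
#'   index.
#' @return `pos_to_cell` gives the column-major cell index; `cell_to_pos`
#'   the `c(row, col)` pair.
#' @keywords internal
#' @export
pos_to_cell <- function(grid, p) {
  p <- as.integer(p)
  if (length(p) != 2 || anyNA(p))
    stop("position must be a c(row, col) pair")
  if (p[1] < 1 || p[1] > grid$n_rows || p[2] < 1 || p[2] > grid$n_cols)
    stop(sprintf("position [%d, %d] outside %d x %d grid",
                 p[1], p[2], grid$n_rows, grid$n_cols))
  (p[2] - 1L) * grid$n_rows + p[1]
}

#' @rdname pos_to_cell
#' @param cell A cell index in `1:grid$n_cells`.
#' @export
cell_to_pos <- function(grid, cell) {
  cell <- as.integer(cell)
  if (cell < 1 || cell > grid$n_cells) stop("cell index outside grid")
  c(grid$row[cell], grid$col[cell])
}

#' Manhattan distance between two grid positions
#'
#' Distance to the target is defined as the minimum number of 4-connected
#' steps between two cells, i.e. \eqn{|r_a - r_b| + |c_a - c_b|}.
#'
#' @param grid A [grid_world()].
#' @param a,b Positions as `c(row, col)` pairs.
#' @return Non-negative integer number of steps.
#' @examples
#' g <- grid_world(20, 20)
#' manhattan_distance(g, c(2, 2), c(5, 5))  # 6
#' @export
manhattan_distance <- function(grid, a, b) {
  ca <- pos_to_cell(grid, a)
  cb <- pos_to_cell(grid, b)
  abs(grid$row[ca] - grid$row[cb]) + abs(grid$col[ca] - grid$col[cb])
}

# internal, vectorised over cell indices
.cell_dist <- function(grid, cells, cell) {
  abs(grid$row[cells] - grid$row[cell]) + abs(grid$col[cells] - grid$col[cell])
}

#' In-grid 4-neighbours of a position
#'
#' @inheritParams manhattan_distance
#' @param p Position `c(row, col)`.
#' @return A matrix with one row per neighbouring position and columns
#'   `row`, `col`; between 1 and 4 rows.
#' @export
neighbours <- function(grid, p) {
  k <- pos_to_cell(grid, p)
  nb <- grid$nbrs[[k]]
  cbind(row = grid$row[nb], col = grid$col[nb])
}

#' True class of an observed movement
#'
#' Given the (hidden) target, every adjacent move belongs to exactly one
#' class: `TR` if the destination is the target, `SO` if the origin was the
#' target, otherwise `TT` when the move reduces the Manhattan distance to
#' the target and `FA` when it increases it.  A 4-connected move always
#' changes the distance by exactly 1, so the four classes are exhaustive
#' and mutually exclusive.
#'
#' @inheritParams manhattan_distance
#' @param origin,destination Positions `c(row, col)`; must be 4-adjacent.
#' @param target Position of the true target.
#' @return One of `"TT"`, `"TR"`, `"FA"`, `"SO"`.
#' @examples
#' g <- grid_world(20, 20)
#' true_movement_class(g, c(2, 2), c(2, 3), target = c(5, 5))  # "TT"
#' true_movement_class(g, c(2, 2), c(2, 1), target = c(5, 5))  # "FA"
#' @export
true_movement_class <- function(grid, origin, destination, target) {
  co <- pos_to_cell(grid, origin)
  cd <- pos_to_cell(grid, destination)
  ct <- pos_to_cell(grid, target)
  if (.cell_dist(grid, co, cd) != 1L)
    stop("origin and destination are not 4-adjacent")
  .movement_class_cells(grid, co, cd, ct)
}

# internal version on cell indices; `ct` may be a hypothesised target
.movement_class_cells <- function(grid, co, cd, ct) {
  if (cd == ct) return("TR")
  if (co == ct) return("SO")
  if (.cell_dist(grid, cd, ct) < .cell_dist(grid, co, ct)) "TT" else "FA"
}

#' True class of a target-identification action
#'
#' Identifying cell `p` is a correct target identification (`CTI`) exactly
#' when `p` is the target, otherwise a false one (`FTI`).
#'
#' @inheritParams true_movement_class
#' @param p Position being identified.
#' @return `"CTI"` or `"FTI"`.
#' @export
true_ti_class <- function(grid, p, target) {
  if (pos_to_cell(grid, p) == pos_to_cell(grid, target)) "CTI" else "FTI"
}

#' Initialise a simulated run
#'
#' The target is placed uniformly at random over all cells; the robot
#' starts at a cell drawn uniformly from all cells at Manhattan distance at
#' least 2 from the target (no maximum distance).
#'
#' @inheritParams manhattan_distance
#' @return A list of class `episode_state` with elements `grid`,
#'   `target`, `robot` (cell indices), `previous` (`NA` before the first
#'   move), `t` (movement counter) and `initial_distance`.
#' @export
init_episode <- function(grid) {
  target <- sample.int(grid$n_cells, 1L)
  eligible <- which(.cell_dist(grid, seq_len(grid$n_cells), target) >= 2L)
  if (length(eligible) == 0L)
    stop("grid too small: no start cell at distance >= 2 from target")
  robot <- eligible[sample.int(length(eligible), 1L)]
  structure(
    list(grid = grid, target = target, robot = robot, previous = NA_integer_,
         t = 0L, initial_distance = .cell_dist(grid, robot, target)),
    class = "episode_state")
}

#' First step of a shortest path
#'
#' Returns a neighbour of `from` one step closer to `to`; when both axis
#' moves qualify (2-D grids) one is chosen uniformly at random.
#'
#' @inheritParams manhattan_distance
#' @param from,to Positions `c(row, col)` with `from != to`.
#' @return A position `c(row, col)` adjacent to `from`.
#' @export
shortest_path_first_step <- function(grid, from, to) {
  cf <- pos_to_cell(grid, from)
  ct <- pos_to_cell(grid, to)
  if (cf == ct) stop("already at destination: no move to make")
  cell_to_pos(grid, .first_step_cells(grid, cf, ct))
}

.first_step_cells <- function(grid, cf, ct) {
  nb <- grid$nbrs[[cf]]
  d0 <- .cell_dist(grid, cf, ct)
  closer <- nb[.cell_dist(grid, nb, ct) == d0 - 1L]
  if (length(closer) == 1L) closer else closer[sample.int(length(closer), 1L)]
}
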