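#' Next action under the React strategy
#'
#' React places full trust in the most recent classifier output and keeps
#' no longer-term memory.  A `TR` output triggers identification of the
#' current cell; an error output (`FA` or `SO`) sends the robot back to
#' its previous cell, undoing the move; a `TT` output sends it to a random
#' neighbour excluding the previous cell (the exclusion lasts one action
#' only).  Before any output is available -- the first action, or the
#' action following an undone identification -- all neighbours are
#' eligible.  On a 1-D grid end-cell whose only neighbour is the previous
#' cell, the `TT` exclusion is waived so the robot can still move.
#'
#' @param grid A [grid_world()].
#' @param current Current position `c(row, col)`.
#' @param previous Previous position, or `NULL` if none applies.
#' @param last_obs Latest movement classifier output, or `NULL`.
#' @return A list `list(type = "identify"|"move", cell = <position>)`.
#' @export
react_next_action <- function(grid, current, previous = NULL,
                              last_obs = NULL) {
  cc <- pos_to_cell(grid, current)
  cp <- if (is.null(previous)) NA_integer_ else pos_to_cell(grid, previous)
  if (!is.null(last_obs)) {
    if (identical(last_obs, "TR"))
      return(list(type = "identify", cell = current))
    if (last_obs %in% c("FA", "SO")) {
      if (is.na(cp)) stop("cannot undo an error with no previous position")
      return(list(type = "move", cell = cell_to_pos(grid, cp)))
    }
    if (!identical(last_obs, "TT"))
      stop(sprintf("'%s' is not a movement observation", last_obs))
  }
  nb <- grid$nbrs[[cc]]
  if (identical(last_obs, "TT") && !is.na(cp)) {
    keep <- nb[nb != cp]
    if (length(keep) > 0L) nb <- keep  # waive exclusion at a dead end
  }
  nxt <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
  list(type = "move", cell = cell_to_pos(grid, nxt))
}

#' Next action under the Random baseline strategy
#'
#' With probability `1/(n*m)` the current cell is identified as the target
#' (ending the run; this baseline uses no identification classification);
#' otherwise the robot moves to a uniformly random in-grid neighbour.
#'
#' @param grid A [grid_world()].
#' @param current Current position `c(row, col)`.
#' @return A list `list(type = "identify"|"move", cell = <position>)`.
#' @export
random_next_action <- function(grid, current) {
  cc <- pos_to_cell(grid, current)
  if (stats::runif(1) < 1 / grid$n_cells)
    return(list(type = "identify", cell = current))
  nb <- grid$nbrs[[cc]]
  nxt <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
  list(type = "move", cell = cell_to_pos(grid, nxt))
}
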