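#' Uniform prior over candidate target locations
#'
#' At the start of each run every cell has probability `1/(n*m)` of being
#' the target.  The posterior field is stored as a numeric vector over cell
#' indices (column-major), summing to 1.
#'
#' @param grid A [grid_world()].
#' @return Numeric vector of length `grid$n_cells`.
#' @export
posterior_init <- function(grid) {
  rep(1 / grid$n_cells, grid$n_cells)
}

#' Counterfactual class of a move under a hypothesised target
#'
#' The Bayes update asks, for every cell: *if this cell were the target,
#' what class would the observed move have been?*  The rule is identical to
#' [true_movement_class()] evaluated with the hypothesised cell as target.
#'
#' @inheritParams true_movement_class
#' @param hypothesised_target The cell assumed to be the target.
#' @return One of `"TT"`, `"TR"`, `"FA"`, `"SO"`.
#' @examples
#' g <- grid_world(9, 1)
#' # move from location 5 to 6 on the 1-D grid
#' counterfactual_state(g, c(5, 1), c(6, 1), hypothesised_target = c(3, 1))
#' @export
counterfactual_state <- function(grid, origin, destination,
                                 hypothesised_target) {
  true_movement_class(grid, origin, destination, hypothesised_target)
}

# Vectorised counterfactual class indices (into MOVEMENT_CLASSES) for all
# cells of the grid, for a move between cell indices co -> cd.
.counterfactual_all <- function(grid, co, cd) {
  cells <- seq_len(grid$n_cells)
  d_orig <- .cell_dist(grid, cells, co)
  d_dest <- .cell_dist(grid, cells, cd)
  cls <- ifelse(d_dest < d_orig, 1L, 3L)  # TT else FA
  cls[cd] <- 2L                           # destination hypothesis: TR
  cls[co] <- 4L                           # origin hypothesis: SO
  cls
}

#' Bayesian posterior update after a movement observation
#'
#' Each cell's posterior mass is multiplied by the likelihood of the
#' classifier output under the counterfactual class the move would have had
#' if that cell were the target, divided by the marginal probability of the
#' output, and the field is renormalised to sum to 1 over the grid.  (The
#' marginal divisor is constant across cells and cancels in the
#' normalisation; it is applied for fidelity to the update's textbook form.)
#'
#' @param posterior Numeric posterior vector from [posterior_init()] or a
#'   previous update.
#' @param grid A [grid_world()].
#' @param origin,destination The observed move, as `c(row, col)` positions.
#' @param observation Classifier output: a movement class label, or a
#'   numeric probability vector of length 4 for soft (graded) outputs, in
#'   which case the effective likelihood column is the weighted average of
#'   the columns of `A`.
#' @param A A 4-by-4 movement [likelihood_matrix()] (the robot's assumed
#'   model).
#' @return The updated posterior vector (sums to 1).
#' @export
bayes_update_movement <- function(posterior, grid, origin, destination,
                                  observation, A) {
  co <- pos_to_cell(grid, origin)
  cd <- pos_to_cell(grid, destination)
  if (.cell_dist(grid, co, cd) != 1L)
    stop("origin and destination are not 4-adjacent")
  k <- ncol(A)
  lik_row <- .observation_row(observation, A)
  cls <- if (k == 4L) .counterfactual_all(grid, co, cd)
         else .binary_counterfactual_all(grid, co, cd)
  .posterior_update(posterior, lik_row[cls], marginal = sum(lik_row) / k)
}

# binary variant: counterfactual classes collapsed to correct (TT/TR) = 1,
# error (FA/SO) = 2
.binary_counterfactual_all <- function(grid, co, cd) {
  cls4 <- .counterfactual_all(grid, co, cd)
  ifelse(cls4 <= 2L, 1L, 2L)
}

# likelihood row P(O_t | state j) for all states j: one-hot label -> a row
# of A; numeric weights -> weighted average of rows (soft observation)
.observation_row <- function(observation, A) {
  if (is.character(observation)) {
    i <- match(observation, rownames(A))
    if (is.na(i))
      stop(sprintf("observation '%s' does not match this likelihood matrix",
                   observation))
    A[i, ]
  } else if (is.numeric(observation)) {
    if (length(observation) != nrow(A) || any(observation < 0))
      stop("soft observation must be a non-negative vector over the classes")
    as.numeric(observation %*% A) / sum(observation)
  } else stop("observation must be a class label or a numeric weight vector")
}

.posterior_update <- function(posterior, lik, marginal) {
  unnorm <- as.numeric(lik) * posterior / marginal
  s <- sum(unnorm)
  if (s <= 0) stop("posterior update annihilated all probability mass")
  unnorm / s
}

#' Bayesian posterior update after a target-identification observation
#'
#' After a deselection (identification judged false), the posterior is
#' updated with the 2-by-2 identification likelihood matrix.  The
#' counterfactual class is `CTI` for the identified cell -- if it were the
#' target, the identification would have been correct -- and `FTI` for
#' every other cell.
#'
#' @inheritParams bayes_update_movement
#' @param loc The identified position `c(row, col)`.
#' @param observation An identification class label (`"CTI"` or `"FTI"`)
#'   or a soft length-2 weight vector.
#' @param A2 The 2-by-2 identification [likelihood_matrix()].
#' @return The updated posterior vector.
#' @export
bayes_update_ti <- function(posterior, grid, loc, observation, A2) {
  cl <- pos_to_cell(grid, loc)
  if (!all(dim(A2) == 2)) stop("identification likelihood matrix must be 2 x 2")
  lik_row <- .observation_row(observation, A2)
  cls <- rep(2L, grid$n_cells)  # FTI hypothesis everywhere ...
  cls[cl] <- 1L                 # ... except the identified cell (CTI)
  .posterior_update(posterior, lik_row[cls], marginal = sum(lik_row) / 2)
}

#' Evidence thresholds for a stringency setting
#'
#' The stringency parameter (0.1 to 0.9) controls how much posterior mass
#' the robot's current cell must hold before it is identified as the
#' target.  Two thresholds are derived: a lower one, applied when the
#' latest movement output is `TR` (`lower = stringency`, so at stringency
#' 0.1 a `TR` output triggers identification once the cell holds more than
#' a 10% chance), and a higher one applied otherwise
#' (`upper = (stringency + 0.1) / (stringency + 0.2)`, which at stringency
#' 0.1 equals 2/3 -- the cell must be more than twice as likely as all
#' other cells combined).  The upper formula is also the single threshold
#' used by the binary-classification variant.
#'
#' @param stringency Numeric in \[0.1, 0.9\].
#' @return A list with `stringency`, `lower`, `upper`.
#' @export
stringency_thresholds <- function(stringency) {
  if (stringency < 0.1 - 1e-12 || stringency > 0.9 + 1e-12)
    stop("stringency must lie in [0.1, 0.9]")
  list(stringency = stringency,
       lower = stringency,
       upper = (stringency + 0.1) / (stringency + 0.2))
}

#' Should the current cell be identified as the target?
#'
#' Run after the posterior has been updated for a movement action.  The
#' current cell is identified when the movement output was `TR` and its
#' posterior exceeds the lower threshold, or when the output was not `TR`
#' but the posterior exceeds the upper threshold.  The binary variant,
#' which has no `TR` output, uses the upper threshold alone.
#'
#' @param p_current Posterior probability of the robot's current cell.
#' @param last_obs The latest movement classifier output (a movement class
#'   label, or a binary-variant label `"correct"`/`"error"`).
#' @param thresholds A list from [stringency_thresholds()].
#' @param binary Logical; `TRUE` for the binary-classification variant.
#' @return `TRUE` to identify the current cell, else `FALSE`.
#' @examples
#' th <- stringency_thresholds(0.1)
#' decide_identification(0.15, "TR", th)   # TRUE
#' decide_identification(0.70, "TT", th)   # TRUE (0.70 > 2/3)
#' @export
decide_identification <- function(p_current, last_obs, thresholds,
                                  binary = FALSE) {
  if (last_obs %in% TI_CLASSES)
    stop("decide_identification expects a movement observation")
  if (binary) return(p_current > thresholds$upper)
  if (identical(last_obs, "TR")) p_current > thresholds$lower
  else p_current > thresholds$upper
}

#' Next action under the Bayesian-inference strategy
#'
#' If the identification rule fires, the action is to identify the current
#' cell.  Otherwise the robot targets the cell with the highest posterior
#' probability (ties broken uniformly at random) and takes the first step
#' of a shortest path towards it.  When the argmax is the current cell but
#' the identification thresholds are unmet, the robot steps towards the
#' most probable *other* cell to gather discriminating evidence.
#'
#' @param posterior Posterior vector.
#' @param grid A [grid_world()].
#' @param current Current position `c(row, col)`.
#' @param last_obs Latest movement classifier output.
#' @param thresholds From [stringency_thresholds()].
#' @param binary Logical; binary-variant decision rule.
#' @return A list: either `list(type = "identify", cell = current)` or
#'   `list(type = "move", cell = <next position>)`, positions as
#'   `c(row, col)`.
#' @export
next_action_bayes <- function(posterior, grid, current, last_obs, thresholds,
                              binary = FALSE) {
  cc <- pos_to_cell(grid, current)
  if (decide_identification(posterior[cc], last_obs, thresholds, binary))
    return(list(type = "identify", cell = current))
  goal <- .argmax_goal(posterior, cc)
  list(type = "move",
       cell = cell_to_pos(grid, .first_step_cells(grid, cc, goal)))
}

# argmax cell of the posterior, ties uniform at random; if the argmax is
# the current cell, the best other cell is used instead
.argmax_goal <- function(posterior, current_cell) {
  mx <- max(posterior)
  cand <- which(posterior >= mx - 1e-15)
  goal <- if (length(cand) == 1L) cand else cand[sample.int(length(cand), 1L)]
  if (goal == current_cell) {
    others <- posterior
    others[current_cell] <- -Inf
    mx2 <- max(others)
    cand2 <- which(others >= mx2 - 1e-15)
    goal <- if (length(cand2) == 1L) cand2
            else cand2[sample.int(length(cand2), 1L)]
  }
  goal
}
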