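#' Simulate one navigation run
#'
#' Runs a single episode: the target and start cell are drawn by
#' [init_episode()], the first action is a uniformly random neighbour move
#' (all strategies), and thereafter the chosen strategy proposes actions.
#' After every movement the true class is labelled against the hidden
#' target and a classifier output is sampled from the participant's
#' movement sampler matrix, standing in for single-trial EEG
#' classification.  Identification actions (except under the Random
#' strategy and the `no_tic` variant) trigger a sampled identification
#' output: `CTI` ends the run, `FTI` deselects the cell and the run
#' continues.  Runs exceeding `step_cap` movement actions are terminated
#' and flagged `capped` (and scored incorrect).
#'
#' @param strategy `"bayes"`, `"react"` or `"random"`.
#' @param grid A [grid_world()].
#' @param profile A `participant_profile` (required for `bayes` and
#'   `react`).
#' @param stringency Evidence threshold setting in \[0.1, 0.9\]
#'   (Bayesian strategy only).
#' @param variant Bayesian system variant: `"full"` (4-way movement
#'   classification + identification classification), `"no_tic"` (run ends
#'   at the first identification action) or `"binary"` (collapsed 2-by-2
#'   correct/error movement model with the single threshold
#'   `(stringency + 0.1) / (stringency + 0.2)`).
#' @param step_cap Maximum number of movement actions (default
#'   `50 * n_cells`).
#' @return A one-row data frame: `participant`, `strategy`, `variant`,
#'   `stringency`, `grid`, `movement_steps`, `initial_distance`,
#'   `identified_row`, `identified_col`, `correct`, `n_deselections`,
#'   `capped`.
#' @examples
#' set.seed(1)
#' p <- participant_profile(diag(4), diag(2))
#' run_episode("bayes", grid_world(9, 1), p, stringency = 0.5)
#' @export
run_episode <- function(strategy = c("bayes", "react", "random"), grid,
                        profile = NULL, stringency = 0.5,
                        variant = c("full", "no_tic", "binary"),
                        step_cap = 50 * grid$n_cells) {
  rec <- .episode(match.arg(strategy), grid, profile, stringency,
                  match.arg(variant), step_cap)
  as.data.frame(rec, stringsAsFactors = FALSE)
}

# Engine on cell indices; returns a plain list (one record).
.episode <- function(strategy, grid, profile, stringency, variant, step_cap) {
  if (strategy != "random" && is.null(profile))
    stop(sprintf("the %s strategy requires a participant profile", strategy))
  st <- init_episode(grid)
  target <- st$target
  cur <- st$robot
  d0 <- st$initial_distance
  res <- if (strategy == "random") {
    # every Random action -- including the first -- identifies with
    # probability 1/(n*m), else moves
    .loop_random(grid, cur, target, 0L, step_cap)
  } else {
    # classifier-driven strategies need an observation before they can
    # act: the first action is a uniformly random neighbour move
    nb <- grid$nbrs[[cur]]
    prev <- cur
    cur <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
    if (strategy == "react")
      .loop_react(grid, cur, prev, target, profile, 1L, step_cap)
    else
      .loop_bayes(grid, cur, prev, target, profile, stringency,
                  variant, 1L, step_cap)
  }
  list(participant = if (is.null(profile)) "none" else profile$id,
       strategy = strategy,
       variant = if (strategy == "bayes") variant else "full",
       stringency = if (strategy == "bayes") stringency else NA_real_,
       grid = sprintf("%dx%d", grid$n_rows, grid$n_cols),
       movement_steps = res$steps,
       initial_distance = d0,
       identified_row = if (is.na(res$identified)) NA_integer_
                        else grid$row[res$identified],
       identified_col = if (is.na(res$identified)) NA_integer_
                        else grid$col[res$identified],
       correct = !res$capped && !is.na(res$identified) &&
                 res$identified == target,
       n_deselections = res$ndesel,
       capped = res$capped)
}

.loop_random <- function(grid, cur, target, steps, step_cap) {
  p_id <- 1 / grid$n_cells
  repeat {
    if (stats::runif(1) < p_id)
      return(list(identified = cur, steps = steps, ndesel = 0L,
                  capped = FALSE))
    nb <- grid$nbrs[[cur]]
    cur <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
    steps <- steps + 1L
    if (steps >= step_cap)
      return(list(identified = NA_integer_, steps = steps, ndesel = 0L,
                  capped = TRUE))
  }
}

.loop_react <- function(grid, cur, prev, target, profile, steps, step_cap) {
  Amv <- profile$movement_sampler
  Ati <- profile$ti_sampler
  ndesel <- 0L
  repeat {
    true_cls <- .movement_class_cells(grid, prev, cur, target)
    obs <- .sample_col(Amv, match(true_cls, MOVEMENT_CLASSES))
    if (obs == 2L) {  # TR output: identify the current cell
      ti_true <- if (cur == target) 1L else 2L
      if (.sample_col(Ati, ti_true) == 1L)  # CTI output ends the run
        return(list(identified = cur, steps = steps, ndesel = ndesel,
                    capped = FALSE))
      ndesel <- ndesel + 1L
      # identification undone; next action: any neighbour is eligible
      nb <- grid$nbrs[[cur]]
      nxt <- if (length(nb) == 1L) nb else nb[sample.int(length(nb), 1L)]
    } else if (obs == 1L) {  # TT output: exclude previous for one action
      nb <- grid$nbrs[[cur]]
      keep <- nb[nb != prev]
      if (length(keep) == 0L) keep <- nb  # dead end: waive the exclusion
      nxt <- if (length(keep) == 1L) keep
             else keep[sample.int(length(keep), 1L)]
    } else {  # FA or SO output: move back, undoing the error
      nxt <- prev
    }
    prev <- cur
    cur <- nxt
    steps <- steps + 1L
    if (steps >= step_cap)
      return(list(identified = NA_integer_, steps = steps, ndesel = ndesel,
                  capped = TRUE))
  }
}

.loop_bayes <- function(grid, cur, prev, target, profile, stringency,
                        variant, steps, step_cap) {
  th <- stringency_thresholds(stringency)
  binary <- identical(variant, "binary")
  Amv_s <- profile$movement_sampler
  Amv_a <- profile$movement_assumed
  if (binary) {
    Amv_s <- .collapse_likelihood(Amv_s)
    Amv_a <- .collapse_likelihood(Amv_a)
  }
  Ati_s <- profile$ti_sampler
  Ati_a <- profile$ti_assumed
  k <- ncol(Amv_a)
  posterior <- posterior_init(grid)
  ndesel <- 0L
  repeat {
    # --- classify the movement just performed and update the posterior
    true_cls <- .movement_class_cells(grid, prev, cur, target)
    j <- match(true_cls, MOVEMENT_CLASSES)
    if (binary) j <- if (j <= 2L) 1L else 2L
    obs <- .sample_col(Amv_s, j)
    lik_row <- Amv_a[obs, ]
    cls <- if (binary) .binary_counterfactual_all(grid, prev, cur)
           else .counterfactual_all(grid, prev, cur)
    posterior <- .posterior_update(posterior, lik_row[cls],
                                   marginal = sum(lik_row) / k)
    obs_label <- rownames(Amv_a)[obs]
    # --- identification decision
    if (decide_identification(posterior[cur], obs_label, th,
                              binary = binary)) {
      if (identical(variant, "no_tic"))
        return(list(identified = cur, steps = steps, ndesel = 0L,
                    capped = FALSE))
      ti_true <- if (cur == target) 1L else 2L
      if (.sample_col(Ati_s, ti_true) == 1L)
        return(list(identified = cur, steps = steps, ndesel = ndesel,
                    capped = FALSE))
      # FTI output: deselect and downdate the identified cell
      ndesel <- ndesel + 1L
      lik_ti <- Ati_a[2L, ]
      cls_ti <- rep(2L, grid$n_cells)
      cls_ti[cur] <- 1L
      posterior <- .posterior_update(posterior, lik_ti[cls_ti],
                                     marginal = sum(lik_ti) / 2)
    }
    # --- next movement: towards the most probable cell
    goal <- .argmax_goal(posterior, cur)
    prev <- cur
    cur <- .first_step_cells(grid, cur, goal)
    steps <- steps + 1L
    if (steps >= step_cap)
      return(list(identified = NA_integer_, steps = steps, ndesel = ndesel,
                  capped = TRUE))
  }
}

#' Percentage of targets correctly identified (PTCI)
#'
#' @param records A data frame of run records (from [run_episode()] or
#'   [run_sweep()]) with a logical `correct` column.
#' @return `100 * (number correct) / (number of runs)`.
#' @export
ptci <- function(records) {
  if (NROW(records) == 0) stop("no run records")
  100 * mean(records$correct)
}

#' Mean normalised steps (MNS)
#'
#' Over runs ending in a correct identification, the number of movement
#' actions divided by the initial start-to-target Manhattan distance,
#' averaged.  Normalisation accounts for the variable starting distance;
#' 1.0 is a direct shortest path.
#'
#' @inheritParams ptci
#' @return The mean normalised step count, or `NA` if no run was correct.
#' @export
mns <- function(records) {
  if (NROW(records) == 0) stop("no run records")
  ok <- records$correct
  if (!any(ok)) return(NA_real_)
  mean(records$movement_steps[ok] / records$initial_distance[ok])
}

#' Run a simulation sweep
#'
#' Simulates every combination of grid, strategy, variant, stringency and
#' participant for `runs_per_participant` runs each, with a reproducible
#' per-combination seed derived from `seed`.  Stringency and variant are
#' Bayesian-strategy parameters; for other strategies a single placeholder
#' combination is run and non-default values are ignored with a warning.
#'
#' @param grids Named list of [grid_world()] objects (names used as grid
#'   labels; defaults to the 9x1 and 20x20 study grids).
#' @param strategies Character vector from `c("bayes", "react", "random")`.
#' @param profiles List of `participant_profile` objects (one virtual
#'   subject each).
#' @param stringencies Numeric vector of stringency settings (Bayesian
#'   strategy; default `seq(0.1, 0.9, by = 0.1)`).
#' @param variants Character vector of Bayesian variants.
#' @param runs_per_participant Runs per combination per participant
#'   (default 1000).
#' @param seed Integer base seed.
#' @param step_cap Per-episode movement cap (default `50 * n_cells`).
#' @return A data frame with one row per run (see [run_episode()]).
#' @seealso [aggregate_sweep()] for participant-level summaries.
#' @export
run_sweep <- function(grids = list(`9x1` = grid_world(9, 1),
                                   `20x20` = grid_world(20, 20)),
                      strategies = "bayes", profiles,
                      stringencies = seq(0.1, 0.9, by = 0.1),
                      variants = "full", runs_per_participant = 1000,
                      seed = 1, step_cap = NULL) {
  stopifnot(runs_per_participant >= 1)
  if (any(!strategies %in% c("bayes", "react", "random")))
    stop("unknown strategy")
  out <- vector("list", 0L)
  combo <- 0L
  for (gname in names(grids)) {
    grid <- grids[[gname]]
    cap <- if (is.null(step_cap)) 50L * grid$n_cells else step_cap
    for (strat in strategies) {
      strs <- if (strat == "bayes") stringencies else NA_real_
      vars <- if (strat == "bayes") variants else "full"
      if (strat != "bayes" &&
          (length(stringencies) > 1 || length(variants) > 1))
        warning(sprintf(
          "stringency/variant settings do not apply to the %s strategy",
          strat))
      for (v in vars) for (s in strs) for (pi in seq_along(profiles)) {
        combo <- combo + 1L
        set.seed(derive_seed(seed, combo))
        recs <- vector("list", runs_per_participant)
        for (r in seq_len(runs_per_participant))
          recs[[r]] <- .episode(strat, grid, profiles[[pi]],
                                if (is.na(s)) 0.5 else s,
                                v, cap)
        out[[length(out) + 1L]] <- .bind_records(recs)
      }
    }
  }
  do.call(rbind, out)
}

# bind a list of .episode() record lists into a data frame, column-wise
.bind_records <- function(recs) {
  fields <- names(recs[[1L]])
  cols <- lapply(fields, function(f)
    unlist(lapply(recs, `[[`, f), use.names = FALSE))
  names(cols) <- fields
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Derive a reproducible sub-seed
#'
#' Expands one base seed into independent per-combination seeds, kept
#' within the 32-bit integer range.
#'
#' @param seed Integer base seed.
#' @param i Positive integer stream index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 48271) %% 2147483647)
}

#' Aggregate a sweep into participant-level summary rows
#'
#' For each (grid, strategy, variant, stringency) combination, computes
#' PTCI and MNS per participant and reports their mean and standard
#' deviation across participants, matching the headline mean +/- s.d.
#' presentation.  Per-run pooled MNS values (all correct runs from all
#' participants combined) are also reported as `mns_pooled`.
#'
#' @param runs A per-run data frame from [run_sweep()].
#' @return A data frame with one row per combination: `grid`, `strategy`,
#'   `variant`, `stringency`, `n_runs`, `ptci_mean`, `ptci_sd`,
#'   `mns_mean`, `mns_sd`, `mns_pooled`.
#' @export
aggregate_sweep <- function(runs) {
  key <- interaction(runs$grid, runs$strategy, runs$variant,
                     addNA(factor(runs$stringency)), drop = TRUE)
  rows <- lapply(split(runs, key), function(d) {
    per <- split(d, d$participant)
    p_ptci <- vapply(per, ptci, numeric(1))
    p_mns <- vapply(per, mns, numeric(1))
    ok <- d$correct
    data.frame(
      grid = d$grid[1], strategy = d$strategy[1], variant = d$variant[1],
      stringency = d$stringency[1], n_runs = nrow(d),
      ptci_mean = mean(p_ptci), ptci_sd = stats::sd(p_ptci),
      mns_mean = mean(p_mns, na.rm = TRUE),
      mns_sd = stats::sd(p_mns, na.rm = TRUE),
      mns_pooled = if (any(ok))
        mean(d$movement_steps[ok] / d$initial_distance[ok]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$grid, out$strategy, out$variant, out$stringency), ]
}
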