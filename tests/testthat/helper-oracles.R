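# Independent oracles used across the suite.  These re-derive the model
# from first principles -- explicit per-cell enumeration, no shared code
# with the package internals beyond the public class orderings.

# Manhattan distance between (row, col) pairs, written out directly.
oracle_dist <- function(a, b) abs(a[1] - b[1]) + abs(a[2] - b[2])

# Movement class re-derived from the distance delta alone.
oracle_movement_class <- function(origin, destination, target) {
  if (all(destination == target)) return("TR")
  if (all(origin == target)) return("SO")
  if (oracle_dist(destination, target) < oracle_dist(origin, target)) "TT"
  else "FA"
}

# Cell-by-cell evaluation of the posterior update for a movement
# observation: for each cell (i, j), multiply the prior by the likelihood
# of the output under the class the move would have had were (i, j) the
# target, divide by the output's marginal, and renormalise over the grid.
oracle_bayes_movement <- function(prior, n_rows, n_cols, origin,
                                  destination, obs_label, A) {
  k <- ncol(A)
  classes <- colnames(A)
  obs_i <- match(obs_label, rownames(A))
  marginal <- sum(A[obs_i, ]) / k
  unnorm <- numeric(n_rows * n_cols)
  for (j in seq_len(n_cols)) for (i in seq_len(n_rows)) {
    cell <- (j - 1) * n_rows + i
    cls <- oracle_movement_class(origin, destination, c(i, j))
    if (k == 2)  # binary variant: correct vs error
      cls <- if (cls %in% c("TT", "TR")) "correct" else "error"
    lik <- A[obs_i, match(cls, classes)]
    unnorm[cell] <- lik * prior[cell] / marginal
  }
  unnorm / sum(unnorm)
}

# Same enumeration for a target-identification observation.
oracle_bayes_ti <- function(prior, n_rows, n_cols, loc, obs_label, A2) {
  obs_i <- match(obs_label, rownames(A2))
  marginal <- sum(A2[obs_i, ]) / 2
  unnorm <- numeric(n_rows * n_cols)
  for (j in seq_len(n_cols)) for (i in seq_len(n_rows)) {
    cell <- (j - 1) * n_rows + i
    cls <- if (all(c(i, j) == loc)) "CTI" else "FTI"
    lik <- A2[obs_i, match(cls, colnames(A2))]
    unnorm[cell] <- lik * prior[cell] / marginal
  }
  unnorm / sum(unnorm)
}

# Reference stepwise selection trace built on lm + add1/drop1 F-tests.
oracle_stepwise <- function(x, y01, entry_p = 0.05, removal_p = 0.10,
                            max_features = 60) {
  df <- data.frame(y = y01, x)
  vars <- colnames(x)
  sel <- character(0)
  repeat {
    if (length(sel) >= max_features) break
    fml <- stats::as.formula(paste("y ~", if (length(sel) > 0)
      paste(sel, collapse = " + ") else "1"))
    fit <- stats::lm(fml, data = df)
    cand <- setdiff(vars, sel)
    if (length(cand) == 0) break
    a1 <- stats::add1(fit, scope = stats::as.formula(
      paste("~ . +", paste(cand, collapse = " + "))), test = "F")
    pv <- a1[["Pr(>F)"]][-1]
    names(pv) <- rownames(a1)[-1]
    best <- names(pv)[which.min(pv)]
    if (min(pv) >= entry_p) break
    sel <- c(sel, best)
    repeat {
      if (length(sel) < 2) break
      fit2 <- stats::lm(stats::as.formula(
        paste("y ~", paste(sel, collapse = " + "))), data = df)
      d1 <- stats::drop1(fit2, test = "F")
      pv2 <- d1[["Pr(>F)"]][-1]
      names(pv2) <- rownames(d1)[-1]
      worst <- names(pv2)[which.max(pv2)]
      if (max(pv2) <= removal_p) break
      sel <- setdiff(sel, worst)
    }
  }
  match(sel, vars)
}

# Noisy test profile used in several simulation tests: movement diagonal
# 0.7 (off-diagonals 0.1), identification diagonal 0.8.
noisy_profile <- function(id = "noisy") {
  A <- matrix(0.1, 4, 4); diag(A) <- 0.7
  A2 <- matrix(0.2, 2, 2); diag(A2) <- 0.8
  participant_profile(A, A2, id = id)
}

perfect_profile <- function(id = "perfect") {
  participant_profile(diag(4), diag(2), id = id)
}

run_many <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) run_episode(...)))
}
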