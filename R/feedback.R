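#' Class labels for a likelihood-matrix kind
#'
#' @param kind `"movement"` (4 classes) or `"identification"` (2 classes).
#' @return Character vector of class labels in canonical order.
#' @keywords internal
#' @export
kind_classes <- function(kind) {
  switch(match.arg(kind, c("movement", "identification")),
         movement = MOVEMENT_CLASSES,
         identification = TI_CLASSES)
}

#' Construct a likelihood matrix
#'
#' A likelihood matrix `A` is the robot's model of classifier reliability:
#' `A[i, j] = P(observation i | true class j)`.  Rows index classifier
#' outputs (observations), columns index true hidden classes, both in the
#' canonical order `TT, TR, FA, SO` (movements) or `CTI, FTI`
#' (identifications).  Every column is a probability distribution.
#'
#' @param entries A k-by-k non-negative numeric matrix (k = 4 for
#'   movements, 2 for identifications).  Columns are normalised to sum
#'   to 1.
#' @param kind `"movement"` or `"identification"`.
#' @param floor Minimum probability given to any entry after
#'   normalisation (default `1e-6`); entries are floored and columns
#'   re-normalised so that no observation ever has exactly zero likelihood
#'   under any class.  Set to 0 to disable.
#' @return A `likelihood_matrix`: the column-stochastic matrix with class
#'   dimnames and a `kind` attribute.
#' @examples
#' likelihood_matrix(diag(4), "movement")
#' @export
likelihood_matrix <- function(entries, kind = c("movement", "identification"),
                              floor = 1e-6) {
  kind <- match.arg(kind)
  classes <- kind_classes(kind)
  k <- length(classes)
  entries <- as.matrix(entries)
  if (!all(dim(entries) == k))
    stop(sprintf("%s likelihood matrix must be %d x %d", kind, k, k))
  if (any(entries < 0) || anyNA(entries))
    stop("likelihood entries must be non-negative and finite")
  cs <- colSums(entries)
  if (any(cs == 0))
    stop(sprintf("degenerate class: column(s) %s sum to zero",
                 paste(classes[cs == 0], collapse = ", ")))
  m <- sweep(entries, 2, cs, "/")
  if (floor > 0) {
    m <- pmax(m, floor)
    m <- sweep(m, 2, colSums(m), "/")
  }
  dimnames(m) <- list(observation = classes, state = classes)
  structure(m, kind = kind, class = c("likelihood_matrix", "matrix", "array"))
}

#' Likelihood matrix from a classification contingency table
#'
#' Converts counts of (predicted, actual) classifications -- e.g. from
#' leave-one-out cross-validation on training epochs -- into the
#' column-stochastic likelihood matrix `P(output | true class)`.
#'
#' @param counts A k-by-k matrix of non-negative counts with
#'   `counts[predicted, actual]`.
#' @inheritParams likelihood_matrix
#' @return A [likelihood_matrix()].
#' @examples
#' tab <- matrix(c(7, 1, 1, 1,  1, 7, 1, 1,  1, 1, 7, 1,  1, 1, 1, 7), 4, 4)
#' likelihood_from_counts(tab, "movement")
#' @export
likelihood_from_counts <- function(counts,
                                   kind = c("movement", "identification"),
                                   floor = 1e-6) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency table must hold non-negative integer counts")
  likelihood_matrix(counts, kind = kind, floor = floor)
}

#' Collapse a 4-way movement contingency table to binary correct/error
#'
#' Pools `TT` and `TR` into a "correct" class and `FA` and `SO` into an
#' "error" class, on both the predicted and actual margins, before any
#' normalisation.  Used by the binary-classification system variant.
#'
#' @param counts A 4-by-4 movement contingency table
#'   (`counts[predicted, actual]` in `TT, TR, FA, SO` order).
#' @return A 2-by-2 counts matrix with dimnames `correct`, `error`; its
#'   total equals the input total.
#' @export
collapse_to_binary <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 4))
    stop("expected a 4 x 4 movement contingency table")
  grp <- c(1L, 1L, 2L, 2L)  # TT,TR -> correct; FA,SO -> error
  out <- matrix(0, 2, 2, dimnames = list(predicted = c("correct", "error"),
                                         actual = c("correct", "error")))
  for (i in 1:4) for (j in 1:4)
    out[grp[i], grp[j]] <- out[grp[i], grp[j]] + counts[i, j]
  out
}

# Collapse a 4x4 movement likelihood matrix to the 2x2 correct/error model
# used by the binary variant.  Columns within a group are averaged (each
# true class is assumed equally likely within its group), rows summed.
.collapse_likelihood <- function(A) {
  grp <- c(1L, 1L, 2L, 2L)
  out <- matrix(0, 2, 2)
  for (j in 1:2) {
    cols <- A[, grp == j, drop = FALSE]
    pooled <- rowMeans(cols)
    out[1, j] <- sum(pooled[grp == 1L])
    out[2, j] <- sum(pooled[grp == 2L])
  }
  dimnames(out) <- list(observation = c("correct", "error"),
                        state = c("correct", "error"))
  structure(out, kind = "binary",
            class = c("likelihood_matrix", "matrix", "array"))
}

#' One-hot observation vector
#'
#' Classifier outputs are one-hot binary vectors over the class set, e.g.
#' `[1 0 0 0]` for a movement classified as `TT`.
#'
#' @param label A class label valid for `kind`.
#' @param kind `"movement"` or `"identification"`.
#' @return A named 0/1 vector with a single 1 at the class position.
#' @export
observation_vector <- function(label, kind = c("movement", "identification")) {
  classes <- kind_classes(match.arg(kind))
  if (!label %in% classes)
    stop(sprintf("'%s' is not a %s class", label, kind))
  stats::setNames(as.integer(classes == label), classes)
}

#' Sample a classifier output for a true action class
#'
#' Draws an observation from the column of the likelihood matrix indexed by
#' the true class.  In simulations this stands in for retrieving a held-out
#' EEG trial of that class and running it through the trained classifier.
#'
#' @param m A [likelihood_matrix()].
#' @param true_state A class label indexing a column of `m`.
#' @return The sampled class label (a row name of `m`).
#' @export
sample_observation <- function(m, true_state) {
  j <- match(true_state, colnames(m))
  if (is.na(j))
    stop(sprintf("'%s' does not name a class of this %s matrix",
                 true_state, attr(m, "kind")))
  rownames(m)[.sample_col(m, j)]
}

# fast internal: sample a row index from column j of a stochastic matrix
.sample_col <- function(m, j) {
  u <- stats::runif(1)
  cs <- cumsum(m[, j])
  which(u <= cs)[1L]
}

#' Marginal probability of an observation
#'
#' Under a uniform prior over the k hidden classes the marginal probability
#' of classifier output `o` is the sum of its row of `A` divided by the sum
#' of all entries, i.e. (row sum)/k for a column-stochastic matrix.  This
#' divisor appears in the Bayes update but cancels under posterior
#' normalisation.
#'
#' @param m A [likelihood_matrix()].
#' @param o A class label naming a row of `m`.
#' @return A probability.
#' @export
observation_marginal <- function(m, o) {
  i <- match(o, rownames(m))
  if (is.na(i)) stop(sprintf("'%s' does not name an observation class", o))
  sum(m[i, ]) / sum(m)
}

#' Synthesise a virtual participant profile
#'
#' A participant profile bundles the matrices that drive a simulation for
#' one virtual subject: *sampler* matrices, playing the role of the true
#' test-set confusion behaviour from which observations are drawn, and
#' *assumed* matrices, the robot's model of that behaviour (in the real
#' workflow a leave-one-out estimate from training data).  Per-class
#' diagonal accuracies are drawn uniformly from the given ranges and the
#' residual probability is spread over the off-diagonal entries by a
#' symmetric Dirichlet draw.  `mismatch` blends the assumed matrices with
#' an independent draw to emulate the discrepancy between a training-set
#' estimate and test-set behaviour; at 0 the robot's model is exact.
#'
#' @param movement_accuracy Length-2 numeric range in (0.25, 1] for the
#'   per-class diagonal of the 4-way movement matrix.
#' @param ti_accuracy Length-2 numeric range in (0.5, 1] for the diagonal
#'   of the 2-way identification matrix.
#' @param mismatch Blend weight in \[0, 1\] between the sampler matrix and
#'   an independently drawn matrix for the assumed model (default 0).
#' @param id Participant label.
#' @param floor Likelihood floor passed to [likelihood_matrix()].
#' @return A list of class `participant_profile` with elements
#'   `movement_sampler`, `movement_assumed`, `ti_sampler`, `ti_assumed`,
#'   `id`.
#' @examples
#' set.seed(1)
#' p <- synth_participant(c(0.6, 0.8), c(0.7, 0.9))
#' p$movement_sampler
#' @export
synth_participant <- function(movement_accuracy = c(0.55, 0.85),
                              ti_accuracy = c(0.65, 0.90),
                              mismatch = 0, id = "synthetic",
                              floor = 1e-6) {
  .check_range <- function(r, lo, what) {
    if (length(r) != 2 || r[1] > r[2] || r[1] <= lo || r[2] > 1)
      stop(sprintf("%s accuracy range must lie in (%g, 1]", what, lo))
  }
  .check_range(movement_accuracy, 0.25, "movement")
  .check_range(ti_accuracy, 0.5, "identification")
  if (mismatch < 0 || mismatch > 1) stop("mismatch must be in [0, 1]")

  draw <- function(k, rng) {
    m <- matrix(0, k, k)
    for (j in seq_len(k)) {
      acc <- stats::runif(1, rng[1], rng[2])
      off <- stats::rgamma(k - 1L, shape = 1)
      off <- off / sum(off) * (1 - acc)
      m[j, j] <- acc
      m[-j, j] <- off
    }
    m
  }
  mv <- draw(4L, movement_accuracy)
  ti <- draw(2L, ti_accuracy)
  blend <- function(m, k, rng) {
    if (mismatch == 0) return(m)
    (1 - mismatch) * m + mismatch * draw(k, rng)
  }
  structure(
    list(
      movement_sampler = likelihood_matrix(mv, "movement", floor = floor),
      movement_assumed = likelihood_matrix(blend(mv, 4L, movement_accuracy),
                                           "movement", floor = floor),
      ti_sampler = likelihood_matrix(ti, "identification", floor = floor),
      ti_assumed = likelihood_matrix(blend(ti, 2L, ti_accuracy),
                                     "identification", floor = floor),
      id = id),
    class = "participant_profile")
}

#' Build a participant profile from explicit matrices
#'
#' @param movement 4-by-4 movement matrix (counts or probabilities),
#'   `[predicted, actual]`.
#' @param ti 2-by-2 identification matrix.
#' @param id Participant label.
#' @param floor Likelihood floor.
#' @return A `participant_profile` whose sampler and assumed matrices are
#'   identical.
#' @export
participant_profile <- function(movement, ti, id = "profile", floor = 1e-6) {
  mv <- likelihood_matrix(movement, "movement", floor = floor)
  tm <- likelihood_matrix(ti, "identification", floor = floor)
  structure(list(movement_sampler = mv, movement_assumed = mv,
                 ti_sampler = tm, ti_assumed = tm, id = id),
            class = "participant_profile")
}

#' Read or write a contingency table as CSV
#'
#' Tables are stored with a header row naming the classes in canonical
#' order (`TT, TR, FA, SO` or `CTI, FTI`); rows are predicted classes,
#' columns actual classes.
#'
#' @param path File path.
#' @param counts Matrix to write.
#' @return `read_contingency_csv` returns the counts matrix with class
#'   dimnames.
#' @export
write_contingency_csv <- function(counts, path) {
  utils::write.csv(as.data.frame(as.matrix(counts)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_contingency_csv
#' @export
read_contingency_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
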