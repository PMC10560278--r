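#' EEG channel montage
#'
#' The eight recording channels, in storage order.
#' @export
EEG_CHANNELS <- c("Fz", "Cz", "Oz", "Pz", "C3", "C4", "PO7", "PO8")

#' Preprocessing configuration for ERP epochs
#'
#' Epochs are band-pass filtered (zero-phase 4th-order Butterworth),
#' resampled to `downsample_to` Hz, baseline-corrected per channel to the
#' mean of the `baseline` interval, and the `window` interval is
#' concatenated across channels into one feature vector.  Window
#' endpoints are half-open `[from, to)`, so the default 200--700 ms window
#' at 64 Hz yields 32 samples per channel (256 features over 8 channels).
#'
#' @param passband Length-2 numeric, Hz.  Stage-1 (correct-vs-error) and
#'   identification classifiers use 1--10 Hz; stage-2 subclassifiers use
#'   1--32 Hz.
#' @param downsample_to Target sampling rate in Hz (default 64).
#' @param window Feature window in seconds relative to the action onset
#'   (default `c(0.2, 0.7)`).
#' @param baseline Baseline interval in seconds (default `c(-0.2, 0)`).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(passband = c(1, 10), downsample_to = 64,
                              window = c(0.2, 0.7), baseline = c(-0.2, 0)) {
  if (passband[2] > downsample_to / 2)
    stop("passband must lie below the downsampled Nyquist frequency")
  if (baseline[1] >= baseline[2] || window[1] >= window[2])
    stop("intervals must be increasing")
  structure(list(passband = passband, downsample_to = downsample_to,
                 window = window, baseline = baseline),
            class = "preprocess_config")
}

#' Extract classifier features from one epoch
#'
#' @param signal A channels-by-samples numeric matrix.
#' @param times Numeric vector of sample times in seconds relative to the
#'   event (length `ncol(signal)`).
#' @param srate Native sampling rate in Hz.
#' @param cfg A [preprocess_config()].
#' @return A numeric feature vector (channels concatenated in order).
#' @export
preprocess_epoch <- function(signal, times, srate, cfg = preprocess_config()) {
  if (times[1] > cfg$baseline[1] || times[length(times)] < cfg$window[2])
    stop("epoch does not cover the baseline and feature window")
  ds <- cfg$downsample_to
  # resample on the event-locked 1/ds grid covering the epoch
  n_lo <- ceiling(times[1] * ds)
  n_hi <- floor(times[length(times)] * ds)
  t_new <- (n_lo:n_hi) / ds
  base_idx <- t_new >= cfg$baseline[1] & t_new < cfg$baseline[2]
  win_idx <- t_new >= cfg$window[1] & t_new < cfg$window[2]
  feats <- lapply(seq_len(nrow(signal)), function(ch) {
    filtered <- .zero_phase_bandpass(signal[ch, ], srate, cfg$passband)
    y <- stats::approx(times, filtered, xout = t_new)$y
    y[win_idx] - mean(y[base_idx])
  })
  unlist(feats, use.names = FALSE)
}

# Zero-phase 4th-order Butterworth band-pass, applied as the squared
# magnitude response (forward-backward filtering) in the frequency
# domain.  The direct IIR recursion is ill-conditioned for narrow
# low-frequency bands (poles near the unit circle), so the response is
# evaluated from the designed coefficients and applied by FFT instead;
# the channel mean is removed and the signal odd-reflected at both ends
# to suppress edge effects.
.response_cache <- new.env(parent = emptyenv())

# squared magnitude response of the designed filter on an N-point grid
.bandpass_response <- function(N, srate, passband) {
  key <- paste(N, srate, passband[1], passband[2], sep = "|")
  if (!is.null(.response_cache[[key]])) return(.response_cache[[key]])
  bf <- signal::butter(4, passband / (srate / 2), type = "pass")
  ew <- exp(-2i * pi * (seq_len(N) - 1L) / N)
  H_num <- Reduce(function(acc, bk) acc * ew + bk, bf$b)
  H_den <- Reduce(function(acc, ak) acc * ew + ak, bf$a)
  H2 <- Mod(H_num / H_den)^2
  .response_cache[[key]] <- H2
  H2
}

.zero_phase_bandpass <- function(x, srate, passband) {
  n <- length(x)
  x0 <- x - mean(x)
  pad <- n - 1L
  pre <- 2 * x0[1] - x0[(pad + 1L):2L]
  post <- 2 * x0[n] - x0[(n - 1L):(n - pad)]
  xp <- c(pre, x0, post)
  N <- length(xp)
  H2 <- .bandpass_response(N, srate, passband)
  y <- Re(stats::fft(stats::fft(xp) * H2, inverse = TRUE)) / N
  y[pad + seq_len(n)]
}

#' Extract features from a set of epochs
#'
#' @param epochs An `eeg_epochs` object (see
#'   [generate_synthetic_epochs()]).
#' @param cfg A [preprocess_config()].
#' @return A numeric matrix with one row per epoch.
#' @export
preprocess_epochs <- function(epochs, cfg = preprocess_config()) {
  n <- dim(epochs$data)[3]
  t(vapply(seq_len(n),
           function(i) preprocess_epoch(epochs$data[, , i], epochs$times,
                                        epochs$srate, cfg),
           numeric(.n_features(epochs, cfg))))
}

.n_features <- function(epochs, cfg) {
  ds <- cfg$downsample_to
  n_lo <- ceiling(epochs$times[1] * ds)
  n_hi <- floor(epochs$times[length(epochs$times)] * ds)
  t_new <- (n_lo:n_hi) / ds
  nrow(epochs$data[, , 1, drop = FALSE]) *
    sum(t_new >= cfg$window[1] & t_new < cfg$window[2])
}

#' Fit a stepwise linear discriminant (SWLDA) classifier
#'
#' Binary classification by least-squares regression of the 0/1 class
#' indicator on a feature subset chosen by stepwise selection: at each
#' iteration the candidate whose partial F-test is most significant enters
#' if its p-value is below `entry_p`, then any included feature whose
#' t-test p-value exceeds `removal_p` is removed (most insignificant
#' first).  Selection stops at convergence or `max_features`.  The
#' discriminant score for new data is the fitted regression value,
#' thresholded at 0.5.
#'
#' @param x Feature matrix (rows = trials).
#' @param y Binary labels: a factor or character vector with exactly two
#'   distinct values.  The second level is coded 1.
#' @param entry_p Forward-entry significance threshold (default 0.05).
#' @param removal_p Backward-removal threshold (default 0.10).
#' @param max_features Maximum number of retained features (default 60).
#' @return An object of class `swlda`: `selected` (feature indices),
#'   `intercept`, `weights`, `levels`, plus the selection parameters.
#' @export
swlda_fit <- function(x, y, entry_p = 0.05, removal_p = 0.10,
                      max_features = 60) {
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(y) != 2)
    stop("labels must contain exactly two classes")
  if (min(table(y)) < 2) stop("need at least 2 trials per class")
  lev <- levels(y)
  y01 <- as.numeric(y == lev[2])
  n <- nrow(x); p <- ncol(x)
  sel <- integer(0)
  seen <- character(0)
  repeat {
    if (length(sel) >= max_features) break
    # forward step: partial F-test of each candidate given current model
    base <- cbind(1, x[, sel, drop = FALSE])
    qr_b <- qr(base)
    Q <- qr.Q(qr_b)
    ry <- y01 - Q %*% crossprod(Q, y01)
    cand <- setdiff(seq_len(p), sel)
    if (length(cand) == 0L) break
    Xc <- x[, cand, drop = FALSE]
    Rx <- Xc - Q %*% crossprod(Q, Xc)
    ssx <- colSums(Rx^2)
    sxy <- as.numeric(crossprod(Rx, ry))
    rss0 <- sum(ry^2)
    gain <- ifelse(ssx > 1e-10, sxy^2 / ssx, 0)
    rss1 <- pmax(rss0 - gain, 0)
    df2 <- n - (length(sel) + 1L) - 1L
    if (df2 < 1L) break
    Fstat <- ifelse(rss1 > 0, gain / (rss1 / df2), Inf)
    pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
    pval[ssx <= 1e-10] <- 1
    best <- which.min(pval)
    if (pval[best] >= entry_p) break
    sel <- c(sel, cand[best])
    # backward steps: drop features that have become insignificant
    repeat {
      if (length(sel) < 2L) break
      fit <- stats::lm.fit(cbind(1, x[, sel, drop = FALSE]), y01)
      dfree <- n - length(sel) - 1L
      if (dfree < 1L) break
      sigma2 <- sum(fit$residuals^2) / dfree
      R <- qr.R(fit$qr)
      xtxinv_diag <- diag(chol2inv(R))
      tstat <- fit$coefficients / sqrt(sigma2 * xtxinv_diag)
      pv <- 2 * stats::pt(abs(tstat[-1]), dfree, lower.tail = FALSE)
      worst <- which.max(pv)
      if (is.na(pv[worst]) || pv[worst] <= removal_p) break
      sel <- sel[-worst]
    }
    key <- paste(sort(sel), collapse = ",")
    if (key %in% seen) break  # selection cycle: stop
    seen <- c(seen, key)
  }
  coefs <- if (length(sel) > 0)
    stats::lm.fit(cbind(1, x[, sel, drop = FALSE]), y01)$coefficients
  else mean(y01)
  structure(list(selected = sel, intercept = coefs[1],
                 weights = if (length(sel) > 0) coefs[-1] else numeric(0),
                 levels = lev, entry_p = entry_p, removal_p = removal_p,
                 max_features = max_features),
            class = "swlda")
}

#' @export
print.swlda <- function(x, ...) {
  cat(sprintf("<swlda: %d features selected (%s vs %s)>\n",
              length(x$selected), x$levels[1], x$levels[2]))
  invisible(x)
}

#' Discriminant scores and class predictions from an SWLDA model
#'
#' @param object A fitted [swlda_fit()] model.
#' @param newx Feature matrix of new trials.
#' @param type `"class"` for labels, `"score"` for raw discriminant
#'   values.
#' @param ... Unused.
#' @return Character vector of labels, or numeric scores.
#' @export
predict.swlda <- function(object, newx, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  score <- if (length(object$selected) > 0)
    drop(object$intercept + newx[, object$selected, drop = FALSE] %*%
           object$weights)
  else rep(object$intercept, nrow(newx))
  if (type == "score") return(score)
  object$levels[ifelse(score > 0.5, 2L, 1L)]
}

#' Fit the 2-stage movement classification tree
#'
#' Stage 1 classifies epochs as responses to correct (`TT`/`TR`) or
#' erroneous (`FA`/`SO`) movements on 1--10 Hz features; stage 2
#' subclassifies within the branch (`TT` vs `TR`, or `FA` vs `SO`) on
#' 1--32 Hz features.  Stage-2 models are trained on the epochs whose true
#' class belongs to the branch.
#'
#' @param epochs A movement-kind `eeg_epochs` object.
#' @param entry_p,removal_p,max_features Passed to [swlda_fit()].
#' @param cfg_stage1 Preprocessing for stage 1 (default 1--10 Hz).
#' @param cfg_stage2 Preprocessing for stage 2 (default 1--32 Hz).
#' @return A list of class `classifier_tree`: `stage1`, `stage2_correct`,
#'   `stage2_error`, and the two configurations.
#' @export
fit_classifier_tree <- function(epochs, entry_p = 0.05, removal_p = 0.10,
                                max_features = 60,
                                cfg_stage1 = preprocess_config(c(1, 10)),
                                cfg_stage2 = preprocess_config(c(1, 32))) {
  if (!all(epochs$labels %in% MOVEMENT_CLASSES))
    stop("expected movement epochs with TT/TR/FA/SO labels")
  f1 <- preprocess_epochs(epochs, cfg_stage1)
  f2 <- preprocess_epochs(epochs, cfg_stage2)
  .tree_fit(f1, f2, as.character(epochs$labels), entry_p, removal_p,
            max_features, cfg_stage1, cfg_stage2)
}

.tree_fit <- function(f1, f2, labels, entry_p, removal_p, max_features,
                      cfg_stage1, cfg_stage2) {
  grp <- ifelse(labels %in% c("TT", "TR"), "correct", "error")
  ok <- grp == "correct"
  structure(list(
    stage1 = swlda_fit(f1, factor(grp, c("correct", "error")),
                       entry_p, removal_p, max_features),
    stage2_correct = swlda_fit(f2[ok, , drop = FALSE],
                               factor(labels[ok], c("TT", "TR")),
                               entry_p, removal_p, max_features),
    stage2_error = swlda_fit(f2[!ok, , drop = FALSE],
                             factor(labels[!ok], c("FA", "SO")),
                             entry_p, removal_p, max_features),
    cfg_stage1 = cfg_stage1, cfg_stage2 = cfg_stage2),
    class = "classifier_tree")
}

#' Classify movement epochs with a fitted tree
#'
#' @param tree A [fit_classifier_tree()] model.
#' @param epochs A movement-kind `eeg_epochs` object.
#' @param trace If `TRUE`, also return the stage-1 routing decisions.
#' @return Character vector of predicted classes (`TT`, `TR`, `FA`, `SO`);
#'   with `trace = TRUE`, a data frame with columns `stage1` and `class`.
#' @export
classify_movement <- function(tree, epochs, trace = FALSE) {
  f1 <- preprocess_epochs(epochs, tree$cfg_stage1)
  f2 <- preprocess_epochs(epochs, tree$cfg_stage2)
  .tree_predict(tree, f1, f2, trace)
}

.tree_predict <- function(tree, f1, f2, trace = FALSE) {
  route <- predict(tree$stage1, f1)
  out <- character(nrow(f1))
  is_c <- route == "correct"
  if (any(is_c))
    out[is_c] <- predict(tree$stage2_correct, f2[is_c, , drop = FALSE])
  if (any(!is_c))
    out[!is_c] <- predict(tree$stage2_error, f2[!is_c, , drop = FALSE])
  if (trace) data.frame(stage1 = route, class = out,
                        stringsAsFactors = FALSE)
  else out
}

#' Fit and apply the target-identification (TI) classifier
#'
#' A single SWLDA model separating correct (`CTI`) from false (`FTI`)
#' identifications on 1--10 Hz features, event-locked to the
#' identification cue.
#'
#' @param epochs An identification-kind `eeg_epochs` object.
#' @param entry_p,removal_p,max_features Passed to [swlda_fit()].
#' @param cfg Preprocessing configuration (default 1--10 Hz).
#' @return For `fit_ti_classifier`, a list of class `ti_classifier` with
#'   the `model` and `cfg`; for `classify_ti`, predicted labels.
#' @export
fit_ti_classifier <- function(epochs, entry_p = 0.05, removal_p = 0.10,
                              max_features = 60,
                              cfg = preprocess_config(c(1, 10))) {
  if (!all(epochs$labels %in% TI_CLASSES))
    stop("expected identification epochs with CTI/FTI labels")
  f <- preprocess_epochs(epochs, cfg)
  structure(list(model = swlda_fit(f, factor(epochs$labels, TI_CLASSES),
                                   entry_p, removal_p, max_features),
                 cfg = cfg),
            class = "ti_classifier")
}

#' @rdname fit_ti_classifier
#' @param classifier A fitted `ti_classifier`.
#' @export
classify_ti <- function(classifier, epochs) {
  f <- preprocess_epochs(epochs, classifier$cfg)
  predict(classifier$model, f)
}

#' Leave-one-out likelihood matrix from labelled epochs
#'
#' For each epoch, the classifier (movement tree or TI model) is refitted
#' on all remaining epochs and used to classify the held-out one; the
#' predicted-by-actual counts are accumulated and converted to a
#' column-stochastic likelihood matrix via [likelihood_from_counts()].
#' This mirrors estimating the robot's reliability model from training
#' data without touching the test set.
#'
#' @param epochs An `eeg_epochs` object (movement or identification kind).
#' @param entry_p,removal_p,max_features Passed to [swlda_fit()].
#' @param floor Likelihood floor for [likelihood_from_counts()].
#' @return A [likelihood_matrix()] with the raw counts attached as
#'   attribute `"counts"`.
#' @export
loo_likelihood <- function(epochs, entry_p = 0.05, removal_p = 0.10,
                           max_features = 60, floor = 1e-6) {
  labels <- as.character(epochs$labels)
  kind <- if (all(labels %in% MOVEMENT_CLASSES)) "movement"
          else if (all(labels %in% TI_CLASSES)) "identification"
          else stop("epochs mix movement and identification labels")
  if (min(table(labels)) < 2)
    stop("leave-one-out needs at least 2 epochs per class")
  classes <- kind_classes(kind)
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(predicted = classes, actual = classes))
  n <- length(labels)
  if (kind == "movement") {
    cfg1 <- preprocess_config(c(1, 10))
    cfg2 <- preprocess_config(c(1, 32))
    f1 <- preprocess_epochs(epochs, cfg1)
    f2 <- preprocess_epochs(epochs, cfg2)
    for (i in seq_len(n)) {
      tree <- .tree_fit(f1[-i, , drop = FALSE], f2[-i, , drop = FALSE],
                        labels[-i], entry_p, removal_p, max_features,
                        cfg1, cfg2)
      pred <- .tree_predict(tree, f1[i, , drop = FALSE],
                            f2[i, , drop = FALSE])
      counts[pred, labels[i]] <- counts[pred, labels[i]] + 1L
    }
  } else {
    cfg <- preprocess_config(c(1, 10))
    f <- preprocess_epochs(epochs, cfg)
    for (i in seq_len(n)) {
      m <- swlda_fit(f[-i, , drop = FALSE], factor(labels[-i], classes),
                     entry_p, removal_p, max_features)
      pred <- predict(m, f[i, , drop = FALSE])
      counts[pred, labels[i]] <- counts[pred, labels[i]] + 1L
    }
  }
  out <- likelihood_from_counts(counts, kind, floor = floor)
  attr(out, "counts") <- counts
  out
}
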