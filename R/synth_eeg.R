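#' Synthetic event-related potential templates
#'
#' Idealised per-class ERP waveforms emulating the qualitative structure
#' of grand-average responses to observed robot actions: erroneous
#' actions (`FA`, `SO`, `FTI`) evoke larger peaks than correct ones
#' (`TT`, `TR`, `CTI`), and within each branch the classes differ in peak
#' amplitude and latency (`TR` above `TT`, `SO` above `FA`).  Each
#' template is a positive central peak followed by a smaller opposite
#' deflection, scaled per channel by a fronto-central topography.
#'
#' @param kind `"movement"` (classes `TT, TR, FA, SO`) or
#'   `"identification"` (`CTI, FTI`).
#' @param srate Sampling rate in Hz (default 500).
#' @param tmin,tmax Epoch span in seconds relative to the action onset
#'   (defaults -0.5 and 1.0).
#' @return A list of class `erp_templates`: `waves` (named list of
#'   channels-by-samples matrices, microvolts), `times`, `srate`, `kind`.
#' @export
erp_templates <- function(kind = c("movement", "identification"),
                          srate = 500, tmin = -0.5, tmax = 1.0) {
  kind <- match.arg(kind)
  times <- seq(tmin, tmax, by = 1 / srate)
  # peak amplitude (uV) and latency (s) per class; errors larger
  params <- if (kind == "movement")
    list(TT = c(2.0, 0.32), TR = c(4.0, 0.40),
         FA = c(5.5, 0.34), SO = c(8.0, 0.45))
  else
    list(CTI = c(3.0, 0.36), FTI = c(7.0, 0.43))
  topo <- c(Fz = 1.0, Cz = 1.1, Oz = 0.5, Pz = 0.9,
            C3 = 0.8, C4 = 0.8, PO7 = 0.4, PO8 = 0.4)
  waves <- lapply(params, function(pr) {
    amp <- pr[1]; lat <- pr[2]
    w <- amp * exp(-((times - lat)^2) / (2 * 0.05^2)) -
      0.4 * amp * exp(-((times - lat - 0.18)^2) / (2 * 0.07^2))
    out <- outer(topo, w)
    rownames(out) <- EEG_CHANNELS
    out
  })
  structure(list(waves = waves, times = times, srate = srate, kind = kind),
            class = "erp_templates")
}

# coloured (1/f^exponent power) noise of length n, unit variance
.coloured_noise <- function(n, exponent = 1) {
  white <- stats::rnorm(n)
  if (exponent == 0) return(white)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  spec <- spec * f^(-exponent / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Generate labelled synthetic ERP epochs
#'
#' Each epoch is its class template, scaled by a trial-level amplitude
#' jitter, plus independent coloured noise per channel.  Class counts may
#' be imbalanced, e.g. following the paradigm's preset action
#' probabilities.
#'
#' @param templates An [erp_templates()] set.
#' @param n_per_class Named integer vector of epoch counts per class
#'   (names must match the template classes).
#' @param noise_sd Noise standard deviation in microvolts (default 2;
#'   0 gives noise-free epochs).
#' @param amp_jitter Standard deviation of the multiplicative amplitude
#'   jitter around 1 (default 0.1; truncated at 0.1 from below).
#' @param noise_exponent Spectral exponent of the coloured noise
#'   (default 1, i.e. pink).
#' @return An object of class `eeg_epochs`: `data` (channels x samples x
#'   epochs array), `times`, `srate`, `labels` (character), `kind`.
#' @examples
#' tpl <- erp_templates("identification")
#' set.seed(1)
#' e <- generate_synthetic_epochs(tpl, c(CTI = 5, FTI = 5), noise_sd = 1)
#' dim(e$data)
#' @export
generate_synthetic_epochs <- function(templates, n_per_class,
                                      noise_sd = 2, amp_jitter = 0.1,
                                      noise_exponent = 1) {
  classes <- names(templates$waves)
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% classes))
    stop("n_per_class must be named by the template classes")
  labels <- rep(names(n_per_class), times = n_per_class)
  n <- length(labels)
  ns <- length(templates$times)
  nch <- length(EEG_CHANNELS)
  data <- array(0, dim = c(nch, ns, n),
                dimnames = list(EEG_CHANNELS, NULL, NULL))
  for (i in seq_len(n)) {
    amp <- max(0.1, 1 + stats::rnorm(1, sd = amp_jitter))
    ep <- amp * templates$waves[[labels[i]]]
    if (noise_sd > 0)
      ep <- ep + noise_sd *
        t(vapply(seq_len(nch), function(ch) .coloured_noise(ns, noise_exponent),
                 numeric(ns)))
    data[, , i] <- ep
  }
  structure(list(data = data, times = templates$times,
                 srate = templates$srate, labels = labels,
                 kind = templates$kind),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs: %d epochs, %d channels, %.2f..%.2f s @ %g Hz>\n",
              dim(x$data)[3], dim(x$data)[1], x$times[1],
              x$times[length(x$times)], x$srate))
  print(table(x$labels))
  invisible(x)
}

#' Subset an epoch set
#'
#' @param x An `eeg_epochs` object.
#' @param i Epoch indices.
#' @param ... Unused.
#' @return An `eeg_epochs` object with the selected epochs.
#' @export
`[.eeg_epochs` <- function(x, i, ...) {
  structure(list(data = x$data[, , i, drop = FALSE], times = x$times,
                 srate = x$srate, labels = x$labels[i], kind = x$kind),
            class = "eeg_epochs")
}

#' Stratified train/test split of an epoch set
#'
#' Within each class, `train_frac` of the epochs (rounded, at least 1 per
#' class on each side) are assigned to the training set and the remainder
#' to the test set, mirroring the 85/15 split used to separate classifier
#' training data from the trials replayed during simulations.
#'
#' @param epochs An `eeg_epochs` object.
#' @param train_frac Fraction assigned to training (default 0.85).
#' @return A list with `train` and `test` epoch sets.
#' @export
split_train_test <- function(epochs, train_frac = 0.85) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  idx_train <- integer(0)
  for (cl in unique(epochs$labels)) {
    idx <- which(epochs$labels == cl)
    n_tr <- min(length(idx) - 1L, max(1L, round(train_frac * length(idx))))
    idx_train <- c(idx_train, sample(idx, n_tr))
  }
  idx_train <- sort(idx_train)
  list(train = epochs[idx_train],
       test = epochs[setdiff(seq_along(epochs$labels), idx_train)])
}

#' Write or read an epoch set as plain-text files
#'
#' The on-disk layout is a directory holding `manifest.csv` (columns
#' `epoch_id`, `label`, `file`, plus header metadata `srate` and `kind`
#' stored in `meta.csv`) and one CSV per epoch with channels as rows.
#'
#' @param epochs An `eeg_epochs` object.
#' @param dir Directory path (created if needed).
#' @return `read_epochs_dir` returns the `eeg_epochs` object.
#' @export
write_epochs_dir <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(epochs$data)[3]
  files <- sprintf("epoch_%04d.csv", seq_len(n))
  for (i in seq_len(n))
    utils::write.csv(epochs$data[, , i], file.path(dir, files[i]),
                     row.names = TRUE)
  utils::write.csv(
    data.frame(epoch_id = seq_len(n), label = epochs$labels, file = files),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(srate = epochs$srate, kind = epochs$kind,
               tmin = epochs$times[1],
               tmax = epochs$times[length(epochs$times)]),
    file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_epochs_dir
#' @export
read_epochs_dir <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  meta <- utils::read.csv(file.path(dir, "meta.csv"))
  sigs <- lapply(manifest$file, function(f)
    as.matrix(utils::read.csv(file.path(dir, f), row.names = 1)))
  ns <- ncol(sigs[[1]])
  data <- array(unlist(sigs), dim = c(nrow(sigs[[1]]), ns, length(sigs)),
                dimnames = list(rownames(sigs[[1]]), NULL, NULL))
  structure(list(data = data,
                 times = seq(meta$tmin, meta$tmax, length.out = ns),
                 srate = meta$srate, labels = as.character(manifest$label),
                 kind = meta$kind),
            class = "eeg_epochs")
}
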