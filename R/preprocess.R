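# Baseline-drift calibration, peripheral-wake trimming, epoching and
# per-epoch normalization: turns a raw labelled recording into the
# model-ready epoch dataset.

.new_epoch_dataset <- function(epochs) {
  labs <- vapply(epochs, `[[`, "", "label")
  counts <- table(factor(labs, levels = stage_levels()))
  structure(list(epochs = epochs,
                 stage_counts = as.integer(counts)),
            class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat("epoch_dataset:", length(x$epochs), "epochs of",
      EPOCH_SAMPLES, "samples\n")
  cat("  stage counts:",
      paste(stage_levels(), x$stage_counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Median-filter baseline correction
#'
#' Estimates the slow baseline as the running median over a centered
#' temporal neighborhood (edges handled by reflection) and subtracts it
#' from the signal. A 1-second window at 100 Hz passes sleep-relevant
#' rhythms (>= 0.5 Hz) largely untouched while absorbing drift; the
#' window in samples is rounded to the nearest odd integer.
#'
#' @param signal Numeric vector.
#' @param window_s Neighborhood width in seconds (default 1.0).
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @return Baseline-corrected signal, same length as the input.
#' @export
median_baseline_correct <- function(signal, window_s = 1.0,
                                    sampling_rate = SAMPLING_RATE) {
  k <- round(window_s * sampling_rate)
  if (k %% 2 == 0) k <- k + 1L          # runmed needs an odd window
  if (k < 3) stop("median window must span at least 3 samples")
  if (length(signal) < k) stop("signal shorter than the median window")
  h <- (k - 1L) %/% 2L
  padded <- c(rev(signal[2:(h + 1L)]), signal, rev(signal[(length(signal) - h):(length(signal) - 1L)]))
  baseline <- stats::runmed(padded, k, endrule = "keep")
  baseline <- baseline[(h + 1L):(h + length(signal))]
  signal - baseline
}

#' Trim wake periods before and after sleep
#'
#' Finds the first and last non-wake epochs and keeps a margin of
#' flanking wake epochs on each side (default 60 epochs = 30 minutes),
#' clipped to the recording; everything outside is discarded as
#' pre/post-bed time.
#'
#' @param labels Character vector of per-epoch stage names.
#' @param margin_epochs Flanking wake epochs to retain on each side.
#' @return Integer vector `c(first, last)` of 0-based epoch indices
#'   (inclusive range to keep).
#' @export
trim_peripheral_wake <- function(labels, margin_epochs = 60L) {
  sleep <- which(labels != "W")
  if (!length(sleep)) stop("no sleep present: all epochs are wake")
  first <- max(1L, min(sleep) - margin_epochs)
  last <- min(length(labels), max(sleep) + margin_epochs)
  c(first - 1L, last - 1L)
}

.zscore_epoch <- function(x) {
  mu <- mean(x)
  s <- stats::sd(x)
  if (s < .Machine$double.eps) return(x - mu)
  (x - mu) / s
}

#' Build the model-ready epoch dataset from a labelled recording
#'
#' Applies median baseline correction to the full signal, slices it
#' into 3000-sample epochs, attaches per-epoch labels, trims peripheral
#' wake, removes epochs labelled `"DROP"`, and (by default) z-scores
#' each epoch to zero mean and unit variance.
#'
#' @param recording List with `samples` and `sampling_rate` (100 Hz).
#' @param labels Character vector of per-epoch outcomes (stage names or
#'   `"DROP"`), length `floor(length(samples)/3000)`.
#' @param median_window_s Baseline window in seconds; `0` disables the
#'   correction.
#' @param wake_margin_epochs Margin for [trim_peripheral_wake()].
#' @param normalize_epochs Z-score each epoch (default TRUE).
#' @return An `epoch_dataset`: list with `epochs` (each `samples`,
#'   `label`, `source_epoch_index`) and `stage_counts`.
#' @export
build_dataset <- function(recording, labels, median_window_s = 1.0,
                          wake_margin_epochs = 60L, normalize_epochs = TRUE) {
  x <- recording$samples
  if (recording$sampling_rate != SAMPLING_RATE) {
    stop("recording must be at ", SAMPLING_RATE, " Hz (use load_recording)")
  }
  n_ep <- floor(length(x) / EPOCH_SAMPLES)
  if (length(x) %% EPOCH_SAMPLES != 0) {
    warning("trailing partial epoch of ",
            length(x) - n_ep * EPOCH_SAMPLES, " samples truncated")
  }
  if (length(labels) != n_ep) {
    stop("label list length ", length(labels),
         " does not match epoch count ", n_ep)
  }
  if (median_window_s > 0) {
    x <- median_baseline_correct(x, median_window_s, SAMPLING_RATE)
  }
  # peripheral-wake trim: DROP epochs count as non-sleep
  lab_for_trim <- ifelse(labels == "DROP", "W", labels)
  keep <- trim_peripheral_wake(lab_for_trim, wake_margin_epochs)
  idx <- (keep[1]:keep[2]) + 1L
  idx <- idx[labels[idx] != "DROP"]
  eps <- lapply(idx, function(i) {
    s <- x[((i - 1L) * EPOCH_SAMPLES + 1L):(i * EPOCH_SAMPLES)]
    if (any(!is.finite(s))) stop("non-finite samples in epoch ", i - 1L)
    if (normalize_epochs) s <- .zscore_epoch(s)
    list(samples = s, label = labels[i], source_epoch_index = i - 1L)
  })
  .new_epoch_dataset(eps)
}

#' Split an epoch dataset into train and test parts
#'
#' Stratified split: within each stage, a fixed fraction goes to the
#' training set, the remainder to the test set.
#'
#' @param dataset An `epoch_dataset`.
#' @param train_fraction Fraction per stage assigned to training.
#' @param seed Integer seed for the within-stage shuffle.
#' @return List with `train` and `test` epoch datasets.
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "epoch_dataset"))
  labs <- vapply(dataset$epochs, `[[`, "", "label")
  set.seed(seed)
  tr <- logical(length(labs))
  for (s in unique(labs)) {
    i <- which(labs == s)
    n_tr <- floor(length(i) * train_fraction)
    tr[sample(i, n_tr)] <- TRUE
  }
  list(train = .new_epoch_dataset(dataset$epochs[tr]),
       test = .new_epoch_dataset(dataset$epochs[!tr]))
}
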