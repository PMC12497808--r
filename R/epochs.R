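#' Labeled EEG epoch container
#'
#' An `eeg_epochs` object is the unit all pipelines operate on: a dense array
#' of cue-aligned trials with class labels and recording metadata.
#'
#' @param data numeric array `(n_trials, n_channels, n_samples)` of amplitudes
#'   (microvolt scale). Must be free of `NA`/`NaN`/`Inf`.
#' @param labels integer vector of length `n_trials` with class indices in
#'   `0..K-1` (the container convention; they are not R indices). Arbitrary
#'   source labels are remapped to `0..K-1` in first-appearance order unless
#'   they already follow the convention.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per channel.
#' @param class_names character vector naming classes `0..K-1`. When labels
#'   are remapped, the original labels (as strings) become the class names.
#' @param trial_ids optional character vector of unique provenance ids; used
#'   to verify that train/test splits stay disjoint. Autogenerated if absent.
#'
#' @return An object of class `eeg_epochs` (a validated list with the fields
#'   above plus `n_classes`).
#' @export
eeg_epochs <- function(data, labels, fs, channel_names = NULL,
                       class_names = NULL, trial_ids = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (trials x channels x samples)")
  n_trials <- dim(data)[1L]
  if (length(labels) != n_trials)
    stop("length(labels) must equal the number of trials")

  uniq <- unique(labels)
  if (is.numeric(labels) && all(labels == floor(labels)) &&
      all(labels >= 0) && max(c(labels, -1)) == length(uniq) - 1L &&
      setequal(uniq, seq_len(length(uniq)) - 1L)) {
    labels <- as.integer(labels)
    if (is.null(class_names)) class_names <- as.character(sort(uniq))
  } else {
    # remap to 0..K-1 in first-appearance order
    labels <- as.integer(match(labels, uniq) - 1L)
    class_names <- as.character(uniq)
  }

  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2L]))
  if (is.null(trial_ids))
    trial_ids <- if (n_trials > 0) paste0("trial", seq_len(n_trials)) else character(0)

  obj <- structure(list(
    data = data, labels = labels, fs = fs,
    channel_names = as.character(channel_names),
    class_names = as.character(class_names),
    n_classes = length(class_names),
    trial_ids = as.character(trial_ids)
  ), class = "eeg_epochs")
  validate_epochs(obj)
  obj
}

#' Validate an epoch container's invariants
#'
#' Checks dimensional consistency, label range, channel-name length, absence
#' of non-finite amplitudes and uniqueness of trial ids. Called by every
#' constructor and loader; exported for use on externally built objects.
#'
#' @param x an `eeg_epochs` object.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_epochs <- function(x) {
  stopifnot(inherits(x, "eeg_epochs"))
  d <- dim(x$data)
  if (length(d) != 3L) stop("data must be trials x channels x samples")
  if (d[1L] > 0 && any(!is.finite(x$data)))
    stop("data contains NaN/Inf amplitudes")
  if (length(x$labels) != d[1L]) stop("labels/trials mismatch")
  if (d[1L] > 0 && (min(x$labels) < 0L || max(x$labels) >= x$n_classes))
    stop("labels must lie in 0..K-1")
  if (length(x$channel_names) != d[2L])
    stop("channel_names length must equal n_channels")
  if (anyDuplicated(x$trial_ids)) stop("trial_ids must be unique")
  if (length(x$trial_ids) != d[1L]) stop("trial_ids/trials mismatch")
  invisible(x)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz, %d classes\n",
              d[1L], d[2L], d[3L], x$fs, x$n_classes))
  if (d[1L] > 0) {
    tab <- table(factor(x$labels, levels = 0:(x$n_classes - 1L)))
    cat("  per-class counts:", paste(x$class_names, as.integer(tab),
                                     sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of trials per epoch set
#' @param x an `eeg_epochs` object.
#' @return integer trial count.
#' @export
n_trials <- function(x) dim(x$data)[1L]

#' Subset trials of an epoch set
#' @param x an `eeg_epochs` object.
#' @param idx integer vector of trial indices (1-based).
#' @return an `eeg_epochs` with the selected trials.
#' @export
subset_epochs <- function(x, idx) {
  eeg_epochs(x$data[idx, , , drop = FALSE], x$labels[idx], x$fs,
             x$channel_names, x$class_names, x$trial_ids[idx])
}

#' Combine epoch sets with identical metadata
#' @param ... `eeg_epochs` objects sharing fs, channel and class names.
#' @return the concatenated `eeg_epochs`.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  ref <- xs[[1L]]
  for (x in xs[-1L]) {
    if (x$fs != ref$fs || !identical(x$channel_names, ref$channel_names) ||
        !identical(x$class_names, ref$class_names))
      stop("epoch sets differ in fs/channel_names/class_names")
  }
  eeg_epochs(
    do.call(abind3, lapply(xs, `[[`, "data")),
    unlist(lapply(xs, `[[`, "labels")), ref$fs,
    ref$channel_names, ref$class_names,
    unlist(lapply(xs, `[[`, "trial_ids"))
  )
}

# bind 3-D arrays along dim 1
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])[-1L]
  n <- sum(vapply(xs, function(x) dim(x)[1L], 0L))
  out <- array(0, c(n, d))
  at <- 0L
  for (x in xs) {
    k <- dim(x)[1L]
    if (k > 0) out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}

#' Train/test split pair
#'
#' @param train,test `eeg_epochs` sharing fs, channel and class names, with
#'   disjoint trial ids (no leakage).
#' @return a `dataset_split` list.
#' @export
dataset_split <- function(train, test) {
  stopifnot(inherits(train, "eeg_epochs"), inherits(test, "eeg_epochs"))
  if (train$fs != test$fs ||
      !identical(train$channel_names, test$channel_names) ||
      !identical(train$class_names, test$class_names))
    stop("train and test must share fs/channel_names/class_names")
  if (length(intersect(train$trial_ids, test$trial_ids)) > 0)
    stop("train and test share trial ids (leakage)")
  structure(list(train = train, test = test), class = "dataset_split")
}

#' Write an epoch set to the multi-array container
#'
#' The container is an RDS file holding a named list with keys `X`
#' (trials x channels x samples), `y` (integer labels 0..K-1), `fs`,
#' `channel_names`, `class_names` and `trial_ids`. Round trips are lossless
#' at stored precision.
#'
#' @param epochs an `eeg_epochs` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(epochs, path) {
  validate_epochs(epochs)
  obj <- list(X = epochs$data, y = epochs$labels, fs = epochs$fs,
              channel_names = epochs$channel_names,
              class_names = epochs$class_names,
              trial_ids = epochs$trial_ids)
  ok <- tryCatch({ saveRDS(obj, path); TRUE }, error = function(e) FALSE)
  if (!ok) stop("cannot write container to ", path)
  invisible(path)
}

#' Read an epoch set from the multi-array container
#'
#' @param path container file written by [save_epochs()] (or any RDS file
#'   holding at least the keys `X` (3-D array), `y` (vector) and `fs`).
#' @return a validated `eeg_epochs`; labels are coerced to integer.
#' @export
load_epochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- readRDS(path)
  for (key in c("X", "y", "fs"))
    if (is.null(obj[[key]])) stop("container missing key `", key, "`")
  if (length(dim(obj$X)) != 3L) stop("key `X` must be a 3-D array")
  if (dim(obj$X)[1L] != length(obj$y))
    stop("shape mismatch between X and y")
  eeg_epochs(obj$X, obj$y, obj$fs, obj$channel_names, obj$class_names,
             obj$trial_ids)
}

#' Extract the cue-aligned 4-second analysis window
#'
#' Standard motor-imagery epoching: the 4 s of signal following the visual
#' cue (1000 samples at 250 Hz). `cue_onset` is a 0-based sample offset and
#' the window is half-open, so the returned samples are
#' `[cue_onset, cue_onset + 4 fs)` in 0-based terms — the cue sample is
#' included, with exactly `4 * fs` samples returned.
#'
#' @param raw_trial numeric matrix `(channels, samples)`.
#' @param cue_onset 0-based sample index of cue onset.
#' @param fs sampling rate in Hz.
#' @return matrix `(channels, 4 * fs)`.
#' @export
cue_aligned_window <- function(raw_trial, cue_onset, fs) {
  stopifnot(is.matrix(raw_trial), cue_onset >= 0)
  len <- as.integer(round(4 * fs))
  if (cue_onset + len > ncol(raw_trial))
    stop("cue-aligned window exceeds the recording")
  raw_trial[, (cue_onset + 1L):(cue_onset + len), drop = FALSE]
}
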