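#' Segmentation-recombination augmentation settings
#'
#' Training trials are cut into `n_segments` non-overlapping temporal
#' segments of `segment_len` samples (8 x 125 for 4-s trials at 250 Hz) and
#' new same-class trials are assembled by drawing each segment slot from a
#' uniformly chosen donor trial of the same class — all channels moved
#' together, so spatial correlations survive. The augmented set is generated
#' once, deterministically, before training.
#'
#' @param n_segments number of temporal segments per trial.
#' @param segment_len segment length in samples; `n_segments * segment_len`
#'   must equal the trial length of the set being augmented.
#' @param factor non-negative integer: how many augmented trials to create
#'   per original trial of each class (`factor = 1` doubles the set).
#' @param seed RNG seed controlling donor choices.
#' @return an `augmentation_config` list.
#' @export
augmentation_config <- function(n_segments = 8, segment_len = 125,
                                factor = 1, seed = 0) {
  if (factor < 0 || factor != floor(factor))
    stop("factor must be a non-negative integer")
  structure(list(n_segments = as.integer(n_segments),
                 segment_len = as.integer(segment_len),
                 factor = as.integer(factor), seed = seed),
            class = "augmentation_config")
}

#' Augment a training set by within-class segment recombination
#'
#' Returns the original trials followed by `factor * n` new trials (`n` the
#' original count), with labels preserved; per-class counts of the augmented
#' trials equal `factor` times the original class histogram. The function
#' deliberately takes only a training set — test epochs must never be
#' augmented — and records provenance: which donor supplied every segment.
#'
#' @param train an [eeg_epochs()] training set.
#' @param config an [augmentation_config()]; its `n_segments * segment_len`
#'   must match the set's trial length.
#' @return an `eeg_epochs` whose attribute `"provenance"` is a data frame
#'   with one row per augmented trial and segment (`trial_id`, `segment`,
#'   `donor_id`).
#' @export
segment_recombine <- function(train, config) {
  validate_epochs(train)
  stopifnot(inherits(config, "augmentation_config"))
  d <- dim(train$data)
  if (config$n_segments * config$segment_len != d[3L])
    stop("n_segments * segment_len must equal the trial length (",
         d[3L], " samples)")
  counts <- table(factor(train$labels, levels = 0:(train$n_classes - 1L)))
  if (any(counts == 0))
    stop("every class needs at least one trial to donate segments")

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)

  n_new <- config$factor * d[1L]
  if (n_new == 0) {
    attr(train, "provenance") <-
      data.frame(trial_id = character(0), segment = integer(0),
                 donor_id = character(0))
    return(train)
  }

  seg_idx <- lapply(seq_len(config$n_segments), function(s)
    ((s - 1L) * config$segment_len + 1L):(s * config$segment_len))
  by_class <- split(seq_len(d[1L]), train$labels)

  new_labels <- rep(rep(0:(train$n_classes - 1L), as.integer(counts)),
                    config$factor)
  new_data <- array(0, c(n_new, d[2L], d[3L]))
  prov <- vector("list", n_new)
  new_ids <- paste0("aug", seq_len(n_new))
  for (i in seq_len(n_new)) {
    pool <- by_class[[as.character(new_labels[i])]]
    donors <- pool[sample.int(length(pool), config$n_segments, replace = TRUE)]
    for (s in seq_len(config$n_segments))
      new_data[i, , seg_idx[[s]]] <- train$data[donors[s], , seg_idx[[s]]]
    prov[[i]] <- data.frame(trial_id = new_ids[i],
                            segment = seq_len(config$n_segments),
                            donor_id = train$trial_ids[donors])
  }

  out <- eeg_epochs(abind3(train$data, new_data),
                    c(train$labels, new_labels), train$fs,
                    train$channel_names, train$class_names,
                    c(train$trial_ids, new_ids))
  attr(out, "provenance") <- do.call(rbind, prov)
  out
}
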