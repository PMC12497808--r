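#' Transfer-learning protocol settings
#'
#' Leave-one-subject-out (LOSO) protocol: pre-train from scratch on the
#' pooled first-session data of all source subjects (200 epochs), then
#' fine-tune every layer (none frozen) on a fraction of the target subject's
#' training session — a single stratified subset per adaptation rate — for
#' 200 epochs at the same learning rate, without validation or early
#' stopping.
#'
#' @param pretrain_epochs,finetune_epochs epoch counts of the two phases.
#' @param adaptation_rates fractions of the target training session used for
#'   fine-tuning.
#' @param lr Adam learning rate for both phases.
#' @param batch_size minibatch size.
#' @return a `transfer_config` list.
#' @export
transfer_config <- function(pretrain_epochs = 200, finetune_epochs = 200,
                            adaptation_rates = seq(0, 1, by = 0.1),
                            lr = 5e-4, batch_size = 32) {
  if (any(adaptation_rates < 0 | adaptation_rates > 1))
    stop("adaptation rates must lie in [0, 1]")
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 adaptation_rates = adaptation_rates, lr = lr,
                 batch_size = as.integer(batch_size)),
            class = "transfer_config")
}

#' Pool source subjects and pre-train for a held-out target
#'
#' Pools the training sessions of every subject except the target and trains
#' a fresh model on the pool; the target's trials are never touched, which
#' the disjoint trial ids make verifiable.
#'
#' @param all_subjects named list of [dataset_split()] objects, one per
#'   subject.
#' @param target name of the held-out subject (must be in `all_subjects`).
#' @param model_cfg a [model_config()].
#' @param cfg a [transfer_config()].
#' @param seed seed for initialisation and training.
#' @return the pre-trained `mi_model`; its `pooled_ids` field records the
#'   provenance ids of every trial seen.
#' @export
loso_pretrain <- function(all_subjects, target, model_cfg,
                          cfg = transfer_config(), seed = 0) {
  if (length(all_subjects) < 2) stop("need at least two subjects")
  if (!target %in% names(all_subjects))
    stop("target subject `", target, "` not found")
  sources <- all_subjects[setdiff(names(all_subjects), target)]
  pooled <- do.call(bind_epochs, lapply(sources, function(s) s$train))
  model <- build_model(model_cfg, seed = seed)
  model <- train(model, pooled,
                 train_config(epochs = cfg$pretrain_epochs,
                              batch_size = cfg$batch_size, lr = cfg$lr,
                              seed = seed))
  model$pooled_ids <- pooled$trial_ids
  model
}

#' Fine-tune a pre-trained model on a fraction of the target session
#'
#' Draws a single class-stratified subset of `floor(rate * n)` trials
#' without replacement (stratification keeps every class represented at
#' small rates) and updates all layers. `rate = 0` returns the model
#' unchanged.
#'
#' @param model a pre-trained `mi_model`.
#' @param target_train the target subject's training-session
#'   [eeg_epochs()].
#' @param rate fraction of trials to adapt on, in `[0, 1]`.
#' @param cfg a [transfer_config()].
#' @param seed seed for the subset draw and fine-tuning.
#' @return the adapted `mi_model` (with `finetune_ids` recording the subset
#'   used).
#' @export
finetune_with_rate <- function(model, target_train, rate,
                               cfg = transfer_config(), seed = 0) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  if (rate == 0) return(model)
  idx <- stratified_subset(target_train$labels, rate, seed)
  subset <- subset_epochs(target_train, idx)
  model <- train(model, subset,
                 train_config(epochs = cfg$finetune_epochs,
                              batch_size = cfg$batch_size, lr = cfg$lr,
                              seed = seed))
  model$finetune_ids <- subset$trial_ids
  model
}

# single stratified draw: floor(rate * n) trials total, allocated to classes
# proportionally (largest-remainder rounding), at least one per class when
# the budget allows
stratified_subset <- function(labels, rate, seed) {
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- length(labels)
  total <- floor(rate * n)
  by_class <- split(seq_len(n), labels)
  want <- rate * lengths(by_class)
  take <- floor(want)
  rem <- total - sum(take)
  if (rem > 0) {
    extra <- order(want - take, decreasing = TRUE)[seq_len(rem)]
    take[extra] <- take[extra] + 1L
  }
  if (total >= length(by_class)) take <- pmax(take, 1L)
  idx <- unlist(lapply(seq_along(by_class), function(i) {
    k <- min(take[i], length(by_class[[i]]))
    if (k == 0) return(integer(0))
    by_class[[i]][sample.int(length(by_class[[i]]), k)]
  }))
  sort(idx)
}
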