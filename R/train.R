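#' Forward pass of the decoder
#'
#' @param model an `mi_model` from [build_model()] (trained or not).
#' @param x input trials: an [eeg_epochs()] or an array
#'   `(n_trials, channels, samples)`; a single `(channels, samples)` matrix
#'   is treated as one trial.
#' @param capture_attention if `TRUE`, also return the attention
#'   probabilities of every encoder layer and head.
#' @return list with `logits` (`n x K` matrix) and, when requested,
#'   `attention` (`n_sa_layers x n_heads x seq x seq x n` array) plus the
#'   final temporal-network feature maps `features`
#'   (`F2 x seq x n`). Evaluation mode: batch-norm running statistics,
#'   no dropout.
#' @export
model_forward <- function(model, x, capture_attention = FALSE) {
  stopifnot(inherits(model, "mi_model"))
  xc <- as_input_array(x)
  out <- net_forward(model$params, model$running, model$cfg, xc,
                     training = FALSE, capture_attention = capture_attention)
  list(logits = out$logits, attention = out$attention,
       features = out$features)
}

#' Intermediate feature maps of every stage
#'
#' Runs an evaluation-mode forward pass and returns each stage's output
#' cube (`features x length x trials`): `conv_block`, `ms_conv`,
#' `sa_encoder`, `channel_se`, `tdscfn`. Useful for inspecting the shape
#' chain and for feature-level analyses.
#'
#' @param model an `mi_model`.
#' @param x input trials (as in [model_forward()]).
#' @return named list of arrays.
#' @export
model_stages <- function(model, x) {
  xc <- as_input_array(x)
  net_forward(model$params, model$running, model$cfg, xc,
              training = FALSE)$cache$stages
}

as_input_array <- function(x) {
  if (inherits(x, "eeg_epochs")) x <- x$data
  if (is.matrix(x)) x <- array(x, c(1L, dim(x)))
  stopifnot(length(dim(x)) == 3L)
  aperm(x, c(2L, 3L, 1L))                       # -> (C, T, B)
}

#' Training hyperparameters
#'
#' Defaults are the reference protocol: Adam (moments 0.9/0.999) on the
#' cross-entropy of the logits, batch size 32, learning rate 5e-4, no weight
#' decay, no schedule, no early stopping; the final-epoch weights are the
#' trained model. Epoch count defaults to 1000 for full runs; tests and
#' examples use far fewer.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param weight_decay L2 coefficient (0 in the reference protocol).
#' @param seed RNG seed governing shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 1000, batch_size = 32, lr = 5e-4,
                         weight_decay = 0, seed = 0) {
  stopifnot(epochs > 0, batch_size > 0, lr >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, seed = seed),
            class = "train_config")
}

softmax_xent <- function(logits, labels) {
  pr <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(pr[idx], 1e-12)))
  dl <- pr
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n)
}

#' Train a decoder
#'
#' Minibatch Adam on the cross-entropy loss. Fully deterministic for a fixed
#' `(seed, data, config)` triple: shuffling and dropout draw from one seeded
#' RNG stream. Augment the training set beforehand if desired — this
#' function performs no augmentation itself.
#'
#' @param model an `mi_model`.
#' @param train_set an [eeg_epochs()] whose class count matches the model
#'   head.
#' @param cfg a [train_config()].
#' @param verbose print the epoch loss every `verbose` epochs (0 = silent).
#' @return the trained `mi_model`, with `loss_trace` (mean epoch loss,
#'   length `epochs`) attached.
#' @export
train <- function(model, train_set, cfg = train_config(), verbose = 0) {
  stopifnot(inherits(model, "mi_model"), inherits(cfg, "train_config"))
  validate_epochs(train_set)
  if (train_set$n_classes != model$cfg$n_classes)
    stop("training set has ", train_set$n_classes,
         " classes but the model head expects ", model$cfg$n_classes)
  n <- n_trials(train_set)
  xall <- as_input_array(train_set)
  yall <- train_set$labels

  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(cfg$seed)

  opt <- adam_init(model$params, cfg$lr, weight_decay = cfg$weight_decay)
  trace <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      xb <- xall[, , idx, drop = FALSE]
      fw <- net_forward(model$params, model$running, model$cfg, xb,
                        training = TRUE)
      model$running <- fw$running
      ls <- softmax_xent(fw$logits, yall[idx])
      losses <- c(losses, ls$loss)
      grads <- net_backward(model$params, model$cfg, fw$cache, ls$dlogits)
      upd <- adam_step(opt, model$params, grads)
      opt <- upd$opt
      model$params <- upd$params
    }
    trace[ep] <- mean(losses)
    if (verbose > 0 && ep %% verbose == 0)
      message(sprintf("epoch %d/%d  loss %.4f", ep, cfg$epochs, trace[ep]))
  }
  model$loss_trace <- trace
  model
}

zero_like <- function(x) { x[] <- 0; x }

adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       wd = weight_decay, t = 0L,
       m = lapply(params, zero_like),
       v = lapply(params, zero_like))
}

adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) stop("missing gradient for ", nm)
    dim(gr) <- dim(params[[nm]])
    if (opt$wd > 0) gr <- gr + opt$wd * params[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * gr
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * gr * gr
    step <- opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
    params[[nm]] <- params[[nm]] - step
  }
  list(opt = opt, params = params)
}

#' Evaluate a decoder on a test set
#'
#' @param model a trained `mi_model`.
#' @param test_set an [eeg_epochs()]; must be non-empty.
#' @param batch_size forward-pass batch size.
#' @return list with `accuracy`, `kappa` (Cohen's kappa from the confusion
#'   marginals), `confusion` (`K x K` matrix, rows = true, cols = predicted)
#'   and `predicted` labels.
#' @export
evaluate <- function(model, test_set, batch_size = 64) {
  validate_epochs(test_set)
  n <- n_trials(test_set)
  if (n == 0) stop("empty test set")
  xall <- as_input_array(test_set)
  K <- model$cfg$n_classes
  pred <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    lg <- net_forward(model$params, model$running, model$cfg,
                      xall[, , idx, drop = FALSE], training = FALSE)$logits
    pred[idx] <- max.col(lg, ties.method = "first") - 1L
  }
  cm <- table(factor(test_set$labels, levels = 0:(K - 1L)),
              factor(pred, levels = 0:(K - 1L)))
  cm <- unclass(matrix(as.integer(cm), K, K,
                       dimnames = list(true = 0:(K - 1L),
                                       predicted = 0:(K - 1L))))
  acc <- sum(diag(cm)) / n
  p0 <- acc
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kap <- if (pe < 1) (p0 - pe) / (1 - pe) else 0
  list(accuracy = acc, kappa = kap, confusion = cm, predicted = pred)
}

#' Chance-corrected kappa implied by an accuracy on a balanced task
#'
#' For balanced K-class data with chance agreement `1/K`, Cohen's kappa
#' reduces to `(acc - 1/K) / (1 - 1/K)`. This is the convention behind the
#' kappa scores usually printed next to mean accuracies in motor-imagery
#' benchmarks (e.g. an accuracy of 0.8492 on a balanced 4-class task implies
#' kappa 0.7989).
#'
#' @param acc accuracy as a fraction in `[0, 1]`.
#' @param K number of classes (>= 2).
#' @return kappa value.
#' @export
kappa_from_accuracy <- function(acc, K) {
  if (K < 2) stop("K must be at least 2")
  if (acc < 0 || acc > 1) stop("acc must lie in [0, 1]")
  (acc - 1 / K) / (1 - 1 / K)
}
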