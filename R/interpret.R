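# Perturbation sensitivity suite: four families of input occlusions applied
# to raw trials (no retraining), scored by the Euclidean distance between
# the model's logits on clean and perturbed input.

perturb_input <- function(x) {
  if (inherits(x, "eeg_epochs")) x$data else
    if (is.matrix(x)) array(x, c(1L, dim(x))) else x
}

#' Zero a random fraction of time points
#'
#' Draws `floor(ratio * T)` distinct time indices and zeroes them across all
#' channels of every trial (the same mask for all trials of the call, so the
#' perturbation is a fixed treatment).
#'
#' @param x trials: `eeg_epochs`, `(n, C, T)` array or `(C, T)` matrix.
#' @param ratio fraction of time points in `(0, 1]`.
#' @param seed RNG seed fixing the selection.
#' @return perturbed array `(n, C, T)`.
#' @export
perturb_time_slices <- function(x, ratio, seed = 0) {
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  xa <- perturb_input(x)
  Tn <- dim(xa)[3L]
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(Tn, floor(ratio * Tn))
  xa[, , idx] <- 0
  xa
}

#' Zero one contiguous 200-sample time segment
#'
#' @param x trials as in [perturb_time_slices()].
#' @param position 1-based segment index in `1..floor(T / seg_len)`.
#' @param seg_len segment length in samples.
#' @return perturbed array `(n, C, T)`.
#' @export
perturb_time_segment <- function(x, position, seg_len = 200) {
  xa <- perturb_input(x)
  Tn <- dim(xa)[3L]
  npos <- Tn %/% seg_len
  if (position < 1 || position > npos)
    stop("position must lie in 1..", npos)
  idx <- ((position - 1L) * seg_len + 1L):(position * seg_len)
  xa[, , idx] <- 0
  xa
}

#' Zero a random fraction of channels
#'
#' @param x trials as in [perturb_time_slices()].
#' @param ratio fraction of channels in `(0, 1]`; `floor(ratio * C)`
#'   channels are zeroed over the whole trial.
#' @param seed RNG seed fixing the selection.
#' @return perturbed array `(n, C, T)`.
#' @export
perturb_channels <- function(x, ratio, seed = 0) {
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  xa <- perturb_input(x)
  C <- dim(xa)[2L]
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  idx <- sample.int(C, floor(ratio * C))
  xa[, idx, ] <- 0
  xa
}

#' Enumerate the spatio-temporal occlusion grid
#'
#' Regions are blocks of `ch_block` channels x `t_block` samples; the last
#' channel block may be smaller when C is not a multiple. Enumeration is
#' channel-major and 1-based: region 1 covers channels 1-5 in the first time
#' block, region 2 channels 6-10, and so on.
#'
#' @param C,T_samples trial geometry.
#' @param ch_block,t_block block sizes.
#' @return data frame with one row per region (`region`, `ch_from`, `ch_to`,
#'   `t_from`, `t_to`).
#' @export
spatial_regions <- function(C, T_samples, ch_block = 5, t_block = 200) {
  nch <- ceiling(C / ch_block)
  nt <- T_samples %/% t_block
  grid <- expand.grid(cb = seq_len(nch), tb = seq_len(nt))
  grid <- grid[order(grid$tb, grid$cb), ]
  data.frame(region = seq_len(nrow(grid)),
             ch_from = (grid$cb - 1L) * ch_block + 1L,
             ch_to = pmin(grid$cb * ch_block, C),
             t_from = (grid$tb - 1L) * t_block + 1L,
             t_to = grid$tb * t_block)
}

#' Zero one spatio-temporal region
#'
#' @param x trials as in [perturb_time_slices()].
#' @param region_index 1-based index into [spatial_regions()].
#' @param ch_block,t_block block sizes of the region grid.
#' @return perturbed array `(n, C, T)`.
#' @export
perturb_spatial_region <- function(x, region_index, ch_block = 5,
                                   t_block = 200) {
  xa <- perturb_input(x)
  grid <- spatial_regions(dim(xa)[2L], dim(xa)[3L], ch_block, t_block)
  if (region_index < 1 || region_index > nrow(grid))
    stop("region_index must lie in 1..", nrow(grid))
  r <- grid[region_index, ]
  xa[, r$ch_from:r$ch_to, r$t_from:r$t_to] <- 0
  xa
}

#' Output difference under a perturbation
#'
#' Euclidean distance between the model's logits on clean and perturbed
#' input (pre-softmax, so saturation cannot mask sensitivity), averaged over
#' trials.
#'
#' @param model a trained `mi_model`.
#' @param x clean trials.
#' @param x_pert perturbed trials of identical shape.
#' @return mean per-trial Euclidean logit distance.
#' @export
output_difference <- function(model, x, x_pert) {
  xa <- perturb_input(x); xp <- perturb_input(x_pert)
  if (!identical(dim(xa), dim(xp))) stop("clean/perturbed shape mismatch")
  l0 <- model_forward(model, xa)$logits
  l1 <- model_forward(model, xp)$logits
  mean(sqrt(rowSums((l0 - l1)^2)))
}

#' Perturbation sweep
#'
#' Runs one perturbation family over its settings and returns the mean
#' output difference per setting.
#'
#' @param model a trained `mi_model`.
#' @param x trials to perturb.
#' @param family one of `"time_slice"`, `"time_segment"`, `"channel"`,
#'   `"spatial_region"`.
#' @param settings ratios (time_slice/channel) or 1-based indices
#'   (time_segment/spatial_region); defaults per family.
#' @param seed seed for the random families.
#' @return data frame `family`, `setting`, `output_difference`.
#' @export
perturbation_sweep <- function(model, x,
                               family = c("time_slice", "time_segment",
                                          "channel", "spatial_region"),
                               settings = NULL, seed = 0) {
  family <- match.arg(family)
  xa <- perturb_input(x)
  if (is.null(settings)) {
    settings <- switch(family,
      time_slice = seq(0.1, 0.5, by = 0.1),
      channel = seq(0.1, 0.5, by = 0.1),
      time_segment = seq_len(dim(xa)[3L] %/% 200L),
      spatial_region = seq_len(nrow(spatial_regions(dim(xa)[2L], dim(xa)[3L]))))
  }
  od <- vapply(settings, function(s) {
    xp <- switch(family,
      time_slice = perturb_time_slices(xa, s, seed),
      channel = perturb_channels(xa, s, seed),
      time_segment = perturb_time_segment(xa, s),
      spatial_region = perturb_spatial_region(xa, s))
    output_difference(model, xa, xp)
  }, 0)
  data.frame(family = family, setting = settings, output_difference = od)
}

#' Gradient-weighted class activation map
#'
#' Computes the gradient of the chosen class logit with respect to the final
#' temporal-network feature map (`F2 x seq`), averages it over time to get
#' one weight per feature, and forms the signed weighted sum of the feature
#' maps: the temporal relevance profile (sign distinguishes amplitude
#' increase from decrease, i.e. ERS from ERD). The per-channel relevance
#' back-projects the summed temporal relevance through the absolute spatial
#' filter weights of the conv block's depthwise stage, normalised to sum
#' to 1 across channels.
#'
#' Because the classifier is affine in the flattened feature map, the
#' gradient is exact and closed-form: the class row of the classifier
#' weight matrix.
#'
#' @param model a trained `mi_model`.
#' @param x a single trial (`(C, T)` matrix, 1-trial `eeg_epochs` or
#'   `(1, C, T)` array).
#' @param class_index 0-based class index of the logit to explain.
#' @return a `relevance_map` list: `temporal` (length `seq_len`),
#'   `per_channel` (length C, signed), `feature_weights` (length F2).
#' @export
grad_cam <- function(model, x, class_index) {
  cfg <- model$cfg
  if (class_index < 0 || class_index >= cfg$n_classes)
    stop("class_index must lie in 0..K-1")
  xa <- perturb_input(x)
  if (dim(xa)[1L] != 1L) stop("grad_cam explains a single trial")
  fw <- model_forward(model, xa)
  feat <- matrix(fw$features[, , 1L], cfg$F2, cfg$seq_len)
  grad <- matrix(model$params$fc.w[class_index + 1L, ], cfg$F2, cfg$seq_len)
  w <- rowMeans(grad)                           # one weight per feature map
  temporal <- as.vector(crossprod(feat, w))     # signed, length seq_len
  sp <- apply(abs(model$params$cb.spatial.w), 3L, sum)   # |weights| per channel
  per_channel <- sum(temporal) * sp / sum(sp)
  structure(list(temporal = temporal, per_channel = per_channel,
                 feature_weights = w),
            class = "relevance_map")
}

#' Export attention maps for a set of trials
#'
#' Runs a capture-enabled forward pass and returns the attention
#' probabilities averaged over trials: an array
#' `(n_sa_layers, n_heads, seq, seq)` whose rows (last axis) sum to 1.
#'
#' @param model a trained `mi_model`.
#' @param x trials.
#' @param path optional RDS path to persist the array.
#' @return the attention array, invisibly when `path` is given.
#' @export
export_attention <- function(model, x, path = NULL) {
  fw <- model_forward(model, x, capture_attention = TRUE)
  a <- fw$attention
  d <- dim(a)
  avg <- array(0, d[1:4])
  for (b in seq_len(d[5L])) avg <- avg + a[, , , , b]
  avg <- avg / d[5L]
  if (!is.null(path)) {
    saveRDS(avg, path)
    return(invisible(avg))
  }
  avg
}
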