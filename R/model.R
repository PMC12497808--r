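#' Network hyperparameter record
#'
#' Collects every architectural hyperparameter of the decoder in one
#' validated record. Defaults are the canonical configuration for 4-s
#' 250 Hz trials: 16 temporal filters doubled by the spatial depthwise stage
#' to 32 feature maps, four parallel temporal kernels (15/31/51/75 samples),
#' a 4-layer 8-head self-attention encoder of width 32 with a 128-wide
#' feed-forward, squeeze-and-excitation with reduction 4, and a two-block
#' dilated causal depthwise-separable temporal network with kernel 4 (whose
#' receptive field, 19, covers the 15-step sequence reaching it).
#'
#' @param C input EEG channels.
#' @param T_samples samples per trial.
#' @param n_classes number of classes K.
#' @param F1 temporal filter count.
#' @param D depth multiplier of the spatial depthwise stage; `F2 = D * F1`.
#' @param temporal_kernel temporal conv kernel length (samples).
#' @param pool1,pool2 average-pooling widths after the conv block and the
#'   multi-scale stage; the attention sequence length is
#'   `T_samples / (pool1 * pool2)`.
#' @param ms_kernels four odd kernel lengths of the multi-scale branches.
#' @param n_heads,n_sa_layers,ffn_hidden self-attention encoder geometry;
#'   the model width equals `F2` and must divide by `n_heads`.
#' @param r squeeze-and-excitation reduction ratio (divides `F1`).
#' @param Kt temporal-network kernel size.
#' @param L temporal-network residual blocks; the multi-level fusion wiring
#'   defines exactly two blocks, so only `L = 2` builds a network (the
#'   receptive-field formula accepts any `L`).
#' @param dropout global dropout probability.
#' @return a validated `model_config` list with derived fields `F2`,
#'   `seq_len` and `d_model`.
#' @export
model_config <- function(C = 22, T_samples = 1000, n_classes = 4,
                         F1 = 16, D = 2, temporal_kernel = 32,
                         pool1 = 8, ms_kernels = c(15, 31, 51, 75),
                         pool2 = 8, n_heads = 8, n_sa_layers = 4,
                         ffn_hidden = 128, r = 4, Kt = 4, L = 2,
                         dropout = 0.3) {
  F2 <- D * F1
  seq_len <- (T_samples %/% pool1) %/% pool2
  cfg <- list(C = C, T_samples = T_samples, n_classes = n_classes,
              F1 = F1, D = D, F2 = F2, temporal_kernel = temporal_kernel,
              pool1 = pool1, ms_kernels = ms_kernels, pool2 = pool2,
              d_model = F2, n_heads = n_heads, n_sa_layers = n_sa_layers,
              ffn_hidden = ffn_hidden, r = r, Kt = Kt, L = L,
              dropout = dropout, seq_len = seq_len)
  if (length(ms_kernels) != 4L || any(ms_kernels %% 2 == 0))
    stop("ms_kernels must be four odd kernel lengths")
  if (F2 %% 4 != 0) stop("F2 must divide by the four multi-scale branches")
  if (cfg$d_model %% n_heads != 0) stop("d_model must divide by n_heads")
  if (F1 %% r != 0) stop("F1 must divide by the SE reduction r")
  if (Kt < 1 || L < 1) stop("Kt and L must be >= 1")
  if (receptive_field(Kt, L) < seq_len)
    warning("temporal-network receptive field (", receptive_field(Kt, L),
            ") smaller than the sequence length (", seq_len, ")")
  class(cfg) <- "model_config"
  cfg
}

#' Receptive field of the dilated causal temporal network
#'
#' With kernel size `Kt` and `L` residual blocks whose dilation doubles per
#' block (two convolutions per block), the number of input steps influencing
#' one output step is `1 + 2 * (Kt - 1) * (2^L - 1)`.
#'
#' @param Kt convolution kernel size (>= 1).
#' @param L number of residual blocks (>= 1).
#' @return integer receptive field size in samples.
#' @export
receptive_field <- function(Kt, L) {
  if (Kt < 1 || L < 1) stop("Kt and L must be positive")
  as.integer(1 + 2 * (Kt - 1) * (2^L - 1))
}

glorot <- function(dims, fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -s, s), dims)
}

conv_init <- function(out_ch, in_pg, k) glorot(c(out_ch, in_pg, k), in_pg * k, k * out_ch)

wn_init <- function(out_ch, in_pg, k) {
  v <- conv_init(out_ch, in_pg, k)
  list(v = v, g = sqrt(rowSums(matrix(v, nrow = out_ch)^2)))
}

#' Build an untrained decoder
#'
#' Instantiates every trainable tensor (Glorot-uniform weights, unit batch
#' norm scales, zero biases, weight-norm gains initialised to the weight
#' norms) plus batch-norm running statistics. Deterministic for a fixed
#' seed.
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed for the initialisation draws.
#' @return an object of class `mi_model` holding `cfg`, the named parameter
#'   list `params` and batch-norm running state `running`.
#' @export
build_model <- function(cfg, seed = 0) {
  stopifnot(inherits(cfg, "model_config"))
  if (cfg$L != 2)
    stop("the fusion temporal network is defined for L = 2 residual blocks")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)

  F1 <- cfg$F1; F2 <- cfg$F2; d <- cfg$d_model; S <- cfg$seq_len
  p <- list()
  # conv block: temporal (no bias), BN, spatial depthwise (no bias), BN
  p$cb.temporal.w <- conv_init(F1, 1, cfg$temporal_kernel)
  p$cb.bn1.gamma <- rep(1, F1); p$cb.bn1.beta <- numeric(F1)
  p$cb.spatial.w <- glorot(c(F1, cfg$D, cfg$C), cfg$C, cfg$D)
  p$cb.bn2.gamma <- rep(1, F2); p$cb.bn2.beta <- numeric(F2)
  # multi-scale temporal convolutions (biased) + shared BN
  for (i in 1:4) {
    k <- cfg$ms_kernels[i]
    p[[paste0("ms.b", i, ".w")]] <- conv_init(F2 / 4, F2, k)
    p[[paste0("ms.b", i, ".b")]] <- numeric(F2 / 4)
  }
  p$ms.bn.gamma <- rep(1, F2); p$ms.bn.beta <- numeric(F2)
  # self-attention encoder layers
  for (l in seq_len(cfg$n_sa_layers)) {
    pre <- paste0("sa", l, ".")
    for (nm in c("wq", "wk", "wv", "wo"))
      p[[paste0(pre, nm)]] <- glorot(c(d, d), d, d)
    for (nm in c("bq", "bk", "bv", "bo"))
      p[[paste0(pre, nm)]] <- numeric(d)
    p[[paste0(pre, "ln1.gamma")]] <- rep(1, d)
    p[[paste0(pre, "ln1.beta")]] <- numeric(d)
    p[[paste0(pre, "ffn.w1")]] <- glorot(c(d, cfg$ffn_hidden), d, cfg$ffn_hidden)
    p[[paste0(pre, "ffn.b1")]] <- numeric(cfg$ffn_hidden)
    p[[paste0(pre, "ffn.w2")]] <- glorot(c(cfg$ffn_hidden, d), cfg$ffn_hidden, d)
    p[[paste0(pre, "ffn.b2")]] <- numeric(d)
    p[[paste0(pre, "ln2.gamma")]] <- rep(1, d)
    p[[paste0(pre, "ln2.beta")]] <- numeric(d)
  }
  # channel compression + squeeze-and-excitation (all bias-free)
  p$se.compress.w <- glorot(c(F1, F2), F2, F1)
  p$se.bn.gamma <- rep(1, F1); p$se.bn.beta <- numeric(F1)
  p$se.w1 <- glorot(c(F1 / cfg$r, F1), F1, F1 / cfg$r)
  p$se.w2 <- glorot(c(F1, F1 / cfg$r), F1 / cfg$r, F1)
  # temporal fusion network; weight norm on pointwise and kernel-Kt convs
  p$tcn.b1.dw.w <- conv_init(F1, 1, cfg$Kt); p$tcn.b1.dw.b <- numeric(F1)
  wn <- wn_init(F2, F1, 1)
  p$tcn.b1.pw.v <- wn$v; p$tcn.b1.pw.g <- wn$g; p$tcn.b1.pw.b <- numeric(F2)
  p$tcn.b1.bn1.gamma <- rep(1, F2); p$tcn.b1.bn1.beta <- numeric(F2)
  wn <- wn_init(F2, F2, cfg$Kt)
  p$tcn.b1.conv.v <- wn$v; p$tcn.b1.conv.g <- wn$g; p$tcn.b1.conv.b <- numeric(F2)
  p$tcn.b1.bn2.gamma <- rep(1, F2); p$tcn.b1.bn2.beta <- numeric(F2)
  p$tcn.res.w <- conv_init(F2, F1, 1); p$tcn.res.b <- numeric(F2)
  p$tcn.b2.dw.w <- conv_init(F2, 1, cfg$Kt); p$tcn.b2.dw.b <- numeric(F2)
  wn <- wn_init(F2, F2, 1)
  p$tcn.b2.pw.v <- wn$v; p$tcn.b2.pw.g <- wn$g; p$tcn.b2.pw.b <- numeric(F2)
  p$tcn.b2.bn1.gamma <- rep(1, F2); p$tcn.b2.bn1.beta <- numeric(F2)
  wn <- wn_init(F2, F2, cfg$Kt)
  p$tcn.b2.conv.v <- wn$v; p$tcn.b2.conv.g <- wn$g; p$tcn.b2.conv.b <- numeric(F2)
  p$tcn.b2.bn2.gamma <- rep(1, F2); p$tcn.b2.bn2.beta <- numeric(F2)
  # classifier over the flattened (F2 x seq_len) feature map
  p$fc.w <- glorot(c(cfg$n_classes, F2 * S), F2 * S, cfg$n_classes)
  p$fc.b <- numeric(cfg$n_classes)

  running <- list(cb.bn1 = bn_state(F1), cb.bn2 = bn_state(F2),
                  ms.bn = bn_state(F2), se.bn = bn_state(F1),
                  tcn.b1.bn1 = bn_state(F2), tcn.b1.bn2 = bn_state(F2),
                  tcn.b2.bn1 = bn_state(F2), tcn.b2.bn2 = bn_state(F2))
  structure(list(cfg = cfg, params = p, running = running),
            class = "mi_model")
}

#' @export
print.mi_model <- function(x, ...) {
  cat(sprintf("<mi_model> C=%d T=%d K=%d; %s trainable parameters\n",
              x$cfg$C, x$cfg$T_samples, x$cfg$n_classes,
              format(count_parameters(x$cfg)$total, big.mark = ",")))
  invisible(x)
}

#' Per-block trainable-parameter accounting
#'
#' Computes the trainable-parameter count of every block from the
#' configuration alone (conv weights and biases, batch-norm scales and
#' shifts, weight-norm gains, attention projections, layer norms,
#' classifier; batch-norm running statistics are not trainable and are
#' excluded). For the canonical 22-channel 4-class configuration the blocks
#' count 1,312 / 44,128 / 50,816 / 672 / 11,024 / 1,924 parameters for a
#' total of 109,876.
#'
#' @param cfg a [model_config()].
#' @return a `param_count_report` list with fields `conv_block`, `ms_conv`,
#'   `sa_encoder`, `channel_se`, `tdscfn`, `classifier` and `total`.
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  F1 <- cfg$F1; F2 <- cfg$F2; d <- cfg$d_model; h <- cfg$ffn_hidden
  conv_block <- F1 * cfg$temporal_kernel + 2 * F1 + F2 * cfg$C + 2 * F2
  ms_conv <- sum((F2 / 4) * F2 * cfg$ms_kernels + F2 / 4) + 2 * F2
  sa_layer <- 4 * (d * d + d) + (d * h + h + h * d + d) + 2 * 2 * d
  sa_encoder <- cfg$n_sa_layers * sa_layer
  channel_se <- F1 * F2 + 2 * F1 + 2 * F1 * F1 / cfg$r
  tdscfn <-
    (F1 * cfg$Kt + F1) + (F2 * F1 + 2 * F2) + 2 * F2 +       # b1 dw, pw(+gain), bn
    (F2 * F2 * cfg$Kt + 2 * F2) + 2 * F2 +                   # b1 conv(+gain), bn
    (F2 * F1 + F2) +                                         # shared residual proj
    (F2 * cfg$Kt + F2) + (F2 * F2 + 2 * F2) + 2 * F2 +       # b2 dw, pw(+gain), bn
    (F2 * F2 * cfg$Kt + 2 * F2) + 2 * F2                     # b2 conv(+gain), bn
  classifier <- cfg$n_classes * F2 * cfg$seq_len + cfg$n_classes
  rep <- list(conv_block = conv_block, ms_conv = ms_conv,
              sa_encoder = sa_encoder, channel_se = channel_se,
              tdscfn = tdscfn, classifier = classifier)
  rep$total <- sum(unlist(rep))
  structure(rep, class = "param_count_report")
}

#' @export
print.param_count_report <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-12s %10s\n", nm, format(x[[nm]], big.mark = ",")))
  invisible(x)
}

#' Enumerate trainable tensors of a built model
#'
#' Walks the instantiated parameter list and tallies element counts per
#' block; the independent cross-check of [count_parameters()].
#'
#' @param model an `mi_model`.
#' @return a `param_count_report` from direct enumeration.
#' @export
enumerate_parameters <- function(model) {
  stopifnot(inherits(model, "mi_model"))
  sizes <- vapply(model$params, length, 0L)
  group <- function(prefix) as.numeric(sum(sizes[startsWith(names(sizes), prefix)]))
  rep <- list(conv_block = group("cb."), ms_conv = group("ms."),
              sa_encoder = group("sa"), channel_se = group("se."),
              tdscfn = group("tcn."), classifier = group("fc."))
  rep$total <- sum(unlist(rep))
  structure(rep, class = "param_count_report")
}
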