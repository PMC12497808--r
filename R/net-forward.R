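# Forward pass of the full decoder. Internal layout: (features, length,
# batch) cubes between stages, tokens-in-rows matrices inside the attention
# encoder. Every stage returns its cache so net_backward() can replay it.

# x: (C, T, B) array -> list(logits (B x K), attention, features, cache, running)
net_forward <- function(params, running, cfg, x, training = FALSE,
                        capture_attention = FALSE) {
  p <- params
  C <- cfg$C; Tn <- cfg$T_samples; B <- dim(x)[3L]
  F1 <- cfg$F1; F2 <- cfg$F2; d <- cfg$d_model; S <- cfg$seq_len
  drop <- cfg$dropout
  cache <- list(B = B)

  if (dim(x)[1L] != C || dim(x)[2L] != Tn)
    stop("conv_block: input shaped (", dim(x)[1L], ",", dim(x)[2L],
         ") but config expects (", C, ",", Tn, ")")
  if (anyNA(x) || any(is.infinite(x)))
    stop("conv_block: non-finite values in the input trials")

  ## ---- conv block --------------------------------------------------------
  # temporal conv: shared 1-D filters applied to each channel independently;
  # even kernel padded (left k/2, right k/2 - 1) so the length stays T
  kT <- cfg$temporal_kernel
  xin <- array(aperm(x, c(2L, 1L, 3L)), c(1L, Tn, C * B))
  y1 <- conv1d(xin, p$cb.temporal.w, NULL,
               pad_l = kT %/% 2, pad_r = kT %/% 2 - 1L)    # (F1, T, C*B)
  bn <- bn_fwd(matrix(y1, F1), p$cb.bn1.gamma, p$cb.bn1.beta,
               running$cb.bn1, training)
  running$cb.bn1 <- bn$run; cache$cb.bn1 <- bn$cache
  # spatial depthwise: per temporal filter, D learned channel combinations
  sp_in <- aperm(array(bn$y, c(F1, Tn, C, B)), c(1L, 3L, 2L, 4L)) # (F1,C,T,B)
  y2 <- array(0, c(F2, Tn * B))
  for (f in seq_len(F1)) {
    xf <- matrix(sp_in[f, , , ], C, Tn * B)
    y2[(f - 1L) * cfg$D + seq_len(cfg$D), ] <-
      matrix(p$cb.spatial.w[f, , ], cfg$D, C) %*% xf
  }
  cache$sp_in <- sp_in; cache$xin <- xin
  bn <- bn_fwd(y2, p$cb.bn2.gamma, p$cb.bn2.beta, running$cb.bn2, training)
  running$cb.bn2 <- bn$run; cache$cb.bn2 <- bn$cache
  e1 <- elu_fwd(bn$y); cache$cb.elu <- e1
  a1 <- avgpool_fwd(array(e1, c(F2, Tn, B)), cfg$pool1)     # (F2, T1, B)
  dr <- dropout_fwd(a1, drop, training)
  cache$cb.drop <- dr$mask
  a1 <- dr$y
  T1 <- dim(a1)[2L]
  cache$a1 <- a1

  ## ---- multi-scale temporal convolutions ---------------------------------
  ms <- array(0, c(F2, T1, B))
  nb <- F2 %/% 4L
  for (i in 1:4) {
    k <- cfg$ms_kernels[i]
    ms[(i - 1L) * nb + seq_len(nb), , ] <-
      conv1d(a1, p[[paste0("ms.b", i, ".w")]], p[[paste0("ms.b", i, ".b")]],
             pad_l = (k - 1L) %/% 2L, pad_r = (k - 1L) %/% 2L)
  }
  bn <- bn_fwd(matrix(ms, F2), p$ms.bn.gamma, p$ms.bn.beta,
               running$ms.bn, training)
  running$ms.bn <- bn$run; cache$ms.bn <- bn$cache
  e2 <- elu_fwd(bn$y); cache$ms.elu <- e2
  a2 <- avgpool_fwd(array(e2, c(F2, T1, B)), cfg$pool2)     # (F2, S, B)
  dr <- dropout_fwd(a2, drop, training)
  cache$ms.drop <- dr$mask; cache$ms.T1 <- T1
  a2 <- dr$y

  ## ---- self-attention encoder --------------------------------------------
  X <- t(matrix(a2, d))                                     # (B*S, d), s fastest
  if (any(!is.finite(X)))
    stop("sa_encoder: non-finite activations reaching the attention stage")
  attn <- if (capture_attention)
    array(0, c(cfg$n_sa_layers, cfg$n_heads, S, S, B)) else NULL
  cache$sa <- vector("list", cfg$n_sa_layers)
  for (l in seq_len(cfg$n_sa_layers)) {
    lay <- sa_layer_fwd(p, l, X, B, S, cfg$n_heads, drop, training)
    cache$sa[[l]] <- lay$cache
    if (capture_attention) attn[l, , , , ] <- aperm(lay$A, c(3L, 1L, 2L, 4L))
    X <- lay$y
  }
  a3 <- array(t(X), c(d, S, B))

  ## ---- channel compression + squeeze-and-excitation ----------------------
  h0 <- p$se.compress.w %*% matrix(a3, F2)                  # (F1, S*B)
  cache$se.in <- a3
  bn <- bn_fwd(h0, p$se.bn.gamma, p$se.bn.beta, running$se.bn, training)
  running$se.bn <- bn$run; cache$se.bn <- bn$cache
  hc <- array(elu_fwd(bn$y), c(F1, S, B)); cache$se.elu <- hc
  z <- matrix(0, F1, B)
  for (b in seq_len(B)) z[, b] <- rowMeans(matrix(hc[, , b], F1, S))
  s1 <- p$se.w1 %*% z
  s1r <- relu_fwd(s1)
  gate <- sigmoid(p$se.w2 %*% s1r)                          # (F1, B)
  cache$se.z <- z; cache$se.s1 <- s1; cache$se.s1r <- s1r; cache$se.gate <- gate
  gatearr <- aperm(array(gate, c(F1, B, S)), c(1L, 3L, 2L))
  a4 <- hc * gatearr                                        # (F1, S, B)
  cache$se.gatearr <- gatearr

  ## ---- temporal depthwise-separable fusion network ------------------------
  tf <- tcn_fwd(p, cfg, a4, running, training)
  running <- tf$running
  cache$tcn <- tf$cache
  cache$tcn.in <- a4
  feat <- tf$y                                              # (F2, S, B)

  ## ---- classifier ---------------------------------------------------------
  flat <- matrix(feat, F2 * S, B)
  logits <- t(p$fc.w %*% flat + p$fc.b)
  cache$flat <- flat
  cache$stages <- list(conv_block = a1, ms_conv = a2, sa_encoder = a3,
                       channel_se = a4, tdscfn = feat)

  list(logits = logits, attention = attn, features = feat,
       cache = cache, running = running)
}

# one post-norm encoder layer: MHA + residual + LN, FFN + residual + LN
sa_layer_fwd <- function(p, l, X, B, S, H, drop, training) {
  pre <- paste0("sa", l, ".")
  d <- ncol(X); dk <- d %/% H
  Q <- lin_fwd(X, p[[paste0(pre, "wq")]], p[[paste0(pre, "bq")]])
  K <- lin_fwd(X, p[[paste0(pre, "wk")]], p[[paste0(pre, "bk")]])
  V <- lin_fwd(X, p[[paste0(pre, "wv")]], p[[paste0(pre, "bv")]])
  A <- array(0, c(S, S, H, B))
  Amask <- vector("list", B * H)
  O <- matrix(0, nrow(X), d)
  scl <- 1 / sqrt(dk)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * S + 1L):(b * S)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Sc <- (Q[rows, cols, drop = FALSE] %*%
               t(K[rows, cols, drop = FALSE])) * scl
      Ah <- softmax_rows(Sc)
      A[, , h, b] <- Ah
      dr <- dropout_fwd(Ah, drop, training)
      Amask[(b - 1L) * H + h] <- list(dr$mask)
      O[rows, cols] <- dr$y %*% V[rows, cols, drop = FALSE]
    }
  }
  Yo <- lin_fwd(O, p[[paste0(pre, "wo")]], p[[paste0(pre, "bo")]])
  dro <- dropout_fwd(Yo, drop, training)
  r1 <- X + dro$y
  ln1 <- ln_fwd(r1, p[[paste0(pre, "ln1.gamma")]], p[[paste0(pre, "ln1.beta")]])
  Ff <- lin_fwd(ln1$y, p[[paste0(pre, "ffn.w1")]], p[[paste0(pre, "ffn.b1")]])
  Fg <- gelu_fwd(Ff)
  F2o <- lin_fwd(Fg, p[[paste0(pre, "ffn.w2")]], p[[paste0(pre, "ffn.b2")]])
  drf <- dropout_fwd(F2o, drop, training)
  r2 <- ln1$y + drf$y
  ln2 <- ln_fwd(r2, p[[paste0(pre, "ln2.gamma")]], p[[paste0(pre, "ln2.beta")]])
  list(y = ln2$y, A = A,
       cache = list(X = X, Q = Q, K = K, V = V, A = A, Amask = Amask, O = O,
                    drom = dro$mask, ln1 = ln1$cache, ln1y = ln1$y, Ff = Ff,
                    Fg = Fg, drfm = drf$mask, ln2 = ln2$cache))
}

# two-block dilated causal depthwise-separable network with multi-level
# residual fusion; the 1x1 input projection is shared by both blocks
tcn_fwd <- function(p, cfg, x, running, training) {
  F1 <- cfg$F1; F2 <- cfg$F2; Kt <- cfg$Kt; drop <- cfg$dropout
  S <- dim(x)[2L]; B <- dim(x)[3L]
  cc <- list()
  res <- conv1d(x, p$tcn.res.w, p$tcn.res.b)                 # (F2, S, B)
  cc$res_in <- x

  blk <- function(xb, pre, dil, run1, run2, groups_in) {
    c1 <- list()
    dw_w <- p[[paste0(pre, "dw.w")]]
    a <- conv1d(xb, dw_w, p[[paste0(pre, "dw.b")]],
                pad_l = (Kt - 1L) * dil, dil = dil, groups = groups_in)
    c1$dw_in <- xb
    pw_w <- wn_weight(p[[paste0(pre, "pw.v")]], p[[paste0(pre, "pw.g")]])
    pw <- conv1d(a, pw_w, p[[paste0(pre, "pw.b")]])
    c1$pw_in <- a; c1$pw_w <- pw_w
    bn1 <- bn_fwd(matrix(pw, F2), p[[paste0(pre, "bn1.gamma")]],
                  p[[paste0(pre, "bn1.beta")]], run1, training)
    d1 <- dropout_fwd(bn1$y, drop, training)
    c1$bn1 <- bn1$cache; c1$d1m <- d1$mask
    h <- array(d1$y, c(F2, S, B))
    cv_w <- wn_weight(p[[paste0(pre, "conv.v")]], p[[paste0(pre, "conv.g")]])
    cv <- conv1d(h, cv_w, p[[paste0(pre, "conv.b")]],
                 pad_l = (Kt - 1L) * dil, dil = dil)
    c1$cv_in <- h; c1$cv_w <- cv_w
    e <- elu_fwd(cv)
    c1$cv_elu <- e
    bn2 <- bn_fwd(matrix(e, F2), p[[paste0(pre, "bn2.gamma")]],
                  p[[paste0(pre, "bn2.beta")]], run2, training)
    d2 <- dropout_fwd(bn2$y, drop, training)
    c1$bn2 <- bn2$cache; c1$d2m <- d2$mask
    list(path = array(d2$y, c(F2, S, B)), cache = c1,
         run1 = bn1$run, run2 = bn2$run)
  }

  b1 <- blk(x, "tcn.b1.", 1L, running$tcn.b1.bn1, running$tcn.b1.bn2, F1)
  running$tcn.b1.bn1 <- b1$run1; running$tcn.b1.bn2 <- b1$run2
  out1 <- elu_fwd(b1$path + res)
  cc$b1 <- b1$cache; cc$out1 <- out1; cc$res <- res

  b2 <- blk(out1, "tcn.b2.", 2L, running$tcn.b2.bn1, running$tcn.b2.bn2, F2)
  running$tcn.b2.bn1 <- b2$run1; running$tcn.b2.bn2 <- b2$run2
  out2 <- elu_fwd(b2$path + out1 + res)
  cc$b2 <- b2$cache; cc$out2 <- out2

  list(y = out2, cache = cc, running = running)
}
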