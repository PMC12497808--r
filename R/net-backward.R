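# Backward pass mirroring net_forward(): hand-derived gradients for every
# stage, returning a gradient list parallel to the parameter list.

net_backward <- function(params, cfg, cache, dlogits) {
  p <- params
  F1 <- cfg$F1; F2 <- cfg$F2; d <- cfg$d_model; S <- cfg$seq_len
  B <- cache$B; Tn <- cfg$T_samples; C <- cfg$C
  g <- list()

  ## classifier
  g$fc.w <- t(dlogits) %*% t(cache$flat)
  g$fc.b <- colSums(dlogits)
  dfeat <- array(t(p$fc.w) %*% t(dlogits), c(F2, S, B))

  ## temporal fusion network
  tb <- tcn_bwd(p, cfg, cache$tcn, dfeat)
  g <- c(g, tb$grads)
  da4 <- tb$dx

  ## squeeze-and-excitation
  hc <- cache$se.elu
  dhc <- da4 * cache$se.gatearr
  gate <- cache$se.gate
  dgate <- matrix(0, F1, B)
  prod <- da4 * hc
  for (b in seq_len(B)) dgate[, b] <- rowSums(matrix(prod[, , b], F1, S))
  ds2 <- dgate * gate * (1 - gate)
  g$se.w2 <- ds2 %*% t(cache$se.s1r)
  ds1r <- t(p$se.w2) %*% ds2
  ds1 <- ds1r * (cache$se.s1 > 0)
  g$se.w1 <- ds1 %*% t(cache$se.z)
  dz <- t(p$se.w1) %*% ds1
  dhc <- dhc + aperm(array(dz / S, c(F1, B, S)), c(1L, 3L, 2L))
  delu <- elu_bwd(dhc, hc)
  bnb <- bn_bwd(matrix(delu, F1), cache$se.bn, p$se.bn.gamma)
  g$se.bn.gamma <- bnb$dgamma; g$se.bn.beta <- bnb$dbeta
  Xm <- matrix(cache$se.in, F2)
  g$se.compress.w <- bnb$dx %*% t(Xm)
  da3 <- array(t(p$se.compress.w) %*% bnb$dx, c(d, S, B))

  ## self-attention encoder
  dX <- t(matrix(da3, d))
  for (l in rev(seq_len(cfg$n_sa_layers))) {
    lb <- sa_layer_bwd(p, l, cache$sa[[l]], dX, B, S, cfg$n_heads)
    g <- c(g, lb$grads)
    dX <- lb$dX
  }
  da2 <- array(t(dX), c(F2, S, B))

  ## multi-scale stage
  T1 <- cache$ms.T1
  da2 <- dropout_bwd(da2, cache$ms.drop)
  dpool <- avgpool_bwd(da2, cfg$pool2, T1)
  delu <- elu_bwd(matrix(dpool, F2), cache$ms.elu)
  bnb <- bn_bwd(delu, cache$ms.bn, p$ms.bn.gamma)
  g$ms.bn.gamma <- bnb$dgamma; g$ms.bn.beta <- bnb$dbeta
  dms <- array(bnb$dx, c(F2, T1, B))
  da1 <- array(0, c(F2, T1, B))
  nb <- F2 %/% 4L
  for (i in 1:4) {
    k <- cfg$ms_kernels[i]
    rows <- (i - 1L) * nb + seq_len(nb)
    cg <- conv1d_grad(cache$a1, p[[paste0("ms.b", i, ".w")]],
                      dms[rows, , , drop = FALSE],
                      pad_l = (k - 1L) %/% 2L, pad_r = (k - 1L) %/% 2L)
    da1 <- da1 + cg$dx
    g[[paste0("ms.b", i, ".w")]] <- cg$dw
    g[[paste0("ms.b", i, ".b")]] <- cg$db
  }

  ## conv block
  da1 <- dropout_bwd(da1, cache$cb.drop)
  dpool <- avgpool_bwd(da1, cfg$pool1, Tn)
  delu <- elu_bwd(matrix(dpool, F2), cache$cb.elu)
  bnb <- bn_bwd(delu, cache$cb.bn2, p$cb.bn2.gamma)
  g$cb.bn2.gamma <- bnb$dgamma; g$cb.bn2.beta <- bnb$dbeta
  dy2 <- bnb$dx                                            # (F2, T*B)
  g$cb.spatial.w <- array(0, dim(p$cb.spatial.w))
  dsp <- array(0, c(F1, C, Tn, B))
  for (f in seq_len(F1)) {
    rows <- (f - 1L) * cfg$D + seq_len(cfg$D)
    dYf <- dy2[rows, , drop = FALSE]
    Xf <- matrix(cache$sp_in[f, , , ], C, Tn * B)
    g$cb.spatial.w[f, , ] <- dYf %*% t(Xf)
    dsp[f, , , ] <- array(t(matrix(p$cb.spatial.w[f, , ], cfg$D, C)) %*% dYf,
                          c(C, Tn, B))
  }
  dy1 <- matrix(aperm(dsp, c(1L, 3L, 2L, 4L)), F1)         # (F1, T*C*B)
  bnb <- bn_bwd(dy1, cache$cb.bn1, p$cb.bn1.gamma)
  g$cb.bn1.gamma <- bnb$dgamma; g$cb.bn1.beta <- bnb$dbeta
  kT <- cfg$temporal_kernel
  cg <- conv1d_grad(cache$xin, p$cb.temporal.w,
                    array(bnb$dx, c(F1, Tn, C * B)),
                    pad_l = kT %/% 2, pad_r = kT %/% 2 - 1L, has_bias = FALSE)
  g$cb.temporal.w <- cg$dw

  g[names(params)]                      # fixed order; absent -> NULL error later
}

sa_layer_bwd <- function(p, l, cc, dY, B, S, H) {
  pre <- paste0("sa", l, ".")
  d <- ncol(dY); dk <- d %/% H; scl <- 1 / sqrt(dk)
  g <- list()

  l2 <- ln_bwd(dY, cc$ln2)
  g[[paste0(pre, "ln2.gamma")]] <- l2$dgamma
  g[[paste0(pre, "ln2.beta")]] <- l2$dbeta
  dr2 <- l2$dx
  dF2o <- dropout_bwd(dr2, cc$drfm)
  lb <- lin_bwd(dF2o, cc$Fg, p[[paste0(pre, "ffn.w2")]])
  g[[paste0(pre, "ffn.w2")]] <- lb$dw; g[[paste0(pre, "ffn.b2")]] <- lb$db
  dFf <- gelu_bwd(lb$dx, cc$Ff)
  lb <- lin_bwd(dFf, cc$ln1y, p[[paste0(pre, "ffn.w1")]])
  g[[paste0(pre, "ffn.w1")]] <- lb$dw; g[[paste0(pre, "ffn.b1")]] <- lb$db
  dln1y <- dr2 + lb$dx

  l1 <- ln_bwd(dln1y, cc$ln1)
  g[[paste0(pre, "ln1.gamma")]] <- l1$dgamma
  g[[paste0(pre, "ln1.beta")]] <- l1$dbeta
  dr1 <- l1$dx
  dYo <- dropout_bwd(dr1, cc$drom)
  lb <- lin_bwd(dYo, cc$O, p[[paste0(pre, "wo")]])
  g[[paste0(pre, "wo")]] <- lb$dw; g[[paste0(pre, "bo")]] <- lb$db
  dO <- lb$dx

  dQ <- matrix(0, nrow(dY), d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * S + 1L):(b * S)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      A <- cc$A[, , h, b]
      mask <- cc$Amask[[(b - 1L) * H + h]]
      Ad <- if (is.null(mask)) A else A * mask
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cc$V[rows, cols, drop = FALSE]
      dAd <- dOb %*% t(Vb)
      dV[rows, cols] <- dV[rows, cols] + t(Ad) %*% dOb
      dA <- dropout_bwd(dAd, mask)
      dS <- A * (dA - rowSums(dA * A))
      dSc <- dS * scl
      dQ[rows, cols] <- dQ[rows, cols] + dSc %*% cc$K[rows, cols, drop = FALSE]
      dK[rows, cols] <- dK[rows, cols] + t(dSc) %*% cc$Q[rows, cols, drop = FALSE]
    }
  }
  dX <- dr1
  lb <- lin_bwd(dQ, cc$X, p[[paste0(pre, "wq")]])
  g[[paste0(pre, "wq")]] <- lb$dw; g[[paste0(pre, "bq")]] <- lb$db
  dX <- dX + lb$dx
  lb <- lin_bwd(dK, cc$X, p[[paste0(pre, "wk")]])
  g[[paste0(pre, "wk")]] <- lb$dw; g[[paste0(pre, "bk")]] <- lb$db
  dX <- dX + lb$dx
  lb <- lin_bwd(dV, cc$X, p[[paste0(pre, "wv")]])
  g[[paste0(pre, "wv")]] <- lb$dw; g[[paste0(pre, "bv")]] <- lb$db
  dX <- dX + lb$dx
  list(dX = dX, grads = g)
}

tcn_bwd <- function(p, cfg, cc, dout2) {
  F1 <- cfg$F1; F2 <- cfg$F2; Kt <- cfg$Kt
  S <- dim(dout2)[2L]; B <- dim(dout2)[3L]
  g <- list()

  blk_bwd <- function(pre, c1, dpath, dil, groups_in) {
    gb <- list()
    dd2 <- dropout_bwd(matrix(dpath, F2), c1$d2m)
    bnb <- bn_bwd(dd2, c1$bn2, p[[paste0(pre, "bn2.gamma")]])
    gb[[paste0(pre, "bn2.gamma")]] <- bnb$dgamma
    gb[[paste0(pre, "bn2.beta")]] <- bnb$dbeta
    dcv <- elu_bwd(array(bnb$dx, c(F2, S, B)), c1$cv_elu)
    cg <- conv1d_grad(c1$cv_in, c1$cv_w, dcv,
                      pad_l = (Kt - 1L) * dil, dil = dil)
    wb <- wn_bwd(cg$dw, p[[paste0(pre, "conv.v")]], p[[paste0(pre, "conv.g")]])
    gb[[paste0(pre, "conv.v")]] <- wb$dv
    gb[[paste0(pre, "conv.g")]] <- wb$dg
    gb[[paste0(pre, "conv.b")]] <- cg$db
    dd1 <- dropout_bwd(matrix(cg$dx, F2), c1$d1m)
    bnb <- bn_bwd(dd1, c1$bn1, p[[paste0(pre, "bn1.gamma")]])
    gb[[paste0(pre, "bn1.gamma")]] <- bnb$dgamma
    gb[[paste0(pre, "bn1.beta")]] <- bnb$dbeta
    cg <- conv1d_grad(c1$pw_in, c1$pw_w, array(bnb$dx, c(F2, S, B)))
    wb <- wn_bwd(cg$dw, p[[paste0(pre, "pw.v")]], p[[paste0(pre, "pw.g")]])
    gb[[paste0(pre, "pw.v")]] <- wb$dv
    gb[[paste0(pre, "pw.g")]] <- wb$dg
    gb[[paste0(pre, "pw.b")]] <- cg$db
    cg <- conv1d_grad(c1$dw_in, p[[paste0(pre, "dw.w")]], cg$dx,
                      pad_l = (Kt - 1L) * dil, dil = dil, groups = groups_in)
    gb[[paste0(pre, "dw.w")]] <- cg$dw
    gb[[paste0(pre, "dw.b")]] <- cg$db
    list(dx = cg$dx, grads = gb)
  }

  de2 <- elu_bwd(dout2, cc$out2)
  dres <- de2
  dout1 <- de2
  b2 <- blk_bwd("tcn.b2.", cc$b2, de2, 2L, F2)
  g <- c(g, b2$grads)
  dout1 <- dout1 + b2$dx

  de1 <- elu_bwd(dout1, cc$out1)
  dres <- dres + de1
  b1 <- blk_bwd("tcn.b1.", cc$b1, de1, 1L, F1)
  g <- c(g, b1$grads)
  dx <- b1$dx

  cg <- conv1d_grad(cc$res_in, p$tcn.res.w, dres)
  g$tcn.res.w <- cg$dw
  g$tcn.res.b <- cg$db
  dx <- dx + cg$dx

  list(dx = dx, grads = g)
}
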