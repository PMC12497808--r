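# Numerical primitives for the network: each primitive has a forward that
# returns (y, cache) and a matching backward. Feature maps are stored as
# (features, length, batch) arrays so the first dimension recycles in
# elementwise ops; token matrices for the attention stage store tokens in
# rows. Batch norm keeps running statistics for evaluation mode; only the
# training-mode backward is exercised by the optimizer.

#' @useDynLib mieeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

conv1d <- function(x, w, b = NULL, pad_l = 0, pad_r = 0, dil = 1, groups = 1) {
  has_bias <- !is.null(b)
  if (!has_bias) b <- numeric(dim(w)[1L])
  conv1d_fwd_cpp(x, w, b, pad_l, pad_r, dil, groups, has_bias)
}

conv1d_grad <- function(x, w, dy, pad_l = 0, pad_r = 0, dil = 1, groups = 1,
                        has_bias = TRUE) {
  conv1d_bwd_cpp(x, w, dy, pad_l, pad_r, dil, groups, has_bias)
}

# ---- batch norm over rows of a (features x N) matrix -----------------------

bn_fwd <- function(xm, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  nr <- nrow(xm); nc <- ncol(xm)
  if (training) {
    mu <- .rowMeans(xm, nr, nc)
    xc <- xm - mu
    v <- .rowMeans(xc * xc, nr, nc)
    invstd <- 1 / sqrt(v + eps)
    xhat <- xc * invstd
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var +
      momentum * v * (if (nc > 1) nc / (nc - 1) else 1)
  } else {
    invstd <- 1 / sqrt(run$var + eps)
    xhat <- (xm - run$mean) * invstd
  }
  list(y = xhat * gamma + beta,
       cache = list(xhat = xhat, invstd = invstd, training = training),
       run = run)
}

bn_bwd <- function(dy, cache, gamma) {
  nr <- nrow(dy); nc <- ncol(dy)
  dxhat <- dy * gamma
  dgamma <- .rowSums(dy * cache$xhat, nr, nc)
  dbeta <- .rowSums(dy, nr, nc)
  if (cache$training) {
    dx <- cache$invstd *
      (dxhat - .rowMeans(dxhat, nr, nc) -
         cache$xhat * .rowMeans(dxhat * cache$xhat, nr, nc))
  } else {
    dx <- dxhat * cache$invstd
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

bn_state <- function(nf) list(mean = numeric(nf), var = rep(1, nf))

# ---- activations -----------------------------------------------------------

elu_fwd <- function(x) {
  neg <- x < 0
  x[neg] <- exp(x[neg]) - 1
  x
}

elu_bwd <- function(dy, y) {
  g <- y
  pos <- y > 0
  g[pos] <- 1
  g[!pos] <- y[!pos] + 1
  dy * g
}

gelu_fwd <- function(x) x * stats::pnorm(x)
gelu_bwd <- function(dy, x) dy * (stats::pnorm(x) + x * stats::dnorm(x))

relu_fwd <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(m) {
  m <- exp(m - apply(m, 1L, max))
  m / rowSums(m)
}

# ---- dropout (inverted scaling; mask drawn from the session RNG) -----------

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  list(y = x * mask, mask = mask)
}

dropout_bwd <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- average pooling, kernel == stride, over the length axis ---------------

avgpool_fwd <- function(x, k) {
  d <- dim(x)                                  # (f, L, b)
  lo <- d[2L] %/% k
  xr <- array(x[, seq_len(lo * k), , drop = FALSE], c(d[1L], k, lo, d[3L]))
  y <- array(0, c(d[1L], lo, d[3L]))
  for (i in seq_len(k))
    y <- y + array(xr[, i, , , drop = FALSE], c(d[1L], lo, d[3L]))
  y / k
}

avgpool_bwd <- function(dy, k, L_in) {
  d <- dim(dy)                                 # (f, lo, b)
  dx <- array(0, c(d[1L], k, d[2L], d[3L]))
  g <- dy / k
  for (i in seq_len(k)) dx[, i, , ] <- g
  dim(dx) <- c(d[1L], k * d[2L], d[3L])
  if (k * d[2L] < L_in) {                      # pooled tail cropped: zero grad
    full <- array(0, c(d[1L], L_in, d[3L]))
    full[, seq_len(k * d[2L]), ] <- dx
    dx <- full
  }
  dx
}

# ---- layer norm over rows of a tokens-in-rows (N x d) matrix ---------------

ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  gm <- matrix(gamma, nrow(x), ncol(x), byrow = TRUE)
  list(y = xhat * gm + matrix(beta, nrow(x), ncol(x), byrow = TRUE),
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma))
}

ln_bwd <- function(dy, cache) {
  gm <- matrix(cache$gamma, nrow(dy), ncol(dy), byrow = TRUE)
  dxhat <- dy * gm
  dx <- cache$invstd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx,
       dgamma = colSums(dy * cache$xhat),
       dbeta = colSums(dy))
}

# ---- affine on tokens-in-rows matrices -------------------------------------

lin_fwd <- function(x, w, b) x %*% w + matrix(b, nrow(x), length(b), byrow = TRUE)

lin_bwd <- function(dy, x, w) {
  list(dx = dy %*% t(w), dw = crossprod(x, dy), db = colSums(dy))
}

# ---- weight normalization: w = g * v / ||v||, one gain per output channel --

wn_weight <- function(v, g) {
  out <- dim(v)[1L]
  norms <- sqrt(rowSums(matrix(v, nrow = out)^2))
  array(v * (g / norms), dim(v))
}

wn_bwd <- function(dw, v, g) {
  out <- dim(v)[1L]
  vm <- matrix(v, nrow = out)
  norms <- sqrt(rowSums(vm^2))
  dot <- rowSums(matrix(dw, nrow = out) * vm)
  dg <- dot / norms
  dv <- array(dw * (g / norms) - v * (g * dot / norms^3), dim(v))
  list(dv = dv, dg = dg)
}
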