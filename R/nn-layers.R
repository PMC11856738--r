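# Differentiable layer primitives. Feature batches are stored as
# (H, W, N, C) arrays so that flattening gives an (H*W*N) x C matrix whose
# columns are channels; every layer is then one GEMM plus reshapes.
# Each *_fwd returns list(y, cache); each *_bwd consumes the upstream
# gradient and the cache and returns the input gradient plus parameter
# gradients.

# column-wise add / multiply of a per-column vector (fast sweep(x, 2, v));
# the C++ kernels avoid materializing the recycled vector
cadd <- function(x, v) {
  d <- dim(x)
  if (length(d) != 2L) dim(x) <- c(length(x) / length(v), length(v))
  out <- col_add_cpp(x, v)
  if (length(d) != 2L) dim(out) <- d
  out
}
cmul <- function(x, v) {
  d <- dim(x)
  if (length(d) != 2L) dim(x) <- c(length(x) / length(v), length(v))
  out <- col_mul_cpp(x, v)
  if (length(d) != 2L) dim(out) <- d
  out
}

he_weights <- function(fan_in, n_out, n_row) {
  matrix(stats::rnorm(n_row * n_out, sd = sqrt(2 / fan_in)), n_row, n_out)
}

as_feat_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(prod(d[1:3]), d[4])
  x
}

as_feat_arr <- function(m, d_spatial) {
  dim(m) <- c(d_spatial, ncol(m))
  m
}

# --- kxk convolution (zero padding), via im2col + GEMM ----------------------

conv_fwd <- function(x, W, b, k = 3L, stride = 1L, pad = 1L) {
  d <- dim(x)
  cols <- im2col_cpp(x, d[1], d[2], d[3], d[4], k, k, stride, pad)
  y <- cadd(cols %*% W, b)
  ho <- (d[1] + 2L * pad - k) %/% stride + 1L
  wo <- (d[2] + 2L * pad - k) %/% stride + 1L
  dim(y) <- c(ho, wo, d[3], ncol(W))
  list(y = y, cache = list(cols = cols, d_in = d, k = k, stride = stride,
                           pad = pad))
}

conv_bwd <- function(dy, W, cache) {
  d_out <- dim(dy)
  dym <- as_feat_mat(dy)
  dW <- crossprod(cache$cols, dym)
  db <- colSums(dym)
  dxm <- tcrossprod(dym, W)
  d <- cache$d_in
  dx <- col2im_cpp(dxm, d[1], d[2], d[3], d[4], cache$k, cache$k,
                   cache$stride, cache$pad)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# --- 1x1 convolution (channel mixing) ---------------------------------------

conv1x1_fwd <- function(x, W, b) {
  d <- dim(x)
  xm <- as_feat_mat(x)
  y <- cadd(xm %*% W, b)
  dim(y) <- c(d[1:3], ncol(W))
  list(y = y, cache = list(xm = xm, d_in = d))
}

conv1x1_bwd <- function(dy, W, cache) {
  dym <- as_feat_mat(dy)
  dx <- tcrossprod(dym, W)
  dim(dx) <- cache$d_in
  list(dx = dx, dW = crossprod(cache$xm, dym), db = colSums(dym))
}

# --- instance normalization (per sample, per channel, over H*W) -------------

instnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- prod(d[1:2])
  xm <- x
  dim(xm) <- c(m, d[3] * d[4])  # columns indexed by (sample, channel)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = m)
  istd <- 1 / sqrt(colMeans(xc * xc) + eps)
  xhat <- cmul(xc, istd)
  gcol <- rep(gamma, each = d[3])
  bcol <- rep(beta, each = d[3])
  y <- cadd(cmul(xhat, gcol), bcol)
  dim(y) <- d
  list(y = y, cache = list(xhat = xhat, istd = istd, gcol = gcol, d_in = d))
}

instnorm_bwd <- function(dy, cache) {
  d <- cache$d_in
  m <- prod(d[1:2])
  dym <- dy
  dim(dym) <- c(m, d[3] * d[4])
  xhat <- cache$xhat
  dgamma_col <- colSums(dym * xhat)
  dbeta_col <- colSums(dym)
  # collapse per-(sample, channel) sums over samples -> per-channel grads
  n <- d[3]; cc <- d[4]
  grp <- rep(seq_len(cc), each = n)
  dgamma <- as.numeric(rowsum(dgamma_col, grp))
  dbeta <- as.numeric(rowsum(dbeta_col, grp))
  dxhat <- cmul(dym, cache$gcol)
  t1 <- colMeans(dxhat)
  t2 <- colMeans(dxhat * xhat)
  dx <- cmul(cadd(dxhat, -t1) - cmul(xhat, t2), cache$istd)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- leaky rectifier --------------------------------------------------------

lrelu_fwd <- function(x, slope = 0.01) {
  r <- lrelu_cpp(x, slope)
  y <- r$y; fac <- r$fac
  dim(y) <- dim(x); dim(fac) <- dim(x)
  list(y = y, cache = fac)
}

lrelu_bwd <- function(dy, cache) dy * cache

# --- 2x2 stride-2 transposed convolution (non-overlapping upsampling) -------
# W is C_in x (4*C_out); column (off + 4*(co-1)) maps input channels onto the
# output pixel at 2x2-block offset `off` ((dh,dw) in (0,0),(1,0),(0,1),(1,1)).

upconv_offsets <- matrix(c(0L, 0L, 1L, 0L, 0L, 1L, 1L, 1L), nrow = 2)

upconv_fwd <- function(x, W, b) {
  d <- dim(x)
  c_out <- ncol(W) %/% 4L
  xm <- as_feat_mat(x)
  ym <- xm %*% W
  out <- array(0, c(2L * d[1], 2L * d[2], d[3], c_out))
  hs <- seq(1L, 2L * d[1], by = 2L)
  ws <- seq(1L, 2L * d[2], by = 2L)
  for (off in 1:4) {
    blk <- cadd(ym[, off + 4L * (seq_len(c_out) - 1L), drop = FALSE], b)
    dim(blk) <- c(d[1:3], c_out)
    out[hs + upconv_offsets[1, off], ws + upconv_offsets[2, off], , ] <- blk
  }
  list(y = out, cache = list(xm = xm, d_in = d))
}

upconv_bwd <- function(dy, W, cache) {
  d <- cache$d_in
  c_out <- ncol(W) %/% 4L
  hs <- seq(1L, 2L * d[1], by = 2L)
  ws <- seq(1L, 2L * d[2], by = 2L)
  dym <- matrix(0, prod(d[1:3]), ncol(W))
  db <- numeric(c_out)
  for (off in 1:4) {
    blk <- dy[hs + upconv_offsets[1, off], ws + upconv_offsets[2, off], , ,
              drop = FALSE]
    dim(blk) <- c(prod(d[1:3]), c_out)
    db <- db + colSums(blk)
    dym[, off + 4L * (seq_len(c_out) - 1L)] <- blk
  }
  dW <- crossprod(cache$xm, dym)
  dx <- tcrossprod(dym, W)
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

# --- channel concatenation --------------------------------------------------

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[1:3] == db[1:3]))
  out <- c(a, b)
  dim(out) <- c(da[1:3], da[4] + db[4])
  out
}

# --- per-position class softmax ---------------------------------------------

softmax_channels <- function(logits) {
  d <- dim(logits)
  p <- row_softmax(as_feat_mat(logits))
  dim(p) <- d
  p
}
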