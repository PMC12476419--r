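# Differentiable building blocks.  Each *_fwd returns list(y, cache);
# each *_bwd consumes the upstream gradient and the cache and returns
# the input gradient plus any parameter gradients.  Feature maps are
# arrays (D, H, W, C); convolution weights are arrays
# (3, 3, 3, Cin, Cout).

conv3d_fwd <- function(x, w, b, stride = 1L) {
  d <- dim(x)
  r <- cpp_conv3d_fwd(x, d[1:3], d[4], w,
                      as.double(b), stride)
  array(r$out, c(r$dims, length(b)))
}

conv3d_bwd <- function(x, w, stride, dout) {
  d <- dim(x); dw <- dim(w)
  r <- cpp_conv3d_bwd(x, d[1:3], d[4], w, dw[5],
                      stride, dout)
  list(dx = array(r$dx, d), dw = array(r$dw, dw), db = as.numeric(r$db))
}

dwconv3d_fwd <- function(x, w) {
  d <- dim(x)
  array(cpp_dwconv3d_fwd(x, d[1:3], d[4], w), d)
}

dwconv3d_bwd <- function(x, w, dout) {
  d <- dim(x)
  r <- cpp_dwconv3d_bwd(x, d[1:3], d[4], w,
                        dout)
  list(dx = array(r$dx, d), dw = array(r$dw, dim(w)))
}

# trilinear resize of a feature map to new spatial dims
resize_fm <- function(x, odims) {
  d <- dim(x)
  array(cpp_resize3d(x, d[1:3], d[4], as.integer(odims)),
        c(odims, d[4]))
}

resize_fm_adj <- function(dout, indims) {
  d <- dim(dout)
  array(cpp_resize3d_adj(dout, d[1:3], d[4],
                         as.integer(indims)), c(indims, d[4]))
}

# fused instance norm + leaky ReLU (single C pass)
inl_fwd <- function(x, gamma, beta, slope = 0.01, eps = 1e-5) {
  d <- dim(x)
  r <- cpp_inl_fwd(x, prod(d[1:3]), d[4], gamma, beta, slope, eps)
  list(y = array(r$y, d),
       cache = list(xhat = r$xhat, istd = r$istd, gamma = gamma,
                    beta = beta, slope = slope, d = d))
}

inl_bwd <- function(dout, cache) {
  d <- cache$d
  r <- cpp_inl_bwd(dout, cache$xhat, cache$istd, cache$gamma,
                   cache$beta, cache$slope, prod(d[1:3]))
  list(dx = array(r$dx, d), dgamma = as.numeric(r$dgamma),
       dbeta = as.numeric(r$dbeta))
}

instnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- prod(d[1:3]); C <- d[4]
  xm <- fm_mat(x)
  mu <- .colMeans(xm, n, C)
  v <- .colMeans(xm * xm, n, C) - mu^2
  istd <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- xm
  y <- xm
  for (j in seq_len(C)) {              # column loop beats large rep()
    xhat[, j] <- (xm[, j] - mu[j]) * istd[j]
    y[, j] <- xhat[, j] * gamma[j] + beta[j]
  }
  list(y = mat_fm(y, d[1:3]),
       cache = list(xhat = xhat, istd = istd, gamma = gamma,
                    sdims = d[1:3]))
}

instnorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  n <- nrow(xhat); C <- ncol(xhat)
  dm <- fm_mat(dout)
  dxh <- dm * xhat
  dgamma <- .colSums(dxh, n, C)
  dbeta <- .colSums(dm, n, C)
  m1 <- dbeta / n
  m2 <- dgamma / n
  sc <- cache$gamma * cache$istd
  dx <- dm
  for (j in seq_len(C))
    dx[, j] <- (dm[, j] - m1[j] - xhat[, j] * m2[j]) * sc[j]
  list(dx = mat_fm(dx, cache$sdims), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, slope = 0.01) {
  f <- slope + (1 - slope) * (x > 0)
  list(y = x * f, cache = f)
}

lrelu_bwd <- function(dout, cache) dout * cache

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  mask <- array((runif(length(x)) >= p) / (1 - p), dim(x))
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# 1x1x1 (point-wise) convolution: pure channel mixing.  w is Cin x Cout.
pwconv_fwd <- function(x, w, b = NULL) {
  d <- dim(x)
  y <- fm_mat(x) %*% w
  if (!is.null(b)) y <- y + rep(b, each = nrow(y))
  mat_fm(y, d[1:3])
}

pwconv_bwd <- function(x, w, dout, hasBias = TRUE) {
  d <- dim(x)
  dm <- fm_mat(dout)
  xm <- fm_mat(x)
  out <- list(dx = mat_fm(dm %*% t(w), d[1:3]), dw = crossprod(xm, dm))
  if (hasBias) out$db <- colSums(dm)
  out
}

concat_fm <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[1:3], db[1:3]))
  mat_fm(cbind(fm_mat(a), fm_mat(b)), da[1:3])
}

split_fm <- function(d, c1) {
  dd <- dim(d)
  m <- fm_mat(d)
  list(a = mat_fm(m[, seq_len(c1), drop = FALSE], dd[1:3]),
       b = mat_fm(m[, -seq_len(c1), drop = FALSE], dd[1:3]))
}
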