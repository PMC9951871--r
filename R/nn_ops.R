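# Internal neural-network primitives: weight standardization, Group
# Normalization, ReLU, softmax, and thin wrappers over the compiled
# convolution kernels. Feature maps are H x W x C arrays; kernels are
# k x k x Cin x Cout arrays reshaped to (k*k*Cin) x Cout matrices for the
# GEMM-based convolution.

as_wmat <- function(w) {
  d <- dim(w)
  dim(w) <- c(d[1] * d[2] * d[3], d[4])
  w
}

conv_fwd <- function(x, w, pad = (dim(w)[1] - 1L) %/% 2L) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  .conv2d_fwd_cpp(x, as_wmat(w), dim(w)[1], pad)
}

conv_bwd <- function(x, w, dy, pad = (dim(w)[1] - 1L) %/% 2L) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  out <- .conv2d_bwd_cpp(x, as_wmat(w), dy, dim(w)[1], pad)
  dim(out$dw) <- dim(w)
  out
}

#' Standardize a convolution kernel per output filter
#'
#' Re-parameterizes a kernel so that, for every output filter, the weights
#' have zero mean and unit variance over the input-channel x spatial
#' extent, with a small `eps` added to the variance for stability
#' (zero-variance filters map to zero). Applied to convolution weights at
#' use time in every encoder/decoder convolution.
#'
#' @param w Kernel array `k x k x Cin x Cout` (at least 2 elements per
#'   filter).
#' @param eps Variance floor.
#' @return Standardized kernel, same shape.
#' @export
standardize_kernel <- function(w, eps = 1e-7) {
  d <- dim(w)
  n <- prod(d[-length(d)])
  wm <- w
  dim(wm) <- c(n, d[length(d)])
  mu <- colMeans(wm)
  v <- colMeans(wm^2) - mu^2
  ctr <- sweep(wm, 2L, mu)
  out <- sweep(ctr, 2L, sqrt(v + eps), "/")
  dim(out) <- d
  out
}

# gradient of loss wrt raw kernel, given gradient wrt standardized kernel
standardize_kernel_bwd <- function(w, dwhat, eps = 1e-7) {
  d <- dim(w)
  n <- prod(d[-length(d)])
  wm <- w; dim(wm) <- c(n, d[length(d)])
  gm <- dwhat; dim(gm) <- c(n, d[length(d)])
  mu <- colMeans(wm)
  v <- colMeans(wm^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  what <- sweep(sweep(wm, 2L, mu), 2L, inv, "*")
  gmean <- colMeans(gm)
  gdot <- colMeans(gm * what)
  out <- sweep(gm, 2L, gmean) - sweep(what, 2L, gdot, "*")
  out <- sweep(out, 2L, inv, "*")
  dim(out) <- d
  out
}

group_norm_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]
  if (C %% groups != 0L) stop("groupnorm groups must divide channel count")
  m <- C %/% groups * hw  # elements per group
  xm <- x; dim(xm) <- c(m, groups)
  mu <- colMeans(xm)
  inv <- 1 / sqrt(colMeans(xm^2) - mu^2 + eps)
  xhat <- (xm - rep(mu, each = m)) * rep(inv, each = m)
  y <- xhat * rep(gamma, each = hw) + rep(beta, each = hw)
  dim(xhat) <- d; dim(y) <- d
  list(y = y, xhat = xhat, inv = inv, groups = groups)
}

group_norm_bwd <- function(cache, gamma, dy) {
  xhat <- cache$xhat
  d <- dim(xhat); hw <- d[1] * d[2]; C <- d[3]; groups <- cache$groups
  m <- C %/% groups * hw
  xm <- xhat; dim(xm) <- c(hw, C)
  dym <- dy; dim(dym) <- c(hw, C)
  dgamma <- colSums(dym * xm)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = hw)
  dim(dxhat) <- c(m, groups); dim(xm) <- c(m, groups)
  gmean <- colMeans(dxhat)
  gdot <- colMeans(dxhat * xm)
  dx <- (dxhat - rep(gmean, each = m) - xm * rep(gdot, each = m)) *
    rep(cache$inv, each = m)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, mask = m)
}

softmax_channels <- function(logits) {
  d <- dim(logits); hw <- d[1] * d[2]
  lm <- logits; dim(lm) <- c(hw, d[3])
  mx <- lm[, 1]
  for (k in seq_len(d[3])[-1]) mx <- pmax(mx, lm[, k])
  e <- exp(lm - mx)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}

# per-pixel sum over channels (for softmax backward)
channel_dot_sum <- function(a, b) {
  d <- dim(a); hw <- d[1] * d[2]
  am <- a; dim(am) <- c(hw, d[3])
  bm <- b; dim(bm) <- c(hw, d[3])
  s <- rowSums(am * bm)
  dim(s) <- d[1:2]
  s
}
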