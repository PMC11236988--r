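# Network primitives with explicit forward/backward passes.  There is no
# autograd here: each forward returns the cache its backward needs, and the
# trainer chains them by hand.  All parameter tensors are plain numeric
# arrays/matrices so checkpoints serialize trivially.

IN_EPS <- 1e-5

# ---- instance normalization (per channel over spatial positions) -----------

instnorm_fwd <- function(x, gamma, beta) {
  ds <- dim(x)
  nvox <- prod(ds[1:3])
  m <- matrix(x, nvox, ds[4])
  mu <- colMeans(m)
  xc <- m - rep(mu, each = nvox)
  v <- colSums(xc^2) / nvox
  istd <- 1 / sqrt(v + IN_EPS)
  xhat <- xc * rep(istd, each = nvox)
  y <- xhat * rep(gamma, each = nvox) + rep(beta, each = nvox)
  dim(y) <- ds
  list(y = y, xhat = xhat, istd = istd, dims = ds)
}

instnorm_bwd <- function(cache, gamma, dy) {
  ds <- cache$dims
  nvox <- prod(ds[1:3])
  dym <- matrix(dy, nvox, ds[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = nvox)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- (dxhat - rep(s1 / nvox, each = nvox) -
           cache$xhat * rep(s2 / nvox, each = nvox)) *
    rep(cache$istd, each = nvox)
  dim(dx) <- ds
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations -----------------------------------------------------------

LRELU_SLOPE <- 0.01

lrelu_fwd <- function(x) {
  x * ((x >= 0) * (1 - LRELU_SLOPE) + LRELU_SLOPE)
}

lrelu_bwd <- function(x, dy) {
  dy * ((x >= 0) * (1 - LRELU_SLOPE) + LRELU_SLOPE)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- fully connected -------------------------------------------------------

fc_fwd <- function(x, W, b) as.numeric(W %*% x + b)

fc_bwd <- function(x, W, dy) {
  list(dx = as.numeric(crossprod(W, dy)),
       dW = tcrossprod(dy, x),
       db = dy)
}

# ---- conv wrappers ---------------------------------------------------------

conv3d_forward <- function(x, W, b, stride, keep_cols = FALSE) {
  .conv3d_fwd(as.numeric(x), dim(x), W, b, as.integer(stride), keep_cols)
}

conv3d_backward <- function(dy, xdim, W, cols, stride, need_dx = TRUE) {
  .conv3d_bwd(as.numeric(dy), as.integer(xdim), W, cols,
              as.integer(stride), need_dx)
}

# 1x1x1 convolution (channel squeeze) as a voxel-wise matrix product.
conv1x1_fwd <- function(x, W, b) {
  ds <- dim(x)
  nvox <- prod(ds[1:3])
  m <- matrix(x, nvox, ds[4])
  y <- sweep(m %*% t(W), 2, b, `+`)
  dim(y) <- c(ds[1:3], nrow(W))
  y
}

conv1x1_bwd <- function(x, W, dy) {
  ds <- dim(x)
  nvox <- prod(ds[1:3])
  xm <- matrix(x, nvox, ds[4])
  dym <- matrix(dy, nvox, nrow(W))
  dx <- dym %*% W
  dim(dx) <- ds
  list(dx = dx, dW = t(dym) %*% xm, db = colSums(dym))
}
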