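# Minimal CNN building blocks on plain R arrays of dim (H, W, C, N), with
# hand-derived backward passes and an Adam optimizer. 3x3 convolutions go
# through compiled im2col/col2im; everything else is vectorized R.

# ---- convolution -----------------------------------------------------------

# 3x3 same convolution. W is a (9*Cin) x Cout matrix, b length Cout.
# Returns the output array and the im2col matrix, which the backward pass
# reuses (recomputing it would double the gather cost).
conv3_forward <- function(x, W, b, keep_cols = FALSE) {
  d <- dim(x)
  Cout <- ncol(W)
  xc <- im2col3_cpp(as.vector(x), d[1], d[2], d[3], d[4])
  y <- sweep_add_bias(xc %*% W, b)
  y <- array(mat2arr_cpp(y, d[1], d[2], Cout, d[4]),
             dim = c(d[1], d[2], Cout, d[4]))
  if (keep_cols) list(y = y, xc = xc, xdim = d) else y
}

# `fw` is the conv3_forward(..., keep_cols = TRUE) result
conv3_backward <- function(fw, W, dy) {
  d <- fw$xdim
  Cout <- dim(dy)[3]
  dym <- arr2mat_cpp(as.vector(dy), dim(dy)[1], dim(dy)[2], Cout, d[4])
  dW <- crossprod(fw$xc, dym)
  db <- colSums(dym)
  dxc <- tcrossprod(dym, W)
  dx <- array(col2im3_cpp(dxc, d[1], d[2], d[3], d[4]), dim = d)
  list(dx = dx, dW = dW, db = db)
}

# 1x1 convolution (channel projection)
conv1_forward <- function(x, W, b = NULL) {
  d <- dim(x)
  Cout <- ncol(W)
  xm <- arr2mat_cpp(as.vector(x), d[1], d[2], d[3], d[4])
  y <- xm %*% W
  if (!is.null(b)) y <- sweep_add_bias(y, b)
  array(mat2arr_cpp(y, d[1], d[2], Cout, d[4]),
        dim = c(d[1], d[2], Cout, d[4]))
}

conv1_backward <- function(x, W, dy, bias = TRUE) {
  d <- dim(x)
  Cout <- ncol(W)
  dym <- arr2mat_cpp(as.vector(dy), d[1], d[2], Cout, d[4])
  xm <- arr2mat_cpp(as.vector(x), d[1], d[2], d[3], d[4])
  dW <- crossprod(xm, dym)
  dxm <- tcrossprod(dym, W)
  dx <- array(mat2arr_cpp(dxm, d[1], d[2], d[3], d[4]), dim = d)
  list(dx = dx, dW = dW, db = if (bias) colSums(dym) else NULL)
}

sweep_add_bias <- function(y, b) {
  y + matrix(b, nrow = nrow(y), ncol = length(b), byrow = TRUE)
}

# ---- elementwise and pooling ----------------------------------------------

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(x, dy) dy * (x > 0)

# 2x2 max pooling (even H, W); returns value and argmax code for backward
maxpool2_forward <- function(x) {
  d <- dim(x)
  i1 <- seq(1, d[1], 2); i2 <- seq(2, d[1], 2)
  j1 <- seq(1, d[2], 2); j2 <- seq(2, d[2], 2)
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  c_ <- x[i1, j2, , , drop = FALSE]; e <- x[i2, j2, , , drop = FALSE]
  y <- pmax(a, b, c_, e)
  arg <- 1L * (a == y)
  arg[arg == 0 & b == y] <- 2L
  arg[arg == 0 & c_ == y] <- 3L
  arg[arg == 0] <- 4L
  list(y = y, arg = arg)
}

maxpool2_backward <- function(arg, dy, dims) {
  dx <- array(0, dim = dims)
  i1 <- seq(1, dims[1], 2); i2 <- seq(2, dims[1], 2)
  j1 <- seq(1, dims[2], 2); j2 <- seq(2, dims[2], 2)
  dx[i1, j1, , ] <- dy * (arg == 1L)
  dx[i2, j1, , ] <- dy * (arg == 2L)
  dx[i1, j2, , ] <- dy * (arg == 3L)
  dx[i2, j2, , ] <- dy * (arg == 4L)
  dx
}

# global average pool over the spatial axes: (H,W,C,N) -> C x N matrix
gap_forward <- function(x) {
  d <- dim(x)
  apply(x, c(3, 4), mean)
}
gap_backward <- function(dy, dims) {
  sc <- 1 / (dims[1] * dims[2])
  array(rep(as.vector(dy), each = dims[1] * dims[2]) * sc, dim = dims)
}

# ---- resampling ------------------------------------------------------------

# nearest-neighbour downsampling by integer factor
down_nearest <- function(x, f) {
  d <- dim(x)
  x[seq(1, d[1], f), seq(1, d[2], f), , , drop = FALSE]
}
down_nearest_backward <- function(dy, dims, f) {
  dx <- array(0, dim = dims)
  dx[seq(1, dims[1], f), seq(1, dims[2], f), , ] <- dy
  dx
}

# linear interpolation matrix taking n samples to n*f (cell-centred grid)
interp_matrix <- function(n, f) {
  out <- n * f
  pos <- ((seq_len(out) - 0.5) / f) - 0.5   # source coordinate, 0-based
  lo <- floor(pos)
  frac <- pos - lo
  M <- matrix(0, out, n)
  for (i in seq_len(out)) {
    l <- min(max(lo[i], 0), n - 1)
    h <- min(l + 1, n - 1)
    w <- if (lo[i] < 0 || lo[i] >= n - 1) 0 else frac[i]
    M[i, l + 1] <- M[i, l + 1] + (1 - w)
    M[i, h + 1] <- M[i, h + 1] + w
  }
  M
}

# bilinear upsampling by factor f via separable interpolation matrices
up_linear <- function(x, f) {
  d <- dim(x)
  Mh <- interp_matrix(d[1], f)
  Mw <- interp_matrix(d[2], f)
  x1 <- Mh %*% matrix(x, nrow = d[1])                        # rows
  x1 <- array(x1, c(d[1] * f, d[2], d[3], d[4]))
  x2 <- aperm(x1, c(2, 1, 3, 4))
  x2 <- Mw %*% matrix(x2, nrow = d[2])
  aperm(array(x2, c(d[2] * f, d[1] * f, d[3], d[4])), c(2, 1, 3, 4))
}
up_linear_backward <- function(dy, dims, f) {
  Mh <- interp_matrix(dims[1], f)
  Mw <- interp_matrix(dims[2], f)
  d <- dim(dy)
  g <- aperm(dy, c(2, 1, 3, 4))
  g <- crossprod(Mw, matrix(g, nrow = d[2]))
  g <- aperm(array(g, c(dims[2], d[1], d[3], d[4])), c(2, 1, 3, 4))
  g <- crossprod(Mh, matrix(g, nrow = d[1]))
  array(g, c(dims[1], dims[2], d[3], d[4]))
}

# nearest upsampling by 2 (used in the decoder)
up_nearest2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}
up_nearest2_backward <- function(dy, dims) {
  i1 <- seq(1, dims[1] * 2, 2); j1 <- seq(1, dims[2] * 2, 2)
  dy[i1, j1, , , drop = FALSE] + dy[i1 + 1, j1, , , drop = FALSE] +
    dy[i1, j1 + 1, , , drop = FALSE] + dy[i1 + 1, j1 + 1, , , drop = FALSE]
}

# ---- losses ----------------------------------------------------------------

# replicate an (H,W,N) array across a channel axis -> (H,W,C,N)
bcast_ch <- function(m, C) {
  d <- dim(m)
  aperm(array(rep(m, times = C), dim = c(d[1], d[2], d[3], C)),
        c(1, 2, 4, 3))
}

# flatten (H,W,C,N) to a (H*W*N) x C matrix of per-pixel channel rows
flatten_ch <- function(z) {
  d <- dim(z)
  arr2mat_cpp(as.vector(z), d[1], d[2], d[3], d[4])
}
unflatten_ch <- function(m, d) {
  array(mat2arr_cpp(m, d[1], d[2], d[3], d[4]), dim = d)
}

rowmax_mat <- function(m) {
  r <- m[, 1]
  for (j in 2:ncol(m)) r <- pmax(r, m[, j])
  r
}

# channel-axis softmax for (H,W,C,N)
softmax4 <- function(z) {
  d <- dim(z)
  zm <- flatten_ch(z)
  e <- exp(zm - rowmax_mat(zm))
  unflatten_ch(e / rowSums(e), d)
}

# combined loss: 0.5 * pixel cross-entropy + 0.5 * (1 - mean soft Dice),
# with gradient w.r.t. logits. `y` is a one-hot array like `z`.
seg_loss <- function(z, y, eps = 1e-6) {
  d <- dim(z)
  C <- d[3]
  npix <- prod(d[c(1, 2, 4)])
  zm <- flatten_ch(z)
  ym <- flatten_ch(y)
  e <- exp(zm - rowmax_mat(zm))
  p <- e / rowSums(e)
  ce <- -sum(ym * log(pmax(p, 1e-12))) / npix
  S <- colSums(p * ym)
  Dn <- colSums(p) + colSums(ym)
  dice_c <- (2 * S + eps) / (Dn + eps)
  loss <- 0.5 * ce + 0.5 * (1 - mean(dice_c))
  # d(dice_c)/dp = (2*y*(Dn+eps) - (2*S+eps)) / (Dn+eps)^2, per class
  gp <- -0.5 / C *
    (2 * ym * rep(1 / (Dn + eps), each = nrow(ym)) -
       rep((2 * S + eps) / (Dn + eps)^2, each = nrow(ym)))
  # chain through softmax, add the CE shortcut
  gz <- p * (gp - rowSums(gp * p)) + 0.5 * (p - ym) / npix
  list(loss = loss, grad = unflatten_ch(gz, d),
       prob = unflatten_ch(p, d))
}

# softmax + cross-entropy for class logits (C x N matrix), labels 1..C
class_loss <- function(z, labels) {
  zmax <- apply(z, 2, max)
  e <- exp(sweep(z, 2, zmax))
  p <- sweep(e, 2, colSums(e), "/")
  n <- ncol(z)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  g <- p
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / n, prob = p)
}

# ---- dense layers ----------------------------------------------------------

dense_forward <- function(x, W, b) W %*% x + b           # x: in x N
dense_backward <- function(x, W, dy) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))
}

# ---- initialization and Adam -----------------------------------------------

he_conv3 <- function(cin, cout) {
  matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), 9 * cin, cout)
}
he_conv1 <- function(cin, cout) {
  matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
}
he_dense <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nout, nin)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}
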