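## Minimal neural-network core: dense layers with hand-written forward and
## reverse passes, exact a.e. double-backprop for gradient penalties under
## piecewise-linear activations, a strided im2col convolution (used by the
## perceptual loss and the toy feature extractor), and an Adam optimizer
## operating on nested parameter lists.  Batches are row-major matrices
## (one sample per row).

LRELU_SLOPE <- 0.2

lrelu <- function(a) {
  neg <- a < 0
  a - (1 - LRELU_SLOPE) * (a * neg)
}
lrelu_mask <- function(a) 1 - (1 - LRELU_SLOPE) * (a < 0)

softplus <- function(x) {
  ## numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## He-style initialization, drawing from the current RNG stream.
nn_linear_init <- function(din, dout, gain = 1) {
  list(W = matrix(rnorm(din * dout, 0, gain * sqrt(2 / din)), din, dout),
       b = numeric(dout))
}

## ---- generic dense MLP (lrelu hidden, linear output) ----

mlp_init <- function(sizes) {
  layers <- vector("list", length(sizes) - 1)
  for (l in seq_along(layers)) {
    layers[[l]] <- nn_linear_init(sizes[l], sizes[l + 1])
  }
  layers
}

mlp_forward <- function(layers, x, final_linear = TRUE) {
  L <- length(layers)
  hs <- vector("list", L + 1)
  as <- vector("list", L)
  hs[[1]] <- x
  for (l in seq_len(L)) {
    a <- hs[[l]] %*% layers[[l]]$W
    a <- sweep(a, 2, layers[[l]]$b, "+")
    as[[l]] <- a
    hs[[l + 1]] <- if (l == L && final_linear) a else lrelu(a)
  }
  list(out = hs[[L + 1]], hs = hs, as = as, final_linear = final_linear)
}

## returns grads (same shape as layers) and the input gradient
mlp_backward <- function(layers, cache, dout) {
  L <- length(layers)
  grads <- vector("list", L)
  d <- dout
  for (l in rev(seq_len(L))) {
    da <- if (l == L && cache$final_linear) d else d * lrelu_mask(cache$as[[l]])
    grads[[l]] <- list(W = crossprod(cache$hs[[l]], da), b = colSums(da))
    d <- tcrossprod(da, layers[[l]]$W)
  }
  list(grads = grads, dx = d)
}

## ---- convolution via im2col (stride s, valid padding) ----

conv2d_init <- function(k, cin, cout, gain = 1) {
  fan_in <- k * k * cin
  list(W = matrix(rnorm(fan_in * cout, 0, gain * sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

im2col <- function(x, k, stride) {
  d <- dim(x)  # n, H, W, C
  n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  oh <- (H - k) %/% stride + 1
  ow <- (W - k) %/% stride + 1
  cols <- array(0, c(n, oh, ow, k * k * C))
  idx <- 0
  for (c in seq_len(C)) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    idx <- idx + 1
    cols[, , , idx] <- x[, seq(ki, by = stride, length.out = oh),
                         seq(kj, by = stride, length.out = ow), c]
  }
  list(cols = matrix(cols, n * oh * ow, k * k * C), n = n, oh = oh, ow = ow,
       k = k, C = C, H = H, W = W, stride = stride)
}

conv2d_forward <- function(layer, x, stride = 2) {
  ic <- im2col(x, layer$k, stride)
  out <- ic$cols %*% layer$W
  out <- sweep(out, 2, layer$b, "+")
  dim(out) <- c(ic$n, ic$oh, ic$ow, layer$cout)
  list(out = out, ic = ic)
}

conv2d_backward <- function(layer, cache, dout) {
  ic <- cache$ic
  dmat <- matrix(dout, ic$n * ic$oh * ic$ow, layer$cout)
  dW <- crossprod(ic$cols, dmat)
  db <- colSums(dmat)
  dcols <- tcrossprod(dmat, layer$W)
  dim(dcols) <- c(ic$n, ic$oh, ic$ow, ic$k * ic$k * ic$C)
  dx <- array(0, c(ic$n, ic$H, ic$W, ic$C))
  idx <- 0
  for (c in seq_len(ic$C)) for (kj in seq_len(ic$k)) for (ki in seq_len(ic$k)) {
    idx <- idx + 1
    ri <- seq(ki, by = ic$stride, length.out = ic$oh)
    cj <- seq(kj, by = ic$stride, length.out = ic$ow)
    dx[, ri, cj, c] <- dx[, ri, cj, c] + dcols[, , , idx]
  }
  list(dW = dW, db = db, dx = dx)
}

## ---- Adam over nested lists of numeric arrays ----

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0, beta2 = 0.99,
                      eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  ## bias correction folded into scalars; beta1 = 0 skips the first moment
  s2 <- sqrt(1 - beta2^t)
  c1 <- 1 / (1 - beta1^t)
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (!is.null(names(p)) && all(nzchar(names(p)))) names(p)
              else seq_along(p)
      out_p <- p; out_m <- m; out_v <- v
      for (k in keys) {
        if (is.null(p[[k]]) || is.null(g[[k]])) next
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      v2 <- beta2 * v + (1 - beta2) * g * g
      if (beta1 == 0) {
        list(p = p - (lr * s2) * g / (sqrt(v2) + eps * s2), m = m, v = v2)
      } else {
        m2 <- beta1 * m + (1 - beta1) * g
        list(p = p - (lr * c1 * s2) * m2 / (sqrt(v2) + eps * s2),
             m = m2, v = v2)
      }
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

## elementwise addition of two grad lists (b may have NULL slots)
grads_add <- function(a, b, scale = 1) {
  if (is.null(b)) return(a)
  if (is.list(a)) {
    keys <- if (!is.null(names(a)) && all(nzchar(names(a)))) names(a)
            else seq_along(a)
    for (k in keys) {
      if (!is.null(b[[k]]) && !is.null(a[[k]])) {
        a[[k]] <- grads_add(a[[k]], b[[k]], scale)
      }
    }
    a
  } else {
    a + scale * b
  }
}

grads_zero_like <- function(params) {
  if (is.list(params)) lapply(params, grads_zero_like) else params * 0
}
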