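## Gradient correctness of the hand-written backprop, checked against
## central finite differences on tiny networks.

test_that("dense and convolution backprop match finite differences", {
  set.seed(42)
  layers <- mlp_init(c(5, 7, 3))
  x <- matrix(rnorm(4 * 5), 4)
  R <- matrix(rnorm(4 * 3), 4)
  loss <- function(ls) sum(mlp_forward(ls, x)$out * R)
  fw <- mlp_forward(layers, x)
  bk <- mlp_backward(layers, fw, R)
  f_w <- function(v) { l <- layers; l[[1]]$W[] <- v; loss(l) }
  expect_lt(max(abs(numeric_gradient(f_w, as.vector(layers[[1]]$W)) -
                    as.vector(bk$grads[[1]]$W))), 1e-6)
  f_x <- function(v) { x2 <- x; x2[1, ] <- v; sum(mlp_forward(layers, x2)$out * R) }
  expect_lt(max(abs(numeric_gradient(f_x, x[1, ]) - bk$dx[1, ])), 1e-6)

  cl <- conv2d_init(3, 2, 4)
  xc <- array(rnorm(2 * 8 * 8 * 2), c(2, 8, 8, 2))
  Rc <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  fwc <- conv2d_forward(cl, xc, 2)
  bkc <- conv2d_backward(cl, fwc, Rc)
  f_cw <- function(v) { c2 <- cl; c2$W[1:12] <- v
    sum(conv2d_forward(c2, xc, 2)$out * Rc) }
  expect_lt(max(abs(numeric_gradient(f_cw, cl$W[1:12]) - bkc$dW[1:12])), 1e-6)
  f_cx <- function(v) { x2 <- xc; x2[1, 1:4, 2, 1] <- v
    sum(conv2d_forward(cl, x2, 2)$out * Rc) }
  expect_lt(max(abs(numeric_gradient(f_cx, xc[1, 1:4, 2, 1]) -
                    bkc$dx[1, 1:4, 2, 1])), 1e-6)
})

test_that("generator and discriminator backprop match finite differences", {
  cfg <- gan_config(p = 6, image_size = 16, latent_dim = 8, map_width = 8,
                    iters = 1, seed = 3)
  params <- stimedit:::gan_init_params(cfg)
  n <- 3
  outdim <- 16 * 16 * 2
  set.seed(1)
  x <- matrix(rnorm(n * outdim, 0, 0.3), n, outdim)
  cvec <- c(0L, 1L, 0L)
  ## discriminator side
  dl <- function(prm) {
    mean(softplus(-stimedit:::disc_forward(prm, x, cvec)$logit))
  }
  fw <- stimedit:::disc_forward(params$disc, x, cvec)
  bk <- stimedit:::disc_backward(params$disc, fw,
                                 -stimedit:::sigmoid(-fw$logit) / n)
  f1 <- function(v) { p <- params$disc; p$layers[[1]]$W[1:20] <- v; dl(p) }
  expect_lt(max(abs(numeric_gradient(f1, params$disc$layers[[1]]$W[1:20]) -
                    bk$grads$layers[[1]]$W[1:20])), 1e-6)
  f2 <- function(v) { p <- params$disc; p$cemb[2, ] <- v; dl(p) }
  expect_lt(max(abs(numeric_gradient(f2, params$disc$cemb[2, ]) -
                    bk$grads$cemb[2, ])), 1e-6)

  ## generator side (mapping + synthesis through a fixed linear functional)
  S <- stimedit:::n_style_slots(16)
  z <- matrix(rnorm(n * 6), n, 6)
  widths <- stimedit:::syn_widths(16)
  noise <- lapply(widths, function(w) matrix(rnorm(n * w), n, w))
  R <- matrix(rnorm(n * outdim), n, outdim)
  gl <- function(map, syn) {
    mf <- stimedit:::mapping_forward_internal(map, z, cvec)
    sum(stimedit:::synthesis_forward(syn, rep(list(mf$w), S), noise)$out * R)
  }
  mf <- stimedit:::mapping_forward_internal(params$map, z, cvec)
  sf <- stimedit:::synthesis_forward(params$syn, rep(list(mf$w), S), noise)
  sb <- stimedit:::synthesis_backward(params$syn, sf, R)
  gm <- stimedit:::mapping_backward(params$map, mf$cache, cvec,
                                    Reduce(`+`, sb$dstyles))
  fA <- function(v) { s <- params$syn; s$hidden[[1]]$A[1:20] <- v
    gl(params$map, s) }
  expect_lt(max(abs(numeric_gradient(fA, params$syn$hidden[[1]]$A[1:20]) -
                    sb$grads$hidden[[1]]$A[1:20])), 1e-5)
  fW <- function(v) { s <- params$syn; s$out$W[1:20] <- v; gl(params$map, s) }
  expect_lt(max(abs(numeric_gradient(fW, params$syn$out$W[1:20]) -
                    sb$grads$out$W[1:20])), 1e-5)
  fM <- function(v) { m <- params$map; m$layers[[1]]$W[1:20] <- v
    gl(m, params$syn) }
  expect_lt(max(abs(numeric_gradient(fM, params$map$layers[[1]]$W[1:20]) -
                    gm$layers[[1]]$W[1:20])), 1e-5)
})

test_that("R1 double-backprop matches finite differences of the penalty", {
  cfg <- gan_config(p = 4, image_size = 16, latent_dim = 8, map_width = 8,
                    iters = 1, seed = 5)
  params <- stimedit:::gan_init_params(cfg)
  set.seed(2)
  x <- matrix(rnorm(3 * 512, 0, 0.3), 3, 512)
  cvec <- c(1L, 0L, 1L)
  r1 <- loss_r1(params$disc, x, cvec, return_grads = TRUE)
  r1f <- function(prm) loss_r1(prm, x, cvec)$value
  f1 <- function(v) { p <- params$disc; p$layers[[1]]$W[1:20] <- v; r1f(p) }
  expect_lt(max(abs(numeric_gradient(f1, params$disc$layers[[1]]$W[1:20]) -
                    r1$grads$layers[[1]]$W[1:20])), 1e-6)
  f2 <- function(v) { p <- params$disc; p$layers[[2]]$W[1:20] <- v; r1f(p) }
  expect_lt(max(abs(numeric_gradient(f2, params$disc$layers[[2]]$W[1:20]) -
                    r1$grads$layers[[2]]$W[1:20])), 1e-6)
  f3 <- function(v) { p <- params$disc; p$v <- v; r1f(p) }
  expect_lt(max(abs(numeric_gradient(f3, params$disc$v) - r1$grads$v)), 1e-6)
})

test_that("path-length double-backprop matches its frozen-linearization reference", {
  cfg <- gan_config(p = 4, image_size = 16, latent_dim = 8, map_width = 8,
                    iters = 1, seed = 7)
  params <- stimedit:::gan_init_params(cfg)
  syn <- params$syn
  S <- stimedit:::n_style_slots(16)
  n <- 3
  set.seed(3)
  w <- matrix(rnorm(n * 8), n, 8)
  widths <- stimedit:::syn_widths(16)
  noise <- lapply(widths, function(wd) matrix(rnorm(n * wd), n, wd))
  sf <- stimedit:::synthesis_forward(syn, rep(list(w), S), noise)
  y <- matrix(rnorm(n * 512), n, 512)
  a_pl <- 0.4
  pl <- loss_path(syn, sf, a_pl, y = y, return_grads = TRUE)
  ## reference: rebuild the vjp with the activation linearization frozen
  masks <- lapply(sf$as, lrelu_mask)
  tanhd <- sf$tanhd
  frozen <- function(s) {
    Tm <- y * tanhd
    L <- length(s$hidden)
    dw <- tcrossprod(Tm, s$out$A)
    dh <- tcrossprod(Tm, s$out$W)
    for (l in rev(seq_len(L))) {
      da <- dh * masks[[l]]
      dw <- dw + tcrossprod(da, s$hidden[[l]]$A)
      if (!is.null(s$hidden[[l]]$W)) dh <- tcrossprod(da, s$hidden[[l]]$W)
    }
    mean((sqrt(rowSums(dw^2)) - a_pl)^2)
  }
  expect_equal(frozen(syn), pl$value)
  fA <- function(v) { s <- syn; s$hidden[[1]]$A[1:15] <- v; frozen(s) }
  expect_lt(max(abs(numeric_gradient(fA, syn$hidden[[1]]$A[1:15]) -
                    pl$grads$hidden[[1]]$A[1:15])), 1e-6)
  fW <- function(v) { s <- syn; s$hidden[[2]]$W[1:15] <- v; frozen(s) }
  expect_lt(max(abs(numeric_gradient(fW, syn$hidden[[2]]$W[1:15]) -
                    pl$grads$hidden[[2]]$W[1:15])), 1e-6)
  fO <- function(v) { s <- syn; s$out$A[1:15] <- v; frozen(s) }
  expect_lt(max(abs(numeric_gradient(fO, syn$out$A[1:15]) -
                    pl$grads$out$A[1:15])), 1e-6)
})
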