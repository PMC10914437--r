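## Dual-encoder inversion of the trained generator.  A global encoder
## (editability pathway, also the contrastive embedding network) and a
## per-layer offset encoder (reconstruction pathway) map a real cell crop
## into the generator's style space; the final latent is the mapping-
## network base for the cell's expression plus the global term plus
## per-layer offsets (additive fusion).  Feeding an edited expression to
## the mapping pathway while encoding the original image manipulates the
## reconstruction.

#' Inversion configuration
#'
#' @param lambda1,lambda2,lambda3 weights of the contrastive, l2 and
#'   perceptual loss terms.
#' @param tau contrastive temperature.
#' @param enc_width encoder hidden width.
#' @param global_scale,offset_scale tanh bounds of the global latent term
#'   and the per-layer offsets.
#' @param batch_size,iters,ckpt_every training schedule.
#' @param lr Adam learning rate.
#' @param momentum momentum-encoder decay for the contrastive keys.
#' @param holdout fraction of cells held out for PSNR/SSIM model selection.
#' @param seed RNG seed.
#' @return object of class `inversion_config`.
#' @export
inversion_config <- function(lambda1 = 0.5, lambda2 = 1.0, lambda3 = 0.8,
                             tau = 0.07, enc_width = 256,
                             global_scale = 0.5, offset_scale = 0.1,
                             batch_size = 8, iters = 600, ckpt_every = 200,
                             lr = 1e-3, momentum = 0.99, holdout = 0.1,
                             seed = 1L) {
  assert_that(lambda1 >= 0 && lambda2 >= 0 && lambda3 >= 0,
              "loss weights must be >= 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 tau = tau, enc_width = enc_width,
                 global_scale = global_scale, offset_scale = offset_scale,
                 batch_size = as.integer(batch_size),
                 iters = as.integer(iters),
                 ckpt_every = as.integer(ckpt_every),
                 lr = lr, momentum = momentum, holdout = holdout,
                 seed = as.integer(seed)),
            class = "inversion_config")
}

## fixed random perceptual feature stack (two strided convolutions)
percep_init <- function(seed = 914) {
  with_seed(seed, list(conv2d_init(3, 2, 8), conv2d_init(3, 8, 16)))
}

percep_forward <- function(percep, x) {
  c1 <- conv2d_forward(percep[[1]], x, stride = 2)
  h1 <- lrelu(c1$out)
  c2 <- conv2d_forward(percep[[2]], h1, stride = 2)
  h2 <- lrelu(c2$out)
  list(h1 = h1, h2 = h2, c1 = c1, c2 = c2)
}

#' Reconstruction losses (pixel and perceptual)
#'
#' `l2` is the mean squared pixel error; `lpip` is the mean squared
#' distance between the activations of a fixed random-weight convolutional
#' feature stack evaluated on both images (a deterministic stand-in
#' perceptual metric; an externally trained feature network can be plugged
#' in through `percep`).
#'
#' @param x,xhat image arrays of identical shape (n x H x W x C or
#'   H x W x C).
#' @param percep optional perceptual stack from `percep_init()`.
#' @return list with `l2` and `lpip`.
#' @export
loss_reconstruction <- function(x, xhat, percep = NULL) {
  assert_that(identical(dim(x), dim(xhat)), "shapes differ")
  if (length(dim(x)) == 3) {
    x <- array(x, c(1, dim(x))); xhat <- array(xhat, c(1, dim(xhat)))
  }
  percep <- percep %||% percep_init()
  l2 <- mean((x - xhat)^2)
  fx <- percep_forward(percep, x)
  fy <- percep_forward(percep, xhat)
  lpip <- mean((fx$h1 - fy$h1)^2) + mean((fx$h2 - fy$h2)^2)
  list(l2 = l2, lpip = lpip)
}

## gradient of the lpip term with respect to xhat
lpip_backward <- function(percep, fx, fy) {
  d2 <- 2 * (fy$h2 - fx$h2) / length(fy$h2)
  dc2 <- d2 * lrelu_mask(fy$c2$out)
  bk2 <- conv2d_backward(percep[[2]], fy$c2, dc2)
  dh1 <- bk2$dx + 2 * (fy$h1 - fx$h1) / length(fy$h1)
  dc1 <- dh1 * lrelu_mask(fy$c1$out)
  conv2d_backward(percep[[1]], fy$c1, dc1)$dx
}

## ---- encoders ----

inversion_init_params <- function(cfg, gan_model) {
  din <- gan_model$cfg$image_size^2 * gan_model$cfg$channels
  dw <- gan_model$cfg$latent_dim
  S <- n_style_slots(gan_model$cfg$image_size)
  with_seed(derive_seed(cfg$seed, 43), {
    list(
      ec = list(trunk = mlp_init(c(din, cfg$enc_width, 128)),
                head_lat = nn_linear_init(128, dw, gain = 0.2),
                head_emb = nn_linear_init(128, 64)),
      ep = list(trunk = mlp_init(c(din, cfg$enc_width)),
                head = nn_linear_init(cfg$enc_width, S * dw, gain = 0.2)),
      S = S, dw = dw)
  })
}

ec_forward <- function(ec, x) {
  tf <- mlp_forward(ec$trunk, x, final_linear = FALSE)
  h <- tf$out
  lat_raw <- sweep(h %*% ec$head_lat$W, 2, ec$head_lat$b, "+")
  emb <- sweep(h %*% ec$head_emb$W, 2, ec$head_emb$b, "+")
  list(lat_raw = lat_raw, emb = emb, trunk = tf, h = h)
}

ep_forward <- function(ep, x) {
  tf <- mlp_forward(ep$trunk, x, final_linear = FALSE)
  raw <- sweep(tf$out %*% ep$head$W, 2, ep$head$b, "+")
  list(raw = raw, trunk = tf)
}

#' Encode an image into the generator's style space
#'
#' Combines the mapping-network base latent for the cell's expression and
#' class with the global-encoder term and the per-layer offset-encoder
#' terms (both tanh-bounded), producing a `style_latent` that the frozen
#' generator decodes.  With zero encoder outputs the latent equals the
#' mapping base exactly.
#'
#' @param image H x W x 2 array (or n x H x W x 2 batch) in `[0, 1]`.
#' @param expr matching expression vector(s); substitute an edited vector
#'   here to manipulate the reconstruction.
#' @param c class label(s).
#' @param inv an `inversion_model` (from [train_inversion()]).
#' @param gan the `gan_model` whose generator is inverted.
#' @return a `style_latent` with `global` and `offsets` set.
#' @export
encode <- function(image, expr, c, inv, gan) {
  if (length(dim(image)) == 3) image <- array(image, c(1, dim(image)))
  assert_that(dim(image)[2] == gan$cfg$image_size &&
              dim(image)[4] == gan$cfg$channels,
              "image shape does not match the generator")
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  assert_that(nrow(expr) == dim(image)[1],
              "image / expression cardinality mismatch")
  x <- images_to_flat(image) * 2 - 1
  base <- mapping_forward(expr, c, gan)
  cfg <- inv$cfg
  ecf <- ec_forward(inv$params$ec, x)
  epf <- ep_forward(inv$params$ep, x)
  S <- inv$params$S; dw <- inv$params$dw
  offs <- lapply(seq_len(S), function(s) {
    tanh(epf$raw[, ((s - 1) * dw + 1):(s * dw), drop = FALSE]) * cfg$offset_scale
  })
  base$global <- tanh(ecf$lat_raw) * cfg$global_scale
  base$offsets <- offs
  base
}

l2_normalize_rows <- function(m) m / pmax(sqrt(rowSums(m^2)), 1e-12)

#' Contrastive (InfoNCE) loss between images and reconstructions
#'
#' Embeds both image sets with the global encoder, L2-normalizes, and
#' treats each (x_i, xhat_i) pair as the positive against the other batch
#' members at temperature `tau`.
#'
#' @param x,xhat image batches (n x H x W x C), n >= 2.
#' @param encoder an `inversion_model`, an `ec` parameter list, or a
#'   function mapping a flattened batch matrix to embeddings.
#' @param tau temperature.
#' @return scalar loss.
#' @export
loss_contrastive <- function(x, xhat, encoder, tau = 0.07) {
  assert_that(dim(x)[1] >= 2, "contrastive loss needs a batch of >= 2 pairs")
  assert_that(identical(dim(x), dim(xhat)), "shapes differ")
  embed <- if (is.function(encoder)) {
    encoder
  } else {
    ec <- if (inherits(encoder, "inversion_model")) encoder$params$ec else encoder
    function(m) ec_forward(ec, m)$emb
  }
  q <- l2_normalize_rows(embed(images_to_flat(xhat) * 2 - 1))
  k <- l2_normalize_rows(embed(images_to_flat(x) * 2 - 1))
  sims <- tcrossprod(q, k) / tau
  mx <- apply(sims, 1, max)
  lse <- mx + log(rowSums(exp(sims - mx)))
  mean(lse - diag(sims))
}

## InfoNCE gradient with respect to the (unnormalized) query embeddings
infonce_query_grad <- function(q_raw, k, tau) {
  q <- l2_normalize_rows(q_raw)
  sims <- tcrossprod(q, k) / tau
  mx <- apply(sims, 1, max)
  p <- exp(sims - mx)
  p <- p / rowSums(p)
  n <- nrow(q)
  dq <- (p %*% k - k) / (tau * n)   # d mean-loss / d q
  ## through the normalization: q = e / ||e||
  nrm <- pmax(sqrt(rowSums(q_raw^2)), 1e-12)
  (dq - rowSums(dq * q) * q) / nrm
}

#' Train the inversion encoders against a frozen generator
#'
#' Optimizes the weighted sum of the contrastive, l2 and perceptual losses
#' over the training cells, with a momentum copy of the global encoder
#' providing the contrastive keys.  PSNR and SSIM on a held-out split are
#' logged at checkpoint cadence; the returned model carries the checkpoint
#' with the best held-out SSIM.
#'
#' @param dataset a `cellcrop_dataset`.
#' @param gan_model trained generator (frozen).
#' @param cfg an [inversion_config()].
#' @param verbose print progress?
#' @return object of class `inversion_model` with `params` (selected),
#'   `params_final`, `cfg`, `trace`, `selected_iter`, `holdout_idx`.
#' @export
train_inversion <- function(dataset, gan_model, cfg, verbose = FALSE) {
  stopifnot(inherits(dataset, "cellcrop_dataset"),
            inherits(gan_model, "gan_model"),
            inherits(cfg, "inversion_config"))
  n <- nrow(dataset$expr)
  params <- inversion_init_params(cfg, gan_model)
  percep <- percep_init(derive_seed(cfg$seed, 47))
  x_all <- images_to_flat(dataset$images) * 2 - 1
  labels <- as.integer(dataset$labels)
  base_all <- mapping_forward(dataset$expr, labels, gan_model)$w
  S <- params$S; dw <- params$dw
  hs <- gan_model$cfg$image_size
  syn <- gan_model$params$syn

  holdout_idx <- with_seed(derive_seed(cfg$seed, 53),
                           sample(n, max(2, round(cfg$holdout * n))))
  train_idx <- setdiff(seq_len(n), holdout_idx)

  opt <- adam_init(list(ec = params$ec, ep = params$ep))
  ec_m <- params$ec
  trace <- list()
  best <- list(ssim = -Inf, params = NULL, iter = NA_integer_)

  reconstruct_batch <- function(prm, idx) {
    x <- x_all[idx, , drop = FALSE]
    ecf <- ec_forward(prm$ec, x)
    epf <- ep_forward(prm$ep, x)
    gl <- tanh(ecf$lat_raw) * cfg$global_scale
    styles <- vector("list", S)
    offs_raw <- vector("list", S)
    for (s in seq_len(S)) {
      raw <- epf$raw[, ((s - 1) * dw + 1):(s * dw), drop = FALSE]
      offs_raw[[s]] <- raw
      styles[[s]] <- base_all[idx, , drop = FALSE] + gl + tanh(raw) * cfg$offset_scale
    }
    sf <- synthesis_forward(syn, styles, noise = NULL)
    list(x = x, ecf = ecf, epf = epf, gl = gl, offs_raw = offs_raw, sf = sf)
  }

  eval_holdout <- function(prm) {
    rb <- reconstruct_batch(prm, holdout_idx)
    xhat <- flat_to_images((rb$sf$out + 1) / 2, hs)
    xtru <- dataset$images[holdout_idx, , , , drop = FALSE]
    ps <- ss <- numeric(length(holdout_idx))
    for (i in seq_along(holdout_idx)) {
      ps[i] <- psnr(xtru[i, , , ], xhat[i, , , ])
      ss[i] <- ssim(xtru[i, , , ], xhat[i, , , ])
    }
    c(psnr = mean(ps[is.finite(ps)]), ssim = mean(ss))
  }

  ## pre-training baseline so improvement over training is measurable
  hv0 <- eval_holdout(params)
  trace[[1]] <- data.frame(iter = 0L, l2 = NA_real_,
                           psnr = hv0["psnr"], ssim = hv0["ssim"])
  with_seed(derive_seed(cfg$seed, 59), {
    for (it in seq_len(cfg$iters)) {
      idx <- sample(train_idx, min(cfg$batch_size, length(train_idx)))
      B <- length(idx)
      rb <- reconstruct_batch(params, idx)
      xhat_flat <- rb$sf$out

      ## ---- pixel + perceptual terms ----
      dxhat <- cfg$lambda2 * 2 * (xhat_flat - rb$x) / length(rb$x)
      if (cfg$lambda3 > 0) {
        ximg <- flat_to_images(rb$x, hs)
        yimg <- flat_to_images(xhat_flat, hs)
        fx <- percep_forward(percep, ximg)
        fy <- percep_forward(percep, yimg)
        dlp <- lpip_backward(percep, fx, fy)
        dxhat <- dxhat + cfg$lambda3 * matrix(dlp, B, ncol(xhat_flat))
      }

      ## ---- contrastive term (query = reconstruction, keys = momentum) ----
      gec <- NULL
      if (cfg$lambda1 > 0 && B >= 2) {
        ecf_q <- ec_forward(params$ec, xhat_flat)
        k <- l2_normalize_rows(ec_forward(ec_m, rb$x)$emb)
        de <- infonce_query_grad(ecf_q$emb, k, cfg$tau) * cfg$lambda1
        dh <- tcrossprod(de, params$ec$head_emb$W)
        gq_emb <- list(W = crossprod(ecf_q$h, de), b = colSums(de))
        tb <- mlp_backward(params$ec$trunk, ecf_q$trunk, dh)
        gec <- list(trunk = tb$grads,
                    head_lat = list(W = matrix(0, nrow(params$ec$head_lat$W),
                                               ncol(params$ec$head_lat$W)),
                                    b = numeric(length(params$ec$head_lat$b))),
                    head_emb = gq_emb)
        dxhat <- dxhat + tb$dx
      }

      ## ---- back through the frozen generator into the encoders ----
      sb <- synthesis_backward(syn, rb$sf, dxhat)
      dgl <- Reduce(`+`, sb$dstyles)
      dlat_raw <- dgl * cfg$global_scale * (1 - tanh(rb$ecf$lat_raw)^2)
      dh_lat <- tcrossprod(dlat_raw, params$ec$head_lat$W)
      tb_lat <- mlp_backward(params$ec$trunk, rb$ecf$trunk, dh_lat)
      gec_syn <- list(trunk = tb_lat$grads,
                      head_lat = list(W = crossprod(rb$ecf$h, dlat_raw),
                                      b = colSums(dlat_raw)),
                      head_emb = list(W = matrix(0, nrow(params$ec$head_emb$W),
                                                 ncol(params$ec$head_emb$W)),
                                      b = numeric(length(params$ec$head_emb$b))))
      gec <- if (is.null(gec)) gec_syn else grads_add(gec, gec_syn)

      draw <- matrix(0, B, S * dw)
      for (s in seq_len(S)) {
        cols <- ((s - 1) * dw + 1):(s * dw)
        draw[, cols] <- sb$dstyles[[s]] * cfg$offset_scale *
          (1 - tanh(rb$offs_raw[[s]])^2)
      }
      gep_head <- list(W = crossprod(rb$epf$trunk$out, draw), b = colSums(draw))
      tb_ep <- mlp_backward(params$ep$trunk, rb$epf$trunk,
                            tcrossprod(draw, params$ep$head$W))
      gep <- list(trunk = tb_ep$grads, head = gep_head)

      st <- adam_step(list(ec = params$ec, ep = params$ep),
                      list(ec = gec, ep = gep), opt,
                      lr = cfg$lr, beta1 = 0.5, beta2 = 0.99)
      params$ec <- st$params$ec; params$ep <- st$params$ep
      opt <- st$state
      ec_m <- momentum_update(ec_m, params$ec, cfg$momentum)

      if (it %% cfg$ckpt_every == 0 || it == cfg$iters) {
        hv <- eval_holdout(params)
        l2v <- mean((xhat_flat - rb$x)^2)
        trace[[length(trace) + 1]] <- data.frame(
          iter = it, l2 = l2v, psnr = hv["psnr"], ssim = hv["ssim"])
        if (hv["ssim"] > best$ssim) {
          best <- list(ssim = hv["ssim"], params = params, iter = it)
        }
        if (verbose) {
          message(sprintf("iter %5d  l2 %.4f  holdout PSNR %.2f  SSIM %.3f",
                          it, l2v, hv["psnr"], hv["ssim"]))
        }
      }
    }
  })
  structure(list(params = best$params %||% params, params_final = params,
                 cfg = cfg, trace = do.call(rbind, trace),
                 selected_iter = best$iter, holdout_idx = holdout_idx),
            class = "inversion_model")
}

momentum_update <- function(target, source, m) {
  walk <- function(t, s) {
    if (is.list(t)) {
      for (k in seq_along(t)) t[[k]] <- walk(t[[k]], s[[k]])
      t
    } else {
      m * t + (1 - m) * s
    }
  }
  walk(target, source)
}

#' @export
print.inversion_model <- function(x, ...) {
  cat(sprintf("inversion_model: selected checkpoint at iter %s (holdout SSIM %.3f)\n",
              x$selected_iter, max(x$trace$ssim)))
  invisible(x)
}

#' Reconstruct (and optionally edit) real cell crops
#'
#' Encodes each original image, substitutes the given expression in the
#' mapping pathway (the original expression gives the plain reconstruction;
#' an edited expression manipulates it), and decodes through the frozen
#' generator with noise disabled, so calls are deterministic.
#'
#' @param images n x H x W x 2 array in `[0, 1]`.
#' @param expr n x p expression matrix (original or edited).
#' @param c class labels.
#' @param inv trained `inversion_model`.
#' @param gan trained `gan_model`.
#' @return n x H x W x 2 array in `[0, 1]` with a `provenance` attribute.
#' @export
reconstruct_edited <- function(images, expr, c, inv, gan) {
  if (length(dim(images)) == 3) images <- array(images, c(1, dim(images)))
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  assert_that(dim(images)[1] == nrow(expr),
              "image / expression cardinality mismatch")
  latent <- encode(images, expr, c, inv, gan)
  out <- (generator_forward(latent, gan, noise_seed = NULL) + 1) / 2
  attr(out, "provenance") <- list(n = nrow(expr),
                                  labels = rep(c, length.out = nrow(expr)),
                                  edited = TRUE)
  out
}
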