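## Expression-conditioned generative adversarial model.  The "text" input
## is the per-cell expression vector: a mapping network turns the
## standardized expression (plus a class embedding for the binary
## normal/tumor label) into a style latent that modulates every layer of a
## dense synthesis network with per-layer noise injection; a projection
## discriminator conditions on the same binary label.  Training minimizes
## the non-saturating adversarial loss plus lazily-applied R1 and
## path-length regularizers.

slog1p <- function(x) sign(x) * log1p(abs(x))

standardize_expr <- function(expr, stats) {
  z <- slog1p(expr)
  sweep(sweep(z, 2, stats$mu), 2, stats$sd, "/")
}

expr_norm_stats <- function(expr) {
  z <- slog1p(expr)
  list(mu = colMeans(z), sd = pmax(apply(z, 2, stats::sd), 1e-6))
}

#' GAN configuration
#'
#' Desk-scale defaults (32x32 images, a few thousand iterations) train in
#' minutes on one CPU; the full-scale profile used for real data
#' (800k iterations, batch 16) is available as `gan_config(profile =
#' "full")` but is not exercised by the test suite.
#'
#' @param p conditioning dimension (panel size).
#' @param image_size output edge length; power of two, >= 16.
#' @param latent_dim style latent width.
#' @param map_width,mapping_depth mapping-network hidden width and depth.
#' @param lambda_r1,lambda_path regularizer weights.
#' @param lambda_mismatch weight of the matching-aware discriminator term
#'   (real images paired with the wrong label are treated as fake), which
#'   accelerates class-conditional learning at desk scale; 0 disables.
#' @param r1_every,path_every lazy-regularization cadences (D / G steps).
#' @param batch_size,iters,ckpt_every training schedule.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param pl_decay path-length running-mean decay.
#' @param seed RNG seed for initialization and training.
#' @param profile `"desk"` or `"full"` (800k iterations, batch 16).
#' @return object of class `gan_config`.
#' @export
gan_config <- function(p, image_size = 32, latent_dim = 64,
                       map_width = 64, mapping_depth = 2,
                       lambda_r1 = 1, lambda_path = 2,
                       lambda_mismatch = 1,
                       r1_every = 16, path_every = 8,
                       batch_size = 16, iters = 1500, ckpt_every = 500,
                       lr = 2e-3, beta1 = 0, beta2 = 0.99,
                       pl_decay = 0.99,
                       seed = 1L, profile = c("desk", "full")) {
  profile <- match.arg(profile)
  assert_that(lambda_r1 >= 0 && lambda_path >= 0, "loss weights must be >= 0")
  assert_that(image_size >= 16 && bitwAnd(image_size, image_size - 1L) == 0,
              "image_size must be a power of two >= 16")
  if (profile == "full") { iters <- 800000L; batch_size <- 16L }
  structure(list(p = as.integer(p), image_size = as.integer(image_size),
                 channels = 2L, latent_dim = as.integer(latent_dim),
                 map_width = map_width, mapping_depth = mapping_depth,
                 lambda_r1 = lambda_r1, lambda_path = lambda_path,
                 lambda_mismatch = lambda_mismatch,
                 r1_every = r1_every, path_every = path_every,
                 batch_size = as.integer(batch_size), iters = as.integer(iters),
                 ckpt_every = as.integer(ckpt_every),
                 lr = lr, beta1 = beta1, beta2 = beta2, pl_decay = pl_decay,
                 seed = as.integer(seed), profile = profile),
            class = "gan_config")
}

syn_widths <- function(image_size) {
  n_layers <- as.integer(log2(image_size)) - 2L
  pmin(64L * 2L^(seq_len(n_layers) - 1L), 256L)
}

n_style_slots <- function(image_size) length(syn_widths(image_size)) + 1L

## ---- parameter initialization ----

gan_init_params <- function(cfg) {
  dw <- cfg$latent_dim
  outdim <- cfg$image_size^2 * cfg$channels
  widths <- syn_widths(cfg$image_size)
  L <- length(widths)
  with_seed(derive_seed(cfg$seed, 31), {
    map <- list(
      cemb = matrix(rnorm(2 * cfg$p, 0, 0.1), 2, cfg$p),
      layers = mlp_init(c(cfg$p, rep(cfg$map_width, cfg$mapping_depth), dw)))
    hidden <- vector("list", L)
    for (l in seq_len(L)) {
      hidden[[l]] <- list(
        W = if (l > 1) nn_linear_init(widths[l - 1], widths[l])$W else NULL,
        A = nn_linear_init(dw, widths[l])$W,
        b = numeric(widths[l]),
        s = 0)
    }
    syn <- list(hidden = hidden,
                out = list(W = nn_linear_init(widths[L], outdim, gain = 0.25)$W,
                           A = nn_linear_init(dw, outdim, gain = 0.1)$W,
                           b = numeric(outdim)))
    disc <- list(
      layers = mlp_init(c(outdim, 128, 64)),
      v = rnorm(64, 0, 0.1), b = 0,
      cemb = matrix(rnorm(2 * 64, 0, 0.1), 2, 64))
    list(map = map, syn = syn, disc = disc)
  })
}

## ---- mapping network ----

mapping_forward_internal <- function(map, z, c) {
  u <- z + map$cemb[c + 1L, , drop = FALSE]
  mf <- mlp_forward(map$layers, u, final_linear = TRUE)
  list(w = mf$out, cache = mf, c = c)
}

mapping_backward <- function(map, cache, c, dw) {
  mb <- mlp_backward(map$layers, cache, dw)
  dcemb <- matrix(0, 2, ncol(mb$dx))
  for (k in 0:1) {
    rows <- which(c == k)
    if (length(rows)) dcemb[k + 1L, ] <- colSums(mb$dx[rows, , drop = FALSE])
  }
  list(layers = mb$grads, cemb = dcemb)
}

#' Map expression vectors to style latents
#'
#' Standardizes expression with the model's stored per-gene statistics
#' (signed log1p, then z-score — robust to the negative values that edited
#' expression may contain), adds the class embedding and runs the mapping
#' network.  Deterministic given the parameters.
#'
#' @param expr n x p matrix (or length-p vector) of raw expression; edited
#'   real-valued vectors are allowed.
#' @param c integer class labels (0/1), length n (recycled if scalar).
#' @param model a `gan_model` (from [train_gan()]) or a bare parameter list
#'   with `params` and `norm_stats`.
#' @return object of class `style_latent` with the per-layer latent `w`
#'   broadcast over `n_slots` synthesis layers.
#' @export
mapping_forward <- function(expr, c, model) {
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  assert_that(ncol(expr) == model$cfg$p, "expression has wrong length")
  c <- as.integer(rep(c, length.out = nrow(expr)))
  z <- standardize_expr(expr, model$norm_stats)
  mf <- mapping_forward_internal(model$params$map, z, c)
  structure(list(w = mf$w, n_slots = n_style_slots(model$cfg$image_size),
                 c = c),
            class = "style_latent")
}

## resolve a style_latent (possibly with offsets) into per-slot matrices
resolve_styles <- function(latent) {
  S <- latent$n_slots
  styles <- vector("list", S)
  for (s in seq_len(S)) {
    w <- latent$w
    if (!is.null(latent$global)) w <- w + latent$global
    if (!is.null(latent$offsets)) w <- w + latent$offsets[[s]]
    styles[[s]] <- w
  }
  styles
}

## ---- synthesis network ----

synthesis_forward <- function(syn, styles, noise = NULL) {
  L <- length(syn$hidden)
  n <- nrow(styles[[1]])
  as <- hs <- eps <- vector("list", L)
  h <- NULL
  for (l in seq_len(L)) {
    lay <- syn$hidden[[l]]
    a <- styles[[l]] %*% lay$A
    if (!is.null(lay$W)) a <- a + h %*% lay$W
    a <- sweep(a, 2, lay$b, "+")
    e <- if (is.null(noise)) matrix(0, n, ncol(a)) else noise[[l]]
    a <- a + lay$s * e
    eps[[l]] <- e
    as[[l]] <- a
    h <- lrelu(a)
    hs[[l]] <- h
  }
  a_out <- h %*% syn$out$W + styles[[L + 1]] %*% syn$out$A
  a_out <- sweep(a_out, 2, syn$out$b, "+")
  out <- tanh(a_out)
  list(out = out, as = as, hs = hs, eps = eps, a_out = a_out,
       tanhd = 1 - out^2, styles = styles)
}

synthesis_backward <- function(syn, cache, dout) {
  L <- length(syn$hidden)
  styles <- cache$styles
  da_out <- dout * cache$tanhd
  grads <- list(hidden = vector("list", L),
                out = list(W = crossprod(cache$hs[[L]], da_out),
                           A = crossprod(styles[[L + 1]], da_out),
                           b = colSums(da_out)))
  dstyles <- vector("list", L + 1)
  dstyles[[L + 1]] <- tcrossprod(da_out, syn$out$A)
  dh <- tcrossprod(da_out, syn$out$W)
  for (l in rev(seq_len(L))) {
    lay <- syn$hidden[[l]]
    da <- dh * lrelu_mask(cache$as[[l]])
    grads$hidden[[l]] <- list(
      W = if (!is.null(lay$W)) crossprod(cache$hs[[l - 1]], da) else NULL,
      A = crossprod(styles[[l]], da),
      b = colSums(da),
      s = sum(da * cache$eps[[l]]))
    dstyles[[l]] <- tcrossprod(da, lay$A)
    if (!is.null(lay$W)) dh <- tcrossprod(da, lay$W)
  }
  list(grads = grads, dstyles = dstyles)
}

#' Generate images from style latents
#'
#' Runs the synthesis network.  Output is in (-1, 1) through the final
#' tanh; per-layer noise is the only stochasticity and is a pure function
#' of `noise_seed`, so calls are bit-reproducible.
#'
#' @param latent a `style_latent` (optionally carrying inversion offsets).
#' @param model a `gan_model`.
#' @param noise_seed integer seed, or `NULL` to disable noise.
#' @return n x H x W x 2 array in (-1, 1).
#' @export
generator_forward <- function(latent, model, noise_seed = 0L) {
  stopifnot(inherits(latent, "style_latent"))
  styles <- resolve_styles(latent)
  n <- nrow(styles[[1]])
  syn <- model$params$syn
  noise <- NULL
  if (!is.null(noise_seed)) {
    widths <- vapply(syn$hidden, function(l) ncol(l$A), numeric(1))
    noise <- with_seed(derive_seed(noise_seed, 37), {
      lapply(widths, function(wd) matrix(rnorm(n * wd), n, wd))
    })
  }
  sf <- synthesis_forward(syn, styles, noise)
  flat_to_images(sf$out, model$cfg$image_size, model$cfg$channels)
}

flat_to_images <- function(flat, size, channels = 2L) {
  array(flat, c(nrow(flat), size, size, channels))
}

images_to_flat <- function(images) {
  d <- dim(images)
  matrix(images, d[1], prod(d[-1]))
}

## ---- discriminator ----

disc_forward <- function(disc, x, c) {
  mf <- mlp_forward(disc$layers, x, final_linear = FALSE)
  h <- mf$out
  u <- sweep(disc$cemb[c + 1L, , drop = FALSE], 2, disc$v, "+")
  logit <- rowSums(h * u) + disc$b
  list(logit = logit, h = h, u = u, cache = mf, c = c)
}

disc_backward <- function(disc, fw, dlogit) {
  dh <- dlogit * fw$u
  dv <- colSums(dlogit * fw$h)
  db <- sum(dlogit)
  dcemb <- matrix(0, 2, length(disc$v))
  for (k in 0:1) {
    rows <- which(fw$c == k)
    if (length(rows)) {
      dcemb[k + 1L, ] <- colSums((dlogit * fw$h)[rows, , drop = FALSE])
    }
  }
  mb <- mlp_backward(disc$layers, fw$cache, dh)
  list(grads = list(layers = mb$grads, v = dv, b = db, cemb = dcemb),
       dx = mb$dx)
}

#' Conditional non-saturating adversarial loss
#'
#' Logistic GAN loss with projection-style class conditioning (the class
#' enters through the discriminator's projection embedding and the
#' generator's mapping input).  `side = "generator"` returns
#' `mean(softplus(-logit_fake))`; `side = "discriminator"` returns
#' `mean(softplus(-logit_real)) + mean(softplus(logit_fake))`.
#'
#' @param logit_real,logit_fake discriminator logits (either may be NULL
#'   depending on `side`).
#' @param side `"generator"` or `"discriminator"`.
#' @return scalar loss.
#' @export
loss_adversarial_conditional <- function(logit_real = NULL, logit_fake = NULL,
                                         side = c("discriminator", "generator")) {
  side <- match.arg(side)
  if (side == "generator") {
    assert_that(!is.null(logit_fake), "generator side needs fake logits")
    return(mean(softplus(-logit_fake)))
  }
  assert_that(!is.null(logit_real) && !is.null(logit_fake),
              "discriminator side needs both logit sets")
  mean(softplus(-logit_real)) + mean(softplus(logit_fake))
}

## gradient of D's logit with respect to its input, per sample
disc_input_grad <- function(disc, fw) {
  L <- length(disc$layers)
  d <- fw$u  # d_L
  da_list <- vector("list", L)
  for (l in rev(seq_len(L))) {
    da <- d * lrelu_mask(fw$cache$as[[l]])
    da_list[[l]] <- da
    d <- tcrossprod(da, disc$layers[[l]]$W)
  }
  list(g = d, da = da_list)
}

#' R1 gradient penalty
#'
#' One half of the batch-mean squared norm of the discriminator's input
#' gradient at real samples.  With `return_grads = TRUE` also returns the
#' exact (a.e.) parameter gradients of the penalty, obtained by
#' double-backprop through the piecewise-linear discriminator.
#'
#' @param disc discriminator parameters (or a `gan_model`, whose
#'   discriminator is used).
#' @param x n x d matrix of real samples (flattened images in (-1, 1)).
#' @param c class labels.
#' @param return_grads also compute parameter gradients?
#' @return list with `value` and optionally `grads`.
#' @export
loss_r1 <- function(disc, x, c, return_grads = FALSE) {
  if (inherits(disc, "gan_model")) disc <- disc$params$disc
  c <- as.integer(rep(c, length.out = nrow(x)))
  fw <- disc_forward(disc, x, c)
  ig <- disc_input_grad(disc, fw)
  B <- nrow(x)
  value <- 0.5 * sum(ig$g^2) / B
  if (!return_grads) return(list(value = value))
  L <- length(disc$layers)
  gbar <- ig$g / B
  grads <- list(layers = vector("list", L), v = numeric(length(disc$v)),
                b = 0, cemb = matrix(0, 2, length(disc$v)))
  cl <- gbar
  for (l in seq_len(L)) {
    dA <- cl %*% disc$layers[[l]]$W
    grads$layers[[l]] <- list(W = crossprod(cl, ig$da[[l]]),
                              b = numeric(length(disc$layers[[l]]$b)))
    cl <- dA * lrelu_mask(fw$cache$as[[l]])
  }
  grads$v <- colSums(cl)
  for (k in 0:1) {
    rows <- which(c == k)
    if (length(rows)) grads$cemb[k + 1L, ] <- colSums(cl[rows, , drop = FALSE])
  }
  list(value = value, grads = grads)
}

#' Path-length regularizer
#'
#' Penalizes the deviation of `||J_w' y||` (the style-Jacobian of the
#' synthesis network contracted with unit-variance image-shaped noise)
#' from a running mean `a`, as in style-based generators.  Parameter
#' gradients are computed by double-backprop with the activation
#' linearization frozen (exact a.e. for the piecewise-linear hidden layers;
#' the curvature of the output tanh is deliberately dropped).
#'
#' @param syn synthesis parameters (or a `gan_model`).
#' @param cache a [synthesis_forward()] cache for the batch.
#' @param a running mean of the path length.
#' @param y optional noise matrix (defaults to fresh standard normals).
#' @param return_grads also compute parameter gradients?
#' @return list with `value`, `norms` (per-sample path lengths), and
#'   optionally `grads` (for hidden `W`/`A` and output `W`/`A`).
#' @export
loss_path <- function(syn, cache, a, y = NULL, return_grads = FALSE) {
  if (inherits(syn, "gan_model")) syn <- syn$params$syn
  L <- length(syn$hidden)
  n <- nrow(cache$out)
  outdim <- ncol(cache$out)
  ## default contraction noise: unit variance per pixel, scaled by
  ## 1/sqrt(outdim) so the path length is a pixel-average rather than a
  ## pixel-sum (the usual convention for this regularizer; keeps its
  ## strength comparable across image sizes)
  if (is.null(y)) y <- matrix(rnorm(n * outdim), n, outdim) / sqrt(outdim)
  Tm <- y * cache$tanhd
  dw_slots <- vector("list", L + 1)
  da_list <- vector("list", L)
  dw_slots[[L + 1]] <- tcrossprod(Tm, syn$out$A)
  dh <- tcrossprod(Tm, syn$out$W)
  for (l in rev(seq_len(L))) {
    da <- dh * lrelu_mask(cache$as[[l]])
    da_list[[l]] <- da
    dw_slots[[l]] <- tcrossprod(da, syn$hidden[[l]]$A)
    if (!is.null(syn$hidden[[l]]$W)) dh <- tcrossprod(da, syn$hidden[[l]]$W)
  }
  g <- Reduce(`+`, dw_slots)
  m <- sqrt(rowSums(g^2))
  value <- mean((m - a)^2)
  res <- list(value = value, norms = m)
  if (!return_grads) return(res)
  Q <- (2 * (m - a) / (n * pmax(m, 1e-8))) * g
  grads <- list(hidden = vector("list", L),
                out = list(W = NULL, A = NULL, b = NULL))
  ## dw_1 = da_1 %*% t(A_1), so dP/d(da_1) = Q %*% A_1
  u <- Q %*% syn$hidden[[1]]$A
  grads$hidden[[1]] <- list(W = NULL, A = crossprod(Q, da_list[[1]]),
                            b = numeric(length(syn$hidden[[1]]$b)), s = 0)
  if (L >= 2) {
    for (l in 2:L) {
      e_prev <- u * lrelu_mask(cache$as[[l - 1]])
      grads$hidden[[l]] <- list(
        W = crossprod(e_prev, da_list[[l]]),
        A = crossprod(Q, da_list[[l]]),
        b = numeric(length(syn$hidden[[l]]$b)), s = 0)
      u <- Q %*% syn$hidden[[l]]$A + e_prev %*% syn$hidden[[l]]$W
    }
  }
  e_top <- u * lrelu_mask(cache$as[[L]])
  grads$out <- list(W = crossprod(e_top, Tm),
                    A = crossprod(Q, Tm),
                    b = numeric(length(syn$out$b)))
  res$grads <- grads
  res
}

## ---- training ----

#' Train the expression-conditioned GAN
#'
#' Alternating discriminator/generator steps with the non-saturating
#' logistic loss, lazy R1 (every `r1_every` D steps) and lazy path-length
#' regularization (every `path_every` G steps), Adam updates, and periodic
#' checkpoints at which the toy-extractor dFID between generated and real
#' images is logged.  The returned model carries the checkpoint with the
#' lowest dFID (model selection) alongside the final parameters.
#'
#' @param dataset a `cellcrop_dataset` with both classes present.
#' @param cfg a [gan_config()].
#' @param verbose print progress?
#' @return object of class `gan_model`: `params` (selected), `params_final`,
#'   `cfg`, `norm_stats`, `trace` (per-checkpoint metrics), `pl_mean`,
#'   `selected_iter`.
#' @export
train_gan <- function(dataset, cfg, verbose = FALSE) {
  stopifnot(inherits(dataset, "cellcrop_dataset"), inherits(cfg, "gan_config"))
  if (length(unique(dataset$labels)) < 2) {
    stop("training requires both classes in the dataset", call. = FALSE)
  }
  assert_that(cfg$p == ncol(dataset$expr), "cfg$p does not match the panel")
  n <- nrow(dataset$expr)
  x_real <- images_to_flat(dataset$images) * 2 - 1
  norm_stats <- expr_norm_stats(dataset$expr)
  z_all <- standardize_expr(dataset$expr, norm_stats)
  labels <- as.integer(dataset$labels)
  params <- gan_init_params(cfg)
  ## output bias starts at the dataset mean image (in pre-tanh units), so
  ## early training only has to learn modulation around the mean cell
  mean_img <- pmin(pmax(colMeans(x_real), -0.99), 0.99)
  ## the 1.5 factor saturates flat background regions (suppressing
  ## weight-induced speckle there) while leaving structures trainable
  params$syn$out$b <- 1.5 * atanh(mean_img)
  opt_d <- adam_init(params$disc)
  opt_g <- adam_init(list(map = params$map, syn = params$syn))
  pl_mean <- NA_real_   # warm-started at the first observed path length
  extractor <- toy_extractor()
  B <- cfg$batch_size
  S <- n_style_slots(cfg$image_size)
  trace <- list()
  best <- list(dfid = Inf, params = NULL, iter = NA_integer_)
  widths <- syn_widths(cfg$image_size)

  gen_batch <- function(idx) {
    z <- z_all[idx, , drop = FALSE]
    c <- labels[idx]
    mf <- mapping_forward_internal(params$map, z, c)
    styles <- rep(list(mf$w), S)
    noise <- lapply(widths, function(wd) matrix(rnorm(length(idx) * wd),
                                                length(idx), wd))
    sf <- synthesis_forward(params$syn, styles, noise)
    list(mf = mf, sf = sf, c = c)
  }

  eval_dfid <- function() {
    m <- min(n, 192L)
    idx <- sample(n, m)
    gb <- gen_batch(idx)
    gen_imgs <- flat_to_images((gb$sf$out + 1) / 2, cfg$image_size)
    dfid(gen_imgs, dataset$images[idx, , , , drop = FALSE],
         extractor = extractor, repeats = 2, subsample = m,
         seed = cfg$seed)$mean
  }

  with_seed(derive_seed(cfg$seed, 41), {
    for (it in seq_len(cfg$iters)) {
      ## ---- discriminator step ----
      idx_r <- sample(n, B)
      idx_f <- sample(n, B)
      gb <- gen_batch(idx_f)
      xr <- x_real[idx_r, , drop = FALSE]
      cr <- labels[idx_r]
      fr <- disc_forward(params$disc, xr, cr)
      ff <- disc_forward(params$disc, gb$sf$out, gb$c)
      dlog_r <- -sigmoid(-fr$logit) / B
      dlog_f <- sigmoid(ff$logit) / B
      gd <- disc_backward(params$disc, fr, dlog_r)$grads
      gd <- grads_add(gd, disc_backward(params$disc, ff, dlog_f)$grads)
      if (cfg$lambda_mismatch > 0) {
        ## matching-aware term: real images with flipped labels are "fake",
        ## forcing the projection embedding to carry the class
        fm <- disc_forward(params$disc, xr, 1L - cr)
        dlog_m <- cfg$lambda_mismatch * sigmoid(fm$logit) / B
        gd <- grads_add(gd, disc_backward(params$disc, fm, dlog_m)$grads)
      }
      if (it %% cfg$r1_every == 0 && cfg$lambda_r1 > 0) {
        r1 <- loss_r1(params$disc, xr, cr, return_grads = TRUE)
        gd <- grads_add(gd, r1$grads, scale = cfg$lambda_r1 * cfg$r1_every)
      }
      st <- adam_step(params$disc, gd, opt_d, lr = cfg$lr,
                      beta1 = cfg$beta1, beta2 = cfg$beta2)
      params$disc <- st$params; opt_d <- st$state

      ## ---- generator step (reusing the fake batch) ----
      fg <- disc_forward(params$disc, gb$sf$out, gb$c)
      dlogit <- -sigmoid(-fg$logit) / B
      dx <- disc_backward(params$disc, fg, dlogit)$dx
      sb <- synthesis_backward(params$syn, gb$sf, dx)
      dwm <- Reduce(`+`, sb$dstyles)
      gm <- mapping_backward(params$map, gb$mf$cache, gb$c, dwm)
      gg <- list(map = gm, syn = sb$grads)
      if (it %% cfg$path_every == 0 && cfg$lambda_path > 0) {
        if (is.na(pl_mean)) {
          ## warm start: measuring the initial path length instead of
          ## penalizing toward zero keeps the style pathway alive
          pl_mean <- mean(loss_path(params$syn, gb$sf, 0)$norms)
        } else {
          pl <- loss_path(params$syn, gb$sf, pl_mean, return_grads = TRUE)
          gg$syn <- grads_add(gg$syn, pl$grads,
                              scale = cfg$lambda_path * cfg$path_every)
          pl_mean <- pl_mean + (1 - cfg$pl_decay) * (mean(pl$norms) - pl_mean)
        }
      }
      st <- adam_step(list(map = params$map, syn = params$syn), gg, opt_g,
                      lr = cfg$lr, beta1 = cfg$beta1, beta2 = cfg$beta2)
      params$map <- st$params$map; params$syn <- st$params$syn
      opt_g <- st$state

      if (it %% cfg$ckpt_every == 0 || it == cfg$iters) {
        d <- eval_dfid()
        ld <- loss_adversarial_conditional(fr$logit, ff$logit)
        lg <- loss_adversarial_conditional(logit_fake = fg$logit,
                                           side = "generator")
        trace[[length(trace) + 1]] <- data.frame(
          iter = it, loss_d = ld, loss_g = lg, dfid = d)
        if (d < best$dfid) {
          best <- list(dfid = d, params = params, iter = it)
        }
        if (verbose) {
          message(sprintf("iter %6d  lossD %.3f  lossG %.3f  dFID %.2f",
                          it, ld, lg, d))
        }
      }
    }
  })
  structure(list(params = best$params %||% params, params_final = params,
                 cfg = cfg, norm_stats = norm_stats,
                 trace = do.call(rbind, trace), pl_mean = pl_mean,
                 selected_iter = best$iter),
            class = "gan_model")
}

#' @export
print.gan_model <- function(x, ...) {
  cat(sprintf("gan_model: p = %d, %dx%d images, selected checkpoint at iter %s (dFID %.2f)\n",
              x$cfg$p, x$cfg$image_size, x$cfg$image_size,
              x$selected_iter, min(x$trace$dfid)))
  invisible(x)
}

#' Generate images for (possibly edited) expression vectors
#'
#' One image per expression row, conditioned on the given class labels;
#' rows edited toward another population are conventionally generated with
#' the target population's label.  Deterministic given `noise_seed`.
#'
#' @param expr n x p matrix (raw or edited, real-valued allowed).
#' @param labels class labels (0/1), length n or scalar.
#' @param model a trained `gan_model`.
#' @param noise_seed integer noise seed.
#' @return n x H x W x 2 array in `[0, 1]`, with a `provenance` attribute
#'   linking images to their expression rows.
#' @export
generate_edited <- function(expr, labels, model, noise_seed = 0L) {
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  if (nrow(expr) == 0) {
    return(array(0, c(0, model$cfg$image_size, model$cfg$image_size, 2)))
  }
  latent <- mapping_forward(expr, labels, model)
  img <- generator_forward(latent, model, noise_seed = noise_seed)
  out <- (img + 1) / 2
  attr(out, "provenance") <- list(n = nrow(expr),
                                  labels = rep(labels, length.out = nrow(expr)),
                                  noise_seed = noise_seed)
  out
}

#' Save / load a model checkpoint
#'
#' Single-file RDS container with a version tag; works for `gan_model` and
#' `inversion_model` objects.
#'
#' @param model model object.
#' @param path destination file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(container_version = "stimedit-ckpt-1", model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return the stored model.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  assert_that(identical(obj$container_version, "stimedit-ckpt-1"),
              "not a recognized checkpoint container")
  obj$model
}
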