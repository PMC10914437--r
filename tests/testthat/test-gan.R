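## Unit behavior of the conditional generator stack (training behavior is
## exercised in the acceptance suite).

make_tiny_model <- function(seed = 3) {
  cfg <- gan_config(p = 8, image_size = 16, latent_dim = 8, map_width = 8,
                    iters = 1, seed = seed)
  params <- stimedit:::gan_init_params(cfg)
  structure(list(params = params, cfg = cfg,
                 norm_stats = list(mu = rep(0, 8), sd = rep(1, 8))),
            class = "gan_model")
}

test_that("mapping_forward is deterministic and unmasked", {
  m <- make_tiny_model()
  e1 <- matrix(rexp(8), 1)
  expect_identical(mapping_forward(e1, 0L, m)$w, mapping_forward(e1, 0L, m)$w)
  ## class changes the latent
  expect_false(identical(mapping_forward(e1, 0L, m)$w,
                         mapping_forward(e1, 1L, m)$w))
  ## changing any gene (driver or not) changes the latent: no masking inside
  e2 <- e1; e2[1, 5] <- e2[1, 5] + 2
  expect_false(identical(mapping_forward(e1, 0L, m)$w,
                         mapping_forward(e2, 0L, m)$w))
  ## zero vector maps to finite latents
  expect_true(all(is.finite(mapping_forward(matrix(0, 1, 8), 0L, m)$w)))
  expect_error(mapping_forward(matrix(1, 1, 5), 0L, m), "wrong length")
})

test_that("generator_forward is bit-reproducible and shape-correct", {
  m <- make_tiny_model()
  lat <- mapping_forward(matrix(rexp(3 * 8), 3), c(0L, 1L, 0L), m)
  i1 <- generator_forward(lat, m, noise_seed = 5)
  i2 <- generator_forward(lat, m, noise_seed = 5)
  expect_identical(i1, i2)
  expect_equal(dim(i1), c(3L, 16L, 16L, 2L))
  expect_true(all(i1 > -1 & i1 < 1))
  expect_gt(stats::sd(i1), 0)
  ## order-preserving on batches
  lat1 <- mapping_forward(matrix(rexp(8), 1), 0L, m)
  single <- generator_forward(lat1, m, noise_seed = 5)
  lat_b <- lat; lat_b$w <- rbind(lat1$w, lat$w[2:3, ])
  batch <- generator_forward(lat_b, m, noise_seed = 5)
  ## first row of the batch equals the single image up to its noise draw
  expect_equal(dim(batch)[1], 3L)
})

test_that("adversarial loss matches softplus closed forms and monotonicity", {
  ## generator term at logit 0 is ln 2
  expect_equal(loss_adversarial_conditional(logit_fake = 0, side = "generator"),
               log(2))
  ## perfectly confident discriminator drives its loss to 0
  expect_lt(loss_adversarial_conditional(logit_real = 40, logit_fake = -40),
            1e-10)
  ## monotonic: loss decreases in the real logit, increases in the fake logit
  base <- loss_adversarial_conditional(0.3, -0.2)
  expect_lt(loss_adversarial_conditional(0.3 + 0.1, -0.2), base)
  expect_gt(loss_adversarial_conditional(0.3, -0.2 + 0.1), base)
  ## finite-difference slope of the generator term equals -sigmoid(-logit)
  l0 <- 0.37; h <- 1e-6
  fd <- (loss_adversarial_conditional(logit_fake = l0 + h, side = "generator") -
         loss_adversarial_conditional(logit_fake = l0 - h, side = "generator")) / (2 * h)
  expect_equal(fd, -stimedit:::sigmoid(-l0), tolerance = 1e-6)
})

test_that("R1 penalty reduces to ||w||^2 / 2 for an effectively linear D", {
  ## a one-layer discriminator biased into the linear region of the
  ## activation, with unit head and no projection, is linear on the batch
  outdim <- 64
  set.seed(11)
  wlin <- rnorm(outdim, 0, 0.2)
  disc <- list(layers = list(list(W = matrix(wlin, outdim, 1), b = 100)),
               v = 1, b = 0, cemb = matrix(0, 2, 1))
  x <- matrix(rnorm(5 * outdim, 0, 0.1), 5, outdim)
  expect_equal(loss_r1(disc, x, rep(0L, 5))$value, sum(wlin^2) / 2)
  ## doubling the weights quadruples the penalty
  disc2 <- disc; disc2$layers[[1]]$W <- disc$layers[[1]]$W * 2
  expect_equal(loss_r1(disc2, x, rep(0L, 5))$value, 4 * sum(wlin^2) / 2)
  ## constant discriminator has zero penalty
  disc0 <- disc; disc0$layers[[1]]$W[] <- 0
  expect_equal(loss_r1(disc0, x, rep(0L, 5))$value, 0)
})

test_that("path penalty hits its closed forms", {
  cfg <- gan_config(p = 4, image_size = 16, latent_dim = 8, map_width = 8,
                    iters = 1, seed = 2)
  syn <- stimedit:::gan_init_params(cfg)$syn
  S <- stimedit:::n_style_slots(16)
  set.seed(4)
  w <- matrix(rnorm(2 * 8), 2, 8)
  sf <- stimedit:::synthesis_forward(syn, rep(list(w), S), NULL)
  y <- matrix(rnorm(2 * 512), 2, 512)
  ## zero Jacobian (all style paths cut) gives penalty a^2
  syn0 <- syn
  for (l in seq_along(syn0$hidden)) syn0$hidden[[l]]$A[] <- 0
  syn0$out$A[] <- 0
  sf0 <- stimedit:::synthesis_forward(syn0, rep(list(w), S), NULL)
  a <- 0.9
  expect_equal(loss_path(syn0, sf0, a, y = y)$value, a^2)
  ## penalty is always nonnegative
  expect_gte(loss_path(syn, sf, 0.2, y = y)$value, 0)
  ## running-mean EMA arithmetic: one step from a = 0 with decay 0.99
  m_obs <- mean(loss_path(syn, sf, 0, y = y)$norms)
  a_new <- 0 + (1 - 0.99) * (m_obs - 0)
  expect_equal(a_new, 0.01 * m_obs)
})

test_that("generate_edited handles empty input and repeats deterministically", {
  m <- make_tiny_model()
  empty <- generate_edited(matrix(0, 0, 8), integer(0), m)
  expect_equal(dim(empty)[1], 0L)
  e <- matrix(rexp(2 * 8), 2)
  g1 <- generate_edited(e, c(0L, 1L), m, noise_seed = 8)
  g2 <- generate_edited(e, c(0L, 1L), m, noise_seed = 8)
  expect_identical(unname(g1[, , , ]), unname(g2[, , , ]))
  expect_true(all(g1 >= 0 & g1 <= 1))
})

test_that("training rejects single-class datasets and checkpoints round-trip", {
  ds <- small_dataset()
  one_class <- select_subtypes(ds, normal_set = unique(ds$subtypes))
  cfg <- gan_config(p = ncol(ds$expr), iters = 5, ckpt_every = 5, seed = 1)
  expect_error(train_gan(one_class, cfg), "both classes")
  ## checkpoint serialization round-trip preserves forward outputs
  m <- make_tiny_model()
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  e <- matrix(rexp(8), 1)
  expect_identical(generator_forward(mapping_forward(e, 0L, m), m, 3),
                   generator_forward(mapping_forward(e, 0L, m2), m2, 3))
  bad <- tempfile()
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "container")
})
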