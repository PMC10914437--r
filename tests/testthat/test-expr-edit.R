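test_that("compute_scm matches hand-computed cases", {
  G <- matrix(c(1, 0, 0, 2), 2, byrow = TRUE)
  expect_equal(compute_scm(G), diag(c(0.5, 2)))
  r <- c(3, 1, 2)
  expect_equal(compute_scm(matrix(r, 1)), outer(r, r))
  set.seed(4)
  Gr <- matrix(rnorm(30), 10, 3)
  expect_equal(compute_scm(Gr), compute_scm(Gr[sample(10), ]))
  expect_error(compute_scm(Gr[0, , drop = FALSE]), "at least one row")
})

test_that("eigendecompose sorts, fixes signs, and reconstructs", {
  d <- eigendecompose(diag(c(0.5, 2)))
  expect_equal(d$lam, c(2, 0.5))
  expect_equal(abs(d$O), diag(2)[, 2:1])
  expect_true(all(apply(d$O, 2, function(v) v[which.max(abs(v))] > 0)))

  ## degenerate spectrum: deterministic across calls
  d1 <- eigendecompose(diag(4))
  d2 <- eigendecompose(diag(4))
  expect_identical(d1$O, d2$O)
  expect_equal(d1$lam, rep(1, 4))

  ## reconstruction property on random PSD matrices
  for (s in 1:4) {
    m <- random_psd(8, seed = s)
    d <- eigendecompose(m)
    expect_lt(max(abs(crossprod(d$O) - diag(8))), 1e-10)
    expect_lt(rel_frobenius(d$O %*% (d$lam * t(d$O)), m), 1e-8)
    expect_true(all(diff(d$lam) <= 1e-12))
  }
  expect_error(eigendecompose(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  expect_error(eigendecompose(matrix(c(1, 2, 2, 1), 2)), "negative eigenvalue")
})

test_that("the worked 2x2 transform matches the brute-force oracle", {
  G0 <- matrix(c(1, 0, 0, 2), 2, byrow = TRUE)
  G1 <- matrix(c(3, 0, 0, 1), 2, byrow = TRUE)
  d0 <- eigendecompose(compute_scm(G0), n = 2)
  d1 <- eigendecompose(compute_scm(G1), n = 2)
  Gp <- match_transform(G0, d0, d1, "full")
  expect_equal(Gp, matrix(c(0, 1, 3, 0), 2, byrow = TRUE), tolerance = 1e-12)
  expect_equal(compute_scm(Gp), diag(c(4.5, 0.5)), tolerance = 1e-12)
  ## brute-force oracle: multiply the factors explicitly
  s <- sqrt(d1$lam / d0$lam)
  oracle <- G0 %*% d0$O %*% diag(s) %*% t(d1$O)
  expect_equal(Gp, oracle)
  expect_equal(crossprod(oracle) / 2, compute_scm(G1))
})

test_that("full-mode matching reproduces the target second moment exactly", {
  set.seed(21)
  for (rep in 1:3) {
    Gi <- matrix(rexp(300 * 20), 300)
    Gj <- matrix(rexp(300 * 20) * runif(1, 0.5, 3), 300)
    di <- eigendecompose(compute_scm(Gi))
    dj <- eigendecompose(compute_scm(Gj))
    Gp <- match_transform(Gi, di, dj, "full")
    expect_lt(rel_frobenius(compute_scm(Gp), compute_scm(Gj)), 1e-10)
  }
})

test_that("self-edit is the bit-exact identity", {
  set.seed(5)
  G <- matrix(rexp(50 * 6), 50)
  d <- eigendecompose(compute_scm(G))
  expect_identical(match_transform(G, d, d, "full"), G)
})

test_that("match_transform is a fixed linear map (batch concatenation)", {
  set.seed(31)
  Ga <- matrix(rexp(40 * 6), 40)
  Gb <- matrix(rexp(30 * 6), 30)
  Gj <- matrix(rexp(100 * 6) * 2, 100)
  di <- eigendecompose(compute_scm(rbind(Ga, Gb)))
  dj <- eigendecompose(compute_scm(Gj))
  whole <- match_transform(rbind(Ga, Gb), di, dj, "full")
  parts <- rbind(match_transform(Ga, di, dj, "full"),
                 match_transform(Gb, di, dj, "full"))
  expect_equal(whole, parts, tolerance = 1e-12)
})

test_that("leading mode rescales only the top eigenvalue on coincident bases", {
  p <- 10
  O <- eigendecompose(random_psd(p, seed = 8))$O
  lam_i <- sort(c(9, runif(p - 1, 0.5, 4)), decreasing = TRUE)
  lam_j <- sort(c(25, runif(p - 1, 0.5, 4)), decreasing = TRUE)
  Si <- O %*% (lam_i * t(O))
  Sj <- O %*% (lam_j * t(O))
  ## construct G_i with SCM exactly Si (n = p rows)
  Gi <- sqrt(p) * (sqrt(lam_i) * t(O))
  di <- eigendecompose(Si, n = p)
  dj <- eigendecompose(Sj, n = p)
  Gp <- match_transform(Gi, di, dj, "leading")
  Sp <- compute_scm(Gp)
  dp <- eigendecompose(Sp)
  expect_lt(abs(dp$lam[1] - dj$lam[1]) / dj$lam[1], 1e-6)
  ## trailing spectrum unchanged
  expect_equal(dp$lam[-1], di$lam[-1], tolerance = 1e-8)
  ## Frobenius perturbation is exactly the leading-eigenvalue change
  expect_equal(sqrt(sum((Sp - Si)^2)), abs(dj$lam[1] - di$lam[1]),
               tolerance = 1e-8)
})

test_that("zero-eigenvalue directions follow the pseudo-inverse rule", {
  set.seed(13)
  ## rank-deficient source: 2 identical columns
  base <- matrix(rexp(100 * 3), 100)
  Gi <- cbind(base, base[, 3])
  Gj <- matrix(rexp(100 * 4), 100)
  di <- eigendecompose(compute_scm(Gi))
  dj <- eigendecompose(compute_scm(Gj))
  expect_equal(di$lam[4], 0, tolerance = 1e-10)
  Gp <- match_transform(Gi, di, dj, "full")
  expect_true(all(is.finite(Gp)))
  ## all-zero population is rejected
  dz <- eigendecompose(matrix(0, 4, 4))
  expect_error(match_transform(matrix(0, 5, 4), dz, dj), "all-zero")
})

test_that("restrict_edit freezes the complement of the edited genes", {
  set.seed(17)
  G <- matrix(rexp(20 * 6), 20)
  Gp <- G + matrix(rnorm(120), 20)
  expect_identical(restrict_edit(G, Gp, NULL), Gp)
  expect_identical(restrict_edit(G, Gp, seq_len(6)), Gp)
  expect_identical(restrict_edit(G, Gp, integer(0)), G)
  r <- restrict_edit(G, Gp, c(2L, 5L))
  expect_identical(r[, c(2, 5)], Gp[, c(2, 5)])
  expect_identical(r[, c(1, 3, 4, 6)], G[, c(1, 3, 4, 6)])
})

test_that("edit_population shifts driver expression toward the target", {
  ds <- big_dataset()
  ed <- edit_population(ds, edit_spec("full", source = 1, target = 0))
  expect_lt(ed$provenance$scm_residual, 1e-10)
  drv <- ds$cfg$driver_genes
  src <- ds$labels == 1
  tgt <- ds$labels == 0
  for (g in drv) {
    m_src <- mean(ds$expr[src, g])
    m_tgt <- mean(ds$expr[tgt, g])
    m_ed <- mean(ed$expr_edited[, g])
    expect_lt(abs(m_ed - m_tgt), abs(m_src - m_tgt))
  }
  ## the shift is highly significant on the driver genes
  shift <- expression_shift_test(ds$expr[src, drv, drop = FALSE],
                                 ed$expr_edited[, drv, drop = FALSE])
  expect_true(all(shift$p <= 1e-4))
  ## both directions match their targets by construction
  ed2 <- edit_population(ds, edit_spec("full", source = 0, target = 1))
  expect_lt(ed2$provenance$scm_residual, 1e-10)
  ## leading mode: top eigenvalue of the edited SCM matches the target
  edl <- edit_population(ds, edit_spec("leading", source = 1, target = 0))
  lam_t <- eigendecompose(compute_scm(ds$expr[tgt, , drop = FALSE]))$lam[1]
  lam_e <- eigendecompose(compute_scm(edl$expr_edited))$lam[1]
  expect_lt(abs(lam_e - lam_t) / lam_t, 1e-6)
  ## gene-restricted edit freezes non-driver columns bit-exactly
  edr <- edit_population(ds, edit_spec("full", edit_genes = drv,
                                       source = 1, target = 0))
  expect_identical(edr$expr_edited[, -drv], ds$expr[ds$labels == 1, -drv])
})
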