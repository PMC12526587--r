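# Independent scalar re-implementations used as oracles.
brute_ce <- function(probs, y) {
  tot <- 0
  for (i in seq_len(nrow(probs))) tot <- tot - log(probs[i, y[i] + 1])
  tot / nrow(probs)
}

brute_mc <- function(F, y, mode = "literal") {
  B <- nrow(F)
  tot <- 0
  for (u in 1:B) for (v in 1:B) if (u != v)
    tot <- tot + sum((F[u, ] - F[v, ])^2)
  Tm <- if (mode == "literal") tot / B else tot / (B * (B - 1))
  num <- 0; den <- 0
  for (u in 1:B) for (v in 1:B) if (u != v) {
    e <- exp(-sum((F[u, ] - F[v, ])^2) / Tm)
    if (y[u] != y[v]) num <- num + e else den <- den + e
  }
  list(L = log(num / den), Tm = Tm)
}

test_that("multilinear map is the flattened per-row outer product", {
  f <- matrix(0, 1, 4); f[1, 2] <- 1
  g <- matrix(c(1, 0), 1, 2)
  phi <- multilinear_map(f, g)
  expect_equal(ncol(phi), 8L)
  expect_equal(which(phi[1, ] == 1), 2L)   # flat index of (a=2, b=1)
  expect_equal(sum(phi != 0), 1L)

  set.seed(17)
  f <- matrix(rnorm(5 * 7), 5, 7)
  g <- t(apply(matrix(runif(15), 5, 3), 1, function(r) r / sum(r)))
  phi <- multilinear_map(f, g)
  for (i in 1:5) {
    expect_equal(phi[i, ], as.vector(outer(f[i, ], g[i, ])), tolerance = 1e-12)
    expect_equal(sqrt(sum(phi[i, ]^2)),
                 sqrt(sum(f[i, ]^2)) * sqrt(sum(g[i, ]^2)), tolerance = 1e-12)
  }
  gu <- matrix(0.5, 5, 2)
  phiu <- multilinear_map(f, gu)
  expect_equal(phiu[, 1:7], 0.5 * f, ignore_attr = TRUE)
  expect_equal(phiu[, 8:14], 0.5 * f, ignore_attr = TRUE)
})

test_that("adversarial loss matches hand-computed discriminator outputs", {
  # zeroed discriminator outputs exactly 0.5 everywhere
  b <- tiny_bundle(seed = 2)
  D0 <- b$D
  D0$params <- cd$zero_like(D0$params)
  set.seed(18)
  fs <- matrix(rnorm(3 * 6), 3, 6)
  ps <- t(apply(matrix(runif(6), 3, 2), 1, function(r) r / sum(r)))
  ft <- matrix(rnorm(2 * 6), 2, 6)
  pt <- t(apply(matrix(runif(4), 2, 2), 1, function(r) r / sum(r)))
  expect_equal(adversarial_loss(D0, fs, ps, ft, pt), 2 * log(2),
               tolerance = 1e-10)

  # single-unit discriminator engineered to output 0.2 / 0.7
  phi_s <- multilinear_map(fs[1, , drop = FALSE], ps[1, , drop = FALSE])
  phi_t <- multilinear_map(ft[1, , drop = FALSE], pt[1, , drop = FALSE])
  s1 <- sum(phi_s); s2 <- sum(phi_t)
  a <- (stats::qlogis(0.2) - stats::qlogis(0.7)) / (s1 - s2)
  bb <- stats::qlogis(0.2) - a * s1
  D1 <- build_discriminator(12L, hidden = 1L, dropout = 0)
  D1$params$W1 <- matrix(1, 12, 1); D1$params$b1 <- 1e3   # pass-through sum
  D1$params$W2 <- matrix(1, 1, 1); D1$params$b2 <- 0
  D1$params$W3 <- matrix(a, 1, 1); D1$params$b3 <- bb - a * 1e3
  out <- D_forward(D1, rbind(phi_s, phi_t))$out
  expect_equal(out, c(0.2, 0.7), tolerance = 1e-8)
  expect_equal(adversarial_loss(D1, fs[1, , drop = FALSE],
                                ps[1, , drop = FALSE],
                                ft[1, , drop = FALSE],
                                pt[1, , drop = FALSE]),
               -log(0.8) - log(0.7), tolerance = 1e-6)

  # fully fooled discriminator (in the G-optimal direction) drives L to 0+
  eps <- 1e-4
  a2 <- (stats::qlogis(eps) - stats::qlogis(1 - eps)) / (s1 - s2)
  b2 <- stats::qlogis(eps) - a2 * s1
  D2 <- D1
  D2$params$W3 <- matrix(a2, 1, 1); D2$params$b3 <- b2 - a2 * 1e3
  L <- adversarial_loss(D2, fs[1, , drop = FALSE], ps[1, , drop = FALSE],
                        ft[1, , drop = FALSE], pt[1, , drop = FALSE])
  expect_gt(L, 0)
  expect_lt(L, 3 * eps)
})

test_that("cross-entropy losses match their closed forms and scalar oracle", {
  p_perfect <- rbind(c(1, 0), c(0, 1))
  expect_lt(cd$cross_entropy(p_perfect, c(0L, 1L)), 1e-6)
  p_unif <- matrix(0.5, 4, 2)
  expect_equal(cd$cross_entropy(p_unif, c(0L, 1L, 0L, 1L)), log(2),
               tolerance = 1e-12)
  p3 <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.55, 0.45))
  y3 <- c(0L, 1L, 1L)
  expect_equal(cd$cross_entropy(p3, y3), brute_ce(p3, y3), tolerance = 1e-12)
  expect_error(cd$cross_entropy(p3, c(0L, 1L, 2L)), "out of range")

  # through the networks: classification_loss == oracle on C(G(x))
  b <- tiny_bundle(seed = 4)
  ds <- tiny_dataset(n = 6, seed = 5)
  probs <- predict(b, ds)$probs
  expect_equal(classification_loss(b$C, b$G, ds), brute_ce(probs, ds$y),
               tolerance = 1e-10)
  empty <- list(X = ds$X[0, , drop = FALSE])
  skipped <- pseudo_ce_loss(b$C, b$G, empty, integer(0))
  expect_equal(as.numeric(skipped), 0)
  expect_true(attr(skipped, "skipped"))
})

test_that("MC loss matches brute force, closed forms, and behaves", {
  set.seed(19)
  F4 <- matrix(c(0, 0, 1, 0, 0, 1, 2, 2), 4, 2, byrow = TRUE)
  y4 <- c(0L, 0L, 1L, 1L)
  got <- mc_loss(F4, y4)
  want <- brute_mc(F4, y4)
  expect_equal(got$L_MC, want$L, tolerance = 1e-10)
  expect_equal(got$T_m, want$Tm, tolerance = 1e-10)

  # equidistant configuration: regular tetrahedron, two points per class
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  eq <- mc_loss(tet, c(0L, 0L, 1L, 1L))
  expect_equal(eq$L_MC, log(8 / 4), tolerance = 1e-10)

  # strictly decreasing as two Gaussian classes separate (x1, x2, x4, x8)
  base <- matrix(rnorm(16 * 5, sd = 0.3), 16, 5)
  yb <- rep(0:1, each = 8)
  vals <- vapply(c(1, 2, 4, 8), function(s) {
    Fb <- base
    Fb[yb == 1, 1] <- Fb[yb == 1, 1] + s
    mc_loss(Fb, yb)$L_MC
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  # invariances: translation, rotation, global scaling, label permutation
  Fb <- base; Fb[yb == 1, 1] <- Fb[yb == 1, 1] + 2
  ref <- mc_loss(Fb, yb)$L_MC
  expect_equal(mc_loss(Fb + 3.7, yb)$L_MC, ref, tolerance = 1e-10)
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  expect_equal(mc_loss(Fb %*% Q, yb)$L_MC, ref, tolerance = 1e-10)
  expect_equal(mc_loss(Fb * 13.7, yb)$L_MC, ref, tolerance = 1e-8)
  expect_equal(mc_loss(Fb, 1L - yb)$L_MC, ref, tolerance = 1e-12)

  # degenerate batches skip the term
  one_class <- mc_loss(matrix(rnorm(8), 4, 2), rep(0L, 4))
  expect_true(one_class$skipped)
  expect_equal(one_class$L_MC, 0)

  # pairmean mode only rescales T_m, leaving the loss unchanged
  lit <- mc_loss(Fb, yb, "literal")
  pm <- mc_loss(Fb, yb, "pairmean")
  expect_equal(pm$T_m * (16 - 1), lit$T_m, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(pm$L_MC, lit$L_MC)))
})

test_that("combined objective is the documented scalar", {
  losses <- list(L_adv = 1.0, L_MC = 0.2, L_cls = 0.3, L_CE = 0.1)
  expect_equal(combined_objective(losses, 0.5),
               0.5 * (1.0 - 0.2) - 0.3 - 0.1)
  expect_equal(combined_objective(losses, 0.5), 0, tolerance = 1e-12)
  expect_equal(combined_objective(list(L_adv = 0, L_MC = 0, L_cls = 0,
                                       L_CE = 0), 1), 0)
  expect_equal(combined_objective(losses, 0), -0.4)
  expect_error(combined_objective(losses, -1), "lambda")
  rep <- loss_report(L_cls = 0.3, L_CE = 0.1, L_adv = 1, L_MC = 0.2,
                     T_m = 2, lambda = 0.5, B_m = 8L)
  expect_equal(rep$combined, 0)
})
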