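test_that("feature extractor obeys its shape/finiteness/determinism contract", {
  b <- tiny_bundle(seed = 3)
  X0 <- matrix(0, 5, 40)
  f <- G_forward(b$G, X0)$features
  expect_equal(dim(f), c(5L, 6L))
  expect_true(all(is.finite(f)))

  # per-sample independence: permuting the batch permutes the outputs
  set.seed(8)
  X <- matrix(runif(6 * 40), 6, 40)
  f1 <- G_forward(b$G, X)$features
  perm <- c(4, 1, 6, 2, 5, 3)
  f2 <- G_forward(b$G, X[perm, ])$features
  expect_equal(f2, f1[perm, ], tolerance = 1e-12)

  # identical seeds give identical networks and outputs
  b2 <- tiny_bundle(seed = 3)
  expect_identical(G_forward(b2$G, X)$features, f1)
  b3 <- tiny_bundle(seed = 4)
  expect_false(identical(G_forward(b3$G, X)$features, f1))
})

test_that("classifier and discriminator have the contracted geometry", {
  b <- tiny_bundle(seed = 1, n_classes = 2L)
  expect_equal(b$D$input_dim, 6L * 2L)
  expect_equal(nrow(b$D$params$W1), 12L)

  set.seed(2)
  f <- matrix(rnorm(400 * 6), 400, 6)
  probs <- C_forward(b$C, f)$probs
  expect_equal(rowSums(probs), rep(1, 400), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  # fresh init is symmetric: mean probabilities near uniform over a big batch
  expect_equal(unname(colMeans(probs)), c(0.5, 0.5), tolerance = 0.1)

  out <- D_forward(b$D, multilinear_map(f, probs))$out
  expect_true(all(out > 0 & out < 1))
})

test_that("xavier re-initialization is deterministic with the right scale", {
  cfg <- net_config(320L)   # default-size layers for a stable variance check
  b <- model_bundle(320L, 2L, config = cfg, seed = 9)
  b1 <- xavier_init(b, seed = 42)
  b2 <- xavier_init(b, seed = 42)
  expect_identical(flatten_params(b1$G$params), flatten_params(b2$G$params))
  expect_identical(flatten_params(b1$D$params), flatten_params(b2$D$params))

  # variance ~ 2/(fan_in + fan_out) within 10% on large layers
  W <- b1$G$params$fusion$W
  expect_equal(var(as.vector(W)), 2 / (nrow(W) + ncol(W)), tolerance = 0.1)
  Wd <- b1$D$params$W1
  expect_equal(var(as.vector(Wd)), 2 / (nrow(Wd) + ncol(Wd)), tolerance = 0.1)

  # biases exactly zero, LayerNorm gains exactly one
  expect_identical(b1$G$params$patch$b, numeric(cfg$d_model))
  expect_identical(b1$C$params$b, numeric(2))
  expect_identical(b1$G$params$fusion$g, rep(1, cfg$feature_dim))
})

test_that("all three components receive gradient from the combined objective", {
  b <- tiny_bundle(seed = 5, dropout = 0)
  set.seed(6)
  Xs <- matrix(runif(8 * 40), 8, 40); ys <- rep(0:1, 4)
  Xt <- matrix(runif(8 * 40), 8, 40)

  fs <- G_forward(b$G, Xs, keep_cache = TRUE)
  cs <- C_forward(b$C, fs$features)
  ft <- G_forward(b$G, Xt, keep_cache = TRUE)
  ct <- C_forward(b$C, ft$features)
  adv <- cd$adversarial_forward(b$D, fs$features, cs$probs, ft$features,
                                ct$probs)
  ag <- cd$adversarial_grads(b$D, adv)
  mc <- cd$mc_loss_internal(fs$features, ys)
  dlog <- cd$ce_dlogits(cs$probs, ys)
  cb <- C_backward(b$C, fs$features, dlog)
  dF_s <- cb$dF + mc$dF - ag$dfs
  gG <- G_backward(b$G, fs$cache, dF_s)

  leaf_nonzero <- function(g) {
    ok <- TRUE
    rec <- function(x) {
      if (is.list(x)) lapply(x, rec)
      else if (all(x == 0)) ok <<- FALSE
    }
    rec(g)
    ok
  }
  expect_true(leaf_nonzero(gG))
  expect_true(leaf_nonzero(cb$grads))
  expect_true(leaf_nonzero(ag$D_grads))
})

test_that("hand-written backward passes match finite differences", {
  b <- tiny_bundle(seed = 11, dropout = 0)
  set.seed(12)
  X <- matrix(runif(4 * 40), 4, 40)
  y <- c(0L, 1L, 1L, 0L)
  loss_of <- function(flatG) {
    G <- b$G
    G$params <- cd$unflatten_params(G$params, flatG)
    f <- G_forward(G, X)$features
    cd$cross_entropy(C_forward(b$C, f)$probs, y)
  }
  fw <- G_forward(b$G, X, keep_cache = TRUE)
  dlog <- cd$ce_dlogits(C_forward(b$C, fw$features)$probs, y)
  cb <- C_backward(b$C, fw$features, dlog)
  analytic <- flatten_params(G_backward(b$G, fw$cache, cb$dF))
  flat <- flatten_params(b$G$params)
  idx <- sort(sample(length(flat), 60))
  eps <- 1e-6
  for (j in idx) {
    fp <- flat; fp[j] <- fp[j] + eps
    fm <- flat; fm[j] <- fm[j] - eps
    num <- (loss_of(fp) - loss_of(fm)) / (2 * eps)
    expect_equal(analytic[j], num, tolerance = 1e-5)
  }
})
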