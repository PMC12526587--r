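test_that("baseline correction recovers known polynomial backgrounds", {
  set.seed(11)
  grid <- default_grid(400)
  x <- (grid - mean(range(grid))) / (diff(range(grid)) / 2)

  # pure cubic, no peaks: an ordinary least-squares cubic fit is the oracle
  cubic <- 2 + 0.5 * x - 1.2 * x^2 + 0.8 * x^3
  corrected <- correct_baseline(spectrum(grid, cubic))
  ols_fit <- stats::lm.fit(cbind(1, x, x^2, x^3), cubic)$fitted.values
  expect_lt(max(abs(corrected$intensities)), 1e-6 * diff(range(cubic)))
  expect_lt(max(abs(cubic - ols_fit)), 1e-8)   # oracle sanity

  # all-zero spectrum stays zero
  z <- correct_baseline(spectrum(grid, rep(0, 400)))
  expect_equal(z$intensities, rep(0, 400))

  # peaks + cubic baseline: compare against subtracting the generator truth
  peaks <- exp(-(grid - 800)^2 / 200) + 0.7 * exp(-(grid - 1200)^2 / 300) +
    0.5 * exp(-(grid - 1700)^2 / 250)
  signal <- peaks + cubic
  corrected <- correct_baseline(spectrum(grid, signal))
  peak_idx <- vapply(c(800, 1200, 1700), function(w) which.min(abs(grid - w)),
                     integer(1))
  rel_err <- abs(corrected$intensities[peak_idx] - peaks[peak_idx]) /
    peaks[peak_idx]
  expect_lt(max(rel_err), 0.05)

  expect_error(correct_baseline(spectrum(grid[1:3], c(1, 2, 3))), "length")
})

test_that("mean smoothing matches the brute-force moving average", {
  n <- 60
  grid <- seq_len(n)
  expect_equal(smooth_mean(spectrum(grid, rep(3.5, n)), 9)$intensities,
               rep(3.5, n))

  imp <- rep(0, n); imp[30] <- 1
  sm <- smooth_mean(spectrum(grid, imp), 9)
  expect_equal(sm$intensities[26:34], rep(1 / 9, 9))
  expect_equal(sum(sm$intensities[26:34] > 0), 9)

  set.seed(4)
  v <- rnorm(n)
  brute <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - 4):min(n, i + 4)
    mean(v[idx])
  }, numeric(1))
  expect_equal(smooth_mean(spectrum(grid, v), 9)$intensities, brute)

  expect_error(smooth_mean(spectrum(grid, v), 8), "odd")
})

test_that("min-max normalization is the exact affine map", {
  s <- spectrum(c(1, 2, 3), c(0, 5, 10))
  expect_equal(minmax_normalize(s)$intensities, c(0, 0.5, 1))
  set.seed(5)
  v <- rnorm(50)
  out <- minmax_normalize(spectrum(seq_len(50), v))$intensities
  expect_equal(out, (v - min(v)) / (max(v) - min(v)))
  unit <- minmax_normalize(spectrum(seq_len(50), out))
  expect_equal(unit$intensities, out)
  expect_error(minmax_normalize(spectrum(1:3, rep(2, 3))), "constant")
})

test_that("preprocessing pipeline is idempotent up to re-normalization", {
  set.seed(9)
  grid <- default_grid(200)
  bands <- exp(-(grid - 900)^2 / 5000) + 0.6 * exp(-(grid - 1500)^2 / 8000)
  X <- matrix(rep(bands, 3), 3, byrow = TRUE) * runif(3, 0.8, 1.2) +
    matrix(rnorm(3 * 200, sd = 0.01), 3, 200) +
    outer(runif(3), (grid - 500) / 1500)
  ds <- spectral_dataset(X, wavenumbers = grid, domain = "source")
  once <- preprocess_dataset(ds)
  twice <- preprocess_dataset(once)
  expect_true(all(once$X >= 0 & once$X <= 1))
  # a second pass only re-scales: correlation with the first pass stays ~1
  # (the baseline refit and edge smoothing move the curve by well under 1%)
  for (i in 1:3)
    expect_gt(stats::cor(once$X[i, ], twice$X[i, ]), 0.995)
})

test_that("domain split partitions controls 1:1 and samples 7:3, reproducibly", {
  set.seed(2)
  grid <- default_grid(50)
  mk <- function(n, domain) spectral_dataset(matrix(runif(n * 50), n),
                                             wavenumbers = grid,
                                             domain = domain)
  controls <- mk(68, "source")
  disease_src <- mk(72, "source")
  disease_tgt <- mk(72, "target")
  pair <- make_domain_split(controls, disease_src, disease_tgt,
                            split_spec(seed = 3))
  n_src_ctrl <- sum(pair$source_train$y == 0) + sum(pair$source_test$y == 0)
  n_tgt_ctrl <- sum(pair$sealed$train == 0) + sum(pair$sealed$test == 0)
  expect_equal(n_src_ctrl, 34)
  expect_equal(n_tgt_ctrl, 34)

  # determinism under a fixed seed
  pair2 <- make_domain_split(controls, disease_src, disease_tgt,
                             split_spec(seed = 3))
  expect_identical(pair$source_train$X, pair2$source_train$X)
  expect_identical(pair$target_test$X, pair2$target_test$X)

  # 7:3 count + disjointness + completeness on 100 source samples
  n_train <- nrow(pair$source_train$X); n_test <- nrow(pair$source_test$X)
  expect_equal(n_train + n_test, 34 + 72)
  expect_equal(n_train, round(0.7 * 34) + round(0.7 * 72))
  ids <- c(pair$source_train$sample_ids, pair$source_test$sample_ids)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("SMOTE balances every class exactly and interpolates on segments", {
  set.seed(21)
  grid <- default_grid(30)
  X <- rbind(matrix(runif(72 * 30), 72), matrix(runif(34 * 30) + 2, 34))
  ds <- spectral_dataset(X, y = rep(c(1L, 0L), c(72, 34)), wavenumbers = grid,
                         domain = "source")
  bal <- smote_balance(ds, target_count = 300, seed = 5)
  expect_equal(as.integer(table(bal$y)), c(300L, 300L))

  # class at target already: untouched
  same <- smote_balance(ds, target_count = 72, seed = 5)
  expect_equal(sum(same$y == 1), 72L)

  # every synthetic row lies on a segment between two real same-class rows
  synth_idx <- grep("smote", bal$sample_ids)
  expect_gt(length(synth_idx), 0)
  for (i in sample(synth_idx, 25)) {
    cls <- bal$y[i]
    real <- ds$X[ds$y == cls, , drop = FALSE]
    p <- bal$X[i, ]
    seg_dist <- apply(real, 1, function(a) {
      min(apply(real, 1, function(b) {
        ab <- b - a
        if (sum(ab^2) == 0) return(sqrt(sum((p - a)^2)))
        t <- sum((p - a) * ab) / sum(ab^2)
        t <- min(max(t, 0), 1)
        sqrt(sum((p - a - t * ab)^2))
      }))
    })
    expect_lt(min(seg_dist), 1e-8)
  }

  tiny <- spectral_dataset(matrix(runif(3 * 30), 3), y = c(0L, 0L, 1L),
                           wavenumbers = grid, domain = "source")
  expect_error(smote_balance(tiny, 10), "at least 2")
})

test_that("PCA harmonization shares one orthonormal basis across domains", {
  set.seed(31)
  grid <- default_grid(120)
  src <- spectral_dataset(matrix(rnorm(40 * 120), 40), wavenumbers = grid,
                          domain = "source")
  tgt <- spectral_dataset(matrix(rnorm(35 * 120), 35), wavenumbers = grid,
                          domain = "target")
  harm <- suppressWarnings(pca_harmonize(src, tgt, 50))
  expect_equal(ncol(harm$source$X), 50)
  expect_equal(ncol(harm$target$X), 50)
  expect_lt(max(abs(crossprod(harm$rotation) - diag(50))), 1e-8)

  # low-rank data is captured completely
  base <- matrix(rnorm(5 * 120), 5)
  lowr <- matrix(rnorm(40 * 5), 40) %*% base
  src_lr <- spectral_dataset(lowr, wavenumbers = grid, domain = "source")
  tgt_lr <- spectral_dataset(lowr[1:10, ] + 1e-3, wavenumbers = grid,
                             domain = "target")
  harm_lr <- pca_harmonize(src_lr, tgt_lr, 10)
  expect_equal(harm_lr$explained, 1.0, tolerance = 1e-6)

  # row order of the fitting pool only changes signs: projected distances match
  perm <- sample(40)
  src_p <- cd$subset_dataset(src, perm)
  harm_p <- suppressWarnings(pca_harmonize(src_p, tgt, 10))
  d1 <- as.matrix(dist(suppressWarnings(pca_harmonize(src, tgt, 10))$target$X))
  d2 <- as.matrix(dist(harm_p$target$X))
  expect_equal(d1, d2, tolerance = 1e-6)

  expect_error(pca_harmonize(src, tgt, 120), "rank")
})
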