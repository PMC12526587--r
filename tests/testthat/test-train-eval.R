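test_that("short training runs are bit-reproducible and logged", {
  pair <- tiny_pair(seed = 2)
  cfg <- train_config(iterations = 5L, iteration_unit = "step", batch = 8L,
                      lr = 1e-4, mode = "cdan_pl", seed = 31,
                      net = tiny_net(80L))
  f1 <- train(pair, cfg)
  f2 <- train(pair, cfg)
  expect_identical(flatten_params(f1$bundle$G$params),
                   flatten_params(f2$bundle$G$params))
  expect_identical(flatten_params(f1$bundle$D$params),
                   flatten_params(f2$bundle$D$params))
  expect_identical(f1$log, f2$log)
  expect_equal(nrow(f1$log), 5L)
  expect_named(f1$log, c("iter", "epoch", "L_cls", "L_CE", "L_adv", "L_MC",
                         "T_m", "combined", "lambda", "kept_count"))
  expect_true(all(is.finite(f1$log$L_cls)))
  expect_true(all(is.finite(f1$log$L_adv)))

  f3 <- train(pair, local({ c3 <- cfg; c3$seed <- 32L; c3 }))
  expect_false(identical(flatten_params(f1$bundle$G$params),
                         flatten_params(f3$bundle$G$params)))
})

test_that("training modes gate their loss components as specified", {
  pair <- tiny_pair(seed = 3)
  base <- train_config(iterations = 4L, iteration_unit = "step", batch = 8L,
                       lr = 1e-4, seed = 5, net = tiny_net(80L))
  so <- train(pair, local({ x <- base; x$mode <- "source_only"; x }))
  expect_true(all(so$log$L_adv == 0))
  expect_true(all(so$log$L_CE == 0))
  expect_true(all(so$log$kept_count == 0))

  mc <- train(pair, local({ x <- base; x$mode <- "cdan_mc"; x }))
  expect_true(all(mc$log$L_adv != 0))
  expect_true(all(mc$log$L_CE == 0))

  pl <- train(pair, local({ x <- base; x$mode <- "cdan_pl"; x }))
  expect_true(all(pl$log$L_adv != 0))
})

test_that("evaluation reports accuracies, confusion and the permutation null", {
  pair <- tiny_pair(seed = 4)
  b <- model_bundle(80L, 2L, config = tiny_net(80L), seed = 2)
  ev <- evaluate_model(b, pair$target_test, pair$sealed$test)
  n_test <- nrow(pair$target_test$X)
  # conservation: every test sample lands in exactly one confusion cell
  expect_equal(sum(ev$confusion), n_test)
  pred <- predict(b, pair$target_test)$labels
  expect_equal(ev$accuracy, 100 * mean(pred == pair$sealed$test))
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 100)

  # a perfect predictor scores 100 with a diagonal confusion matrix
  ev_perfect <- evaluate_model(b, pair$target_test, pred)
  expect_equal(ev_perfect$accuracy, 100)
  expect_equal(sum(ev_perfect$confusion) - sum(diag(ev_perfect$confusion)), 0)

  # label shuffling pushes accuracy into the binomial chance band
  set.seed(77)
  accs <- replicate(30, {
    evaluate_model(b, pair$target_test, sample(pair$sealed$test))$accuracy
  })
  band <- 100 * (0.5 + c(-1, 1) * 1.96 * sqrt(0.25 / n_test))
  expect_gt(mean(accs), band[1] - 10)
  expect_lt(mean(accs), band[2] + 10)
})

test_that("t-SNE export covers every sample and is seed-stable", {
  pair <- tiny_pair(seed = 5)
  b <- model_bundle(80L, 2L, config = tiny_net(80L), seed = 3)
  emb <- tsne_export(b, pair, perplexity = 5, max_iter = 120, seed = 9)
  n_all <- nrow(pair$source_train$X) + nrow(pair$source_test$X) +
    nrow(pair$target_train$X) + nrow(pair$target_test$X)
  expect_equal(nrow(emb$table), n_all)
  expect_setequal(unique(emb$table$domain), c("source", "target"))
  expect_false(any(is.na(emb$table$class)))

  emb2 <- tsne_export(b, pair, perplexity = 5, max_iter = 120, seed = 9)
  expect_identical(emb$table, emb2$table)
})

test_that("Grad-CAM maps are normalized and the key-peak rule is exact", {
  pair <- tiny_pair(seed = 6)
  b <- model_bundle(80L, 2L, config = tiny_net(80L), seed = 4)
  amap <- gradcam_spectrum(b, pair$target_test, target_class = 1L)
  expect_true(all(amap$contributions >= 0 & amap$contributions <= 1))
  expect_equal(max(amap$contributions), 1)
  expect_equal(length(amap$contributions), 80L)

  # hand-built contribution curve: maxima at 0.7 and 0.4 -> one key peak
  wn <- seq(500, 2000, length.out = 21)
  contrib <- rep(0.1, 21)
  contrib[6] <- 0.7; contrib[5] <- 0.5; contrib[7] <- 0.5
  contrib[15] <- 0.4; contrib[14] <- 0.3; contrib[16] <- 0.3
  kp <- extract_key_peaks(contrib, wn)
  expect_equal(nrow(kp), 1L)
  expect_equal(kp$wavenumber, wn[6])
  expect_equal(kp$contribution, 0.7)
  # threshold is strict: a plateau exactly at 0.5 is not a key peak
  expect_equal(nrow(extract_key_peaks(rep(0.5, 21), wn)), 0L)
})

test_that("different-grid tasks train through the PCA-harmonized space", {
  pair <- generate_transfer_task("nonhomologous_like", seed = 4)
  pair$source_train$X <- pair$source_train$X[1:40, ]
  pair$source_train$y <- pair$source_train$y[1:40]
  pair$source_train$sample_ids <- pair$source_train$sample_ids[1:40]
  pair <- suppressWarnings(prepare_pair(pair, smote_count = 30L, seed = 4,
                                        pca_components = 20L))
  expect_equal(ncol(pair$source_train$X), 20L)
  expect_equal(ncol(pair$target_test$X), 20L)
  cfg <- train_config(iterations = 3L, iteration_unit = "step", batch = 8L,
                      lr = 1e-4, mode = "cdan_pl", seed = 6,
                      net = net_config(20L, patch = 4L, stride = 4L,
                                       d_model = 8L, n_heads = 2L,
                                       n_layers = 1L, ffn_dim = 12L,
                                       conv_kernels = c(3L, 5L, 7L),
                                       conv_channels = 2L, feature_dim = 6L,
                                       disc_hidden = 5L))
  fit <- train(pair, cfg)
  expect_equal(nrow(fit$log), 3L)
  ev <- evaluate_model(fit$bundle, pair$target_test, pair$sealed$test)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 100)
})

test_that("pipeline artifacts round-trip through CSV", {
  ds <- tiny_dataset(n = 8, seed = 7)
  dir <- tempfile(); dir.create(dir)
  main <- file.path(dir, "spectra.csv")
  side <- file.path(dir, "labels.csv")
  write_spectra_csv(ds, main, sidecar = side)
  back <- read_spectra_csv(main, sidecar = side)
  expect_equal(back$X, ds$X, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$y, ds$y)
  expect_equal(back$wavenumbers, ds$wavenumbers, tolerance = 1e-8)
  unlink(dir, recursive = TRUE)
})
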