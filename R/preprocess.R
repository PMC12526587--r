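#' Iterative polynomial baseline correction
#'
#' Removes the slowly varying fluorescence background under Raman peaks by
#' iteratively re-fitted least-squares polynomial fitting (modified polyfit):
#' at each round a degree-`degree` polynomial is fitted to the working trace,
#' points above the fit are clipped down to it, and the fit repeats until the
#' relative change in the fit residual drops below `loss_gradient` or
#' `max_iter` rounds have run. The returned spectrum is the input minus the
#' final baseline estimate.
#'
#' @param spec a [spectrum()].
#' @param degree polynomial degree (default 3).
#' @param max_iter maximum refit rounds (default 100).
#' @param loss_gradient relative residual-change stopping threshold
#'   (default 0.001).
#' @return A baseline-corrected [spectrum()] of the same length.
#' @export
correct_baseline <- function(spec, degree = 3L, max_iter = 100L,
                             loss_gradient = 0.001) {
  stopifnot(inherits(spec, "spectrum"))
  if (degree < 1L) stop_input("degree must be >= 1")
  if (max_iter < 1L) stop_input("max_iter must be >= 1")
  if (loss_gradient <= 0) stop_input("loss_gradient must be > 0")
  y <- spec$intensities
  n <- length(y)
  if (n <= degree + 1L) stop_input("spectrum length must exceed degree + 1")
  if (!all(is.finite(y))) stop_input("non-finite intensities")
  w <- spec$wavenumbers
  if (diff(range(w)) == 0) stop_input("degenerate (constant) wavenumber grid")
  # centred/scaled abscissa + orthogonal design keeps the fit well conditioned
  x <- (w - mean(w)) / (diff(range(w)) / 2)
  basis <- cbind(1, stats::poly(x, degree = degree, raw = FALSE))
  qr_basis <- qr(basis)
  work <- y
  prev_res <- Inf
  fit <- rep(0, n)
  for (it in seq_len(max_iter)) {
    beta <- qr.coef(qr_basis, work)
    fit <- drop(basis %*% beta)
    res <- sqrt(mean((work - fit)^2))
    work <- pmin(work, fit)   # clip peaks to the running baseline
    if (is.finite(prev_res)) {
      if (prev_res == 0 || abs(prev_res - res) / max(prev_res, .Machine$double.eps)
          < loss_gradient) break
    }
    prev_res <- res
  }
  spectrum(w, y - fit)
}

#' Mean (moving-average) smoothing
#'
#' Centered moving average with an odd window; at the edges the window
#' shrinks to the points actually measured, so no intensities are invented
#' outside the grid.
#'
#' @param spec a [spectrum()].
#' @param window odd window width (default 9).
#' @return A smoothed [spectrum()] of the same length.
#' @export
smooth_mean <- function(spec, window = 9L) {
  stopifnot(inherits(spec, "spectrum"))
  window <- as.integer(window)
  n <- length(spec$intensities)
  if (window < 1L || window %% 2L == 0L)
    stop_input("window must be odd and >= 1 (got %d)", window)
  if (window > n) stop_input("window (%d) exceeds spectrum length (%d)", window, n)
  h <- (window - 1L) %/% 2L
  # cumulative-sum formulation of the shrink-to-valid moving average
  cs <- c(0, cumsum(spec$intensities))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  spectrum(spec$wavenumbers, out)
}

#' Min-max normalization of one spectrum
#'
#' Affine rescaling so the minimum maps to 0 and the maximum to 1, matching
#' the input range convention of the networks.
#'
#' @param spec a [spectrum()].
#' @return A [spectrum()] with intensities in `[0, 1]`.
#' @export
minmax_normalize <- function(spec) {
  stopifnot(inherits(spec, "spectrum"))
  r <- range(spec$intensities)
  if (r[1] == r[2])
    stop_input("constant spectrum cannot be min-max normalized")
  spectrum(spec$wavenumbers, (spec$intensities - r[1]) / (r[2] - r[1]))
}

# Row-wise application of the spectrum pipeline to a dataset matrix.
apply_rowwise <- function(ds, fn, label) {
  out <- ds$X
  for (i in seq_len(nrow(out))) {
    res <- tryCatch(fn(spectrum(ds$wavenumbers, out[i, ])),
                    error = function(e)
                      stop_input("%s failed on row %s: %s", label,
                                 ds$sample_ids[i], conditionMessage(e)))
    out[i, ] <- res$intensities
  }
  ds$X <- out
  ds
}

#' Standard preprocessing pipeline for a dataset
#'
#' Applies, in this fixed order: iterative polynomial baseline correction,
#' mean smoothing, and per-spectrum min-max normalization. The order is part
#' of the method: normalization last fixes the input range the networks see.
#'
#' @param ds a [spectral_dataset()].
#' @param degree,max_iter,loss_gradient see [correct_baseline()].
#' @param window see [smooth_mean()].
#' @return The preprocessed [spectral_dataset()].
#' @export
preprocess_dataset <- function(ds, degree = 3L, max_iter = 100L,
                               loss_gradient = 0.001, window = 9L) {
  ds <- apply_rowwise(ds, function(s)
    correct_baseline(s, degree, max_iter, loss_gradient), "baseline correction")
  ds <- apply_rowwise(ds, function(s) smooth_mean(s, window), "smoothing")
  apply_rowwise(ds, minmax_normalize, "normalization")
}

#' Split specification for domain construction
#'
#' @param control_split_ratio fraction of healthy controls assigned to the
#'   source domain (default 0.5, a 1:1 split).
#' @param train_test_ratio fraction of each domain used for training
#'   (default 0.7, a 7:3 split).
#' @param seed integer seed making the split reproducible.
#' @param stratified stratify the 7:3 split by class (default TRUE).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(control_split_ratio = 0.5, train_test_ratio = 0.7,
                       seed = 1L, stratified = TRUE) {
  if (control_split_ratio <= 0 || control_split_ratio >= 1 ||
      train_test_ratio <= 0 || train_test_ratio >= 1)
    stop_input("split ratios must lie in (0, 1)")
  structure(list(control_split_ratio = control_split_ratio,
                 train_test_ratio = train_test_ratio,
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Seeded stratified (or plain) train/test index split.
train_test_indices <- function(y, n, ratio, stratified) {
  if (is.null(y) || !stratified) {
    n_train <- round(ratio * n)
    train <- sort(sample.int(n, n_train))
  } else {
    train <- integer(0)
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      train <- c(train, sample(idx, round(ratio * length(idx))))
    }
    train <- sort(train)
  }
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Assemble a transfer task from controls and two disease cohorts
#'
#' Healthy controls are partitioned disjointly between the two domains at
#' `control_split_ratio`; the source domain pairs its controls with the
#' source-disease cohort (labels kept) and the target domain pairs the rest
#' with the target-disease cohort (labels sealed). Each domain is then split
#' into train/test at `train_test_ratio`. Class code 0 = healthy control,
#' 1 = disease.
#'
#' @param controls healthy-control [spectral_dataset()] (labels ignored).
#' @param disease_source disease cohort for the source domain.
#' @param disease_target disease cohort for the target domain.
#' @param split a [split_spec()].
#' @return An object of class `domain_pair`: labeled `source_train` /
#'   `source_test`, unlabeled `target_train` / `target_test`, and sealed
#'   target label vectors in `$sealed` (evaluation only).
#' @export
make_domain_split <- function(controls, disease_source, disease_target, split) {
  stopifnot(inherits(split, "split_spec"))
  for (ds in list(disease_source, disease_target))
    if (!isTRUE(all.equal(controls$wavenumbers, ds$wavenumbers)))
      stop_input("input datasets do not share a feature grid")
  classes <- c("healthy", "disease")
  with_seed(split$seed, {
    nc <- nrow(controls$X)
    n_src <- round(split$control_split_ratio * nc)
    src_ctrl_idx <- sort(sample.int(nc, n_src))
    tgt_ctrl_idx <- setdiff(seq_len(nc), src_ctrl_idx)

    build <- function(ctrl_idx, disease, domain) {
      ctrl <- controls$X[ctrl_idx, , drop = FALSE]
      X <- rbind(ctrl, disease$X)
      y <- c(rep(0L, nrow(ctrl)), rep(1L, nrow(disease$X)))
      ids <- make.unique(c(controls$sample_ids[ctrl_idx], disease$sample_ids))
      spectral_dataset(X, y = y, wavenumbers = controls$wavenumbers,
                       domain = domain, classes = classes, sample_ids = ids)
    }
    source <- build(src_ctrl_idx, disease_source, "source")
    target <- build(tgt_ctrl_idx, disease_target, "target")

    si <- train_test_indices(source$y, nrow(source$X), split$train_test_ratio,
                             split$stratified)
    ti <- train_test_indices(target$y, nrow(target$X), split$train_test_ratio,
                             split$stratified)
    source_train <- subset_dataset(source, si$train)
    source_test <- subset_dataset(source, si$test)
    target_train <- subset_dataset(target, ti$train)
    target_test <- subset_dataset(target, ti$test)
    sealed <- list(train = target_train$y, test = target_test$y)
    target_train$y <- NULL
    target_test$y <- NULL
    domain_pair(source_train, source_test, target_train, target_test, sealed)
  })
}

#' Bundle a labeled source and unlabeled target domain into a transfer task
#'
#' @param source_train,source_test labeled source [spectral_dataset()]s.
#' @param target_train,target_test unlabeled target datasets.
#' @param sealed list with `train`/`test` integer label vectors used only at
#'   evaluation time; never visible to training.
#' @return An object of class `domain_pair`.
#' @export
domain_pair <- function(source_train, source_test, target_train, target_test,
                        sealed) {
  if (is.null(source_train$y)) stop_input("source domain must be labeled")
  if (!is.null(target_train$y) || !is.null(target_test$y))
    stop_input("target datasets must not expose labels; pass them via `sealed`")
  # different grids are allowed here; pca_harmonize/prepare_pair aligns them
  # before any model sees the pair
  structure(list(source_train = source_train, source_test = source_test,
                 target_train = target_train, target_test = target_test,
                 sealed = sealed),
            class = "domain_pair")
}

#' @export
print.domain_pair <- function(x, ...) {
  cat(sprintf(paste0("<domain_pair> source %d/%d train/test, ",
                     "target %d/%d train/test, %d features\n"),
              nrow(x$source_train$X), nrow(x$source_test$X),
              nrow(x$target_train$X), nrow(x$target_test$X),
              ncol(x$source_train$X)))
  invisible(x)
}

#' SMOTE class balancing
#'
#' Oversamples every class up to `target_count` rows by synthetic minority
#' interpolation: each synthetic row is `x_i + u * (x_nn - x_i)` with
#' `u ~ U(0, 1)`, where `x_nn` is one of the `k_neighbors` same-class nearest
#' neighbors (Euclidean) of a real row `x_i`. Original rows are preserved;
#' classes already at or above `target_count` are left unchanged.
#'
#' @param ds a labeled [spectral_dataset()].
#' @param target_count rows per class after balancing (default 300).
#' @param k_neighbors neighbors per real sample (default 5).
#' @param seed integer seed.
#' @return A balanced [spectral_dataset()].
#' @export
smote_balance <- function(ds, target_count = 300L, k_neighbors = 5L, seed = 1L) {
  if (is.null(ds$y)) stop_input("smote_balance needs a labeled dataset")
  counts <- table(ds$y)
  with_seed(seed, {
    new_X <- list(ds$X)
    new_y <- list(ds$y)
    new_ids <- list(ds$sample_ids)
    for (cl in as.integer(names(counts))) {
      idx <- which(ds$y == cl)
      n_need <- target_count - length(idx)
      if (n_need <= 0) next
      if (length(idx) < 2L)
        stop_input("class %d has < 2 real samples; SMOTE needs at least 2", cl)
      Xc <- ds$X[idx, , drop = FALSE]
      k <- min(k_neighbors, length(idx) - 1L)
      D <- as.matrix(dist(Xc))
      diag(D) <- Inf
      ord <- apply(D, 1, function(d) order(d)[seq_len(k)])
      nn <- if (k == 1L) matrix(ord, ncol = 1L) else t(ord)
      base <- sample.int(length(idx), n_need, replace = TRUE)
      pick <- nn[cbind(base, sample.int(k, n_need, replace = TRUE))]
      u <- runif(n_need)
      synth <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      new_X[[length(new_X) + 1L]] <- synth
      new_y[[length(new_y) + 1L]] <- rep(cl, n_need)
      new_ids[[length(new_ids) + 1L]] <-
        sprintf("%s_smote%d_%04d", ds$domain, cl, seq_len(n_need))
    }
    spectral_dataset(do.call(rbind, new_X), y = unlist(new_y),
                     wavenumbers = ds$wavenumbers, domain = ds$domain,
                     classes = ds$classes,
                     sample_ids = make.unique(unlist(new_ids)))
  })
}

# Linear-interpolation resampling of a dataset onto a common grid; the
# minimal-assumption alignment when two spectrometers use different grids.
resample_to_grid <- function(ds, grid) {
  X <- t(apply(ds$X, 1, function(row)
    approx(ds$wavenumbers, row, xout = grid, rule = 2)$y))
  spectral_dataset(X, y = ds$y, wavenumbers = grid, domain = ds$domain,
                   classes = ds$classes, sample_ids = ds$sample_ids)
}

#' PCA harmonization of two domains onto one shared basis
#'
#' Fits a single PCA basis on the pooled rows of both datasets (after linear
#' resampling onto a common grid if the grids differ) and projects both into
#' the leading `n_components` scores, so the adversarial game sees one
#' feature space. Warns if the cumulative explained-variance ratio falls
#' below 0.99.
#'
#' @param source,target [spectral_dataset()]s.
#' @param n_components principal components to keep (default 50).
#' @return A list `(source, target, explained, rotation, center, grid)`;
#'   `explained` is the cumulative explained-variance ratio.
#' @export
pca_harmonize <- function(source, target, n_components = 50L) {
  if (nrow(source$X) == 0 || nrow(target$X) == 0)
    stop_input("both datasets must be nonempty")
  if (!isTRUE(all.equal(source$wavenumbers, target$wavenumbers))) {
    grid <- if (ncol(source$X) <= ncol(target$X)) source$wavenumbers
            else target$wavenumbers
    source <- resample_to_grid(source, grid)
    target <- resample_to_grid(target, grid)
  }
  pooled <- rbind(source$X, target$X)
  feasible <- min(ncol(pooled), nrow(pooled) - 1L)
  if (n_components > feasible)
    stop_input("n_components (%d) exceeds feasible rank (%d)",
               n_components, feasible)
  pc <- prcomp(pooled, center = TRUE, scale. = FALSE)
  var_ratio <- pc$sdev^2 / sum(pc$sdev^2)
  explained <- sum(var_ratio[seq_len(n_components)])
  if (explained < 0.99)
    warning(sprintf("cumulative explained variance %.4f < 0.99 at %d components",
                    explained, n_components))
  project <- function(ds) {
    scores <- sweep(ds$X, 2, pc$center) %*% pc$rotation[, seq_len(n_components),
                                                        drop = FALSE]
    spectral_dataset(scores, y = ds$y, wavenumbers = seq_len(n_components),
                     domain = ds$domain, classes = ds$classes,
                     sample_ids = ds$sample_ids)
  }
  list(source = project(source), target = project(target),
       explained = explained,
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
       center = pc$center, grid = source$wavenumbers)
}

# Project a further dataset with an already-fitted harmonization basis.
apply_pca <- function(ds, harm) {
  if (!isTRUE(all.equal(ds$wavenumbers, harm$grid)))
    ds <- resample_to_grid(ds, harm$grid)
  scores <- sweep(ds$X, 2, harm$center) %*% harm$rotation
  spectral_dataset(scores, y = ds$y, wavenumbers = seq_len(ncol(scores)),
                   domain = ds$domain, classes = ds$classes,
                   sample_ids = ds$sample_ids)
}

#' Preprocess and balance a whole transfer task
#'
#' Convenience wrapper running [preprocess_dataset()] on all four partitions
#' of a [domain_pair()] and [smote_balance()] on the two training pools
#' (source with its true labels, target with its sealed labels kept sealed:
#' SMOTE on the target train pool uses the sealed labels only to balance the
#' pool and the resulting labels stay sealed).
#'
#' @param pair a [domain_pair()].
#' @param smote_count rows per class after SMOTE (default 300); `NULL`
#'   disables balancing.
#' @param k_neighbors,seed passed to [smote_balance()].
#' @param pca_components harmonize both domains onto this many shared
#'   principal components (fitted on the pooled training rows). `NULL`
#'   (default) skips PCA unless the two domains sit on different grids, in
#'   which case 50 components are used.
#' @param ... passed to [preprocess_dataset()].
#' @return The processed [domain_pair()].
#' @export
prepare_pair <- function(pair, smote_count = 300L, k_neighbors = 5L,
                         seed = 1L, pca_components = NULL, ...) {
  stopifnot(inherits(pair, "domain_pair"))
  pair$source_train <- preprocess_dataset(pair$source_train, ...)
  pair$source_test <- preprocess_dataset(pair$source_test, ...)
  pair$target_train <- preprocess_dataset(pair$target_train, ...)
  pair$target_test <- preprocess_dataset(pair$target_test, ...)
  grids_differ <- !isTRUE(all.equal(pair$source_train$wavenumbers,
                                    pair$target_train$wavenumbers))
  if (grids_differ && is.null(pca_components)) pca_components <- 50L
  if (!is.null(pca_components)) {
    harm <- pca_harmonize(pair$source_train, pair$target_train,
                          pca_components)
    pair$source_train <- harm$source
    pair$target_train <- harm$target
    pair$source_test <- apply_pca(pair$source_test, harm)
    pair$target_test <- apply_pca(pair$target_test, harm)
  }
  if (!is.null(smote_count)) {
    pair$source_train <- smote_balance(pair$source_train, smote_count,
                                       k_neighbors, seed)
    tt <- pair$target_train
    tt$y <- pair$sealed$train
    tt$classes <- pair$source_train$classes
    tt <- smote_balance(tt, smote_count, k_neighbors, seed + 1L)
    pair$sealed$train <- tt$y
    tt$y <- NULL
    pair$target_train <- tt
  }
  pair
}
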