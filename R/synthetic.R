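#' Gaussian peak specification for synthetic Raman spectra
#'
#' @param center peak center (cm^-1), inside the grid range.
#' @param width Gaussian sigma (cm^-1), > 0.
#' @param base_amplitude amplitude shared by all classes.
#' @param class_effect additive amplitude delta applied to the disease class;
#'   0 for non-discriminative background bands.
#' @return An object of class `peak_spec`.
#' @export
peak_spec <- function(center, width, base_amplitude, class_effect = 0) {
  if (width <= 0) stop_input("peak width must be > 0")
  structure(list(center = center, width = width,
                 base_amplitude = base_amplitude, class_effect = class_effect),
            class = "peak_spec")
}

#' Domain shift specification for one acquisition setup
#'
#' Describes how one spectrometer setup distorts the ideal peak-sum signal:
#' an additive cubic fluorescence baseline, a multiplicative gain, i.i.d.
#' Gaussian noise, per-sample peak-center jitter, and (optionally) a
#' per-peak multiplicative response factor emulating the band-intensity
#' differences between excitation wavelengths. Baseline and gain are removed
#' by preprocessing; peak response and jitter survive it, so they carry the
#' domain shift the adaptation has to close.
#'
#' @param baseline_coeffs length-4 cubic coefficients (constant first),
#'   evaluated on the grid rescaled to `[-1, 1]`.
#' @param gain multiplicative factor, > 0.
#' @param noise_sd Gaussian noise standard deviation, >= 0.
#' @param peak_jitter_sd per-sample jitter of peak centers (cm^-1).
#' @param seed integer seed for this domain's draws.
#' @param peak_response optional per-peak multiplicative response factors
#'   (recycled to the number of peaks; default all 1).
#' @param wavenumber_offset systematic calibration offset of this setup
#'   (cm^-1, added to every peak center; default 0).
#' @return An object of class `domain_shift_spec`.
#' @export
domain_shift_spec <- function(baseline_coeffs = c(0, 0, 0, 0), gain = 1,
                              noise_sd = 0, peak_jitter_sd = 0, seed = 1L,
                              peak_response = 1, wavenumber_offset = 0) {
  if (gain <= 0) stop_input("gain must be > 0")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  structure(list(baseline_coeffs = rep_len(as.numeric(baseline_coeffs), 4L),
                 gain = gain, noise_sd = noise_sd,
                 peak_jitter_sd = peak_jitter_sd, seed = as.integer(seed),
                 peak_response = as.numeric(peak_response),
                 wavenumber_offset = wavenumber_offset),
            class = "domain_shift_spec")
}

#' Default wavenumber grid
#'
#' @param n grid points (default 600).
#' @param from,to range in cm^-1 (default 500-2000).
#' @return Numeric grid.
#' @export
default_grid <- function(n = 600L, from = 500, to = 2000) {
  seq(from, to, length.out = n)
}

# Noise-free closed-form expectation of one class's spectrum under a shift.
expected_spectrum <- function(class_code, peaks, shift, grid) {
  x <- (grid - mean(range(grid))) / (diff(range(grid)) / 2)
  baseline <- drop(cbind(1, x, x^2, x^3) %*% shift$baseline_coeffs)
  resp <- rep_len(shift$peak_response, length(peaks))
  off <- shift$wavenumber_offset %||% 0
  sig <- rep(0, length(grid))
  for (j in seq_along(peaks)) {
    p <- peaks[[j]]
    amp <- p$base_amplitude + if (class_code > 0) p$class_effect else 0
    sig <- sig + resp[j] * amp *
      exp(-(grid - p$center - off)^2 / (2 * p$width^2))
  }
  shift$gain * sig + baseline
}

#' Generate one synthetic spectral domain
#'
#' Each spectrum is `gain * sum of Gaussian peaks` (centers jittered per
#' sample, the `class_effect` added for the disease class, per-peak response
#' factors applied) plus a cubic polynomial baseline and i.i.d. Gaussian
#' noise. Fully reproducible from `shift$seed`.
#'
#' @param n_per_class named integer vector, class name -> count, in class-code
#'   order (first entry becomes code 0 / "healthy").
#' @param peaks list of [peak_spec()]s.
#' @param shift a [domain_shift_spec()].
#' @param grid strictly increasing wavenumber grid.
#' @param domain domain tag.
#' @return A labeled [spectral_dataset()].
#' @export
generate_domain <- function(n_per_class, peaks, shift, grid = default_grid(),
                            domain = "source") {
  if (length(peaks) == 0) stop_input("empty peak list")
  if (any(diff(grid) <= 0)) stop_input("grid must be strictly increasing")
  if (any(n_per_class < 0)) stop_input("n_per_class values must be >= 0")
  for (p in peaks)
    if (p$center < min(grid) || p$center > max(grid))
      stop_input("peak center %.1f outside grid range", p$center)
  classes <- names(n_per_class) %||% paste0("class", seq_along(n_per_class) - 1L)
  x <- (grid - mean(range(grid))) / (diff(range(grid)) / 2)
  baseline <- drop(cbind(1, x, x^2, x^3) %*% shift$baseline_coeffs)
  resp <- rep_len(shift$peak_response, length(peaks))
  n_total <- sum(n_per_class)
  with_seed(shift$seed, {
    X <- matrix(0, n_total, length(grid))
    y <- integer(n_total)
    row <- 0L
    for (ci in seq_along(n_per_class)) {
      code <- ci - 1L
      for (s in seq_len(n_per_class[ci])) {
        row <- row + 1L
        sig <- rep(0, length(grid))
        for (j in seq_along(peaks)) {
          p <- peaks[[j]]
          amp <- p$base_amplitude + if (code > 0) p$class_effect else 0
          ctr <- p$center + (shift$wavenumber_offset %||% 0) +
            if (shift$peak_jitter_sd > 0) rnorm(1, 0, shift$peak_jitter_sd)
            else 0
          sig <- sig + resp[j] * amp * exp(-(grid - ctr)^2 / (2 * p$width^2))
        }
        noise <- if (shift$noise_sd > 0) rnorm(length(grid), 0, shift$noise_sd)
                 else 0
        X[row, ] <- shift$gain * sig + baseline + noise
        y[row] <- code
      }
    }
    spectral_dataset(X, y = y, wavenumbers = grid, domain = domain,
                     classes = classes)
  })
}

# Build peak_spec list from a config data.frame-like list, scaling the
# class effect by `effect_scale` (per-domain disease-signature strength).
peaks_from_config <- function(peak_tab, effect_scale = 1) {
  lapply(seq_along(peak_tab$center), function(j)
    peak_spec(peak_tab$center[j], peak_tab$width[j],
              peak_tab$base_amplitude[j],
              peak_tab$class_effect[j] * effect_scale))
}

#' Load a named synthetic task preset
#'
#' Presets ship as YAML under `inst/presets`: `easy` (strong shared disease
#' signature, mild acquisition shift), `hard` (weak signature, strong shift),
#' `homologous_like` and `nonhomologous_like` (the latter generates the two
#' domains on different grids so the PCA harmonization path is exercised).
#'
#' @param name preset name or a path to a YAML file.
#' @return A config list for [generate_transfer_task()].
#' @export
preset_config <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("presets", paste0(name, ".yaml"), package = "cdanpl")
  if (!nzchar(path) || !file.exists(path))
    stop_input("unknown preset '%s'", name)
  cfg <- yaml::read_yaml(path)
  cfg
}

#' Generate a complete two-domain transfer task
#'
#' Draws a labeled source domain and an unlabeled target domain from the
#' config's peak table and per-domain shift specs, splits each 7:3 into
#' train/test (stratified), and seals the target labels for evaluation.
#'
#' @param config a preset name or config list (see [preset_config()]).
#' @param seed overrides the config seed when not `NULL`; all domain draws
#'   and splits derive from it.
#' @return A [domain_pair()] with sealed target labels.
#' @export
generate_transfer_task <- function(config = "easy", seed = NULL) {
  if (is.character(config)) config <- preset_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  make_grid <- function(g) default_grid(n = g$points %||% g$n %||% 600L,
                                        from = g$from %||% 500,
                                        to = g$to %||% 2000)
  grid_s <- make_grid(config$grid %||% list())
  grid_t <- if (!is.null(config$target_grid)) make_grid(config$target_grid)
            else grid_s

  src_shift <- do.call(domain_shift_spec,
                       modifyList(config$source_shift, list(seed = seed)))
  tgt_shift <- do.call(domain_shift_spec,
                       modifyList(config$target_shift, list(seed = seed + 1L)))
  src_peaks <- peaks_from_config(config$peaks,
                                 config$source_effect_scale %||% 1)
  tgt_peaks <- peaks_from_config(config$peaks,
                                 config$target_effect_scale %||% 1)
  counts <- function(x) setNames(as.integer(unlist(x)), names(x))
  source <- generate_domain(counts(config$source_counts), src_peaks, src_shift,
                            grid_s, domain = "source")
  target <- generate_domain(counts(config$target_counts), tgt_peaks, tgt_shift,
                            grid_t, domain = "target")

  ratio <- config$train_test_ratio %||% 0.7
  with_seed(seed + 2L, {
    si <- train_test_indices(source$y, nrow(source$X), ratio, TRUE)
    ti <- train_test_indices(target$y, nrow(target$X), ratio, TRUE)
    source_train <- subset_dataset(source, si$train)
    source_test <- subset_dataset(source, si$test)
    target_train <- subset_dataset(target, ti$train)
    target_test <- subset_dataset(target, ti$test)
    sealed <- list(train = target_train$y, test = target_test$y)
    target_train$y <- NULL
    target_test$y <- NULL
    pair <- domain_pair(source_train, source_test, target_train, target_test,
                        sealed)
    attr(pair, "config") <- config
    attr(pair, "seed") <- seed
    pair
  })
}

#' Source-trained linear probe accuracy
#'
#' Sanity oracle for task learnability and transfer gaps: fits LDA on the
#' leading principal components of the (preprocessed) source training
#' spectra and scores any evaluation set. Deliberately simple and fast; not
#' part of the adversarial model.
#'
#' @param train labeled [spectral_dataset()].
#' @param test [spectral_dataset()] to score.
#' @param test_labels labels for `test` (defaults to `test$y`).
#' @param n_pc principal components retained (default 10).
#' @return Accuracy in `[0, 1]`.
#' @export
linear_probe_accuracy <- function(train, test, test_labels = test$y,
                                  n_pc = 10L) {
  if (is.null(test_labels)) stop_input("test labels required for scoring")
  n_pc <- min(n_pc, ncol(train$X), nrow(train$X) - 2L)
  pc <- prcomp(train$X, center = TRUE, scale. = FALSE)
  tr <- pc$x[, seq_len(n_pc), drop = FALSE]
  te <- sweep(test$X, 2, pc$center) %*% pc$rotation[, seq_len(n_pc), drop = FALSE]
  fit <- MASS::lda(tr, grouping = factor(train$y))
  pred <- as.integer(as.character(predict(fit, te)$class))
  mean(pred == test_labels)
}
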