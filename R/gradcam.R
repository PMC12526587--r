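#' Grad-CAM attribution over the wavenumber axis
#'
#' Gradient-weighted class activation mapping on the multi-scale convolution
#' branch (the only branch with positional feature maps). For each kernel
#' scale, the channel weights are the mean gradient of the target-class
#' logit with respect to the post-ReLU convolution activation maps; the
#' rectified weighted channel sum is linearly interpolated onto the
#' wavenumber grid, summed over scales, averaged over the supplied spectra,
#' and min-max normalized to `[0, 1]`. Peaks whose contribution exceeds 0.5
#' are reported as key characteristic peaks.
#'
#' @param bundle a trained [model_bundle()].
#' @param spectra matrix of spectra or a [spectral_dataset()].
#' @param target_class 0-based class whose evidence is attributed
#'   (default 1, the disease class).
#' @param wavenumbers grid for the output axis; taken from `spectra` when it
#'   is a dataset.
#' @return An object of class `attribution_map`: `wavenumbers`,
#'   `contributions` in `[0, 1]`, and `key_peaks`
#'   (data.frame of local maxima with contribution > 0.5).
#' @export
gradcam_spectrum <- function(bundle, spectra, target_class = 1L,
                             wavenumbers = NULL) {
  if (inherits(spectra, "spectral_dataset")) {
    wavenumbers <- spectra$wavenumbers
    X <- spectra$X
  } else {
    X <- as.matrix(spectra)
  }
  cfg <- bundle$config
  wavenumbers <- wavenumbers %||% seq_len(cfg$input_len)
  if (target_class < 0L || target_class >= bundle$n_classes)
    stop_input("target_class out of range")
  fw <- G_forward(bundle$G, X, keep_cache = TRUE)
  cache <- fw$cache
  B <- cache$B

  # d(logit_class)/d(features), then back through LayerNorm + ReLU + fusion
  # to the concatenated branch vector; only the GAP part feeds the CAM.
  dF <- matrix(bundle$C$params$W[, target_class + 1L], B,
               cfg$feature_dim, byrow = TRUE)
  lb <- layernorm_bwd(cache$lnf, dF)
  dZf <- lb$dX * (cache$Zf > 0)
  dZcat <- tcrossprod(dZf, bundle$G$params$fusion$W)

  grid_map <- matrix(0, B, length(wavenumbers))
  off <- cfg$d_model
  any_grad <- FALSE
  for (j in seq_along(cfg$conv_kernels)) {
    ch <- cfg$conv_channels
    k <- cfg$conv_kernels[j]
    cc <- cache$conv_caches[[j]]
    dgap <- dZcat[, (off + 1L):(off + ch), drop = FALSE]
    off <- off + ch
    if (any(dgap != 0)) any_grad <- TRUE
    alpha <- dgap / cc$P                      # B x ch channel weights
    # weighted channel sum per position: rows of Ac are (sample, position)
    A <- cc$Ac                                # (B*P) x ch, sample-major
    w_rows <- alpha[rep(seq_len(B), each = cc$P), , drop = FALSE]
    cam <- rowSums(A * w_rows)                # length B*P
    cam <- matrix(cam, nrow = cc$P)           # positions x samples
    cam[cam < 0] <- 0                         # ReLU on the map
    stride <- cfg$conv_stride %||% 1L
    centers <- wavenumbers[(seq_len(cc$P) - 1L) * stride + 1L +
                             (k - 1L) %/% 2L]
    for (b in seq_len(B))
      grid_map[b, ] <- grid_map[b, ] +
        approx(centers, cam[, b], xout = wavenumbers, rule = 2)$y
  }
  if (!any_grad)
    warning("all Grad-CAM gradients are zero; attribution map is degenerate")
  contrib <- colMeans(grid_map)
  rng <- range(contrib)
  contrib <- if (rng[2] > rng[1]) (contrib - rng[1]) / (rng[2] - rng[1])
             else contrib * 0
  structure(list(wavenumbers = wavenumbers, contributions = contrib,
                 key_peaks = extract_key_peaks(contrib, wavenumbers)),
            class = "attribution_map")
}

#' Extract key characteristic peaks from a contribution vector
#'
#' A key peak is a local maximum of the contribution curve whose value
#' strictly exceeds the threshold (0.5 by default).
#'
#' @param contributions numeric vector in `[0, 1]`.
#' @param wavenumbers matching grid.
#' @param threshold contribution cutoff (default 0.5).
#' @return data.frame with `wavenumber` and `contribution`, one row per key
#'   peak.
#' @export
extract_key_peaks <- function(contributions, wavenumbers, threshold = 0.5) {
  n <- length(contributions)
  if (length(wavenumbers) != n)
    stop_input("contributions and wavenumbers differ in length")
  left <- c(-Inf, contributions[-n])
  right <- c(contributions[-1], -Inf)
  is_max <- contributions >= left & contributions > right
  keep <- is_max & contributions > threshold
  data.frame(wavenumber = wavenumbers[keep],
             contribution = contributions[keep])
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %d points, %d key peak(s)\n",
              length(x$contributions), nrow(x$key_peaks)))
  if (nrow(x$key_peaks) > 0) {
    cat(sprintf("  %.1f cm^-1 (%.2f)\n", x$key_peaks$wavenumber,
                x$key_peaks$contribution), sep = "")
  }
  invisible(x)
}
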