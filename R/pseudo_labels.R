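#' KNN pseudo-labels in the shared feature space
#'
#' Assigns each target sample the majority class among its `K` Euclidean
#' nearest labeled source samples. Majority ties are broken by the smallest
#' summed neighbor distance among the tied classes, then by the lowest class
#' code. `knn_probs` are the neighbor class frequencies (rows sum to 1).
#'
#' @param target_features matrix (n_target x d).
#' @param source_features matrix (n_source x d).
#' @param source_labels 0-based class codes for the source rows.
#' @param K neighbors (1 <= K <= n_source).
#' @param n_classes total classes (defaults to `max(source_labels) + 1`).
#' @return List with `labels` (0-based) and `knn_probs`.
#' @export
knn_pseudo_labels <- function(target_features, source_features, source_labels,
                              K = 5L, n_classes = NULL) {
  target_features <- as.matrix(target_features)
  source_features <- as.matrix(source_features)
  ns <- nrow(source_features)
  if (ns == 0L) stop_input("empty source set")
  if (ncol(target_features) != ncol(source_features))
    stop_input("feature dimensions differ (%d vs %d)",
               ncol(target_features), ncol(source_features))
  K <- as.integer(K)
  if (K < 1L || K > ns) stop_input("K must satisfy 1 <= K <= n_source")
  nc <- as.integer(n_classes %||% (max(source_labels) + 1L))
  # squared Euclidean distances via the expansion ||a||^2 + ||b||^2 - 2ab'
  d2 <- outer(rowSums(target_features^2), rowSums(source_features^2), `+`) -
    2 * tcrossprod(target_features, source_features)
  d2[d2 < 0] <- 0
  nt <- nrow(target_features)
  labels <- integer(nt)
  probs <- matrix(0, nt, nc)
  for (i in seq_len(nt)) {
    ord <- order(d2[i, ])[seq_len(K)]
    cls <- source_labels[ord]
    cnt <- tabulate(cls + 1L, nbins = nc)
    probs[i, ] <- cnt / K
    top <- which(cnt == max(cnt)) - 1L
    if (length(top) == 1L) {
      labels[i] <- top
    } else {
      sums <- vapply(top, function(cl) sum(sqrt(d2[i, ord[cls == cl]])),
                     numeric(1))
      best <- top[sums == min(sums)]
      labels[i] <- min(best)
    }
  }
  list(labels = labels, knn_probs = probs)
}

#' Confidence filtering of pseudo-labels
#'
#' Keeps a sample iff its maximum class probability strictly exceeds the
#' confidence threshold `kappa`.
#'
#' @param probs matrix with rows on the probability simplex.
#' @param kappa threshold in `[0, 1]`.
#' @return Logical keep mask.
#' @export
filter_by_confidence <- function(probs, kappa) {
  if (kappa < 0 || kappa > 1) stop_input("kappa must lie in [0, 1]")
  apply(as.matrix(probs), 1, max) > kappa
}

#' Decision-level fusion of neuron and KNN predictions
#'
#' @param neuron_probs classifier softmax probabilities (n x classes).
#' @param knn_probs KNN neighbor-frequency probabilities, same shape.
#' @param w fusion weight in `[0, 1]`; the fused row is
#'   `w * neuron + (1 - w) * knn`.
#' @return List with `fused_probs` (rows remain on the simplex) and `labels`
#'   (argmax, 0-based).
#' @export
fuse_decisions <- function(neuron_probs, knn_probs, w = 0.5) {
  neuron_probs <- as.matrix(neuron_probs); knn_probs <- as.matrix(knn_probs)
  if (!all(dim(neuron_probs) == dim(knn_probs)))
    stop_input("probability matrices differ in shape")
  if (w < 0 || w > 1) stop_input("w must lie in [0, 1]")
  fused <- w * neuron_probs + (1 - w) * knn_probs
  list(fused_probs = fused, labels = max.col(fused, ties.method = "first") - 1L)
}

#' Generate, fuse and filter pseudo-labels for a target dataset
#'
#' Composes the three stages: neuron probabilities from `C(G(x_t))`, KNN
#' probabilities in the G-feature space against the labeled source samples,
#' decision-level fusion with weight `w`, and kappa-filtering on the fused
#' confidence (the fused prediction is the final one, so its confidence is
#' what the threshold guards). Evaluation mode; no parameters are updated.
#'
#' @param bundle a [model_bundle()].
#' @param source_ds labeled source [spectral_dataset()] (or list with `X`,`y`).
#' @param target_ds target [spectral_dataset()] (labels ignored/absent).
#' @param K KNN neighbors (default 5).
#' @param kappa confidence threshold (default 0.9).
#' @param w fusion weight (default 0.5).
#' @return An object of class `pseudo_label_set`: `labels`, `confidence`,
#'   `keep_mask`, `components` (neuron/knn probs and `w`), and a warning
#'   flag `all_filtered` when nothing survives the threshold.
#' @export
generate_pseudo_labels <- function(bundle, source_ds, target_ds, K = 5L,
                                   kappa = 0.9, w = 0.5) {
  fs <- forward_eval(bundle, source_ds$X)
  ft <- forward_eval(bundle, target_ds$X)
  pseudo_label_set_from_features(ft$features, ft$probs, fs$features,
                                 source_ds$y, K, kappa, w,
                                 n_classes = bundle$n_classes)
}

# Core pseudo-label composition on precomputed features/probabilities.
pseudo_label_set_from_features <- function(target_features, neuron_probs,
                                           source_features, source_labels,
                                           K, kappa, w, n_classes) {
  knn <- knn_pseudo_labels(target_features, source_features, source_labels,
                           K, n_classes)
  fus <- fuse_decisions(neuron_probs, knn$knn_probs, w)
  keep <- filter_by_confidence(fus$fused_probs, kappa)
  structure(list(labels = fus$labels,
                 confidence = apply(fus$fused_probs, 1, max),
                 keep_mask = keep,
                 components = list(neuron_probs = neuron_probs,
                                   knn_probs = knn$knn_probs,
                                   fusion_weight = w),
                 all_filtered = !any(keep)),
            class = "pseudo_label_set")
}

#' @export
print.pseudo_label_set <- function(x, ...) {
  cat(sprintf("<pseudo_label_set> %d samples, %d kept (%.1f%%)%s\n",
              length(x$labels), sum(x$keep_mask),
              100 * mean(x$keep_mask),
              if (x$all_filtered) " [all filtered]" else ""))
  invisible(x)
}

#' Dump a pseudo-label audit table
#'
#' One row per target sample: neuron, KNN and fused label, fused confidence
#' and keep flag.
#'
#' @param pls a `pseudo_label_set`.
#' @param sample_ids optional ids.
#' @param path optional CSV path; when given the table is also written.
#' @return The audit `data.frame`, invisibly when written.
#' @export
pseudo_label_audit <- function(pls, sample_ids = NULL, path = NULL) {
  tab <- data.frame(
    sample_id = sample_ids %||% seq_along(pls$labels),
    neuron_label = max.col(pls$components$neuron_probs,
                           ties.method = "first") - 1L,
    knn_label = max.col(pls$components$knn_probs, ties.method = "first") - 1L,
    fused_label = pls$labels,
    confidence = pls$confidence,
    kept = pls$keep_mask)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
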