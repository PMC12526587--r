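# Exact t-SNE on a feature matrix. Standard formulation: per-point
# bandwidths fixed by a binary search on the perplexity, symmetrized input
# affinities, Student-t low-dimensional kernel, gradient descent with
# momentum and early exaggeration. Exact (O(n^2)) is fine at the sample
# counts this package works with (hundreds to ~1-2k).
tsne_embed <- function(X, dims = 2L, perplexity = 30, max_iter = 1000L,
                       seed = 1L, eta = 100, momentum = c(0.5, 0.8),
                       exaggeration = 4, exaggeration_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop_input("t-SNE needs at least 4 samples")
  perplexity <- min(perplexity, (n - 1) / 3)
  sq <- rowSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  D2[D2 < 0] <- 0; diag(D2) <- 0
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(H - target) < 1e-5) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  with_seed(seed, {
    Y <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
    dY <- matrix(0, n, dims)
    gains <- matrix(1, n, dims)
    for (iter in seq_len(max_iter)) {
      Pe <- if (iter <= exaggeration_iter) P * exaggeration else P
      sqy <- rowSums(Y^2)
      num <- 1 / (1 + outer(sqy, sqy, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- num / sum(num)
      Q[Q < 1e-12] <- 1e-12
      L <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (iter <= 250) momentum[1] else momentum[2]
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- mom * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

# Mean silhouette width of a labeling over a squared-distance-free feature
# matrix; uses cluster::silhouette when available, else a direct computation.
silhouette_score <- function(X, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L) return(NA_real_)
  d <- dist(X)
  if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(labels, d)
    return(mean(sil[, "sil_width"]))
  }
  Dm <- as.matrix(d)
  n <- nrow(Dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(Dm[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(Dm[i, labels == cl]), numeric(1)))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Export a 2-D t-SNE embedding of the learned feature space
#'
#' Embeds the G-features of all source and target samples (train and test)
#' into 2-D and tags every row with its domain, split and class (target
#' classes come from the sealed labels and are used for visualization and
#' the alignment score only). Also computes a cluster-agreement diagnostic:
#' the mean silhouette of the class labeling versus that of the domain
#' labeling on the pooled features — after successful adaptation classes
#' should separate more than domains.
#'
#' @param bundle a trained [model_bundle()].
#' @param pair the [domain_pair()] the bundle was trained on.
#' @param path optional CSV output path for the embedding table.
#' @param perplexity,max_iter,seed t-SNE settings (defaults 30 / 1000 / 1).
#' @return List with the embedding `table` (data.frame: `tsne1`, `tsne2`,
#'   `domain`, `split`, `class`) and the `silhouette` list
#'   (`class`, `domain`).
#' @export
tsne_export <- function(bundle, pair, path = NULL, perplexity = 30,
                        max_iter = 1000L, seed = 1L) {
  parts <- list(
    list(ds = pair$source_train, split = "train", y = pair$source_train$y),
    list(ds = pair$source_test, split = "test", y = pair$source_test$y),
    list(ds = pair$target_train, split = "train", y = pair$sealed$train),
    list(ds = pair$target_test, split = "test", y = pair$sealed$test))
  feats <- lapply(parts, function(p) predict(bundle, p$ds)$features)
  X <- do.call(rbind, feats)
  domain <- unlist(lapply(parts, function(p) rep(p$ds$domain, nrow(p$ds$X))))
  split <- unlist(lapply(parts, function(p) rep(p$split, nrow(p$ds$X))))
  y <- unlist(lapply(parts, function(p) p$y))
  Y <- tsne_embed(X, perplexity = perplexity, max_iter = max_iter, seed = seed)
  tab <- data.frame(tsne1 = Y[, 1], tsne2 = Y[, 2], domain = domain,
                    split = split, class = y)
  sil <- list(class = silhouette_score(X, y),
              domain = silhouette_score(X, domain))
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  list(table = tab, silhouette = sil)
}
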