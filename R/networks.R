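#' Network configuration for the dual-branch feature extractor
#'
#' The extractor G has two branches: (i) a token branch — linear patch
#' embedding of the spectrum plus a learned positional embedding, followed by
#' post-norm self-attention encoder layers — and (ii) a multi-scale
#' convolution branch — parallel 1-D convolutions at three (or more) kernel
#' widths, ReLU, global average pooling. The branch outputs are concatenated
#' and fused by one fully connected layer with ReLU and LayerNorm into the
#' shared feature space of dimension `feature_dim`.
#'
#' @param input_len spectrum length the network accepts.
#' @param patch,stride patch embedding window and hop (defaults 16/16).
#' @param d_model token width (default 64); must be divisible by `n_heads`.
#' @param n_heads attention heads (default 4).
#' @param n_layers encoder layers (default 2).
#' @param ffn_dim encoder feed-forward width (default 128).
#' @param conv_kernels kernel widths of the parallel convolutions
#'   (default `c(3, 7, 15)`; at least 3 scales).
#' @param conv_channels channels per kernel scale (default 16).
#' @param conv_stride hop of the convolutions (default 1).
#' @param feature_dim fused feature dimension (default 64).
#' @param disc_hidden discriminator hidden width (default 128).
#' @param dropout discriminator dropout rate (default 0.5).
#' @return A config list (class `net_config`).
#' @export
net_config <- function(input_len, patch = 16L, stride = 16L, d_model = 64L,
                       n_heads = 4L, n_layers = 2L, ffn_dim = 128L,
                       conv_kernels = c(3L, 7L, 15L), conv_channels = 16L,
                       conv_stride = 1L, feature_dim = 64L,
                       disc_hidden = 128L, dropout = 0.5) {
  if (d_model %% n_heads != 0)
    stop_input("d_model (%d) must be divisible by n_heads (%d)",
               d_model, n_heads)
  if (input_len < max(conv_kernels))
    stop_input("input_len (%d) is below the largest conv kernel (%d)",
               input_len, max(conv_kernels))
  if (input_len < patch)
    stop_input("input_len (%d) is below the patch size (%d)", input_len, patch)
  if (length(conv_kernels) < 3L)
    stop_input("the multi-scale branch needs >= 3 kernel scales")
  n_tokens <- (input_len - patch) %/% stride + 1L
  structure(list(input_len = as.integer(input_len), patch = as.integer(patch),
                 stride = as.integer(stride), d_model = as.integer(d_model),
                 n_heads = as.integer(n_heads), n_layers = as.integer(n_layers),
                 ffn_dim = as.integer(ffn_dim),
                 conv_kernels = as.integer(conv_kernels),
                 conv_channels = as.integer(conv_channels),
                 conv_stride = as.integer(conv_stride),
                 feature_dim = as.integer(feature_dim),
                 disc_hidden = as.integer(disc_hidden), dropout = dropout,
                 n_tokens = n_tokens),
            class = "net_config")
}

#' Build the dual-branch feature extractor G
#'
#' @param input_len spectrum length.
#' @param feature_dim fused feature dimension.
#' @param config optional [net_config()]; built from the defaults otherwise.
#' @return Parameter list for G (class `feature_extractor`).
#' @export
build_feature_extractor <- function(input_len, feature_dim = 64L,
                                    config = NULL) {
  cfg <- config %||% net_config(input_len, feature_dim = feature_dim)
  if (cfg$input_len != input_len)
    stop_input("config input_len (%d) != input_len (%d)", cfg$input_len,
               input_len)
  d <- cfg$d_model
  layers <- lapply(seq_len(cfg$n_layers), function(l) list(
    Wq = xavier_mat(d, d), bq = numeric(d),
    Wk = xavier_mat(d, d), bk = numeric(d),
    Wv = xavier_mat(d, d), bv = numeric(d),
    Wo = xavier_mat(d, d), bo = numeric(d),
    g1 = rep(1, d), b1n = numeric(d),
    W1 = xavier_mat(d, cfg$ffn_dim), b1 = numeric(cfg$ffn_dim),
    W2 = xavier_mat(cfg$ffn_dim, d), b2 = numeric(d),
    g2 = rep(1, d), b2n = numeric(d)))
  conv <- lapply(cfg$conv_kernels, function(k) list(
    W = xavier_mat(k, cfg$conv_channels), b = numeric(cfg$conv_channels)))
  fuse_in <- d + length(cfg$conv_kernels) * cfg$conv_channels
  params <- list(
    patch = list(W = xavier_mat(cfg$patch, d), b = numeric(d)),
    pos = xavier_mat(cfg$n_tokens, d),
    layers = layers,
    conv = conv,
    fusion = list(W = xavier_mat(fuse_in, cfg$feature_dim),
                  b = numeric(cfg$feature_dim),
                  g = rep(1, cfg$feature_dim),
                  bn = numeric(cfg$feature_dim)))
  structure(list(params = params, config = cfg), class = "feature_extractor")
}

#' Build the class classifier C
#'
#' A single linear layer with softmax output; this is also the FC prediction
#' head the pseudo-label generator reads.
#'
#' @param feature_dim feature dimension.
#' @param n_classes number of classes (>= 2).
#' @return Parameter list (class `classifier`).
#' @export
build_classifier <- function(feature_dim, n_classes) {
  if (feature_dim <= 0 || n_classes < 2)
    stop_input("feature_dim must be > 0 and n_classes >= 2")
  structure(list(params = list(W = xavier_mat(feature_dim, n_classes),
                               b = numeric(n_classes)),
                 feature_dim = as.integer(feature_dim),
                 n_classes = as.integer(n_classes)),
            class = "classifier")
}

#' Build the conditional domain discriminator D
#'
#' Two ReLU hidden layers with dropout and a sigmoid output; consumes the
#' multilinear map phi(f, g) of dimension `feature_dim * n_classes`.
#'
#' @param input_dim `feature_dim * n_classes`.
#' @param hidden hidden width (default 128).
#' @param dropout dropout rate (default 0.5).
#' @return Parameter list (class `discriminator`).
#' @export
build_discriminator <- function(input_dim, hidden = 128L, dropout = 0.5) {
  if (input_dim <= 0) stop_input("input_dim must be > 0")
  structure(list(params = list(W1 = xavier_mat(input_dim, hidden),
                               b1 = numeric(hidden),
                               W2 = xavier_mat(hidden, hidden),
                               b2 = numeric(hidden),
                               W3 = xavier_mat(hidden, 1L), b3 = numeric(1L)),
                 input_dim = as.integer(input_dim), dropout = dropout),
            class = "discriminator")
}

#' Bundle the three trainable components
#'
#' @param input_len spectrum length the bundle accepts.
#' @param n_classes number of classes.
#' @param config optional [net_config()].
#' @param seed Xavier initialization seed.
#' @return An object of class `model_bundle` holding G, C and D.
#' @export
model_bundle <- function(input_len, n_classes = 2L, config = NULL, seed = 1L) {
  cfg <- config %||% net_config(input_len)
  bundle <- with_seed(seed, {
    G <- build_feature_extractor(input_len, cfg$feature_dim, cfg)
    C <- build_classifier(cfg$feature_dim, n_classes)
    D <- build_discriminator(cfg$feature_dim * n_classes, cfg$disc_hidden,
                             cfg$dropout)
    structure(list(G = G, C = C, D = D, config = cfg,
                   n_classes = as.integer(n_classes), seed = as.integer(seed)),
              class = "model_bundle")
  })
  xavier_init(bundle, seed)
}

#' @export
print.model_bundle <- function(x, ...) {
  np <- length(flatten_params(list(x$G$params, x$C$params, x$D$params)))
  cat(sprintf(paste0("<model_bundle> input %d, %d classes, feature_dim %d, ",
                     "%d parameters\n"),
              x$config$input_len, x$n_classes, x$config$feature_dim, np))
  invisible(x)
}

#' Re-draw all weights by the Xavier/Glorot scheme
#'
#' Weight matrices (and the positional embedding) are re-drawn uniformly on
#' `[-sqrt(6/(fan_in+fan_out)), +...]`; biases are set to zero and LayerNorm
#' gains to one. Deterministic under `seed`.
#'
#' @param bundle a [model_bundle()].
#' @param seed integer seed.
#' @return The re-initialized bundle.
#' @export
xavier_init <- function(bundle, seed = 1L) {
  redraw <- function(p) {
    if (is.list(p)) {
      for (nm in names(p)) {
        if (is.list(p[[nm]]) && is.null(names(p[[nm]]))) {
          p[[nm]] <- lapply(p[[nm]], redraw)
        } else if (is.list(p[[nm]])) {
          p[[nm]] <- redraw(p[[nm]])
        } else if (nm == "pos" || startsWith(nm, "W")) {
          p[[nm]] <- xavier_mat(nrow(p[[nm]]), ncol(p[[nm]]))
        } else if (startsWith(nm, "g")) {
          p[[nm]] <- rep(1, length(p[[nm]]))
        } else {
          p[[nm]] <- p[[nm]] * 0
        }
      }
    }
    p
  }
  with_seed(seed, {
    bundle$G$params <- redraw(bundle$G$params)
    bundle$C$params <- redraw(bundle$C$params)
    bundle$D$params <- redraw(bundle$D$params)
  })
  bundle$seed <- as.integer(seed)
  bundle
}

# --- G forward / backward ----------------------------------------------

# Multi-head self-attention on sample-major token rows; the per-sample,
# per-head block attention itself runs in the compiled kernel.
mhsa_fwd <- function(H, lp, B, T, n_heads) {
  Q <- add_bias(H %*% lp$Wq, lp$bq)
  K <- add_bias(H %*% lp$Wk, lp$bk)
  V <- add_bias(H %*% lp$Wv, lp$bv)
  kr <- .attn_fwd_cpp(Q, K, V, B, T, n_heads)
  out <- add_bias(kr$O %*% lp$Wo, lp$bo)
  list(out = out, Q = Q, K = K, V = V, O = kr$O, A = kr$A, H = H)
}

mhsa_bwd <- function(cache, lp, dout, B, T, n_heads) {
  dWo <- crossprod(cache$O, dout); dbo <- colSums(dout)
  dO <- tcrossprod(dout, lp$Wo)
  kr <- .attn_bwd_cpp(cache$Q, cache$K, cache$V, cache$A, dO, B, T, n_heads)
  H <- cache$H
  dH <- tcrossprod(kr$dQ, lp$Wq) + tcrossprod(kr$dK, lp$Wk) +
    tcrossprod(kr$dV, lp$Wv)
  list(dH = dH,
       grads = list(Wq = crossprod(H, kr$dQ), bq = colSums(kr$dQ),
                    Wk = crossprod(H, kr$dK), bk = colSums(kr$dK),
                    Wv = crossprod(H, kr$dV), bv = colSums(kr$dV),
                    Wo = dWo, bo = dbo))
}

#' Forward pass of the feature extractor
#'
#' @param G a `feature_extractor`.
#' @param X batch matrix (samples x input_len) in `[0, 1]`.
#' @param keep_cache keep intermediates for a backward pass / Grad-CAM.
#' @return List with `features` (batch x feature_dim) and, when requested,
#'   `cache`.
#' @export
G_forward <- function(G, X, keep_cache = FALSE) {
  cfg <- G$config; p <- G$params
  X <- as.matrix(X)
  if (ncol(X) != cfg$input_len)
    stop_input("input length %d != configured %d", ncol(X), cfg$input_len)
  B <- nrow(X); T <- cfg$n_tokens
  # token branch
  pidx <- window_index(cfg$input_len, cfg$patch, cfg$stride)
  Pm <- gather_windows(X, pidx)                       # (B*T) x patch
  H <- add_bias(Pm %*% p$patch$W, p$patch$b) +
    p$pos[rep(seq_len(T), B), , drop = FALSE]
  layer_caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lp <- p$layers[[l]]
    att <- mhsa_fwd(H, lp, B, T, cfg$n_heads)
    R1 <- H + att$out
    ln1 <- layernorm_fwd(R1, lp$g1, lp$b1n)
    Z1 <- add_bias(ln1$out %*% lp$W1, lp$b1)
    A1 <- relu(Z1)
    F1 <- add_bias(A1 %*% lp$W2, lp$b2)
    R2 <- ln1$out + F1
    ln2 <- layernorm_fwd(R2, lp$g2, lp$b2n)
    layer_caches[[l]] <- list(att = att, ln1 = ln1, Z1 = Z1, A1 = A1,
                              ln2 = ln2)
    H <- ln2$out
  }
  tok <- rowsum(H, rep(seq_len(B), each = T)) / T     # B x d_model
  # conv branch
  conv_caches <- vector("list", length(cfg$conv_kernels))
  gaps <- vector("list", length(cfg$conv_kernels))
  for (j in seq_along(cfg$conv_kernels)) {
    k <- cfg$conv_kernels[j]
    cidx <- window_index(cfg$input_len, k, cfg$conv_stride %||% 1L)
    Xc <- gather_windows(X, cidx)                     # (B*P) x k
    Zc <- add_bias(Xc %*% p$conv[[j]]$W, p$conv[[j]]$b)
    Ac <- relu(Zc)
    Pk <- nrow(cidx)
    gaps[[j]] <- rowsum(Ac, rep(seq_len(B), each = Pk)) / Pk
    conv_caches[[j]] <- list(Xc = Xc, Zc = Zc, Ac = Ac, P = Pk)
  }
  Zcat <- cbind(tok, do.call(cbind, gaps))
  Zf <- add_bias(Zcat %*% p$fusion$W, p$fusion$b)
  Af <- relu(Zf)
  lnf <- layernorm_fwd(Af, p$fusion$g, p$fusion$bn)
  out <- list(features = lnf$out)
  if (keep_cache)
    out$cache <- list(B = B, T = T, Pm = Pm, layer_caches = layer_caches,
                      H_final = H, conv_caches = conv_caches, Zcat = Zcat,
                      Zf = Zf, lnf = lnf)
  out
}

#' Backward pass of the feature extractor
#'
#' @param G a `feature_extractor`.
#' @param cache cache from [G_forward()] with `keep_cache = TRUE`.
#' @param dF gradient of the loss w.r.t. the features.
#' @return Gradient list shaped like `G$params`.
#' @export
G_backward <- function(G, cache, dF) {
  cfg <- G$config; p <- G$params
  B <- cache$B; T <- cache$T
  lb <- layernorm_bwd(cache$lnf, dF)
  dAf <- lb$dX
  dZf <- dAf * (cache$Zf > 0)
  gW_f <- crossprod(cache$Zcat, dZf)
  gb_f <- colSums(dZf)
  dZcat <- tcrossprod(dZf, p$fusion$W)
  d <- cfg$d_model
  dtok <- dZcat[, seq_len(d), drop = FALSE]
  # conv branch
  conv_grads <- vector("list", length(cfg$conv_kernels))
  off <- d
  for (j in seq_along(cfg$conv_kernels)) {
    ch <- cfg$conv_channels
    dgap <- dZcat[, (off + 1L):(off + ch), drop = FALSE]
    off <- off + ch
    cc <- cache$conv_caches[[j]]
    dAc <- dgap[rep(seq_len(B), each = cc$P), , drop = FALSE] / cc$P
    dZc <- dAc * (cc$Zc > 0)
    conv_grads[[j]] <- list(W = crossprod(cc$Xc, dZc), b = colSums(dZc))
  }
  # token branch
  dH <- dtok[rep(seq_len(B), each = T), , drop = FALSE] / T
  layer_grads <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- p$layers[[l]]; lc <- cache$layer_caches[[l]]
    l2 <- layernorm_bwd(lc$ln2, dH)
    dR2 <- l2$dX
    dF1 <- dR2
    gW2 <- crossprod(lc$A1, dF1); gb2 <- colSums(dF1)
    dA1 <- tcrossprod(dF1, lp$W2)
    dZ1 <- dA1 * (lc$Z1 > 0)
    gW1 <- crossprod(lc$ln1$out, dZ1); gb1 <- colSums(dZ1)
    dN1 <- dR2 + tcrossprod(dZ1, lp$W1)
    l1 <- layernorm_bwd(lc$ln1, dN1)
    dR1 <- l1$dX
    mb <- mhsa_bwd(lc$att, lp, dR1, B, T, cfg$n_heads)
    dH <- dR1 + mb$dH
    layer_grads[[l]] <- c(mb$grads,
                          list(g1 = l1$dg, b1n = l1$db,
                               W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                               g2 = l2$dg, b2n = l2$db))
  }
  dpos <- rowsum(dH, rep(seq_len(T), B))
  list(patch = list(W = crossprod(cache$Pm, dH), b = colSums(dH)),
       pos = dpos,
       layers = layer_grads,
       conv = conv_grads,
       fusion = list(W = gW_f, b = gb_f, g = lb$dg, bn = lb$db))
}

# --- classifier ---------------------------------------------------------

#' Classifier forward pass
#'
#' @param C a `classifier`.
#' @param F feature matrix (batch x feature_dim).
#' @return List with `logits` and softmax `probs` (rows on the simplex).
#' @export
C_forward <- function(C, F) {
  logits <- add_bias(F %*% C$params$W, C$params$b)
  list(logits = logits, probs = softmax_rows(logits))
}

# Backward from a gradient on the logits; returns C grads + feature grad.
C_backward <- function(C, F, dlogits) {
  list(grads = list(W = crossprod(F, dlogits), b = colSums(dlogits)),
       dF = tcrossprod(dlogits, C$params$W))
}

# Gradient on logits of mean softmax cross-entropy toward labels y (0-based),
# i.e. d/dlogits of -mean(log p_y): (p - onehot(y)) / n.
ce_dlogits <- function(probs, y) {
  n <- nrow(probs)
  dl <- probs
  dl[cbind(seq_len(n), y + 1L)] <- dl[cbind(seq_len(n), y + 1L)] - 1
  dl / n
}

# --- discriminator ------------------------------------------------------

#' Discriminator forward pass
#'
#' @param D a `discriminator`.
#' @param Phi multilinear-map matrix (batch x input_dim).
#' @param train apply dropout (draws from the current RNG stream).
#' @return List with `out` (domain probabilities in (0,1)) and `cache`.
#' @export
D_forward <- function(D, Phi, train = FALSE) {
  p <- D$params
  Z1 <- add_bias(Phi %*% p$W1, p$b1); A1 <- relu(Z1)
  m1 <- NULL; m2 <- NULL
  if (train && D$dropout > 0) {
    m1 <- matrix(runif(length(A1)) >= D$dropout, nrow(A1), ncol(A1)) /
      (1 - D$dropout)
    A1 <- A1 * m1
  }
  Z2 <- add_bias(A1 %*% p$W2, p$b2); A2 <- relu(Z2)
  if (train && D$dropout > 0) {
    m2 <- matrix(runif(length(A2)) >= D$dropout, nrow(A2), ncol(A2)) /
      (1 - D$dropout)
    A2 <- A2 * m2
  }
  out <- drop(sigmoid(add_bias(A2 %*% p$W3, p$b3)))
  list(out = out,
       cache = list(Phi = Phi, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
                    m1 = m1, m2 = m2, out = out))
}

# Backward from gradient on the sigmoid output; returns D grads + dPhi.
D_backward <- function(D, cache, dout) {
  p <- D$params
  s <- cache$out
  dz3 <- matrix(dout * s * (1 - s), ncol = 1L)
  gW3 <- crossprod(cache$A2, dz3); gb3 <- colSums(dz3)
  dA2 <- dz3 %*% t(p$W3)
  if (!is.null(cache$m2)) dA2 <- dA2 * cache$m2
  dZ2 <- dA2 * (cache$Z2 > 0)
  gW2 <- crossprod(cache$A1, dZ2); gb2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, p$W2)
  if (!is.null(cache$m1)) dA1 <- dA1 * cache$m1
  dZ1 <- dA1 * (cache$Z1 > 0)
  list(grads = list(W1 = crossprod(cache$Phi, dZ1), b1 = colSums(dZ1),
                    W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3),
       dPhi = tcrossprod(dZ1, p$W1))
}

# Chunked evaluation-mode forward of C(G(x)); no caches, no dropout.
forward_eval <- function(bundle, X, chunk = 64L) {
  n <- nrow(X)
  feats <- matrix(0, n, bundle$config$feature_dim)
  probs <- matrix(0, n, bundle$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    f <- G_forward(bundle$G, X[idx, , drop = FALSE])$features
    feats[idx, ] <- f
    probs[idx, ] <- C_forward(bundle$C, f)$probs
  }
  list(features = feats, probs = probs)
}

#' Predict class probabilities and labels
#'
#' @param object a [model_bundle()].
#' @param newdata matrix of spectra or a [spectral_dataset()].
#' @param ... unused.
#' @return List with `probs` (n x classes), `labels` (0-based codes) and
#'   `features`.
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectral_dataset")) newdata$X else
    as.matrix(newdata)
  fw <- forward_eval(object, X)
  list(probs = fw$probs, labels = max.col(fw$probs) - 1L,
       features = fw$features)
}
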