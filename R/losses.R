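# Probability clamp keeping every log() in the objectives finite.
.prob_eps <- 1e-7
clamp_prob <- function(p) pmin(pmax(p, .prob_eps), 1 - .prob_eps)

#' Multilinear conditioning map phi(f, g) = f (x) g
#'
#' Row i of the result is the flattened outer product of feature row `f_i`
#' with probability row `g_i`; entry `(a, b)` of the outer product sits at
#' flat column `a + (b - 1) * d`. This is the conditioning vector the domain
#' discriminator consumes, of dimension `feature_dim * n_classes`.
#'
#' @param f feature matrix (batch x d).
#' @param g probability matrix (batch x c).
#' @return Matrix (batch x d*c).
#' @export
multilinear_map <- function(f, g) {
  f <- as.matrix(f); g <- as.matrix(g)
  if (nrow(f) != nrow(g)) stop_input("batch sizes differ (%d vs %d)",
                                     nrow(f), nrow(g))
  d <- ncol(f); c <- ncol(g)
  f[, rep(seq_len(d), c), drop = FALSE] *
    g[, rep(seq_len(c), each = d), drop = FALSE]
}

# Pull a gradient on phi back to the feature rows (g held fixed/detached).
multilinear_map_df <- function(dPhi, g) {
  d <- ncol(dPhi) / ncol(g)
  df <- matrix(0, nrow(dPhi), d)
  for (b in seq_len(ncol(g)))
    df <- df + dPhi[, ((b - 1) * d + 1):(b * d), drop = FALSE] * g[, b]
  df
}

#' Conditional adversarial loss
#'
#' `L_adv = -mean_s log(1 - D(phi(f_s, p_s))) - mean_t log(D(phi(f_t, p_t)))`.
#' Under this sign convention the discriminator minimizes `L_adv` (pushing
#' source outputs to 0 and target outputs to 1) while the feature extractor
#' maximizes it through gradient reversal. Discriminator outputs are clamped
#' away from 0/1 so the loss stays finite on saturated batches.
#'
#' @param D a `discriminator`.
#' @param G_feats_s,probs_s source features and class probabilities.
#' @param G_feats_t,probs_t target features and class probabilities.
#' @return The scalar loss.
#' @export
adversarial_loss <- function(D, G_feats_s, probs_s, G_feats_t, probs_t) {
  adv <- adversarial_forward(D, G_feats_s, probs_s, G_feats_t, probs_t,
                             train = FALSE)
  adv$value
}

# Forward + everything needed for both sides of the adversarial game.
adversarial_forward <- function(D, fs, ps, ft, pt, train = FALSE) {
  Phi_s <- multilinear_map(fs, ps)
  Phi_t <- multilinear_map(ft, pt)
  fw <- D_forward(D, rbind(Phi_s, Phi_t), train = train)
  ns <- nrow(Phi_s); nt <- nrow(Phi_t)
  ds <- clamp_prob(fw$out[seq_len(ns)])
  dt <- clamp_prob(fw$out[ns + seq_len(nt)])
  value <- -mean(log(1 - ds)) - mean(log(dt))
  list(value = value, fw = fw, ds = ds, dt = dt, ns = ns, nt = nt,
       ps = ps, pt = pt)
}

# Gradients of L_adv for the discriminator (to minimize) and the feature
# rows (raw dL/df; the trainer applies the reversal sign).
adversarial_grads <- function(D, adv) {
  dout <- c(1 / ((1 - adv$ds) * adv$ns), -1 / (adv$dt * adv$nt))
  bk <- D_backward(D, adv$fw$cache, dout)
  dPhi_s <- bk$dPhi[seq_len(adv$ns), , drop = FALSE]
  dPhi_t <- bk$dPhi[adv$ns + seq_len(adv$nt), , drop = FALSE]
  list(D_grads = bk$grads,
       dfs = multilinear_map_df(dPhi_s, adv$ps),
       dft = multilinear_map_df(dPhi_t, adv$pt),
       dPhi_s = dPhi_s, dPhi_t = dPhi_t)
}

# Pull a gradient on phi back to the conditioning probability rows.
multilinear_map_dg <- function(dPhi, f) {
  d <- ncol(f); c <- ncol(dPhi) / d
  dg <- matrix(0, nrow(dPhi), c)
  for (b in seq_len(c))
    dg[, b] <- rowSums(dPhi[, ((b - 1) * d + 1):(b * d), drop = FALSE] * f)
  dg
}

#' Source classification loss
#'
#' Mean negative log-likelihood of the true source labels under `C(G(x))`.
#'
#' @param C a `classifier`.
#' @param G a `feature_extractor`.
#' @param source_batch labeled [spectral_dataset()] (or list with `X`, `y`).
#' @return The scalar loss.
#' @export
classification_loss <- function(C, G, source_batch) {
  f <- G_forward(G, source_batch$X)$features
  cross_entropy(C_forward(C, f)$probs, source_batch$y)
}

#' Pseudo-label cross-entropy loss
#'
#' Mean negative log-likelihood of the kept pseudo-labels under `C(G(x))`,
#' computed over the confidence-filtered target samples.
#'
#' @param C a `classifier`.
#' @param G a `feature_extractor`.
#' @param kept_target_batch [spectral_dataset()] (or list with `X`) holding
#'   only the kept rows.
#' @param pseudo_labels 0-based pseudo-label codes for those rows.
#' @return The scalar loss; `0` with attribute `skipped = TRUE` on an empty
#'   kept set.
#' @export
pseudo_ce_loss <- function(C, G, kept_target_batch, pseudo_labels) {
  if (length(pseudo_labels) == 0L || nrow(kept_target_batch$X) == 0L)
    return(structure(0, skipped = TRUE))
  f <- G_forward(G, kept_target_batch$X)$features
  cross_entropy(C_forward(C, f)$probs, pseudo_labels)
}

# Mean CE of 0-based labels under probability rows.
cross_entropy <- function(probs, y) {
  if (any(y >= ncol(probs)))
    stop_input("label code %d out of range for %d classes", max(y),
               ncol(probs))
  -mean(log(clamp_prob(probs[cbind(seq_len(nrow(probs)), y + 1L)])))
}

#' Metric-constraint (MC) loss and its normalization coefficient
#'
#' Fisher-style pairwise-distance ratio penalty. With squared Euclidean
#' distances `d_uv` over ordered pairs `u != v`, the normalization
#' coefficient is `T_m = (1/B) * sum_uv d_uv` (the printed literal form;
#' `tm_mode = "pairmean"` uses the pair-count mean instead, which only
#' rescales `T_m`), and
#' `L_MC = log( sum_{y_u != y_v} exp(-d_uv/T_m) /
#'              sum_{y_u = y_v, u != v} exp(-d_uv/T_m) )`.
#' The loss falls as classes separate and same-class points tighten; it is
#' invariant to translation, rotation and global scaling of the features.
#'
#' @param features matrix (batch x d).
#' @param labels 0-based class codes.
#' @param tm_mode `"literal"` (default) or `"pairmean"`.
#' @return List with `L_MC`, `T_m` and `skipped` (TRUE when the batch has no
#'   cross-class or no same-class pair, in which case `L_MC = 0` and the
#'   term is omitted from that step).
#' @export
mc_loss <- function(features, labels, tm_mode = c("literal", "pairmean")) {
  mc_loss_internal(as.matrix(features), as.integer(labels),
                   match.arg(tm_mode), want_grad = FALSE)
}

mc_loss_internal <- function(F, y, tm_mode = "literal", want_grad = TRUE) {
  B <- nrow(F)
  skip <- function() list(L_MC = 0, T_m = NA_real_, skipped = TRUE,
                          dF = if (want_grad) F * 0 else NULL)
  if (B < 2L) return(skip())
  same <- outer(y, y, `==`); diag(same) <- NA   # NA marks u == v
  if (!any(same == FALSE, na.rm = TRUE) || !any(same == TRUE, na.rm = TRUE))
    return(skip())
  sq <- rowSums(F^2)
  D2 <- outer(sq, sq, `+`) - 2 * tcrossprod(F)
  D2[D2 < 0] <- 0; diag(D2) <- 0
  npairs <- B * (B - 1)
  a <- if (tm_mode == "literal") 1 / B else 1 / npairs
  T_m <- a * sum(D2)
  if (T_m <= 0) return(skip())
  S <- exp(-D2 / T_m)
  diff_mask <- !same & !is.na(same)
  same_mask <- same & !is.na(same)
  S_diff <- sum(S[diff_mask]); S_same <- sum(S[same_mask])
  L <- log(S_diff) - log(S_same)
  out <- list(L_MC = L, T_m = T_m, skipped = FALSE)
  if (want_grad) {
    Cm <- matrix(0, B, B)
    Cm[diff_mask] <- 1 / S_diff
    Cm[same_mask] <- -1 / S_same
    M <- sum(Cm * S * D2) / T_m^2
    Gm <- -Cm * S / T_m + a * M
    diag(Gm) <- 0
    out$dF <- 4 * (F * rowSums(Gm) - Gm %*% F)
  }
  out
}

#' Loss report for one training step
#'
#' @param L_cls,L_CE,L_adv,L_MC component losses.
#' @param T_m MC normalization coefficient.
#' @param lambda adversarial/MC trade-off weight.
#' @param B_m source batch size.
#' @return An object of class `loss_report` including the `combined` scalar.
#' @export
loss_report <- function(L_cls = 0, L_CE = 0, L_adv = 0, L_MC = 0,
                        T_m = NA_real_, lambda = 1, B_m = NA_integer_) {
  rep <- list(L_cls = L_cls, L_CE = L_CE, L_adv = L_adv, L_MC = L_MC,
              T_m = T_m, lambda = lambda, B_m = B_m)
  rep$combined <- combined_objective(rep, lambda)
  structure(rep, class = "loss_report")
}

#' Combined min-max objective value
#'
#' The adversarial game is realized with gradient reversal: the
#' discriminator descends `L_adv` while the feature extractor and classifier
#' descend `L_cls + L_CE + lambda * (L_MC - L_adv)`. The reported scalar is
#' `lambda * (L_adv - L_MC) - L_cls - L_CE`, the quantity the G/C side
#' maximizes.
#'
#' @param losses list or `loss_report` with `L_adv`, `L_MC`, `L_cls`, `L_CE`.
#' @param lambda trade-off weight, >= 0.
#' @return Scalar objective value.
#' @export
combined_objective <- function(losses, lambda = 1) {
  if (lambda < 0) stop_input("lambda must be >= 0")
  lambda * (losses$L_adv - losses$L_MC) -
    losses$L_cls - (losses$L_CE %||% 0)
}
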