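#' Training configuration
#'
#' Defaults follow the method's published settings: RMSprop, Xavier
#' initialization, learning rate 1e-5, batch 32, 500 iterations, results
#' averaged over 3 runs. An "iteration" is counted as one epoch — one pass
#' over the balanced source training pool in `ceiling(n / batch)` batches —
#' because at this learning rate RMSprop moves each parameter by at most
#' `lr` per update, so 500 single-batch updates could not move any layer off
#' its initialization scale; `iteration_unit = "step"` keeps the literal
#' single-update reading available.
#'
#' @param iterations training iterations (default 500).
#' @param iteration_unit `"epoch"` (default) or `"step"`.
#' @param batch batch size (default 32).
#' @param lr learning rate (default 1e-5).
#' @param optimizer only `"rmsprop"` is implemented.
#' @param rho,eps RMSprop smoothing constant and stabilizer.
#' @param lambda adversarial/MC trade-off weight (default 1).
#' @param lambda_warmup ramp lambda 0 -> `lambda` over the first 30% of
#'   updates (default FALSE).
#' @param kappa pseudo-label confidence threshold (default 0.9).
#' @param K KNN neighbors for pseudo-labeling (default 5).
#' @param w decision-fusion weight (default 0.5).
#' @param mode `"cdan_pl"` (full method), `"cdan_mc"` (no pseudo-labels;
#'   conditional adversarial net constrained by the MC loss) or
#'   `"source_only"` (supervised source training, no adaptation).
#' @param mc_on_targets include kept pseudo-labeled target samples in the MC
#'   batch alongside the source samples (default TRUE).
#' @param tm_mode MC normalization mode, see [mc_loss()].
#' @param condition_grad propagate adversarial gradients through the
#'   conditioning probabilities as the literal objective prescribes
#'   (default FALSE: the conditioning vector is detached, matching the
#'   reference conditional-adversarial design).
#' @param seed training seed.
#' @param n_runs runs to average in [run_experiment()] (default 3).
#' @param net optional [net_config()]; a default is built from the data.
#' @return An object of class `train_config`.
#' @export
train_config <- function(iterations = 500L, iteration_unit = c("epoch", "step"),
                         batch = 32L, lr = 1e-5, optimizer = "rmsprop",
                         rho = 0.99, eps = 1e-8, lambda = 1,
                         lambda_warmup = FALSE, kappa = 0.9, K = 5L, w = 0.5,
                         mode = c("cdan_pl", "cdan_mc", "source_only"),
                         mc_on_targets = TRUE,
                         tm_mode = c("literal", "pairmean"),
                         condition_grad = FALSE, seed = 1L, n_runs = 3L,
                         net = NULL) {
  if (iterations < 1L || batch < 1L || lr <= 0)
    stop_input("iterations and batch must be positive, lr > 0")
  if (!identical(optimizer, "rmsprop"))
    stop_input("only the rmsprop optimizer is implemented")
  structure(list(iterations = as.integer(iterations),
                 iteration_unit = match.arg(iteration_unit),
                 batch = as.integer(batch), lr = lr, optimizer = optimizer,
                 rho = rho, eps = eps, lambda = lambda,
                 lambda_warmup = isTRUE(lambda_warmup), kappa = kappa,
                 K = as.integer(K), w = w, mode = match.arg(mode),
                 mc_on_targets = isTRUE(mc_on_targets),
                 tm_mode = match.arg(tm_mode),
                 condition_grad = isTRUE(condition_grad),
                 seed = as.integer(seed), n_runs = as.integer(n_runs),
                 net = net),
            class = "train_config")
}

check_finite_loss <- function(value, component, step) {
  if (!all(is.finite(value)))
    stop(sprintf("non-finite %s loss at update %d; aborting training",
                 component, step), call. = FALSE)
  value
}

# Softmax backward: gradient on logits from a gradient on the probabilities.
softmax_bwd <- function(P, dP) P * (dP - rowSums(dP * P))

#' Train a model on a transfer task
#'
#' Runs the adversarial training loop: per update, a source batch and an
#' independently sampled target batch pass through G and C; the conditional
#' discriminator D descends the adversarial loss on the multilinear vectors
#' while G (and C) descend `L_cls + L_CE + lambda * (L_MC - L_adv)` via
#' gradient reversal, all under RMSprop. Pseudo-labels are regenerated at
#' every epoch from the current model over the full training pools,
#' kappa-filtered, and consumed by the cross-entropy and (optionally) MC
#' terms. `mode = "source_only"` trains only the supervised source loss;
#' `mode = "cdan_mc"` drops the pseudo-label path.
#'
#' @param pair a preprocessed [domain_pair()].
#' @param cfg a [train_config()].
#' @param bundle optional pre-built [model_bundle()]; otherwise built from
#'   `cfg$net` (or defaults) and Xavier-initialized under `cfg$seed`.
#' @param log_path optional CSV path receiving the per-update loss log.
#' @return List with the trained `bundle` and the loss `log` data.frame.
#' @export
train <- function(pair, cfg = train_config(), bundle = NULL, log_path = NULL) {
  stopifnot(inherits(pair, "domain_pair"), inherits(cfg, "train_config"))
  src <- pair$source_train
  tgt <- pair$target_train
  if (ncol(src$X) != ncol(tgt$X))
    stop_input(paste("source and target feature grids differ (%d vs %d);",
                     "run prepare_pair() for PCA harmonization first"),
               ncol(src$X), ncol(tgt$X))
  ncls <- n_classes(src)
  if (is.null(bundle)) {
    net <- cfg$net %||% net_config(ncol(src$X))
    bundle <- model_bundle(ncol(src$X), ncls, config = net, seed = cfg$seed)
  }
  G <- bundle$G; C <- bundle$C; D <- bundle$D
  n_src <- nrow(src$X); n_tgt <- nrow(tgt$X)
  steps_per_epoch <- ceiling(n_src / cfg$batch)
  total_steps <- if (cfg$iteration_unit == "epoch")
    cfg$iterations * steps_per_epoch else cfg$iterations
  n_epochs <- ceiling(total_steps / steps_per_epoch)

  stG <- rmsprop_state(G$params)
  stC <- rmsprop_state(C$params)
  stD <- rmsprop_state(D$params)
  adapt <- cfg$mode != "source_only"
  use_pl <- cfg$mode == "cdan_pl"
  log_cols <- c("iter", "epoch", "L_cls", "L_CE", "L_adv", "L_MC", "T_m",
                "combined", "lambda", "kept_count")
  log <- matrix(NA_real_, total_steps, length(log_cols),
                dimnames = list(NULL, log_cols))
  step <- 0L

  with_seed(cfg$seed, {
    for (epoch in seq_len(n_epochs)) {
      pls <- NULL
      if (use_pl) {
        eb <- bundle; eb$G <- G; eb$C <- C
        pls <- generate_pseudo_labels(eb, src, tgt, cfg$K, cfg$kappa, cfg$w)
      }
      src_order <- sample.int(n_src)
      for (bi in seq_len(steps_per_epoch)) {
        if (step >= total_steps) break
        step <- step + 1L
        lam <- if (cfg$lambda_warmup)
          cfg$lambda * min(1, step / (0.3 * total_steps)) else cfg$lambda
        is_ <- src_order[((bi - 1L) * cfg$batch + 1L):min(bi * cfg$batch,
                                                          n_src)]
        Xs <- src$X[is_, , drop = FALSE]; ys <- src$y[is_]

        fs_out <- G_forward(G, Xs, keep_cache = TRUE)
        fs <- fs_out$features
        cs <- C_forward(C, fs)
        L_cls <- check_finite_loss(cross_entropy(cs$probs, ys),
                                   "classification", step)
        dlog_s <- ce_dlogits(cs$probs, ys)

        L_CE <- 0; L_adv <- 0; L_MC <- 0; T_m <- NA_real_; kept_n <- 0L
        dF_t <- NULL; ft_out <- NULL; dlog_t <- NULL

        if (adapt) {
          it_ <- if (n_tgt >= cfg$batch) sample.int(n_tgt, cfg$batch)
                 else sample.int(n_tgt, cfg$batch, replace = TRUE)
          Xt <- tgt$X[it_, , drop = FALSE]
          ft_out <- G_forward(G, Xt, keep_cache = TRUE)
          ft <- ft_out$features
          ct <- C_forward(C, ft)

          adv <- adversarial_forward(D, fs, cs$probs, ft, ct$probs,
                                     train = TRUE)
          L_adv <- check_finite_loss(adv$value, "adversarial", step)
          ag <- adversarial_grads(D, adv)
          upd <- rmsprop_update(D$params, ag$D_grads, stD, cfg$lr, cfg$rho,
                                cfg$eps)
          D$params <- upd$params; stD <- upd$state

          # pseudo-label CE on the kept part of this target batch
          dF_t <- matrix(0, nrow(ft), ncol(ft))
          dlog_t <- matrix(0, nrow(ft), ncls)
          mc_F <- fs; mc_y <- ys
          if (use_pl) {
            kept <- pls$keep_mask[it_]
            kept_n <- sum(kept)
            if (kept_n > 0L) {
              pl <- pls$labels[it_][kept]
              L_CE <- check_finite_loss(
                cross_entropy(ct$probs[kept, , drop = FALSE], pl),
                "pseudo-label cross-entropy", step)
              dlog_t[kept, ] <- ce_dlogits(ct$probs[kept, , drop = FALSE], pl)
              if (cfg$mc_on_targets) {
                mc_F <- rbind(fs, ft[kept, , drop = FALSE])
                mc_y <- c(ys, pl)
              }
            }
          }
          mc <- mc_loss_internal(mc_F, mc_y, cfg$tm_mode)
          if (!mc$skipped) {
            L_MC <- check_finite_loss(mc$L_MC, "metric-constraint", step)
            T_m <- mc$T_m
          }
          dF_mc_s <- mc$dF[seq_len(nrow(fs)), , drop = FALSE]
          dF_mc_t <- if (nrow(mc$dF) > nrow(fs))
            mc$dF[(nrow(fs) + 1L):nrow(mc$dF), , drop = FALSE] else NULL

          # G/C side: descend L_cls + L_CE + lam * (L_MC - L_adv)
          dF_s <- lam * (dF_mc_s - ag$dfs)
          dF_t <- dF_t - lam * ag$dft
          if (!is.null(dF_mc_t) && kept_n > 0L) {
            ki <- which(kept)
            dF_t[ki, ] <- dF_t[ki, ] + lam * dF_mc_t
          }
          if (cfg$condition_grad) {
            # literal objective: adversarial gradient also flows through the
            # conditioning probabilities into the classifier
            dgs <- multilinear_map_dg(ag$dPhi_s, fs)
            dgt <- multilinear_map_dg(ag$dPhi_t, ft)
            dlog_s <- dlog_s - lam * softmax_bwd(cs$probs, dgs)
            dlog_t <- dlog_t - lam * softmax_bwd(ct$probs, dgt)
          }
          cb_t <- C_backward(C, ft, dlog_t)
          dF_t <- dF_t + cb_t$dF
          cb_s <- C_backward(C, fs, dlog_s)
          gC <- add_params(cb_s$grads, cb_t$grads)
          dF_s <- dF_s + cb_s$dF
          gG <- add_params(G_backward(G, fs_out$cache, dF_s),
                           G_backward(G, ft_out$cache, dF_t))
        } else {
          cb_s <- C_backward(C, fs, dlog_s)
          gC <- cb_s$grads
          gG <- G_backward(G, fs_out$cache, cb_s$dF)
        }

        upd <- rmsprop_update(G$params, gG, stG, cfg$lr, cfg$rho, cfg$eps)
        G$params <- upd$params; stG <- upd$state
        upd <- rmsprop_update(C$params, gC, stC, cfg$lr, cfg$rho, cfg$eps)
        C$params <- upd$params; stC <- upd$state

        log[step, ] <- c(step, epoch, L_cls, L_CE, L_adv, L_MC, T_m,
                         combined_objective(
                           list(L_adv = L_adv, L_MC = L_MC, L_cls = L_cls,
                                L_CE = L_CE), lam),
                         lam, kept_n)
      }
    }
  })
  bundle$G <- G; bundle$C <- C; bundle$D <- D
  log <- as.data.frame(log[seq_len(step), , drop = FALSE])
  if (!is.null(log_path)) utils::write.csv(log, log_path, row.names = FALSE)
  list(bundle = bundle, log = log)
}

#' Evaluate a trained model on a labeled test set
#'
#' @param bundle a [model_bundle()].
#' @param ds [spectral_dataset()] to score.
#' @param labels 0-based true labels (defaults to `ds$y`; pass the sealed
#'   target labels for target-domain evaluation).
#' @return List with `accuracy` (percent), `per_class` (percent per class)
#'   and the `confusion` matrix (true x predicted counts).
#' @export
evaluate_model <- function(bundle, ds, labels = ds$y) {
  if (is.null(labels)) stop_input("evaluation requires labels")
  pred <- predict(bundle, ds)$labels
  ncls <- bundle$n_classes
  confusion <- table(factor(labels, levels = 0:(ncls - 1L)),
                     factor(pred, levels = 0:(ncls - 1L)),
                     dnn = c("true", "predicted"))
  per_class <- 100 * diag(confusion) / pmax(rowSums(confusion), 1L)
  list(accuracy = 100 * mean(pred == labels), per_class = per_class,
       confusion = confusion)
}

#' Run a full experiment: repeated training + target evaluation
#'
#' Trains `cfg$n_runs` models with fresh seeds (`cfg$seed + run - 1`) on the
#' fixed splits of `pair` and scores each on the target test set against the
#' sealed labels. Reported accuracies are the mean and standard deviation
#' over runs, in percent.
#'
#' @param pair a preprocessed [domain_pair()] with sealed target labels.
#' @param cfg a [train_config()].
#' @param task optional task name carried into the report.
#' @return An object of class `eval_report`.
#' @export
run_experiment <- function(pair, cfg = train_config(), task = "transfer") {
  accs <- numeric(cfg$n_runs)
  last <- NULL
  for (run in seq_len(cfg$n_runs)) {
    run_cfg <- cfg
    run_cfg$seed <- cfg$seed + run - 1L
    fit <- train(pair, run_cfg)
    last <- evaluate_model(fit$bundle, pair$target_test, pair$sealed$test)
    accs[run] <- last$accuracy
  }
  structure(list(accuracy_mean = mean(accs),
                 accuracy_sd = if (cfg$n_runs > 1) sd(accs) else 0,
                 runs = accs, per_class = last$per_class,
                 confusion = last$confusion, mode = cfg$mode, task = task,
                 bundle = fit$bundle),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s [%s]: %.2f +/- %.2f %% over %d run(s)\n",
              x$task, x$mode, x$accuracy_mean, x$accuracy_sd,
              length(x$runs)))
  invisible(x)
}
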