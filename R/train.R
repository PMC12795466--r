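#' Training configuration
#'
#' @param epochs number of full-batch epochs.
#' @param learning_rate Adam learning rate.
#' @param optimizer only `"adam"`.
#' @param weight_decay L2 coefficient added to gradients.
#' @param seed master seed; fans out to parameter init, the hold-out split
#'   and dropout.
#' @param grl_gamma shape of the gradient-reversal ramp.
#' @param use_gda if FALSE, the adversarial branch is ablated: the domain
#'   loss weight is forced to 0 and the discriminator receives no gradient.
#' @param holdout_fraction fraction of target cells held out of every loss
#'   (0 disables the hold-out protocol).
#' @param weights a [loss_weights()] object.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 300, learning_rate = 1e-3,
                         optimizer = c("adam"), weight_decay = 1e-4,
                         seed = 0, grl_gamma = 10, use_gda = TRUE,
                         holdout_fraction = 0, weights = loss_weights()) {
  optimizer <- match.arg(optimizer)
  stopifnot(epochs >= 1, holdout_fraction >= 0, holdout_fraction < 1)
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 optimizer = optimizer, weight_decay = weight_decay,
                 seed = seed, grl_gamma = grl_gamma, use_gda = use_gda,
                 holdout_fraction = holdout_fraction, weights = weights),
            class = "train_config")
}

#' Linear schedule for the entropy-loss weight
#'
#' `lambda_e(t) = lambda_e_max * epoch / total_epochs`: the entropy
#' constraint ramps in only as alignment and classification mature.
#'
#' @param epoch current epoch (0..total_epochs).
#' @param total_epochs total epochs.
#' @param lambda_e_max final value.
#' @return Scalar weight.
#' @export
lambda_e_schedule <- function(epoch, total_epochs, lambda_e_max) {
  stopifnot(epoch >= 0, epoch <= total_epochs)
  lambda_e_max * epoch / total_epochs
}

#' Gradient-reversal strength schedule
#'
#' `lambda_grl = 2 / (1 + exp(-gamma * progress)) - 1`, ramping
#' monotonically from 0 toward 1 over training.
#'
#' @param progress training progress in `[0, 1]`.
#' @param gamma ramp sharpness.
#' @return Scalar in `[0, 1)`.
#' @export
grl_schedule <- function(progress, gamma = 10) {
  stopifnot(progress >= 0, progress <= 1)
  2 / (1 + exp(-gamma * progress)) - 1
}

#' Hold-out split of target cells
#'
#' Deterministic under `seed`; the hold-out gets `floor(fraction * n)` rows,
#' the remainder trains.
#'
#' @param n number of target cells.
#' @param fraction hold-out fraction in (0, 1).
#' @param seed RNG seed.
#' @return List with integer vectors `train` and `holdout` (sorted, disjoint,
#'   covering `1:n`).
#' @export
holdout_split <- function(n, fraction = 0.2, seed = 0) {
  stopifnot(fraction > 0, fraction < 1)
  n_hold <- floor(fraction * n)
  if (n_hold == 0 || n_hold == n) stop("fraction yields an empty partition")
  set.seed(seed)
  hold <- sort(sample.int(n, n_hold))
  list(train = setdiff(seq_len(n), hold), holdout = hold)
}

# ---- full-batch forward over both domains -------------------------------

full_forward <- function(model, Xs, gs, Xt, gt, training = TRUE,
                         update_state = training) {
  e_pr_s <- encoder_forward(model, Xs, gs, "src_private", training, update_state)
  e_pr_t <- encoder_forward(model, Xt, gt, "tgt_private", training, update_state)
  e_sh_s <- encoder_forward(model, Xs, gs, "shared", training, update_state)
  if (update_state) model$state$shared <- e_sh_s$state
  e_sh_t <- encoder_forward(model, Xt, gt, "shared", training, update_state)
  if (update_state) {
    model$state$src_private <- e_pr_s$state
    model$state$tgt_private <- e_pr_t$state
    model$state$shared <- e_sh_t$state
  }
  Zs <- cbind(e_pr_s$h, e_sh_s$h)
  Zt <- cbind(e_pr_t$h, e_sh_t$h)
  Ss <- tcrossprod(Zs)
  St <- tcrossprod(Zt)
  disc_s <- disc_forward(model$params$disc, e_sh_s$h)
  disc_t <- disc_forward(model$params$disc, e_sh_t$h)
  pred_s <- pred_forward(model$params$pred, e_sh_s$h)
  pred_t <- pred_forward(model$params$pred, e_sh_t$h)
  list(model = model,
       e_pr_s = e_pr_s, e_pr_t = e_pr_t, e_sh_s = e_sh_s, e_sh_t = e_sh_t,
       Zs = Zs, Zt = Zt, Ss = Ss, St = St,
       disc_s = disc_s, disc_t = disc_t, pred_s = pred_s, pred_t = pred_t)
}

# rec_s/rec_t: optional precomputed cpp_rec_bce results (fused loss+grad)
compute_loss_components <- function(fwd, y, Bs, Bt,
                                    rec_s = cpp_rec_bce(fwd$Ss, as.matrix(Bs), 1e-7),
                                    rec_t = cpp_rec_bce(fwd$St, as.matrix(Bt), 1e-7)) {
  list(cls = classification_loss(fwd$pred_s$psi, y),
       dom = domain_loss(fwd$disc_s$p, fwd$disc_t$p),
       ent = entropy_loss(fwd$pred_t$psi),
       diff = difference_loss(list(h_sh_source = fwd$e_sh_s$h,
                                   h_pr_source = fwd$e_pr_s$h,
                                   h_sh_target = fwd$e_sh_t$h,
                                   h_pr_target = fwd$e_pr_t$h)),
       rec = rec_s$loss + rec_t$loss)
}

# Backward over the whole objective. Effective term weights come from
# `weights`/`lambda_e` unless `term_select` isolates one component (weight 1,
# used by gradient diagnostics). Returns parameter gradients, and input
# gradients dXs/dXt when want_dX = TRUE.
full_backward <- function(model, fwd, y, Bs, Bt, weights, lambda_e,
                          lambda_grl, use_gda = TRUE, want_dX = FALSE,
                          term_select = NULL, rec_s = NULL, rec_t = NULL) {
  cfg <- model$cfg
  d_h <- cfg$d_h
  n_s <- nrow(fwd$e_sh_s$h)
  n_t <- nrow(fwd$e_sh_t$h)

  if (is.null(term_select)) {
    w <- list(cls = 1, dom = if (use_gda) weights$lambda_d else 0,
              ent = lambda_e, diff = weights$lambda_f, rec = weights$lambda_r)
  } else {
    w <- list(cls = 0, dom = 0, ent = 0, diff = 0, rec = 0)
    w[[term_select]] <- 1
  }

  dHpr_s <- matrix(0, n_s, d_h); dHsh_s <- matrix(0, n_s, d_h)
  dHpr_t <- matrix(0, n_t, d_h); dHsh_t <- matrix(0, n_t, d_h)
  grads <- zero_like(model$params)

  # classification: d(BCE)/d(logit) = (psi - y)/n
  if (w$cls != 0) {
    dlog <- w$cls * (.clip_prob(fwd$pred_s$psi) - y) / n_s
    pb <- pred_backward(model$params$pred, dlog, fwd$pred_s$cache)
    grads$pred <- add_params(grads$pred, pb$grads)
    dHsh_s <- dHsh_s + pb$dh
  }
  # entropy: d/d(logit) = -logit * psi * (1 - psi) / n
  if (w$ent != 0) {
    psi <- fwd$pred_t$psi
    dlog <- w$ent * (-fwd$pred_t$logit * psi * (1 - psi)) / n_t
    pb <- pred_backward(model$params$pred, dlog, fwd$pred_t$cache)
    grads$pred <- add_params(grads$pred, pb$grads)
    dHsh_t <- dHsh_t + pb$dh
  }
  # adversarial: minimize domain-label BCE; GRL flips encoder-side gradient
  if (w$dom != 0) {
    ds <- .clip_prob(fwd$disc_s$p)
    dt <- .clip_prob(fwd$disc_t$p)
    dls <- w$dom * (ds - 1) / n_s
    dlt <- w$dom * dt / n_t
    dbs <- disc_backward(model$params$disc, dls, fwd$disc_s$cache)
    dbt <- disc_backward(model$params$disc, dlt, fwd$disc_t$cache)
    grads$disc <- add_params(grads$disc, add_params(dbs$grads, dbt$grads))
    dHsh_s <- dHsh_s - lambda_grl * dbs$dh
    dHsh_t <- dHsh_t - lambda_grl * dbt$dh
  }
  # difference: M = H_sh' H_pr; dH_sh = 2 H_pr M'; dH_pr = 2 H_sh M
  if (w$diff != 0) {
    Ms_ <- crossprod(fwd$e_sh_s$h, fwd$e_pr_s$h)
    Mt_ <- crossprod(fwd$e_sh_t$h, fwd$e_pr_t$h)
    dHsh_s <- dHsh_s + w$diff * 2 * fwd$e_pr_s$h %*% t(Ms_)
    dHpr_s <- dHpr_s + w$diff * 2 * fwd$e_sh_s$h %*% Ms_
    dHsh_t <- dHsh_t + w$diff * 2 * fwd$e_pr_t$h %*% t(Mt_)
    dHpr_t <- dHpr_t + w$diff * 2 * fwd$e_sh_t$h %*% Mt_
  }
  # reconstruction: dS = (sigmoid(S) - B)/n^2, dZ = 2 dS Z
  if (w$rec != 0) {
    if (is.null(rec_s)) rec_s <- cpp_rec_bce(fwd$Ss, as.matrix(Bs), 1e-7)
    if (is.null(rec_t)) rec_t <- cpp_rec_bce(fwd$St, as.matrix(Bt), 1e-7)
    dZs <- (2 * w$rec) * rec_s$dS %*% fwd$Zs
    dZt <- (2 * w$rec) * rec_t$dS %*% fwd$Zt
    dHpr_s <- dHpr_s + dZs[, 1:d_h, drop = FALSE]
    dHsh_s <- dHsh_s + dZs[, (d_h + 1):(2 * d_h), drop = FALSE]
    dHpr_t <- dHpr_t + dZt[, 1:d_h, drop = FALSE]
    dHsh_t <- dHsh_t + dZt[, (d_h + 1):(2 * d_h), drop = FALSE]
  }

  dXs <- NULL; dXt <- NULL
  eb <- encoder_backward(model, dHpr_s, fwd$e_pr_s$cache, want_dX)
  grads$src_private <- add_params(grads$src_private, eb$grads)
  if (want_dX) dXs <- eb$dX
  eb <- encoder_backward(model, dHpr_t, fwd$e_pr_t$cache, want_dX)
  grads$tgt_private <- add_params(grads$tgt_private, eb$grads)
  if (want_dX) dXt <- eb$dX
  eb <- encoder_backward(model, dHsh_s, fwd$e_sh_s$cache, want_dX)
  grads$shared <- add_params(grads$shared, eb$grads)
  if (want_dX) dXs <- dXs + eb$dX
  eb <- encoder_backward(model, dHsh_t, fwd$e_sh_t$cache, want_dX)
  grads$shared <- add_params(grads$shared, eb$grads)
  if (want_dX) dXt <- dXt + eb$dX

  list(grads = grads, dXs = dXs, dXt = dXt)
}


#' Train the full adversarial model
#'
#' Full-batch training: every epoch runs one forward pass of both domains
#' through the private and shared encoders, inner-product decoders,
#' GRL + discriminator and predictor, computes the five losses, and takes a
#' single Adam step on the weighted total. Graphs are prebuilt and static.
#' With `cfg$holdout_fraction > 0`, a deterministic subset of target cells
#' (and the corresponding subgraph of the prebuilt adjacency) is excluded
#' from the entire training computation, so no loss receives any
#' contribution from held-out cells.
#'
#' @param source list with `x` (standardized `expression_matrix`), `y`
#'   (binary labels) and `graph` (a `cell_graph`).
#' @param target list with `x` and `graph`.
#' @param model_cfg a [model_config()]; its seed is derived from
#'   `cfg$seed`.
#' @param cfg a [train_config()].
#' @return A list of class `dagformer_fit`: `model` (trained), `state`
#'   (`history` data frame of per-epoch losses and discriminator accuracy,
#'   `holdout` indices, `seed`), plus the configs.
#' @export
train_dagformer <- function(source, target, model_cfg = model_config(),
                            cfg = train_config()) {
  Xs <- if (inherits(source$x, "expression_matrix")) source$x$values else as.matrix(source$x)
  Xt_full <- if (inherits(target$x, "expression_matrix")) target$x$values else as.matrix(target$x)
  y <- as.numeric(source$y)
  if (ncol(Xs) != ncol(Xt_full)) stop("gene columns not aligned across domains")

  hold <- NULL
  Xt <- Xt_full
  gt_graph <- target$graph
  if (cfg$holdout_fraction > 0) {
    hold <- holdout_split(nrow(Xt_full), cfg$holdout_fraction, seed = cfg$seed)
    Xt <- Xt_full[hold$train, , drop = FALSE]
    gt_graph <- subset_cell_graph(target$graph, hold$train)
  }

  model_cfg$seed <- (cfg$seed * 1009 + 7) %% 2147483647
  model <- init_model(ncol(Xs), model_cfg)
  set.seed((cfg$seed * 2027 + 11) %% 2147483647) # dropout / any loop sampling

  gs <- graph_csr(source$graph)
  gt <- graph_csr(gt_graph)
  skeleton <- model$params
  theta <- flatten_params(model$params)
  opt_m <- numeric(length(theta))
  opt_v <- numeric(length(theta))
  history <- vector("list", cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    lambda_e <- lambda_e_schedule(epoch, cfg$epochs, cfg$weights$lambda_e_max)
    lambda_grl <- grl_schedule(epoch / cfg$epochs, cfg$grl_gamma)
    fwd <- full_forward(model, Xs, gs, Xt, gt, training = TRUE)
    model <- fwd$model
    rec_s <- cpp_rec_bce(fwd$Ss, gs$binary, 1e-7)
    rec_t <- cpp_rec_bce(fwd$St, gt$binary, 1e-7)
    comp <- compute_loss_components(fwd, y, gs$binary, gt$binary, rec_s, rec_t)
    bad <- names(comp)[!vapply(comp, is.finite, logical(1))]
    if (length(bad) > 0)
      stop("non-finite loss term at epoch ", epoch, ": ", paste(bad, collapse = ", "))
    rep_row <- total_loss(comp$cls, comp$dom, comp$ent, comp$diff, comp$rec,
                          weights = if (cfg$use_gda) cfg$weights else
                            modifyList(cfg$weights, list(lambda_d = 0)),
                          epoch = epoch, total_epochs = cfg$epochs)
    # balanced accuracy: chance = 0.5 regardless of domain sizes
    rep_row$disc_acc <- (mean(fwd$disc_s$p > 0.5) + mean(fwd$disc_t$p <= 0.5)) / 2
    history[[epoch]] <- rep_row
    bwd <- full_backward(model, fwd, y, gs$binary, gt$binary, cfg$weights,
                         lambda_e, lambda_grl, use_gda = cfg$use_gda,
                         rec_s = rec_s, rec_t = rec_t)
    free_forward_caches(fwd)
    gflat <- flatten_params(bwd$grads)
    cpp_adam_flat(theta, gflat, opt_m, opt_v, epoch, cfg$learning_rate,
                  0.9, 0.999, 1e-8, cfg$weight_decay)
    model$params <- unflatten_params(theta, skeleton)
  }

  structure(list(model = model,
                 state = list(history = do.call(rbind, history),
                              holdout = hold, seed = cfg$seed),
                 cfg = cfg, model_cfg = model_cfg),
            class = "dagformer_fit")
}

#' @export
print.dagformer_fit <- function(x, ...) {
  h <- x$state$history
  cat(sprintf("<dagformer_fit> %d epochs; final total loss %.4f (cls %.4f, disc acc %.3f)\n",
              nrow(h), h$total[nrow(h)], h$cls[nrow(h)], h$disc_acc[nrow(h)]))
  invisible(x)
}

#' Predict drug response for target cells
#'
#' Eval-mode forward through the shared encoder (batch-norm running
#' statistics, no dropout) and the predictor; labels call a cell sensitive
#' when `psi >= 0.5`. If truth labels are supplied (evaluation only),
#' ACC/AUC/AUPR are attached.
#'
#' @param fit a `dagformer_fit` (or a `dagformer_model`).
#' @param target list with `x` and `graph` covering the cells to score.
#' @param y_true optional truth labels for evaluation.
#' @return A list of class `prediction_result`: `psi`, `label`, `cell_id`,
#'   and `metrics` (NULL without truth).
#' @export
predict_dagformer <- function(fit, target, y_true = NULL) {
  model <- if (inherits(fit, "dagformer_fit")) fit$model else fit
  x <- target$x
  X <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (ncol(X) != model$d_in) stop("gene mismatch vs. training")
  h <- encode(model, X, target$graph, "shared", training = FALSE)
  psi <- predict_response(model, h)
  ids <- if (inherits(x, "expression_matrix")) x$sample_ids else
    paste0("cell", seq_len(nrow(X)))
  metrics <- if (!is.null(y_true)) compute_metrics(psi, y_true) else NULL
  structure(list(cell_id = ids, psi = psi, label = as.integer(psi >= 0.5),
                 metrics = metrics),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %d cells, %d called sensitive\n",
              length(x$psi), sum(x$label)))
  if (!is.null(x$metrics))
    cat(sprintf("  ACC %.3f  AUC %.3f  AUPR %.3f\n",
                x$metrics$ACC, x$metrics$AUC, x$metrics$AUPR))
  invisible(x)
}

#' Classification metrics: ACC, AUC, AUPR
#'
#' ACC is computed at threshold 0.5. AUC is the probability that a random
#' positive outranks a random negative, ties counting one half (rank
#' formula). AUPR is average precision, the step-wise integral of the
#' precision-recall curve over descending score thresholds.
#'
#' @param psi predicted probabilities.
#' @param y_true binary truth labels.
#' @return List with `ACC`, `AUC`, `AUPR` (the latter two `NA` when only one
#'   class is present).
#' @export
compute_metrics <- function(psi, y_true) {
  y <- as.integer(y_true)
  stopifnot(length(psi) == length(y))
  acc <- mean((psi >= 0.5) == (y == 1))
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) return(list(ACC = acc, AUC = NA_real_, AUPR = NA_real_))
  r <- rank(psi, ties.method = "average")
  auc <- (sum(r[y == 1]) - np * (np + 1) / 2) / (np * nn)
  ord <- order(-psi)
  ys <- y[ord]; ps <- psi[ord]
  grp_last <- !duplicated(ps, fromLast = TRUE) # last index of each tie group
  tp <- cumsum(ys)[grp_last]
  npred <- seq_along(ys)[grp_last]
  precision <- tp / npred
  recall <- tp / np
  aupr <- sum(diff(c(0, recall)) * precision)
  list(ACC = acc, AUC = auc, AUPR = aupr)
}

#' Paired GDA ablation runs
#'
#' For each seed, trains two models on identical data differing only in
#' `use_gda`, scores the target cells against the evaluation-only truth
#' labels, and reports per-seed and median metrics.
#'
#' @param source,target as in [train_dagformer()].
#' @param y_true evaluation-only truth labels for the target cells.
#' @param model_cfg,cfg base configurations (seed is overridden per run).
#' @param seeds integer vector (>= 3 seeds).
#' @return A data.frame with one row per (seed, variant) and columns
#'   `seed`, `use_gda`, `ACC`, `AUC`, `AUPR`, `disc_acc`; medians per variant
#'   in attribute `"medians"`.
#' @export
run_ablation <- function(source, target, y_true, model_cfg = model_config(),
                         cfg = train_config(), seeds = 0:4) {
  if (length(seeds) < 3) stop("need >= 3 seeds")
  rows <- list()
  for (s in seeds) {
    for (gda in c(TRUE, FALSE)) {
      cfg_i <- cfg
      cfg_i$seed <- s
      cfg_i$use_gda <- gda
      fit <- train_dagformer(source, target, model_cfg, cfg_i)
      pr <- predict_dagformer(fit, target, y_true)
      h <- fit$state$history
      rows[[length(rows) + 1]] <- data.frame(
        seed = s, use_gda = gda, ACC = pr$metrics$ACC, AUC = pr$metrics$AUC,
        AUPR = pr$metrics$AUPR, disc_acc = h$disc_acc[nrow(h)])
    }
  }
  out <- do.call(rbind, rows)
  med <- stats::aggregate(out[c("ACC", "AUC", "AUPR", "disc_acc")],
                          by = list(use_gda = out$use_gda), FUN = stats::median)
  attr(out, "medians") <- med
  out
}

#' Per-row input gradients of each loss term on the target matrix
#'
#' Diagnostic for the hold-out contract: trains nothing, just initializes a
#' model under the config's seed, runs one training-mode forward on the
#' hold-out-restricted data, and backpropagates each loss term separately to
#' the target expression matrix. Rows of the returned matrix are all target
#' cells (held-out cells included); entries are gradient L2 norms.
#'
#' @param source,target as in [train_dagformer()].
#' @param model_cfg,cfg configurations; `cfg$holdout_fraction` may be 0.
#' @return Matrix (n_target x 5) with columns cls, dom, ent, diff, rec.
#' @export
target_input_gradients <- function(source, target, model_cfg = model_config(),
                                   cfg = train_config()) {
  Xs <- source$x$values
  Xt_full <- target$x$values
  y <- as.numeric(source$y)
  n_full <- nrow(Xt_full)
  idx <- seq_len(n_full)
  gt_graph <- target$graph
  if (cfg$holdout_fraction > 0) {
    hold <- holdout_split(n_full, cfg$holdout_fraction, seed = cfg$seed)
    idx <- hold$train
    gt_graph <- subset_cell_graph(target$graph, idx)
  }
  Xt <- Xt_full[idx, , drop = FALSE]
  model_cfg$seed <- (cfg$seed * 1009 + 7) %% 2147483647
  model <- init_model(ncol(Xs), model_cfg)
  gs <- graph_csr(source$graph)
  gt <- graph_csr(gt_graph)
  fwd <- full_forward(model, Xs, gs, Xt, gt, training = TRUE,
                      update_state = FALSE)
  terms <- c("cls", "dom", "ent", "diff", "rec")
  out <- matrix(0, n_full, length(terms), dimnames = list(NULL, terms))
  for (tm in terms) {
    bwd <- full_backward(model, fwd, y, gs$binary, gt$binary, cfg$weights,
                         lambda_e = 1, lambda_grl = 1, want_dX = TRUE,
                         term_select = tm)
    full_grad <- matrix(0, n_full, ncol(Xt_full))
    full_grad[idx, ] <- bwd$dXt
    out[, tm] <- sqrt(rowSums(full_grad^2))
  }
  free_forward_caches(fwd)
  out
}
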