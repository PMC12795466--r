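#' Loss weights for the composite training objective
#'
#' The total objective is
#' `L = L_cls + lambda_d * L_dom + lambda_e * L_ent + lambda_f * L_diff +
#' lambda_r * L_rec`, with `lambda_e` following a linear ramp from 0 to
#' `lambda_e_max` over training (see [lambda_e_schedule()]).
#'
#' @param lambda_d domain-adversarial loss weight.
#' @param lambda_e_max final entropy-loss weight.
#' @param lambda_f difference (orthogonality) loss weight.
#' @param lambda_r graph-reconstruction loss weight.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(lambda_d = 0.5, lambda_e_max = 0.01,
                         lambda_f = 1e-4, lambda_r = 0.3) {
  stopifnot(lambda_d >= 0, lambda_e_max >= 0, lambda_f >= 0, lambda_r >= 0)
  structure(list(lambda_d = lambda_d, lambda_e_max = lambda_e_max,
                 lambda_f = lambda_f, lambda_r = lambda_r),
            class = "loss_weights")
}

.clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Source-domain classification loss
#'
#' Mean binary cross-entropy (natural log) between predicted sensitivity
#' probabilities and source labels.
#'
#' @param psi predicted probabilities.
#' @param y binary labels (1 = sensitive).
#' @param eps clipping bound applied before taking logs.
#' @return Non-negative scalar.
#' @export
classification_loss <- function(psi, y, eps = 1e-7) {
  if (length(psi) != length(y)) stop("length mismatch between psi and y")
  p <- .clip_prob(psi, eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Target-domain entropy loss
#'
#' Mean Bernoulli entropy of the predicted target probabilities; minimizing
#' it sharpens the decision boundary on unlabeled cells. Range `[0, ln 2]`.
#'
#' @inheritParams classification_loss
#' @return Scalar in `[0, ln 2]`.
#' @export
entropy_loss <- function(psi, eps = 1e-7) {
  p <- .clip_prob(psi, eps)
  -mean(p * log(p) + (1 - p) * log(1 - p))
}

#' Domain-adversarial loss
#'
#' Returns `mean(log D(source)) + mean(log(1 - D(target)))`: the
#' discriminator maximizes this quantity while the shared encoder minimizes
#' it through the gradient reversal layer. Training realizes the min-max by
#' minimizing the equivalent domain-label binary cross-entropy (source = 1,
#' target = 0), which equals the negative of this value.
#'
#' @param d_source,d_target discriminator probabilities per domain.
#' @param eps clipping bound.
#' @return Scalar (non-positive; supremum 0 at perfect discrimination).
#' @export
domain_loss <- function(d_source, d_target, eps = 1e-7) {
  ds <- .clip_prob(d_source, eps)
  dt <- .clip_prob(d_target, eps)
  mean(log(ds)) + mean(log(1 - dt))
}

#' Difference (soft orthogonality) loss
#'
#' Squared Frobenius norms of the shared-by-private feature cross-products,
#' summed over the two domains:
#' `||H_sh_s' H_pr_s||_F^2 + ||H_sh_t' H_pr_t||_F^2`. Zero exactly when the
#' shared and private subspaces are orthogonal in both domains.
#'
#' @param features list with `h_sh_source`, `h_pr_source`, `h_sh_target`,
#'   `h_pr_target` (a domain may be omitted by passing NULL for its pair).
#' @return Non-negative scalar.
#' @export
difference_loss <- function(features) {
  term <- function(h_sh, h_pr) {
    if (is.null(h_sh) || is.null(h_pr)) return(0)
    if (nrow(h_sh) != nrow(h_pr)) stop("row count mismatch between shared and private features")
    sum(crossprod(h_sh, h_pr)^2)
  }
  term(features$h_sh_source, features$h_pr_source) +
    term(features$h_sh_target, features$h_pr_target)
}

#' Graph reconstruction loss (one domain)
#'
#' Mean binary cross-entropy over all n^2 adjacency entries between the
#' decoded edge probabilities and the binary symmetrized adjacency (with
#' self-loops, before degree normalization). The two domains' terms are
#' summed in the total objective.
#'
#' @param g_hat reconstructed edge probabilities (n x n).
#' @param g_bin binary target adjacency (n x n).
#' @param eps clipping bound.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(g_hat, g_bin, eps = 1e-7) {
  g_bin <- as.matrix(g_bin)
  if (any(g_bin != 0 & g_bin != 1)) stop("reconstruction target must be binary")
  if (!all(dim(g_hat) == dim(g_bin))) stop("shape mismatch")
  p <- .clip_prob(g_hat, eps)
  -mean(g_bin * log(p) + (1 - g_bin) * log(1 - p))
}

#' Combine loss components into a weighted total
#'
#' The adversarial term enters the minimized total as the domain-label
#' binary cross-entropy (`-dom`); the reported `dom` keeps the adversarial
#' sign convention of [domain_loss()]. `lambda_e` is taken from its linear
#' schedule at the current epoch.
#'
#' @param cls,dom,ent,diff,rec loss components (`dom` as returned by
#'   [domain_loss()]).
#' @param weights a [loss_weights()] object.
#' @param epoch,total_epochs schedule position for `lambda_e`.
#' @return A one-row `data.frame` (class `loss_report`) with the components,
#'   the effective `lambda_e` and the minimized `total`.
#' @export
total_loss <- function(cls, dom, ent, diff, rec, weights = loss_weights(),
                       epoch = 1, total_epochs = 1) {
  lambda_e <- lambda_e_schedule(epoch, total_epochs, weights$lambda_e_max)
  dom_bce <- -dom
  total <- cls + weights$lambda_d * dom_bce + lambda_e * ent +
    weights$lambda_f * diff + weights$lambda_r * rec
  structure(data.frame(epoch = epoch, cls = cls, dom = dom, dom_bce = dom_bce,
                       ent = ent, diff = diff, rec = rec,
                       lambda_e = lambda_e, total = total),
            class = c("loss_report", "data.frame"))
}
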