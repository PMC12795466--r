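#' Model configuration for the graph-transformer encoders and heads
#'
#' The hidden width must factor as `d_h = n_heads * d_k`. `literal_ffn = TRUE`
#' applies the feed-forward network without a second residual/normalization;
#' the conventional second-residual variant is available with
#' `literal_ffn = FALSE`. `attention_scaled` optionally divides attention
#' logits by `sqrt(d_k)` (off by default: the logits are already modulated by
#' the normalized adjacency).
#'
#' @param d_h hidden dimension.
#' @param n_layers number of transformer layers per encoder.
#' @param n_heads attention heads.
#' @param d_k per-head dimension.
#' @param dropout dropout rate on the attention output during training.
#' @param ffn_hidden feed-forward hidden width.
#' @param literal_ffn logical, see Details.
#' @param attention_scaled logical, see Details.
#' @param disc_hidden domain-discriminator hidden width.
#' @param seed seed for parameter initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(d_h = 64, n_layers = 2, n_heads = 4, d_k = 16,
                         dropout = 0, ffn_hidden = 128, literal_ffn = TRUE,
                         attention_scaled = FALSE, disc_hidden = 64, seed = 0) {
  if (d_h != n_heads * d_k) stop("d_h must equal n_heads * d_k")
  stopifnot(n_layers >= 1, dropout >= 0, dropout < 1)
  structure(list(d_h = d_h, n_layers = n_layers, n_heads = n_heads, d_k = d_k,
                 dropout = dropout, ffn_hidden = ffn_hidden,
                 literal_ffn = literal_ffn, attention_scaled = attention_scaled,
                 disc_hidden = disc_hidden, seed = seed),
            class = "model_config")
}

# Glorot-uniform matrix
.glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

.init_layer <- function(cfg) {
  list(W_Q = .glorot(cfg$d_h, cfg$d_h),
       W_K = .glorot(cfg$d_h, cfg$d_h),
       W_V = .glorot(cfg$d_h, cfg$d_h),
       bn1_gamma = rep(1, cfg$d_h), bn1_beta = rep(0, cfg$d_h),
       W1 = .glorot(cfg$d_h, cfg$ffn_hidden), b1 = rep(0, cfg$ffn_hidden),
       W2 = .glorot(cfg$ffn_hidden, cfg$d_h), b2 = rep(0, cfg$d_h),
       bn2_gamma = rep(1, cfg$d_h), bn2_beta = rep(0, cfg$d_h))
}

.init_encoder <- function(d_in, cfg) {
  list(W_proj = .glorot(d_in, cfg$d_h),
       layers = lapply(seq_len(cfg$n_layers), function(l) .init_layer(cfg)))
}

.init_bn_state <- function(cfg) {
  lapply(seq_len(cfg$n_layers), function(l)
    list(bn1_mean = rep(0, cfg$d_h), bn1_var = rep(1, cfg$d_h),
         bn2_mean = rep(0, cfg$d_h), bn2_var = rep(1, cfg$d_h)))
}

#' Initialize a model: three encoders, discriminator, predictor
#'
#' The source-private, target-private and shared encoders have disjoint
#' parameter sets; the shared encoder applies one parameter set to both
#' domains. Weights use Glorot-uniform initialization under `cfg$seed`.
#'
#' @param d_in number of genes (input features).
#' @param cfg a [model_config()].
#' @return A list of class `dagformer_model` with elements `params`
#'   (encoders `src_private`, `tgt_private`, `shared`; `disc`; `pred`),
#'   `state` (batch-norm running statistics per encoder), `cfg` and `d_in`.
#' @export
init_model <- function(d_in, cfg = model_config()) {
  set.seed(cfg$seed)
  params <- list(
    src_private = .init_encoder(d_in, cfg),
    tgt_private = .init_encoder(d_in, cfg),
    shared = .init_encoder(d_in, cfg),
    disc = list(W1 = .glorot(cfg$d_h, cfg$disc_hidden), b1 = rep(0, cfg$disc_hidden),
                W2 = .glorot(cfg$disc_hidden, 1), b2 = rep(0, 1)),
    pred = list(W = .glorot(cfg$d_h, 1), b = rep(0, 1)))
  state <- list(src_private = .init_bn_state(cfg),
                tgt_private = .init_bn_state(cfg),
                shared = .init_bn_state(cfg))
  structure(list(params = params, state = state, cfg = cfg, d_in = d_in),
            class = "dagformer_model")
}

# row-wise bias add: column j gets b[j]
.addb <- function(A, b) A + rep(b, each = nrow(A))

.sigmoid <- function(z) 1 / (1 + exp(-z))

#' Linear input projection with ReLU
#'
#' `H0 = ReLU(X W_proj)`, no bias.
#'
#' @param x numeric matrix (n x d).
#' @param w_proj projection matrix (d x d_h).
#' @return n x d_h matrix.
#' @export
input_projection <- function(x, w_proj) {
  if (ncol(x) != nrow(w_proj)) stop("shape mismatch: X has ", ncol(x),
                                    " columns but W_proj has ", nrow(w_proj), " rows")
  pre <- x %*% w_proj
  h <- pmax(pre, 0)
  attr(h, "relu_mask") <- pre > 0
  h
}

# Multi-head graph-sparsified attention forward.
# ghat: dense normalized adjacency; mask: numeric 0/1 matrix (ghat > 0).
# Off-graph logits are excluded from the softmax by zeroing their
# (bounded) exponentials; row maxima clamped at >= 0 keep exp() stable.
# Returns list(out, cache) where cache holds Q, K, V and per-head softmax
# probabilities for the backward pass.
attention_forward <- function(h, layer, ghat, mask, cfg) {
  Q <- h %*% layer$W_Q
  K <- h %*% layer$W_K
  V <- h %*% layer$W_V
  scale <- if (cfg$attention_scaled) 1 / sqrt(cfg$d_k) else 1
  r <- cpp_attention_forward(Q, K, V, ghat, cfg$n_heads, cfg$d_k, scale)
  list(out = r$out, cache = list(Q = Q, K = K, V = V, P = r$P, h = h,
                                 ghat = ghat, scale = scale))
}

#' Graph-sparsified multi-head attention
#'
#' Per head, attention logits between a node and each of its graph neighbors
#' are the query-key dot products weighted by the normalized adjacency entry;
#' softmax is taken over the neighbor set only, and the weighted neighbor
#' values are concatenated across heads.
#'
#' @param h node features (n x d_h).
#' @param graph a normalized `cell_graph` on the same n nodes.
#' @param layer a layer parameter list (elements `W_Q`, `W_K`, `W_V`).
#' @param cfg a [model_config()].
#' @return n x d_h matrix of attended features.
#' @export
sparse_attention <- function(h, graph, layer, cfg) {
  stopifnot(inherits(graph, "cell_graph"), isTRUE(graph$normalized))
  ghat <- as.matrix(graph$adjacency)
  if (nrow(ghat) != nrow(h)) stop("graph node count does not match feature rows")
  attention_forward(h, layer, ghat, ghat > 0, cfg)$out
}

# One transformer block forward with cache (C++ kernel does attention,
# residual + batch norm and the FFN in one call).
block_forward <- function(h_in, layer, ghat, mask, cfg, training, bn_state) {
  if (training && nrow(h_in) < 2)
    stop("batch of size 1 with batch-norm in training mode; use eval-mode statistics")
  drop_mask <- NULL
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    drop_mask <- matrix((stats::runif(nrow(h_in) * cfg$d_h) < keep) / keep,
                        nrow(h_in), cfg$d_h)
  }
  scale <- if (cfg$attention_scaled) 1 / sqrt(cfg$d_k) else 1
  r <- cpp_block_forward(h_in, ghat, layer$W_Q, layer$W_K, layer$W_V,
                         layer$bn1_gamma, layer$bn1_beta, layer$W1, layer$b1,
                         layer$W2, layer$b2, layer$bn2_gamma, layer$bn2_beta,
                         cfg$n_heads, cfg$d_k, scale, cfg$literal_ffn, training,
                         bn_state$bn1_mean, bn_state$bn1_var,
                         bn_state$bn2_mean, bn_state$bn2_var,
                         0.1, 1e-5, drop_mask)
  list(h = r$h,
       cache = list(cpp = r, h_in = h_in, ghat = ghat, scale = scale,
                    drop_mask = drop_mask, training = training),
       state = list(bn1_mean = as.numeric(r$bn1_mean),
                    bn1_var = as.numeric(r$bn1_var),
                    bn2_mean = as.numeric(r$bn2_mean),
                    bn2_var = as.numeric(r$bn2_var)))
}

#' One graph-transformer block
#'
#' Attention output plus residual, batch normalization, then the
#' feed-forward network (`ReLU(. W1 + b1) W2 + b2`); with
#' `literal_ffn = FALSE` the FFN output is added back residually and
#' normalized again.
#'
#' @param h_in node features (n x d_h).
#' @param graph a normalized `cell_graph`.
#' @param layer layer parameters (see [init_model()]).
#' @param cfg a [model_config()].
#' @param training logical; training mode uses full-batch statistics.
#' @return n x d_h matrix.
#' @export
transformer_block <- function(h_in, graph, layer, cfg, training = FALSE) {
  ghat <- as.matrix(graph$adjacency)
  st <- list(bn1_mean = rep(0, cfg$d_h), bn1_var = rep(1, cfg$d_h),
             bn2_mean = rep(0, cfg$d_h), bn2_var = rep(1, cfg$d_h))
  block_forward(h_in, layer, ghat, ghat > 0, cfg, training, st)$h
}

# CSR view of a cell_graph for the sparse C++ kernels, plus the dense
# binary reconstruction target. Self-loops are part of the graph, so every
# row has >= 1 edge.
graph_csr <- function(g) {
  A <- as(as(g$adjacency, "generalMatrix"), "RsparseMatrix")
  list(row_ptr = A@p, col_idx = A@j, gvals = A@x,
       binary = as.matrix(g$binary), n = nrow(A))
}

# Full encoder forward (internal). The C++ kernel keeps all layer caches
# behind an external pointer; `which` selects the parameter set.
# update_state=TRUE refreshes that encoder's BN running statistics.
encoder_forward <- function(model, X, gr, which, training,
                            update_state = training) {
  enc <- model$params[[which]]
  cfg <- model$cfg
  if (training && nrow(X) < 2)
    stop("batch of size 1 with batch-norm in training mode; use eval-mode statistics")
  drop_masks <- NULL
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    drop_masks <- lapply(seq_len(cfg$n_layers), function(l)
      matrix((stats::runif(nrow(X) * cfg$d_h) < keep) / keep, nrow(X), cfg$d_h))
  }
  scale <- if (cfg$attention_scaled) 1 / sqrt(cfg$d_k) else 1
  r <- cpp_encoder_forward(X, gr$row_ptr, gr$col_idx, gr$gvals,
                           enc$W_proj, enc$layers, cfg$n_heads,
                           cfg$d_k, scale, cfg$literal_ffn, training,
                           model$state[[which]], 0.1, 1e-5, drop_masks)
  state <- lapply(r$state, function(s) lapply(s, as.numeric))
  list(h = r$h, cache = list(ptr = r$cache, which = which), state = state)
}

#' Encode a domain with one of the three encoders
#'
#' @param model a `dagformer_model`.
#' @param x standardized `expression_matrix` (or plain matrix).
#' @param graph matching normalized `cell_graph`.
#' @param which `"src_private"`, `"tgt_private"` or `"shared"`.
#' @param training logical; eval mode (default) uses batch-norm running
#'   statistics and applies no dropout.
#' @return n x d_h embedding matrix.
#' @export
encode <- function(model, x, graph, which = c("shared", "src_private", "tgt_private"),
                   training = FALSE) {
  which <- match.arg(which)
  X <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  fwd <- encoder_forward(model, X, graph_csr(graph), which, training,
                         update_state = FALSE)
  cpp_encoder_cache_free(fwd$cache$ptr)
  fwd$h
}

#' Inner-product graph decoder
#'
#' Concatenates private and shared embeddings and maps pairwise inner
#' products through a sigmoid: `sigmoid(Z Z^T)` with `Z = [H_pr, H_sh]`.
#'
#' @param h_pr,h_sh per-domain private and shared embeddings (equal row
#'   counts).
#' @return Symmetric n x n matrix of edge probabilities in (0, 1).
#' @export
inner_product_decode <- function(h_pr, h_sh) {
  if (nrow(h_pr) != nrow(h_sh)) stop("row count mismatch between private and shared features")
  z <- cbind(h_pr, h_sh)
  .sigmoid(tcrossprod(z))
}

#' Gradient reversal layer (forward part)
#'
#' Identity in the forward pass; during backpropagation the incoming
#' gradient is multiplied by `-lambda_grl` (realized inside the training
#' backward pass).
#'
#' @param h features.
#' @param lambda_grl non-negative reversal strength.
#' @return `h`, unchanged.
#' @export
gradient_reversal <- function(h, lambda_grl = 1) {
  stopifnot(lambda_grl >= 0)
  h
}

disc_forward <- function(params, h) {
  a1 <- .addb(h %*% params$W1, params$b1)
  r1 <- pmax(a1, 0)
  logit <- .addb(r1 %*% params$W2, params$b2)
  p <- .sigmoid(logit)
  list(p = as.numeric(p), cache = list(h = h, a1_mask = a1 > 0, r1 = r1))
}

pred_forward <- function(params, h) {
  logit <- .addb(h %*% params$W, params$b)
  list(psi = as.numeric(.sigmoid(logit)), logit = as.numeric(logit),
       cache = list(h = h))
}

#' Domain discriminator
#'
#' Two-layer fully connected network with ReLU and sigmoid output,
#' predicting the probability that a shared embedding originates from the
#' source (bulk) domain. During training its input passes through the
#' gradient reversal layer.
#'
#' @param model a `dagformer_model`.
#' @param h_sh shared embeddings (n x d_h).
#' @return Numeric vector of domain probabilities in (0, 1).
#' @export
discriminate_domain <- function(model, h_sh) {
  p <- disc_forward(model$params$disc, h_sh)$p
  pmin(pmax(p, 1e-7), 1 - 1e-7)
}

#' Drug-response predictor
#'
#' Single affine layer plus sigmoid on the shared embedding; `psi[i]` is the
#' probability that sample i is drug-sensitive (label 1).
#'
#' @param model a `dagformer_model`.
#' @param h_sh shared embeddings (n x d_h).
#' @return Numeric vector of sensitivity probabilities in (0, 1).
#' @export
predict_response <- function(model, h_sh) {
  psi <- pred_forward(model$params$pred, h_sh)$psi
  pmin(pmax(psi, 1e-7), 1 - 1e-7)
}
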