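# Independent brute-force oracles. These re-derive every quantity from its
# defining formula with explicit loops and must stay independent of the
# package's implementation paths.

oracle_pearson <- function(X) {
  n <- nrow(X)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- X[i, ] - mean(X[i, ])
    xj <- X[j, ] - mean(X[j, ])
    den <- sqrt(sum(xi^2)) * sqrt(sum(xj^2))
    C[i, j] <- if (den == 0) 0 else sum(xi * xj) / den
  }
  C
}

oracle_spearman <- function(X) {
  oracle_pearson(t(apply(X, 1, rank))) # average ranks for ties
}

oracle_cosine <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))

oracle_knn <- function(X, k) {
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    sims <- vapply(seq_len(n), function(j) oracle_cosine(X[i, ], X[j, ]), 0)
    sims[i] <- -Inf
    ord <- order(-sims, seq_len(n)) # ties toward the smaller index
    A[i, ord[seq_len(k)]] <- 1
  }
  A
}

# dense neighbor-loop attention reference: logits ghat_ij * (Q_i . K_j),
# softmax over the neighbor set, weighted neighbor values, concatenated heads
oracle_attention <- function(H, layer, ghat, n_heads, d_k, scale = 1) {
  n <- nrow(H)
  Q <- H %*% layer$W_Q
  K <- H %*% layer$W_K
  V <- H %*% layer$W_V
  out <- matrix(0, n, n_heads * d_k)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * d_k + 1):(h * d_k)
    for (i in seq_len(n)) {
      nb <- which(ghat[i, ] > 0)
      logits <- vapply(nb, function(j)
        ghat[i, j] * sum(Q[i, idx] * K[j, idx]) * scale, 0)
      w <- exp(logits - max(logits))
      w <- w / sum(w)
      out[i, idx] <- colSums(w * V[nb, idx, drop = FALSE])
    }
  }
  out
}

rand_expr <- function(n, g, seed, domain = "target") {
  set.seed(seed)
  expression_matrix(matrix(stats::rnorm(n * g), n, g),
                    domain = domain, stage = "standardized")
}

# small two-domain setup for training tests
tiny_setup <- function(seed = 0, n_source = 60, n_target = 80, n_genes = 40,
                       n_informative = 10, k = 5, ...) {
  ds <- generate_synthetic(synth_config(
    n_source = n_source, n_target = n_target, n_genes = n_genes,
    n_informative = n_informative, seed = seed, ...))
  src <- standardize_source(ds$source$x)
  tgt <- standardize_source(ds$target$x)
  bal <- balance_classes(src, ds$source$y, balance_params(seed = seed))
  list(source = list(x = bal$x, y = bal$y,
                     graph = build_cell_graph(bal$x, "knn", k = k)),
       target = list(x = tgt, graph = build_cell_graph(tgt, "knn", k = k)),
       truth = ds$truth)
}

tiny_model_cfg <- function(...) {
  model_config(d_h = 16, n_layers = 2, n_heads = 2, d_k = 8,
               ffn_hidden = 24, disc_hidden = 12, ...)
}
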