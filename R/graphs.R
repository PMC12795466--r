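#' Spearman correlation matrix between samples
#'
#' Entry (i, j) is the Pearson correlation of the within-sample gene ranks of
#' samples i and j (ties receive average ranks). Rows with constant
#' expression have undefined correlation; their off-diagonal entries are set
#' to 0 and the rows flagged.
#'
#' @param x an `expression_matrix` (n >= 2 samples, >= 2 genes).
#' @return A list of class `correlation_matrix` with fields `values`
#'   (n x n), `method = "srcc"` and `constant_rows`.
#' @export
spearman_matrix <- function(x) {
  .correlation_matrix(x, "srcc")
}

#' Pearson correlation matrix between samples
#'
#' @inheritParams spearman_matrix
#' @return A `correlation_matrix` with `method = "pcc"`.
#' @export
pearson_matrix <- function(x) {
  .correlation_matrix(x, "pcc")
}

.correlation_matrix <- function(x, method) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (nrow(v) < 2 || ncol(v) < 2) stop("need >= 2 samples and >= 2 genes")
  const <- apply(v, 1, function(r) max(r) - min(r) == 0)
  cm <- suppressWarnings(stats::cor(t(v), method = if (method == "srcc") "spearman" else "pearson"))
  if (any(const)) {
    cm[const, ] <- 0
    cm[, const] <- 0
  }
  cm[is.na(cm)] <- 0
  diag(cm)[!const] <- 1
  structure(list(values = cm, method = method,
                 constant_rows = x$sample_ids[const]),
            class = "correlation_matrix")
}

#' Threshold a correlation matrix at its top-percent quantile
#'
#' The cutoff `theta` is the `(100 - percent)`-th percentile of the
#' off-diagonal upper-triangle correlations (self-correlations excluded);
#' an edge (i, j) is kept iff `C_ij > theta` (strict), so ties at the cutoff
#' are dropped.
#'
#' @param corr a `correlation_matrix`.
#' @param percent top percentage of pairs to keep, in (0, 100].
#' @return Binary symmetric adjacency matrix (zero diagonal) with attribute
#'   `"theta"`.
#' @export
threshold_top_percent <- function(corr, percent = 20) {
  stopifnot(inherits(corr, "correlation_matrix"), percent > 0, percent <= 100)
  C <- corr$values
  ut <- C[upper.tri(C)]
  theta <- stats::quantile(ut, probs = 1 - percent / 100, names = FALSE, type = 7)
  A <- (C > theta) * 1
  diag(A) <- 0
  A <- A * upper.tri(A)
  A <- A + t(A)
  attr(A, "theta") <- theta
  A
}

#' Cosine K-nearest-neighbor adjacency
#'
#' Directed edge i -> j iff j is among the K largest cosine similarities to
#' i, self excluded; ties are broken toward the smaller sample index.
#'
#' @param x an `expression_matrix` with no zero-norm rows.
#' @param k number of neighbors, `1 <= k < n`.
#' @return Directed binary adjacency matrix (rows = sources).
#' @export
knn_graph <- function(x, k = 15) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  n <- nrow(v)
  stopifnot(k >= 1, k < n)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0))
    stop("zero-norm expression vector for sample: ", x$sample_ids[nrm == 0][1])
  vs <- v / nrm
  sim <- tcrossprod(vs)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sim[i, ]
    s[i] <- -Inf
    # order() is stable: ties resolve to the smaller index
    nb <- order(-s)[seq_len(k)]
    A[i, nb] <- 1
  }
  A
}

#' Symmetrize and degree-normalize an adjacency matrix
#'
#' Symmetrization is by union (`max(A, t(A))`), self-loops are added to every
#' node, and the result is normalized as `D^{-1/2} A D^{-1/2}` with D the
#' degree diagonal. The pre-normalization binary matrix (with self-loops) is
#' retained as the reconstruction target and for hold-out subgraphs.
#'
#' @param A square non-negative adjacency matrix.
#' @param method,params bookkeeping copied into the result.
#' @return A `cell_graph` object: `adjacency` (normalized, sparse),
#'   `binary` (symmetrized + self-loops, sparse), `neighbor_lists`, `method`,
#'   `params`, `normalized = TRUE`.
#' @export
symmetrize_normalize <- function(A, method = "custom", params = list()) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), all(A >= 0))
  S <- pmax(A, t(A))
  S[S > 0] <- 1
  diag(S) <- 1
  deg <- rowSums(S)
  dinv <- 1 / sqrt(deg)
  Ghat <- S * tcrossprod(dinv) # D^{-1/2} S D^{-1/2}
  nb <- apply(S > 0, 1, which, simplify = FALSE)
  nb <- lapply(nb, function(v) sort(unname(v)))
  structure(list(adjacency = Matrix::Matrix(Ghat, sparse = TRUE),
                 binary = Matrix::Matrix(S, sparse = TRUE),
                 neighbor_lists = nb, method = method, params = params,
                 normalized = TRUE),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d nodes, %d undirected edges [method=%s, normalized=%s]\n",
              nrow(x$adjacency),
              (Matrix::nnzero(x$binary) - nrow(x$binary)) / 2,
              x$method, x$normalized))
  invisible(x)
}

#' Build a cellular neighbor graph from standardized expression
#'
#' Dispatches to the Spearman/Pearson top-percent thresholding or cosine-KNN
#' strategies, then symmetrizes and normalizes. Graphs are built once, before
#' training, and reused at every epoch.
#'
#' @param x standardized `expression_matrix`.
#' @param method `"knn"`, `"pcc"` or `"srcc"`.
#' @param k neighbors for `"knn"`.
#' @param percent top-percent threshold for `"pcc"`/`"srcc"`.
#' @return A `cell_graph`.
#' @export
build_cell_graph <- function(x, method = c("knn", "pcc", "srcc"),
                             k = 15, percent = 20) {
  method <- match.arg(method)
  A <- switch(method,
    knn = knn_graph(x, k = k),
    pcc = threshold_top_percent(pearson_matrix(x), percent = percent),
    srcc = threshold_top_percent(spearman_matrix(x), percent = percent))
  params <- if (method == "knn") list(K = k) else list(percent = percent)
  symmetrize_normalize(A, method = method, params = params)
}

# Restrict a cell_graph to a row subset (hold-out protocol): the binary
# adjacency is subset, self-loops kept, degrees recomputed.
subset_cell_graph <- function(g, idx) {
  S <- as.matrix(g$binary)[idx, idx, drop = FALSE]
  diag(S) <- 1
  out <- symmetrize_normalize(S, method = g$method, params = g$params)
  out
}

#' Write a cell graph as a TSV edge list plus JSON header
#'
#' @param g a `cell_graph`.
#' @param path output TSV path; the header is written to `<path>.json`.
#' @export
write_cell_graph <- function(g, path) {
  m <- Matrix::summary(Matrix::Matrix(g$adjacency, sparse = TRUE))
  df <- data.frame(node_i = m$i, node_j = m$j, weight = m$x)
  data.table::fwrite(df, path, sep = "\t")
  jsonlite::write_json(list(method = g$method, params = g$params,
                            n = nrow(g$adjacency), normalized = g$normalized),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
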