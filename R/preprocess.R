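#' Quality-control parameters for single-cell filtering
#'
#' Cells with very few detected genes, cells dominated by mitochondrial
#' counts, and genes detected in too few cells are removed. Mitochondrial
#' genes are identified by id prefix (human convention `"MT-"`,
#' case-insensitive).
#'
#' @param min_genes_per_cell minimum detected (nonzero) genes a cell must have.
#' @param min_cells_per_gene minimum cells in which a gene must be detected.
#' @param max_mito_fraction maximum fraction of a cell's counts allowed on
#'   mitochondrial genes.
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_genes_per_cell = 200, min_cells_per_gene = 3,
                      max_mito_fraction = 0.2, mito_prefix = "MT-") {
  stopifnot(min_cells_per_gene >= 1, max_mito_fraction > 0, max_mito_fraction <= 1)
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix), class = "qc_params")
}

#' Quality-filter single cells and genes
#'
#' Cell filters run first (low detected-gene count, high mitochondrial
#' fraction, both evaluated on the raw counts), then genes detected in fewer
#' than `min_cells_per_gene` of the *surviving* cells are dropped. The filter
#' report records removed ids and the reason for each.
#'
#' @param x target-domain `expression_matrix` at stage `"raw"`, non-negative
#'   counts.
#' @param params a [qc_params()] object.
#' @return An `expression_matrix` at stage `"qc"` with attribute
#'   `"filter_report"` (lists `cells_removed`, `genes_removed`, `reasons`).
#' @export
qc_filter_cells <- function(x, params = qc_params()) {
  stopifnot(inherits(x, "expression_matrix"), inherits(params, "qc_params"))
  if (x$domain != "target") stop("QC applies to target-domain counts")
  v <- x$values
  if (any(v < 0)) stop("negative counts in input")

  detected <- rowSums(v > 0)
  mito <- grepl(paste0("^", params$mito_prefix), x$gene_ids, ignore.case = TRUE)
  totals <- rowSums(v)
  mito_frac <- if (any(mito)) rowSums(v[, mito, drop = FALSE]) / pmax(totals, 1) else rep(0, nrow(v))

  low_genes <- detected < params$min_genes_per_cell
  high_mito <- mito_frac > params$max_mito_fraction
  keep_cells <- !(low_genes | high_mito)
  if (!any(keep_cells)) stop("all cells removed by QC")

  v2 <- v[keep_cells, , drop = FALSE]
  cells_per_gene <- colSums(v2 > 0)
  keep_genes <- cells_per_gene >= params$min_cells_per_gene

  reasons <- character(0)
  if (any(low_genes)) reasons[x$sample_ids[low_genes]] <- "low_gene_count"
  if (any(high_mito)) reasons[x$sample_ids[high_mito & !low_genes]] <- "high_mito_fraction"

  out <- expression_matrix(v2[, keep_genes, drop = FALSE],
                           x$sample_ids[keep_cells], x$gene_ids[keep_genes],
                           domain = x$domain, stage = "qc")
  attr(out, "filter_report") <- list(
    cells_removed = x$sample_ids[!keep_cells],
    genes_removed = x$gene_ids[!keep_genes],
    reasons = as.list(reasons))
  out
}

# Per-gene z-score with population (n-denominator) sd; zero-variance genes
# become all-zero columns, flagged in attr "zero_variance_genes".
.zscore_columns <- function(v, gene_ids) {
  mu <- colMeans(v)
  sd_pop <- sqrt(colMeans(sweep(v, 2, mu)^2))
  zero_var <- sd_pop < .Machine$double.eps^0.5
  sd_safe <- ifelse(zero_var, 1, sd_pop)
  z <- sweep(sweep(v, 2, mu), 2, sd_safe, "/")
  z[, zero_var] <- 0
  attr(z, "zero_variance_genes") <- gene_ids[zero_var]
  z
}

#' Normalize and standardize a single-cell count matrix
#'
#' Per-cell counts are rescaled to sum `target_sum`, log(1+x)-transformed,
#' then z-scored per gene (population sd). Zero-variance genes map to
#' all-zero columns.
#'
#' @param x target `expression_matrix` with non-negative counts (stage
#'   `"raw"` or `"qc"`).
#' @param target_sum per-cell total after count normalization.
#' @return An `expression_matrix` at stage `"standardized"` with attribute
#'   `"zero_variance_genes"`.
#' @export
normalize_target <- function(x, target_sum = 1e4) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (any(v < 0)) stop("negative counts in input")
  totals <- rowSums(v)
  if (any(totals == 0)) {
    bad <- x$sample_ids[totals == 0][1]
    stop("cell with total count 0: ", bad)
  }
  v <- v / totals * target_sum
  v <- log1p(v)
  z <- .zscore_columns(v, x$gene_ids)
  out <- expression_matrix(z, x$sample_ids, x$gene_ids,
                           domain = x$domain, stage = "standardized")
  attr(out, "zero_variance_genes") <- attr(z, "zero_variance_genes")
  out
}

#' Z-score a bulk expression matrix
#'
#' Per-gene standardization to mean 0, population sd 1. Bulk source data is
#' assumed already normalized upstream (e.g. RMA), so no count scaling or log
#' transform is applied.
#'
#' @param x source `expression_matrix`.
#' @return Stage-`"standardized"` matrix with attribute
#'   `"zero_variance_genes"`.
#' @export
standardize_source <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (anyNA(x$values)) stop("NaN/NA in input")
  z <- .zscore_columns(x$values, x$gene_ids)
  out <- expression_matrix(z, x$sample_ids, x$gene_ids,
                           domain = x$domain, stage = "standardized")
  attr(out, "zero_variance_genes") <- attr(z, "zero_variance_genes")
  out
}

#' Restrict two expression matrices to their shared genes
#'
#' Both matrices are subset to the gene intersection, columns in identical
#' lexicographically sorted order, so downstream models are independent of
#' input column order.
#'
#' @param xs,xt `expression_matrix` objects.
#' @return A list `(source, target, n_shared)`.
#' @export
intersect_genes <- function(xs, xt) {
  shared <- sort(intersect(xs$gene_ids, xt$gene_ids))
  if (length(shared) == 0) stop("empty gene intersection")
  sub <- function(x) {
    expression_matrix(x$values[, shared, drop = FALSE], x$sample_ids, shared,
                      domain = x$domain, stage = x$stage)
  }
  list(source = sub(xs), target = sub(xt), n_shared = length(shared))
}

#' Class-balancing parameters (SMOTE + random undersampling)
#'
#' @param smote_ratio minority/majority ratio reached by SMOTE oversampling.
#' @param final_ratio minority/majority ratio reached by undersampling the
#'   majority afterwards (1 = exactly balanced).
#' @param k_smote number of minority nearest neighbors SMOTE interpolates
#'   toward.
#' @param seed RNG seed making the balancing deterministic.
#' @return A list of class `balance_params`.
#' @export
balance_params <- function(smote_ratio = 0.5, final_ratio = 1.0,
                           k_smote = 5, seed = 0) {
  stopifnot(smote_ratio > 0, smote_ratio <= 1,
            final_ratio > 0, final_ratio <= 1, k_smote >= 1)
  structure(list(smote_ratio = smote_ratio, final_ratio = final_ratio,
                 k_smote = k_smote, seed = seed), class = "balance_params")
}

#' Balance source-domain classes by SMOTE then random undersampling
#'
#' SMOTE raises the minority (sensitive) count to
#' `round(smote_ratio * majority)`; each synthetic sample is a convex
#' combination `x + u * (neighbor - x)` of a minority sample and one of its
#' `k_smote` minority nearest neighbors (Euclidean), `u ~ U(0,1)`. The
#' majority is then randomly undersampled so that
#' minority/majority = `final_ratio`. Defaults give an exactly balanced 1:1
#' output.
#'
#' @param x standardized source `expression_matrix`.
#' @param y binary labels (1 = sensitive, 0 = resistant) aligned to rows of
#'   `x`.
#' @param params a [balance_params()] object.
#' @return A list `(x, y)`; `x` carries attribute `"smote_parents"`, a matrix
#'   with one row per synthetic sample giving the two parent row indices and
#'   the interpolation weight.
#' @export
balance_classes <- function(x, y, params = balance_params()) {
  stopifnot(inherits(x, "expression_matrix"), inherits(params, "balance_params"))
  y <- as.integer(y)
  if (length(y) != nrow(x$values)) stop("label length mismatch")
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts == 0)) stop("both classes must be present")

  minority <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  majority <- 1L - minority
  idx_min <- which(y == minority)
  idx_maj <- which(y == majority)
  n_min <- length(idx_min); n_maj <- length(idx_maj)
  if (n_min < params$k_smote + 1)
    stop("minority class too small for k_smote = ", params$k_smote)

  set.seed(params$seed)
  target_min <- round(params$smote_ratio * n_maj)
  n_new <- max(0L, target_min - n_min)

  Xmin <- x$values[idx_min, , drop = FALSE]
  synth <- NULL
  parents <- NULL
  if (n_new > 0) {
    d2 <- as.matrix(stats::dist(Xmin))^2
    diag(d2) <- Inf
    nn <- t(apply(d2, 1, function(r) order(r)[seq_len(params$k_smote)]))
    base_i <- sample.int(n_min, n_new, replace = TRUE)
    nb_pick <- sample.int(params$k_smote, n_new, replace = TRUE)
    u <- stats::runif(n_new)
    nb_i <- nn[cbind(base_i, nb_pick)]
    synth <- Xmin[base_i, , drop = FALSE] +
      u * (Xmin[nb_i, , drop = FALSE] - Xmin[base_i, , drop = FALSE])
    rownames(synth) <- paste0("smote_", seq_len(n_new))
    parents <- cbind(parent_a = idx_min[base_i], parent_b = idx_min[nb_i], u = u)
  }
  n_min_after <- n_min + n_new

  keep_maj_n <- min(n_maj, round(n_min_after / params$final_ratio))
  keep_maj <- sort(sample(idx_maj, keep_maj_n))

  vals <- rbind(x$values[idx_min, , drop = FALSE], synth,
                x$values[keep_maj, , drop = FALSE])
  ids <- c(x$sample_ids[idx_min],
           if (n_new > 0) rownames(synth) else character(0),
           x$sample_ids[keep_maj])
  y_out <- c(rep(minority, n_min_after), rep(majority, keep_maj_n))

  out <- expression_matrix(vals, ids, x$gene_ids, domain = x$domain, stage = x$stage)
  attr(out, "smote_parents") <- parents
  list(x = out, y = as.integer(y_out))
}
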