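#' Expression matrix container
#'
#' A light S3 wrapper around a dense samples-by-genes matrix carrying sample
#' ids, gene ids, the domain of origin (labeled bulk source vs. unlabeled
#' single-cell target) and a processing stage tag. All preprocessing and
#' graph-construction functions consume and return this container.
#'
#' @param values numeric matrix, rows = samples/cells, columns = genes.
#' @param sample_ids character vector, one per row.
#' @param gene_ids character vector, one per column; must be unique.
#' @param domain `"source"` (bulk, labeled) or `"target"` (single-cell).
#' @param stage processing stage: `"raw"`, `"qc"`, `"normalized"` or
#'   `"standardized"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_ids = rownames(values),
                              gene_ids = colnames(values),
                              domain = c("source", "target"),
                              stage = c("raw", "qc", "normalized", "standardized")) {
  domain <- match.arg(domain)
  stage <- match.arg(stage)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values))
    stop("sample_ids length does not match number of rows")
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length does not match number of columns")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids")
  if (stage %in% c("normalized", "standardized") && anyNA(values))
    stop("missing values not allowed at stage ", stage)
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, sample_ids = sample_ids,
                 gene_ids = gene_ids, domain = domain, stage = stage),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d samples x %d genes [domain=%s, stage=%s]\n",
              nrow(x$values), ncol(x$values), x$domain, x$stage))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Load an expression matrix from disk
#'
#' Dense CSV/TSV files are read with samples in rows: the first column holds
#' sample ids and the header holds gene ids. MatrixMarket triplets are assumed
#' gene-major (genes x cells, the common sparse convention) and are transposed
#' on load so that the orientation contract -- rows are samples/cells -- holds
#' for every format.
#'
#' @param path file path (for `mtx_triplet`, the `.mtx` file).
#' @param format `"csv"`, `"tsv"` or `"mtx_triplet"`.
#' @param domain `"source"` or `"target"`.
#' @param row_names,col_names for `mtx_triplet`: paths to one-id-per-line
#'   files naming the MTX rows (genes) and columns (cells). Default to
#'   `<path>.rownames` / `<path>.colnames`.
#' @return An `expression_matrix` at stage `"raw"`.
#' @export
load_expression <- function(path, format = c("csv", "tsv", "mtx_triplet"),
                            domain = c("source", "target"),
                            row_names = paste0(path, ".rownames"),
                            col_names = paste0(path, ".colnames")) {
  format <- match.arg(format)
  domain <- match.arg(domain)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
    sample_ids <- as.character(dt[[1]])
    genes <- colnames(dt)[-1]
    if (anyDuplicated(genes)) stop("duplicate gene ids")
    mat <- as.matrix(dt[, -1, drop = FALSE])
    expression_matrix(mat, sample_ids, genes, domain = domain, stage = "raw")
  } else {
    if (!file.exists(row_names)) stop("missing row-name file: ", row_names)
    if (!file.exists(col_names)) stop("missing column-name file: ", col_names)
    m <- Matrix::readMM(path)
    rn <- readLines(row_names)
    cn <- readLines(col_names)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("shape mismatch between matrix and id files")
    # stored gene x cell; transpose to cells x genes
    mat <- t(as.matrix(m))
    expression_matrix(mat, cn, rn, domain = domain, stage = "raw")
  }
}

#' Write an expression matrix as delimited text
#'
#' First column `sample_id`, remaining columns one per gene; round-trips
#' through [load_expression()].
#'
#' @param x an `expression_matrix`.
#' @param path output path.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @export
write_expression <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(sample_id = x$sample_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}
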