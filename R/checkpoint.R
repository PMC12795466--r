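#' Save a trained model checkpoint
#'
#' Writes a checkpoint directory: `weights.rds` (parameters and batch-norm
#' running statistics, R serialization) plus a human-readable
#' `manifest.json` recording the model configuration, input dimension and
#' package version.
#'
#' @param model a `dagformer_model` (or `dagformer_fit`, whose model is
#'   saved).
#' @param path checkpoint directory (created if needed).
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "dagformer_fit")) model <- model$model
  stopifnot(inherits(model, "dagformer_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(params = model$params, state = model$state), file.path(path, "weights.rds"))
  jsonlite::write_json(
    list(model_config = unclass(model$cfg), d_in = model$d_in,
         package_version = as.character(utils::packageVersion("dagformer"))),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path a directory written by [save_checkpoint()].
#' @return A `dagformer_model`.
#' @export
load_checkpoint <- function(path) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"), simplifyVector = TRUE)
  w <- readRDS(file.path(path, "weights.rds"))
  cfg <- do.call(model_config, man$model_config)
  structure(list(params = w$params, state = w$state, cfg = cfg,
                 d_in = man$d_in),
            class = "dagformer_model")
}

#' Export embeddings as TSV for external visualization
#'
#' Runs an eval-mode forward pass through the chosen encoder and writes one
#' row per sample (`sample_id` followed by the embedding dimensions),
#' suitable for UMAP or other external tools.
#'
#' @param model a `dagformer_model` or `dagformer_fit`.
#' @param x an `expression_matrix`.
#' @param graph matching `cell_graph`.
#' @param path output TSV path.
#' @param which encoder: `"shared"`, `"src_private"` or `"tgt_private"`.
#' @return Invisibly, `path`.
#' @export
export_embeddings <- function(model, x, graph, path, which = "shared") {
  if (inherits(model, "dagformer_fit")) model <- model$model
  h <- encode(model, x, graph, which)
  ids <- if (inherits(x, "expression_matrix")) x$sample_ids else
    paste0("s", seq_len(nrow(h)))
  df <- data.frame(sample_id = ids, h, check.names = FALSE)
  colnames(df)[-1] <- paste0("dim", seq_len(ncol(h)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
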