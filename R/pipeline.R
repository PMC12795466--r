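#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates simulate/load -> preprocess -> build-graph -> train ->
#' predict -> evaluate. The configuration is a nested list (or a YAML/JSON
#' file path) with top-level sections `out_dir`, `seed`, and optionally
#' `simulate` (or `data`), `preprocess`, `graph`, `model`, `train`. Unknown
#' top-level keys raise a schema error naming the key. A run manifest
#' (config snapshot, seeds, input hashes, package version, stage timings,
#' output paths) is written before training and finalized at the end;
#' per-epoch losses stream to `losses.jsonl` and predictions to
#' `predictions.tsv`.
#'
#' @param config nested list, or path to a YAML or JSON config file.
#' @return Invisibly, a list with `fit`, `prediction`, `metrics` and
#'   `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  allowed <- c("out_dir", "seed", "simulate", "data", "preprocess", "graph",
               "model", "train")
  bad <- setdiff(names(config), allowed)
  if (length(bad) > 0) stop("unknown config key: ", paste(bad, collapse = ", "))
  if (is.null(config$out_dir)) stop("config requires out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 0 else as.integer(config$seed)

  paths <- list(manifest = file.path(out_dir, "manifest.json"),
                losses = file.path(out_dir, "losses.jsonl"),
                predictions = file.path(out_dir, "predictions.tsv"),
                metrics = file.path(out_dir, "metrics.json"))
  timings <- list()
  manifest <- list(config = config, seed = seed,
                   package_version = as.character(utils::packageVersion("dagformer")),
                   status = "started")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  tic <- function() proc.time()[["elapsed"]]

  # ---- stage: simulate or load -----------------------------------------
  t0 <- tic()
  truth <- NULL
  if (!is.null(config$simulate)) {
    preset <- if (is.null(config$simulate$preset)) "separable" else config$simulate$preset
    scfg <- synth_preset(preset, seed = seed)
    overrides <- config$simulate[setdiff(names(config$simulate), c("preset", "seed"))]
    if (length(overrides) > 0) scfg[names(overrides)] <- overrides
    ds <- generate_synthetic(scfg)
    src_x <- ds$source$x; src_y <- ds$source$y
    tgt_x <- ds$target$x; truth <- ds$truth
    manifest$simulate <- ds$manifest
  } else if (!is.null(config$data)) {
    d <- config$data
    fmt <- if (is.null(d$format)) "csv" else d$format
    src_x <- load_expression(d$source, fmt, domain = "source")
    tgt_x <- load_expression(d$target, fmt, domain = "target")
    lab <- data.table::fread(d$source_labels, data.table = FALSE)
    src_y <- as.integer(lab[[2]])[match(src_x$sample_ids, as.character(lab[[1]]))]
    if (anyNA(src_y)) stop("source labels do not cover all source samples")
    if (!is.null(d$truth)) {
      tl <- data.table::fread(d$truth, data.table = FALSE)
      truth <- as.integer(tl[[2]])[match(tgt_x$sample_ids, as.character(tl[[1]]))]
    }
    manifest$input_hashes <- as.list(tools::md5sum(
      unlist(d[intersect(names(d), c("source", "source_labels", "target", "truth"))])))
  } else stop("config requires either a simulate or a data section")
  timings$load <- tic() - t0

  # ---- stage: preprocess ------------------------------------------------
  t0 <- tic()
  pp <- config$preprocess
  getd <- function(x, nm, def) if (is.null(x[[nm]])) def else x[[nm]]
  target_counts <- getd(pp, "target_counts", all(tgt_x$values >= 0))
  if (target_counts) {
    qp <- qc_params(min_genes_per_cell = getd(pp, "min_genes", 200),
                    min_cells_per_gene = getd(pp, "min_cells_per_gene", 3),
                    max_mito_fraction = getd(pp, "max_mito", 0.2),
                    mito_prefix = getd(pp, "mito_prefix", "MT-"))
    keep_before <- tgt_x$sample_ids
    tgt_x <- qc_filter_cells(tgt_x, qp)
    if (!is.null(truth)) truth <- truth[match(tgt_x$sample_ids, keep_before)]
    tgt_x <- normalize_target(tgt_x, target_sum = getd(pp, "target_sum", 1e4))
  } else {
    tgt_x <- standardize_source(tgt_x) # already-continuous expression: z-score only
  }
  src_x <- standardize_source(src_x)
  ig <- intersect_genes(src_x, tgt_x)
  src_x <- ig$source; tgt_x <- ig$target
  if (isTRUE(getd(pp, "balance", TRUE))) {
    bp <- balance_params(smote_ratio = getd(pp, "smote_ratio", 0.5),
                         final_ratio = getd(pp, "final_ratio", 1.0),
                         k_smote = getd(pp, "k_smote", 5),
                         seed = seed)
    bal <- balance_classes(src_x, src_y, bp)
    src_x <- bal$x; src_y <- bal$y
  }
  timings$preprocess <- tic() - t0

  # ---- stage: build graphs ---------------------------------------------
  t0 <- tic()
  gcfg <- config$graph
  method <- getd(gcfg, "method", "knn")
  k <- getd(gcfg, "k", 15)
  percent <- getd(gcfg, "percent", 20)
  gs <- build_cell_graph(src_x, method, k = min(k, nrow(src_x$values) - 1), percent = percent)
  gt <- build_cell_graph(tgt_x, method, k = min(k, nrow(tgt_x$values) - 1), percent = percent)
  timings$graph <- tic() - t0

  # ---- stage: train -----------------------------------------------------
  t0 <- tic()
  mcfg <- do.call(model_config, c(config$model, list()))
  tr <- config$train
  w <- do.call(loss_weights, if (is.null(tr$weights)) list() else tr$weights)
  tcfg <- train_config(epochs = getd(tr, "epochs", 300),
                       learning_rate = getd(tr, "learning_rate", 1e-3),
                       weight_decay = getd(tr, "weight_decay", 1e-4),
                       seed = seed,
                       grl_gamma = getd(tr, "grl_gamma", 10),
                       use_gda = getd(tr, "use_gda", TRUE),
                       holdout_fraction = getd(tr, "holdout_fraction", 0),
                       weights = w)
  fit <- train_dagformer(list(x = src_x, y = src_y, graph = gs),
                         list(x = tgt_x, graph = gt), mcfg, tcfg)
  h <- fit$state$history
  con <- file(paths$losses, "w")
  for (i in seq_len(nrow(h)))
    writeLines(jsonlite::toJSON(as.list(h[i, ]), auto_unbox = TRUE, digits = NA), con)
  close(con)
  timings$train <- tic() - t0

  # ---- stage: predict & evaluate ---------------------------------------
  t0 <- tic()
  pr <- predict_dagformer(fit, list(x = tgt_x, graph = gt), y_true = truth)
  data.table::fwrite(data.frame(cell_id = pr$cell_id, psi = pr$psi,
                                label = pr$label),
                     paths$predictions, sep = "\t")
  metrics <- pr$metrics
  if (!is.null(metrics))
    jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE, digits = NA)
  timings$predict <- tic() - t0

  manifest$timings <- timings
  manifest$status <- "finished"
  manifest$outputs <- paths
  manifest$final_losses <- as.list(h[nrow(h), ])
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(fit = fit, prediction = pr, metrics = metrics, paths = paths))
}
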