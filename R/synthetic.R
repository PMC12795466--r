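#' Configuration for the two-domain synthetic generator
#'
#' The generator emulates the statistical structure the method assumes:
#' a class-discriminative signal shared by both domains, a domain shift
#' affecting the target (single-cell) features, and bulk-like smoothing in
#' the source (each bulk sample averages several same-class cells). Labels
#' are exposed only for the source; target truth labels are carried in a
#' separate evaluation-only slot.
#'
#' @param n_source,n_target sample/cell counts.
#' @param n_genes total genes; `n_informative` of them separate the classes.
#' @param n_informative informative genes.
#' @param effect_size class-mean separation on informative genes, in units
#'   of `noise_sd`.
#' @param shift_strength magnitude of the additive target-domain offset
#'   (applied with random sign to a random half of the genes) and scale of
#'   the multiplicative jitter (lognormal, sdlog `0.1 * shift_strength`).
#' @param bulk_group_size cells averaged per pseudo-bulk source sample.
#' @param noise_sd per-gene cell-level noise sd.
#' @param class_balance_source,class_balance_target sensitive-class
#'   fractions.
#' @param counts if TRUE, generate negative-binomial counts (with library
#'   size variation and mitochondrial genes) for exercising the QC path
#'   instead of the Gaussian expression the model consumes.
#' @param seed RNG seed; generation is bit-reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_source = 200, n_target = 300, n_genes = 300,
                         n_informative = 40, effect_size = 2.0,
                         shift_strength = 1.0, bulk_group_size = 10,
                         noise_sd = 1.0, class_balance_source = 0.25,
                         class_balance_target = 0.5, counts = FALSE,
                         seed = 0) {
  stopifnot(n_informative <= n_genes, n_source >= 2, n_target >= 2,
            n_genes >= 2, effect_size >= 0, bulk_group_size >= 1,
            class_balance_source > 0, class_balance_source < 1,
            class_balance_target > 0, class_balance_target < 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Preset synthetic configurations
#'
#' `"separable"` uses the generator defaults (clear class signal plus a unit
#' domain shift); `"shifted"` doubles the domain shift to stress the
#' adversarial alignment; `"null"` removes the class signal entirely.
#'
#' @param preset one of `"separable"`, `"shifted"`, `"null"`.
#' @param seed RNG seed.
#' @return A `synth_config`.
#' @export
synth_preset <- function(preset = c("separable", "shifted", "null"), seed = 0) {
  preset <- match.arg(preset)
  switch(preset,
         separable = synth_config(seed = seed),
         shifted = synth_config(shift_strength = 2.0, seed = seed),
         null = synth_config(effect_size = 0, seed = seed))
}

#' Generate a two-domain synthetic dataset
#'
#' Latent class means differ by `effect_size * noise_sd` on the informative
#' genes. Target cells are drawn per class with Gaussian noise, then receive
#' the domain shift (additive offsets of magnitude `shift_strength` with
#' random sign on a random half of the genes, plus per-gene multiplicative
#' jitter). Source pseudo-bulk samples average `bulk_group_size` same-class
#' cells drawn without the shift and add small measurement noise
#' (`0.2 * noise_sd`), emulating the smoothed expression of bulk profiles.
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_dataset`: `source` (`x`, `y`), `target`
#'   (`x`), `truth` (evaluation-only target labels), `manifest` (the full
#'   config).
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  g <- config$n_genes
  info <- seq_len(config$n_informative)
  mu_sens <- rep(0, g); mu_res <- rep(0, g)
  half <- config$effect_size * config$noise_sd / 2
  mu_sens[info] <- half
  mu_res[info] <- -half

  draw_cells <- function(n, y) {
    mu <- rbind(mu_res, mu_sens)[y + 1, , drop = FALSE]
    mu + matrix(stats::rnorm(n * g, sd = config$noise_sd), n, g)
  }

  if (config$counts) return(.generate_counts(config, mu_sens, mu_res))

  # target single cells, then domain shift
  n_t <- config$n_target
  y_t <- stats::rbinom(n_t, 1, config$class_balance_target)
  Xt <- draw_cells(n_t, y_t)
  shifted_genes <- sample.int(g, floor(g / 2))
  offset <- rep(0, g)
  offset[shifted_genes] <- config$shift_strength *
    sample(c(-1, 1), length(shifted_genes), replace = TRUE)
  scale_jit <- exp(stats::rnorm(g, sd = 0.1 * config$shift_strength))
  Xt <- sweep(Xt, 2, scale_jit, "*")
  Xt <- sweep(Xt, 2, offset, "+")

  # source pseudo-bulk: mean of bulk_group_size same-class cells + noise
  n_s <- config$n_source
  y_s <- stats::rbinom(n_s, 1, config$class_balance_source)
  # guarantee both classes
  if (sum(y_s) < 2) y_s[1:2] <- 1
  if (sum(1 - y_s) < 2) y_s[1:2] <- 0
  Xs <- t(vapply(seq_len(n_s), function(i) {
    cells <- draw_cells(config$bulk_group_size, rep(y_s[i], config$bulk_group_size))
    colMeans(cells) + stats::rnorm(g, sd = 0.2 * config$noise_sd)
  }, numeric(g)))

  gene_ids <- sprintf("G%04d", seq_len(g))
  src <- expression_matrix(Xs, sprintf("bulk_%03d", seq_len(n_s)), gene_ids,
                           domain = "source", stage = "raw")
  tgt <- expression_matrix(Xt, sprintf("cell_%04d", seq_len(n_t)), gene_ids,
                           domain = "target", stage = "raw")
  structure(list(source = list(x = src, y = as.integer(y_s)),
                 target = list(x = tgt),
                 truth = as.integer(y_t),
                 manifest = unclass(config)),
            class = "synth_dataset")
}

# Negative-binomial count mode for exercising QC: informative signal enters
# through the NB mean; gene 1..5 are mitochondrial ("MT-"), library sizes
# vary lognormally, and a few cells get an inflated mitochondrial fraction.
.generate_counts <- function(config, mu_sens, mu_res) {
  g <- config$n_genes
  n_t <- config$n_target
  y_t <- stats::rbinom(n_t, 1, config$class_balance_target)
  base <- exp(stats::rnorm(g, mean = 1, sd = 1)) # per-gene baseline expression
  mu_mat <- rbind(mu_res, mu_sens)[y_t + 1, , drop = FALSE]
  lib <- exp(stats::rnorm(n_t, mean = 0, sd = 0.3))
  mu_counts <- (exp(mu_mat * 0.5) * rep(base, each = n_t)) * lib
  Xt <- matrix(stats::rnbinom(n_t * g, mu = as.vector(mu_counts), size = 2), n_t, g)
  n_mito <- min(5, g)
  mito_boost <- sample.int(n_t, max(1, round(0.05 * n_t)))
  Xt[mito_boost, seq_len(n_mito)] <- Xt[mito_boost, seq_len(n_mito)] +
    matrix(stats::rpois(length(mito_boost) * n_mito,
                        lambda = mean(mu_counts) * g * 0.1),
           length(mito_boost), n_mito)
  gene_ids <- c(sprintf("MT-G%02d", seq_len(n_mito)),
                sprintf("G%04d", seq_len(g - n_mito)))
  n_s <- config$n_source
  y_s <- stats::rbinom(n_s, 1, config$class_balance_source)
  if (sum(y_s) < 2) y_s[1:2] <- 1
  mu_s <- rbind(mu_res, mu_sens)[y_s + 1, , drop = FALSE]
  Xs <- mu_s + matrix(stats::rnorm(n_s * g, sd = config$noise_sd / sqrt(config$bulk_group_size)), n_s, g)
  src <- expression_matrix(Xs, sprintf("bulk_%03d", seq_len(n_s)), gene_ids,
                           domain = "source", stage = "raw")
  tgt <- expression_matrix(Xt, sprintf("cell_%04d", seq_len(n_t)), gene_ids,
                           domain = "target", stage = "raw")
  structure(list(source = list(x = src, y = as.integer(y_s)),
                 target = list(x = tgt),
                 truth = as.integer(y_t),
                 manifest = unclass(config)),
            class = "synth_dataset")
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Emits `source.csv` + `source_labels.csv`, `target.csv`, a separately
#' named `target_truth_labels.csv` (evaluation only, never a training
#' input), and `manifest.json` recording the full configuration and seed.
#' Matrices round-trip through [load_expression()].
#'
#' @param ds a `synth_dataset`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
write_fixture <- function(ds, dir) {
  stopifnot(inherits(ds, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    source = file.path(dir, "source.csv"),
    source_labels = file.path(dir, "source_labels.csv"),
    target = file.path(dir, "target.csv"),
    truth = file.path(dir, "target_truth_labels.csv"),
    manifest = file.path(dir, "manifest.json"))
  write_expression(ds$source$x, paths$source)
  data.table::fwrite(data.frame(sample_id = ds$source$x$sample_ids,
                                label = ds$source$y), paths$source_labels)
  write_expression(ds$target$x, paths$target)
  data.table::fwrite(data.frame(cell_id = ds$target$x$sample_ids,
                                label = ds$truth), paths$truth)
  jsonlite::write_json(ds$manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
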