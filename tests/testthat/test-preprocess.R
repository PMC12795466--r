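test_that("load_expression reads dense and sparse formats with rows-as-samples orientation", {
  d <- withr::local_tempdir()
  x <- expression_matrix(matrix(as.numeric(1:6), 3, 2), c("s1", "s2", "s3"),
                         c("gA", "gB"), "source", "raw")
  write_expression(x, file.path(d, "m.csv"))
  y <- load_expression(file.path(d, "m.csv"), "csv", "source")
  expect_equal(dim(y), c(3L, 2L))
  expect_equal(y$values, x$values)
  expect_equal(y$stage, "raw")

  # MTX triplet stored gene-major (3 genes x 2 cells) is transposed on load
  m <- Matrix::Matrix(matrix(c(1, 0, 2, 0, 3, 0), 3, 2), sparse = TRUE)
  Matrix::writeMM(m, file.path(d, "t.mtx"))
  writeLines(c("g1", "g2", "g3"), file.path(d, "t.mtx.rownames"))
  writeLines(c("c1", "c2"), file.path(d, "t.mtx.colnames"))
  z <- load_expression(file.path(d, "t.mtx"), "mtx_triplet", "target")
  expect_equal(dim(z), c(2L, 3L))
  expect_equal(unname(z$values["c2", "g2"]), 3)

  writeLines(c("id,gA,gA", "s1,1,2"), file.path(d, "dup.csv"))
  expect_error(load_expression(file.path(d, "dup.csv"), "csv", "source"),
               "duplicate gene")
  expect_error(load_expression(file.path(d, "nope.csv"), "csv", "source"),
               "not found")
})

test_that("qc_filter_cells applies cell filters then gene filters, matching a rule oracle", {
  counts <- rbind(
    c(5, 3, 2, 1, 0, 4, 2, 1),  # fine
    c(1, 0, 0, 0, 0, 0, 0, 0),  # only 1 detected gene -> removed
    c(9, 1, 1, 1, 1, 1, 1, 1),  # mito fraction 9/16 > 0.2 -> removed
    c(0, 2, 3, 1, 2, 0, 1, 4),  # fine
    c(1, 4, 0, 2, 3, 1, 0, 2),  # fine
    c(0, 1, 2, 3, 0, 0, 4, 0))  # fine
  genes <- c("MT-G1", paste0("G", 1:7))
  x <- expression_matrix(counts, paste0("c", 1:6), genes, "target", "raw")
  p <- qc_params(min_genes_per_cell = 3, min_cells_per_gene = 3,
                 max_mito_fraction = 0.2, mito_prefix = "MT-")
  out <- qc_filter_cells(x, p)

  # independent rule application
  mito_frac <- counts[, 1] / rowSums(counts)
  keep_cells <- rowSums(counts > 0) >= 3 & mito_frac <= 0.2
  keep_genes <- colSums(counts[keep_cells, ] > 0) >= 3
  expect_equal(out$sample_ids, paste0("c", 1:6)[keep_cells])
  expect_equal(out$gene_ids, genes[keep_genes])
  rep <- attr(out, "filter_report")
  expect_setequal(rep$cells_removed, paste0("c", 1:6)[!keep_cells])

  # threshold behavior from the rules: mito fraction 0.25 > 0.20 removes the
  # cell; a gene seen in exactly 2 cells with min_cells_per_gene = 3 is cut
  x2 <- expression_matrix(rbind(c(1, 3), c(0, 4), c(0, 5)),
                          paste0("c", 1:3), c("MT-1", "G1"), "target", "raw")
  out2 <- qc_filter_cells(x2, qc_params(min_genes_per_cell = 1,
                                        min_cells_per_gene = 1,
                                        max_mito_fraction = 0.2))
  expect_false("c1" %in% out2$sample_ids) # mito fraction 0.25

  x3 <- expression_matrix(cbind(c(1, 1, 0, 0), matrix(1, 4, 2)),
                          paste0("c", 1:4), c("rare", "G1", "G2"),
                          "target", "raw")
  out3 <- qc_filter_cells(x3, qc_params(min_genes_per_cell = 1,
                                        min_cells_per_gene = 3))
  expect_false("rare" %in% out3$gene_ids)

  expect_error(qc_filter_cells(expression_matrix(matrix(-1, 2, 2),
                                                 domain = "target"),
                               qc_params(min_genes_per_cell = 1)),
               "negative")
})

test_that("qc_filter_cells is order-stable", {
  set.seed(7)
  counts <- matrix(rpois(30 * 20, 2), 30, 20)
  genes <- c("MT-1", paste0("G", 1:19))
  x <- expression_matrix(counts, paste0("c", 1:30), genes, "target", "raw")
  p <- qc_params(min_genes_per_cell = 8, min_cells_per_gene = 5)
  a <- qc_filter_cells(x, p)
  perm <- sample(30)
  xp <- expression_matrix(counts[perm, ], paste0("c", 1:30)[perm], genes,
                          "target", "raw")
  b <- qc_filter_cells(xp, p)
  expect_setequal(a$sample_ids, b$sample_ids)
  expect_equal(a$gene_ids, b$gene_ids)
})

test_that("normalize_target matches a step-by-step oracle", {
  counts <- rbind(c(1, 2, 7), c(0, 5, 5), c(3, 3, 4), c(2, 0, 8))
  x <- expression_matrix(counts, paste0("c", 1:4), paste0("g", 1:3),
                         "target", "raw")
  ts <- 100
  out <- normalize_target(x, target_sum = ts)

  scaled <- counts / rowSums(counts) * ts
  expect_equal(rowSums(scaled), rep(ts, 4))
  logged <- log1p(scaled)
  z <- logged
  for (j in 1:3) {
    mu <- mean(logged[, j])
    sdp <- sqrt(mean((logged[, j] - mu)^2))
    z[, j] <- (logged[, j] - mu) / sdp
  }
  expect_equal(unname(out$values), unname(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(out$stage, "standardized")

  # a zero count stays exactly zero through the log step
  zero_in <- counts == 0
  expect_true(all(log1p(scaled)[zero_in] == 0))
  expect_error(normalize_target(expression_matrix(rbind(c(0, 0), c(1, 2)),
                                                  domain = "target")),
               "total count 0")
})

test_that("standardize_source z-scores with population sd and handles degenerate genes", {
  x <- expression_matrix(cbind(c(1, 2, 3), c(5, 5, 5)), paste0("s", 1:3),
                         c("g1", "g2"), "source", "raw")
  out <- standardize_source(x)
  expect_equal(unname(out$values[, 1]), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(out$values[, 2]), c(0, 0, 0))
  expect_equal(attr(out, "zero_variance_genes"), "g2")
  # idempotence on already-standardized data
  again <- standardize_source(out)
  expect_equal(again$values[, 1], out$values[, 1], tolerance = 1e-6)
})

test_that("intersect_genes restricts to the sorted shared gene set", {
  a <- expression_matrix(matrix(1:6, 2, 3), NULL, c("A", "B", "C"), "source", "raw")
  b <- expression_matrix(matrix(1:6, 2, 3), NULL, c("B", "C", "D"), "target", "raw")
  out <- intersect_genes(a, b)
  expect_equal(out$source$gene_ids, c("B", "C"))
  expect_equal(out$target$gene_ids, c("B", "C"))
  expect_equal(out$n_shared, 2L)
  expect_equal(out$source$values, a$values[, c("B", "C")])

  # identical gene sets: unchanged up to sorted column order
  c1 <- expression_matrix(matrix(1:6, 2, 3), NULL, c("C", "A", "B"), "source", "raw")
  out2 <- intersect_genes(c1, c1)
  expect_equal(out2$source$gene_ids, c("A", "B", "C"))
  expect_equal(out2$source$values, c1$values[, c("A", "B", "C")])

  d1 <- expression_matrix(matrix(1:4, 2, 2), NULL, c("X", "Y"), "target", "raw")
  expect_error(intersect_genes(a, d1), "empty gene intersection")
})

test_that("balance_classes reproduces the two-step SMOTE + undersampling contract", {
  set.seed(11)
  n_res <- 714; n_sens <- 115
  vals <- matrix(rnorm((n_res + n_sens) * 10), ncol = 10)
  y <- c(rep(0L, n_res), rep(1L, n_sens))
  x <- expression_matrix(vals, sprintf("cl%03d", seq_along(y)), paste0("g", 1:10),
                         "source", "standardized")
  out <- balance_classes(x, y, balance_params(seed = 3))
  expect_equal(sum(out$y == 1), 357L) # round(0.5 * 714)
  expect_equal(sum(out$y == 0), 357L)

  # every synthetic sample is a convex combination of its two minority parents
  parents <- attr(out$x, "smote_parents")
  expect_equal(nrow(parents), 357L - 115L)
  for (r in sample(nrow(parents), 25)) {
    pa <- vals[parents[r, "parent_a"], ]
    pb <- vals[parents[r, "parent_b"], ]
    synth <- unname(out$x$values[115 + r, ]) # minority originals come first
    expect_true(all(synth >= pmin(pa, pb) - 1e-12))
    expect_true(all(synth <= pmax(pa, pb) + 1e-12))
    dir1 <- synth - pa
    dir2 <- pb - pa
    u <- sum(dir1 * dir2) / sum(dir2 * dir2)
    expect_true(u >= 0 && u <= 1)
    expect_equal(dir1, u * dir2, tolerance = 1e-8)
  }

  # bit-reproducible under the seed
  out2 <- balance_classes(x, y, balance_params(seed = 3))
  expect_identical(out$x$values, out2$x$values)
  expect_identical(out$y, out2$y)

  # already balanced input with defaults is unchanged in counts
  y_bal <- rep(c(0L, 1L), each = 30)
  xb <- expression_matrix(matrix(rnorm(60 * 5), 60, 5), NULL, paste0("g", 1:5),
                          "source", "standardized")
  outb <- balance_classes(xb, y_bal, balance_params(seed = 1))
  expect_equal(as.vector(table(outb$y)), c(30L, 30L))

  expect_error(balance_classes(xb, rep(0L, 60), balance_params()),
               "both classes")
})
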