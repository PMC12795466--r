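test_that("input projection is a bias-free linear map with ReLU", {
  W <- matrix(c(1, -1, 0.5, 2, 0, -3), 3, 2)
  X <- matrix(c(1, 0, 2, 1, -1, 0), 2, 3)
  H <- input_projection(X, W)
  expect_equal(unname(H), pmax(X %*% W, 0), ignore_attr = TRUE)
  expect_equal(input_projection(matrix(0, 2, 3), W), matrix(0, 2, 2),
               ignore_attr = TRUE)
  expect_equal(input_projection(X, W * 0), matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(input_projection(X, matrix(0, 4, 2)), "shape mismatch")
})

test_that("sparse attention matches trivial neighbor cases and the dense oracle", {
  cfg <- model_config(d_h = 8, n_layers = 1, n_heads = 2, d_k = 4,
                      ffn_hidden = 8, seed = 1)
  set.seed(2)
  layer <- list(W_Q = matrix(rnorm(64), 8, 8), W_K = matrix(rnorm(64), 8, 8),
                W_V = matrix(rnorm(64), 8, 8))

  # node with a single neighbor (its self-loop) gets softmax weight 1
  A <- matrix(0, 3, 3); A[2, 3] <- 1
  g <- symmetrize_normalize(A)
  H <- matrix(rnorm(24), 3, 8)
  out <- sparse_attention(H, g, layer, cfg)
  V <- H %*% layer$W_V
  expect_equal(out[1, 1:4], V[1, 1:4], tolerance = 1e-12) # head 1 of isolated node

  x <- rand_expr(7, 5, seed = 8)
  g2 <- build_cell_graph(x, "knn", k = 2)
  H2 <- matrix(rnorm(7 * 8), 7, 8)
  expect_equal(sparse_attention(H2, g2, layer, cfg),
               oracle_attention(H2, layer, as.matrix(g2$adjacency), 2, 4),
               tolerance = 1e-10)
})

test_that("the sparse encoder path agrees with the layer-op composition", {
  cfg <- model_config(d_h = 8, n_layers = 1, n_heads = 2, d_k = 4,
                      ffn_hidden = 12, disc_hidden = 6, seed = 5)
  x <- rand_expr(9, 6, seed = 10)
  g <- build_cell_graph(x, "knn", k = 3)
  model <- init_model(6, cfg)
  h_enc <- encode(model, x, g, "shared", training = FALSE)
  h0 <- input_projection(x$values, model$params$shared$W_proj)
  attr(h0, "relu_mask") <- NULL
  h1 <- transformer_block(h0, g, model$params$shared$layers[[1]], cfg,
                          training = FALSE)
  expect_equal(h_enc, h1, tolerance = 1e-10)
})

test_that("encoders are parameter-disjoint and the shared encoder is weight-tied", {
  cfg <- tiny_model_cfg(seed = 2)
  x <- rand_expr(10, 7, seed = 3)
  g <- build_cell_graph(x, "knn", k = 3)
  model <- init_model(7, cfg)

  h_shared_1 <- encode(model, x, g, "shared")
  # mutating a private encoder leaves the others untouched
  model2 <- model
  model2$params$src_private$W_proj <- model2$params$src_private$W_proj * 0
  expect_equal(encode(model2, x, g, "shared"), h_shared_1)
  expect_equal(encode(model2, x, g, "tgt_private"),
               encode(model, x, g, "tgt_private"))
  expect_false(isTRUE(all.equal(encode(model2, x, g, "src_private"),
                                encode(model, x, g, "src_private"))))

  # the shared encoder applies one parameter set to any domain's input
  x2 <- rand_expr(10, 7, seed = 4, domain = "source")
  model3 <- model
  model3$params$shared$layers[[1]]$W_Q <- model3$params$shared$layers[[1]]$W_Q + 0.1
  expect_false(isTRUE(all.equal(encode(model3, x, g, "shared"), h_shared_1)))
  expect_false(isTRUE(all.equal(encode(model3, x2, g, "shared"),
                                encode(model, x2, g, "shared"))))

  # deterministic in eval mode
  expect_identical(encode(model, x, g, "shared"), encode(model, x, g, "shared"))
})

test_that("encoder outputs are permutation-equivariant in eval mode", {
  cfg <- tiny_model_cfg(seed = 7)
  x <- rand_expr(12, 9, seed = 12)
  g <- build_cell_graph(x, "knn", k = 4)
  model <- init_model(9, cfg)
  h <- encode(model, x, g, "shared")

  set.seed(99)
  perm <- sample(12)
  xp <- expression_matrix(x$values[perm, ], x$sample_ids[perm], x$gene_ids,
                          x$domain, x$stage)
  gp <- build_cell_graph(xp, "knn", k = 4)
  hp <- encode(model, xp, gp, "shared")
  expect_equal(hp, h[perm, ], tolerance = 1e-10)
})

test_that("inner-product decoder, discriminator and predictor match hand computations", {
  expect_equal(inner_product_decode(matrix(0, 3, 2), matrix(0, 3, 2)),
               matrix(0.5, 3, 3))
  Hp <- rbind(c(1, 0), c(0, 2))
  Hs <- rbind(c(0.5, 1), c(-1, 0))
  P <- inner_product_decode(Hp, Hs)
  Z <- cbind(Hp, Hs)
  expect_equal(P, 1 / (1 + exp(-Z %*% t(Z))))
  expect_equal(P, t(P))
  expect_error(inner_product_decode(matrix(0, 2, 2), matrix(0, 3, 2)),
               "row count mismatch")

  cfg <- tiny_model_cfg(seed = 1)
  model <- init_model(5, cfg)
  H <- matrix(rnorm(3 * 16), 3, 16)
  # zero weights -> 0.5 everywhere for both heads
  m0 <- model
  m0$params$disc <- lapply(m0$params$disc, function(p) p * 0)
  m0$params$pred <- lapply(m0$params$pred, function(p) p * 0)
  expect_equal(discriminate_domain(m0, H), rep(0.5, 3))
  expect_equal(predict_response(m0, H), rep(0.5, 3))

  # hand computation for one sample
  h1 <- matrix(rnorm(16), 1, 16)
  d <- model$params$disc
  a1 <- pmax(h1 %*% d$W1 + matrix(d$b1, 1), 0)
  expect_equal(discriminate_domain(model, h1),
               as.numeric(1 / (1 + exp(-(a1 %*% d$W2 + d$b2)))))
  p <- model$params$pred
  expect_equal(predict_response(model, h1),
               as.numeric(1 / (1 + exp(-(h1 %*% p$W + p$b)))))
  expect_true(all(discriminate_domain(model, H) > 0 &
                    discriminate_domain(model, H) < 1))
})

test_that("gradient_reversal is the identity in the forward pass", {
  H <- matrix(rnorm(6), 2, 3)
  expect_identical(gradient_reversal(H, 0.5), H)
  expect_identical(gradient_reversal(H, 0), H)
  expect_error(gradient_reversal(H, -1))
})

test_that("analytic parameter gradients match central finite differences", {
  ds <- generate_synthetic(synth_config(n_source = 14, n_target = 16,
                                        n_genes = 10, n_informative = 4,
                                        seed = 1))
  src <- standardize_source(ds$source$x)
  tgt <- standardize_source(ds$target$x)
  gs <- dagformer:::graph_csr(build_cell_graph(src, "knn", k = 4))
  gt <- dagformer:::graph_csr(build_cell_graph(tgt, "knn", k = 4))
  cfg <- model_config(d_h = 8, n_layers = 2, n_heads = 2, d_k = 4,
                      ffn_hidden = 10, disc_hidden = 6, seed = 3)
  model <- init_model(10, cfg)
  # keep decoder logits unsaturated so the clipped loss stays differentiable
  for (enc in c("src_private", "tgt_private", "shared"))
    model$params[[enc]]$layers[[2]]$W2 <- model$params[[enc]]$layers[[2]]$W2 * 0.3
  Xs <- src$values; Xt <- tgt$values; y <- ds$source$y
  fwd <- dagformer:::full_forward(model, Xs, gs, Xt, gt, training = TRUE,
                                  update_state = FALSE)

  setval <- function(lst, path, i, delta) {
    if (length(path) == 1) {
      lst[[path[[1]]]][i] <- lst[[path[[1]]]][i] + delta
      lst
    } else {
      lst[[path[[1]]]] <- setval(lst[[path[[1]]]], path[-1], i, delta)
      lst
    }
  }
  getval <- function(lst, path) {
    for (p in path) lst <- lst[[p]]
    lst
  }
  lossfun <- function(m, term) {
    f <- dagformer:::full_forward(m, Xs, gs, Xt, gt, training = TRUE,
                                  update_state = FALSE)
    c2 <- dagformer:::compute_loss_components(f, y, gs$binary, gt$binary)
    dagformer:::free_forward_caches(f)
    switch(term, cls = c2$cls, dom = -c2$dom, ent = c2$ent,
           diff = c2$diff, rec = c2$rec)
  }
  cases <- list(
    list(list("shared", "W_proj"), 5, "cls"),
    list(list("shared", "layers", 1L, "W_Q"), 7, "cls"),
    list(list("shared", "layers", 2L, "bn1_gamma"), 3, "cls"),
    list(list("shared", "layers", 1L, "W1"), 9, "cls"),
    list(list("pred", "W"), 2, "ent"),
    list(list("disc", "W1"), 4, "dom"),
    list(list("src_private", "layers", 2L, "W_V"), 5, "diff"),
    list(list("tgt_private", "layers", 1L, "W_Q"), 8, "rec"))
  for (cs in cases) {
    path <- cs[[1]]; i <- cs[[2]]; term <- cs[[3]]
    b <- dagformer:::full_backward(model, fwd, y, gs$binary, gt$binary,
                                   loss_weights(), 1, 0, term_select = term)
    g_an <- getval(b$grads, path)[i]
    h <- 1e-5
    mp <- model; mp$params <- setval(model$params, path, i, h)
    mm <- model; mm$params <- setval(model$params, path, i, -h)
    g_nu <- (lossfun(mp, term) - lossfun(mm, term)) / (2 * h)
    expect_lt(abs(g_an - g_nu) / max(abs(g_nu), 1e-7), 1e-4)
  }
  dagformer:::free_forward_caches(fwd)
})
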