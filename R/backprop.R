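# Hand-written backward passes mirroring the forward functions in model.R.
# Gradients are returned in lists shaped exactly like the parameter lists so
# the optimizer can walk the two structures in parallel.

zero_like <- function(p) {
  if (is.list(p)) return(lapply(p, zero_like))
  z <- numeric(length(p))
  if (!is.null(dim(p))) dim(z) <- dim(p)
  z
}

# Backward through a full encoder (C++ cache). Returns grads (same shape as
# encoder params) and dX (gradient w.r.t. the input expression matrix).
encoder_backward <- function(model, dh, cache, want_dX = TRUE) {
  cpp_encoder_backward(cache$ptr, dh, want_dX)
}

# release the C++ caches of one full forward pass
free_forward_caches <- function(fwd) {
  for (nm in c("e_pr_s", "e_pr_t", "e_sh_s", "e_sh_t"))
    cpp_encoder_cache_free(fwd[[nm]]$cache$ptr)
  invisible(NULL)
}

# flatten/unflatten a nested parameter list to a single numeric vector
flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, skeleton) {
  i <- 0L
  rebuild <- function(s) {
    if (is.list(s)) return(lapply(s, rebuild))
    len <- length(s)
    v <- flat[(i + 1L):(i + len)]
    i <<- i + len
    dm <- dim(s)
    if (!is.null(dm)) dim(v) <- dm
    v
  }
  rebuild(skeleton)
}

# discriminator backward from dlogit (n x 1)
disc_backward <- function(params, dlogit, cache) {
  dlogit <- matrix(dlogit, ncol = 1)
  g <- list()
  g$W2 <- crossprod(cache$r1, dlogit)
  g$b2 <- sum(dlogit)
  dr1 <- tcrossprod(dlogit, params$W2)
  da1 <- dr1 * cache$a1_mask
  g$W1 <- crossprod(cache$h, da1)
  g$b1 <- colSums(da1)
  list(grads = g, dh = tcrossprod(da1, params$W1))
}

pred_backward <- function(params, dlogit, cache) {
  dlogit <- matrix(dlogit, ncol = 1)
  list(grads = list(W = crossprod(cache$h, dlogit), b = sum(dlogit)),
       dh = tcrossprod(dlogit, params$W))
}

# elementwise walk over two parameter structures; matches by name when both
# lists are named (gradient lists may be assembled in a different order)
map2_params <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    by_name <- !is.null(names(a)) && !is.null(names(b)) &&
      all(names(a) != "") && setequal(names(a), names(b))
    for (i in seq_along(a)) {
      bi <- if (by_name) b[[names(a)[i]]] else b[[i]]
      out[[i]] <- map2_params(f, a[[i]], bi)
    }
    out
  } else f(a, b)
}

add_params <- function(a, b) map2_params(`+`, a, b)

scale_params <- function(a, s) {
  if (is.list(a)) lapply(a, scale_params, s = s) else a * s
}

# Adam step over the whole nested parameter list. st holds m, v, t.
adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1
  t <- st$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      newp <- p; newm <- m; newv <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        newp[[i]] <- r$p; newm[[i]] <- r$m; newv[[i]] <- r$v
      }
      return(list(p = newp, m = newm, v = newv))
    }
    g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- walk(params, grads, st$m, st$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
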