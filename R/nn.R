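# Minimal dense-network engine: multilayer perceptrons with ReLU hidden
# units, optional batch normalization on hidden layers, linear or sigmoid
# output, analytic backpropagation, and an Adam optimizer over nested
# parameter trees.  There is no autodiff framework in this stack, so the
# gradients are derived by hand and checked against numerical gradients in
# the test suite.

#' Create a multilayer perceptron
#'
#' Hidden layers are affine + (optional batch normalization) + ReLU; the
#' output layer is affine with a configurable activation.  Weights use He
#' initialization from the current RNG state, so wrap construction in a
#' seeded context for reproducibility.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param activation hidden activation, `"relu"` (default) or `"linear"`.
#' @param out_activation `"linear"` (default), `"sigmoid"` or `"relu"`.
#' @param batchnorm apply batch normalization to hidden layers.
#' @param init_scale optional fixed s.d. for weight init (default He).
#' @return an object of class `pc_mlp`.
#' @keywords internal
mlp_new <- function(sizes, activation = "relu", out_activation = "linear",
                    batchnorm = FALSE, init_scale = NULL) {
  if (length(sizes) < 2L) pc_stop("an MLP needs at least input and output widths",
                                  "pertcycle_config_error")
  nl <- length(sizes) - 1L
  layers <- vector("list", nl)
  running <- vector("list", nl)
  for (i in seq_len(nl)) {
    fin <- sizes[i]; fout <- sizes[i + 1L]
    sd <- if (is.null(init_scale)) sqrt(2 / fin) else init_scale
    L <- list(W = matrix(stats::rnorm(fin * fout, 0, sd), fin, fout),
              b = numeric(fout))
    if (batchnorm && i < nl) {
      L$gamma <- rep(1, fout)
      L$beta <- numeric(fout)
      running[[i]] <- list(mean = numeric(fout), var = rep(1, fout))
    }
    layers[[i]] <- L
  }
  structure(list(sizes = as.integer(sizes), activation = activation,
                 out_activation = out_activation, batchnorm = batchnorm,
                 params = layers, running = running,
                 bn_momentum = 0.1, bn_eps = 1e-5),
            class = "pc_mlp")
}

apply_activation <- function(A, kind) {
  switch(kind,
         relu = pmax(A, 0),
         linear = A,
         sigmoid = stats::plogis(A),
         pc_stop(sprintf("unknown activation '%s'", kind), "pertcycle_config_error"))
}

#' Forward pass through an MLP
#'
#' @param net a `pc_mlp`.
#' @param X input matrix (samples x features) or a single vector.
#' @param train use batch statistics for batch norm and record them into the
#'   running averages; `FALSE` (evaluation mode) uses running statistics and
#'   is fully deterministic.
#' @param keep_cache retain per-layer intermediates for `mlp_backward()`.
#' @return list with `out`, `cache` (or NULL), and `running` (updated
#'   running statistics when `train = TRUE`; assign back into the net).
#' @keywords internal
mlp_forward <- function(net, X, train = FALSE, keep_cache = train) {
  X <- as_row_matrix(X)
  if (ncol(X) != net$sizes[1L])
    pc_stop(sprintf("input width %d does not match network input %d",
                    ncol(X), net$sizes[1L]), "pertcycle_shape_error")
  nl <- length(net$params)
  cache <- if (keep_cache) vector("list", nl) else NULL
  running <- net$running
  H <- X
  for (i in seq_len(nl)) {
    L <- net$params[[i]]
    A <- H %*% L$W
    A <- sweep(A, 2L, L$b, "+")
    hidden <- i < nl
    ci <- list(H_in = H)
    if (hidden && net$batchnorm) {
      if (train) {
        mu <- colMeans(A)
        v <- colMeans(sweep(A, 2L, mu, "-")^2)
        m <- net$bn_momentum
        running[[i]]$mean <- (1 - m) * running[[i]]$mean + m * mu
        running[[i]]$var <- (1 - m) * running[[i]]$var + m * v
      } else {
        mu <- running[[i]]$mean
        v <- running[[i]]$var
      }
      xhat <- sweep(sweep(A, 2L, mu, "-"), 2L, sqrt(v + net$bn_eps), "/")
      A <- sweep(sweep(xhat, 2L, L$gamma, "*"), 2L, L$beta, "+")
      ci$xhat <- xhat
      ci$var <- v
    }
    ci$pre <- A
    H <- apply_activation(A, if (hidden) net$activation else net$out_activation)
    if (keep_cache) cache[[i]] <- ci
  }
  list(out = H, cache = cache, running = running)
}

#' Backward pass through an MLP
#'
#' @param net the `pc_mlp` used in the forward pass.
#' @param cache cache returned by `mlp_forward(..., keep_cache = TRUE)`.
#' @param dOut gradient of the scalar loss w.r.t. the network output.
#' @return list with `grads` (tree mirroring `net$params`) and `dX`.
#' @keywords internal
mlp_backward <- function(net, cache, dOut) {
  nl <- length(net$params)
  grads <- vector("list", nl)
  D <- dOut
  for (i in rev(seq_len(nl))) {
    L <- net$params[[i]]
    ci <- cache[[i]]
    act <- if (i < nl) net$activation else net$out_activation
    D <- switch(act,
                relu = D * (ci$pre > 0),
                linear = D,
                sigmoid = {
                  s <- stats::plogis(ci$pre)
                  D * s * (1 - s)
                })
    g <- list()
    if (i < nl && net$batchnorm) {
      xhat <- ci$xhat
      n <- nrow(xhat)
      g$gamma <- colSums(D * xhat)
      g$beta <- colSums(D)
      Dx <- sweep(D, 2L, L$gamma, "*")
      inv <- 1 / sqrt(ci$var + net$bn_eps)
      s1 <- colSums(Dx) / n
      s2 <- colSums(Dx * xhat) / n
      D <- sweep(Dx - matrix(s1, n, length(s1), byrow = TRUE) -
                   xhat * matrix(s2, n, length(s2), byrow = TRUE),
                 2L, inv, "*")
    }
    gW <- crossprod(ci$H_in, D)
    gb <- colSums(D)
    out <- list(W = gW, b = gb)
    if (!is.null(g$gamma)) { out$gamma <- g$gamma; out$beta <- g$beta }
    grads[[i]] <- out
    D <- D %*% t(L$W)
  }
  list(grads = grads, dX = D)
}

# ---- parameter trees -------------------------------------------------------

# Apply f over the numeric leaves of one or two parallel nested lists.
tree_map <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a))
      out[[k]] <- tree_map(f, a[[k]], if (!is.null(b)) b[[k]])
    out
  } else if (is.null(b)) f(a) else f(a, b)
}

tree_zero <- function(params) tree_map(function(x) x * 0, params)

tree_add <- function(a, b) tree_map(`+`, a, b)

tree_scale <- function(a, s) tree_map(function(x) x * s, a)

#' Adam optimizer state for a parameter tree
#' @keywords internal
adam_new <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

#' One Adam update step
#'
#' @param params,grads parallel nested lists of numeric leaves.
#' @return list with updated `params` and optimizer `state`.
#' @keywords internal
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  scale <- lr / bc1
  vh <- tree_map(function(v) sqrt(v / bc2) + eps, state$v)
  step <- tree_map(function(m, v) scale * m / v, state$m, vh)
  list(params = tree_map(`-`, params, step), state = state)
}
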