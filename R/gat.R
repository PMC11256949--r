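# Graph attention drug encoder: two attention layers, mean pooling over
# atoms, and a linear projection into the latent space.  Attention weights
# follow the softmax-of-elu formulation; the self term is included in the
# normalization so each node's weights (self + neighbors) sum to one.

elu <- function(t) ifelse(t > 0, t, exp(t) - 1)
elu_grad <- function(t) ifelse(t > 0, 1, exp(t))

check_attention_params <- function(h, params) {
  W <- params$W
  a <- params$a
  if (ncol(h) != ncol(W))
    pc_stop(sprintf("embedding width %d does not match W input width %d",
                    ncol(h), ncol(W)), "pertcycle_shape_error")
  if (length(a) != 2L * nrow(W))
    pc_stop(sprintf("attention vector length %d must be twice W output width %d",
                    length(a), nrow(W)), "pertcycle_shape_error")
  invisible(TRUE)
}

# mask of attended sets: neighbors plus self
attention_mask <- function(g) {
  V <- g$node_count
  M <- diag(1, V)
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      M[g$edges[r, 1], g$edges[r, 2]] <- 1
      M[g$edges[r, 2], g$edges[r, 1]] <- 1
    }
  }
  M
}

gat_attention_forward <- function(g, h, params) {
  check_attention_params(h, params)
  W <- params$W
  Fout <- nrow(W)
  Wh <- h %*% t(W)
  a1 <- params$a[seq_len(Fout)]
  a2 <- params$a[Fout + seq_len(Fout)]
  p <- drop(Wh %*% a1)
  q <- drop(Wh %*% a2)
  V <- g$node_count
  M <- attention_mask(g)
  Tm <- outer(p, rep(1, V)) + outer(rep(1, V), q)
  E <- exp(elu(Tm)) * M
  alpha <- E / rowSums(E)
  list(alpha = alpha, Wh = Wh, Tm = Tm, M = M, a1 = a1, a2 = a2, h = h)
}

#' Attention scores of a graph attention layer
#'
#' For each node `k` the scores over its attended set (first-order
#' neighbors plus `k` itself) are the softmax of
#' `elu(a . [W h_k || W h_l])`; entries outside the attended set are zero
#' and every row sums to one over the attended set.
#'
#' @param g a [drug_graph()].
#' @param h node embedding matrix (`node_count` rows).
#' @param params list with `W` (F_out x F_in weight matrix) and `a`
#'   (attention vector of length `2 * F_out`).
#' @return dense `node_count` x `node_count` score matrix.
#' @export
attention_scores <- function(g, h, params) {
  h <- as_row_matrix(h)
  if (nrow(h) != g$node_count)
    pc_stop("embedding row count must equal node count", "pertcycle_shape_error")
  gat_attention_forward(g, h, params)$alpha
}

#' One graph attention layer
#'
#' Updates each node embedding to
#' `relu(alpha_kk W h_k + sum_l alpha_kl W h_l)` with the attention
#' scores of [attention_scores()].
#'
#' @inheritParams attention_scores
#' @return updated embedding matrix (`node_count` x F_out).
#' @export
gat_layer <- function(g, h, params) {
  h <- as_row_matrix(h)
  if (nrow(h) != g$node_count)
    pc_stop("embedding row count must equal node count", "pertcycle_shape_error")
  fw <- gat_attention_forward(g, h, params)
  pmax(fw$alpha %*% fw$Wh, 0)
}

gat_layer_forward <- function(g, h, params) {
  fw <- gat_attention_forward(g, h, params)
  pre <- fw$alpha %*% fw$Wh
  fw$pre <- pre
  fw$out <- pmax(pre, 0)
  fw
}

# Backward through one GAT layer.  dOut: gradient wrt the layer output.
# Returns parameter gradients and the gradient wrt the input embeddings.
gat_layer_backward <- function(params, cache, dOut) {
  W <- params$W
  dpre <- dOut * (cache$pre > 0)
  alpha <- cache$alpha
  Wh <- cache$Wh
  dalpha <- dpre %*% t(Wh)
  dWh <- t(alpha) %*% dpre                      # aggregation term
  P <- alpha * dalpha
  srow <- rowSums(P)
  dU <- alpha * sweep(dalpha, 1L, srow, "-")    # masked softmax backward
  dT <- dU * elu_grad(cache$Tm) * cache$M
  rs <- rowSums(dT)
  cs <- colSums(dT)
  dWh <- dWh + outer(rs, cache$a1) + outer(cs, cache$a2)
  da <- c(drop(crossprod(Wh, rs)), drop(crossprod(Wh, cs)))
  dW <- crossprod(dWh, cache$h)
  dh <- dWh %*% W
  list(grads = list(W = dW, a = da), dh = dh)
}

# ---- full drug encoder -----------------------------------------------------

gat_encoder_new <- function(feature_dim, hidden = c(32L, 32L), latent_dim) {
  mk_layer <- function(fin, fout) {
    list(W = matrix(stats::rnorm(fout * fin, 0, sqrt(2 / fin)), fout, fin),
         a = stats::rnorm(2L * fout, 0, 0.1))
  }
  list(kind = "gat",
       feature_dim = as.integer(feature_dim),
       params = list(
         l1 = mk_layer(feature_dim, hidden[1]),
         l2 = mk_layer(hidden[1], hidden[2]),
         proj = list(W = matrix(stats::rnorm(hidden[2] * latent_dim, 0,
                                             sqrt(1 / hidden[2])),
                                hidden[2], latent_dim),
                     b = numeric(latent_dim))))
}

gat_encode <- function(enc, g, keep_cache = FALSE) {
  p <- enc$params
  if (ncol(g$node_features) != enc$feature_dim)
    pc_stop(sprintf("graph feature width %d does not match encoder input %d",
                    ncol(g$node_features), enc$feature_dim),
            "pertcycle_shape_error")
  c1 <- gat_layer_forward(g, g$node_features, p$l1)
  c2 <- gat_layer_forward(g, c1$out, p$l2)
  pooled <- colMeans(c2$out)
  emb <- drop(pooled %*% p$proj$W) + p$proj$b
  if (!keep_cache) return(list(emb = emb))
  list(emb = emb, c1 = c1, c2 = c2, pooled = pooled, V = g$node_count)
}

gat_encode_backward <- function(enc, cache, demb) {
  p <- enc$params
  gproj <- list(W = outer(cache$pooled, demb), b = demb)
  dpooled <- drop(p$proj$W %*% demb)
  V <- cache$V
  dh2 <- matrix(dpooled / V, V, length(dpooled), byrow = TRUE)
  b2 <- gat_layer_backward(p$l2, cache$c2, dh2)
  b1 <- gat_layer_backward(p$l1, cache$c1, b2$dh)
  list(l1 = b1$grads, l2 = b2$grads, proj = gproj)
}

#' Encode a drug molecule into the latent space
#'
#' Two graph attention layers followed by mean pooling over atoms and a
#' linear projection to the model's latent dimension.  Deterministic given
#' parameters and invariant to node relabeling.
#'
#' @param g a [drug_graph()] (e.g. from [smiles_to_graph()]).
#' @param model a [model_state()] whose perturbation encoder is a GAT.
#' @return numeric latent vector of length `model$latent_dim`.
#' @export
encode_drug <- function(g, model) {
  enc <- model$pert_encoder
  if (is.null(enc) || enc$kind != "gat")
    pc_stop("model has no GAT perturbation encoder", "pertcycle_config_error")
  gat_encode(enc, g)$emb
}

#' Encode a genetic perturbation into the latent space
#'
#' A single affine map applied to the one-hot encoding of the target gene
#' (equivalently: a learned embedding column per vocabulary gene plus a
#' shared bias).
#'
#' @param target_gene gene identifier, must be in the model's vocabulary.
#' @param model a [model_state()] built with `pert_encoder = "genetic"`.
#' @return numeric latent vector.
#' @export
encode_genetic <- function(target_gene, model) {
  enc <- model$pert_encoder
  if (is.null(enc) || enc$kind != "genetic")
    pc_stop("model has no genetic perturbation encoder", "pertcycle_config_error")
  idx <- match(target_gene, enc$vocab)
  if (is.na(idx))
    pc_stop(sprintf("target gene '%s' not in the perturbation vocabulary (%d genes)",
                    target_gene, length(enc$vocab)),
            "pertcycle_vocab_error", data = list(vocab_size = length(enc$vocab)))
  drop(enc$params$W[, idx]) + enc$params$b
}

# ---- dose ------------------------------------------------------------------

dose_net_new <- function(latent_dim, hidden = 8L) {
  list(W1 = matrix(stats::rnorm(hidden, 0, 1), 1L, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden * latent_dim, 0, sqrt(1 / hidden)),
                   hidden, latent_dim),
       b2 = rep(1, latent_dim))   # bias 1: zero-information dose ~ no-op
}

dose_embedding_forward <- function(dn, dose) {
  u <- log10(dose + 1e-6)
  hpre <- drop(u * dn$W1) + dn$b1
  h <- tanh(hpre)
  e <- drop(h %*% dn$W2) + dn$b2
  list(e = e, h = h, u = u)
}

#' Scale a perturbation embedding by a dose
#'
#' The dose is mapped through a small network (`log10(dose)` input, one
#' tanh hidden layer) to a latent-length vector which multiplies the drug
#' embedding element-wise.  A missing dose (`NA`) leaves the embedding
#' unchanged.
#'
#' @param d latent drug embedding (numeric vector of length L).
#' @param dose nonnegative scalar, or `NA` for "no dose information".
#' @param model a [model_state()] built with `dose = TRUE`.
#' @return numeric latent vector.
#' @export
apply_dose <- function(d, dose, model) {
  if (is.null(dose) || length(dose) == 0L || is.na(dose)) return(d)
  if (!is.finite(dose) || dose < 0)
    pc_stop("dose must be a nonnegative finite scalar", "pertcycle_config_error")
  dn <- model$dose_net
  if (is.null(dn))
    pc_stop("model was built without a dose network (dose = FALSE)",
            "pertcycle_config_error")
  d * dose_embedding_forward(dn, dose)$e
}
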