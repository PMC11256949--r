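test_that("smiles_to_graph counts atoms and bonds", {
  g <- smiles_to_graph("C")
  expect_equal(g$node_count, 1L)
  expect_equal(nrow(g$edges), 0L)
  g <- smiles_to_graph("CC")
  expect_equal(g$node_count, 2L)
  expect_equal(nrow(g$edges), 1L)
  # benzene: aromatic ring, 6 atoms / 6 bonds (value checked against a
  # standard SMILES parser)
  g <- smiles_to_graph("c1ccccc1")
  expect_equal(g$node_count, 6L)
  expect_equal(nrow(g$edges), 6L)
  expect_equal(g$node_features[, atom_feature_dim() - 1L], rep(1, 6))  # aromatic flag
  expect_equal(g$node_features[, atom_feature_dim() - 2L], rep(2, 6))  # degree
  # branches, two-letter elements, charges, explicit bonds
  g <- smiles_to_graph("CC(=O)[O-]")      # acetate: 4 heavy atoms, 3 bonds
  expect_equal(g$node_count, 4L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$node_features[4L, atom_feature_dim()], -1)
  g <- smiles_to_graph("ClCCl")
  expect_equal(g$node_count, 3L)
  slot_cl <- match("Cl", pertcycle:::ELEMENT_VOCAB)
  expect_equal(sum(g$node_features[, slot_cl]), 2)
  expect_error(smiles_to_graph("C(("), class = "pertcycle_smiles_error")
  err <- tryCatch(smiles_to_graph("C?C"), error = function(e) e)
  expect_match(conditionMessage(err), "C\\?C")
})

test_that("attention scores normalize over the attended set", {
  set.seed(5)
  # singleton: a lone node attends only to itself
  g1 <- drug_graph(matrix(rnorm(3), 1, 3), matrix(integer(), 0, 2))
  p <- list(W = matrix(rnorm(6), 2, 3), a = rnorm(4))
  expect_equal(attention_scores(g1, g1$node_features, p)[1, 1], 1.0)
  # 3-node path, W = identity, a = 0: uniform over N(k) + self
  g3 <- drug_graph(matrix(rnorm(9), 3, 3), rbind(c(1, 2), c(2, 3)))
  p0 <- list(W = diag(3), a = rep(0, 6))
  al <- attention_scores(g3, g3$node_features, p0)
  expect_equal(al[1, ], c(1/2, 1/2, 0))
  expect_equal(al[2, ], c(1/3, 1/3, 1/3))
  # random graphs/parameters: every row sums to 1 over the attended set
  for (i in 1:20) {
    V <- sample(2:6, 1)
    edges <- cbind(seq_len(V - 1L), 2:V)
    g <- drug_graph(matrix(rnorm(V * 3), V, 3), edges)
    pr <- list(W = matrix(rnorm(9), 3, 3), a = rnorm(6))
    al <- attention_scores(g, g$node_features, pr)
    expect_equal(rowSums(al), rep(1, V), tolerance = 1e-6)
  }
  expect_error(attention_scores(g3, g3$node_features,
                                list(W = diag(2), a = rep(0, 4))),
               class = "pertcycle_shape_error")
})

test_that("gat_layer matches a scalar loop oracle and handles edge cases", {
  set.seed(6)
  g <- drug_graph(matrix(rnorm(6), 2, 3), matrix(c(1L, 2L), 1, 2))
  p <- list(W = matrix(rnorm(6) * 0.3, 2, 3), a = rnorm(4) * 0.3)
  h <- g$node_features
  # scalar re-evaluation of the attention + aggregation equations
  Wh <- h %*% t(p$W)
  a1 <- p$a[1:2]; a2 <- p$a[3:4]
  nb <- list(c(1L, 2L), c(1L, 2L))  # attended sets incl self
  oracle <- matrix(0, 2, 2)
  myelu <- function(t) if (t > 0) t else exp(t) - 1
  for (k in 1:2) {
    e <- sapply(nb[[k]], function(l)
      exp(myelu(sum(a1 * Wh[k, ]) + sum(a2 * Wh[l, ]))))
    al <- e / sum(e)
    agg <- rep(0, 2)
    for (j in seq_along(nb[[k]])) agg <- agg + al[j] * Wh[nb[[k]][j], ]
    oracle[k, ] <- pmax(agg, 0)
  }
  expect_equal(gat_layer(g, h, p), oracle, tolerance = 1e-6, ignore_attr = TRUE)
  # all-zero input embeddings give all-zero output
  expect_equal(gat_layer(g, matrix(0, 2, 3), p), matrix(0, 2, 2),
               ignore_attr = TRUE)
  # 1-node graph with identity weights returns nonnegative h unchanged
  g1 <- drug_graph(matrix(abs(rnorm(3)), 1, 3), matrix(integer(), 0, 2))
  expect_equal(gat_layer(g1, g1$node_features, list(W = diag(3), a = rnorm(6))),
               g1$node_features, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("GAT encoder backprop matches numerical gradients", {
  set.seed(8)
  enc <- pertcycle:::gat_encoder_new(3L, c(4L, 4L), 5L)
  g <- drug_graph(matrix(rnorm(9), 3, 3), rbind(c(1, 2), c(2, 3)))
  tgt <- rnorm(5)
  fc <- pertcycle:::gat_encode(enc, g, keep_cache = TRUE)
  gr <- pertcycle:::gat_encode_backward(enc, fc, 2 * (fc$emb - tgt))
  for (layer in c("l1", "l2", "proj")) {
    for (pn in names(enc$params[[layer]])) {
      p0 <- enc$params[[layer]][[pn]]
      fn <- function(v) {
        e2 <- enc
        e2$params[[layer]][[pn]] <- if (is.matrix(p0)) matrix(v, nrow(p0)) else v
        sum((pertcycle:::gat_encode(e2, g)$emb - tgt)^2)
      }
      expect_equal(as.numeric(gr[[layer]][[pn]]), num_grad(fn, as.numeric(p0)),
                   tolerance = 1e-6)
    }
  }
})

test_that("encode_drug is invariant to node relabeling and isomorphism", {
  set.seed(9)
  m <- tiny_model(feature_dim = 3L)
  feats <- matrix(rnorm(12), 4, 3)
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  g <- drug_graph(feats, edges)
  perm <- c(3L, 1L, 4L, 2L)
  inv <- order(perm)
  g_perm <- drug_graph(feats[perm, ], cbind(inv[edges[, 1]], inv[edges[, 2]]))
  expect_equal(encode_drug(g, m), encode_drug(g_perm, m), tolerance = 1e-5)
  # isomorphic pair with identical features -> equal embeddings
  g_iso <- drug_graph(feats[perm, ],
                      matrix(inv[as.integer(edges)], ncol = 2))
  expect_equal(encode_drug(g, m), encode_drug(g_iso, m), tolerance = 1e-5)
})

test_that("genetic encoder is a one-hot affine lookup", {
  vocab <- c("TP53", "KRAS", "MYC")
  m <- model_state(5L, latent_dim = 3L, enc_hidden = c(4L), disc_hidden = c(4L),
                   batchnorm = FALSE, pert_encoder = "genetic",
                   genetic_vocab = vocab, seed = 2L)
  # zero weights, zero bias -> zero vector
  m0 <- m
  m0$pert_encoder$params$W[] <- 0
  m0$pert_encoder$params$b[] <- 0
  expect_equal(encode_genetic("KRAS", m0), rep(0, 3))
  # identity-like weights reproduce the one-hot column
  mi <- m
  mi$pert_encoder$params$W <- rbind(diag(3))
  mi$pert_encoder$params$b[] <- 0
  expect_equal(encode_genetic("KRAS", mi), c(0, 1, 0))
  # random fixed weights: embeddings are the corresponding columns + bias
  for (gene in vocab) {
    j <- match(gene, vocab)
    expect_equal(encode_genetic(gene, m),
                 m$pert_encoder$params$W[, j] + m$pert_encoder$params$b,
                 tolerance = 1e-12)
  }
  err <- tryCatch(encode_genetic("BRCA1", m), error = function(e) e)
  expect_s3_class(err, "pertcycle_vocab_error")
  expect_match(conditionMessage(err), "3")
})

test_that("dose embedding multiplies element-wise", {
  m <- tiny_model(L = 4L)
  m$dose_net <- withr::with_seed(4, pertcycle:::dose_net_new(4L))
  d <- c(1, -2, 0.5, 3)
  # all-ones dose embedding leaves d unchanged
  m1 <- m
  m1$dose_net$W2[] <- 0
  m1$dose_net$b2[] <- 1
  expect_equal(apply_dose(d, 10, m1), d)
  # all-zeros dose embedding annihilates
  m1$dose_net$b2[] <- 0
  expect_equal(apply_dose(d, 10, m1), rep(0, 4))
  # fixed parameters match the elementwise-product oracle
  e <- pertcycle:::dose_embedding_forward(m$dose_net, 2.5)$e
  expect_equal(apply_dose(d, 2.5, m), d * e, tolerance = 1e-7)
  # absent dose is a no-op; negative dose is an error
  expect_identical(apply_dose(d, NA, m), d)
  expect_error(apply_dose(d, -1, m), class = "pertcycle_config_error")
})
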