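# Shared fixtures and independent reference implementations used as
# oracles.  Everything here is deliberately naive (per-sample loops, plain
# vector arithmetic) and independent of the package's vectorized paths.

# Reference forward pass of an MLP without batch norm: plain per-layer
# vector arithmetic on a single sample.
ref_mlp_forward <- function(net, x) {
  stopifnot(!net$batchnorm)
  nl <- length(net$params)
  h <- x
  for (i in seq_len(nl)) {
    L <- net$params[[i]]
    a <- drop(h %*% L$W) + L$b
    act <- if (i < nl) net$activation else net$out_activation
    h <- switch(act, relu = pmax(a, 0), linear = a, sigmoid = 1 / (1 + exp(-a)))
  }
  h
}

# Central-difference numerical gradient of scalar f at x.
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

# Small random path graphs with a given feature width.
toy_graphs <- function(k, feature_dim = 4L, nodes = 3L, seed = 1L) {
  set.seed(seed)
  gs <- lapply(seq_len(k), function(j) {
    V <- nodes
    edges <- if (V > 1L) cbind(seq_len(V - 1L), 2:V) else matrix(integer(), 0L, 2L)
    drug_graph(matrix(rnorm(V * feature_dim), V, feature_dim), edges)
  })
  names(gs) <- sprintf("drug%02d", seq_len(k))
  gs
}

toy_records <- function(pids, kind = "drug") {
  data.frame(sample_id = sprintf("s%03d", seq_along(pids)),
             perturbation_id = pids,
             kind = kind,
             smiles = NA_character_, target_gene = NA_character_,
             dose = NA_real_, context_id = "ctx",
             stringsAsFactors = FALSE)
}

# Small random model with a GAT perturbation encoder over toy graphs.
tiny_model <- function(G = 6L, L = 3L, hidden = c(5L), batchnorm = FALSE,
                       feature_dim = 4L, shared = FALSE, seed = 1L) {
  model_state(G, latent_dim = L, enc_hidden = hidden, disc_hidden = c(4L),
              batchnorm = batchnorm, shared_autoencoder = shared,
              pert_encoder = "gat", pert_feature_dim = feature_dim,
              gat_hidden = c(4L, 4L), seed = seed)
}

# Model whose four autoencoder networks are exact identity maps (latent
# dimension equals the gene count, single affine layers).
identity_model <- function(G = 4L) {
  m <- model_state(G, latent_dim = G, enc_hidden = integer(),
                   disc_hidden = integer(), batchnorm = FALSE,
                   pert_encoder = "none", seed = 1L)
  eye <- list(W = diag(G), b = numeric(G))
  for (nm in c("enc_control", "dec_treated", "enc_treated", "dec_control"))
    m[[nm]]$params[[1L]] <- eye
  m
}

# Build a small delimited dataset on disk; returns the matrix path.
write_toy_delimited <- function(dir, mat, records) {
  path <- file.path(dir, "expr.csv")
  ds <- expression_dataset(mat, records)
  write_expression(ds, path)
  path
}

# Loop-based loss oracles: every loss recomputed per sample with
# ref_mlp_forward, independent of the vectorized implementations.

ref_embed <- function(rec, m, graphs) {
  if (rec$kind == "control") return(numeric(m$latent_dim))
  encode_drug(graphs[[rec$perturbation_id]], m)
}

ref_losses <- function(x, y, records, m, graphs, assignment) {
  n_x <- nrow(x); n_y <- nrow(y)
  embs <- lapply(seq_len(n_y), function(i)
    ref_embed(as.list(records[i, ]), m, graphs))
  et <- pertcycle:::net_enc_treated(m)
  dc <- pertcycle:::net_dec_control(m)
  reco <- mean(sapply(seq_len(n_x), function(i) {
    xi <- x[i, ]
    sum((xi - ref_mlp_forward(m$dec_treated, ref_mlp_forward(m$enc_control, xi)))^2)
  }))
  idl <- mean(sapply(seq_len(n_y), function(i) {
    yi <- y[i, ]
    sum((yi - ref_mlp_forward(m$dec_treated, ref_mlp_forward(m$enc_control, yi)))^2)
  }))
  cyc <- mean(sapply(seq_len(n_x), function(i) {
    xi <- x[i, ]; d <- embs[[assignment[i]]]
    yh <- ref_mlp_forward(m$dec_treated, ref_mlp_forward(m$enc_control, xi) + d)
    xh <- ref_mlp_forward(dc, ref_mlp_forward(et, yh) - d)
    sum((xi - xh)^2)
  })) + mean(sapply(seq_len(n_y), function(i) {
    yi <- y[i, ]; d <- embs[[i]]
    xh <- ref_mlp_forward(dc, ref_mlp_forward(et, yi) - d)
    yh <- ref_mlp_forward(m$dec_treated, ref_mlp_forward(m$enc_control, xh) + d)
    sum((yi - yh)^2)
  }))
  cl <- function(p) pmin(pmax(p, 1e-7), 1 - 1e-7)
  s_ry <- sapply(seq_len(n_y), function(i)
    cl(ref_mlp_forward(m$disc_treated, y[i, ])))
  s_fy <- sapply(seq_len(n_x), function(i) {
    d <- embs[[assignment[i]]]
    cl(ref_mlp_forward(m$disc_treated,
                       ref_mlp_forward(m$dec_treated,
                                       ref_mlp_forward(m$enc_control, x[i, ]) + d)))
  })
  s_rx <- sapply(seq_len(n_x), function(i)
    cl(ref_mlp_forward(m$disc_control, x[i, ])))
  s_fx <- sapply(seq_len(n_y), function(i)
    cl(ref_mlp_forward(m$disc_control,
                       ref_mlp_forward(dc, ref_mlp_forward(et, y[i, ]) -
                                             embs[[i]]))))
  list(reco = reco, identity = idl, cyc = cyc,
       gen_fwd = -mean(log(s_fy)),
       disc_fwd = -(mean(log(s_ry)) + mean(log(1 - s_fy))),
       gen_rev = -mean(log(s_fx)),
       disc_rev = -(mean(log(s_rx)) + mean(log(1 - s_fx))))
}

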