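# Model state: dual encoder-decoder pairs, two discriminators, the
# perturbation encoder, and the latent additive arithmetic.

#' Construct a model state
#'
#' Two encoder-decoder pairs share one latent space: the forward pair
#' (`enc_control`, `dec_treated`) predicts treated profiles from controls
#' after adding a perturbation vector; the reverse pair (`enc_treated`,
#' `dec_control`) restores controls after subtracting it.  With
#' `shared_autoencoder = TRUE` the two pairs are literally the same
#' network.  Two discriminators score profiles as real-vs-generated for
#' adversarial training on unpaired data.
#'
#' All networks are MLPs with ReLU hidden units and linear outputs
#' (expression values may be signed after normalization); discriminators
#' end in a sigmoid.  Weights are drawn from a seeded RNG, so construction
#' is reproducible.
#'
#' @param n_genes number of genes/features G.
#' @param latent_dim bottleneck width L (default 128).
#' @param enc_hidden hidden widths of the encoders; decoders are mirrored.
#' @param disc_hidden hidden widths of the discriminators.
#' @param batchnorm apply batch normalization to hidden layers.
#' @param shared_autoencoder use a single autoencoder for both directions.
#' @param pert_encoder `"gat"` (drug graphs), `"genetic"` (one-hot target
#'   gene), or `"none"`.
#' @param pert_feature_dim atom-feature width for the GAT encoder (defaults
#'   to [atom_feature_dim()], i.e. SMILES-derived graphs).
#' @param gat_hidden widths of the two GAT layers.
#' @param genetic_vocab character vector of target genes (required for
#'   `pert_encoder = "genetic"`).
#' @param dose add a dose-embedding network (element-wise multiplicative).
#' @param gene_ids optional gene identifiers carried for IO.
#' @param seed integer root seed for initialization.
#' @return object of class `model_state`.
#' @export
model_state <- function(n_genes, latent_dim = 128L,
                        enc_hidden = c(512L, 256L),
                        disc_hidden = c(256L, 64L),
                        batchnorm = TRUE,
                        shared_autoencoder = FALSE,
                        pert_encoder = c("gat", "genetic", "none"),
                        pert_feature_dim = NULL,
                        gat_hidden = c(32L, 32L),
                        genetic_vocab = NULL,
                        dose = FALSE,
                        gene_ids = NULL,
                        seed = 1L) {
  pert_encoder <- match.arg(pert_encoder)
  n_genes <- as.integer(n_genes)
  latent_dim <- as.integer(latent_dim)
  enc_sizes <- c(n_genes, enc_hidden, latent_dim)
  dec_sizes <- c(latent_dim, rev(enc_hidden), n_genes)
  disc_sizes <- c(n_genes, disc_hidden, 1L)
  mk <- function(tag, sizes, out = "linear") {
    with_seed(derive_seed(seed, tag),
              mlp_new(sizes, out_activation = out, batchnorm = batchnorm))
  }
  m <- list(
    n_genes = n_genes, latent_dim = latent_dim,
    gene_ids = gene_ids,
    shared_autoencoder = isTRUE(shared_autoencoder),
    batchnorm = isTRUE(batchnorm),
    enc_control = mk("enc_control", enc_sizes),
    dec_treated = mk("dec_treated", dec_sizes),
    enc_treated = if (!shared_autoencoder) mk("enc_treated", enc_sizes),
    dec_control = if (!shared_autoencoder) mk("dec_control", dec_sizes),
    disc_treated = mk("disc_treated", disc_sizes, out = "sigmoid"),
    disc_control = mk("disc_control", disc_sizes, out = "sigmoid"),
    pert_encoder = NULL, dose_net = NULL,
    graph_library = NULL)
  if (pert_encoder == "gat") {
    fd <- if (is.null(pert_feature_dim)) atom_feature_dim() else as.integer(pert_feature_dim)
    m$pert_encoder <- with_seed(derive_seed(seed, "pert_gat"),
                                gat_encoder_new(fd, gat_hidden, latent_dim))
  } else if (pert_encoder == "genetic") {
    if (is.null(genetic_vocab))
      pc_stop("pert_encoder = 'genetic' requires genetic_vocab",
              "pertcycle_config_error")
    V <- length(genetic_vocab)
    m$pert_encoder <- with_seed(derive_seed(seed, "pert_genetic"), list(
      kind = "genetic", vocab = genetic_vocab,
      params = list(W = matrix(stats::rnorm(latent_dim * V, 0, sqrt(1 / V)),
                               latent_dim, V),
                    b = numeric(latent_dim))))
  }
  if (dose)
    m$dose_net <- with_seed(derive_seed(seed, "dose"), dose_net_new(latent_dim))
  structure(m, class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("<model_state> G=%d, L=%d, %s autoencoder, pert encoder: %s%s\n",
              x$n_genes, x$latent_dim,
              if (x$shared_autoencoder) "shared" else "dual",
              if (is.null(x$pert_encoder)) "none" else x$pert_encoder$kind,
              if (!is.null(x$dose_net)) ", dose net" else ""))
  invisible(x)
}

# Accessors honoring the shared-autoencoder switch.
net_enc_treated <- function(m) if (m$shared_autoencoder) m$enc_control else m$enc_treated
net_dec_control <- function(m) if (m$shared_autoencoder) m$dec_treated else m$dec_control

#' Encode expression profiles into the latent space
#'
#' `encode_control()` uses the forward encoder (unperturbed states);
#' `encode_treated()` uses the reverse encoder (perturbed states).  In
#' evaluation mode (the default) batch normalization uses running
#' statistics, so the map is deterministic.
#'
#' @param x numeric vector of length G or a samples x G matrix.
#' @param m a [model_state()].
#' @return latent vector (or matrix, matching the input shape).
#' @export
encode_control <- function(x, m) {
  was_vec <- !is.matrix(x)
  out <- mlp_forward(m$enc_control, x, train = FALSE)$out
  if (was_vec) drop(out) else out
}

#' @rdname encode_control
#' @export
encode_treated <- function(x, m) {
  was_vec <- !is.matrix(x)
  out <- mlp_forward(net_enc_treated(m), x, train = FALSE)$out
  if (was_vec) drop(out) else out
}

decode_treated <- function(z, m) mlp_forward(m$dec_treated, z, train = FALSE)$out
decode_control <- function(z, m) mlp_forward(net_dec_control(m), z, train = FALSE)$out

#' Latent perturbation arithmetic
#'
#' A perturbation acts as vector addition in the latent space:
#' `add_perturbation()` computes the perturbed latent state `z + d`;
#' `remove_perturbation()` withdraws it (`z' - d`).  The two are exact
#' inverses.
#'
#' @param z latent vector (or matrix of row vectors).
#' @param d perturbation embedding of the same latent length.
#' @return latent vector/matrix.
#' @export
add_perturbation <- function(z, d) {
  if (is.matrix(z)) {
    if (ncol(z) != length(d))
      pc_stop("latent and perturbation lengths differ", "pertcycle_shape_error")
    sweep(z, 2L, d, "+")
  } else {
    if (length(z) != length(d))
      pc_stop("latent and perturbation lengths differ", "pertcycle_shape_error")
    z + d
  }
}

#' @rdname add_perturbation
#' @export
remove_perturbation <- function(z, d) add_perturbation(z, -d)

#' Resolve a perturbation record to a latent embedding
#'
#' Controls map to the zero vector (making reconstruction the d = 0
#' special case of the forward path).  Drugs resolve through, in order:
#' the supplied `graphs`, the model's stored graph library, or the
#' record's SMILES string; the dose (when present and the model has a dose
#' network) multiplies the embedding element-wise.  Genetic perturbations
#' use the one-layer genetic encoder.
#'
#' @param record a perturbation record (one-row data frame or named list
#'   with `kind`, `perturbation_id` and kind-specific fields).
#' @param m a [model_state()].
#' @param graphs optional named list of [drug_graph()]s.
#' @return numeric latent vector.
#' @export
resolve_embedding <- function(record, m, graphs = NULL) {
  record <- as.list(record)
  kind <- record$kind
  if (kind == "control") return(numeric(m$latent_dim))
  if (kind == "genetic") return(encode_genetic(record$target_gene, m))
  pid <- record$perturbation_id
  g <- graphs[[pid]]
  if (is.null(g)) g <- m$graph_library[[pid]]
  if (is.null(g)) {
    if (is.null(record$smiles) || is.na(record$smiles))
      pc_stop(sprintf("perturbation '%s' has no graph and no SMILES", pid),
              "pertcycle_vocab_error")
    g <- smiles_to_graph(record$smiles)
  }
  d <- encode_drug(g, m)
  dose <- record$dose
  if (!is.null(m$dose_net) && !is.null(dose) && length(dose) && !is.na(dose))
    d <- apply_dose(d, dose, m)
  d
}

#' Predict the response to a perturbation
#'
#' Forward direction: encode the control profile, add the perturbation
#' embedding, decode through the treated-state decoder.
#'
#' @param x control expression profile (vector of length G) or matrix.
#' @param pert perturbation record (see [resolve_embedding()]).
#' @param m a [model_state()].
#' @param graphs optional named list of [drug_graph()]s.
#' @return predicted treated profile, same shape as `x`.
#' @export
predict_response <- function(x, pert, m, graphs = NULL) {
  d <- resolve_embedding(pert, m, graphs)
  was_vec <- !is.matrix(x)
  z <- mlp_forward(m$enc_control, x, train = FALSE)$out
  out <- decode_treated(add_perturbation(z, d), m)
  if (was_vec) drop(out) else out
}

#' Restore the control state from a treated profile
#'
#' Reverse direction: encode the treated profile, withdraw the
#' perturbation embedding, decode through the control-state decoder.
#'
#' @param y treated expression profile (vector of length G) or matrix.
#' @inheritParams predict_response
#' @return predicted control profile, same shape as `y`.
#' @export
restore_control <- function(y, pert, m, graphs = NULL) {
  d <- resolve_embedding(pert, m, graphs)
  was_vec <- !is.matrix(y)
  z <- mlp_forward(net_enc_treated(m), y, train = FALSE)$out
  out <- decode_control(remove_perturbation(z, d), m)
  if (was_vec) drop(out) else out
}

#' Discriminator score of an expression profile
#'
#' @param profile expression vector of length G (or matrix).
#' @param which `"treated"` scores real-vs-generated treated profiles,
#'   `"control"` scores control profiles.
#' @param m a [model_state()].
#' @return score(s) in (0, 1).
#' @export
discriminate <- function(profile, which = c("treated", "control"), m) {
  which <- match.arg(which)
  net <- if (which == "treated") m$disc_treated else m$disc_control
  was_vec <- !is.matrix(profile)
  out <- mlp_forward(net, profile, train = FALSE)$out
  if (was_vec) drop(out) else drop(out)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' One archive holds all parameter tensors plus the shape configuration;
#' loading refuses archives whose stored shapes are internally
#' inconsistent.
#'
#' @param m a [model_state()].
#' @param path file path for the checkpoint archive.
#' @export
save_checkpoint <- function(m, path) {
  saveRDS(list(format = "pertcycle_checkpoint", version = 1L, model = m), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pertcycle_checkpoint"))
    pc_stop("not a pertcycle checkpoint archive", "pertcycle_io_error")
  m <- obj$model
  for (nm in c("enc_control", "dec_treated", "enc_treated", "dec_control",
               "disc_treated", "disc_control")) {
    net <- m[[nm]]
    if (is.null(net)) next
    for (i in seq_along(net$params)) {
      W <- net$params[[i]]$W
      if (nrow(W) != net$sizes[i] || ncol(W) != net$sizes[i + 1L])
        pc_stop(sprintf("checkpoint shape mismatch in %s layer %d", nm, i),
                "pertcycle_io_error")
    }
  }
  m
}
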