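# Synthetic data with known ground truth, generated from the model's own
# structural assumption: perturbations act additively in a latent space,
# profiles are a (possibly mildly nonlinear) decoding of the latent state
# plus i.i.d. Gaussian observation noise.  Values are on a signed,
# log-like scale, so evaluation uses `log_space = TRUE`.

#' Synthetic-data configuration
#'
#' Defaults describe a desk-scale world: 60 genes, an 8-dimensional true
#' latent space, 20 perturbations with effects determined linearly by an
#' 8-dimensional perturbation feature vector, 200 cells per condition, and
#' observation noise sd 0.05 (small relative to the unit-scale biological
#' variation).
#'
#' @param n_genes G.
#' @param latent_dim_true q, dimension of the generating latent space.
#' @param n_perturbations K.
#' @param cells_per_condition n cells for every perturbation arm (and as
#'   many controls per arm).
#' @param noise_sd additive observation noise sd.
#' @param decoder_kind `"linear"` or `"mild_nonlinear"` (linear map
#'   followed by a gentle `t + 0.25 tanh(t)` bend).
#' @param perturbation_effect_scale scale of the true latent perturbation
#'   vectors relative to the unit cell-to-cell latent variation.
#' @param drug_feature_dim width of the feature vectors that linearly
#'   determine the true effects (enables unseen-perturbation
#'   generalization).
#' @param graph_nodes atoms per toy drug graph.
#' @param paired same latent cell observed in both arms (bulk regime) or
#'   disjoint cohorts per arm (destructive single-cell regime).
#' @param seed integer; the simulation is a pure function of (config, seed).
#' @export
synthetic_config <- function(n_genes = 60L, latent_dim_true = 8L,
                             n_perturbations = 20L,
                             cells_per_condition = 200L,
                             noise_sd = 0.05,
                             decoder_kind = c("linear", "mild_nonlinear"),
                             perturbation_effect_scale = 1,
                             drug_feature_dim = 8L,
                             graph_nodes = 3L,
                             paired = TRUE,
                             seed = 1L) {
  decoder_kind <- match.arg(decoder_kind)
  cfg <- list(n_genes = as.integer(n_genes),
              latent_dim_true = as.integer(latent_dim_true),
              n_perturbations = as.integer(n_perturbations),
              cells_per_condition = as.integer(cells_per_condition),
              noise_sd = noise_sd, decoder_kind = decoder_kind,
              perturbation_effect_scale = perturbation_effect_scale,
              drug_feature_dim = as.integer(drug_feature_dim),
              graph_nodes = as.integer(graph_nodes),
              paired = isTRUE(paired), seed = as.integer(seed))
  if (cfg$latent_dim_true > cfg$n_genes)
    pc_stop("true latent dimension cannot exceed the gene count",
            "pertcycle_config_error")
  if (any(c(cfg$n_genes, cfg$latent_dim_true, cfg$n_perturbations,
            cfg$cells_per_condition, cfg$graph_nodes) <= 0) ||
      !is.finite(cfg$noise_sd) || cfg$noise_sd < 0)
    pc_stop("invalid synthetic configuration", "pertcycle_config_error")
  structure(cfg, class = "synthetic_config")
}

true_decode <- function(decoder, Z) {
  out <- Z %*% t(decoder$W)
  out <- sweep(out, 2L, decoder$mu, "+")
  if (decoder$kind == "mild_nonlinear") out <- out + 0.25 * tanh(out)
  out
}

#' Toy drug graphs whose node features sum to the drug feature vector
#'
#' Each perturbation gets a small path graph; node features are positive
#' shares of the perturbation feature vector, so a graph encoder that
#' pools over atoms can in principle recover the feature vector and hence
#' the true latent effect.
#'
#' @param cfg a [synthetic_config()].
#' @param features optional feature matrix (`drug_feature_dim` x K);
#'   regenerated from the config seed when omitted.
#' @return named list of [drug_graph()]s.
#' @export
simulate_drug_graphs <- function(cfg, features = NULL) {
  if (is.null(features)) features <- simulate_features(cfg)
  K <- cfg$n_perturbations
  V <- cfg$graph_nodes
  with_seed(derive_seed(cfg$seed, "graphs"), {
    graphs <- lapply(seq_len(K), function(j) {
      shares <- stats::runif(V, 0.5, 1.5)
      shares <- shares / sum(shares)
      feats <- outer(shares, features[, j])
      edges <- if (V > 1L) cbind(seq_len(V - 1L), 2:V) else matrix(integer(), 0L, 2L)
      drug_graph(feats, edges)
    })
    names(graphs) <- colnames(features)
    graphs
  })
}

simulate_features <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "features"), {
    f <- matrix(stats::rnorm(cfg$drug_feature_dim * cfg$n_perturbations),
                cfg$drug_feature_dim, cfg$n_perturbations)
    colnames(f) <- sprintf("drug%02d", seq_len(cfg$n_perturbations))
    f
  })
}

#' Simulate an expression dataset with ground truth
#'
#' Latent cells are standard normal in q dimensions; the true effect of
#' perturbation j is `d*_j = B f_j` for a fixed random matrix B and drug
#' features f_j; control profiles decode `z`, treated profiles decode
#' `z + d*_j`, both plus i.i.d. `N(0, noise_sd^2)` noise per gene.  In
#' paired mode the same latent cell is observed in both arms (with
#' independent noise) and the pairing map is recorded; in unpaired mode
#' each arm is an independent latent cohort.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `dataset` (an [expression_dataset()] carrying the toy
#'   drug graphs) and `truth` (true latents, true perturbation vectors,
#'   decoder parameters, drug features).
#' @export
simulate_dataset <- function(cfg) {
  q <- cfg$latent_dim_true
  G <- cfg$n_genes
  K <- cfg$n_perturbations
  n <- cfg$cells_per_condition
  features <- simulate_features(cfg)
  graphs <- simulate_drug_graphs(cfg, features)
  drug_ids <- colnames(features)

  decoder <- with_seed(derive_seed(cfg$seed, "decoder"), list(
    W = matrix(stats::rnorm(G * q, 0, sqrt(1 / q)), G, q),
    mu = stats::rnorm(G, 0, 1),
    kind = cfg$decoder_kind))
  B <- with_seed(derive_seed(cfg$seed, "effects"),
                 matrix(stats::rnorm(q * cfg$drug_feature_dim, 0,
                                     cfg$perturbation_effect_scale /
                                       sqrt(cfg$drug_feature_dim)),
                        q, cfg$drug_feature_dim))
  d_star <- B %*% features
  colnames(d_star) <- drug_ids

  out <- with_seed(derive_seed(cfg$seed, "cells"), {
    z_ctrl <- matrix(stats::rnorm(n * K * q), n * K, q)
    z_trt <- if (cfg$paired) z_ctrl else matrix(stats::rnorm(n * K * q), n * K, q)
    drug_of_row <- rep(seq_len(K), each = n)
    z_shift <- z_trt + t(d_star)[drug_of_row, , drop = FALSE]
    x <- true_decode(decoder, z_ctrl) +
      matrix(stats::rnorm(n * K * G, 0, cfg$noise_sd), n * K, G)
    y <- true_decode(decoder, z_shift) +
      matrix(stats::rnorm(n * K * G, 0, cfg$noise_sd), n * K, G)
    list(z_ctrl = z_ctrl, z_trt = z_trt, x = x, y = y, drug_of_row = drug_of_row)
  })

  gene_ids <- sprintf("g%03d", seq_len(G))
  ctrl_ids <- sprintf("ctrl_%s_c%03d", drug_ids[out$drug_of_row],
                      rep(seq_len(n), K))
  trt_ids <- sprintf("trt_%s_c%03d", drug_ids[out$drug_of_row],
                     rep(seq_len(n), K))
  mat <- rbind(out$x, out$y)
  colnames(mat) <- gene_ids
  rownames(mat) <- c(ctrl_ids, trt_ids)
  records <- data.frame(
    sample_id = c(ctrl_ids, trt_ids),
    perturbation_id = c(rep("control", n * K), drug_ids[out$drug_of_row]),
    kind = c(rep("control", n * K), rep("drug", n * K)),
    smiles = NA_character_,
    target_gene = NA_character_,
    dose = NA_real_,
    context_id = "sim",
    stringsAsFactors = FALSE)
  pairing <- if (cfg$paired)
    stats::setNames(seq_len(n * K), as.character(n * K + seq_len(n * K)))
  ds <- expression_dataset(mat, records, pairing = pairing, graphs = graphs)
  truth <- list(config = cfg, true_latents_control = out$z_ctrl,
                true_latents_treated = out$z_trt,
                d_star = d_star, decoder = decoder, features = features,
                drug_of_row = out$drug_of_row)
  list(dataset = ds, truth = truth)
}

#' Per-perturbation additive-offset least-squares baseline
#'
#' The direct least-squares fit of the model `y = x + delta_j` on paired
#' (control, treated) samples: `delta_j` is the mean of `y - x` over the
#' training pairs of perturbation j.  Under the linear-decoder generative
#' process this is (up to noise) the best additive predictor, so its
#' accuracy bounds what a trained model can achieve.
#'
#' @param x,y paired control/treated matrices.
#' @param records treated records aligned to rows.
#' @return function(newx, perturbation_id) -> predicted treated matrix,
#'   with the per-drug offsets in attribute `"offsets"`.
#' @export
offset_oracle <- function(x, y, records) {
  diffs <- y - x
  offsets <- do.call(rbind, lapply(split(seq_len(nrow(x)),
                                         records$perturbation_id),
                                   function(r) colMeans(diffs[r, , drop = FALSE])))
  f <- function(newx, perturbation_id) {
    newx <- as_row_matrix(newx)
    if (length(perturbation_id) == 1L)
      perturbation_id <- rep(perturbation_id, nrow(newx))
    newx + offsets[perturbation_id, , drop = FALSE]
  }
  attr(f, "offsets") <- offsets
  f
}

#' Train on synthetic data and measure ground-truth recovery
#'
#' Simulates a dataset, holds out `holdout_k` perturbations entirely,
#' trains on the rest, and evaluates the predicted treated mean profiles
#' of the held-out perturbations against the simulated treated means —
#' the unseen-perturbation generalization test.  Also reports how well a
#' best linear map aligns the learned perturbation embeddings with the
#' true latent effect vectors.
#'
#' @param cfg a [synthetic_config()].
#' @param train_cfg a [training_config()].
#' @param holdout_k number of held-out perturbations (0 = evaluate on
#'   training perturbations).
#' @param shuffle_features permute the drug-graph assignment so graph
#'   features no longer determine the true effects (negative control).
#' @return list with `per_drug` data frame, `mean_r2`, `holdout`,
#'   `alignment_r2`, the trained `model` and the simulation `truth`.
#' @export
recovery_experiment <- function(cfg, train_cfg, holdout_k = 0L,
                                shuffle_features = FALSE) {
  if (holdout_k >= cfg$n_perturbations)
    pc_stop("holdout_k must be smaller than the number of perturbations",
            "pertcycle_config_error")
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  graphs <- ds$graphs
  drug_ids <- colnames(sim$truth$features)
  if (shuffle_features) {
    perm <- with_seed(derive_seed(cfg$seed, "shuffle"), sample(length(graphs)))
    graphs <- stats::setNames(graphs[perm], names(graphs))
    ds$graphs <- graphs
  }
  holdout <- if (holdout_k > 0L)
    with_seed(derive_seed(cfg$seed, "holdout"), sample(drug_ids, holdout_k))
  else character()
  train_ids <- setdiff(drug_ids, holdout)
  train_rows <- which(ds$records$kind == "control" |
                        ds$records$perturbation_id %in% train_ids)
  ds_train <- subset_dataset(ds, train_rows)
  fit <- train_model(ds_train, NULL, train_cfg, graphs = graphs)

  eval_ids <- if (length(holdout)) holdout else drug_ids
  is_trt <- ds$records$kind == "drug"
  per_drug <- do.call(rbind, lapply(eval_ids, function(j) {
    trt_rows <- which(is_trt & ds$records$perturbation_id == j)
    ctrl_rows <- if (!is.null(ds$pairing))
      ds$pairing[as.character(trt_rows)] else which(!is_trt)
    req <- expression_dataset(ds$matrix[ctrl_rows, , drop = FALSE],
                              ds$records[trt_rows, , drop = FALSE],
                              graphs = graphs)
    pred <- predict_batch(req, fit$model, graphs = graphs)
    data.frame(perturbation_id = j,
               r2_mean_profile = r2_score(colMeans(pred$matrix),
                                          colMeans(ds$matrix[trt_rows, , drop = FALSE])))
  }))
  # latent alignment: best linear map from learned embeddings to true d*
  d_learned <- vapply(drug_ids, function(j) encode_drug(graphs[[j]], fit$model),
                      numeric(fit$model$latent_dim))
  d_true <- sim$truth$d_star[, drug_ids, drop = FALSE]
  fitlm <- stats::lm.fit(cbind(1, t(d_learned)), t(d_true))
  alignment_r2 <- 1 - sum(fitlm$residuals^2) /
    sum(sweep(t(d_true), 2L, colMeans(t(d_true)))^2)
  list(per_drug = per_drug, mean_r2 = mean(per_drug$r2_mean_profile),
       holdout = holdout, alignment_r2 = alignment_r2,
       model = fit$model, history = fit$history, truth = sim$truth)
}
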