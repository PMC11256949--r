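# Optimization loops.  Paired regime: gradient descent on reconstruction +
# bidirectional MSE.  Unpaired regime: alternating discriminator updates
# and generator updates on the weighted reconstruction + adversarial +
# cycle + identity objective.  All randomness flows from the config seed;
# runs are reproducible on a fixed thread count.

#' Training configuration
#'
#' @param mode `"paired"` (bulk, matched control/treated) or `"unpaired"`
#'   (single-cell, disjoint pools with adversarial alignment).
#' @param epochs,batch_size loop dimensions.
#' @param lr_gen generator/encoder learning rate; defaults to `1e-3`
#'   (paired) or `2e-4` (unpaired).
#' @param lr_disc discriminator learning rate (unpaired only).
#' @param weights a [loss_weights()].
#' @param seed root seed: determines initialization, batch order and the
#'   control-perturbation assignment.
#' @param disc_steps_per_gen_step discriminator updates per generator
#'   update.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param latent_dim,enc_hidden,disc_hidden,batchnorm,shared_autoencoder,
#'   gat_hidden,dose architecture knobs forwarded to [model_state()].
#' @param pert_encoder `"gat"`, `"genetic"` or `"none"`.
#' @param verbose emit one structured log line per epoch.
#' @export
training_config <- function(mode = c("paired", "unpaired"),
                            epochs = 100L, batch_size = 128L,
                            lr_gen = NULL, lr_disc = 2e-4,
                            weights = loss_weights(),
                            seed = 1L,
                            disc_steps_per_gen_step = 1L,
                            patience = 20L,
                            latent_dim = 128L,
                            enc_hidden = c(512L, 256L),
                            disc_hidden = c(256L, 64L),
                            batchnorm = TRUE,
                            shared_autoencoder = FALSE,
                            pert_encoder = "gat",
                            gat_hidden = c(32L, 32L),
                            dose = FALSE,
                            verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(lr_gen)) lr_gen <- if (mode == "paired") 1e-3 else 2e-4
  cfg <- list(mode = mode, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              lr_gen = lr_gen, lr_disc = lr_disc, weights = weights,
              seed = as.integer(seed),
              disc_steps_per_gen_step = as.integer(disc_steps_per_gen_step),
              patience = as.integer(patience),
              latent_dim = as.integer(latent_dim),
              enc_hidden = as.integer(enc_hidden),
              disc_hidden = as.integer(disc_hidden),
              batchnorm = isTRUE(batchnorm),
              shared_autoencoder = isTRUE(shared_autoencoder),
              pert_encoder = pert_encoder,
              gat_hidden = as.integer(gat_hidden),
              dose = isTRUE(dose),
              verbose = isTRUE(verbose))
  stopifnot(cfg$epochs > 0, cfg$batch_size > 0, cfg$lr_gen >= 0,
            cfg$lr_disc >= 0, cfg$patience > 0,
            cfg$disc_steps_per_gen_step > 0)
  structure(cfg, class = "training_config")
}

net_name <- function(m, which) {
  if (m$shared_autoencoder) {
    if (which == "enc_treated") return("enc_control")
    if (which == "dec_control") return("dec_treated")
  }
  which
}

gen_params <- function(m) {
  gp <- list(enc_control = m$enc_control$params,
             dec_treated = m$dec_treated$params)
  if (!m$shared_autoencoder) {
    gp$enc_treated <- m$enc_treated$params
    gp$dec_control <- m$dec_control$params
  }
  if (!is.null(m$pert_encoder)) gp$pert <- m$pert_encoder$params
  if (!is.null(m$dose_net)) gp$dose <- m$dose_net
  gp
}

set_gen_params <- function(m, gp) {
  m$enc_control$params <- gp$enc_control
  m$dec_treated$params <- gp$dec_treated
  if (!m$shared_autoencoder) {
    m$enc_treated$params <- gp$enc_treated
    m$dec_control$params <- gp$dec_control
  }
  if (!is.null(gp$pert)) m$pert_encoder$params <- gp$pert
  if (!is.null(gp$dose)) m$dose_net <- gp$dose
  m
}

disc_params <- function(m) list(disc_treated = m$disc_treated$params,
                                disc_control = m$disc_control$params)

set_disc_params <- function(m, dp) {
  m$disc_treated$params <- dp$disc_treated
  m$disc_control$params <- dp$disc_control
  m
}

# ---- perturbation-embedding forward/backward for training -----------------

embed_forward_train <- function(m, records, graphs) {
  key <- paste(records$perturbation_id, records$dose, sep = "@")
  D <- matrix(0, nrow(records), m$latent_dim)
  info <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    r <- as.list(records[rows[1L], ])
    it <- list(rows = rows, kind = r$kind)
    if (r$kind != "control") {
      enc <- m$pert_encoder
      if (r$kind == "genetic") {
        idx <- match(r$target_gene, enc$vocab)
        if (is.na(idx))
          pc_stop(sprintf("target gene '%s' not in vocabulary", r$target_gene),
                  "pertcycle_vocab_error")
        emb <- drop(enc$params$W[, idx]) + enc$params$b
        it$idx <- idx
      } else {
        g <- graphs[[r$perturbation_id]]
        if (is.null(g)) g <- m$graph_library[[r$perturbation_id]]
        if (is.null(g)) g <- smiles_to_graph(r$smiles)
        gc <- gat_encode(enc, g, keep_cache = TRUE)
        emb <- gc$emb
        it$cache <- gc
      }
      it$emb_raw <- emb
      if (!is.null(m$dose_net) && !is.null(r$dose) && !is.na(r$dose)) {
        it$dosef <- dose_embedding_forward(m$dose_net, r$dose)
        emb <- emb * it$dosef$e
      }
      D[rows, ] <- matrix(emb, length(rows), m$latent_dim, byrow = TRUE)
    }
    info[[k]] <- it
  }
  list(D = D, key = key, info = info)
}

embed_backward_train <- function(m, ef, demb) {
  enc <- m$pert_encoder
  if (is.null(enc)) return(NULL)
  gp <- tree_zero(enc$params)
  gd <- if (!is.null(m$dose_net)) tree_zero(m$dose_net)
  for (it in ef$info) {
    if (it$kind == "control") next
    dtot <- colSums(demb[it$rows, , drop = FALSE])
    if (!is.null(it$dosef)) {
      ddrug <- dtot * it$dosef$e
      de <- dtot * it$emb_raw
      dn <- m$dose_net
      h <- it$dosef$h
      gd$W2 <- gd$W2 + outer(h, de)
      gd$b2 <- gd$b2 + de
      dpre <- drop(dn$W2 %*% de) * (1 - h^2)
      gd$W1 <- gd$W1 + matrix(it$dosef$u * dpre, 1L)
      gd$b1 <- gd$b1 + dpre
    } else ddrug <- dtot
    if (it$kind == "genetic") {
      gp$W[, it$idx] <- gp$W[, it$idx] + ddrug
      gp$b <- gp$b + ddrug
    } else {
      gp <- tree_add(gp, gat_encode_backward(enc, it$cache, ddrug))
    }
  }
  list(pert = gp, dose = gd)
}

# ---- training entry point --------------------------------------------------

#' Train a perturbation-response model
#'
#' Builds a [model_state()] from the config and fits it to the training
#' dataset; validation data drive early stopping (patience epochs without
#' improvement) and best-checkpoint selection.  Paired mode minimizes
#' reconstruction + bidirectional MSE; unpaired mode alternates
#' discriminator maximization with generator minimization of the weighted
#' full objective.  Fakes are detached during the discriminator step (the
#' two optimizers never share gradients).
#'
#' @param ds_train,ds_val [expression_dataset()]s; `ds_val` may be `NULL`.
#' @param cfg a [training_config()].
#' @param graphs optional named list of [drug_graph()]s (defaults to the
#'   training dataset's attached graphs).
#' @return list with `model` (best-validation [model_state()], including
#'   the graph library used), `history` (per-epoch data frame) and
#'   `best_epoch`.
#' @export
train_model <- function(ds_train, ds_val = NULL, cfg, graphs = NULL) {
  if (is.null(graphs)) graphs <- ds_train$graphs
  if (nrow(ds_train$matrix) == 0L)
    pc_stop("training dataset is empty", "pertcycle_config_error")
  G <- ncol(ds_train$matrix)
  genetic_vocab <- NULL
  if (cfg$pert_encoder == "genetic")
    genetic_vocab <- sort(unique(stats::na.omit(ds_train$records$target_gene)))
  pert_feature_dim <- if (cfg$pert_encoder == "gat") {
    if (!is.null(graphs) && length(graphs)) ncol(graphs[[1L]]$node_features)
    else atom_feature_dim()
  }
  m <- model_state(G, latent_dim = cfg$latent_dim,
                   enc_hidden = cfg$enc_hidden, disc_hidden = cfg$disc_hidden,
                   batchnorm = cfg$batchnorm,
                   shared_autoencoder = cfg$shared_autoencoder,
                   pert_encoder = cfg$pert_encoder,
                   pert_feature_dim = pert_feature_dim,
                   gat_hidden = cfg$gat_hidden,
                   genetic_vocab = genetic_vocab,
                   dose = cfg$dose,
                   gene_ids = colnames(ds_train$matrix),
                   seed = derive_seed(cfg$seed, "init"))
  m$graph_library <- graphs

  if (cfg$mode == "paired") train_paired(m, ds_train, ds_val, cfg, graphs)
  else train_unpaired(m, ds_train, ds_val, cfg, graphs)
}

check_finite_loss <- function(loss, epoch, step) {
  if (!is.finite(loss))
    pc_stop(sprintf("training diverged: non-finite loss at epoch %d, step %d",
                    epoch, step), "pertcycle_divergence_error",
            data = list(epoch = epoch, step = step))
}

# ---- paired loop -----------------------------------------------------------

train_paired <- function(m, ds_train, ds_val, cfg, graphs) {
  pairs <- build_pairs(ds_train, "paired")
  vpairs <- if (!is.null(ds_val)) build_pairs(ds_val, "paired")
  n <- nrow(pairs$x)
  opt <- adam_new(gen_params(m))
  history <- vector("list", cfg$epochs)
  best <- list(metric = Inf, model = m, epoch = 0L)
  wait <- 0L

  set.seed(derive_seed(cfg$seed, "paired_loop"))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / cfg$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[(((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n))]
      st <- paired_step(m, pairs$x[idx, , drop = FALSE],
                        pairs$y[idx, , drop = FALSE],
                        pairs$records[idx, , drop = FALSE], graphs)
      m <- st$m
      check_finite_loss(st$loss, epoch, b)
      ep_loss <- ep_loss + st$loss * length(idx)
      if (cfg$lr_gen > 0) {
        up <- adam_step(gen_params(m), st$grads, opt, cfg$lr_gen)
        opt <- up$state
        m <- set_gen_params(m, up$params)
      }
    }
    ep_loss <- ep_loss / n
    val <- if (!is.null(vpairs)) {
      reconstruction_loss(vpairs$x, m, "forward") +
        paired_mse_loss(vpairs$x, vpairs$y, vpairs$records, m, graphs)
    } else ep_loss
    history[[epoch]] <- data.frame(epoch = epoch, train_total = ep_loss,
                                   val_total = val)
    if (cfg$verbose)
      message(sprintf("epoch=%d mode=paired train=%.5f val=%.5f",
                      epoch, ep_loss, val))
    if (val < best$metric - 1e-12) {
      best <- list(metric = val, model = m, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  list(model = best$model, history = do.call(rbind, history[!vapply(history, is.null, TRUE)]),
       best_epoch = best$epoch)
}

paired_step <- function(m, x, y, records, graphs) {
  n <- nrow(x)
  Gr <- tree_zero(gen_params(m))
  addg <- function(name, g) {
    nm <- net_name(m, name)
    Gr[[nm]] <<- tree_add(Gr[[nm]], g)
  }
  fwd <- function(name, X) {
    nm <- net_name(m, name)
    r <- mlp_forward(m[[nm]], X, train = TRUE, keep_cache = TRUE)
    m[[nm]]$running <<- r$running
    r
  }
  bwd <- function(name, cache, dOut) mlp_backward(m[[net_name(m, name)]], cache, dOut)

  ef <- embed_forward_train(m, records, graphs)
  D <- ef$D

  f1 <- fwd("enc_control", x)            # z = F(x), shared by reco + forward MSE
  rec <- fwd("dec_treated", f1$out)      # G(z)
  pred <- fwd("dec_treated", f1$out + D) # G(z + d)
  f2 <- fwd("enc_treated", y)            # z' = F'(y)
  rest <- fwd("dec_control", f2$out - D) # G'(z' - d)

  r_rec <- rec$out - x
  r_pred <- pred$out - y
  r_rest <- rest$out - x
  loss <- mean(rowSums(r_rec^2)) + mean(rowSums(r_pred^2)) +
    mean(rowSums(r_rest^2))

  b_rec <- bwd("dec_treated", rec$cache, 2 * r_rec / n)
  addg("dec_treated", b_rec$grads)
  b_pred <- bwd("dec_treated", pred$cache, 2 * r_pred / n)
  addg("dec_treated", b_pred$grads)
  demb <- b_pred$dX
  b_f1 <- bwd("enc_control", f1$cache, b_rec$dX + b_pred$dX)
  addg("enc_control", b_f1$grads)

  b_rest <- bwd("dec_control", rest$cache, 2 * r_rest / n)
  addg("dec_control", b_rest$grads)
  demb <- demb - b_rest$dX
  b_f2 <- bwd("enc_treated", f2$cache, b_rest$dX)
  addg("enc_treated", b_f2$grads)

  eg <- embed_backward_train(m, ef, demb)
  if (!is.null(eg)) {
    Gr$pert <- tree_add(Gr$pert, eg$pert)
    if (!is.null(eg$dose)) Gr$dose <- tree_add(Gr$dose, eg$dose)
  }
  list(m = m, grads = Gr, loss = loss)
}

# ---- unpaired loop ---------------------------------------------------------

train_unpaired <- function(m, ds_train, ds_val, cfg, graphs) {
  pools <- build_pairs(ds_train, "unpaired")
  vpools <- if (!is.null(ds_val)) build_pairs(ds_val, "unpaired")
  if (nrow(pools$controls) == 0L || nrow(pools$treated) == 0L)
    pc_stop("unpaired training needs both control and treated samples",
            "pertcycle_config_error")
  nx <- nrow(pools$controls)
  ny <- nrow(pools$treated)
  opt_g <- adam_new(gen_params(m))
  opt_d <- adam_new(disc_params(m))
  history <- vector("list", cfg$epochs)
  best <- list(metric = Inf, model = m, epoch = 0L)
  wait <- 0L
  w <- cfg$weights

  set.seed(derive_seed(cfg$seed, "unpaired_loop"))
  for (epoch in seq_len(cfg$epochs)) {
    ordx <- sample.int(nx)
    ordy <- sample.int(ny)
    nb <- min(ceiling(nx / cfg$batch_size), ceiling(ny / cfg$batch_size))
    ep <- c(total = 0, reco = 0, gan = 0, cyc = 0, identity = 0, disc = 0)
    for (b in seq_len(nb)) {
      ix <- ordx[(((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, nx))]
      iy <- ordy[(((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, ny))]
      x <- pools$controls[ix, , drop = FALSE]
      y <- pools$treated[iy, , drop = FALSE]
      rec_y <- pools$treated_records[iy, , drop = FALSE]
      assignment <- sample.int(nrow(rec_y), nrow(x), replace = TRUE)

      for (ds_i in seq_len(cfg$disc_steps_per_gen_step)) {
        st_d <- disc_step(m, x, y, rec_y, assignment, graphs)
        m <- st_d$m
        check_finite_loss(st_d$loss, epoch, b)
        if (cfg$lr_disc > 0) {
          up <- adam_step(disc_params(m), st_d$grads, opt_d, cfg$lr_disc)
          opt_d <- up$state
          m <- set_disc_params(m, up$params)
        }
      }
      st <- gen_step(m, x, y, rec_y, assignment, graphs, w)
      m <- st$m
      check_finite_loss(st$loss["total"], epoch, b)
      if (cfg$lr_gen > 0) {
        up <- adam_step(gen_params(m), st$grads, opt_g, cfg$lr_gen)
        opt_g <- up$state
        m <- set_gen_params(m, up$params)
      }
      ep <- ep + c(st$loss, disc = st_d$loss)
    }
    ep <- ep / nb
    # validation: cycle + identity (adversarial terms are not a progress
    # measure); fixed assignment seed for comparability across epochs
    val <- if (!is.null(vpools)) {
      cycle_loss(vpools$controls, vpools$treated, vpools$treated_records, m,
                 graphs, seed = cfg$seed) +
        identity_loss(vpools$treated, m = m)
    } else ep[["cyc"]] / max(w$lam, 1e-12) + ep[["identity"]] / max(w$identity_weight, 1e-12)
    history[[epoch]] <- data.frame(epoch = epoch, train_total = ep[["total"]],
                                   reco = ep[["reco"]], gan = ep[["gan"]],
                                   cyc = ep[["cyc"]], identity = ep[["identity"]],
                                   disc = ep[["disc"]], val_metric = val)
    if (cfg$verbose)
      message(sprintf("epoch=%d mode=unpaired total=%.5f disc=%.5f val=%.5f",
                      epoch, ep[["total"]], ep[["disc"]], val))
    if (val < best$metric - 1e-12) {
      best <- list(metric = val, model = m, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  list(model = best$model,
       history = do.call(rbind, history[!vapply(history, is.null, TRUE)]),
       best_epoch = best$epoch)
}

# Discriminator update: maximize log D(real) + log(1 - D(fake)) in both
# directions.  Fakes are generated with the current generator and detached
# (no generator gradients are produced here).
disc_step <- function(m, x, y, rec_y, assignment, graphs) {
  n_x <- nrow(x); n_y <- nrow(y)
  ef <- embed_forward_train(m, rec_y, graphs)
  Dt <- ef$D
  Dc <- Dt[assignment, , drop = FALSE]

  fz <- mlp_forward(m$enc_control, x, train = TRUE)
  m$enc_control$running <- fz$running
  fy <- mlp_forward(m$dec_treated, fz$out + Dc, train = TRUE)
  m$dec_treated$running <- fy$running
  fz2 <- mlp_forward(m[[net_name(m, "enc_treated")]], y, train = TRUE)
  m[[net_name(m, "enc_treated")]]$running <- fz2$running
  fx <- mlp_forward(m[[net_name(m, "dec_control")]], fz2$out - Dt, train = TRUE)
  m[[net_name(m, "dec_control")]]$running <- fx$running

  Gd <- tree_zero(disc_params(m))
  loss <- 0
  for (side in c("treated", "control")) {
    nm <- if (side == "treated") "disc_treated" else "disc_control"
    real <- if (side == "treated") y else x
    fake <- if (side == "treated") fy$out else fx$out
    fr <- mlp_forward(m[[nm]], real, train = TRUE, keep_cache = TRUE)
    m[[nm]]$running <- fr$running
    ff <- mlp_forward(m[[nm]], fake, train = TRUE, keep_cache = TRUE)
    m[[nm]]$running <- ff$running
    sr <- clamp01(drop(fr$out)); sf <- clamp01(drop(ff$out))
    loss <- loss - mean(log(sr)) - mean(log(1 - sf))
    dr <- matrix(-1 / (length(sr) * sr), ncol = 1L)
    df <- matrix(1 / (length(sf) * (1 - sf)), ncol = 1L)
    Gd[[nm]] <- tree_add(Gd[[nm]], mlp_backward(m[[nm]], fr$cache, dr)$grads)
    Gd[[nm]] <- tree_add(Gd[[nm]], mlp_backward(m[[nm]], ff$cache, df)$grads)
  }
  list(m = m, grads = Gd, loss = loss)
}

# Generator/encoder update on the full unpaired objective.
gen_step <- function(m, x, y, rec_y, assignment, graphs, w) {
  n_x <- nrow(x); n_y <- nrow(y)
  Gr <- tree_zero(gen_params(m))
  addg <- function(name, g) {
    nm <- net_name(m, name)
    Gr[[nm]] <<- tree_add(Gr[[nm]], g)
  }
  fwd <- function(name, X) {
    nm <- net_name(m, name)
    r <- mlp_forward(m[[nm]], X, train = TRUE, keep_cache = TRUE)
    m[[nm]]$running <<- r$running
    r
  }
  bwd <- function(name, cache, dOut) mlp_backward(m[[net_name(m, name)]], cache, dOut)

  ef <- embed_forward_train(m, rec_y, graphs)
  Dt <- ef$D
  Dc <- Dt[assignment, , drop = FALSE]

  # forward passes
  ec1 <- fwd("enc_control", x)                    # F(x)
  dt_rec <- fwd("dec_treated", ec1$out)           # reco x
  dt_fake <- fwd("dec_treated", ec1$out + Dc)     # y-hat
  et1 <- fwd("enc_treated", y)                    # F'(y)
  dc_rec <- fwd("dec_control", et1$out)           # reco y
  dc_fake <- fwd("dec_control", et1$out - Dt)     # x-hat
  ec2 <- fwd("enc_control", y)                    # identity fwd
  dt_id <- fwd("dec_treated", ec2$out)
  et2 <- fwd("enc_treated", x)                    # identity rev
  dc_id <- fwd("dec_control", et2$out)
  et3 <- fwd("enc_treated", dt_fake$out)          # cycle x: F'(y-hat)
  dc_cyc <- fwd("dec_control", et3$out - Dc)
  ec3 <- fwd("enc_control", dc_fake$out)          # cycle y: F(x-hat)
  dt_cyc <- fwd("dec_treated", ec3$out + Dt)

  # discriminator scores of fakes (generator view; disc params frozen)
  fdy <- mlp_forward(m$disc_treated, dt_fake$out, train = FALSE, keep_cache = TRUE)
  fdx <- mlp_forward(m$disc_control, dc_fake$out, train = FALSE, keep_cache = TRUE)
  sy <- clamp01(drop(fdy$out)); sx <- clamp01(drop(fdx$out))

  r_rec_x <- dt_rec$out - x
  r_rec_y <- dc_rec$out - y
  r_id_y <- dt_id$out - y
  r_id_x <- dc_id$out - x
  r_cyc_x <- dc_cyc$out - x
  r_cyc_y <- dt_cyc$out - y

  l_reco <- mean(rowSums(r_rec_x^2)) + mean(rowSums(r_rec_y^2))
  l_id <- mean(rowSums(r_id_y^2)) + mean(rowSums(r_id_x^2))
  l_cyc <- mean(rowSums(r_cyc_x^2)) + mean(rowSums(r_cyc_y^2))
  l_gan <- -mean(log(sy)) - mean(log(sx))
  total <- w$alpha * l_reco + w$beta * l_gan + w$lam * l_cyc +
    w$identity_weight * l_id

  demb_t <- matrix(0, n_y, m$latent_dim)   # grads into treated-row embeddings
  demb_c <- matrix(0, n_x, m$latent_dim)   # grads into assigned-control embeddings

  # cycle y path: dt_cyc <- ec3 <- dc_fake
  b <- bwd("dec_treated", dt_cyc$cache, w$lam * 2 * r_cyc_y / n_y)
  addg("dec_treated", b$grads)
  demb_t <- demb_t + b$dX
  b2 <- bwd("enc_control", ec3$cache, b$dX)
  addg("enc_control", b2$grads)
  d_dc_fake <- b2$dX
  # cycle x path: dc_cyc <- et3 <- dt_fake
  b <- bwd("dec_control", dc_cyc$cache, w$lam * 2 * r_cyc_x / n_x)
  addg("dec_control", b$grads)
  demb_c <- demb_c - b$dX
  b2 <- bwd("enc_treated", et3$cache, b$dX)
  addg("enc_treated", b2$grads)
  d_dt_fake <- b2$dX
  # GAN generator terms into the fakes (fakes from controls are scored by
  # the treated discriminator, hence length(sy) = n_x)
  b <- mlp_backward(m$disc_treated, fdy$cache,
                    matrix(-w$beta / (length(sy) * sy), ncol = 1L))
  d_dt_fake <- d_dt_fake + b$dX
  b <- mlp_backward(m$disc_control, fdx$cache,
                    matrix(-w$beta / (length(sx) * sx), ncol = 1L))
  d_dc_fake <- d_dc_fake + b$dX
  # fake generators
  b <- bwd("dec_treated", dt_fake$cache, d_dt_fake)
  addg("dec_treated", b$grads)
  demb_c <- demb_c + b$dX
  d_ec1 <- b$dX
  b <- bwd("dec_control", dc_fake$cache, d_dc_fake)
  addg("dec_control", b$grads)
  demb_t <- demb_t - b$dX
  d_et1 <- b$dX
  # reconstruction terms
  b <- bwd("dec_treated", dt_rec$cache, w$alpha * 2 * r_rec_x / n_x)
  addg("dec_treated", b$grads)
  d_ec1 <- d_ec1 + b$dX
  b <- bwd("dec_control", dc_rec$cache, w$alpha * 2 * r_rec_y / n_y)
  addg("dec_control", b$grads)
  d_et1 <- d_et1 + b$dX
  # identity terms
  b <- bwd("dec_treated", dt_id$cache, w$identity_weight * 2 * r_id_y / n_y)
  addg("dec_treated", b$grads)
  b2 <- bwd("enc_control", ec2$cache, b$dX)
  addg("enc_control", b2$grads)
  b <- bwd("dec_control", dc_id$cache, w$identity_weight * 2 * r_id_x / n_x)
  addg("dec_control", b$grads)
  b2 <- bwd("enc_treated", et2$cache, b$dX)
  addg("enc_treated", b2$grads)
  # base encoders
  b <- bwd("enc_control", ec1$cache, d_ec1)
  addg("enc_control", b$grads)
  b <- bwd("enc_treated", et1$cache, d_et1)
  addg("enc_treated", b$grads)

  # perturbation-encoder gradients: fold control-row contributions back
  # onto the treated rows they were assigned from
  demb_all <- demb_t
  for (i in seq_len(n_x))
    demb_all[assignment[i], ] <- demb_all[assignment[i], ] + demb_c[i, ]
  eg <- embed_backward_train(m, ef, demb_all)
  if (!is.null(eg)) {
    Gr$pert <- tree_add(Gr$pert, eg$pert)
    if (!is.null(eg$dose)) Gr$dose <- tree_add(Gr$dose, eg$dose)
  }
  list(m = m, grads = Gr,
       loss = c(total = total, reco = l_reco, gan = l_gan, cyc = l_cyc,
                identity = l_id))
}

# ---- batch prediction ------------------------------------------------------

#' Predict treated profiles for a batch of requests
#'
#' Each row of `ds` is a control profile whose record names the
#' perturbation to apply; the result carries one predicted treated profile
#' per request.  With `direction = "reverse"` rows are treated profiles
#' and the restored controls are returned.
#'
#' @param ds an [expression_dataset()] of requests.
#' @param m a trained [model_state()].
#' @param graphs optional named list of [drug_graph()]s.
#' @param direction `"forward"` or `"reverse"`.
#' @return an [expression_dataset()] of predictions.
#' @export
predict_batch <- function(ds, m, graphs = NULL, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (is.null(graphs)) graphs <- ds$graphs
  n <- nrow(ds$matrix)
  if (n == 0L)
    return(expression_dataset(ds$matrix, ds$records))
  D <- embed_records(ds$records, m, graphs)
  if (direction == "forward") {
    z <- mlp_forward(m$enc_control, ds$matrix, train = FALSE)$out
    out <- decode_treated(z + D, m)
  } else {
    z <- mlp_forward(net_enc_treated(m), ds$matrix, train = FALSE)$out
    out <- decode_control(z - D, m)
  }
  colnames(out) <- colnames(ds$matrix)
  rownames(out) <- rownames(ds$matrix)
  expression_dataset(out, ds$records, graphs = graphs)
}
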