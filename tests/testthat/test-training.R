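# Desk-scale training smoke tests.  The heavier convergence and
# generalization checks live in test-acceptance.R.

small_sim <- function(seed = 13L, paired = TRUE, n = 20L, K = 4L) {
  simulate_dataset(synthetic_config(n_genes = 12L, latent_dim_true = 3L,
                                    n_perturbations = K,
                                    cells_per_condition = n,
                                    noise_sd = 0.05, paired = paired,
                                    seed = seed))
}

small_cfg <- function(mode, epochs, seed = 13L, ...) {
  training_config(mode, epochs = epochs, batch_size = 32L, latent_dim = 4L,
                  enc_hidden = c(16L), disc_hidden = c(8L), batchnorm = FALSE,
                  gat_hidden = c(8L, 8L), seed = seed, ...)
}

test_that("zero learning rate leaves parameters bitwise unchanged", {
  s <- small_sim()
  cfg <- small_cfg("paired", epochs = 1L, lr_gen = 0)
  fit <- train_model(s$dataset, NULL, cfg)
  ref <- model_state(12L, latent_dim = 4L, enc_hidden = c(16L),
                     disc_hidden = c(8L), batchnorm = FALSE,
                     pert_encoder = "gat",
                     pert_feature_dim = ncol(s$dataset$graphs[[1]]$node_features),
                     gat_hidden = c(8L, 8L),
                     gene_ids = colnames(s$dataset$matrix),
                     seed = pertcycle:::derive_seed(cfg$seed, "init"))
  expect_identical(fit$model$enc_control$params, ref$enc_control$params)
  expect_identical(fit$model$pert_encoder$params, ref$pert_encoder$params)
})

test_that("training is reproducible and improves the objective", {
  s <- small_sim()
  cfg <- small_cfg("paired", epochs = 15L)
  f1 <- train_model(s$dataset, NULL, cfg)
  f2 <- train_model(s$dataset, NULL, cfg)
  expect_equal(f1$history$train_total, f2$history$train_total, tolerance = 1e-7)
  expect_lt(tail(f1$history$train_total, 1), f1$history$train_total[1])
  # validation-driven early stopping returns the best epoch
  sp <- split_by_perturbation(s$dataset, split_spec(fractions = c(0.5, 0.25, 0.25),
                                                    seed = 2L))
  f3 <- train_model(sp$train, sp$validation, small_cfg("paired", epochs = 10L))
  expect_lte(f3$best_epoch, nrow(f3$history))
  expect_equal(f3$history$val_total[f3$best_epoch], min(f3$history$val_total))
})

test_that("unpaired training runs, improves, and the discriminator learns", {
  s <- small_sim(paired = FALSE, n = 30L)
  cfg <- small_cfg("unpaired", epochs = 20L, seed = 3L, lr_disc = 2e-3,
                   weights = loss_weights(alpha = 2.5, beta = 2, lam = 6.5,
                                          identity_weight = 1))
  fit <- train_model(s$dataset, NULL, cfg)
  h <- fit$history
  expect_lt(tail(h$cyc, 1), h$cyc[1])
  expect_lt(tail(h$reco, 1), h$reco[1])
  # discriminator separates real from generated on a frozen generator
  pools <- build_pairs(s$dataset, "unpaired")
  m <- fit$model
  fake <- predict_batch(expression_dataset(
    pools$controls,
    transform(pools$treated_records[sample.int(nrow(pools$treated_records),
                                               nrow(pools$controls),
                                               replace = TRUE), ],
              sample_id = paste0("f", seq_len(nrow(pools$controls)))),
    graphs = s$dataset$graphs), m)
  acc <- mean(c(discriminate(pools$treated, "treated", m = m) > 0.5,
                discriminate(fake$matrix, "treated", m = m) < 0.5))
  expect_gt(acc, 0.5)
})

test_that("predict_batch equals per-sample predict_response and handles d = 0", {
  s <- small_sim()
  cfg <- small_cfg("paired", epochs = 2L)
  fit <- train_model(s$dataset, NULL, cfg)
  m <- fit$model
  pairs <- build_pairs(s$dataset, "paired")
  req <- expression_dataset(pairs$x[1:5, ], pairs$records[1:5, ],
                            graphs = s$dataset$graphs)
  pred <- predict_batch(req, m)
  for (i in 1:5)
    expect_equal(pred$matrix[i, ],
                 predict_response(pairs$x[i, ], pairs$records[i, ], m),
                 tolerance = 1e-10, ignore_attr = TRUE)
  # empty request list -> empty output
  empty <- predict_batch(expression_dataset(pairs$x[0, , drop = FALSE],
                                            pairs$records[0, ]), m)
  expect_equal(nrow(empty$matrix), 0L)
  # control requests return the reconstruction path
  ctrl_rec <- pairs$records[1:2, ]
  ctrl_rec$kind <- "control"; ctrl_rec$perturbation_id <- "control"
  ctrl_rec$smiles <- NA
  pred0 <- predict_batch(expression_dataset(pairs$x[1:2, ], ctrl_rec), m)
  recon <- pertcycle:::decode_treated(encode_control(pairs$x[1:2, ], m), m)
  expect_identical(unname(pred0$matrix), unname(recon))
  # reverse direction restores controls
  predr <- predict_batch(expression_dataset(pairs$y[1:3, ], pairs$records[1:3, ],
                                            graphs = s$dataset$graphs),
                         m, direction = "reverse")
  expect_equal(predr$matrix[2, ],
               restore_control(pairs$y[2, ], pairs$records[2, ], m),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("genetic perturbations train end to end", {
  s <- small_sim(n = 15L, K = 3L)
  ds <- s$dataset
  ds$graphs <- NULL
  trt <- ds$records$kind == "drug"
  ds$records$kind[trt] <- "genetic"
  ds$records$target_gene[trt] <- ds$records$perturbation_id[trt]
  cfg <- small_cfg("paired", epochs = 5L, pert_encoder = "genetic")
  fit <- train_model(ds, NULL, cfg)
  expect_equal(fit$model$pert_encoder$kind, "genetic")
  expect_lt(tail(fit$history$train_total, 1), fit$history$train_total[1])
  # unknown gene at prediction time errors
  bad <- ds$records[which(trt)[1], ]
  bad$target_gene <- "NOPE"
  expect_error(predict_response(ds$matrix[1, ], bad, fit$model),
               class = "pertcycle_vocab_error")
})
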