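# Training objectives as pure functions of model outputs (evaluation-mode
# forward passes).  Convention: every loss is a mean over the batch of a
# sum over genes, so loss weights are batch-size invariant.

DISC_EPS <- 1e-7  # clamp discriminator outputs away from {0, 1} before logs

clamp01 <- function(p) pmin(pmax(p, DISC_EPS), 1 - DISC_EPS)

# mean over rows of squared row norms
mean_sq_rownorm <- function(R) mean(rowSums(R^2))

# Embed each record's perturbation; rows grouped by unique
# (perturbation_id, dose) so graphs are encoded once.
embed_records <- function(records, m, graphs = NULL) {
  n <- nrow(records)
  D <- matrix(0, n, m$latent_dim)
  key <- paste(records$perturbation_id, records$dose, sep = "@")
  for (k in unique(key)) {
    rows <- which(key == k)
    D[rows, ] <- matrix(resolve_embedding(records[rows[1L], , drop = FALSE],
                                          m, graphs),
                        length(rows), m$latent_dim, byrow = TRUE)
  }
  D
}

# D17: in unpaired mode each control is cycled under a perturbation drawn
# (seeded) from the batch's treated labels.
assign_cycle_perturbations <- function(n_controls, treated_records, seed = 1L) {
  with_seed(derive_seed(seed, "cycle_assignment"),
            sample.int(nrow(treated_records), n_controls, replace = TRUE))
}

#' Loss weights
#'
#' @param alpha weight of the reconstruction loss.
#' @param beta weight of the adversarial loss.
#' @param lam weight of the cycle-consistency loss (default 10, the
#'   cycleGAN convention; single-cell fits in the source work fine-tune it
#'   in roughly 6-7).
#' @param identity_weight weight of the identity regularizer.
#' @export
loss_weights <- function(alpha = 1, beta = 1, lam = 10, identity_weight = 1) {
  w <- c(alpha = alpha, beta = beta, lam = lam, identity_weight = identity_weight)
  if (any(!is.finite(w)) || any(w < 0))
    pc_stop("loss weights must be finite and nonnegative", "pertcycle_config_error")
  as.list(w)
}

#' Autoencoder reconstruction loss
#'
#' Mean over the batch of the squared reconstruction error
#' `||x - G(F(x))||^2`, through the forward pair (`enc_control`,
#' `dec_treated`) or the reverse pair.
#'
#' @param x batch matrix (samples x G) or single profile.
#' @param m a [model_state()].
#' @param direction `"forward"` or `"reverse"`.
#' @export
reconstruction_loss <- function(x, m, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  x <- as_row_matrix(x)
  if (nrow(x) == 0L) pc_stop("empty batch", "pertcycle_config_error")
  xhat <- if (direction == "forward")
    decode_treated(mlp_forward(m$enc_control, x, train = FALSE)$out, m)
  else
    decode_control(mlp_forward(net_enc_treated(m), x, train = FALSE)$out, m)
  mean_sq_rownorm(x - xhat)
}

#' Paired mean-squared-error loss
#'
#' For aligned (x, y, perturbation) triples: the squared error of
#' predicting the treated state from the control plus the squared error of
#' restoring the control from the treated state, averaged over the batch.
#'
#' @param x matrix of control profiles (one row per triple).
#' @param y matrix of matched treated profiles.
#' @param records perturbation records aligned to rows.
#' @param m a [model_state()].
#' @param graphs optional named list of [drug_graph()]s.
#' @export
paired_mse_loss <- function(x, y, records, m, graphs = NULL) {
  x <- as_row_matrix(x); y <- as_row_matrix(y)
  if (nrow(x) != nrow(y) || nrow(x) != nrow(records))
    pc_stop("paired loss requires aligned x, y and records",
            "pertcycle_pairing_error")
  D <- embed_records(records, m, graphs)
  z <- mlp_forward(m$enc_control, x, train = FALSE)$out
  yhat <- decode_treated(z + D, m)
  z2 <- mlp_forward(net_enc_treated(m), y, train = FALSE)$out
  xhat <- decode_control(z2 - D, m)
  mean_sq_rownorm(y - yhat) + mean_sq_rownorm(x - xhat)
}

#' Bidirectional adversarial losses
#'
#' Forward direction: the treated-state discriminator scores real treated
#' profiles against generated ones `G(F(x) + d)`; reverse direction: the
#' control-state discriminator scores real controls against restored ones
#' `G'(F'(y) - d)`.  Discriminator losses are the negated two-term log
#' objective; generator losses use the non-saturating `-log D(fake)`
#' form.  Scores are clamped away from 0/1 so every term is finite.
#'
#' @param controls matrix of control profiles.
#' @param treated matrix of treated profiles.
#' @param records perturbation records aligned to `treated` rows.
#' @param m a [model_state()].
#' @param graphs optional named list of [drug_graph()]s.
#' @param assignment integer vector mapping each control row to a treated
#'   row whose perturbation it is generated under; defaults to a seeded
#'   draw from the treated labels.
#' @param seed seed for the default assignment.
#' @return list with `gen_fwd`, `disc_fwd`, `gen_rev`, `disc_rev`.
#' @export
adversarial_losses <- function(controls, treated, records, m, graphs = NULL,
                               assignment = NULL, seed = 1L) {
  controls <- as_row_matrix(controls); treated <- as_row_matrix(treated)
  if (nrow(controls) == 0L || nrow(treated) == 0L)
    pc_stop("both pools must be nonempty", "pertcycle_config_error")
  if (is.null(assignment))
    assignment <- assign_cycle_perturbations(nrow(controls), records, seed)
  D_treat <- embed_records(records, m, graphs)
  D_ctrl <- D_treat[assignment, , drop = FALSE]

  fake_y <- decode_treated(
    mlp_forward(m$enc_control, controls, train = FALSE)$out + D_ctrl, m)
  fake_x <- decode_control(
    mlp_forward(net_enc_treated(m), treated, train = FALSE)$out - D_treat, m)

  s_real_y <- clamp01(discriminate(treated, "treated", m = m))
  s_fake_y <- clamp01(discriminate(fake_y, "treated", m = m))
  s_real_x <- clamp01(discriminate(controls, "control", m = m))
  s_fake_x <- clamp01(discriminate(fake_x, "control", m = m))

  list(gen_fwd = -mean(log(s_fake_y)),
       disc_fwd = -(mean(log(s_real_y)) + mean(log(1 - s_fake_y))),
       gen_rev = -mean(log(s_fake_x)),
       disc_rev = -(mean(log(s_real_x)) + mean(log(1 - s_fake_x))))
}

#' Cycle-consistency loss
#'
#' Controls are pushed forward under a perturbation and pulled back
#' (`x -> G(F(x)+d) -> G'(F'(.)-d) ~ x`); treated profiles take the
#' opposite round trip.  Sum of both mean squared cycle errors.
#'
#' @inheritParams adversarial_losses
#' @export
cycle_loss <- function(controls, treated, records, m, graphs = NULL,
                       assignment = NULL, seed = 1L) {
  controls <- as_row_matrix(controls); treated <- as_row_matrix(treated)
  if (nrow(records) == 0L)
    pc_stop("cycle loss needs perturbation labels", "pertcycle_config_error")
  if (is.null(assignment))
    assignment <- assign_cycle_perturbations(nrow(controls), records, seed)
  D_treat <- embed_records(records, m, graphs)
  D_ctrl <- D_treat[assignment, , drop = FALSE]

  # x -> y-hat -> x-hat
  z <- mlp_forward(m$enc_control, controls, train = FALSE)$out
  yh <- decode_treated(z + D_ctrl, m)
  xh <- decode_control(mlp_forward(net_enc_treated(m), yh, train = FALSE)$out - D_ctrl, m)
  # y -> x-hat -> y-hat
  z2 <- mlp_forward(net_enc_treated(m), treated, train = FALSE)$out
  xr <- decode_control(z2 - D_treat, m)
  yr <- decode_treated(mlp_forward(m$enc_control, xr, train = FALSE)$out + D_treat, m)

  mean_sq_rownorm(controls - xh) + mean_sq_rownorm(treated - yr)
}

#' Identity loss
#'
#' Penalizes the forward generator for altering already-treated samples
#' passed through without perturbation addition:
#' `mean ||G(F(y)) - y||^2`.
#'
#' @param treated matrix of treated profiles.
#' @param records perturbation records (unused; kept for a uniform loss
#'   signature).
#' @param m a [model_state()].
#' @export
identity_loss <- function(treated, records = NULL, m) {
  treated <- as_row_matrix(treated)
  if (nrow(treated) == 0L) pc_stop("empty batch", "pertcycle_config_error")
  reconstruction_loss(treated, m, "forward")
}

#' Combine loss components into the training objective
#'
#' Paired regime: the evenly weighted sum `reco + mse`.  Unpaired regime:
#' `alpha * reco + beta * (gen_fwd + gen_rev) + lam * cyc +
#' identity_weight * identity`.
#'
#' @param mode `"paired"` or `"unpaired"`.
#' @param components named list of computed component values: paired needs
#'   `reco`, `mse`; unpaired needs `reco`, `gen_fwd`, `gen_rev`, `cyc`,
#'   `identity`.
#' @param weights a [loss_weights()].
#' @return list with `total` and the per-term `breakdown`.
#' @export
total_loss <- function(mode = c("paired", "unpaired"), components,
                       weights = loss_weights()) {
  mode <- match.arg(mode)
  need <- if (mode == "paired") c("reco", "mse")
          else c("reco", "gen_fwd", "gen_rev", "cyc", "identity")
  missing_c <- setdiff(need, names(components))
  if (length(missing_c))
    pc_stop(sprintf("missing loss component(s) for %s mode: %s", mode,
                    paste(missing_c, collapse = ", ")),
            "pertcycle_config_error")
  if (mode == "paired") {
    total <- components$reco + components$mse
    breakdown <- c(reco = components$reco, mse = components$mse)
  } else {
    gan <- components$gen_fwd + components$gen_rev
    breakdown <- c(reco = weights$alpha * components$reco,
                   gan = weights$beta * gan,
                   cyc = weights$lam * components$cyc,
                   identity = weights$identity_weight * components$identity)
    total <- sum(breakdown)
  }
  list(total = total, breakdown = breakdown)
}
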