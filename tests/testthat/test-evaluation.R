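test_that("r2 and explained variance match hand-computed oracles", {
  a <- c(1, 2, 3, 4)
  p <- c(1.1, 1.9, 3.2, 3.8)
  # SS_res = .01+.01+.04+.04 = 0.10; SS_tot = 5
  expect_equal(r2_score(p, a), 1 - 0.10 / 5, tolerance = 1e-12)
  expect_equal(r2_score(a, a), 1.0)
  expect_equal(r2_score(rep(mean(a), 4), a), 0.0)
  expect_equal(explained_variance(a, a), 1.0)
  # constant bias: EV stays 1, r2 drops -- the discriminating case
  expect_equal(explained_variance(a + 2, a), 1.0)
  expect_lt(r2_score(a + 2, a), 1.0)
  # r2 can be negative (worse than the mean predictor)
  expect_lt(r2_score(rev(a) * 3, a), 0)
  set.seed(4)
  for (i in 1:5) {
    aa <- rnorm(10); pp <- rnorm(10)
    expect_equal(explained_variance(pp, aa),
                 1 - var(aa - pp) / var(aa), tolerance = 1e-12)
  }
  expect_warning(r2_na <- r2_score(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_true(is.na(r2_na))
  expect_error(r2_score(1:3, 1:4), class = "pertcycle_shape_error")
})

test_that("DEG selection thresholds, ranks and breaks ties deterministically", {
  ctrl <- rep(1, 5)
  expect_identical(select_top_degs(ctrl, ctrl), integer())
  # one gene at 4x (log2 fc = 2)
  trt <- ctrl; trt[3] <- 4
  expect_identical(select_top_degs(ctrl, trt), 3L)
  # fabricated fold changes spanning the threshold, log-space convention
  set.seed(13)
  fc <- c(seq(-3, 3, length.out = 59), 1)  # gene 60 ties gene with fc exactly 1
  ctrl2 <- rep(0, 60)
  got <- select_top_degs(ctrl2, fc, n = 50, threshold = 1, log_space = TRUE)
  over <- which(abs(fc) >= 1)
  expect_true(all(got %in% over))
  ord <- over[order(-abs(fc[over]), over)]
  expect_identical(got, head(ord, 50))
  expect_lte(length(got), 50L)
  # truncation to n
  expect_identical(select_top_degs(ctrl2, fc, n = 3, log_space = TRUE), ord[1:3])
  # ratio convention with pseudocount rejects negative means
  expect_error(select_top_degs(c(-1, 1), c(1, 1)),
               class = "pertcycle_config_error")
})

make_eval_fixture <- function() {
  # two conditions, 3 cells each, 4 genes; controls at zero
  genes <- paste0("g", 1:4)
  ctrl <- matrix(0, 3, 4, dimnames = list(NULL, genes))
  a1 <- matrix(rep(c(2, 0, 0, 0), each = 3), 3, 4, dimnames = list(NULL, genes))
  a1[, 2] <- c(0.1, -0.1, 0)
  a2 <- matrix(rep(c(0, 0, 3, 0.5), each = 3), 3, 4, dimnames = list(NULL, genes))
  rec <- data.frame(
    sample_id = sprintf("s%d", 1:9),
    perturbation_id = c(rep("control", 3), rep("dA", 3), rep("dB", 3)),
    kind = c(rep("control", 3), rep("drug", 6)),
    smiles = c(rep(NA, 3), rep("C", 6)),
    context_id = "K562", stringsAsFactors = FALSE)
  list(actual = expression_dataset(rbind(ctrl, a1, a2), rec),
       rec = rec, genes = genes, a1 = a1, a2 = a2)
}

test_that("single-cell evaluation averages cells then scores mean profiles", {
  fx <- make_eval_fixture()
  # predictions identical to actual -> all metrics 1
  pred <- expression_dataset(fx$actual$matrix[4:9, ], fx$rec[4:9, ])
  rep1 <- evaluate_single_cell(pred, fx$actual, log_space = TRUE)
  expect_equal(rep1$per_condition$r2_all, c(1, 1))
  expect_equal(rep1$per_condition$ev_all, c(1, 1))
  # spreadsheet oracle for a perturbed prediction
  pm <- fx$actual$matrix[4:9, ]
  pm[1:3, 1] <- c(1.5, 2.1, 1.8)
  pred2 <- expression_dataset(pm, fx$rec[4:9, ])
  rep2 <- evaluate_single_cell(pred2, fx$actual, log_space = TRUE)
  am <- colMeans(fx$a1)
  pmm <- colMeans(pm[1:3, ])
  expect_equal(rep2$per_condition$r2_all[rep2$per_condition$perturbation_id == "dA"],
               1 - sum((am - pmm)^2) / sum((am - mean(am))^2), tolerance = 1e-12)
  # DEG subset for dA is gene 1 only (|fc|>=1): fewer than 2 DEGs -> NA
  expect_true(is.na(rep2$per_condition$r2_deg[
    rep2$per_condition$perturbation_id == "dA"]))
  # shuffling cell order leaves the report unchanged
  perm <- c(3, 1, 2, 6, 4, 5)
  pred3 <- expression_dataset(pm[perm, ], fx$rec[4:9, ][perm, ])
  rep3 <- evaluate_single_cell(pred3, fx$actual, log_space = TRUE)
  expect_equal(rep3$per_condition$r2_all, rep2$per_condition$r2_all)
  # a condition missing from one side is skipped with a warning
  expect_warning(evaluate_single_cell(
    expression_dataset(pm[1:3, , drop = FALSE], fx$rec[4:6, ]),
    fx$actual, log_space = TRUE), "skipped")
})

test_that("paired evaluation scores per sample without averaging", {
  fx <- make_eval_fixture()
  pm <- fx$actual$matrix[4:9, ] + matrix(rnorm(24, 0, 0.1), 6, 4)
  pred <- expression_dataset(pm, fx$rec[4:9, ])
  rep_ <- evaluate_paired(pred, fx$actual, log_space = TRUE)
  expect_equal(nrow(rep_$per_sample), 6L)
  i <- 2L  # second treated sample of dA
  expect_equal(rep_$per_sample$r2_all[i],
               r2_score(pm[i, ], fx$actual$matrix[4:9, ][i, ]))
  expect_equal(rep_$per_condition$r2_all[rep_$per_condition$perturbation_id == "dA"],
               mean(rep_$per_sample$r2_all[1:3]))
  expect_equal(rep_$summary$mean[rep_$summary$metric == "r2_all"],
               mean(rep_$per_condition$r2_all))
  # identical predictions give exactly 1 everywhere
  rep1 <- evaluate_paired(expression_dataset(fx$actual$matrix[4:9, ],
                                             fx$rec[4:9, ]),
                          fx$actual, log_space = TRUE)
  expect_equal(rep1$per_sample$r2_all, rep(1, 6))
  expect_equal(rep1$per_sample$ev_all, rep(1, 6))
})
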