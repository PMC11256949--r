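test_that("delimited round trip preserves values and records", {
  dir <- withr::local_tempdir()
  mat <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                dimnames = list(NULL, c("gA", "gB")))
  rec <- data.frame(sample_id = c("c1", "c2", "t1"),
                    perturbation_id = c("control", "control", "drugA"),
                    kind = c("control", "control", "drug"),
                    smiles = c(NA, NA, "CCO"),
                    stringsAsFactors = FALSE)
  path <- write_toy_delimited(dir, mat, rec)
  ds <- load_expression(path, "delimited")
  expect_identical(dim(ds$matrix), c(3L, 2L))
  expect_identical(colnames(ds$matrix), c("gA", "gB"))
  expect_identical(unname(ds$matrix), unname(mat))  # bitwise for integers
  expect_identical(ds$records$perturbation_id, rec$perturbation_id)
  expect_identical(ds$records$smiles, rec$smiles)
  expect_equal(sum(ds$records$kind == "drug"), 1L)

  # tab-separated autodetect
  tsv <- file.path(dir, "expr.tsv")
  tab <- utils::read.csv(path, check.names = FALSE)
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  ds2 <- load_expression(tsv, "delimited", metadata = file.path(dir, "expr_meta.csv"))
  expect_equal(ds2$matrix, ds$matrix)
})

test_that("mtx round trip places the listed nonzeros", {
  dir <- withr::local_tempdir()
  # hand-written triplet file: 4 genes x 3 cells, 5 nonzeros
  mtx <- file.path(dir, "m.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               "4 3 5",
               "1 1 2.5", "2 1 1", "3 2 7", "4 3 0.5", "1 3 3"), mtx)
  writeLines(sprintf("g%d", 1:4), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c2", "t1"), file.path(dir, "barcodes.tsv"))
  rec <- toy_records(c("control", "control", "drugA"),
                     kind = c("control", "control", "drug"))
  rec$sample_id <- c("c1", "c2", "t1")
  rec$smiles[3] <- "C"
  utils::write.csv(rec, file.path(dir, "m_meta.csv"), row.names = FALSE)
  ds <- load_expression(mtx, "mtx")
  expect_identical(dim(ds$matrix), c(3L, 4L))  # transposed to samples x genes
  expect_equal(sum(ds$matrix != 0), 5L)
  # densified oracle from the triplets
  dense <- matrix(0, 3, 4)
  trip <- rbind(c(1, 1, 2.5), c(2, 1, 1), c(3, 2, 7), c(4, 3, 0.5), c(1, 3, 3))
  for (r in seq_len(nrow(trip))) dense[trip[r, 2], trip[r, 1]] <- trip[r, 3]
  expect_equal(unname(ds$matrix), dense)

  # write_expression mtx path round-trips
  out <- file.path(dir, "sub", "w.mtx")
  dir.create(dirname(out))
  write_expression(ds, out, "mtx")
  ds2 <- load_expression(out, "mtx", metadata = file.path(dir, "sub", "w_meta.csv"))
  expect_equal(ds2$matrix, ds$matrix, tolerance = 1e-12)
})

test_that("structured errors: h5ad, missing metadata columns, non-numeric cells", {
  expect_error(load_expression("x.h5ad", "h5ad"), class = "pertcycle_format_error")
  dir <- withr::local_tempdir()
  mat <- matrix(1:4, 2, 2, dimnames = list(NULL, c("gA", "gB")))
  path <- write_toy_delimited(dir, mat, toy_records(c("control", "d1"),
                                                    c("control", "genetic")) |>
                                transform(target_gene = c(NA, "TP53")))
  # drop a required metadata column
  meta <- utils::read.csv(file.path(dir, "expr_meta.csv"))
  utils::write.csv(meta[setdiff(names(meta), "kind")],
                   file.path(dir, "expr_meta.csv"), row.names = FALSE)
  err <- tryCatch(load_expression(path, "delimited"), error = function(e) e)
  expect_s3_class(err, "pertcycle_metadata_error")
  expect_match(conditionMessage(err), "kind")
  # non-numeric entry is located
  lines <- readLines(path)
  lines[2] <- sub("^(s001,)[^,]*", "\\1oops", lines[2])
  writeLines(lines, path)
  utils::write.csv(meta, file.path(dir, "expr_meta.csv"), row.names = FALSE)
  err <- tryCatch(load_expression(path, "delimited"), error = function(e) e)
  expect_s3_class(err, "pertcycle_format_error")
  expect_match(conditionMessage(err), "row 1")
})

test_that("perturbation-level split partitions drugs and replicates controls", {
  set.seed(3)
  K <- 10L
  n_per <- 3L
  pids <- c(rep("control", 5), rep(sprintf("d%02d", 1:K), each = n_per))
  kinds <- ifelse(pids == "control", "control", "drug")
  rec <- toy_records(pids, kinds)
  rec$smiles[kinds == "drug"] <- "CC"
  ds <- expression_dataset(matrix(rnorm(length(pids) * 4), ncol = 4,
                                  dimnames = list(NULL, paste0("g", 1:4))), rec)
  sp <- split_spec(fractions = c(0.8, 0.1, 0.1), seed = 7L)
  out <- split_by_perturbation(ds, sp)
  drugs_in <- lapply(out, function(d)
    sort(unique(d$records$perturbation_id[d$records$kind != "control"])))
  expect_length(drugs_in$train, 8L)
  expect_length(drugs_in$validation, 1L)
  expect_length(drugs_in$test, 1L)
  # partition: no overlap, no loss
  expect_setequal(unlist(drugs_in), sprintf("d%02d", 1:K))
  expect_length(unlist(drugs_in), K)
  # controls replicated into every split
  for (d in out) expect_equal(sum(d$records$kind == "control"), 5L)
  # deterministic under the same seed
  out2 <- split_by_perturbation(ds, sp)
  expect_identical(lapply(out2, function(d) d$records$sample_id),
                   lapply(out, function(d) d$records$sample_id))
  # (1,0,0) puts everything in train
  all_train <- split_by_perturbation(ds, split_spec(fractions = c(1, 0, 0)))
  expect_length(unique(all_train$train$records$perturbation_id[
    all_train$train$records$kind != "control"]), K)
  expect_equal(sum(all_train$test$records$kind != "control"), 0L)
})

test_that("split assignment matches an independent shuffle-and-slice oracle", {
  K <- 5L
  pids <- c("control", rep(sprintf("d%d", 1:K), each = 2))
  rec <- toy_records(pids, ifelse(pids == "control", "control", "drug"))
  rec$smiles[rec$kind == "drug"] <- "C"
  ds <- expression_dataset(matrix(0, length(pids), 2,
                                  dimnames = list(NULL, c("a", "b"))), rec)
  seed <- 11L
  out <- split_by_perturbation(ds, split_spec(fractions = c(0.6, 0.2, 0.2),
                                              seed = seed))
  # oracle: shuffle the sorted drug list with the same seeded generator,
  # slice by rounded cumulative fractions
  shuffled <- withr::with_seed(seed, sample(sort(sprintf("d%d", 1:K))))
  cuts <- round(cumsum(c(0.6, 0.2, 0.2)) * K)
  oracle <- list(train = shuffled[1:cuts[1]],
                 validation = shuffled[(cuts[1] + 1):cuts[2]],
                 test = shuffled[(cuts[2] + 1):cuts[3]])
  got <- lapply(out, function(d)
    unique(d$records$perturbation_id[d$records$kind != "control"]))
  for (nm in names(oracle)) expect_setequal(got[[nm]], oracle[[nm]])
})

test_that("build_pairs: explicit pairing, unpaired pools, join errors", {
  mat <- matrix(rnorm(16), 4, 4, dimnames = list(NULL, paste0("g", 1:4)))
  rec <- toy_records(c("control", "control", "dA", "dA"),
                     c("control", "control", "drug", "drug"))
  rec$smiles[3:4] <- "CC"
  ds <- expression_dataset(mat, rec, pairing = c(`3` = 1L, `4` = 2L))
  p <- build_pairs(ds, "paired")
  expect_equal(nrow(p$x), 2L)
  expect_equal(unname(p$x), unname(mat[1:2, ]))
  expect_equal(unname(p$y), unname(mat[3:4, ]))
  u <- build_pairs(ds, "unpaired")
  expect_equal(nrow(u$controls), 2L)
  expect_equal(nrow(u$treated), 2L)
  expect_null(u$pairing)
  # context join with a context lacking controls names the context
  rec2 <- rec
  rec2$context_id <- c("lineA", "lineA", "lineA", "lineB")
  ds2 <- expression_dataset(mat, rec2)
  err <- tryCatch(build_pairs(ds2, "paired"), error = function(e) e)
  expect_s3_class(err, "pertcycle_pairing_error")
  expect_match(conditionMessage(err), "lineB")
  # context join averages the per-context controls
  ds3 <- expression_dataset(mat, transform(rec, context_id = "lineA"))
  p3 <- build_pairs(ds3, "paired")
  expect_equal(p3$x[1, ], colMeans(mat[1:2, ]), ignore_attr = TRUE)
  # orphan treated rows under explicit pairing
  ds4 <- expression_dataset(mat, rec, pairing = c(`3` = 1L))
  expect_error(build_pairs(ds4, "paired"), class = "pertcycle_pairing_error")
})
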