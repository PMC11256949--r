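# Expression datasets, perturbation metadata, format IO, perturbation-level
# splits and paired/unpaired assembly.

#' Construct an expression dataset
#'
#' The central data container: a samples x genes numeric matrix plus one
#' perturbation record per row.  Records are a data frame with columns
#' `sample_id`, `perturbation_id`, `kind` (one of `"drug"`, `"genetic"`,
#' `"control"`) and optionally `smiles`, `target_gene`, `dose`,
#' `context_id`.  Invariants enforced: record count equals row count, all
#' values finite, drugs carry SMILES, genetic perturbations carry a target
#' gene, controls carry neither.
#'
#' @param matrix numeric matrix, samples in rows, genes in columns; column
#'   names are gene identifiers.
#' @param records data frame of perturbation records aligned to rows.
#' @param pairing optional named integer vector mapping treated row indices
#'   (names) to control row indices (values).
#' @param graphs optional named list of [drug_graph()] objects keyed by
#'   `perturbation_id`, used when perturbations have no SMILES (e.g.
#'   synthetic drugs).
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(matrix, records, pairing = NULL, graphs = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) != nrow(matrix))
    pc_stop(sprintf("records rows (%d) do not match matrix rows (%d)",
                    nrow(records), nrow(matrix)), "pertcycle_shape_error")
  check_finite(matrix, "expression matrix")
  required <- c("sample_id", "perturbation_id", "kind")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    pc_stop(sprintf("perturbation metadata is missing column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "pertcycle_metadata_error", data = list(columns = missing_cols))
  bad <- setdiff(unique(records$kind), c("drug", "genetic", "control"))
  if (length(bad))
    pc_stop(sprintf("unknown perturbation kind(s): %s", paste(bad, collapse = ", ")),
            "pertcycle_metadata_error")
  for (opt in c("smiles", "target_gene", "context_id"))
    if (is.null(records[[opt]])) records[[opt]] <- NA_character_
  if (is.null(records[["dose"]])) records[["dose"]] <- NA_real_
  drug_no_smiles <- records$kind == "drug" & is.na(records$smiles)
  if (any(drug_no_smiles) &&
      !all(records$perturbation_id[drug_no_smiles] %in% names(graphs)))
    warning(paste("drug records without SMILES or attached graphs;",
                  "they must resolve through a model's graph library"))
  if (any(records$kind == "genetic" & is.na(records$target_gene)))
    pc_stop("genetic perturbation records must carry target_gene",
            "pertcycle_metadata_error")
  if (!is.null(pairing)) {
    pairing <- stats::setNames(as.integer(pairing), names(pairing))
    ctrl_rows <- which(records$kind == "control")
    if (!all(pairing %in% ctrl_rows))
      pc_stop("pairing values must index control rows", "pertcycle_pairing_error")
  }
  if (is.null(rownames(matrix))) rownames(matrix) <- records$sample_id
  structure(list(matrix = matrix, records = records, pairing = pairing,
                 graphs = graphs),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  k <- setdiff(unique(x$records$perturbation_id[x$records$kind != "control"]), NA)
  cat(sprintf("<expression_dataset> %d samples x %d genes, %d perturbations%s\n",
              nrow(x$matrix), ncol(x$matrix), length(k),
              if (!is.null(x$pairing)) sprintf(", %d pairs", length(x$pairing)) else ""))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

subset_dataset <- function(ds, rows) {
  rec <- ds$records[rows, , drop = FALSE]
  rownames(rec) <- NULL
  pairing <- NULL
  if (!is.null(ds$pairing)) {
    old2new <- stats::setNames(seq_along(rows), as.character(rows))
    keep <- names(ds$pairing)[as.integer(names(ds$pairing)) %in% rows &
                                ds$pairing %in% rows]
    if (length(keep)) {
      pairing <- stats::setNames(
        old2new[as.character(ds$pairing[keep])],
        old2new[keep])
    }
  }
  expression_dataset(ds$matrix[rows, , drop = FALSE], rec, pairing, ds$graphs)
}

# ---- IO --------------------------------------------------------------------

read_metadata_table <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "perturbation_id", "kind")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    pc_stop(sprintf("metadata file '%s' is missing column(s): %s", path,
                    paste(missing_cols, collapse = ", ")),
            "pertcycle_metadata_error", data = list(columns = missing_cols))
  for (col in c("smiles", "target_gene", "context_id"))
    if (!is.null(meta[[col]])) meta[[col]][meta[[col]] %in% c("", "NA")] <- NA
  meta
}

default_meta_path <- function(path) {
  sub("\\.([^.]+)$", "_meta.csv", path)
}

#' Load an expression dataset from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`delimited`}{comma-separated (tab autodetected) matrix with a
#'     header row of gene identifiers and a first `sample_id` column;
#'     perturbation metadata in a sidecar CSV (default `<stem>_meta.csv`).}
#'   \item{`mtx`}{MatrixMarket triplet file (genes x samples, the common
#'     single-cell convention) with sidecar `features.tsv` / `barcodes.tsv`
#'     next to it, plus the metadata CSV.}
#'   \item{`h5ad`}{not supported in this installation (no HDF5 reader is
#'     available offline); a structured error explains the conversion
#'     path.}
#' }
#' Gene order is preserved from the source.
#'
#' @param path path to the matrix file.
#' @param format one of `"delimited"`, `"mtx"`, `"h5ad"`.
#' @param metadata optional path to the perturbation metadata CSV.
#' @return an [expression_dataset()].
#' @export
load_expression <- function(path, format = c("delimited", "mtx", "h5ad"),
                            metadata = NULL) {
  format <- match.arg(format)
  if (format == "h5ad")
    pc_stop(paste0("h5ad input is not supported in this installation ",
                   "(no HDF5 reader available); export the AnnData object to ",
                   "MTX (adata.T via scipy.io.mmwrite + features/barcodes) or ",
                   "delimited CSV and use format='mtx'/'delimited'"),
            "pertcycle_format_error")
  if (!file.exists(path))
    pc_stop(sprintf("file not found: %s", path), "pertcycle_io_error")
  if (is.null(metadata)) metadata <- default_meta_path(path)
  if (!file.exists(metadata))
    pc_stop(sprintf("perturbation metadata file not found: %s", metadata),
            "pertcycle_metadata_error")
  meta <- read_metadata_table(metadata)

  if (format == "delimited") {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1L] != "sample_id")
      pc_stop("delimited matrix must have 'sample_id' as its first column",
              "pertcycle_format_error")
    sample_ids <- as.character(tab[[1L]])
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    if (!is.numeric(mat)) {
      bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))[1L]
      badrow <- which(is.na(suppressWarnings(as.numeric(tab[[bad + 1L]]))))[1L]
      pc_stop(sprintf("non-numeric expression value at row %d, column '%s'",
                      badrow, names(tab)[bad + 1L]), "pertcycle_format_error")
    }
    rownames(mat) <- sample_ids
  } else { # mtx
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    fpath <- file.path(dir, "features.tsv")
    bpath <- file.path(dir, "barcodes.tsv")
    for (p in c(fpath, bpath))
      if (!file.exists(p))
        pc_stop(sprintf("mtx sidecar file not found: %s", p), "pertcycle_io_error")
    genes <- readLines(fpath)
    cells <- readLines(bpath)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      pc_stop("mtx dimensions do not match features/barcodes sidecars",
              "pertcycle_format_error")
    mat <- t(as.matrix(m))
    dimnames(mat) <- list(cells, genes)
  }

  idx <- match(rownames(mat), meta$sample_id)
  if (anyNA(idx))
    pc_stop(sprintf("samples missing from metadata: %s",
                    paste(utils::head(rownames(mat)[is.na(idx)], 5L), collapse = ", ")),
            "pertcycle_metadata_error")
  expression_dataset(mat, meta[idx, , drop = FALSE])
}

#' Write an expression dataset to disk
#'
#' Inverse of [load_expression()] for the `delimited` and `mtx` formats;
#' always writes the perturbation metadata sidecar CSV.
#'
#' @inheritParams load_expression
#' @param ds an [expression_dataset()].
#' @return invisibly, the matrix path.
#' @export
write_expression <- function(ds, path, format = c("delimited", "mtx"),
                             metadata = NULL) {
  format <- match.arg(format)
  if (is.null(metadata)) metadata <- default_meta_path(path)
  cols <- c("sample_id", "perturbation_id", "kind", "smiles", "target_gene",
            "dose", "context_id")
  utils::write.csv(ds$records[, cols], metadata, row.names = FALSE, quote = TRUE)
  if (format == "delimited") {
    tab <- data.frame(sample_id = ds$records$sample_id, ds$matrix,
                      check.names = FALSE)
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(t(ds$matrix), sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(colnames(ds$matrix), file.path(dir, "features.tsv"))
    writeLines(ds$records$sample_id, file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

# ---- splitting -------------------------------------------------------------

#' Specification of a train/validation/test split
#'
#' @param level currently `"perturbation"`: all samples of a perturbation go
#'   to exactly one split, mirroring the unseen-drug evaluation protocol.
#' @param fractions numeric of length 3 (train, validation, test), sums to 1.
#' @param seed integer; the split is deterministic given the seed.
#' @export
split_spec <- function(level = "perturbation", fractions = c(0.8, 0.1, 0.1),
                       seed = 1L) {
  if (!isTRUE(all.equal(sum(fractions), 1, tolerance = 1e-9)) ||
      any(fractions < 0) || any(fractions > 1))
    pc_stop("split fractions must lie in [0,1] and sum to 1",
            "pertcycle_config_error")
  structure(list(level = level, fractions = fractions, seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a dataset at the perturbation level
#'
#' Every non-control `perturbation_id` is assigned to exactly one of the
#' train/validation/test outputs: the sorted perturbation list is shuffled
#' with the seeded generator and sliced by the cumulative fractions.
#' Control samples are replicated into every split — controls are model
#' inputs, never prediction targets.
#'
#' @param ds an [expression_dataset()].
#' @param spec a [split_spec()].
#' @return named list of three `expression_dataset`s: `train`,
#'   `validation`, `test`.
#' @export
split_by_perturbation <- function(ds, spec = split_spec()) {
  if (spec$level != "perturbation")
    pc_stop("only perturbation-level splits are implemented",
            "pertcycle_config_error")
  perts <- sort(unique(ds$records$perturbation_id[ds$records$kind != "control"]))
  K <- length(perts)
  if (K < 3L)
    pc_stop("need at least 3 distinct non-control perturbations to split",
            "pertcycle_config_error")
  cuts <- round(cumsum(spec$fractions) * K)
  sizes <- diff(c(0, cuts))
  if (any(sizes == 0 & spec$fractions > 0))
    pc_stop("too few perturbations to populate every nonzero split fraction",
            "pertcycle_config_error")
  shuffled <- with_seed(spec$seed, sample(perts))
  groups <- list(train = shuffled[seq_len(sizes[1])],
                 validation = if (sizes[2]) shuffled[sizes[1] + seq_len(sizes[2])] else character(),
                 test = if (sizes[3]) shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])] else character())
  lapply(groups, function(ids) {
    rows <- which(ds$records$kind == "control" |
                    ds$records$perturbation_id %in% ids)
    subset_dataset(ds, rows)
  })
}

# ---- pairing ---------------------------------------------------------------

#' Assemble a training-ready dataset
#'
#' In `paired` mode each treated sample is matched to a control sample
#' through the explicit pairing map or, failing that, a join on
#' `context_id` (each context's controls are averaged into one reference
#' profile).  In `unpaired` mode the dataset is split into two unaligned
#' pools and any pairing information is discarded.
#'
#' @param ds an [expression_dataset()].
#' @param mode `"paired"` or `"unpaired"`.
#' @return for `paired`: list with matrices `x` (matched controls), `y`
#'   (treated) and data frame `records` (treated records). For `unpaired`:
#'   list with `controls`, `treated` (matrices) and `control_records`,
#'   `treated_records`.  Both carry `graphs` through.
#' @export
build_pairs <- function(ds, mode = c("paired", "unpaired")) {
  mode <- match.arg(mode)
  is_ctrl <- ds$records$kind == "control"
  treated_rows <- which(!is_ctrl)
  if (mode == "unpaired") {
    return(list(mode = "unpaired",
                controls = ds$matrix[is_ctrl, , drop = FALSE],
                control_records = ds$records[is_ctrl, , drop = FALSE],
                treated = ds$matrix[treated_rows, , drop = FALSE],
                treated_records = ds$records[treated_rows, , drop = FALSE],
                graphs = ds$graphs))
  }
  if (!is.null(ds$pairing)) {
    have <- as.character(treated_rows) %in% names(ds$pairing)
    if (!all(have))
      pc_stop(sprintf("treated samples without a paired control: %s",
                      paste(utils::head(ds$records$sample_id[treated_rows[!have]], 5L),
                            collapse = ", ")),
              "pertcycle_pairing_error",
              data = list(orphans = ds$records$sample_id[treated_rows[!have]]))
    ctrl_idx <- ds$pairing[as.character(treated_rows)]
    x <- ds$matrix[ctrl_idx, , drop = FALSE]
  } else {
    ctx <- ds$records$context_id
    ctrl_by_ctx <- split(which(is_ctrl), ctx[is_ctrl])
    missing_ctx <- setdiff(unique(ctx[treated_rows]), names(ctrl_by_ctx))
    if (length(missing_ctx))
      pc_stop(sprintf("no control samples for context(s): %s",
                      paste(missing_ctx, collapse = ", ")),
              "pertcycle_pairing_error", data = list(contexts = missing_ctx))
    ref <- vapply(ctrl_by_ctx,
                  function(rows) colMeans(ds$matrix[rows, , drop = FALSE]),
                  numeric(ncol(ds$matrix)))
    x <- t(ref)[ctx[treated_rows], , drop = FALSE]
  }
  rec <- ds$records[treated_rows, , drop = FALSE]
  rownames(rec) <- NULL
  rownames(x) <- NULL
  list(mode = "paired", x = x,
       y = ds$matrix[treated_rows, , drop = FALSE],
       records = rec, graphs = ds$graphs)
}
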