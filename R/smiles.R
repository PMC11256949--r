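# Minimal SMILES -> molecular graph parser.  Covers the organic subset
# (B C N O P S F Cl Br I), aromatic lowercase atoms, bracket atoms with
# charges, branches, ring closures (including %nn) and explicit bonds.
# Hydrogens are implicit and never become nodes.  This is deliberately not
# a full cheminformatics engine: no valence checking, no stereochemistry.

ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")

#' Construct a molecular graph
#'
#' @param node_features numeric matrix, one row per atom.
#' @param edges two-column integer matrix of undirected bonds (1-based atom
#'   indices); zero-row matrix for a single atom.
#' @return object of class `drug_graph` with fields `node_features`,
#'   `edges`, `node_count`.
#' @export
drug_graph <- function(node_features, edges) {
  node_features <- as_row_matrix(node_features)
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2L)
  storage.mode(edges) <- "integer"
  n <- nrow(node_features)
  if (n < 1L) pc_stop("a drug graph needs at least one atom", "pertcycle_graph_error")
  if (nrow(edges) && (any(edges < 1L) || any(edges > n)))
    pc_stop("edge endpoints out of range", "pertcycle_graph_error")
  if (nrow(edges) && any(edges[, 1] == edges[, 2]))
    pc_stop("self-loop edges are not allowed (the self term is implicit)",
            "pertcycle_graph_error")
  # canonical undirected representation, duplicates removed
  if (nrow(edges)) {
    e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(e)
  }
  structure(list(node_features = node_features, edges = edges,
                 node_count = n),
            class = "drug_graph")
}

#' @export
print.drug_graph <- function(x, ...) {
  cat(sprintf("<drug_graph> %d atoms, %d bonds, %d features/atom\n",
              x$node_count, nrow(x$edges), ncol(x$node_features)))
  invisible(x)
}

# neighbor index list (excluding self)
graph_neighbors <- function(g) {
  nb <- vector("list", g$node_count)
  for (i in seq_len(g$node_count)) nb[[i]] <- integer()
  if (nrow(g$edges)) {
    for (r in seq_len(nrow(g$edges))) {
      a <- g$edges[r, 1]; b <- g$edges[r, 2]
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  lapply(nb, unique)
}

parse_smiles_atoms <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  i <- 1L; n <- length(chars)
  atoms <- list()      # list of (symbol, aromatic, charge)
  edges <- NULL
  prev_stack <- integer()  # branch stack
  prev <- 0L
  ring_open <- list()
  two_letter <- c("Cl", "Br")
  add_atom <- function(symbol, aromatic, charge) {
    atoms[[length(atoms) + 1L]] <<- list(symbol = symbol, aromatic = aromatic,
                                         charge = charge)
    idx <- length(atoms)
    if (prev > 0L) edges <<- rbind(edges, c(prev, idx))
    prev <<- idx
  }
  while (i <= n) {
    ch <- chars[i]
    nxt <- if (i < n) chars[i + 1L] else ""
    if (ch == "(") { prev_stack <- c(prev_stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(prev_stack))
        pc_stop(sprintf("unbalanced ')' in SMILES '%s'", smiles),
                "pertcycle_smiles_error", data = list(smiles = smiles))
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) { i <- i + 1L; next }
    if (ch == ".") { prev <- 0L; i <- i + 1L; next }
    if (grepl("[0-9]", ch) || ch == "%") {
      if (ch == "%") {
        if (i + 2L > n) pc_stop(sprintf("truncated ring closure in '%s'", smiles),
                                "pertcycle_smiles_error")
        key <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { key <- ch; i <- i + 1L }
      if (prev == 0L)
        pc_stop(sprintf("ring closure before any atom in '%s'", smiles),
                "pertcycle_smiles_error")
      if (!is.null(ring_open[[key]])) {
        edges <- rbind(edges, c(ring_open[[key]], prev))
        ring_open[[key]] <- NULL
      } else ring_open[[key]] <- prev
      next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) pc_stop(sprintf("unclosed '[' in SMILES '%s'", smiles),
                         "pertcycle_smiles_error", data = list(smiles = smiles))
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      sym <- regmatches(body, regexpr("^[0-9]*([A-Z][a-z]?|[a-z])", body))
      sym <- sub("^[0-9]+", "", sym)
      if (!length(sym) || !nzchar(sym))
        pc_stop(sprintf("cannot parse bracket atom '[%s]' in '%s'", body, smiles),
                "pertcycle_smiles_error", data = list(smiles = smiles))
      aromatic <- sym %in% letters
      charge <- 0
      if (grepl("\\+", body)) {
        d <- regmatches(body, regexpr("\\+[0-9]+", body))
        charge <- if (length(d)) as.numeric(sub("\\+", "", d))
                  else lengths(regmatches(body, gregexpr("\\+", body)))
      } else if (grepl("-", body)) {
        d <- regmatches(body, regexpr("-[0-9]+", body))
        charge <- if (length(d)) -as.numeric(sub("-", "", d))
                  else -lengths(regmatches(body, gregexpr("-", body)))
      }
      symU <- if (aromatic) paste0(toupper(substr(sym, 1, 1)),
                                   substring(sym, 2)) else sym
      if (symU != "H") add_atom(symU, aromatic, charge)
      i <- j + 1L; next
    }
    if (paste0(ch, nxt) %in% two_letter) {
      add_atom(paste0(ch, nxt), FALSE, 0); i <- i + 2L; next
    }
    if (grepl("[A-Z]", ch)) { add_atom(ch, FALSE, 0); i <- i + 1L; next }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE, 0); i <- i + 1L; next
    }
    pc_stop(sprintf("unparseable character '%s' at position %d of SMILES '%s'",
                    ch, i, smiles),
            "pertcycle_smiles_error", data = list(smiles = smiles))
  }
  if (length(prev_stack))
    pc_stop(sprintf("unbalanced '(' in SMILES '%s'", smiles),
            "pertcycle_smiles_error", data = list(smiles = smiles))
  if (length(ring_open))
    pc_stop(sprintf("unmatched ring closure(s) in SMILES '%s'", smiles),
            "pertcycle_smiles_error", data = list(smiles = smiles))
  if (!length(atoms))
    pc_stop(sprintf("SMILES '%s' contains no heavy atoms", smiles),
            "pertcycle_smiles_error", data = list(smiles = smiles))
  list(atoms = atoms, edges = edges)
}

#' Atom featurization used by [smiles_to_graph()]
#'
#' One-hot element over a capped vocabulary (C N O S P F Cl Br I, other),
#' concatenated with heavy-atom degree, an aromaticity flag and the formal
#' charge.
#'
#' @return the feature width (used to size the drug encoder input).
#' @export
atom_feature_dim <- function() length(ELEMENT_VOCAB) + 3L

#' Parse a SMILES string into a molecular graph
#'
#' One node per heavy atom, one undirected edge per bond; hydrogens are
#' implicit.  See [atom_feature_dim()] for the per-atom features.
#'
#' @param smiles a SMILES string.
#' @return a [drug_graph()].
#' @export
smiles_to_graph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    pc_stop("smiles must be a single non-empty string", "pertcycle_smiles_error")
  parsed <- parse_smiles_atoms(smiles)
  atoms <- parsed$atoms
  n <- length(atoms)
  edges <- if (is.null(parsed$edges)) matrix(integer(), 0L, 2L) else parsed$edges
  deg <- integer(n)
  if (nrow(edges)) {
    tab <- table(factor(c(edges[, 1], edges[, 2]), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  feats <- matrix(0, n, atom_feature_dim())
  for (k in seq_len(n)) {
    sym <- atoms[[k]]$symbol
    slot <- match(sym, ELEMENT_VOCAB, nomatch = length(ELEMENT_VOCAB))
    feats[k, slot] <- 1
    feats[k, length(ELEMENT_VOCAB) + 1L] <- deg[k]
    feats[k, length(ELEMENT_VOCAB) + 2L] <- as.numeric(atoms[[k]]$aromatic)
    feats[k, length(ELEMENT_VOCAB) + 3L] <- atoms[[k]]$charge
  }
  drug_graph(feats, edges)
}
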