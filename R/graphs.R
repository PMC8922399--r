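#' @title Molecular graphs
#' @description Converts molecules into attributed graphs: atoms are nodes
#'   carrying one-hot/flag feature vectors, bonds are stored as directed edge
#'   pairs carrying bond feature vectors. Stereochemistry (tetrahedral tags,
#'   double-bond E/Z) is encoded so that stereoisomers featurize differently.
#' @name graphs
NULL

#' Default declarative feature schema
#'
#' Atom blocks: element one-hot over a fixed vocabulary, degree one-hot
#' (0-5), formal charge one-hot (-1/0/+1/other), hybridization one-hot,
#' aromaticity flag, attached-hydrogen one-hot (0-4), tetrahedral chirality
#' tag one-hot. Bond blocks: bond-type one-hot, conjugation flag, ring
#' membership flag, E/Z stereo one-hot. The schema is data, not code: widths
#' are derived from the vocabularies, and a fingerprint string identifies it
#' in model checkpoints.
#'
#' @param elements Element vocabulary; anything else maps to the trailing
#'   "other" slot.
#' @return A `feature_schema` list with `atom_dim`, `bond_dim` and the block
#'   vocabularies.
#' @export
default_feature_schema <- function(elements = c("B", "C", "N", "O", "F", "Si",
                                                "P", "S", "Cl", "Br", "I")) {
  schema <- list(
    elements = elements,
    degrees = 0:5,
    charges = c(-1L, 0L, 1L),
    hybridizations = c("SP", "SP2", "SP3", "SP3D", "SP3D2"),
    num_hs = 0:4,
    chiral_tags = c("CW", "CCW"),
    bond_types = c("SINGLE", "DOUBLE", "TRIPLE", "AROMATIC"),
    bond_stereo = c("Z", "E")
  )
  # each one-hot block has a trailing "other/none" slot except pure flags
  schema$atom_dim <- (length(elements) + 1) + (length(schema$degrees) + 1) +
    (length(schema$charges) + 1) + (length(schema$hybridizations) + 1) +
    1 + (length(schema$num_hs) + 1) + (length(schema$chiral_tags) + 1)
  schema$bond_dim <- (length(schema$bond_types) + 1) + 1 + 1 +
    (length(schema$bond_stereo) + 1)
  class(schema) <- "feature_schema"
  schema
}

#' Stable identity string of a schema (stored in checkpoints)
#' @param schema A `feature_schema`.
#' @return Single character string.
#' @export
schema_id <- function(schema) {
  paste(
    paste(schema$elements, collapse = ","), paste(schema$degrees, collapse = ","),
    paste(schema$charges, collapse = ","),
    paste(schema$hybridizations, collapse = ","),
    paste(schema$num_hs, collapse = ","), paste(schema$chiral_tags, collapse = ","),
    paste(schema$bond_types, collapse = ","),
    paste(schema$bond_stereo, collapse = ","),
    sep = "|"
  )
}

one_hot <- function(value, vocab) {
  v <- numeric(length(vocab) + 1)
  idx <- match(value, vocab)
  v[if (is.na(idx)) length(vocab) + 1 else idx] <- 1
  v
}

atom_feature_vector <- function(atom, schema) {
  c(one_hot(atom$symbol, schema$elements),
    one_hot(atom$degree, schema$degrees),
    one_hot(atom$charge, schema$charges),
    one_hot(atom$hybridization, schema$hybridizations),
    as.numeric(isTRUE(atom$aromatic)),
    one_hot(atom$num_h, schema$num_hs),
    one_hot(atom$chiral, schema$chiral_tags))
}

bond_feature_vector <- function(bond, schema) {
  c(one_hot(bond$type, schema$bond_types),
    as.numeric(isTRUE(bond$conjugated)),
    as.numeric(isTRUE(bond$in_ring)),
    one_hot(bond$stereo, schema$bond_stereo))
}

perception_to_graph <- function(p, schema) {
  n <- p$n_atoms
  x <- t(vapply(p$atoms, atom_feature_vector, numeric(schema$atom_dim), schema = schema))
  if (n == 1) x <- matrix(x, nrow = 1)
  nb <- length(p$bonds)
  if (nb > 0) {
    ef1 <- t(vapply(p$bonds, bond_feature_vector, numeric(schema$bond_dim), schema = schema))
    if (nb == 1) ef1 <- matrix(ef1, nrow = 1)
    a <- vapply(p$bonds, function(b) b$begin + 1L, 1L)
    b <- vapply(p$bonds, function(b) b$end + 1L, 1L)
    edge_src <- c(a, b)
    edge_dst <- c(b, a)
    efeat <- rbind(ef1, ef1)
  } else {
    edge_src <- integer(0)
    edge_dst <- integer(0)
    efeat <- matrix(0, nrow = 0, ncol = schema$bond_dim)
  }
  g <- list(n_atoms = n, atom_features = x, edge_src = as.integer(edge_src),
            edge_dst = as.integer(edge_dst), bond_features = efeat,
            neighbor_sets = split(as.integer(edge_src), factor(edge_dst, levels = seq_len(n))),
            schema_id = schema_id(schema))
  class(g) <- "molecular_graph"
  g
}

#' Convert SMILES to molecular graphs
#'
#' Hydrogens stay implicit (an attached-H count feature); each bond is stored
#' as two directed edges. Atoms without neighbors (single-heavy-atom
#' molecules) keep an empty neighbor set here; the network gives them a
#' zero-bond self-message at forward time so they remain scorable.
#'
#' @param smiles Character vector (use one call for many molecules; chemistry
#'   perception is batched).
#' @param schema Feature schema from [default_feature_schema()].
#' @return For length-1 input a `molecular_graph`; otherwise a list of them.
#' @export
mol_to_graph <- function(smiles, schema = default_feature_schema()) {
  percept <- chem_perceive(smiles)
  graphs <- lapply(percept, perception_to_graph, schema = schema)
  if (length(smiles) == 1) graphs[[1]] else graphs
}

#' Batch molecular graphs into one disjoint union
#'
#' @param graphs List of `molecular_graph` objects sharing one schema.
#' @return A `graph_batch`: stacked atom features `x`, shifted directed edges,
#'   stacked bond features, `mol_index` (atom -> molecule), `n_atoms`.
#' @export
batch_graphs <- function(graphs) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  stopifnot(length(graphs) >= 1)
  sid <- unique(vapply(graphs, function(g) g$schema_id, ""))
  if (length(sid) != 1) stop("graphs use different feature schemas")
  n_atoms <- vapply(graphs, function(g) g$n_atoms, 1L)
  offset <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  b <- list(
    x = do.call(rbind, lapply(graphs, function(g) g$atom_features)),
    edge_src = unlist(Map(function(g, o) g$edge_src + o, graphs, offset)),
    edge_dst = unlist(Map(function(g, o) g$edge_dst + o, graphs, offset)),
    efeat = do.call(rbind, lapply(graphs, function(g) g$bond_features)),
    mol_index = rep(seq_along(graphs), times = n_atoms),
    n_atoms = n_atoms,
    schema_id = sid
  )
  class(b) <- "graph_batch"
  b
}

#' Split a batch back into individual graphs
#' @param batch A `graph_batch`.
#' @return List of `molecular_graph` objects in the original order.
#' @export
unbatch_graphs <- function(batch) {
  stopifnot(inherits(batch, "graph_batch"))
  offset <- cumsum(c(0L, batch$n_atoms[-length(batch$n_atoms)]))
  lapply(seq_along(batch$n_atoms), function(m) {
    atoms <- which(batch$mol_index == m)
    sel <- batch$edge_dst %in% atoms
    src <- batch$edge_src[sel] - offset[m]
    dst <- batch$edge_dst[sel] - offset[m]
    n <- batch$n_atoms[m]
    # drop self-loop padding rows from the stored bond features? they are part
    # of the graph representation, so keep them: unbatch is an exact inverse.
    g <- list(n_atoms = n,
              atom_features = batch$x[atoms, , drop = FALSE],
              edge_src = as.integer(src), edge_dst = as.integer(dst),
              bond_features = batch$efeat[sel, , drop = FALSE],
              neighbor_sets = split(as.integer(src), factor(dst, levels = seq_len(n))),
              schema_id = batch$schema_id)
    class(g) <- "molecular_graph"
    g
  })
}
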