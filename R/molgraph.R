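# Molecular graph construction: SMILES -> (atom features, bond features,
# connectivity), the three-matrix representation consumed by the
# convolutional fingerprint.

ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "other")
DEGREE_LEVELS <- 0:5
NUMH_LEVELS <- 0:4
BOND_ORDERS <- c("single", "double", "triple", "aromatic")

#' Atom feature dimensionality shared by all molecules
#' @return integer scalar.
#' @export
atom_feature_dim <- function() {
  length(ELEMENT_VOCAB) + length(DEGREE_LEVELS) + length(NUMH_LEVELS) + 2L
}

#' Bond feature dimensionality shared by all molecules
#' @return integer scalar.
#' @export
bond_feature_dim <- function() length(BOND_ORDERS) + 2L

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  idx <- match(value, levels)
  v[idx] <- 1
  v
}

#' Featurize a single atom
#'
#' Fixed-length concatenation of one-hot blocks and flags:
#' element over \{C, N, O, S, P, F, Cl, Br, I, other\} (elements outside the
#' vocabulary map to the reserved `other` slot), heavy-atom degree 0-5,
#' attached hydrogens 0-4 (both clamped at the top level), a signed formal
#' charge scalar, and an aromaticity flag. Hydrogens are implicit: they
#' contribute to the H-count feature but are never graph nodes.
#'
#' @param element element symbol, e.g. `"C"` or `"Cl"`.
#' @param degree number of heavy-atom neighbours.
#' @param n_h number of attached hydrogens.
#' @param charge integer formal charge.
#' @param aromatic logical aromaticity flag.
#' @return numeric vector of length [atom_feature_dim()].
#' @export
atom_feature_vector <- function(element, degree, n_h, charge, aromatic) {
  if (!element %in% ELEMENT_VOCAB) element <- "other"
  c(one_hot(element, ELEMENT_VOCAB),
    one_hot(min(degree, max(DEGREE_LEVELS)), DEGREE_LEVELS),
    one_hot(min(n_h, max(NUMH_LEVELS)), NUMH_LEVELS),
    as.numeric(charge),
    as.numeric(aromatic))
}

#' Featurize a single bond
#'
#' One-hot bond order over \{single, double, triple, aromatic\} plus
#' conjugation and ring-membership flags. Bond features are undirected:
#' both endpoints see the same vector.
#'
#' @param order one of `"single"`, `"double"`, `"triple"`, `"aromatic"`.
#' @param conjugated logical conjugation flag.
#' @param in_ring logical ring-membership flag.
#' @return numeric vector of length [bond_feature_dim()].
#' @export
bond_feature_vector <- function(order, conjugated, in_ring) {
  if (!order %in% BOND_ORDERS) {
    stop("unknown bond order: ", order, call. = FALSE)
  }
  c(one_hot(order, BOND_ORDERS), as.numeric(conjugated), as.numeric(in_ring))
}

build_molgraph <- function(rec, source_smiles) {
  n_atoms <- length(rec$atoms)
  atom_features <- matrix(0, n_atoms, atom_feature_dim())
  for (i in seq_len(n_atoms)) {
    a <- rec$atoms[[i]]
    atom_features[i, ] <- atom_feature_vector(
      element = a[[1]], degree = a[[2]], n_h = a[[3]],
      charge = a[[4]], aromatic = a[[5]] == 1)
  }
  n_bonds <- length(rec$bonds)
  bond_features <- matrix(0, n_bonds, bond_feature_dim())
  neighbors <- rep(list(integer(0)), n_atoms)
  bond_index <- rep(list(integer(0)), n_atoms)
  for (b in seq_len(n_bonds)) {
    bd <- rec$bonds[[b]]
    i <- bd[[1]] + 1L
    j <- bd[[2]] + 1L
    bond_features[b, ] <- bond_feature_vector(
      order = bd[[3]], conjugated = bd[[4]] == 1, in_ring = bd[[5]] == 1)
    neighbors[[i]] <- c(neighbors[[i]], j)
    neighbors[[j]] <- c(neighbors[[j]], i)
    bond_index[[i]] <- c(bond_index[[i]], b)
    bond_index[[j]] <- c(bond_index[[j]], b)
  }
  g <- structure(
    list(atom_features = atom_features,
         bond_features = bond_features,
         neighbors = neighbors,
         bond_index = bond_index,
         n_atoms = n_atoms,
         n_bonds = n_bonds,
         smiles = rec$canonical,
         source_smiles = source_smiles),
    class = "molgraph")
  add_graph_caches(g)
}

# Precompute the directed edge list and the per-atom sum of incident bond
# features; both are consumed by the batched fingerprint engine.
add_graph_caches <- function(g) {
  deg <- lengths(g$neighbors)
  g$edges <- cbind(from = rep(seq_len(g$n_atoms), deg),
                   to = unlist(g$neighbors, use.names = FALSE))
  nbf <- matrix(0, g$n_atoms, ncol(g$bond_features))
  for (a in which(deg > 0L)) {
    nbf[a, ] <- colSums(g$bond_features[g$bond_index[[a]], , drop = FALSE])
  }
  g$nbf <- nbf
  g
}

#' Convert SMILES to molecular graphs
#'
#' Parses each SMILES with RDKit (one subprocess for the whole batch),
#' canonicalizes it so different spellings of a molecule collapse to one
#' deterministic atom order, and assembles the three-matrix graph: an
#' atom-feature matrix, a bond-feature matrix, and per-atom adjacency lists
#' of (neighbour index, bond index) pairs. Heavy atoms only; hydrogens are
#' implicit features.
#'
#' @param smiles character vector of SMILES strings.
#' @return A list of `molgraph` objects.
#' @seealso [smiles_to_graph()] for the single-molecule form.
#' @export
smiles_to_graphs <- function(smiles) {
  recs <- graph_records(smiles)
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    rec <- recs[[i]]
    if (!is.null(rec$error)) {
      stop("cannot parse SMILES '", smiles[i], "': ", rec$error,
           call. = FALSE)
    }
    out[[i]] <- build_molgraph(rec, smiles[i])
  }
  out
}

#' @rdname smiles_to_graphs
#' @export
smiles_to_graph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  smiles_to_graphs(smiles)[[1]]
}

#' Validate a batch of SMILES without raising on failures
#'
#' @param smiles character vector.
#' @return A data.frame with columns `smiles`, `canonical` (NA on failure)
#'   and `error` (NA on success).
#' @keywords internal
#' @export
validate_smiles <- function(smiles) {
  recs <- graph_records(smiles)
  data.frame(
    smiles = smiles,
    canonical = vapply(recs, function(r)
      if (is.null(r$error)) r$canonical else NA_character_, character(1)),
    error = vapply(recs, function(r)
      if (is.null(r$error)) NA_character_ else r$error, character(1)),
    stringsAsFactors = FALSE)
}

#' Relabel the atoms of a molecular graph
#'
#' Applies a permutation to the atom order (and reshuffles the bond list),
#' producing an isomorphic graph. Used to verify that graph-level
#' featurization and the neural fingerprint are invariant to atom input
#' order.
#'
#' @param graph a `molgraph`.
#' @param perm integer permutation of `seq_len(graph$n_atoms)`;
#'   `perm[old_index] = new_index`.
#' @param bond_perm optional permutation of the bond order.
#' @return A `molgraph` with permuted rows and relabelled indices.
#' @export
permute_graph <- function(graph, perm, bond_perm = NULL) {
  stopifnot(inherits(graph, "molgraph"),
            length(perm) == graph$n_atoms,
            all(sort(perm) == seq_len(graph$n_atoms)))
  if (is.null(bond_perm)) bond_perm <- seq_len(graph$n_bonds)
  stopifnot(all(sort(bond_perm) == seq_len(graph$n_bonds)))
  inv <- order(perm)
  inv_bond <- order(bond_perm)
  g <- graph
  g$atom_features <- graph$atom_features[inv, , drop = FALSE]
  g$bond_features <- graph$bond_features[inv_bond, , drop = FALSE]
  g$neighbors <- lapply(inv, function(old) unname(perm[graph$neighbors[[old]]]))
  g$bond_index <- lapply(inv, function(old) unname(bond_perm[graph$bond_index[[old]]]))
  add_graph_caches(g)
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$smiles, "\n", sep = "")
  cat("  atoms: ", x$n_atoms, "  bonds: ", x$n_bonds,
      "  d_atom: ", ncol(x$atom_features),
      "  d_bond: ", ncol(x$bond_features), "\n", sep = "")
  invisible(x)
}
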