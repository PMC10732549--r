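#' @importFrom stats cmdscale cor optim rnorm runif setNames quantile sd
#' @importFrom utils head read.delim write.table
NULL

# Atomic masses (unified amu) for the elements the parsers accept.
ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.065,
  Cl = 35.453, K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38,
  Se = 78.971, Br = 79.904, I = 126.904
)

BOND_ORDERS <- c("1", "2", "3", "ar")

#' Construct a molecular graph
#'
#' The central container of the package: an ordered atom table, an ordered
#' bond table, and zero or more 3D conformers. Ring perception (an atom/bond
#' is "in a ring" iff it lies on some cycle) is run at construction time.
#'
#' @param mol_id identifier for the molecule.
#' @param atoms data.frame with columns `element` (symbol), `aromatic`
#'   (logical), `charge` (integer formal charge), `n_h` (attached hydrogen
#'   count, implicit or explicit-collapsed).
#' @param bonds data.frame with columns `atom_i`, `atom_j` (1-based atom
#'   indices) and `order` (one of `"1"`, `"2"`, `"3"`, `"ar"`).
#' @param conformers list of conformers, each `list(coords = <N x 3 matrix>,
#'   seed = <integer>)`.
#' @param source_format one of `"smiles"`, `"sdf"`, `"mol2"`.
#' @return an object of class `mol_graph` with ring flags (`in_ring`) set on
#'   atoms and bonds, per-atom masses and bond counts, and a `rotatable`
#'   column on bonds (all `NA` until [label_rotatable()] is applied).
#' @export
molecule_graph <- function(mol_id, atoms, bonds,
                           conformers = list(), source_format = "smiles") {
  n <- nrow(atoms)
  if (n < 1L) stopf("molecule '%s' has no atoms", mol_id)
  atoms$element <- as.character(atoms$element)
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$n_h)) atoms$n_h <- 0L
  atoms$mass <- unname(ATOMIC_MASS[atoms$element])
  atoms$mass[is.na(atoms$mass)] <- 0
  if (nrow(bonds) > 0L) {
    bonds$order <- as.character(bonds$order)
    bad <- !bonds$order %in% BOND_ORDERS
    if (any(bad)) stopf("molecule '%s': invalid bond order '%s'",
                        mol_id, bonds$order[which(bad)[1L]])
    if (any(bonds$atom_i < 1L | bonds$atom_i > n |
            bonds$atom_j < 1L | bonds$atom_j > n))
      stopf("molecule '%s': bond references atom out of range", mol_id)
    if (any(bonds$atom_i == bonds$atom_j))
      stopf("molecule '%s': self-bond", mol_id)
    key <- paste(pmin(bonds$atom_i, bonds$atom_j),
                 pmax(bonds$atom_i, bonds$atom_j))
    if (anyDuplicated(key)) stopf("molecule '%s': duplicate bond", mol_id)
  } else {
    bonds <- data.frame(atom_i = integer(), atom_j = integer(),
                        order = character(), stringsAsFactors = FALSE)
  }
  mol <- structure(
    list(mol_id = as.character(mol_id), atoms = atoms, bonds = bonds,
         conformers = conformers, source_format = source_format),
    class = "mol_graph")
  mol <- perceive_rings(mol)
  mol$atoms$n_bonds <- atom_degrees(mol)
  # an aromatic bond outside any ring is chemically impossible; demote
  if (nrow(mol$bonds) > 0L) {
    fix <- mol$bonds$order == "ar" & !mol$bonds$in_ring
    mol$bonds$order[fix] <- "1"
  }
  mol$bonds$rotatable <- rep(NA, nrow(mol$bonds))
  mol
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %s: %d atoms, %d bonds, %d conformer(s) [%s]\n",
              x$mol_id, nrow(x$atoms), nrow(x$bonds),
              length(x$conformers), x$source_format))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `mol_graph`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

atom_degrees <- function(mol) {
  deg <- integer(n_atoms(mol))
  if (nrow(mol$bonds) > 0L) {
    t1 <- tabulate(mol$bonds$atom_i, nbins = n_atoms(mol))
    t2 <- tabulate(mol$bonds$atom_j, nbins = n_atoms(mol))
    deg <- t1 + t2
  }
  deg
}

# igraph view of the bond graph (isolated atoms kept as vertices)
mol_igraph <- function(mol, bonds = mol$bonds) {
  igraph::graph_from_data_frame(
    d = data.frame(from = bonds$atom_i, to = bonds$atom_j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
}

# A bond is in a ring iff it is not a bridge; an atom is in a ring iff it is
# incident to a ring bond.
perceive_rings <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) {
    mol$bonds$in_ring <- logical(0)
    mol$atoms$in_ring <- rep(FALSE, n_atoms(mol))
    return(mol)
  }
  g <- mol_igraph(mol)
  br <- as.integer(igraph::bridges(g))
  in_ring <- rep(TRUE, nb)
  in_ring[br] <- FALSE
  mol$bonds$in_ring <- in_ring
  atom_ring <- rep(FALSE, n_atoms(mol))
  atom_ring[c(mol$bonds$atom_i[in_ring], mol$bonds$atom_j[in_ring])] <- TRUE
  mol$atoms$in_ring <- atom_ring
  mol
}

# adjacency list: for each atom, data of its incident bonds
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(), bond = integer())
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$atom_i[k]; j <- b$atom_j[k]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$bond <- c(adj[[i]]$bond, k)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$bond <- c(adj[[j]]$bond, k)
  }
  adj
}

# Smallest rings: for each ring bond, the shortest cycle through it
# (BFS in the graph minus that bond). Unique atom sets are returned.
# Used for aromatic pharmacophore features; not a full SSSR engine.
smallest_rings <- function(mol) {
  b <- mol$bonds
  ring_bonds <- which(b$in_ring)
  if (length(ring_bonds) == 0L) return(list())
  g <- mol_igraph(mol)
  rings <- list()
  seen <- character()
  for (k in ring_bonds) {
    g2 <- igraph::delete_edges(g, k)
    sp <- igraph::shortest_paths(g2, from = b$atom_i[k], to = b$atom_j[k],
                                 output = "vpath")$vpath[[1L]]
    cyc <- as.integer(igraph::as_ids(sp))
    if (length(cyc) < 3L) next
    key <- paste(sort(cyc), collapse = ",")
    if (!key %in% seen) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- cyc
    }
  }
  rings
}

# connected components of the subgraph restricted to given bond rows;
# returns integer membership vector over atoms
bond_subgraph_components <- function(mol, bond_rows) {
  g <- mol_igraph(mol, bonds = mol$bonds[bond_rows, , drop = FALSE])
  as.integer(igraph::components(g)$membership)
}

bond_order_numeric <- function(order) {
  v <- c(`1` = 1, `2` = 2, `3` = 3, ar = 1.5)
  unname(v[order])
}
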