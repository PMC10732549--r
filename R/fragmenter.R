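# Rotatable-bond fragmentation.
#
# Bonds in rings and bonds of order 2, 3 or aromatic are non-rotatable (and,
# by default, bonds to hydrogen so explicit-H inputs fragment like their
# implicit-H SMILES counterparts); every other bond is rotatable. Fragments
# are the connected components of the graph restricted to non-rotatable
# bonds; the rotatable bonds between components are the cut bonds. No
# chemistry-aware exceptions (e.g. amide) are made: a strict reading of the
# two stated rules.

#' Label bonds rotatable / non-rotatable
#'
#' @param mol a `mol_graph` (ring perception is done at load time).
#' @param h_bonds_rigid treat bonds to hydrogen atoms as non-rotatable
#'   (default TRUE; rotating a terminal H is meaningless).
#' @return `mol` with the `rotatable` bond column filled:
#'   `rotatable = FALSE` iff the bond is in a ring, has order 2/3/aromatic,
#'   or (by default) touches an explicit hydrogen.
#' @export
label_rotatable <- function(mol, h_bonds_rigid = TRUE) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(mol)
  rigid <- b$in_ring | b$order %in% c("2", "3", "ar")
  if (h_bonds_rigid) {
    h <- mol$atoms$element == "H"
    rigid <- rigid | h[b$atom_i] | h[b$atom_j]
  }
  mol$bonds$rotatable <- !rigid
  mol
}

#' Partition a molecule into rigid fragments
#'
#' Iteratively merging atom clusters across non-rotatable bonds is
#' equivalent to taking connected components of the non-rotatable subgraph,
#' which is how it is computed here.
#'
#' @param mol a `mol_graph`; rotatable labels are computed if absent.
#' @param ... passed to [label_rotatable()].
#' @return a `fragment_partition`: `mol_id`, `clusters` (list of atom index
#'   vectors, disjoint and covering all atoms), `cut_bonds` (bond row
#'   indices of rotatable bonds joining different clusters), and
#'   `membership` (atom -> cluster index).
#' @export
fragment_molecule <- function(mol, ...) {
  if (anyNA(mol$bonds$rotatable)) mol <- label_rotatable(mol, ...)
  rigid_rows <- which(!mol$bonds$rotatable)
  memb <- if (nrow(mol$bonds) == 0L) seq_len(n_atoms(mol))
          else bond_subgraph_components(mol, rigid_rows)
  memb <- match(memb, unique(memb))  # renumber in first-atom order
  clusters <- split(seq_len(n_atoms(mol)), memb)
  names(clusters) <- NULL
  cut <- which(mol$bonds$rotatable &
                 memb[mol$bonds$atom_i] != memb[mol$bonds$atom_j])
  stopifnot(sum(lengths(clusters)) == n_atoms(mol),
            !anyDuplicated(unlist(clusters)))
  structure(list(mol_id = mol$mol_id, clusters = clusters,
                 cut_bonds = cut, membership = memb, mol = mol),
            class = "fragment_partition")
}

#' @export
print.fragment_partition <- function(x, ...) {
  cat(sprintf("<fragment_partition> %s: %d fragments, %d cut bonds\n",
              x$mol_id, length(x$clusters), length(x$cut_bonds)))
  invisible(x)
}

#' Canonical key of a fragment (an atom cluster)
#'
#' Cross-molecule fragment identity for frequency ranking. The key is a
#' deterministic canonical form of the cluster subgraph: three rounds of
#' Morgan-style neighbourhood refinement over (element, aromatic, ring-flag)
#' labels, then the sorted refined atom labels plus the sorted edge
#' descriptors.
#'
#' @param mol a `mol_graph`.
#' @param atoms atom indices of one cluster.
#' @return a single string key.
#' @export
fragment_key <- function(mol, atoms) {
  at <- mol$atoms
  lab <- paste0(at$element[atoms],
                ifelse(at$aromatic[atoms], "a", ""),
                ifelse(at$in_ring[atoms], "R", ""))
  sub <- mol$bonds[mol$bonds$atom_i %in% atoms & mol$bonds$atom_j %in% atoms, ,
                   drop = FALSE]
  loc <- function(v) match(v, atoms)
  for (round in 1:3) {
    nxt <- lab
    for (q in seq_along(atoms)) {
      i <- atoms[q]
      inc <- which(sub$atom_i == i | sub$atom_j == i)
      nb <- ifelse(sub$atom_i[inc] == i, sub$atom_j[inc], sub$atom_i[inc])
      token <- sort(paste0(sub$order[inc], lab[loc(nb)]))
      nxt[q] <- paste0(lab[q], "(", paste(token, collapse = ","), ")")
    }
    lab <- nxt
  }
  edge_desc <- character(nrow(sub))
  for (k in seq_len(nrow(sub))) {
    e <- sort(c(lab[loc(sub$atom_i[k])], lab[loc(sub$atom_j[k])]))
    edge_desc[k] <- paste(e[1L], sub$order[k], e[2L])
  }
  paste(paste(sort(lab), collapse = "+"),
        paste(sort(edge_desc), collapse = ";"), sep = "//")
}

#' Fragment frequency ranking over a compound pool
#'
#' Fragments every molecule, canonicalizes each cluster, counts occurrences
#' across the pool, and ranks by frequency (Zipf order).
#'
#' @param pool nonempty list of `mol_graph`.
#' @param ... passed to [fragment_molecule()].
#' @return data.frame `fragment_key`, `example` (human-readable element
#'   multiset), `count`, `rank` (1-based, ties broken by descriptor order).
#' @export
fragment_frequencies <- function(pool, ...) {
  if (length(pool) == 0L) stopf("empty compound pool")
  keys <- character(); ex <- character()
  for (mol in pool) {
    part <- fragment_molecule(mol, ...)
    for (cl in part$clusters) {
      keys <- c(keys, fragment_key(mol, cl))
      ex <- c(ex, paste(sort(mol$atoms$element[cl]), collapse = ""))
    }
  }
  tab <- table(keys)
  df <- data.frame(fragment_key = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df$example <- ex[match(df$fragment_key, keys)]
  df <- df[order(-df$count, df$fragment_key), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("fragment_key", "example", "count", "rank")]
}
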