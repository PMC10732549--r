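# Inputs to the compound-protein interaction network.
#
# Proteins: per-residue BLOSUM62 substitution profile (20 standard columns,
# zeros for non-standard residues) concatenated with sinusoidal positional
# encoding. Compounds: per-atom concatenated one-hot features plus a
# bond-order-weighted adjacency matrix and a fragment membership map; no
# positional channels (fragment order is arbitrary).

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
ELEMENT_VOCAB <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")  # + "other"
MAX_NBONDS <- 6L

blosum62_rows <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA20, AA20]
    }
    cache
  }
})

#' Encode a protein sequence for the interaction network
#'
#' @param seq a `protein_seq` or plain amino-acid string.
#' @param d_pe number of sinusoidal positional-encoding channels (default 8,
#'   must be even).
#' @return L x (20 + d_pe) numeric matrix; row i holds the BLOSUM62 row of
#'   residue i (all-zero for non-standard symbols) followed by the
#'   positional encoding of position i.
#' @export
encode_protein <- function(seq, d_pe = 8L) {
  if (inherits(seq, "protein_seq")) seq <- seq$sequence
  if (!is.character(seq) || nchar(seq) < 1L) stopf("empty protein sequence")
  if (d_pe %% 2L != 0L) stopf("d_pe must be even")
  aa <- strsplit(toupper(seq), "")[[1L]]
  L <- length(aa)
  B <- blosum62_rows()
  sub <- matrix(0, L, 20L)
  hit <- aa %in% AA20
  sub[hit, ] <- B[aa[hit], , drop = FALSE]
  pe <- matrix(0, L, d_pe)
  pos <- seq_len(L)
  for (k in seq_len(d_pe / 2L)) {
    freq <- 1 / 10000^((2 * (k - 1)) / d_pe)
    pe[, 2L * k - 1L] <- sin(pos * freq)
    pe[, 2L * k] <- cos(pos * freq)
  }
  cbind(sub, pe)
}

#' Encode a compound graph for the interaction network
#'
#' @param mol a `mol_graph`.
#' @param partition matching [fragment_molecule()] output (computed if
#'   missing).
#' @return list with `atom_features` (N x 22: one-hot element with an
#'   "other" slot, one-hot capped bond count, one-hot max incident bond
#'   order, mass/100, formal charge), `adj` (N x N bond-order-weighted
#'   adjacency), `frag_map` (F x N row-normalized membership matrix), and
#'   `membership` (atom -> fragment index).
#' @export
encode_compound <- function(mol, partition = NULL) {
  if (is.null(partition)) partition <- fragment_molecule(mol)
  if (!identical(partition$mol_id, mol$mol_id) ||
      length(partition$membership) != n_atoms(mol))
    stopf("fragment partition does not match molecule '%s'", mol$mol_id)
  n <- n_atoms(mol)
  at <- mol$atoms
  elem_idx <- match(at$element, ELEMENT_VOCAB)
  elem_idx[is.na(elem_idx)] <- length(ELEMENT_VOCAB) + 1L
  E <- matrix(0, n, length(ELEMENT_VOCAB) + 1L)
  E[cbind(seq_len(n), elem_idx)] <- 1
  nb <- pmin(pmax(at$n_bonds, 1L), MAX_NBONDS)
  NB <- matrix(0, n, MAX_NBONDS)
  NB[cbind(seq_len(n), nb)] <- 1
  # max incident bond order, one-hot over 1/2/3/ar (isolated atoms: order 1)
  ordlev <- c("1", "2", "3", "ar")
  maxord <- rep(1L, n)
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    o <- match(b$order[k], ordlev)
    maxord[b$atom_i[k]] <- max(maxord[b$atom_i[k]], o)
    maxord[b$atom_j[k]] <- max(maxord[b$atom_j[k]], o)
  }
  BO <- matrix(0, n, 4L)
  BO[cbind(seq_len(n), maxord)] <- 1
  X <- cbind(E, NB, BO, at$mass / 100, at$charge)
  adj <- matrix(0, n, n)
  if (nrow(b) > 0L) {
    w <- bond_order_numeric(b$order)
    adj[cbind(b$atom_i, b$atom_j)] <- w
    adj[cbind(b$atom_j, b$atom_i)] <- w
  }
  f <- length(partition$clusters)
  Fm <- matrix(0, f, n)
  for (q in seq_len(f)) {
    cl <- partition$clusters[[q]]
    Fm[q, cl] <- 1 / length(cl)
  }
  list(atom_features = X, adj = adj, frag_map = Fm,
       membership = partition$membership)
}

#' Width of the atom feature vector
#' @return integer, fixed across a run.
#' @export
atom_feature_width <- function() length(ELEMENT_VOCAB) + 1L + MAX_NBONDS + 4L + 2L
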