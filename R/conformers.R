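# Conformer generation: seeded distance-geometry embedding.
#
# Target inter-atomic distances are taken from bond-order-dependent ideal
# bond lengths propagated along shortest paths; non-bonded targets are
# jittered per conformer (a cheap surrogate for torsional variation), the
# matrix is embedded in 3D by classical MDS, and a short harmonic relaxation
# restores bond lengths and pushes apart clashing atoms. Everything is
# driven by a per-conformer seed derived from (seed, conformer index), so a
# k = 1 run reproduces the first conformer of a k = 10 run with the same
# seed (prefix determinism).

IDEAL_BOND_LENGTH <- c(`1` = 1.54, `2` = 1.34, `3` = 1.20, ar = 1.40)

#' Generate seeded 3D conformers
#'
#' @param mol a `mol_graph`.
#' @param k number of conformers (positive integer).
#' @param seed integer seed; fixes all coordinates.
#' @param max_atoms size cap; larger queries are refused (the pharmacophore
#'   arm stores only compounds below this size).
#' @return `mol` with `conformers` replaced by exactly `k` entries, each
#'   `list(coords = N x 3 matrix [Angstrom], seed = <derived seed>)`.
#' @export
generate_conformers <- function(mol, k, seed, max_atoms = 50L) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0 || k != round(k))
    stopf("k must be a positive integer")
  n <- n_atoms(mol)
  if (n > max_atoms)
    stopf("molecule '%s' exceeds max_atoms (%d > %d)", mol$mol_id, n, max_atoms)
  mol$conformers <- lapply(seq_len(k), function(i) {
    s <- derive_seed(seed, i)
    list(coords = embed_conformer(mol, s), seed = s)
  })
  mol
}

embed_conformer <- function(mol, conf_seed) {
  n <- n_atoms(mol)
  set.seed(conf_seed)
  if (n == 1L) return(matrix(rep(0, 3L), 1L, 3L))
  b <- mol$bonds
  g <- mol_igraph(mol)
  w <- if (nrow(b) > 0L) unname(IDEAL_BOND_LENGTH[b$order]) else numeric()
  D <- igraph::distances(g, weights = w)
  if (any(!is.finite(D))) D[!is.finite(D)] <- max(D[is.finite(D)]) + 3
  # jitter non-bonded targets, symmetric
  J <- matrix(runif(n * n, 0.85, 1.25), n, n)
  J[lower.tri(J)] <- t(J)[lower.tri(J)]
  bonded <- matrix(FALSE, n, n)
  if (nrow(b) > 0L) {
    bonded[cbind(b$atom_i, b$atom_j)] <- TRUE
    bonded[cbind(b$atom_j, b$atom_i)] <- TRUE
  }
  Dt <- D * ifelse(bonded, 1, J)
  diag(Dt) <- 0
  X <- suppressWarnings(cmdscale(Dt, k = min(3L, n - 1L)))
  if (ncol(X) < 3L) X <- cbind(X, matrix(0, n, 3L - ncol(X)))
  X <- X + matrix(rnorm(n * 3L, sd = 0.05), n, 3L)
  relax_coords(X, b, n)
}

# a few steepest-descent steps: harmonic bonds + soft short-range repulsion
relax_coords <- function(X, bonds, n, iters = 40L, step = 0.1) {
  if (nrow(bonds) == 0L) return(X)
  i <- bonds$atom_i; j <- bonds$atom_j
  r0 <- unname(IDEAL_BOND_LENGTH[bonds$order])
  for (it in seq_len(iters)) {
    G <- matrix(0, n, 3L)
    d <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    len <- sqrt(rowSums(d * d)) + 1e-9
    f <- (len - r0) / len
    gb <- d * f
    for (c in 1:3) {
      G[, c] <- G[, c] + tabulate_sum(i, gb[, c], n) - tabulate_sum(j, gb[, c], n)
    }
    # repulsion for any pair closer than 1.2 A (excluding bonded handled above)
    DD <- as.matrix(stats::dist(X))
    close <- which(DD < 1.2 & DD > 0, arr.ind = TRUE)
    close <- close[close[, 1L] < close[, 2L], , drop = FALSE]
    if (nrow(close) > 0L) {
      for (rix in seq_len(nrow(close))) {
        a <- close[rix, 1L]; bq <- close[rix, 2L]
        d2 <- X[a, ] - X[bq, ]
        l2 <- sqrt(sum(d2 * d2)) + 1e-9
        push <- (1.2 - l2) / l2 * d2
        G[a, ] <- G[a, ] - push
        G[bq, ] <- G[bq, ] + push
      }
    }
    X <- X - step * G
  }
  X
}

tabulate_sum <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}
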