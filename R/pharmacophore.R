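# 3D pharmacophore features and distance-binned triplet keys.
#
# Feature rules (documented, SMARTS-free):
#   aromatic       one feature per aromatic ring, at the ring centroid
#   h-donor        O or N carrying at least one hydrogen
#   h-acceptor     any O; N with no hydrogens and charge <= 0
#   pos-ionizable  atom with formal charge > 0
#   neg-ionizable  atom with formal charge < 0
#   hydrophobic    connected cluster of >= `min_hydrophobic` non-aromatic
#                  carbons with no O/N neighbour, at the cluster centroid
#
# Keys hash every unordered feature triplet (sorted kinds + pairwise
# distances binned at 1 A, capped at 20 A) into a 4096-bit vector; molecules
# with < 3 features fall back to hashed pairs/singletons so they remain
# searchable. Keys depend on distances only, hence are invariant to rigid
# rotation/translation of the conformer.

PH_KINDS <- c("aromatic", "h-donor", "h-acceptor", "hydrophobic",
              "pos-ionizable", "neg-ionizable")

#' Extract pharmacophore features from one conformer
#'
#' @param mol a `mol_graph` with at least `conformer` conformers.
#' @param conformer conformer index (default 1).
#' @param min_hydrophobic minimum carbons per hydrophobic cluster (default 2).
#' @return data.frame `kind`, `x`, `y`, `z`, `member_atoms` (list column);
#'   each center is the centroid of its member atoms.
#' @export
extract_features <- function(mol, conformer = 1L, min_hydrophobic = 2L) {
  if (length(mol$conformers) < conformer)
    stopf("molecule '%s' has no conformer %d; run generate_conformers()",
          mol$mol_id, conformer)
  xyz <- mol$conformers[[conformer]]$coords
  at <- mol$atoms
  feats <- list()
  add <- function(kind, members) {
    ctr <- colMeans(xyz[members, , drop = FALSE])
    feats[[length(feats) + 1L]] <<- list(kind = kind, x = ctr[1L], y = ctr[2L],
                                         z = ctr[3L], member_atoms = members)
  }
  for (ring in smallest_rings(mol))
    if (all(at$aromatic[ring])) add("aromatic", sort(ring))

  has_h <- at$n_h > 0L
  if (any(at$element == "H")) {
    adj <- adjacency_list(mol)
    for (i in seq_len(n_atoms(mol)))
      if (any(at$element[adj[[i]]$nbr] == "H")) has_h[i] <- TRUE
  }
  for (i in which(at$element %in% c("N", "O") & has_h)) add("h-donor", i)
  for (i in which(at$element == "O" |
                  (at$element == "N" & !has_h & at$charge <= 0L)))
    add("h-acceptor", i)
  for (i in which(at$charge > 0L)) add("pos-ionizable", i)
  for (i in which(at$charge < 0L)) add("neg-ionizable", i)

  # hydrophobic carbon clusters
  polar_adjacent <- rep(FALSE, n_atoms(mol))
  b <- mol$bonds
  for (k in seq_len(nrow(b))) {
    if (at$element[b$atom_i[k]] %in% c("N", "O")) polar_adjacent[b$atom_j[k]] <- TRUE
    if (at$element[b$atom_j[k]] %in% c("N", "O")) polar_adjacent[b$atom_i[k]] <- TRUE
  }
  hydro <- at$element == "C" & !at$aromatic & !polar_adjacent
  if (any(hydro)) {
    rows <- which(b$atom_i %in% which(hydro) & b$atom_j %in% which(hydro))
    memb <- bond_subgraph_components(mol, rows)
    for (comp in unique(memb[hydro])) {
      members <- which(hydro & memb == comp)
      if (length(members) >= min_hydrophobic) add("hydrophobic", members)
    }
  }
  if (length(feats) == 0L)
    return(data.frame(kind = character(), x = numeric(), y = numeric(),
                      z = numeric()))
  out <- data.frame(kind = vapply(feats, `[[`, "", "kind"),
                    x = vapply(feats, `[[`, 0, "x"),
                    y = vapply(feats, `[[`, 0, "y"),
                    z = vapply(feats, `[[`, 0, "z"),
                    stringsAsFactors = FALSE)
  out$member_atoms <- lapply(feats, `[[`, "member_atoms")
  out
}

#' Hash a feature set into a pharmacophore key
#'
#' @param features output of [extract_features()].
#' @param nbits key length (default 4096).
#' @param bin_width distance bin width in Angstrom (default 1.0).
#' @param max_dist distance cap in Angstrom (default 20).
#' @return a `pharmacophore_key`: logical `bits`, `n_features`, parameters.
#' @export
pharmacophore_key <- function(features, nbits = 4096L, bin_width = 1.0,
                              max_dist = 20) {
  nf <- nrow(features)
  bits <- logical(nbits)
  binf <- function(d) as.integer(pmin(floor(d / bin_width), max_dist / bin_width))
  descs <- character()
  if (nf >= 3L) {
    xyz <- as.matrix(features[, c("x", "y", "z")])
    D <- as.matrix(stats::dist(xyz))
    trip <- utils::combn(nf, 3L)
    descs <- apply(trip, 2L, function(t3) {
      ks <- features$kind[t3]
      bb <- binf(c(D[t3[1L], t3[2L]], D[t3[1L], t3[3L]], D[t3[2L], t3[3L]]))
      canonical_triplet(ks, bb)
    })
  } else if (nf == 2L) {
    d <- sqrt(sum((as.numeric(features[1L, c("x", "y", "z")]) -
                   as.numeric(features[2L, c("x", "y", "z")]))^2))
    ks <- sort(features$kind)
    descs <- paste("P", ks[1L], ks[2L], binf(d), sep = "|")
  } else if (nf == 1L) {
    descs <- paste("S", features$kind[1L], sep = "|")
  }
  if (length(descs) > 0L) {
    pos <- vapply(descs, function(d) as.integer(fnv1a(d) %% nbits) + 1L, 0L,
                  USE.NAMES = FALSE)
    bits[pos] <- TRUE
  }
  structure(list(bits = bits, n_features = nf,
                 params = list(nbits = nbits, bin_width = bin_width,
                               max_dist = max_dist)),
            class = "pharmacophore_key")
}

# canonical descriptor of an unordered kind-triplet with pairwise bins:
# minimum over the 6 vertex orderings of "k1|k2|k3|d12|d13|d23"
canonical_triplet <- function(kinds, bins) {
  perms <- list(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L))
  pairbin <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    switch(key, `1 2` = bins[1L], `1 3` = bins[2L], `2 3` = bins[3L])
  }
  cand <- vapply(perms, function(p)
    paste("T", kinds[p[1L]], kinds[p[2L]], kinds[p[3L]],
          pairbin(p[1L], p[2L]), pairbin(p[1L], p[3L]), pairbin(p[2L], p[3L]),
          sep = "|"), "")
  min(cand)
}

#' Build a pharmacophore database over a compound library
#'
#' Each molecule below the size cap contributes one key per conformer
#' (`k` seeded conformers are generated per molecule). Oversize molecules
#' are skipped with a notice, mirroring the 2D-only fallback.
#'
#' @param mols list of `mol_graph`.
#' @param k conformers per molecule.
#' @param seed integer seed.
#' @param max_atoms size cap (default 50).
#' @param ... passed to [pharmacophore_key()].
#' @return a `pharma_db`: list with `ids`, `keys` (list of key-bit matrices,
#'   one row per conformer), `params`.
#' @export
build_pharma_db <- function(mols, k = 10L, seed = 1L, max_atoms = 50L, ...) {
  ids <- character(); keys <- list()
  params <- NULL
  for (mol in mols) {
    if (n_atoms(mol) > max_atoms) {
      message(sprintf("skipping %s: %d atoms exceeds max_atoms=%d",
                      mol$mol_id, n_atoms(mol), max_atoms))
      next
    }
    mseed <- derive_seed(seed, fnv1a(mol$mol_id) %% 1e6)
    m <- generate_conformers(mol, k = k, seed = mseed, max_atoms = max_atoms)
    kb <- do.call(rbind, lapply(seq_len(k), function(ci) {
      key <- pharmacophore_key(extract_features(m, ci), ...)
      params <<- key$params
      key$bits
    }))
    ids <- c(ids, mol$mol_id)
    keys[[length(keys) + 1L]] <- kb
  }
  if (length(ids) == 0L) stopf("no molecules small enough for the pharmacophore database")
  structure(list(ids = ids, keys = keys, params = params, k = k, seed = seed,
                 max_atoms = max_atoms),
            class = "pharma_db")
}

#' @export
print.pharma_db <- function(x, ...) {
  cat(sprintf("<pharma_db> %d molecules, %d conformers each, %d-bit keys\n",
              length(x$ids), x$k, x$params$nbits))
  invisible(x)
}

#' 3D pharmacophore similarity search
#'
#' For each query conformer a key is computed; a database molecule's score is
#' the maximum over (query conformer, database conformer) pairs of
#' `|AND(query, db)| / |query bits|`. Hits with score >= `min_overlap` are
#' returned sorted descending, ties broken by mol_id. Recall can only grow
#' with `k_conformers` because scores are maxima over an accumulating
#' conformer set.
#'
#' @param query_mol a `mol_graph` (<= `max_atoms` atoms).
#' @param db a `pharma_db`.
#' @param k_conformers query conformers to use.
#' @param min_overlap minimum score (default 0.5).
#' @param seed seed for query conformers.
#' @param max_atoms query size cap; an oversize query returns a zero-row
#'   result flagged `performed = FALSE` (callers fall back to 2D-only).
#' @return data.frame `mol_id`, `score`, with attribute `performed`.
#' @export
search_3d <- function(query_mol, db, k_conformers = 10L, min_overlap = 0.5,
                      seed = 1L, max_atoms = db$max_atoms) {
  if (n_atoms(query_mol) > max_atoms) {
    out <- data.frame(mol_id = character(), score = numeric())
    attr(out, "performed") <- FALSE
    attr(out, "notice") <- sprintf(
      "no pharmacophore search performed: query has %d atoms (max %d)",
      n_atoms(query_mol), max_atoms)
    return(out)
  }
  qseed <- derive_seed(seed, fnv1a(query_mol$mol_id) %% 1e6)
  qm <- generate_conformers(query_mol, k = k_conformers, seed = qseed,
                            max_atoms = max_atoms)
  nb <- db$params$nbits
  qkeys <- t(vapply(seq_len(k_conformers), function(ci)
    pharmacophore_key(extract_features(qm, ci), nbits = nb,
                      bin_width = db$params$bin_width,
                      max_dist = db$params$max_dist)$bits, logical(nb)))
  qset <- rowSums(qkeys)
  scores <- vapply(db$keys, function(kb) {
    ov <- qkeys %*% t(kb)            # q-conformers x db-conformers AND counts
    sc <- ov / pmax(qset, 1L)
    max(sc)
  }, 0)
  keep <- which(scores >= min_overlap)
  ord <- keep[order(-scores[keep], db$ids[keep])]
  out <- data.frame(mol_id = db$ids[ord], score = scores[ord],
                    stringsAsFactors = FALSE)
  attr(out, "performed") <- TRUE
  out
}

#' Serialize / load a pharmacophore database
#'
#' Tabular format: header line with parameters, then one
#' `mol_id<TAB>conformer<TAB>hex-key` row per (molecule, conformer).
#'
#' @param db a `pharma_db`.
#' @param path file path.
#' @return `write_pharma_db`: `path` invisibly; `read_pharma_db`: a
#'   `pharma_db` with identical query results.
#' @export
write_pharma_db <- function(db, path) {
  hdr <- sprintf("#driftr-phdb v1 nbits=%d bin_width=%g max_dist=%g k=%d seed=%d max_atoms=%d",
                 db$params$nbits, db$params$bin_width, db$params$max_dist,
                 db$k, db$seed, db$max_atoms)
  rows <- character()
  for (i in seq_along(db$ids))
    for (ci in seq_len(nrow(db$keys[[i]])))
      rows <- c(rows, paste(db$ids[i], ci, bits_to_hex(db$keys[[i]][ci, ]),
                            sep = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_pharma_db
#' @export
read_pharma_db <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1L]
  if (!startsWith(hdr, "#driftr-phdb v1")) stopf("not a driftr pharmacophore db: %s", path)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1L]]
  pars <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  nb <- as.integer(pars[["nbits"]])
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids_all <- vapply(rows, `[`, "", 1L)
  ids <- unique(ids_all)
  keys <- lapply(ids, function(id) {
    sel <- which(ids_all == id)
    t(vapply(sel, function(r) {
      v <- hex_to_bits(rows[[r]][3L])
      length(v) <- nb
      v
    }, logical(nb)))
  })
  structure(list(ids = ids, keys = keys,
                 params = list(nbits = nb,
                               bin_width = as.numeric(pars[["bin_width"]]),
                               max_dist = as.numeric(pars[["max_dist"]])),
                 k = as.integer(pars[["k"]]), seed = as.integer(pars[["seed"]]),
                 max_atoms = as.integer(pars[["max_atoms"]])),
            class = "pharma_db")
}
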