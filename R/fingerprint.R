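# Path-based 1024-bit 2D fingerprints (FP2 style).
#
# Linear fragments of 1..7 heavy atoms are enumerated under four rules:
#   (i)   at most seven atoms per fragment;
#   (ii)  single-atom fragments of C, O, N are ignored;
#   (iii) duplicate fragments (same canonical element/bond-order/ring-flag
#         descriptor) are kept once;
#   (iv)  fragments terminate at ring structures: by default a growing path
#         stops when the next atom would re-enter a ring system the path has
#         already left (mode "ring_system"); mode "closure" only forbids
#         revisiting atoms already on the path.
# Each canonical descriptor is hashed (FNV-1a) modulo 1024 to a bit. No
# bit-level compatibility with other FP2 implementations is promised; the
# hash is documented and stable.

FP_NBITS <- 1024L
SINGLE_ATOM_IGNORE <- c("C", "O", "N")

#' Enumerate fingerprint fragment paths
#'
#' Returns all simple linear heavy-atom paths of 1-7 atoms, de-duplicated by
#' canonical descriptor, excluding single C/O/N atoms, with the configured
#' ring-termination rule applied during extension.
#'
#' @param mol a `mol_graph`.
#' @param max_len maximum atoms per path (7).
#' @param ring_mode `"ring_system"` (default) or `"closure"`; see source
#'   header and the methods vignette.
#' @param include_h include explicit hydrogen atoms in paths (default FALSE:
#'   heavy atoms only).
#' @return data.frame with one row per unique fragment: `descriptor`
#'   (canonical string), `n_atoms_path`, and `path` (list column of atom
#'   index vectors, one representative per descriptor).
#' @export
enumerate_paths <- function(mol, max_len = 7L, ring_mode = c("ring_system", "closure"),
                            include_h = FALSE) {
  ring_mode <- match.arg(ring_mode)
  n <- n_atoms(mol)
  eligible <- if (include_h) rep(TRUE, n) else mol$atoms$element != "H"
  adj <- adjacency_list(mol)
  # ring systems: components of the ring-bond subgraph (0 = acyclic atom)
  ringsys <- integer(n)
  ring_rows <- which(mol$bonds$in_ring)
  if (length(ring_rows) > 0L) {
    memb <- bond_subgraph_components(mol, ring_rows)
    ring_atoms <- unique(c(mol$bonds$atom_i[ring_rows], mol$bonds$atom_j[ring_rows]))
    ringsys[ring_atoms] <- memb[ring_atoms]
  }

  paths <- list()
  walk <- function(path, exited) {
    k <- length(path)
    if (k >= 1L) paths[[length(paths) + 1L]] <<- path
    if (k == max_len) return(invisible())
    tip <- path[k]
    for (q in seq_along(adj[[tip]]$nbr)) {
      nxt <- adj[[tip]]$nbr[q]
      if (!eligible[nxt] || nxt %in% path) next
      ex2 <- exited
      rs_tip <- ringsys[tip]; rs_nxt <- ringsys[nxt]
      if (ring_mode == "ring_system") {
        if (rs_nxt > 0L && rs_nxt %in% exited) next  # re-entry: terminate here
        if (rs_tip > 0L && rs_nxt != rs_tip) ex2 <- union(exited, rs_tip)
      }
      walk(c(path, nxt), ex2)
    }
  }
  for (a in which(eligible)) walk(a, integer())

  if (length(paths) == 0L)
    return(data.frame(descriptor = character(), n_atoms_path = integer()))

  # single-atom ignore rule + reverse de-duplication by canonical descriptor
  keep <- vapply(paths, function(p)
    length(p) > 1L || !(mol$atoms$element[p] %in% SINGLE_ATOM_IGNORE), TRUE)
  paths <- paths[keep]
  if (length(paths) == 0L)
    return(data.frame(descriptor = character(), n_atoms_path = integer()))
  desc <- vapply(paths, function(p) path_descriptor(mol, p), "")
  first <- !duplicated(desc)
  out <- data.frame(descriptor = desc[first],
                    n_atoms_path = vapply(paths[first], length, 0L),
                    stringsAsFactors = FALSE)
  out$path <- paths[first]
  out
}

# canonical fragment descriptor: atom tokens (element + aromatic + ring
# flags) interleaved with bond orders, read in the lexicographically
# smaller of the two directions
path_descriptor <- function(mol, path) {
  atok <- paste0(mol$atoms$element[path],
                 ifelse(mol$atoms$aromatic[path], "a", ""),
                 ifelse(mol$atoms$in_ring[path], "R", ""))
  k <- length(path)
  if (k == 1L) return(atok)
  bkey <- paste(pmin(mol$bonds$atom_i, mol$bonds$atom_j),
                pmax(mol$bonds$atom_i, mol$bonds$atom_j))
  btok <- character(k - 1L)
  for (q in seq_len(k - 1L)) {
    row <- match(paste(min(path[q], path[q + 1L]), max(path[q], path[q + 1L])), bkey)
    btok[q] <- mol$bonds$order[row]
  }
  fwd <- paste(c(rbind(atok[-k], btok), atok[k]), collapse = "|")
  ratok <- rev(atok); rbtok <- rev(btok)
  rev_ <- paste(c(rbind(ratok[-k], rbtok), ratok[k]), collapse = "|")
  if (fwd <= rev_) fwd else rev_
}

#' Hash a fragment descriptor to a fingerprint bit
#'
#' Deterministic FNV-1a hash of the canonical descriptor string, reduced
#' modulo 1024 to a bit position (1-based).
#'
#' @param descriptor canonical descriptor string (see [enumerate_paths()]);
#'   a raw forward/reverse pair hashes identically because descriptors are
#'   canonicalized to the lexicographically smaller direction.
#' @return integer bit position in 1..1024.
#' @export
hash_fragment <- function(descriptor) {
  if (!is.character(descriptor) || any(!nzchar(descriptor)))
    stopf("descriptor must be nonempty")
  vapply(descriptor, function(d) as.integer(fnv1a(d) %% FP_NBITS) + 1L,
         0L, USE.NAMES = FALSE)
}

#' Compute the 1024-bit path fingerprint of a molecule
#'
#' @param mol a `mol_graph`.
#' @inheritParams enumerate_paths
#' @return a `fingerprint2d` object: `bits` (logical length 1024), `n_set`,
#'   and `fragments` (provenance: descriptor, bit, representative path).
#' @export
fingerprint <- function(mol, max_len = 7L, ring_mode = c("ring_system", "closure"),
                        include_h = FALSE) {
  ring_mode <- match.arg(ring_mode)
  fr <- enumerate_paths(mol, max_len = max_len, ring_mode = ring_mode,
                        include_h = include_h)
  bits <- logical(FP_NBITS)
  if (nrow(fr) > 0L) {
    fr$bit <- hash_fragment(fr$descriptor)
    bits[fr$bit] <- TRUE
  } else fr$bit <- integer()
  structure(list(bits = bits, n_set = sum(bits), fragments = fr,
                 build_params = list(nbits = FP_NBITS, max_len = max_len,
                                     ring_mode = ring_mode, include_h = include_h)),
            class = "fingerprint2d")
}

#' @export
print.fingerprint2d <- function(x, ...) {
  cat(sprintf("<fingerprint2d> %d/%d bits set, %d unique fragments\n",
              x$n_set, length(x$bits), nrow(x$fragments)))
  invisible(x)
}

#' Tanimoto coefficient between two fingerprints
#'
#' `Tc = c / (a + b - c)` where `a`, `b` are the set-bit counts and `c` the
#' common-bit count. Two all-zero fingerprints compare as 1 (identity
#' convention for the 0/0 case, with a warning).
#'
#' @param fa,fb `fingerprint2d` objects built with identical parameters.
#' @return Tc in \[0, 1\].
#' @export
tanimoto <- function(fa, fb) {
  if (!identical(fa$build_params, fb$build_params))
    stopf("fingerprints were built with different parameters")
  a <- fa$n_set; b <- fb$n_set
  cc <- sum(fa$bits & fb$bits)
  if (a + b == 0L) {
    warnf("both fingerprints are all-zero; Tanimoto defined as 1 (identity convention)")
    return(1)
  }
  cc / (a + b - cc)
}

#' Build a similarity-search index over a compound library
#'
#' @param mols nonempty list of `mol_graph` with unique ids.
#' @inheritParams enumerate_paths
#' @return a `fp_index`: bit matrix (molecules x 1024), ids, set-bit counts,
#'   and the build parameters all entries share.
#' @export
build_index <- function(mols, max_len = 7L, ring_mode = c("ring_system", "closure"),
                        include_h = FALSE) {
  ring_mode <- match.arg(ring_mode)
  if (length(mols) == 0L) stopf("cannot build an index over an empty library")
  ids <- vapply(mols, function(m) m$mol_id, "")
  if (anyDuplicated(ids)) stopf("duplicate mol_id in library: %s",
                                ids[anyDuplicated(ids)])
  M <- matrix(FALSE, length(mols), FP_NBITS)
  for (i in seq_along(mols)) {
    M[i, ] <- fingerprint(mols[[i]], max_len = max_len, ring_mode = ring_mode,
                          include_h = include_h)$bits
  }
  structure(list(ids = ids, bits = M, n_set = rowSums(M),
                 build_params = list(nbits = FP_NBITS, max_len = max_len,
                                     ring_mode = ring_mode, include_h = include_h)),
            class = "fp_index")
}

#' @export
print.fp_index <- function(x, ...) {
  cat(sprintf("<fp_index> %d molecules, %d bits\n", length(x$ids), ncol(x$bits)))
  invisible(x)
}

#' Rank indexed molecules by Tanimoto similarity to a query
#'
#' Equivalent to a brute-force scan: every indexed molecule with
#' `Tc >= tc_min` is returned, sorted by Tc descending, ties broken by
#' mol_id.
#'
#' @param query a `fingerprint2d`.
#' @param index a `fp_index` built with the same parameters.
#' @param tc_min similarity threshold in \[0, 1\] (default 0.85, the usual
#'   structural-similarity cutoff).
#' @return data.frame `mol_id`, `tc`.
#' @export
search_2d <- function(query, index, tc_min = 0.85) {
  if (!identical(query$build_params, index$build_params))
    stopf("query fingerprint and index were built with different parameters")
  if (tc_min < 0 || tc_min > 1) stopf("tc_min must be in [0, 1]")
  a <- index$n_set
  b <- query$n_set
  cc <- as.numeric(index$bits %*% query$bits)
  denom <- a + b - cc
  tc <- ifelse(denom == 0, 1, cc / denom)
  keep <- which(tc >= tc_min)
  ord <- keep[order(-tc[keep], index$ids[keep])]
  data.frame(mol_id = index$ids[ord], tc = tc[ord], stringsAsFactors = FALSE)
}

#' Serialize / load a fingerprint index
#'
#' Versioned tabular format: a `#driftr-fpidx` header line carrying the
#' build parameters, then one `mol_id<TAB>256-hex-digit` row per molecule.
#'
#' @param index a `fp_index`.
#' @param path file path.
#' @return `write_fp_index`: `path`, invisibly. `read_fp_index`: a
#'   `fp_index` giving identical query results.
#' @export
write_fp_index <- function(index, path) {
  hdr <- sprintf("#driftr-fpidx v1 nbits=%d max_len=%d ring_mode=%s include_h=%s",
                 index$build_params$nbits, index$build_params$max_len,
                 index$build_params$ring_mode, index$build_params$include_h)
  rows <- vapply(seq_along(index$ids), function(i)
    paste(index$ids[i], bits_to_hex(index$bits[i, ]), sep = "\t"), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_fp_index
#' @export
read_fp_index <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1L]
  if (!startsWith(hdr, "#driftr-fpidx v1"))
    stopf("not a driftr fingerprint index: %s", path)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1L]]
  pars <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, "", 1L)
  M <- t(vapply(rows, function(r) hex_to_bits(r[2L]), logical(FP_NBITS)))
  structure(list(ids = ids, bits = M, n_set = rowSums(M),
                 build_params = list(nbits = as.integer(pars[["nbits"]]),
                                     max_len = as.integer(pars[["max_len"]]),
                                     ring_mode = pars[["ring_mode"]],
                                     include_h = as.logical(pars[["include_h"]]))),
            class = "fp_index")
}

bits_to_hex <- function(bits) {
  nyb <- matrix(bits, nrow = 4L)
  vals <- as.integer(colSums(nyb * c(8L, 4L, 2L, 1L)))
  paste(format.hexmode(vals), collapse = "")
}

hex_to_bits <- function(hex) {
  vals <- strtoi(strsplit(hex, "")[[1L]], 16L)
  as.logical(rbind(bitwAnd(vals, 8L) > 0L, bitwAnd(vals, 4L) > 0L,
                   bitwAnd(vals, 2L) > 0L, bitwAnd(vals, 1L) > 0L))
}
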