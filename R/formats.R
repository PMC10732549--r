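# Molecule file I/O: SDF (V2000), MOL2 (TRIPOS), SMILES files.
# File formats index atoms from 1; the internal representation is also
# 1-based, so translation at the boundary is the identity here.

#' Read a single molecule
#'
#' @param x a file path, or the content itself (a SMILES string, or full
#'   SDF/MOL2 text).
#' @param fmt `"smiles"`, `"sdf"` or `"mol2"`. Guessed from the file
#'   extension when `x` is a path; defaults to `"smiles"` for bare strings.
#' @param mol_id optional identifier override.
#' @return a [molecule_graph()]. Ring membership is annotated at load time.
#'   Hydrogens implicit in SMILES are recorded as per-atom counts; explicit
#'   hydrogen atoms in SDF/MOL2 are retained as atoms.
#' @export
read_molecule <- function(x, fmt = NULL, mol_id = NULL) {
  if (length(x) != 1L || !is.character(x)) stopf("input must be a single string")
  is_path <- !grepl("\n", x) && file.exists(x)
  if (is.null(fmt)) {
    fmt <- if (is_path) {
      switch(tolower(tools::file_ext(x)),
             sdf = "sdf", mol = "sdf", mol2 = "mol2",
             smi = "smiles", "smiles")
    } else if (grepl("@<TRIPOS>MOLECULE", x)) "mol2"
      else if (grepl("V2000", x)) "sdf"
      else "smiles"
  }
  fmt <- match.arg(fmt, c("smiles", "sdf", "mol2"))
  txt <- if (is_path && fmt != "smiles") readLines(x, warn = FALSE)
         else if (is_path) trimws(readLines(x, warn = FALSE)[1L])
         else x
  switch(fmt,
    smiles = {
      tok <- strsplit(trimws(txt), "[ \t]+")[[1L]]
      if (length(tok) == 0L) stopf("empty SMILES input")
      parse_smiles(tok[1L], mol_id = mol_id %||%
                     (if (length(tok) > 1L) tok[2L] else NULL))
    },
    sdf = {
      mols <- parse_sdf(if (is.character(txt) && length(txt) == 1L)
                          strsplit(txt, "\n")[[1L]] else txt)
      if (length(mols) == 0L) stopf("empty SDF input")
      m <- mols[[1L]]
      if (!is.null(mol_id)) m$mol_id <- mol_id
      m
    },
    mol2 = {
      m <- parse_mol2(if (is.character(txt) && length(txt) == 1L)
                        strsplit(txt, "\n")[[1L]] else txt)
      if (!is.null(mol_id)) m$mol_id <- mol_id
      m
    })
}

#' Read a multi-molecule file
#'
#' @param path path to a `.sdf` (multi-record) or `.smi` file
#'   (one `SMILES [id]` per line).
#' @param fmt `"sdf"` or `"smiles"`; guessed from extension by default.
#' @return list of [molecule_graph()].
#' @export
read_molecules <- function(path, fmt = NULL) {
  if (is.null(fmt))
    fmt <- switch(tolower(tools::file_ext(path)), sdf = "sdf", "smiles")
  lines <- readLines(path, warn = FALSE)
  if (fmt == "sdf") return(parse_sdf(lines))
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    parse_smiles(tok[1L],
                 mol_id = if (length(tok) > 1L) tok[2L] else sprintf("mol%04d", i))
  })
}

sdf_charge_code <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)

parse_sdf <- function(lines) {
  recs <- split(lines, cumsum(c(TRUE, head(lines, -1L) == "$$$$")))
  mols <- list()
  for (rec in recs) {
    rec <- rec[rec != "$$$$"]
    if (all(!nzchar(trimws(rec)))) next
    if (length(rec) < 4L) stopf("SDF parse error: record shorter than header + counts")
    counts <- rec[4L]
    na <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
    nb <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
    if (is.na(na) || is.na(nb))
      stopf("SDF parse error in counts line: '%s'", counts)
    if (length(rec) < 4L + na + nb)
      stopf("SDF parse error: truncated record (expected %d atom + %d bond lines)", na, nb)
    alines <- rec[5L:(4L + na)]
    coords <- matrix(0, na, 3L)
    element <- character(na)
    charge <- integer(na)
    for (i in seq_len(na)) {
      ln <- alines[i]
      coords[i, ] <- as.numeric(c(substr(ln, 1L, 10L), substr(ln, 11L, 20L),
                                  substr(ln, 21L, 30L)))
      element[i] <- trimws(substr(ln, 32L, 34L))
      code <- suppressWarnings(as.integer(substr(ln, 37L, 39L)))
      if (!is.na(code) && code %in% sdf_charge_code)
        charge[i] <- as.integer(names(sdf_charge_code)[match(code, sdf_charge_code)])
      if (any(is.na(coords[i, ])) || !nzchar(element[i]))
        stopf("SDF parse error in atom line %d: '%s'", i, ln)
    }
    order <- character(nb); ai <- integer(nb); aj <- integer(nb)
    if (nb > 0L) {
      blines <- rec[(5L + na):(4L + na + nb)]
      for (k in seq_len(nb)) {
        ln <- blines[k]
        ai[k] <- as.integer(substr(ln, 1L, 3L))
        aj[k] <- as.integer(substr(ln, 4L, 6L))
        ty <- as.integer(substr(ln, 7L, 9L))
        if (is.na(ai[k]) || is.na(aj[k]) || is.na(ty) || !ty %in% c(1L, 2L, 3L, 4L))
          stopf("SDF parse error in bond line %d: '%s'", k, ln)
        order[k] <- if (ty == 4L) "ar" else as.character(ty)
      }
    }
    # M  CHG property lines override atom-block charge codes
    for (ln in rec[grepl("^M  CHG", rec)]) {
      v <- as.integer(strsplit(trimws(substring(ln, 7L)), "[ ]+")[[1L]])
      nn <- v[1L]
      for (q in seq_len(nn)) charge[v[2L * q]] <- v[2L * q + 1L]
    }
    atoms <- data.frame(element = element, aromatic = FALSE,
                        charge = charge, n_h = 0L, stringsAsFactors = FALSE)
    bonds <- data.frame(atom_i = ai, atom_j = aj, order = order,
                        stringsAsFactors = FALSE)
    arom <- unique(c(ai[order == "ar"], aj[order == "ar"]))
    atoms$aromatic[arom] <- TRUE
    name <- trimws(rec[1L])
    mol <- molecule_graph(if (nzchar(name)) name else sprintf("sdf%03d", length(mols) + 1L),
                          atoms, bonds,
                          conformers = if (any(coords != 0))
                            list(list(coords = coords, seed = NA_integer_)) else list(),
                          source_format = "sdf")
    mols[[length(mols) + 1L]] <- mol
  }
  mols
}

#' Write molecules to an SDF (V2000) file
#'
#' The first conformer supplies coordinates (zeros if none). Aromatic bonds
#' are written as type 4; formal charges as `M  CHG` lines.
#'
#' @param mols a `mol_graph` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "mol_graph")) mols <- list(mols)
  out <- character()
  for (mol in mols) {
    n <- n_atoms(mol); nb <- nrow(mol$bonds)
    coords <- if (length(mol$conformers) > 0L) mol$conformers[[1L]]$coords
              else matrix(0, n, 3L)
    rec <- c(mol$mol_id, "  driftr", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    for (i in seq_len(n))
      rec <- c(rec, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                            coords[i, 1L], coords[i, 2L], coords[i, 3L],
                            mol$atoms$element[i]))
    if (nb > 0L) {
      ty <- match(mol$bonds$order, c("1", "2", "3", "ar"))
      for (k in seq_len(nb))
        rec <- c(rec, sprintf("%3d%3d%3d  0  0  0  0",
                              mol$bonds$atom_i[k], mol$bonds$atom_j[k], ty[k]))
    }
    chg <- which(mol$atoms$charge != 0L)
    if (length(chg) > 0L)
      rec <- c(rec, paste0("M  CHG", sprintf("%3d", length(chg)),
                           paste0(sprintf("%4d%4d", chg, mol$atoms$charge[chg]),
                                  collapse = "")))
    rec <- c(rec, "M  END", "$$$$")
    out <- c(out, rec)
  }
  writeLines(out, path)
  invisible(path)
}

parse_mol2 <- function(lines) {
  sec <- function(name) {
    st <- grep(paste0("^@<TRIPOS>", name, "$"), lines)
    if (length(st) == 0L) return(NULL)
    st <- st[1L] + 1L
    en <- st
    while (en <= length(lines) && !grepl("^@<TRIPOS>", lines[en])) en <- en + 1L
    trimws(lines[st:(en - 1L)])
  }
  molsec <- sec("MOLECULE")
  atomsec <- sec("ATOM")
  bondsec <- sec("BOND")
  if (is.null(molsec) || is.null(atomsec))
    stopf("MOL2 parse error: missing MOLECULE or ATOM section")
  atomsec <- atomsec[nzchar(atomsec)]
  n <- length(atomsec)
  element <- character(n); aromatic <- logical(n)
  coords <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    f <- strsplit(atomsec[i], "[ \t]+")[[1L]]
    if (length(f) < 6L) stopf("MOL2 parse error in atom line %d: '%s'", i, atomsec[i])
    coords[i, ] <- as.numeric(f[3:5])
    ty <- strsplit(f[6L], ".", fixed = TRUE)[[1L]]
    element[i] <- ty[1L]
    aromatic[i] <- length(ty) > 1L && ty[2L] == "ar"
  }
  ai <- integer(); aj <- integer(); order <- character()
  if (!is.null(bondsec)) {
    bondsec <- bondsec[nzchar(bondsec)]
    for (k in seq_along(bondsec)) {
      f <- strsplit(bondsec[k], "[ \t]+")[[1L]]
      if (length(f) < 4L) stopf("MOL2 parse error in bond line %d: '%s'", k, bondsec[k])
      ai[k] <- as.integer(f[2L]); aj[k] <- as.integer(f[3L])
      order[k] <- switch(f[4L], ar = "ar", am = "1", du = "1", un = "1",
                         nc = "1", f[4L])
    }
  }
  molecule_graph(
    if (nzchar(molsec[1L])) molsec[1L] else "mol2_molecule",
    data.frame(element = element, aromatic = aromatic, charge = 0L, n_h = 0L,
               stringsAsFactors = FALSE),
    data.frame(atom_i = ai, atom_j = aj, order = order, stringsAsFactors = FALSE),
    conformers = if (any(coords != 0))
      list(list(coords = coords, seed = NA_integer_)) else list(),
    source_format = "mol2")
}

#' Write a molecule to MOL2 (TRIPOS) format
#'
#' @param mol a `mol_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(mol, path) {
  n <- n_atoms(mol); nb <- nrow(mol$bonds)
  coords <- if (length(mol$conformers) > 0L) mol$conformers[[1L]]$coords
            else matrix(0, n, 3L)
  out <- c("@<TRIPOS>MOLECULE", mol$mol_id,
           sprintf(" %d %d 0 0 0", n, nb), "SMALL", "NO_CHARGES", "",
           "@<TRIPOS>ATOM")
  for (i in seq_len(n)) {
    ty <- paste0(mol$atoms$element[i], if (mol$atoms$aromatic[i]) ".ar" else "")
    out <- c(out, sprintf("%7d %-4s %9.4f %9.4f %9.4f %-6s 1 LIG 0.0000",
                          i, paste0(mol$atoms$element[i], i),
                          coords[i, 1L], coords[i, 2L], coords[i, 3L], ty))
  }
  out <- c(out, "@<TRIPOS>BOND")
  if (nb > 0L)
    for (k in seq_len(nb))
      out <- c(out, sprintf("%6d %5d %5d %4s", k, mol$bonds$atom_i[k],
                            mol$bonds$atom_j[k], mol$bonds$order[k]))
  writeLines(out, path)
  invisible(path)
}

#' Write molecules as a SMILES-id file
#'
#' One `SMILES<TAB>id` per line. Only molecules that originated from SMILES
#' retain a faithful string; others are rebuilt atom-by-atom and so must be
#' acyclic or fail. Intended for the synthetic-library round trip where all
#' molecules carry their generating SMILES.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids matching identifiers.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_smi <- function(smiles, ids, path) {
  stopifnot(length(smiles) == length(ids))
  writeLines(paste(smiles, ids, sep = "\t"), path)
  invisible(path)
}
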