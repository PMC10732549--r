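# SMILES parser.
#
# Supported subset: organic-subset atoms (B C N O P S F Cl Br I and aromatic
# b c n o p s), bracket atoms with isotope/chirality (ignored), explicit H
# counts and formal charges, branches, ring-bond closures (digits and %nn),
# bond symbols - = # : (/ and \ are read as single bonds), and '.'
# component separators. Stereochemistry is not interpreted (see Non-goals).
# Implicit hydrogens on organic-subset atoms follow standard SMILES valence
# rules (aromatic bonds count 1.5, summed order rounded up).

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")
DEFAULT_VALENCE <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                        S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

parse_smiles <- function(smiles, mol_id = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    stopf("SMILES input must be a single string")
  s <- trimws(smiles)
  if (nchar(s) == 0L) stopf("empty SMILES input")
  chars <- strsplit(s, "")[[1L]]
  np <- length(chars)

  atoms <- list()          # each: list(element, aromatic, charge, n_h)
  bonds <- list()          # each: list(i, j, order)
  prev <- NA_integer_      # atom awaiting a bond to the next atom
  pending <- NULL          # explicit bond symbol awaiting use
  branch_stack <- integer()
  ring_open <- list()      # closure number -> list(atom, order)

  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    idx <- length(atoms)
    if (!is.na(prev)) {
      ord <- pending
      if (is.null(ord))
        ord <- if (a$aromatic && atoms[[prev]]$aromatic) "ar" else "1"
      bonds[[length(bonds) + 1L]] <<- list(i = prev, j = idx, order = ord)
    }
    pending <<- NULL
    prev <<- idx
    idx
  }

  i <- 1L
  while (i <= np) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = "1", "=" = "2", "#" = "3",
                        ":" = "ar", "/" = "1", "\\" = "1")
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stopf("SMILES parse error at position %d: branch before any atom", i)
      branch_stack <- c(branch_stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch_stack) == 0L)
        stopf("SMILES parse error at position %d: unmatched ')'", i)
      prev <- branch_stack[length(branch_stack)]
      branch_stack <- branch_stack[-length(branch_stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NULL
      i <- i + 1L
    } else if (grepl("[0-9%]", ch)) {
      if (is.na(prev))
        stopf("SMILES parse error at position %d: ring closure before any atom", i)
      if (ch == "%") {
        if (i + 2L > np || !grepl("[0-9]", chars[i + 1L]) || !grepl("[0-9]", chars[i + 2L]))
          stopf("SMILES parse error at position %d: bad %%nn ring number", i)
        num <- paste0(chars[i + 1L], chars[i + 2L])
        i <- i + 3L
      } else {
        num <- ch
        i <- i + 1L
      }
      if (!is.null(ring_open[[num]])) {
        op <- ring_open[[num]]
        ord <- pending %||% op$order
        if (!is.null(pending) && !is.null(op$order) && pending != op$order)
          stopf("SMILES parse error: conflicting bond orders on ring closure %s", num)
        if (is.null(ord))
          ord <- if (atoms[[prev]]$aromatic && atoms[[op$atom]]$aromatic) "ar" else "1"
        bonds[[length(bonds) + 1L]] <- list(i = op$atom, j = prev, order = ord)
        ring_open[[num]] <- NULL
      } else {
        ring_open[[num]] <- list(atom = prev, order = pending)
      }
      pending <- NULL
    } else if (ch == "[") {
      close <- NULL
      for (k in seq(i + 1L, np)) if (chars[k] == "]") { close <- k; break }
      if (is.null(close))
        stopf("SMILES parse error at position %d: unclosed '['", i)
      body <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      add_atom(parse_bracket_atom(body, i))
      i <- close + 1L
    } else {
      # organic-subset atom, possibly two letters
      two <- if (i < np) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(list(element = two, aromatic = FALSE, charge = 0L, n_h = NA_integer_))
        i <- i + 2L
      } else if (ch %in% ORGANIC_SUBSET) {
        add_atom(list(element = ch, aromatic = FALSE, charge = 0L, n_h = NA_integer_))
        i <- i + 1L
      } else if (ch %in% AROMATIC_ORGANIC) {
        add_atom(list(element = toupper(ch), aromatic = TRUE, charge = 0L,
                      n_h = NA_integer_))
        i <- i + 1L
      } else {
        stopf("SMILES parse error at position %d: unexpected character '%s'", i, ch)
      }
    }
  }
  if (length(ring_open) > 0L)
    stopf("SMILES parse error: unclosed ring bond number(s) %s",
          paste(names(ring_open), collapse = ", "))
  if (length(branch_stack) > 0L)
    stopf("SMILES parse error: unclosed branch '('")
  if (length(atoms) == 0L) stopf("empty SMILES input")

  at <- data.frame(
    element = vapply(atoms, function(a) a$element, ""),
    aromatic = vapply(atoms, function(a) a$aromatic, TRUE),
    charge = vapply(atoms, function(a) a$charge, 0L),
    n_h = vapply(atoms, function(a) a$n_h, NA_integer_),
    stringsAsFactors = FALSE)
  bd <- if (length(bonds) > 0L) data.frame(
    atom_i = vapply(bonds, function(b) b$i, 0L),
    atom_j = vapply(bonds, function(b) b$j, 0L),
    order = vapply(bonds, function(b) b$order, ""),
    stringsAsFactors = FALSE)
  else data.frame(atom_i = integer(), atom_j = integer(), order = character())

  # implicit hydrogens on organic-subset atoms (n_h still NA)
  bsum <- numeric(nrow(at))
  if (nrow(bd) > 0L) {
    ords <- bond_order_numeric(bd$order)
    for (k in seq_len(nrow(bd))) {
      bsum[bd$atom_i[k]] <- bsum[bd$atom_i[k]] + ords[k]
      bsum[bd$atom_j[k]] <- bsum[bd$atom_j[k]] + ords[k]
    }
  }
  for (a in seq_len(nrow(at))) {
    if (!is.na(at$n_h[a])) next
    vset <- DEFAULT_VALENCE[[at$element[a]]]
    bs <- ceiling(bsum[a])
    if (is.null(vset)) { at$n_h[a] <- 0L; next }
    ok <- vset[vset >= bs]
    v <- if (length(ok) > 0L) min(ok) else bs
    at$n_h[a] <- as.integer(v - bs)
  }

  molecule_graph(mol_id %||% s, at, bd, source_format = "smiles")
}

parse_bracket_atom <- function(body, pos) {
  rest <- body
  # isotope
  rest <- sub("^[0-9]+", "", rest)
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|as|se|[bcnops])", rest))
  if (length(m) == 0L || nchar(m) == 0L)
    stopf("SMILES parse error at position %d: bad bracket atom '[%s]'", pos, body)
  sym <- m
  rest <- substring(rest, nchar(sym) + 1L)
  aromatic <- sym %in% c(AROMATIC_ORGANIC, "as", "se")
  element <- if (aromatic) {
    if (sym == "as") "As" else if (sym == "se") "Se" else toupper(sym)
  } else sym
  rest <- gsub("@", "", rest)
  n_h <- 0L
  hm <- regmatches(rest, regexpr("^H[0-9]*", rest))
  if (length(hm) == 1L && nchar(hm) > 0L) {
    n_h <- if (nchar(hm) == 1L) 1L else as.integer(substring(hm, 2L))
    rest <- substring(rest, nchar(hm) + 1L)
  }
  charge <- 0L
  cm <- regmatches(rest, regexpr("^(\\++|-+|\\+[0-9]+|-[0-9]+)", rest))
  if (length(cm) == 1L && nchar(cm) > 0L) {
    charge <- if (grepl("^[+-][0-9]", cm)) {
      as.integer(cm)
    } else {
      ifelse(substring(cm, 1L, 1L) == "+", 1L, -1L) * nchar(cm)
    }
    rest <- substring(rest, nchar(cm) + 1L)
  }
  rest <- sub("^:[0-9]+", "", rest)
  if (nchar(rest) > 0L)
    stopf("SMILES parse error at position %d: trailing '%s' in bracket atom", pos, rest)
  list(element = element, aromatic = aromatic, charge = as.integer(charge),
       n_h = n_h)
}
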