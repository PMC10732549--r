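# Independent oracles and fixture generators shared by the suite. Each
# oracle is written from the definition, independently of the package's
# implementation path.

# brute-force ring membership: an edge is in a ring iff removing it leaves
# its endpoints connected (plain BFS, no igraph)
oracle_ring_edges <- function(mol) {
  b <- mol$bonds
  n <- n_atoms(mol)
  vapply(seq_len(nrow(b)), function(k) {
    keep <- b[-k, , drop = FALSE]
    adj <- lapply(seq_len(n), function(i)
      c(keep$atom_j[keep$atom_i == i], keep$atom_i[keep$atom_j == i]))
    src <- b$atom_i[k]; dst <- b$atom_j[k]
    seen <- rep(FALSE, n); seen[src] <- TRUE
    queue <- src
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    seen[dst]
  }, TRUE)
}

# independent simple-path enumerator with the single-atom ignore rule and
# both ring-termination semantics; returns the set of canonical descriptors
oracle_fragment_descriptors <- function(mol, max_len = 7L,
                                        ring_mode = "ring_system") {
  n <- n_atoms(mol)
  heavy <- mol$atoms$element != "H"
  b <- mol$bonds
  nbrs <- lapply(seq_len(n), function(i)
    c(b$atom_j[b$atom_i == i], b$atom_i[b$atom_j == i]))
  ring_edges <- oracle_ring_edges(mol)
  # ring systems by repeated merging over ring edges
  sys_id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (k in which(ring_edges)) {
      a <- sys_id[b$atom_i[k]]; d <- sys_id[b$atom_j[k]]
      if (a != d) { sys_id[sys_id == max(a, d)] <- min(a, d); changed <- TRUE }
    }
    if (!changed) break
  }
  in_ring_atom <- rep(FALSE, n)
  in_ring_atom[c(b$atom_i[ring_edges], b$atom_j[ring_edges])] <- TRUE
  sys_id[!in_ring_atom] <- 0L

  atok <- paste0(mol$atoms$element, ifelse(mol$atoms$aromatic, "a", ""),
                 ifelse(in_ring_atom, "R", ""))
  bond_of <- function(i, j) {
    which((b$atom_i == i & b$atom_j == j) | (b$atom_i == j & b$atom_j == i))
  }
  descs <- character()
  recurse <- function(path, exited) {
    k <- length(path)
    if (k > 1L || !(mol$atoms$element[path] %in% c("C", "O", "N"))) {
      toks <- atok[path[1L]]
      if (k > 1L) for (q in 2:k)
        toks <- c(toks, b$order[bond_of(path[q - 1L], path[q])], atok[path[q]])
      fwd <- paste(toks, collapse = "|")
      bwd <- paste(rev(toks), collapse = "|")
      descs <<- c(descs, min(fwd, bwd))
    }
    if (k == max_len) return()
    for (nxt in nbrs[[path[k]]]) {
      if (!heavy[nxt] || nxt %in% path) next
      ex2 <- exited
      if (ring_mode == "ring_system") {
        if (sys_id[nxt] > 0L && sys_id[nxt] %in% exited) next
        if (sys_id[path[k]] > 0L && sys_id[nxt] != sys_id[path[k]])
          ex2 <- union(exited, sys_id[path[k]])
      }
      recurse(c(path, nxt), ex2)
    }
  }
  for (a in which(heavy)) recurse(a, integer())
  sort(unique(descs))
}

# union-find partition over non-rotatable bonds
oracle_union_find_partition <- function(mol) {
  mol <- label_rotatable(mol)
  parent <- seq_len(n_atoms(mol))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in which(!mol$bonds$rotatable)) {
    ra <- find(mol$bonds$atom_i[k]); rb <- find(mol$bonds$atom_j[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n_atoms(mol)), find, 0L)
  unname(split(seq_len(n_atoms(mol)), roots))
}

# exhaustive pair-counting AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# random chemically-shaped molecule graphs: random tree plus optional extra
# ring-closing edges, random elements/orders (valence not enforced; these
# exercise graph algorithms, not chemistry)
random_molecule <- function(n, seed, p_extra = 0.25) {
  set.seed(seed)
  elements <- sample(c("C", "C", "C", "N", "O", "S", "Cl"), n, replace = TRUE)
  atoms <- data.frame(element = elements, aromatic = FALSE, charge = 0L,
                      n_h = 0L, stringsAsFactors = FALSE)
  if (n == 1L)
    return(molecule_graph(paste0("rnd", seed), atoms,
                          data.frame(atom_i = integer(), atom_j = integer(),
                                     order = character())))
  ai <- integer(); aj <- integer()
  for (v in 2:n) { ai <- c(ai, sample(v - 1L, 1L)); aj <- c(aj, v) }
  n_extra <- rbinom(1L, size = max(0L, n - 3L), prob = p_extra / max(1, n - 3))
  tries <- 0L
  while (n_extra > 0L && tries < 20L) {
    tries <- tries + 1L
    cand <- sort(sample(n, 2L))
    if (!any(ai == cand[1L] & aj == cand[2L])) {
      ai <- c(ai, cand[1L]); aj <- c(aj, cand[2L])
      n_extra <- n_extra - 1L
    }
  }
  orders <- sample(c("1", "1", "1", "2", "3"), length(ai), replace = TRUE)
  molecule_graph(paste0("rnd", seed), atoms,
                 data.frame(atom_i = ai, atom_j = aj, order = orders,
                            stringsAsFactors = FALSE))
}

# small pool of real SMILES for battery tests
smiles_battery <- c(
  "CCO", "c1ccccc1", "Cc1ccccc1", "CC(=O)O", "CC(=O)Oc1ccccc1C(=O)O",
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "C1CCCCC1", "c1ccncc1", "OCC(O)CO",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "NCCc1c[nH]c2ccccc12", "CSCC(N)C(=O)O",
  "c1ccc2ccccc2c1", "C1CCNCC1", "ClCCl", "C(F)(F)F", "CC#N", "CC=CC",
  "c1ccc(-c2ccccc2)cc1", "OC(=O)c1ccccc1O"
)

# one small trained model shared by expensive tests (memoized)
trained_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- synth_config(n_compounds = 60L, n_proteins = 12L, n_clusters = 4L,
                        seed = 11L, n_affinity = 600L, noise_sd = 0.3)
    lib <- gen_compound_library(cfg)
    prots <- gen_proteins(cfg)
    model <- planted_affinity_model(cfg, lib, prots)
    affy <- gen_affinity_data(cfg, lib, prots, model)
    anno <- gen_annotation_db(cfg, lib, prots, model)
    tcfg <- train_config(hidden = 16L, kernel = 7L, epochs = 40L, lr = 1e-3,
                         seed = 11L, batch_size = 8L, n_fc = 3L)
    fit <- cpi_train(affy$data, tcfg)
    cache <<- list(cfg = cfg, library = lib, proteins = prots,
                   planted = model, affinity = affy, annotation = anno,
                   fit = fit)
    cache
  }
})
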