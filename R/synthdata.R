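# Synthetic compound libraries, proteins, annotation databases and affinity
# data with planted structure.
#
# Compounds are scaffold decorations: every compound in a similarity cluster
# shares its cluster's scaffold, guaranteeing high within-cluster Tanimoto
# similarity and lower between-cluster similarity. Proteins are random
# 20-letter sequences with planted 5-mer motifs. Affinities follow a planted
# bilinear map: pKd = 6 + a*u*v + b*u + c*v + noise, where u is a fixed
# random projection of the compound's fingerprint bits and v a fixed random
# projection of the protein's motif 3-mer counts, both standardized over the
# generated population. The map's parameters are returned so tests can use
# the ground truth as an oracle scorer.

#' Synthetic-data configuration
#'
#' @param n_compounds library size (default 300).
#' @param n_proteins protein count (default 50).
#' @param seed master seed; fixes every downstream draw.
#' @param n_clusters planted similarity clusters (default 6).
#' @param scaffold_set sprintf templates with one `%s` substituent slot.
#' @param decoration_rules substituent SMILES vocabulary.
#' @param targets_per_cluster planted true targets per cluster (default 3).
#' @param dup_assay_frac fraction of annotation interactions duplicated
#'   under a second assay id (default 0.3), exercising the multi-assay
#'   confidence rule.
#' @param noise_sd Gaussian noise on planted pKd (default 0.3).
#' @param n_affinity affinity triples to generate (default 2000).
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_compounds = 300L, n_proteins = 50L, seed = 1L,
                         n_clusters = 6L,
                         scaffold_set = default_scaffolds(),
                         decoration_rules = default_decorations(),
                         targets_per_cluster = 3L,
                         dup_assay_frac = 0.3, noise_sd = 0.3,
                         n_affinity = 2000L) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(list(n_compounds = as.integer(n_compounds),
                 n_proteins = as.integer(n_proteins), seed = as.integer(seed),
                 n_clusters = as.integer(n_clusters),
                 scaffold_set = scaffold_set,
                 decoration_rules = decoration_rules,
                 targets_per_cluster = as.integer(targets_per_cluster),
                 dup_assay_frac = dup_assay_frac, noise_sd = noise_sd,
                 n_affinity = as.integer(n_affinity)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_scaffolds <- function() c(
  "c1ccc(%s)cc1",            # benzene
  "C1CCC(%s)CC1",            # cyclohexane
  "c1ccnc(%s)c1",            # pyridine
  "c1ccc2cc(%s)ccc2c1",      # naphthalene
  "C1CCN(%s)CC1",            # piperidine
  "c1ccc(-c2ccc(%s)cc2)cc1", # biphenyl
  "C1CCOC(%s)C1",            # oxane
  "c1cc2ccccc2n1%s"          # indolizine-like fused N-heterocycle
)

#' @rdname synth_config
#' @export
default_decorations <- function() c(
  "C", "CC", "CCC", "CCCC", "C(C)C", "CO", "CCO", "OC", "OCC", "N", "NC",
  "CN", "CCN", "F", "Cl", "Br", "S", "SC", "C=C", "CC=C", "CC(=O)O",
  "CC(=O)N", "C(=O)OC", "CS", "COC", "CCCl", "CCS", "C(C)O", "CC(C)C",
  "CCOC", "CNC", "CCNC", "OCCO", "C(=O)C", "CC(=O)C", "SCC", "NCC",
  "CC(N)C", "COCC", "CCCO", "CC(O)C", "C(F)F", "CCF", "CCCN", "OC(C)C",
  "NC(C)C", "CSC", "CC(=O)OC", "CCC(=O)O", "CCCC(=O)O"
)

#' Generate the synthetic compound library
#'
#' @param cfg a [synth_config()].
#' @return list of `mol_graph`; each carries `$smiles` and `$cluster`
#'   (planted cluster index). Same seed, same library.
#' @export
gen_compound_library <- function(cfg = synth_config()) {
  set.seed(derive_seed(cfg$seed, 1L))
  scaf <- cfg$scaffold_set[((seq_len(cfg$n_clusters) - 1L) %%
                              length(cfg$scaffold_set)) + 1L]
  # validate scaffolds once
  for (s in scaf)
    tryCatch(parse_smiles(sprintf(s, "C")),
             error = function(e) stopf("invalid scaffold SMILES '%s': %s",
                                       s, conditionMessage(e)))
  clusters <- rep(seq_len(cfg$n_clusters), length.out = cfg$n_compounds)
  mols <- vector("list", cfg$n_compounds)
  seen <- character()
  for (i in seq_len(cfg$n_compounds)) {
    cl <- clusters[i]
    repeat {
      dec <- sample(cfg$decoration_rules, 1L)
      smi <- sprintf(scaf[cl], dec)
      if (!smi %in% seen || length(seen) >= cfg$n_clusters * length(cfg$decoration_rules)) break
    }
    seen <- c(seen, smi)
    id <- sprintf("CPD%04d", i)
    m <- parse_smiles(smi, mol_id = id)
    m$smiles <- smi
    m$cluster <- cl
    mols[[i]] <- m
  }
  mols
}

MOTIF_SET <- c("WWKHR", "HHYDE", "KRWCM", "YFDQW", "MWHKY", "DECWH",
               "RYWMK", "QHWED")

#' Generate synthetic protein sequences with planted motifs
#'
#' Random sequences over the 20-letter alphabet; protein i carries motif
#' `MOTIF_SET[(i - 1) %% 8 + 1]` inserted three times, giving the affinity
#' model a recoverable sequence signal.
#'
#' @param cfg a [synth_config()].
#' @return list of `protein_seq`, each with a `motif` element.
#' @export
gen_proteins <- function(cfg = synth_config()) {
  set.seed(derive_seed(cfg$seed, 2L))
  lapply(seq_len(cfg$n_proteins), function(i) {
    L <- sample(120:240, 1L)
    aa <- sample(AA20, L, replace = TRUE)
    motif <- MOTIF_SET[((i - 1L) %% length(MOTIF_SET)) + 1L]
    for (rep_ in 1:3) {
      pos <- sample(L - nchar(motif), 1L)
      aa[pos:(pos + nchar(motif) - 1L)] <- strsplit(motif, "")[[1L]]
    }
    p <- protein_seq(sprintf("PRT%03d", i), paste(aa, collapse = ""))
    p$motif <- motif
    p
  })
}

# 3-mer dictionary spanned by the motif set
motif_kmer_dict <- function(k = 3L) {
  kms <- unlist(lapply(MOTIF_SET, function(m) {
    vapply(seq_len(nchar(m) - k + 1L), function(s) substr(m, s, s + k - 1L), "")
  }))
  sort(unique(kms))
}

kmer_counts <- function(sequence, dict) {
  k <- nchar(dict[1L])
  L <- nchar(sequence)
  if (L < k) return(numeric(length(dict)))
  kms <- vapply(seq_len(L - k + 1L), function(s) substr(sequence, s, s + k - 1L), "")
  as.numeric(table(factor(kms, levels = dict)))
}

#' The planted bilinear affinity model
#'
#' Draws the projection vectors from the config seed and standardizes the
#' compound and protein projections over the supplied populations.
#'
#' @param cfg a [synth_config()].
#' @param library compound library from [gen_compound_library()].
#' @param proteins proteins from [gen_proteins()].
#' @return an `affinity_model`: parameters plus `score(mol, protein)`
#'   returning the noise-free planted pKd.
#' @export
planted_affinity_model <- function(cfg, library, proteins) {
  set.seed(derive_seed(cfg$seed, 3L))
  dict <- motif_kmer_dict()
  w_fp <- rnorm(FP_NBITS)
  w_k <- rnorm(length(dict))
  u_raw <- vapply(library, function(m) sum(fingerprint(m)$bits * w_fp), 0)
  v_raw <- vapply(proteins, function(p) sum(kmer_counts(p$sequence, dict) * w_k), 0)
  um <- mean(u_raw); us <- max(sd(u_raw), 1e-9)
  vm <- mean(v_raw); vs <- max(sd(v_raw), 1e-9)
  coef <- c(inter = 0.8, main_u = 0.4, main_v = 0.4, base = 6)
  model <- list(dict = dict, w_fp = w_fp, w_k = w_k,
                u_center = um, u_scale = us, v_center = vm, v_scale = vs,
                coef = coef)
  model$score <- function(mol, protein) {
    seqc <- if (inherits(protein, "protein_seq")) protein$sequence else protein
    u <- (sum(fingerprint(mol)$bits * w_fp) - um) / us
    v <- (sum(kmer_counts(seqc, dict) * w_k) - vm) / vs
    unname(coef["base"] + coef["inter"] * u * v +
             coef["main_u"] * u + coef["main_v"] * v)
  }
  structure(model, class = "affinity_model")
}

#' Generate the annotation database with planted truth
#'
#' Each cluster's true targets are the proteins with the highest mean
#' planted affinity over the cluster's compounds. Every record has Kd > 0
#' (nM, from the planted pKd) and a `dup_assay_frac` fraction of
#' interactions is duplicated under a second assay id.
#'
#' @param cfg a [synth_config()].
#' @param library compound library.
#' @param proteins protein list.
#' @param model optional [planted_affinity_model()] (recomputed if missing).
#' @return list: `records` (data.frame compound_id, smiles, target_id,
#'   target_sequence, affinity_value \[Kd nM\], measure_type, assay_id,
#'   target_type), `truth` (compound_id -> true target ids), `model`.
#' @export
gen_annotation_db <- function(cfg, library, proteins, model = NULL) {
  if (length(library) == 0L || length(proteins) == 0L)
    stopf("library and protein list must be nonempty")
  if (is.null(model)) model <- planted_affinity_model(cfg, library, proteins)
  set.seed(derive_seed(cfg$seed, 4L))
  pseq <- vapply(proteins, function(p) p$sequence, "")
  pids <- vapply(proteins, function(p) p$prot_id, "")
  clusters <- vapply(library, function(m) m$cluster, 0L)
  # mean planted affinity of each cluster against each protein
  aff <- matrix(0, cfg$n_clusters, length(proteins))
  for (cl in seq_len(cfg$n_clusters)) {
    members <- library[clusters == cl]
    probe <- members[seq_len(min(5L, length(members)))]  # cluster profile
    for (pj in seq_along(proteins))
      aff[cl, pj] <- mean(vapply(probe, function(m) model$score(m, proteins[[pj]]), 0))
  }
  cluster_targets <- lapply(seq_len(cfg$n_clusters), function(cl)
    pids[order(-aff[cl, ])[seq_len(cfg$targets_per_cluster)]])
  rows <- list()
  assay_counter <- 0L
  for (i in seq_along(library)) {
    m <- library[[i]]
    for (tid in cluster_targets[[m$cluster]]) {
      pj <- match(tid, pids)
      pkd <- model$score(m, proteins[[pj]]) + rnorm(1L, sd = cfg$noise_sd)
      kd_nm <- 10^(9 - pkd)
      assay_counter <- assay_counter + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = m$mol_id, smiles = m$smiles, target_id = tid,
        target_sequence = pseq[pj], affinity_value = kd_nm,
        measure_type = "Kd", assay_id = sprintf("ASSAY%05d", assay_counter),
        target_type = "SINGLE PROTEIN", stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  # duplicate a fraction of interactions under a second assay
  ndup <- round(cfg$dup_assay_frac * nrow(records))
  if (ndup > 0L) {
    dup_rows <- sample(nrow(records), ndup)
    dups <- records[dup_rows, , drop = FALSE]
    dups$assay_id <- sprintf("ASSAY%05d", assay_counter + seq_len(ndup))
    dups$affinity_value <- dups$affinity_value * runif(ndup, 0.5, 2)
    records <- rbind(records, dups)
    attr(records, "dup_interactions") <-
      paste(dups$compound_id, dups$target_id, sep = "::")
  } else attr(records, "dup_interactions") <- character()
  truth <- setNames(lapply(library, function(m) cluster_targets[[m$cluster]]),
                    vapply(library, function(m) m$mol_id, ""))
  list(records = records, truth = truth, model = model,
       cluster_targets = cluster_targets)
}

#' Generate affinity training data from the planted model
#'
#' @param cfg a [synth_config()].
#' @param library compound library.
#' @param proteins protein list.
#' @param model optional [planted_affinity_model()].
#' @return list: `data` (list of `list(mol, protein, affinity)` examples
#'   ready for [cpi_train()]), `table` (data.frame view), `model`.
#' @export
gen_affinity_data <- function(cfg, library, proteins, model = NULL) {
  if (is.null(model)) model <- planted_affinity_model(cfg, library, proteins)
  set.seed(derive_seed(cfg$seed, 5L))
  n <- cfg$n_affinity
  ci <- sample(length(library), n, replace = TRUE)
  pi_ <- sample(length(proteins), n, replace = TRUE)
  pkd <- vapply(seq_len(n), function(q)
    model$score(library[[ci[q]]], proteins[[pi_[q]]]), 0) +
    rnorm(n, sd = cfg$noise_sd)
  data <- lapply(seq_len(n), function(q)
    list(mol = library[[ci[q]]], protein = proteins[[pi_[q]]],
         affinity = pkd[q]))
  tab <- data.frame(
    compound_id = vapply(library[ci], function(m) m$mol_id, ""),
    smiles = vapply(library[ci], function(m) m$smiles, ""),
    prot_id = vapply(proteins[pi_], function(p) p$prot_id, ""),
    sequence = vapply(proteins[pi_], function(p) p$sequence, ""),
    affinity = pkd, stringsAsFactors = FALSE)
  list(data = data, table = tab, model = model)
}

#' Generate and write a complete synthetic suite
#'
#' Emits `library.smi`, `proteins.fasta`, `anno.tsv`, `affinities.tsv` and
#' `truth.json` under `dir`.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with the in-memory objects.
#' @export
gen_synth_suite <- function(cfg = synth_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- gen_compound_library(cfg)
  prots <- gen_proteins(cfg)
  model <- planted_affinity_model(cfg, lib, prots)
  anno <- gen_annotation_db(cfg, lib, prots, model)
  affy <- gen_affinity_data(cfg, lib, prots, model)
  write_smi(vapply(lib, function(m) m$smiles, ""),
            vapply(lib, function(m) m$mol_id, ""),
            file.path(dir, "library.smi"))
  write_fasta(prots, file.path(dir, "proteins.fasta"))
  write.table(anno$records, file.path(dir, "anno.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(affy$table, file.path(dir, "affinities.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(anno$truth, file.path(dir, "truth.json"))
  invisible(list(library = lib, proteins = prots, model = model,
                 annotation = anno, affinity = affy))
}
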