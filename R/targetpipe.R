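# End-to-end target identification pipeline:
# query -> bait compounds (2D union 3D similarity) -> annotated targets of
# the baits -> affinity ranking by the interaction network -> confidence by
# the multi-assay rule -> JSON/TSV report.

#' Load and validate an annotation database
#'
#' Tab-separated columns: `compound_id`, `smiles`, `target_id`,
#' `target_sequence`, `affinity_value`, `measure_type`, `assay_id`, and
#' optionally `target_type`. Ingest filters: rows with `target_type` other
#' than `"SINGLE PROTEIN"` are dropped; Kd rows must have
#' `affinity_value > 0`; target sequences must be nonempty.
#'
#' @param x a TSV path or a data.frame with the columns above.
#' @return validated data.frame of interaction records.
#' @export
read_annotation_db <- function(x) {
  rec <- if (is.data.frame(x)) x
         else read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound_id", "smiles", "target_id", "target_sequence",
            "affinity_value", "measure_type", "assay_id")
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0L)
    stopf("annotation db missing column(s): %s", paste(miss, collapse = ", "))
  if ("target_type" %in% names(rec)) {
    drop <- rec$target_type != "SINGLE PROTEIN"
    if (any(drop)) {
      message(sprintf("dropping %d record(s) with target_type != 'SINGLE PROTEIN'",
                      sum(drop)))
      rec <- rec[!drop, , drop = FALSE]
    }
  }
  bad_kd <- rec$measure_type == "Kd" & !(rec$affinity_value > 0)
  if (any(bad_kd)) {
    message(sprintf("dropping %d Kd record(s) with non-positive affinity", sum(bad_kd)))
    rec <- rec[!bad_kd, , drop = FALSE]
  }
  if (any(!nzchar(rec$target_sequence)))
    stopf("annotation db has empty target sequence(s)")
  rownames(rec) <- NULL
  rec
}

#' Find bait compounds for a query
#'
#' Union of the 2D fingerprint arm (Tc >= `tc_min`) and the 3D pharmacophore
#' arm (overlap >= `min_overlap`), deduplicated by mol_id keeping both
#' scores. Queries above the pharmacophore size cap fall back to 2D only
#' with a notice.
#'
#' @param query a `mol_graph`.
#' @param fpindex a `fp_index` (or NULL).
#' @param phdb a `pharma_db` (or NULL).
#' @param tc_min 2D threshold (default 0.85).
#' @param min_overlap 3D threshold (default 0.5).
#' @param k_conformers query conformers for the 3D arm (default 10).
#' @param seed seed for query conformers.
#' @return data.frame `mol_id`, `tc`, `pharmacophore_score` (NA where an arm
#'   did not score the molecule), sorted by best available score; attribute
#'   `notices` carries any fallback message.
#' @export
find_baits <- function(query, fpindex = NULL, phdb = NULL, tc_min = 0.85,
                       min_overlap = 0.5, k_conformers = 10L, seed = 1L) {
  if (is.null(fpindex) && is.null(phdb))
    stopf("at least one of fpindex / phdb is required")
  notices <- character()
  hits2d <- if (!is.null(fpindex))
    search_2d(fingerprint(query, max_len = fpindex$build_params$max_len,
                          ring_mode = fpindex$build_params$ring_mode,
                          include_h = fpindex$build_params$include_h),
              fpindex, tc_min = tc_min)
  else data.frame(mol_id = character(), tc = numeric())
  hits3d <- if (!is.null(phdb)) {
    h <- search_3d(query, phdb, k_conformers = k_conformers,
                   min_overlap = min_overlap, seed = seed)
    if (!isTRUE(attr(h, "performed"))) notices <- c(notices, attr(h, "notice"))
    h
  } else data.frame(mol_id = character(), score = numeric())
  ids <- union(hits2d$mol_id, hits3d$mol_id)
  out <- data.frame(mol_id = ids,
                    tc = hits2d$tc[match(ids, hits2d$mol_id)],
                    pharmacophore_score = hits3d$score[match(ids, hits3d$mol_id)],
                    stringsAsFactors = FALSE)
  best <- pmax(ifelse(is.na(out$tc), -Inf, out$tc),
               ifelse(is.na(out$pharmacophore_score), -Inf, out$pharmacophore_score))
  out <- out[order(-best, out$mol_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "notices") <- notices
  out
}

#' Retrieve annotated targets of the bait compounds
#'
#' @param baits data.frame from [find_baits()] (needs `mol_id`).
#' @param annodb validated records from [read_annotation_db()].
#' @param exclude_self drop records whose compound is the query itself
#'   (leave-self-out evaluation mode); never enlarges the candidate set.
#' @param query_id the query's id, used by `exclude_self`.
#' @return data.frame of candidate targets: `target_id`, `target_sequence`,
#'   `n_assays` (distinct assays supporting any bait-target link),
#'   `n_baits`, `best_tc`, `best_pharmacophore`, `supporting_baits`
#'   (list column of bait mol_ids).
#' @export
retrieve_targets <- function(baits, annodb, exclude_self = FALSE,
                             query_id = NULL) {
  rec <- annodb[annodb$compound_id %in% baits$mol_id, , drop = FALSE]
  if (exclude_self && !is.null(query_id))
    rec <- rec[rec$compound_id != query_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    return(data.frame(target_id = character(), target_sequence = character(),
                      n_assays = integer(), n_baits = integer(),
                      best_tc = numeric(), best_pharmacophore = numeric()))
  tids <- unique(rec$target_id)
  rows <- lapply(tids, function(tid) {
    sub <- rec[rec$target_id == tid, , drop = FALSE]
    bsel <- baits[baits$mol_id %in% sub$compound_id, , drop = FALSE]
    out <- data.frame(
      target_id = tid, target_sequence = sub$target_sequence[1L],
      n_assays = length(unique(sub$assay_id)),
      n_baits = length(unique(sub$compound_id)),
      best_tc = if (all(is.na(bsel$tc))) NA_real_ else max(bsel$tc, na.rm = TRUE),
      best_pharmacophore = if (all(is.na(bsel$pharmacophore_score))) NA_real_
                           else max(bsel$pharmacophore_score, na.rm = TRUE),
      stringsAsFactors = FALSE)
    out$supporting_baits <- list(unique(sub$compound_id))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank candidate targets for a query compound
#'
#' Each candidate is scored against the query by the interaction network (or
#' any scorer function); candidates are sorted by score descending, ties by
#' target_id. Confidence is `"high"` iff the candidate is supported by more
#' than one distinct assay, else `"low"`.
#'
#' @param query a `mol_graph`.
#' @param candidates data.frame from [retrieve_targets()].
#' @param model a `cpi_model`, or a function `(mol, sequence) -> score`.
#' @return candidates with `score`, `affinity` (NA for function scorers),
#'   `confidence` and `rank` columns, sorted.
#' @export
rank_targets <- function(query, candidates, model) {
  n <- nrow(candidates)
  if (n == 0L) {
    candidates$score <- numeric(0); candidates$affinity <- numeric(0)
    candidates$confidence <- character(0); candidates$rank <- integer(0)
    return(candidates)
  }
  score <- rep(NA_real_, n); affinity <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      if (is.function(model)) {
        s <- model(query, candidates$target_sequence[i])
        list(score = s, affinity = NA_real_)
      } else {
        p <- cpi_predict(model, query, candidates$target_sequence[i])
        list(score = p$score, affinity = p$affinity)
      }
    }, error = function(e) {
      warnf("skipping target %s: %s", candidates$target_id[i],
            conditionMessage(e))
      NULL
    })
    if (!is.null(res)) { score[i] <- res$score; affinity[i] <- res$affinity }
  }
  candidates$score <- score
  candidates$affinity <- affinity
  candidates$confidence <- ifelse(candidates$n_assays > 1L, "high", "low")
  keep <- which(!is.na(candidates$score))
  candidates <- candidates[keep[order(-score[keep], candidates$target_id[keep])], ,
                           drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}

#' Run the full target-identification pipeline
#'
#' @param query a `mol_graph` (or SMILES string).
#' @param config list with elements `fpindex`, `phdb`, `annodb`, `model`
#'   (objects or file paths), and optional parameters `tc_min` (0.85),
#'   `min_overlap` (0.5), `k_conformers` (10), `exclude_self` (FALSE),
#'   `seed` (1).
#' @return a `drift_report`: list with sections `query`, `params`,
#'   `compounds` (baits), `targets` (ranked predictions), `fragments` (Zipf
#'   frequency profile over query + baits), `notices`. Fully reproducible
#'   from config + seed.
#' @export
run_pipeline <- function(query, config) {
  if (is.character(query)) query <- read_molecule(query)
  fpindex <- resource(config$fpindex, read_fp_index, "fpindex")
  phdb <- resource(config$phdb, read_pharma_db, "phdb")
  if (is.null(fpindex) && is.null(phdb))
    stopf("missing resource: need fpindex and/or phdb")
  if (is.null(config$annodb)) stopf("missing resource: annodb")
  annodb <- read_annotation_db(config$annodb)
  if (is.null(config$model)) stopf("missing resource: model")
  model <- if (is.character(config$model)) load_checkpoint(config$model)
           else config$model
  p <- list(tc_min = config$tc_min %||% 0.85,
            min_overlap = config$min_overlap %||% 0.5,
            k_conformers = config$k_conformers %||% 10L,
            exclude_self = isTRUE(config$exclude_self),
            seed = config$seed %||% 1L)
  baits <- find_baits(query, fpindex, phdb, tc_min = p$tc_min,
                      min_overlap = p$min_overlap,
                      k_conformers = p$k_conformers, seed = p$seed)
  notices <- attr(baits, "notices") %||% character()
  candidates <- retrieve_targets(baits, annodb,
                                 exclude_self = p$exclude_self,
                                 query_id = query$mol_id)
  targets <- rank_targets(query, candidates, model)
  if (nrow(targets) == 0L)
    notices <- c(notices, "no targets found: bait set or annotation overlap is empty")
  pool_ids <- c(query$mol_id, baits$mol_id)
  pool <- c(list(query), lapply(baits$mol_id, function(id) {
    row <- match(id, annodb$compound_id)
    if (is.na(row)) NULL else parse_smiles(annodb$smiles[row], mol_id = id)
  }))
  pool <- Filter(Negate(is.null), pool)
  fragments <- fragment_frequencies(pool)
  structure(list(query = list(mol_id = query$mol_id, n_atoms = n_atoms(query)),
                 params = p,
                 compounds = baits,
                 targets = targets,
                 fragments = fragments,
                 notices = notices),
            class = "drift_report")
}

resource <- function(x, loader, what) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    if (!file.exists(x)) stopf("missing resource: %s file '%s'", what, x)
    return(loader(x))
  }
  x
}

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("<drift_report> query %s: %d baits, %d ranked targets, %d fragment keys\n",
              x$query$mol_id, nrow(x$compounds), nrow(x$targets),
              nrow(x$fragments)))
  if (length(x$notices) > 0L) cat(" notices:", paste(x$notices, collapse = "; "), "\n")
  invisible(x)
}

#' Write a pipeline report to JSON + TSV
#'
#' `<stem>.json` holds the full report; `<stem>.tsv` the targets table
#' (target_id, score, confidence, n_baits, best_tc).
#'
#' @param report a `drift_report`.
#' @param stem output path stem (without extension).
#' @return character vector of the two paths, invisibly.
#' @export
write_report <- function(report, stem) {
  jpath <- paste0(stem, ".json")
  tpath <- paste0(stem, ".tsv")
  rep2 <- unclass(report)
  rep2$compounds <- report$compounds
  rep2$targets <- report$targets
  if (nrow(rep2$targets) > 0L)
    rep2$targets$supporting_baits <- vapply(
      rep2$targets$supporting_baits, paste, "", collapse = ",")
  jsonlite::write_json(rep2, jpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  tcols <- c("target_id", "score", "confidence", "n_baits", "best_tc")
  tdf <- if (nrow(report$targets) > 0L) report$targets[, tcols]
         else setNames(data.frame(matrix(ncol = 5L, nrow = 0L)), tcols)
  write.table(tdf, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(jpath, tpath))
}

#' Validate a report against the published schema
#'
#' Checks the section layout of a report (or its JSON file) against the
#' schema shipped at `inst/extdata/report-schema.json`: required sections,
#' required fields of each targets/compounds row, and value types.
#'
#' @param x a `drift_report` or path to a report JSON.
#' @return TRUE (invisibly) or an error describing the violation.
#' @export
validate_report <- function(x) {
  rep <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else x
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "driftr"),
                                simplifyVector = TRUE)
  for (sec in schema$required) {
    if (is.null(rep[[sec]])) stopf("report is missing section '%s'", sec)
  }
  tgt <- rep$targets
  if (!is.null(tgt) && length(tgt) > 0L && NROW(tgt) > 0L) {
    tdf <- as.data.frame(tgt)
    for (f in schema$properties$targets$required_fields)
      if (!f %in% names(tdf)) stopf("targets section is missing field '%s'", f)
    if (!all(tdf$confidence %in% c("high", "low")))
      stopf("targets confidence must be 'high' or 'low'")
  }
  cmp <- rep$compounds
  if (!is.null(cmp) && NROW(cmp) > 0L) {
    cdf <- as.data.frame(cmp)
    for (f in schema$properties$compounds$required_fields)
      if (!f %in% names(cdf)) stopf("compounds section is missing field '%s'", f)
  }
  invisible(TRUE)
}
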