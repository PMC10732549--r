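# small deterministic fixture for pipeline-level tests
pipe_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- synth_config(n_compounds = 30L, n_proteins = 10L, n_clusters = 3L,
                        seed = 5L, n_affinity = 60L)
    lib <- gen_compound_library(cfg)
    prots <- gen_proteins(cfg)
    planted <- planted_affinity_model(cfg, lib, prots)
    anno <- gen_annotation_db(cfg, lib, prots, planted)
    cache <<- list(cfg = cfg, lib = lib, prots = prots, planted = planted,
                   anno = anno,
                   fpindex = build_index(lib),
                   phdb = build_pharma_db(lib, k = 3L, seed = 2L),
                   records = read_annotation_db(anno$records),
                   scorer = function(mol, seqn) planted$score(mol, seqn))
    cache
  }
})

test_that("annotation ingest validates columns and applies the Kd / target-type filters", {
  fx <- pipe_fixture()
  rec <- fx$anno$records
  expect_error(read_annotation_db(rec[, -3]), "missing column")
  bad <- rec
  bad$affinity_value[1] <- -5
  expect_message(got <- read_annotation_db(bad), "non-positive")
  expect_equal(nrow(got), nrow(rec) - 1L)
  mixed <- rec
  mixed$target_type[2] <- "PROTEIN COMPLEX"
  expect_message(got2 <- read_annotation_db(mixed), "SINGLE PROTEIN")
  expect_equal(nrow(got2), nrow(rec) - 1L)
  # loading from a TSV file gives the same records
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_annotation_db(path)$compound_id, rec$compound_id)
})

test_that("bait finding unions the 2D and 3D arms and keeps both scores", {
  fx <- pipe_fixture()
  q <- fx$lib[[1]]
  baits <- find_baits(q, fx$fpindex, fx$phdb, tc_min = 0.4, min_overlap = 0.4,
                      k_conformers = 3L, seed = 2L)
  expect_true(q$mol_id %in% baits$mol_id)
  self <- baits[baits$mol_id == q$mol_id, ]
  expect_equal(self$tc, 1.0)
  h2d <- search_2d(fingerprint(q), fx$fpindex, tc_min = 0.4)
  h3d <- search_3d(q, fx$phdb, k_conformers = 3L, min_overlap = 0.4, seed = 2L)
  expect_setequal(baits$mol_id, union(h2d$mol_id, h3d$mol_id))
  expect_error(find_baits(q, NULL, NULL), "at least one")
  big <- read_molecule(paste(rep("C", 60), collapse = ""), mol_id = "big")
  b2 <- find_baits(big, fx$fpindex, fx$phdb, tc_min = 0)
  expect_match(attr(b2, "notices"), "no pharmacophore search performed")
  expect_true(all(is.na(b2$pharmacophore_score)))
})

test_that("target retrieval groups by target with assay counts and provenance", {
  fx <- pipe_fixture()
  q <- fx$lib[[1]]
  baits <- find_baits(q, fx$fpindex, NULL, tc_min = 0.5)
  cand <- retrieve_targets(baits, fx$records)
  expect_true(all(cand$n_assays >= 1L))
  expect_true(all(cand$n_baits >= 1L))
  expect_true(all(vapply(cand$supporting_baits, function(b)
    all(b %in% baits$mol_id), TRUE)))
  # two baits sharing a target merge into one candidate
  expect_false(anyDuplicated(cand$target_id) > 0)
  # exclude_self never increases the candidate set
  cand2 <- retrieve_targets(baits, fx$records, exclude_self = TRUE,
                            query_id = q$mol_id)
  expect_true(all(cand2$target_id %in% cand$target_id))
  expect_lte(sum(cand2$n_assays), sum(cand$n_assays))
  # empty bait set is legal
  none <- retrieve_targets(data.frame(mol_id = character()), fx$records)
  expect_equal(nrow(none), 0L)
})

test_that("target ranking sorts by score and applies the multi-assay confidence rule", {
  fx <- pipe_fixture()
  q <- fx$lib[[4]]
  baits <- find_baits(q, fx$fpindex, NULL, tc_min = 0.5)
  cand <- retrieve_targets(baits, fx$records)
  ranked <- rank_targets(q, cand, fx$scorer)
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_true(all(diff(ranked$score) <= 0))
  expect_setequal(ranked$target_id, cand$target_id)
  expect_equal(ranked$confidence, ifelse(ranked$n_assays > 1L, "high", "low"))
  # confidence boundary: exactly the multi-assay candidates are high
  expect_true(all(ranked$confidence[ranked$n_assays == 1L] == "low"))
  expect_true(all(ranked$confidence[ranked$n_assays >= 2L] == "high"))
})

test_that("a failing candidate is skipped with a warning, not silently dropped", {
  fx <- pipe_fixture()
  q <- fx$lib[[1]]
  cand <- retrieve_targets(find_baits(q, fx$fpindex, NULL, tc_min = 0.5),
                           fx$records)
  flaky <- function(mol, seqn) {
    if (seqn == cand$target_sequence[1]) stop("encoding failure")
    fx$scorer(mol, seqn)
  }
  expect_warning(ranked <- rank_targets(q, cand, flaky), "skipping target")
  expect_equal(nrow(ranked), nrow(cand) - 1L)
})

test_that("the full pipeline produces a valid, reproducible report", {
  fx <- pipe_fixture()
  config <- list(fpindex = fx$fpindex, phdb = fx$phdb, annodb = fx$records,
                 model = fx$scorer, tc_min = 0.85, min_overlap = 0.5,
                 k_conformers = 3L, seed = 2L)
  rep1 <- run_pipeline(fx$lib[[2]], config)
  expect_s3_class(rep1, "drift_report")
  expect_true(validate_report(rep1))
  # every reported target is reachable through a bait (no orphans)
  bait_ids <- rep1$compounds$mol_id
  expect_true(all(vapply(rep1$targets$supporting_baits, function(b)
    any(b %in% bait_ids), TRUE)))
  # determinism: identical runs give byte-identical reports
  rep2 <- run_pipeline(fx$lib[[2]], config)
  s1 <- withr::local_tempfile(); s2 <- withr::local_tempfile()
  write_report(rep1, s1); write_report(rep2, s2)
  expect_identical(readLines(paste0(s1, ".json")), readLines(paste0(s2, ".json")))
  expect_true(file.exists(paste0(s1, ".tsv")))
  expect_true(validate_report(paste0(s1, ".json")))
  # missing resources fail fast with the resource name
  expect_error(run_pipeline(fx$lib[[2]], list(model = fx$scorer,
                                              annodb = fx$records)),
               "fpindex|phdb")
  expect_error(run_pipeline(fx$lib[[2]], list(fpindex = fx$fpindex,
                                              annodb = fx$records)),
               "model")
  expect_error(run_pipeline(fx$lib[[2]], list(fpindex = fx$fpindex,
                                              model = fx$scorer)),
               "annodb")
})

test_that("a query with no similar compounds yields an empty-targets report with notice", {
  fx <- pipe_fixture()
  # a molecule far outside the library chemistry
  q <- read_molecule("BrC(Br)(Br)Br", mol_id = "exotic")
  config <- list(fpindex = fx$fpindex, annodb = fx$records, model = fx$scorer,
                 tc_min = 0.99)
  rep <- run_pipeline(q, config)
  expect_equal(nrow(rep$targets), 0L)
  expect_match(paste(rep$notices, collapse = " "), "no targets")
  expect_true(validate_report(rep))
})
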