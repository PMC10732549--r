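test_that("feature extraction follows the documented rules on toy molecules", {
  benz <- generate_conformers(read_molecule("c1ccccc1", mol_id = "benzene"),
                              k = 1L, seed = 3L)
  fb <- extract_features(benz)
  expect_equal(fb$kind, "aromatic")
  ctr <- colMeans(benz$conformers[[1]]$coords)
  expect_equal(c(fb$x, fb$y, fb$z), unname(ctr), tolerance = 1e-10)

  eth <- generate_conformers(read_molecule("CCO", mol_id = "ethanol"),
                             k = 1L, seed = 3L)
  fe <- extract_features(eth)
  expect_setequal(fe$kind, c("h-donor", "h-acceptor"))
  expect_true(all(vapply(fe$member_atoms, identical, TRUE, 3L)))  # the hydroxyl O

  met <- generate_conformers(read_molecule("C", mol_id = "methane"),
                             k = 1L, seed = 3L)
  expect_equal(nrow(extract_features(met)), 0L)
  expect_equal(extract_features(met, min_hydrophobic = 1L)$kind, "hydrophobic")
  expect_error(extract_features(read_molecule("CCO")), "no conformer")
})

test_that("charged atoms yield ionizable features", {
  m <- generate_conformers(read_molecule("C[N+](C)(C)C", mol_id = "tma"),
                           k = 1L, seed = 5L)
  expect_true("pos-ionizable" %in% extract_features(m)$kind)
  a <- generate_conformers(read_molecule("CC(=O)[O-]", mol_id = "acetate"),
                           k = 1L, seed = 5L)
  expect_true("neg-ionizable" %in% extract_features(a)$kind)
})

test_that("pharmacophore keys are deterministic, binned and size-robust", {
  empty <- pharmacophore_key(data.frame(kind = character(), x = numeric(),
                                        y = numeric(), z = numeric()))
  expect_false(any(empty$bits))
  feats <- data.frame(kind = c("h-donor", "aromatic", "hydrophobic"),
                      x = c(0, 4.2, 0), y = c(0, 0, 3), z = 0,
                      stringsAsFactors = FALSE)
  k1 <- pharmacophore_key(feats)
  expect_identical(k1$bits, pharmacophore_key(feats)$bits)
  # same 1-A bin (distances 4.2 vs 4.9 both fall in [4,5)) -> same key
  feats2 <- feats; feats2$x[2] <- 4.9
  expect_identical(pharmacophore_key(feats2)$bits, k1$bits)
  # different bin -> different key
  feats3 <- feats; feats3$x[2] <- 5.1
  expect_false(identical(pharmacophore_key(feats3)$bits, k1$bits))
  # < 3 features still sets bits (pairs/singletons)
  expect_gt(sum(pharmacophore_key(feats[1:2, ])$bits), 0L)
  expect_gt(sum(pharmacophore_key(feats[1, , drop = FALSE])$bits), 0L)
})

test_that("triplet hashing matches a brute-force triplet enumerator", {
  set.seed(21)
  for (rep_ in 1:5) {
    nf <- sample(3:5, 1L)
    feats <- data.frame(kind = sample(c("aromatic", "h-donor", "h-acceptor",
                                        "hydrophobic"), nf, replace = TRUE),
                        x = runif(nf, 0, 10), y = runif(nf, 0, 10),
                        z = runif(nf, 0, 10), stringsAsFactors = FALSE)
    key <- pharmacophore_key(feats)
    # oracle: enumerate all triplets independently, canonicalize by all 6
    # permutations, hash the same way
    D <- as.matrix(dist(feats[, c("x", "y", "z")]))
    bins <- function(d) as.integer(pmin(floor(d / 1.0), 20L))
    want <- logical(key$params$nbits)
    combs <- combn(nf, 3L)
    for (ci in seq_len(ncol(combs))) {
      t3 <- combs[, ci]
      cands <- character()
      for (p in list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))) {
        o <- t3[p]
        cands <- c(cands, paste("T", feats$kind[o[1]], feats$kind[o[2]],
                                feats$kind[o[3]], bins(D[o[1], o[2]]),
                                bins(D[o[1], o[3]]), bins(D[o[2], o[3]]),
                                sep = "|"))
      }
      want[as.integer(driftr:::fnv1a(min(cands)) %% key$params$nbits) + 1L] <- TRUE
    }
    expect_identical(key$bits, want)
  }
})

test_that("keys are invariant to rigid rotation and translation", {
  mol <- generate_conformers(read_molecule("NCCc1ccc(O)cc1", mol_id = "tyramine-like"),
                             k = 1L, seed = 8L)
  k1 <- pharmacophore_key(extract_features(mol))
  theta <- 0.83
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  rot <- mol
  rot$conformers[[1]]$coords <- mol$conformers[[1]]$coords %*% R +
    matrix(rep(c(5, -2, 11), each = n_atoms(mol)), ncol = 3)
  k2 <- pharmacophore_key(extract_features(rot))
  expect_identical(k1$bits, k2$bits)
})

test_that("3D search retrieves self at rank 1 and respects the size cap", {
  lib <- lapply(seq_along(smiles_battery[1:8]), function(i)
    read_molecule(smiles_battery[i], mol_id = sprintf("m%02d", i)))
  db <- build_pharma_db(lib, k = 3L, seed = 4L)
  hits <- search_3d(lib[[5]], db, k_conformers = 3L, min_overlap = 0.2, seed = 4L)
  expect_true(isTRUE(attr(hits, "performed")))
  expect_equal(hits$mol_id[1], "m05")
  expect_equal(hits$score[1], 1.0)
  expect_true(all(diff(hits$score) <= 0))
  big <- read_molecule(paste(rep("C", 55), collapse = ""), mol_id = "big")
  h2 <- search_3d(big, db)
  expect_false(attr(h2, "performed"))
  expect_match(attr(h2, "notice"), "no pharmacophore search performed")
  path <- withr::local_tempfile(fileext = ".phdb")
  write_pharma_db(db, path)
  db2 <- read_pharma_db(path)
  h3 <- search_3d(lib[[5]], db2, k_conformers = 3L, min_overlap = 0.2, seed = 4L)
  expect_equal(hits, h3, ignore_attr = TRUE)
})

test_that("retrieval never shrinks as conformer count grows (fixed seeds)", {
  lib <- lapply(seq_along(smiles_battery[1:10]), function(i)
    read_molecule(smiles_battery[i], mol_id = sprintf("m%02d", i)))
  db <- build_pharma_db(lib, k = 10L, seed = 6L)
  q <- lib[[10]]
  prev <- character()
  for (k in c(1L, 2L, 5L, 10L)) {
    hits <- search_3d(q, db, k_conformers = k, min_overlap = 0.3, seed = 6L)
    expect_true(all(prev %in% hits$mol_id),
                info = sprintf("k=%d lost hits from smaller k", k))
    prev <- hits$mol_id
  }
})
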