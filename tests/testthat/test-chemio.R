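test_that("SMILES parsing produces correct graphs for canonical cases", {
  m <- read_molecule("CCO")
  expect_equal(n_atoms(m), 3L)
  expect_equal(nrow(m$bonds), 2L)
  expect_false(any(m$atoms$in_ring))
  expect_false(any(m$bonds$in_ring))

  b <- read_molecule("c1ccccc1")
  expect_equal(n_atoms(b), 6L)
  expect_true(all(b$atoms$in_ring))
  expect_true(all(b$bonds$in_ring))
  expect_true(all(b$bonds$order == "ar"))
  expect_equal(b$atoms$n_h, rep(1L, 6L))

  caffeine <- read_molecule("Cn1cnc2c1c(=O)n(C)c(=O)n2C")
  expect_equal(n_atoms(caffeine), 14L)
  expect_equal(nrow(caffeine$bonds), 15L)
})

test_that("SMILES bracket atoms carry charge and explicit hydrogens", {
  m <- read_molecule("[NH4+].[Cl-]")
  expect_equal(m$atoms$charge, c(1L, -1L))
  expect_equal(m$atoms$n_h, c(4L, 0L))
  p <- read_molecule("c1cc[nH]c1")
  expect_equal(sum(p$atoms$element == "N"), 1L)
  expect_equal(p$atoms$n_h[p$atoms$element == "N"], 1L)
})

test_that("invalid SMILES produce structured errors naming the problem", {
  expect_error(read_molecule("C1CC"), "unclosed ring")
  expect_error(read_molecule(""), "empty")
  expect_error(read_molecule("C(("), "unclosed branch|unexpected")
  expect_error(read_molecule("CZq"), "position")
})

test_that("an aromatic bond written outside a ring is demoted to single", {
  # biphenyl written without the explicit single inter-ring bond
  m <- read_molecule("c1ccccc1c1ccccc1")
  bridge <- which(!m$bonds$in_ring)
  expect_length(bridge, 1L)
  expect_equal(m$bonds$order[bridge], "1")
})

test_that("SDF round trip preserves atoms, elements, bonds and orders", {
  for (smi in c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "C[N+](C)(C)C")) {
    m <- read_molecule(smi, mol_id = "probe")
    path <- withr::local_tempfile(fileext = ".sdf")
    write_sdf(m, path)
    m2 <- read_molecule(path, fmt = "sdf")
    expect_equal(n_atoms(m2), n_atoms(m))
    expect_equal(sort(m2$atoms$element), sort(m$atoms$element))
    expect_equal(m2$atoms$charge, m$atoms$charge)
    key <- function(x) sort(paste(pmin(x$bonds$atom_i, x$bonds$atom_j),
                                  pmax(x$bonds$atom_i, x$bonds$atom_j),
                                  x$bonds$order))
    expect_equal(key(m2), key(m))
  }
})

test_that("written SDF is readable by an independent SDF implementation", {
  skip_if_not_installed("ChemmineR")
  m <- read_molecule("CC(=O)Oc1ccccc1C(=O)O", mol_id = "aspirin")
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(m, path)
  sdfset <- ChemmineR::read.SDFset(path)
  expect_equal(length(sdfset), 1L)
  ab <- ChemmineR::atomblock(sdfset[[1]])
  bb <- ChemmineR::bondblock(sdfset[[1]])
  expect_equal(nrow(ab), n_atoms(m))
  expect_equal(nrow(bb), nrow(m$bonds))
  expect_equal(sort(gsub("_[0-9]+$", "", rownames(ab))),
               sort(m$atoms$element))
})

test_that("MOL2 round trip preserves the graph including aromatic orders", {
  m <- read_molecule("Cc1ccccc1O", mol_id = "cresol")
  path <- withr::local_tempfile(fileext = ".mol2")
  write_mol2(m, path)
  m2 <- read_molecule(path, fmt = "mol2")
  expect_equal(n_atoms(m2), n_atoms(m))
  expect_equal(sort(m2$atoms$element), sort(m$atoms$element))
  expect_equal(sum(m2$bonds$order == "ar"), sum(m$bonds$order == "ar"))
  expect_equal(m2$atoms$aromatic, m$atoms$aromatic)
})

test_that("ring perception matches the brute-force cycle-membership oracle", {
  for (seed in 1:40) {
    mol <- random_molecule(sample(2:12, 1L), seed = seed)
    expect_equal(mol$bonds$in_ring, oracle_ring_edges(mol),
                 info = paste("seed", seed))
  }
})

test_that("multi-record SDF and .smi files load every molecule", {
  mols <- lapply(c("CCO", "c1ccccc1"), read_molecule)
  mols[[1]]$mol_id <- "a"; mols[[2]]$mol_id <- "b"
  sdf <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(mols, sdf)
  back <- read_molecules(sdf)
  expect_equal(vapply(back, function(m) m$mol_id, ""), c("a", "b"))
  smi <- withr::local_tempfile(fileext = ".smi")
  write_smi(c("CCO", "c1ccccc1"), c("a", "b"), smi)
  back2 <- read_molecules(smi)
  expect_equal(n_atoms(back2[[2]]), 6L)
})

test_that("conformer generation is seeded, prefix-deterministic and capped", {
  eth <- read_molecule("CCO", mol_id = "ethanol")
  a <- generate_conformers(eth, k = 10L, seed = 7L)
  expect_length(a$conformers, 10L)
  b <- generate_conformers(eth, k = 10L, seed = 7L)
  expect_identical(a$conformers, b$conformers)
  one <- generate_conformers(eth, k = 1L, seed = 7L)
  expect_identical(one$conformers[[1]], a$conformers[[1]])
  expect_false(identical(a$conformers[[1]]$coords, a$conformers[[2]]$coords))
  expect_error(generate_conformers(eth, k = 0L, seed = 1L), "positive")
  big <- read_molecule(paste(rep("C", 51), collapse = ""), mol_id = "c51")
  expect_error(generate_conformers(big, k = 1L, seed = 1L), "exceeds max_atoms")
  # bond lengths near their ideal values after relaxation
  xyz <- a$conformers[[1]]$coords
  d12 <- sqrt(sum((xyz[1, ] - xyz[2, ])^2))
  expect_true(d12 > 1.0 && d12 < 2.1)
})

test_that("protein ingestion uppercases and preserves non-standard symbols", {
  p <- read_protein(">p1\nMKV")
  expect_equal(p$prot_id, "p1")
  expect_equal(p$sequence, "MKV")
  expect_equal(read_protein("mkv")$sequence, "MKV")
  expect_equal(read_protein("MKXV*")$sequence, "MKXV*")
  expect_error(read_protein(""), "empty")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(protein_seq("q1", "MKVL"), protein_seq("q2", "ACDE")), fa)
  back <- read_proteins(fa)
  expect_equal(vapply(back, function(x) x$prot_id, ""), c("q1", "q2"))
  expect_equal(read_protein(fa)$sequence, "MKVL")
})
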