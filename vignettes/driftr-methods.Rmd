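---
title: "Methods: chemical-similarity target identification with attention-based ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-similarity target identification with attention-based ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Most bioactive molecules bind proteins besides their intended target, and
those off-target interactions drive side effects and clinical failures.
`driftr` implements a ligand-based strategy for mapping the target
interaction space of a query compound: find annotated "bait" compounds that
are chemically similar to the query, collect the baits' experimentally
annotated protein targets as candidates, and rank those candidates with a
neural network that predicts compound-protein binding affinity from the
compound's graph and the protein's sequence. The package also identifies
which rigid fragments of the compound the network's attention associates
with binding.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic-data tests do and do
not establish.

# Compound searching

## 2D arm: path fingerprints and Tanimoto similarity

The 2D fingerprint indexes linear fragments (simple paths) of the heavy-atom
bond graph under four rules: (i) a fragment has at most 7 atoms; (ii)
single-atom fragments of C, O and N are ignored; (iii) duplicate fragments —
identical element / bond-order / ring-flag sequences after choosing the
lexicographically smaller read direction — are recorded once; (iv) fragments
terminate at ring structures. Each canonical fragment descriptor is hashed
(FNV-1a, a documented stable hash) modulo 1024 to set one bit of a 1024-bit
vector. No bit-level compatibility with other FP2 implementations is
promised or needed: retrieval behaviour, not the bit layout, is the
contract, and the hash is fixed so indexes are reproducible.

Rule (iv) is ambiguous on its own. The implemented default
(`ring_mode = "ring_system"`) lets a growing path run along ring bonds but
terminates it when the next atom would re-enter a ring system the path has
already left; `ring_mode = "closure"` only forbids revisiting atoms already
on the path. Both are exposed because the strict reading affects only
molecules where a path exits and re-approaches the same fused ring system.

Similarity is the Tanimoto coefficient `Tc = c / (a + b - c)` over set bits.
Two all-zero fingerprints (possible only for molecules with no eligible
fragments, e.g. methane in heavy-atom mode) compare as 1 with a warning: the
formula is 0/0 and the identity convention is the least surprising
completion. The default search threshold is `tc_min = 0.85`, the
conventional cutoff for calling two compounds structurally similar.

## 3D arm: conformers and pharmacophore keys

Pharmacophore features are extracted per conformer with documented rules:
one aromatic feature per aromatic ring at its centroid; O/N atoms with
hydrogens as donors; O atoms and H-free uncharged N atoms as acceptors;
formally charged atoms as positive/negative ionizable; connected clusters of
at least 2 non-aromatic carbons with no O/N neighbour as hydrophobic
centroids. Every unordered feature triplet (sorted kinds plus pairwise
distances binned at 1.0 Å, capped at 20 Å) is hashed into a 4096-bit key;
molecules with fewer than three features fall back to hashed pairs and
singletons so small molecules remain searchable. Keys depend only on
distances, hence are invariant to rigid motion. Bin width, cap and key
length are configurable; the defaults reflect typical pharmacophore distance
tolerances. A database molecule's score against a query is the maximum over
(query conformer, database conformer) pairs of the fraction of query key
bits shared, so retrieval is monotone in the number of conformers by
construction — the property the conformer-count experiments measure.

Conformers are generated by a seeded distance-geometry procedure: ideal
bond lengths (1.54/1.34/1.20/1.40 Å for single/double/triple/aromatic)
propagated along shortest paths give target distances, non-bonded targets
are jittered per conformer (a cheap stand-in for torsional sampling), the
matrix is embedded in 3D by classical multidimensional scaling, and a short
harmonic relaxation restores bond lengths and separates clashes. Everything
is derived from (seed, conformer index), so the first conformer of a k = 10
run equals the k = 1 conformer (prefix determinism) and runs are bit-stable.
These ensembles are geometric surrogates, not Boltzmann samples; they are
adequate for distance-binned key matching, which is the only consumer.
Molecules above `max_atoms = 50` are excluded from the pharmacophore arm
(the pipeline falls back to 2D with a notice), mirroring the size cap of the
reference database design.

# Fragmentation

Bonds in rings and bonds of order 2, 3 or aromatic are non-rotatable;
everything else is rotatable. Fragments are connected components of the
non-rotatable subgraph; the rotatable bonds between components are the cut
bonds. This is deliberately the strict two-rule algorithm: amide and
conjugated single bonds count as rotatable because no chemistry-aware
exceptions are stated, and adding them would change fragment identity
downstream. Bonds to explicit hydrogens are non-rotatable by default
(`h_bonds_rigid = TRUE`) so explicit-H inputs fragment like their implicit-H
SMILES equivalents.

Cross-molecule fragment identity (for the frequency/Zipf ranking) needs a
canonical form the algorithm statement does not define. The package uses
three rounds of Morgan-style neighbourhood refinement over
(element, aromatic, ring) labels and concatenates the sorted refined labels
with the sorted edge descriptors. For the small clusters rotatable-bond
cutting produces, three rounds separate everything we have encountered;
pathological symmetric counterexamples would merge keys, which for frequency
counting is a benign failure mode.

# The interaction network

Proteins are encoded per residue as the 20 BLOSUM62 substitution scores
(all-zero for non-standard symbols) concatenated with `d_pe = 8` sinusoidal
positional-encoding channels. Compounds are encoded per atom as one-hot
element (9 common elements plus an "other" slot), one-hot bond count (capped
at 6), one-hot maximum incident bond order, mass/100 and formal charge, with
a bond-order-weighted adjacency matrix. Residues get positional encoding and
fragments do not: residue order determines structure, whereas fragment order
in a compound is arbitrary, and the architecture keeps the prediction
exactly invariant to fragment permutation (verified by test).

The forward pass: three same-padding 1D convolutions (kernel 7) over the
protein; two graph-convolution layers (self and neighbour linear maps with
bond-order-weighted sum pooling) over atoms; per-fragment mean pooling of
atom embeddings; five feature-wise fully connected layers on each side;
scaled-dot-product cross-attention in which fragments attend over residues
(softmax over residues, single head); the joint representation is the
elementwise product of each fragment embedding with its attention context,
averaged over fragments and mapped linearly to the predicted affinity. The
affinity scale is pKd (-log10 Kd in molar); the display score squashes it
logistically around pKd 6 (micromolar), so 0.5 means micromolar-strength
predicted binding. Hidden width 128, kernel 7 and learning rate 1e-4 are the
package defaults; they are conventional values, surfaced in `train_config()`
because nothing in the method fixes them.

Training minimizes mean squared error on affinity with Adam, mini-batches of
8, and a seeded 80/20 train/test split. Forward, backward and Adam are
implemented in plain matrix algebra inside the package; the backward pass is
validated against central differences to 1e-4 relative error in the test
suite. Single-head attention and mean joint pooling are the defaults where
the design was open.

## Fragment ranking

The attention map is F x L (fragments x residues, rows softmax-normalized).
Because each row sums to 1, raw row mass cannot rank fragments. The ranking
statistic is the fragment's additive share of the predicted affinity:
`sum_l attention[f, l] * salience[f, l]` with
`salience[f, l] = v · (fragment_f ⊙ residue_l)`, which decomposes the
prediction exactly (the affinity minus intercept is the mean of these
shares). An alternative, `"logit_mass"`, ranks by attention concentration.
Ties fall back to fragment index order.

# Pipeline and confidence

Baits are the union of the 2D hits (Tc ≥ 0.85) and 3D hits (overlap ≥ 0.5);
candidates are every annotation record whose compound is a bait, grouped by
target. The final ranking uses the network score alone — similarity scores
are reported as provenance, not blended, since ranking is the network's job
in this design; a blend could be added but defaults off. A predicted
interaction is high confidence iff it is supported by more than one distinct
assay id, otherwise low: the probability that several independent assays all
produced false positives is small. The annotation loader enforces the ingest
filters at the boundary: Kd values must be positive and only single-protein
targets are kept.

The report (JSON + TSV) contains the baits with both similarity scores, the
ranked targets with confidence, and the fragment frequency profile over the
query plus baits; it validates against the JSON schema shipped in
`inst/extdata/report-schema.json`, and identical configurations produce
byte-identical reports.

# Synthetic data: what it emulates and what it does not

The generator plants the structure every test needs: similarity clusters
(compounds in a cluster share a scaffold, so within-cluster Tanimoto exceeds
between-cluster similarity), protein sequences with planted 5-mer motifs,
annotation records that satisfy the ingest filters with a configurable
fraction duplicated across assays, and affinities from a planted bilinear
map — pKd = 6 + 0.8·u·v + 0.4·u + 0.4·v + noise, where u is a fixed random
projection of the fingerprint and v of the motif 3-mer counts, both
standardized over the generated population, with Gaussian noise
(sd 0.3 by default, roughly half a log unit of assay scatter). Defaults are
300 compounds, 50 proteins and 2000 affinity triples.

Synthetic tests establish internal correctness — retrieval equals
brute-force scanning, partitions match union-find, gradients are exact,
the network recovers a recoverable signal, the pipeline recovers planted
truth — not real-world accuracy. Real chemical libraries have property
distributions, tautomers and activity cliffs that scaffold decoration does
not emulate, and real affinity landscapes are not bilinear in fingerprint
bits. Published-scale benchmark numbers require the corresponding public
databases and are out of scope here.

# Problem sizes and numerical choices

The test suite and the examples run at desk scale, chosen so the full suite
completes in well under half an hour on one CPU: the trained fixture uses 60
compounds in 4 clusters, 12 proteins, 600 affinity triples, hidden width 16,
kernel 7, 40 epochs, learning rate 1e-3, batch 8 (this configuration reaches
held-out Pearson r ≈ 0.86 against the planted affinity; wider/longer
settings overfit these small populations before they help). Retrieval
equivalence is checked on a 1000-molecule synthetic index; fragmenter
oracles run on 500 random graphs of up to 30 atoms.

Numerical conventions: 1-based atom indexing internally (the natural R
convention; 1-based file formats translate as the identity), aromatic bonds
are a distinct order rather than Kekulé-expanded, an aromatic bond outside
any ring is demoted to single at load time, ring membership of an edge means
"lies on some cycle" (computed via bridge detection and verified against the
remove-edge connectivity oracle), all-zero/all-zero Tanimoto is 1 with a
warning, ranking ties break lexicographically (mol_id / target_id) or by
fragment index, and every random draw in the package flows from an explicit
integer seed.

# Known limitations

- SMILES support covers the organic subset, brackets, branches, ring
  closures and charges; stereochemistry is parsed over but not interpreted,
  and tautomer/protonation enumeration is out of scope.
- Conformers are distance-geometry surrogates, not force-field ensembles.
- Aromaticity is taken from the input encoding (lowercase SMILES, MOL2 `ar`,
  SDF type 4), not re-perceived from Kekulé structures.
- The pharmacophore key is a documented triplet hash, not a reimplementation
  of any published bit layout; cross-tool key files are not interchangeable.
- Fragment canonical keys use bounded refinement, not full graph
  canonicalization (see above).
- The network is trained per run; no pretrained weights ship with the
  package.
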