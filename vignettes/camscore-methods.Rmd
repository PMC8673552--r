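---
title: "Methods: superposition-free structure and complex evaluation"
author: "camscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: superposition-free structure and complex evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camscore)
```

This vignette documents the models implemented in `camscore`, the choices
made where the design was genuinely open, and what the synthetic fixtures
do and do not demonstrate about real data.

## The structure model

Structures are flat heavy-atom tables plus an entity list. On reading
(PDB or mmCIF), waters and hydrogens are dropped and alternate locations
are resolved to the highest-occupancy conformer, first-in-file on ties —
the common convention of scoring tools, which want one deterministic
coordinate per atom. Entities (unique polymer sequences) come from mmCIF
entity records; the PDB format has none, so entities are inferred by
grouping chains with identical residue-token sequences. Author numbering
is used throughout, with no internal renumbering.

Residue correspondence between a model and a reference chain prefers exact
author numbering: if every reference (number, insertion code, component)
triple has a monotone exact match in the model, that pairing is used.
Otherwise a global Needleman–Wunsch alignment on residue tokens decides
(match +1, mismatch −1, gap −2; ties prefer the diagonal move, then the
vertical one, so the traceback is deterministic). Noncanonical residues are
carried as bracketed PDB component identifiers — `"AC(MLZ)G"` is four
tokens — and compare by component id, so a model that represents a modified
residue correctly aligns against it.

## lDDT

The local Distance Difference Test asks how well a model preserves the
reference's local interatomic distance structure, with no superposition.
Contacts are defined **from the reference only**: all heavy-atom pairs
within the inclusion radius (default 15 Å; same-residue pairs excluded).
A contact is preserved at tolerance $t$ if both atoms exist in the model
(same residue through the alignment, same atom name) and
$|d_\text{model} - d_\text{ref}| < t$; the global score is the preserved
fraction averaged over $t \in \{0.5, 1, 2, 4\}$ Å. Two consequences are
load-bearing and tested: extra model atoms with no reference counterpart
cannot change any score, and deleting a model atom can never raise the
global score.

The global score pools contact counts rather than averaging per-residue
scores. That choice makes the oligomeric extension additive in counts (the
extra-chain penalty below is literally extra denominator), and matches the
original definition of the score. The defaults (15 Å radius, four thresholds)
are the standard settings of the score as originally published; since
benchmarking pipelines leave them implicit, they are exposed in
`lddt_params()`.
Stereochemical plausibility checks and chemically-equivalent atom-name
swaps (ring flips) are not implemented; naive deterministic naming is used.
This is a documented limitation — models that flip, e.g., a tyrosine ring
naming may score slightly low.

`lddt_bs()` restricts the contact set to residues with any heavy atom
within `bs_radius` (default 4.0 Å, configurable: published pocket
definitions vary) of a ligand's heavy atoms, excluding the ligand itself.

## QS-score and chain mapping

The QS-score measures conservation of inter-chain interfaces. Each residue
is reduced to a representative atom (Cβ; Cα for glycine; C1′ for
nucleotides; fallback Cα, then first heavy atom), and inter-chain pairs
within 12 Å become weighted contacts: weight 1 up to 5 Å, decaying
linearly to 0 at 12 Å. The score as originally published uses a specific
decay beyond 5 Å; the piecewise-linear form is our choice, every invariant we rely on
(range, symmetry, identity) holds for any monotone non-increasing weight,
and the form is swappable via `qs_params()`. Shared contacts contribute
$\min(w_m, w_r)$ over $\max(w_m, w_r)$; one-sided contacts — including
everything touching unmapped chains — contribute their weight to the
denominator only. The score is symmetric in model and reference.

Chain mappings are injective and entity-consistent (sequences ≥ 95%
identical over the shorter; models may deviate slightly from the target
sequence, hence a threshold rather than equality). All maximal mappings
are enumerated when their count — the product of per-entity permutation
counts — is at most 720; beyond that a deterministic greedy search seeds
with the chain-pair assignment whose translated interface maximizes QS and
extends by best incremental global QS, with lexicographic tie-breaks. The
cap keeps homo-12-mers tractable; the greedy path is exercised in tests
but never used when exhaustive enumeration is feasible.

## Oligo-lDDT and the best-score rule

The oligomeric lDDT scores the whole complex through the chain mapping:
the contact universe is every reference contact, intra- and inter-chain.
Contacts touching unmapped reference chains (missing chains in the model)
can never be preserved, which penalizes them automatically. Extra model
chains are penalized symmetrically by adding their contacts to the
denominator at every threshold as never-preserved. By default both intra-
and inter-chain contacts of an extra chain count ("full"); an
"inter"-only mode exists because reference implementations differ in
whether intra-chain contacts of extra chains count.

Because a prediction's chain labels and the choice among multiple
biological assemblies carry no information, `best_score()` computes every
requested score for every assembly × mapping candidate and keeps each
score's maximum independently — a model may win QS under one mapping and
oligo-lDDT under another. A single-chain model against a multi-copy
reference is handled by the same machinery: one candidate mapping per
compatible reference chain, best kept.

**Symmetry and mapping identifiability.** For a perfectly symmetric
reference (our cyclic fixtures), the chain mapping is only defined up to
the reference's rotation group: composing a mapping with a C4 rotation of
a cyclic homo-tetramer leaves every reference distance identical, so the
four rotated mappings score *exactly* equally and the winner among them is
a tie-break. The planted-permutation experiment in the test suite and
acceptance script therefore judges recovery within the rotation class:
the winning mapping must be the planted permutation composed with a
rotation, while any non-symmetry mapping (e.g. a transposition) counts as
a failure. At 0.2 Å jitter this recovery is 100/100 at the seeds we ran.

## Ligand pose scores

Chemically equivalent atoms make index-matched RMSD overestimate pose
error, so `symcorr_rmsd()` minimizes over the ligand graph's
automorphisms: permutations preserving element labels and the bond-order
multiset, enumerated by invariant refinement (element, degree, incident
orders, then iterated neighborhood colors) plus backtracking, with the
identity first and a configurable cap (default 10^5). Aromatic bonds are
normalized to order 1.5 on input; bond tables come from TSV or are
attached programmatically — interpretation of chemical line notations is
deliberately out of scope, since pose scoring needs only the graph and
coordinates.

Two frames are exposed because benchmarking practice does not fix one: the
default scores presuperposed coordinates as given, and
`frame = "pocket_superpose"` first Kabsch-superposes mapped binding-site
atom pairs (a local frame robust to domain motion, in the style of
pocket-centred docking assessments). `drmsd()` needs no frame at all: it
is the automorphism-minimized RMS deviation of all intramolecular pairwise
distances, invariant under proper and improper rigid transforms of either
coordinate set.

## Target selection and novelty categories

Prerelease entities are filtered (unknown-residue tokens X/N; polymer
class inconsistent with the declared type), typed (amino sequences of ≥ 30
residues are "protein", shorter are "peptide"), and clustered greedily in
CD-HIT style: sequences sorted by descending length found clusters, and a
sequence joins the first representative with identity ≥ 99%, where
identity is identical aligned positions over the shorter sequence (the
tool convention; the pipeline names the tool, not the formula). Peptides
and nucleic acids cluster on exact identity.

Homology hits pass at ≥ 85% identity and ≥ 70% query-side coverage
(close-homolog tier: BLAST-like, plus exact-lookup hits), or ≥ 70%
probability and ≥ 70% coverage (remote tier: HHblits-like); all
boundaries inclusive. A template structure explains a whole complex when a
perfect bipartite matching pairs every target chain with a template
polymer chain through passing hits — templates covering only part of the
target, or containing extra polymer chains, are rejected. Categories
follow from template availability per tier: NOT_INTERESTING (close
full-complex template), REMOTE_COMPLEX_TEMPLATE, NOVEL_COMPLEX (every
entity has a hit, never together), NO_TEMPLATE_ENTITY, and the monomer
analogues NOVEL_MONOMER, MONOMER_WITH_REMOTE_TEMPLATE and
TEMPLATE_ONLY_IN_OTHER_COMPLEX. The monomer "interesting" gate uses the
close tier only; the remote tier is retrospective. Filtering is limited to these two rules; no further heuristics are
applied.

## Difficulty and QE metrics

Targets bin by the mean lDDT of first-ranked public-server models: hard
below 0.5, easy at or above 0.75, else medium — both boundaries exact and
tested. QE treats a confidence score as a classifier of "good" models
(true lDDT ≥ 0.6; the threshold is stated by the pipeline, the
orientation — good as positive — is the natural QE reading) and reports
ROC AUC, partial ROC AUC over FPR 0–0.2, PR AUC, and partial PR AUC over
recall 0.8–1.0. Curves sweep distinct predicted values descending with
ties grouped; areas are trapezoidal with linear interpolation at window
bounds, and partial areas are reported normalized by window width.
ROC AUC computed this way equals the tie-corrected Mann–Whitney statistic
exactly, which the tests verify on 200 random tables. Both pooled and
per-target/per-server groupings are provided, since both aggregations
are in common use; single-class groups are flagged
undefined rather than dropped.

## Synthetic fixtures

All test inputs are generated: idealized α-helical traces (Cα rise 1.5
Å/residue, 100°/residue, radius 2.3 Å — textbook helix parameters — with
N, C, O, Cβ at fixed ideal offsets), cyclic oligomers with exact
rotational symmetry, Gaussian/rigid/chain-edit perturbations, ligands with
known automorphism groups (2, 12, 24, 1), hit tables constructed to
categorize as requested, and QE sets with Beta(2,2) true lDDT (symmetric,
bounded, populates both classes at 0.6) mixed with uniform noise under a
correlation control. Every generator is a pure function of its arguments
and seed.

Problem sizes in the tests and acceptance script — 12-residue chains,
oligomers up to tetramers, 20 random oracle structures, 100 recovery
replicates, 1000 hit tables — were chosen as the smallest sizes at which
every code path (inter-chain contacts, mapping enumeration and its greedy
fallback, extra/missing-chain penalties) is exercised and the stochastic
properties are stable.

What passing these tests shows: the scores implement their definitions
exactly (oracle equivalence is exact, not approximate), the penalties are
monotone, and the pipeline is deterministic. What it does not show:
behavior on real experimental artifacts — alternate conformations beyond
alt-loc picking, chemically equivalent atom naming, large domain motions,
or disagreements between author and entity numbering more pathological
than the renumbering cases tested.

## Known limitations

- No stereochemistry checks or atom-name swap correction in lDDT.
- The QS contact weight's decay shape between 5 and 12 Å is a documented
  package choice, configurable but not fitted to the published decay.
- mmCIF coverage is the `atom_site`/`entity`/`entity_poly` subset;
  assembly expansion from symmetry operators is out of scope (multiple
  assemblies are supplied as separate files).
- Ligand bond perception is not performed; bonds must be supplied.
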