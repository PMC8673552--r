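Package: camscore
Title: Superposition-Free Evaluation of Predicted Biomolecular Structures and Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring and benchmarking toolkit for continuous blind evaluation
    of predicted protein structures, complexes and ligand poses against
    reference structures. Implements the superposition-free local Distance
    Difference Test (lDDT) with per-residue output, binding-site restricted
    lDDT-BS, the quaternary-structure QS-score with entity-consistent chain
    mapping search, the oligomeric lDDT with missing- and extra-chain
    penalties, best-score selection over multiple reference assemblies,
    symmetry-corrected ligand RMSD and distance RMSD via molecular-graph
    automorphisms, prerelease target filtering, greedy sequence-identity
    clustering, homology-hit aggregation into full-complex templates with
    novelty categorization, target-difficulty binning, and ROC/PR metrics
    for model quality estimation. Includes light-weight PDB, mmCIF and
    extended-FASTA readers and writers and a deterministic synthetic-fixture
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
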