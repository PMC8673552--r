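# camscore

Superposition-free evaluation of predicted biomolecular structures,
complexes and ligand poses against reference structures, in R.

Continuous blind benchmarking of structure-prediction servers needs scores
that (i) do not depend on a global rigid superposition, (ii) extend from
single chains to oligomers with a principled treatment of missing and extra
chains, and (iii) are computed under the *most favorable* combination of
reference assembly and chain mapping, because chain labels of a prediction
carry no meaning. `camscore` implements that evaluation stack, together with
the surrounding pipeline machinery: prerelease target filtering and
clustering, homology-hit aggregation into full-complex templates with
novelty categorization, target-difficulty binning, and ROC/PR metrics for
model quality estimation (QE).

## Scores

**lDDT** (local Distance Difference Test). Contacts are all heavy-atom pairs
of the *reference* within an inclusion radius `R0` (default 15 Å,
same-residue pairs excluded). A contact is preserved at tolerance `t` when
both atoms exist in the model and `|d_model − d_ref| < t`; the global score
averages the preserved fraction over tolerances `{0.5, 1, 2, 4}` Å:

    lDDT = mean_t  ( #preserved(t) / #contacts )

Per-residue scores restrict the same statistic to contacts touching the
residue. Extra model atoms never change the score; missing model atoms count
against it. **lDDT-BS** restricts the contact set to residues within 4 Å of
a ligand.

**QS-score**. Inter-chain residue contacts (representative atoms Cβ, Cα for
Gly, C1′ for nucleotides) are weighted `w(d)` — 1 up to 5 Å, linearly down
to 0 at 12 Å. With model contacts translated into reference residue space
through an entity-consistent chain mapping:

    QS = Σ_shared min(w_m, w_r) / ( Σ_shared max(w_m, w_r) + Σ_model-only w_m + Σ_ref-only w_r )

**oligo-lDDT**. lDDT over the whole complex: all reference contacts (intra-
and inter-chain) scored through the chain mapping, plus the contacts of
unmapped (extra) model chains added to the denominator as never-preserved.
Missing chains are penalized automatically since their contacts cannot be
preserved.

**Best-score rule**. `best_score()` evaluates every reference assembly ×
candidate chain mapping (exhaustive up to 720 mappings, deterministic greedy
beyond) and keeps, per score independently, the most favorable value with
its winning assembly and mapping.

**Ligand scores**. `symcorr_rmsd()` minimizes the pose RMSD over the
ligand's molecular-graph automorphisms (element- and bond-order-preserving
permutations), optionally after superposing on mapped binding-site atoms;
`drmsd()` is the automorphism-minimized RMS deviation of intramolecular
pairwise distances, invariant to any rigid transform.

## Worked example

```r
library(camscore)

ref   <- make_oligomer(make_chain(12, seed = 1), 3)       # cyclic homo-trimer
model <- perturb(ref, mode = "delete_chain", chain = "C") # dimer prediction

report <- best_score(model, ref)
report
#> <complex_score_report>
#>   QS-score:   0.3333 (assembly 1)
#>   oligo-lDDT: 0.5128 (assembly 1)
#>   candidates evaluated: 6
```

The dimer reproduces one of the trimer's three equivalent interfaces
perfectly, so the QS-score is 1/3; the oligo-lDDT is higher (0.51) because
intra-chain contacts of the two modeled chains are preserved and only the
contacts touching the missing chain are lost. Six entity-consistent chain
mappings (3 × 2 injective assignments of the two model chains) were
searched and the best kept.

Ligand symmetry correction:

```r
ring <- make_ligand("ring6")                  # benzene-like C6 ring
ring$coords_model <- ring$coords_ref[c(2:6, 1), ]  # indexing rotated by one
symcorr_rmsd(ring)[c("rmsd", "naive_rmsd")]
#> $rmsd
#> [1] 0
#> $naive_rmsd
#> [1] 1.39
```

A pipeline run from files (`run_score()`, or the shell front-end at
`inst/cli/camscore.R`) writes a deterministic JSON report with the effective
config, tool version and MD5 input checksums:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "camscore.R", package = "camscore"))') \
  score --model model.pdb --ref ref.cif --json report.json
```

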