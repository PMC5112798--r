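# ClustConsrank

Consensus scoring of protein–protein docking models, with a contact-based
clustering step that rescues native-like poses from "false consensus"
ensembles.

## The problem and the method

Docking programs produce ensembles of hundreds to thousands of candidate
poses (decoys) of a binary protein complex. A scorer must pick at most ten
models per target — the CAPRI submission limit — hoping at least one is
native-like. **CONSRANK** is a pure consensus score: writing the contacts of
model *m* as the set *Cₘ* of receptor/ligand residue pairs with any two heavy
atoms within 5 Å, and the conservation of contact *c* over *N* models as

    w(c) = #{ m : c ∈ Cₘ } / N,

a model scores the mean conservation of its own contacts,

    S(m) = (1 / |Cₘ|) Σ_{c ∈ Cₘ} w(c).

Consensus fails when many decoys agree on the same wrong interface.
**Clust-CONSRANK** therefore clusters the models first, on the contact
Hamming distance d(m, m′) = |Cₘ Δ Cₘ′| (the number of contacts by which two
models differ), using agglomerative single or complete linkage cut by
distance (S25, S30, C40–C80) or by maximum cluster count (MC200, MC/5,
MC/10). CONSRANK is then re-run inside each of the ten most populated
clusters and each cluster's top model is selected — a false consensus costs
one slot instead of ten. A redundancy-removal baseline
(`redundancySelect()`), CAPRI-style evaluation (f_nat, ligand RMSD, quality
classes), consensus-map export, PDB I/O with residue-numbering
harmonization, and a seeded rigid-body decoy simulator complete the
package.

## Worked example

```r
library(ClustConsrank)

sim <- t50Scenario(seed = 42)        # 600 decoys, 40% false consensus,
fps <- ensembleFingerprints(sim$ensemble)  # 6% near-native

plain <- consrankSelect(fps)               # pure consensus, top 10
clust <- clustConsrankSelect(fps, preset = "MC/10")

labels <- setNames(sim$truth$class, sim$truth$model_id)
summarizeSelection(plain, labels)$cell
#> [1] "0/0"
summarizeSelection(clust, labels)$cell
#> [1] "1/1"
head(selectedModels(clust), 3)
#>   slot   model_id      score cluster_rank cluster_size within_cluster_rank
#> 1    1 model_0088 0.97426471            1          204                   1
#> 2    2 model_0381 0.06140351            2          114                   1
#> 3    3 model_0333 0.89795918            3           49                   1
```

Every selected model is the consensus champion of one population-ranked
cluster ("0/0" and "1/1" count native-like and high/medium-quality models
among the ten picks). Pure consensus selects ten poses at the dominant
false interface and misses all 36 near-native decoys; the clustered variant
recovers a medium-quality model from the near-native cluster.

For real data: `readEnsemble("dir/")`, `harmonizeNumbering()`,
`ensembleFingerprints()`, then the same scoring/selection calls;
`evaluateEnsemble(models, reference)` classifies against an experimental
structure.

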