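# frasebot

Fragment-based hit finding for proteins without a known ligand: mine
protein–ligand complexes into **FRASEs** — FRAgments in Structural
Environments — and transplant them onto a new target by matching local
residue geometry, then condense the surviving fragments into a 3D
pharmacophore query for library screening.

The package is aimed at computational chemists who have a target structure
(apo or holo PDB) and want seed fragments and a screening query without
running a docking campaign first.

## The method in brief

A FRASE is a chemically sound ligand fragment (50–300 Da, cut only across
acyclic single bonds, rings kept whole with their α-atoms) together with
every protein residue having a heavy atom within 4.5 Å. Screening works on
**residue triplets**: three residues whose Cα atoms form a near-equilateral
triangle with sides in [8, 12] Å. Each residue is encoded as a many-hot
11-bit property string; concatenating the three strings in all six orders
and taking the lexicographic minimum gives an order-invariant 33-bit hash
key, so database and target triplets match by exact key equality. Each
match defines a three-point Kabsch superposition that seeds the database
fragment into the target.

Seeded poses are scored by a small neural network (377–32–16–1, ReLU
hidden layers, sigmoid output) on a distance-weighted interaction
fingerprint

```
f[m, n] = Σ_i Σ_j δ(type_i = m) δ(type_j = n) · w(d_ij),
w(d) = exp(-(d - 3)²) for d ≤ 10 Å, else 0
```

over 29 ligand × 13 protein atom types (377 cells). The network is trained
to separate true crystallographic FRASEs from decoys built by swapping
fragments between FRASEs (two decoys per true FRASE). Survivors of the
collision (≥ 1 Å), buriedness (mean ≥ 5 protein atoms within 5 Å) and
fitness (≥ 0.4) filters are converted to typed pharmacophore features
(HBA/HBD/Pos/Neg/Ar/Hyd), clustered per type under a 3 Å diameter bound,
and the top-ranked cluster centroids become the query.

See `vignettes/frasebot-methods.Rmd` for the full method account and design
notes.

## Worked example

Everything below runs self-contained on synthetic fixtures (no downloads):

```r
library(frasebot)

# a toy target with a planted fragment and known ground truth
tc <- make_toy_complex(fixture_spec(seed = 1, n_env = 8))
target <- tc$complex
target
#> <complex TOY0001: 11 residues, 1 ligands, 0 other hetero atoms>

# a small FRASE database: the target's own planted FRASE plus unrelated ones
db <- c(list(tc$truth$frase),
        lapply(2:4, function(i)
          make_toy_complex(fixture_spec(seed = i, n_env = 8))$truth$frase))

# train the nativeness model on synthetic true FRASEs vs swapped decoys
frs <- make_frase_set(80, seed = 7)
dks <- make_decoys(frs, decoy_spec(2, seed = 8))
model <- train_model(t(sapply(frs, interaction_fingerprint)),
                     t(sapply(dks, interaction_fingerprint)),
                     epochs = 150, seed = 3)
model
#> <nativeness model 377-32-16-1: trained on 80 true / 160 decoy, final BCE 0.4179>

res <- run_pipeline(target, db, model = model,
                    cfg = pipeline_config(fitness_min = 0.01))
res$funnel
#>  target_triplets          matches           seeded collision_burial
#>               11               28               26               26
#>          fitness         features         clusters   query_features
#>               18               54                3                3

res$survivors[[1]]
#> <seeded fragment from TOY0001:planted: min clash 2.49 A, mean burial 9.7, fitness 0.016>

res$query
#> <pharmacophore query: 3 features (Arx1, HBAx1, HBDx1)>
```

The funnel reads: 11 target triplets produced 28 key matches, 26 aligned
poses survived the superposition gate, all 26 passed collision/buriedness,
18 passed the (deliberately permissive, fixture-scale) fitness cut, and
their 54 pharmacophoric features condensed into 3 clusters whose centroids
form the query. `write_query(res$query, "query.json")` exports it. On a
real run the planted self-match appears at superposition residual ~0 with
the fragment recovered in its original pose.

The screen of a real target works the same way: `load_complex("target.pdb")`
for the structure, a FRASE SD file (built with `build_frase_db()` from your
own complex collection) for the database, and a model trained on that
database's fingerprints.

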