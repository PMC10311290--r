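# scXmatch

Cross-species cell-type matching for single-cell/single-nucleus RNA-seq.

Evolutionarily related species share most of their cell types, but their
scRNA-seq datasets cannot be compared column-by-column: gene content differs,
orthology is often many-to-many, and each atlas carries its own annotation
vocabulary. `scXmatch` matches cell types between two species' count matrices
in four steps:

1. **Gene matching.** A weighted bipartite graph between the two species'
   genes is built either from protein-embedding cosine distances (edges where
   `d(u, v) <= tau`, default `tau = 0.005`, each gene capped at its 5 closest
   partners) or from two-directional BLAST tables (E-value `< 1e-6`;
   many-to-many with averaged bitscores, or one-to-one reciprocal best hits).
   Only matches touching a top-2000 highly variable gene are kept.
2. **Shared feature space.** Counts are library-size normalized to 10 000 per
   cell, log-transformed, and z-scored per gene. Each species' matrix is
   extended over `G_A ∪ G_B`: a foreign gene `u` is imputed as the weighted
   average `Σ_v e_uv X_v / Σ_v e_uv` of the within-species genes it is matched
   to, with `e_uv = 1 − d(u,v)/τ` (or the bitscore in BLAST mode).
3. **Model training.** A shared-weight two-layer ReLU network (64 then 32
   units) embeds cells of both species; one linear softmax classifier per
   species predicts its own cell types. The loss is
   `L = L_cls^A + L_cls^B + L_align^A + L_align^B + γ‖θ‖²`, with
   label-smoothed (`ε = 0.1`) cross-entropy weighted by dynamic class weights
   `w_t = (1 − acc_t)·α + 1` (`α = 9`), an alignment term in which each
   cell's 20 nearest opposite-species cells must predict its shared features,
   and `γ = 0.01`. Training uses Adam (lr 0.001, 200 epochs) on
   class-balanced batches of 5000 cells per species.
4. **Transfer and scoring.** Labels are transferred by classifier swapping;
   the two row-normalized confusion matrices are averaged into a combined
   matrix, scored by the **average diagonal score** (ADS: mean combined score
   over ground-truth type pairs, species-specific types excluded) and
   **recall** (fraction of pairs whose score is the strict maximum of its row
   and column).

A seeded synthetic generator (`simulate_species_pair()`) produces paired
datasets with known gene homology and type correspondence, so the whole
pipeline is testable without downloads.

## Worked example

```r
library(scXmatch)

sim <- simulate_species_pair(sim_config(seed = 0))
out <- match_pipeline(sim$dataset_a, sim$dataset_b,
                      sim$embeddings_a, sim$embeddings_b,
                      corr = sim$correspondence,
                      config = match_config(epochs = 100,
                                            batch_per_species = 300,
                                            seed = 0))
print(out$graph)
print(out$model)
print(out$result)
```

```
Gene match graph: speciesA vs speciesB
  150 edges, 150 speciesA genes, 150 speciesB genes (source: embedding)
Cross-species cell-type matching model
  species: speciesA (5 types) vs speciesB (5 types)
  features: 300 shared; embedding: 300 -> 64 -> 32
  100 epochs; final loss 5.0383 (train acc 1.000 / 0.996)
Cell-type match result: speciesA vs speciesB
  ADS: 0.962   recall: 1
  combined matrix (rows = speciesA types):
     T1    T2    T3    T4    T5
T1 1.00 0.025 0.000 0.013 0.025
T2 0.00 0.965 0.013 0.010 0.000
T3 0.00 0.010 0.978 0.000 0.013
T4 0.01 0.000 0.010 0.932 0.010
T5 0.00 0.000 0.000 0.055 0.932
```

All 150 planted homolog pairs are recovered in the gene-match graph. The
combined matrix is strongly diagonal: every one of the five planted type
pairs is the strict maximum of its row and column (recall 1), and the mean
diagonal score is 0.962 — cells of matched types are reciprocally assigned
to each other's labels almost perfectly.

The same pipeline is available from the shell via
`inst/cli/scxmatch.R` with subcommands `simulate`, `match-genes`, `train`
and `evaluate`; every run writes a manifest with its configuration, seed and
input checksums.

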