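---
title: "Matching cell types across species: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching cell types across species: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scXmatch)
```

`scXmatch` matches cell types between two species' single-cell RNA-seq
datasets by (i) pairing genes across species, (ii) building a shared feature
space, (iii) training a shared cell-embedding network with per-species
classifiers, and (iv) swapping the classifiers to transfer labels. This
vignette explains each model component, its assumptions, and the design
decisions taken where the problem left genuine freedom.

## Gene matching

Genes are represented by protein embeddings: fixed-length vectors obtained by
mean-pooling a protein language model's per-residue embeddings
(`pool_residue_embedding()`; sequences are truncated to their first 2500
residues, mirroring common practice for very long proteins). The working
assumption is that orthologous proteins sit close together in embedding
space, so cosine distance is a proxy for homology.

`build_match_graph()` admits all gene pairs with cosine distance at most
`tau` (default 0.005 — a tight threshold appropriate for embeddings of
closely conserved proteins; it is exposed because other embedding models
may need a different scale) and then caps each gene's candidate list at its
`k_max = 5` closest partners. The cap is *directional*; we retain an edge if
it survives the cut of at least one endpoint (`topk_rule = "union"`).
The alternative reading — both endpoints must select the edge
(`"intersection"`) — is offered as a configuration because the union rule,
while it avoids silently dropping asymmetric matches, does allow a popular
gene to exceed degree `k_max` through the other side's selections. Ties at
the cut are broken by partner gene id so that results are identical across
platforms. When several isoforms per gene are available, the gene–gene
distance is the minimum over isoform pairs (`isoform_agg = "min"`): one
similar isoform is enough evidence of homology; the mean is available as an
alternative. Genes with no embedding cannot be matched and are dropped with
a message.

Matches are restricted to informative genes: `select_hvg()` ranks genes by
the classic binned-dispersion flavour (dispersion = variance/mean of the
de-logged normalized data, log-dispersion z-scored within 20 equal-width
bins of log mean) and keeps the top 2000 per species; an edge survives
(`hvg_filter()`) if **either** endpoint is highly variable. Degenerate bins
(a single gene, or identical dispersions) cannot be z-scored; such genes
receive a fixed unit score rather than `NaN`/`Inf`.

In BLAST mode (`blast_to_matches()`), candidate pairs need an E-value below
`1e-6` in at least one direction; the pair score is that direction's
bitscore or the mean of both when both qualify. Many-to-many mode applies
the same top-k and HVG filters with bitscore as (inverse) distance;
one-to-one mode keeps reciprocal best hits only. Bitscores are kept raw as
edge weights: the imputation below normalizes weights within each gene's
match group, so no global rescaling is needed.

## Shared feature space

Counts `x_ij` are library-size normalized so every cell totals
`norm_scale = 10^4`, then transformed as `ln(x + 1)`, then z-scored per gene
(`lognormalize()`, `zscore()`). The z-score uses the population (`ddof = 0`)
standard deviation: on the small fixtures the package is tested with, this
keeps the transform exactly scale-free and deterministic; `ddof = 1` is
available. Zero-variance genes get all-zero columns instead of `NaN`, i.e. a
"no information" baseline that cannot poison the network. Cells with zero
total counts are a hard error naming the cell — such cells should have been
removed upstream, and silently imputing them would hide a QC failure.

`impute_shared()` builds, for both species, a matrix over the ordered union
`G_A ∪ G_B` (feature ids are namespaced `species:gene` to keep symbol
spaces apart). Native columns are the species' own z-scored values; a
foreign gene `u` is the weighted average of the within-species genes it is
matched to, with weights `e_uv = 1 − d(u,v)/τ` clamped to `[0, 1]`
(`edge_weight()`). Because imputation divides by the summed weights, every
imputed entry is a convex combination of native entries — a property the
test suite asserts. A match group whose weights sum to zero (only possible
when a lone edge sits exactly at the threshold) produces a zero column with
a warning. Z-scoring is performed after restricting to the matched gene
sets and before imputation, so imputed values live on the same per-gene
standardized scale as native ones.

## Model and training

The embedding stack is two affine+ReLU layers, `|features| → 64 → 32`,
with weights shared by both species: the network cannot encode which
species a cell came from, which is what lets the classifiers be swapped
later. Each species has one linear softmax classifier over its own type
vocabulary.

The training loss is

```
L = L_cls^A + L_cls^B + L_align^A + L_align^B + γ ||θ||²,    γ = 0.01
```

* **Classification.** Weighted cross-entropy against label-smoothed targets
  (`ε = 0.1`: the true type holds 0.9, the remainder is spread evenly).
  Class weights are dynamic: `w_t = (1 − acc_t)·α + 1` with `α = 9`, so
  weights live in `[1, 10]` and a type misclassified throughout an epoch is
  up-weighted tenfold in the next. Before the first epoch all weights are 1
  (there is no accuracy yet). Per-type accuracy is accumulated from the
  epoch's sampled batches with the species' own classifier; a type that
  happened not to be sampled keeps its previous weight. The logarithm is
  floored at `1e-12`, invisible at reported precision.
* **Alignment.** For each cell, its `K = 20` nearest opposite-species cells
  in the *current* embedding space predict its shared-feature vector; the
  loss is the mean squared error of that prediction, averaged over cells,
  computed per species. Neighbour search happens within the batch — with
  class-balanced batches of 5000 cells this is both the practical and the
  intended granularity. With hard nearest-neighbour selection this term is
  piecewise constant in the parameters and carries no gradient; the default
  therefore uses *soft* neighbours — weights are a softmax over negative
  squared embedding distances restricted to the K nearest — which is the
  minimal relaxation that lets gradients flow while concentrating on the
  same neighbourhood. The literal hard-selection variant is available
  (`align_mode = "hard"`) for ablation; whether the reference
  implementation differentiates through neighbour selection is not
  documented anywhere we could check, so the soft default is this package's
  choice, not a claim about the original.
* **Regularization.** `γ` times the squared L2 norm of all parameters,
  biases included.

Batches are sampled with replacement, each cell weighted by the inverse
size of its type (`sample_batch()`), so expected per-type counts are equal —
important when one species' type proportions are heavily skewed. Training
runs `epochs = 200` Adam steps (lr 0.001, one batch per species per epoch).
Parameters start from uniform Kaiming (fan-in) initialisation; the
initialisation, the sampler and every other random draw use the single seed
in `match_config()`, so two runs with one seed are bit-identical on one
machine (asserted by the tests). Gradients of the full composite loss are
analytic and are verified against central finite differences in the test
suite. A non-finite loss aborts immediately with the epoch and the loss
components.

## Transfer and scoring

`transfer_labels()` runs cells through the opposite species' classifier and
takes the highest-probability type; exact ties go to the first type in the
vocabulary, for determinism. `confusion_normalized()` forms the
row-normalized confusion matrix per direction over *fixed* vocabularies —
types with no cells yield flagged all-zero rows rather than disappearing,
keeping matrix shapes aligned with the correspondence table.
`combine_directions()` averages one matrix with the other's transpose
(rows = species-A types); high entries mark reciprocal matches. `ads()` is
the mean combined score over ground-truth pairs, species-specific types
excluded by construction of the `type_correspondence`; `match_recall()` is
the fraction of pairs that are the *strict* maximum of both their row and
column — ties count as failures, the conservative reading, since a tied
match cannot be called uniquely. Detecting genuinely novel, counterpart-free
types is out of scope: every cell receives some opposite-species label.

## Synthetic data

`simulate_species_pair()` generates the statistical structure the method
assumes, with full ground truth: homologous genes share a latent embedding
perturbed per species by Gaussian noise (`embedding_noise_sd = 0.01`, small
against the unit-scale spacing of independent latents); matched types share
per-gene mean profiles distorted by a log-normal factor
(`type_divergence = 0.1`); counts are negative-binomial (size
`1/dispersion = 2`) around log-normal gene means with a 6-fold marker
elevation per type, plus 10% dropout. Defaults — 5 matched types, 50 vs 40
cells per type, 150 one-to-one homolog pairs, 25 species-specific genes per
species — were fixed once as a small but realistic regime for this class of
model: strong marker structure, mild cross-species proportion imbalance,
overdispersed counts. Knobs exist for duplications (`frac_one_to_two`),
species-specific types, and proportion imbalance. A synthetic BLAST table
is emitted alongside (bitscores decreasing in embedding distance, true
homologs below the E-value threshold, distractor hits above it), so the
BLAST path and the file formats are exercised by the same fixtures.

The generator emulates what the model needs — homologs close in embedding
space, matched types co-expressed — and deliberately not more: no batch
effects, no ambient RNA, no realistic gene-length or GC structure, no
atlas-scale type hierarchies. Passing tests therefore demonstrate that the
implementation recovers planted structure under the model's own
assumptions, not that it resolves the harder ambiguities of real atlases.

## Problem sizes and numerical choices

The test and acceptance runs use scaled-down problems chosen as the
package's own fixture sizes: gene-matching oracles up to 50×50 genes,
alignment-loss oracles up to 20-cell batches, and end-to-end recovery on
the default fixtures (≈ 450 cells, ≈ 350 genes total) trained for 100
epochs with 300-cell batches — ample for the planted separation while
keeping the whole suite under a minute of compute. The paper-scale defaults
(200 epochs, 5000-cell batches, 2000 HVGs) remain the package defaults.

Other numerical details, collected: cosine distances are clamped into
`[0, 2]` against floating-point rounding; k-nearest ties are broken by
index order; checkpoint loading verifies an md5 over the feature ordering
and refuses mismatches; HDF5-based inputs (e.g. `h5ad`) are not read — use
the MatrixMarket bundle (`read_mtx_dataset()`) or the TSV formats.
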