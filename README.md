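# titan

Predicting which T-cell receptors (TCRs) bind which antigenic peptides
(epitopes) is a central open problem of adaptive immunology: repertoire
sequencing yields tens of thousands of TCR β-chain sequences, but public
binding data cover only a few hundred distinct epitopes, and models must be
judged separately on *unseen TCRs* and *unseen epitopes*. This package is a
self-contained R implementation of a bimodal attention network for this
task, together with everything needed to evaluate it honestly at desk
scale.

## What is inside

* **Model** — a two-stream neural network: the TCR stream embedded with
  BLOSUM62 rows (biophysical and learned embeddings available), the
  epitope stream either as amino acids or as atom-level SMILES; parallel
  convolutions (kernels 3/5/11 plus a residual channel) feed per-channel
  *context attention*

  $$u = \tanh(X_1 W_1 + W_3 (X_2 W_2))\,v,\qquad \alpha = \mathrm{softmax}(u),$$

  in both directions (each stream attended under the other as context);
  the α-weighted readouts pass to a dense stack ending in a logistic
  binding probability. Implemented in base R dense algebra with
  hand-derived gradients and Adam; no deep-learning framework required.
* **Baseline** — a k-nearest-neighbour classifier over the sum of
  length-normalized Levenshtein distances of epitope and TCR, with the
  odd-k (1–25) sweep protocol.
* **Data pipeline** — curation (≥15 and ≤400 TCRs per epitope), negative
  generation by shuffling (exact 50/50 balance per TCR), TCR-disjoint and
  strictly disjoint (TCR *and* epitope) 10-fold splits with within-fold
  negatives, and compound–protein-interaction preprocessing for
  pretraining-style data.
* **Chemistry** — peptide→SMILES conversion from stereo-aware residue
  graph templates, randomized-SMILES augmentation that provably preserves
  the molecule (OpenBabel canonicalization is the referee), and an
  atom-level SMILES tokenizer with persistent vocabularies.
* **Interpretability** — attention-map extraction, inter/intra-group
  attention variances, and epitope compression (keep residues with
  α > 0.1) with uniqueness statistics.
* **Synthetic benchmarks** — repertoire-shaped datasets with a planted
  motif rule (learnable by construction) or an epitope-class-only rule
  (unlearnable for unseen epitopes by construction), so every pipeline
  stage is testable without downloads.

## Worked example

```r
library(titan)

# a repertoire-shaped benchmark: 30 epitopes x 100 TCRs, planted 3-mer
# motif rule, 5% label noise
bench <- generate_benchmark(synthetic_config(rng_seed = 11))
table(bench$records$label)   # balanced by construction, then 5% label noise
#>    0    1
#> 2999 3001

# TCR-disjoint folds: no receptor sequence is shared between folds
fa <- make_folds(bench$records, n_folds = 10, mode = "tcr_split", rng_seed = 21)
d  <- apply_folds(bench$records, fa)
train <- d[d$fold > 2, ]; val <- d[d$fold == 2, ]; test <- d[d$fold == 1, ]

# K-NN baseline at k = 13
knn <- knn_model(train, k = 13)
evaluate(predict(knn, test), test$label)$roc_auc
#> [1] 0.8598438

# reduced network (16 filters/channel), CPU-sized; best epoch kept by
# validation ROC-AUC
fit <- titan(train, titan_config_reduced(),
             train_control_reduced(rng_seed = 31), validation = val,
             rng_seed = 41)
evaluate(predict(fit, test), test$label)$roc_auc
#> [1] 0.8727943

# where does the model look? attention rows per stream, context-averaged
att <- extract_attention(fit, test[1:50, c("tcr", "epitope")])
agg <- aggregate_attention(att$epitope)
# drop the <START> column so rows align with residues, then compress
compress_epitopes(agg$references, agg$alpha[, -1])$fraction_unique
#> [1] 0

# epitopes as molecules
peptide_to_smiles("GG")
#> <smiles (canonical)> NCC(=O)NCC(=O)O
augment_smiles(peptide_to_smiles("GG"), rng_seed = 3)
#> <smiles> N(C(=O)CN)CC(=O)O
```

The numbers mean: on receptors never seen in training, the baseline ranks
binding pairs above shuffled pairs about 86% of the time and the reduced
network about 87% (here trained on eight folds with one fold as
validation; the package's verification protocol, which trains on nine,
averages ≈0.90 over three seeds) — against a ceiling of ~95% imposed by
the 5% label noise. The compression result is itself informative: after
this short training the epitope attention is still near-uniform (every
weight below the 0.1 threshold), so compressed epitopes are all empty —
the epitope-fingerprinting behaviour that compression detects only
emerges with far longer training on real repertoires. The two SMILES
strings are different renderings of the same glycylglycine molecule,
which is exactly what the augmentation exploits.

A thin command-line front end is installed with the package
(`exec/titan`): `titan synth`, `titan curate`, `titan split`, `titan knn`,
`titan train`, `titan pep2smi`.

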