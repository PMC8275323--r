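---
title: "Methods: bimodal context attention for TCR-epitope binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bimodal context attention for TCR-epitope binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

A T-cell recognizes an antigen when its T-cell receptor (TCR) binds a short
peptide (epitope) presented on an MHC molecule. Given a dataset
$D = \{(e_i, t_i, a_i)\}_{i=1}^N$ of epitope sequences $e_i$, TCR
$\beta$-chain sequences $t_i$ (CDR3 or the full variable region) and binary
binding labels $a_i$, the package learns a map
$\Phi : E \times T \to [0, 1]$ scoring the probability that an arbitrary
(epitope, TCR) pair binds. Two regimes matter and are kept strictly apart by
the splitting protocol: generalization to *unseen TCRs* (new receptors
against known epitopes -- the clinically common case, since public data
pair tens of thousands of TCRs with only tens to hundreds of distinct
epitopes) and to *unseen epitopes* (where current models, this one
included, degrade sharply).

## The K-NN baseline

Before any network, a non-parametric baseline: the distance between a
stored pair $(e_i, t_i)$ and a query pair $(e_j, t_j)$ is the sum of
length-normalized Levenshtein distances

$$D(e_i, t_i, e_j, t_j) = \frac{Lev(e_i, e_j)}{|e_j|} +
  \frac{Lev(t_i, t_j)}{|t_j|},$$

and the prediction is the mean label of the $k$ nearest training pairs.
As printed, both terms are normalized by the *query* lengths, which makes
the measure asymmetric when lengths differ; we implement exactly that, with
a `symmetric = TRUE` variant (normalizing by mean lengths) available for
study. Only odd $k$ are used so binary votes cannot tie; the sweep protocol
evaluates $k \in \{1, 3, \ldots, 25\}$ by cross-validated ROC-AUC and keeps
the best (ties to the smaller $k$). Distance ties at the $k$-th rank are cut
by stable training order, a deterministic choice the distance itself does
not pin down.

## Sequence encodings

Both streams are tokenized the same way: a shared `<START>`/`<STOP>` flank
token (index 1) around the residue tokens, zero-padded (index 0) to a fixed
length. Amino acids are embedded by one of three schemes:

* **BLOSUM62** (default): each residue's row of the substitution matrix
  over a 26-symbol alphabet (20 standard residues, B/Z/X ambiguity codes,
  U/O with zero rows since the published matrix does not cover them, and
  `*`). This makes the rows 26-dimensional while keeping the published
  scores untouched. Fixed, not trainable.
* **biophysical**: seven physicochemical properties per residue (molecular
  weight, residue weight, pKa, pKb, pKx, pI, hydrophobicity at pH 2),
  z-scored per property over the 20 residues so the heterogeneous units are
  comparable. Fixed.
* **learned**: a 32-dimensional trainable table, randomly initialized under
  the model seed. Also used for SMILES token streams.

The padding row of every table is pinned to zero (and its gradient masked),
so padded positions contribute nothing to convolutions; they still receive
attention mass, as the reference architecture applies no masking -- a
masking flag exists but defaults off.

## Epitopes as molecules: SMILES

Because epitopes are short (5-15 residues), they can be treated as small
molecules. `peptide_to_smiles()` builds the linear peptide explicitly: the
20 residue templates are stored as kekulized molecular graphs with explicit
hydrogens only on stereocentres (L configurations; 2S,3R threonine and
2S,3S isoleucine), and peptide bonds condense the chain N-to-C, removing
one water per bond. The SMILES string is then written by depth-first
traversal of the graph. Since *any* traversal order yields a valid SMILES
of the same molecule, augmentation (`augment_smiles()`) simply restarts the
traversal at a random atom with a random neighbour order; tetrahedral
parities are re-derived for the written neighbour order by permutation
parity, so stereochemistry survives augmentation. Canonicalization -- and
therefore the augmentation-invariance property
`canonicalize(augment(s)) == canonicalize(s)` -- is delegated to OpenBabel,
an independent implementation that never sees the package's graph code.
Stereochemistry is included by default and can be stripped with
`stereo = FALSE`; whether the original pipeline encoded it is not
documented, and the flag makes either choice reproducible.

The atom-level tokenizer treats bracket expressions, two-letter elements,
ring-closure digits and bond symbols as single tokens; the vocabulary
reserves indices 0 (pad), 1 (flank) and 2 (unknown) and should be built
from canonical *and* augmented forms so training never hits unknowns.

## The bimodal attention network

Each stream passes its embedded sequence through parallel channels:
one 1D convolution (same-padding, ReLU, dropout) per kernel size -- 3, 5,
11 in the base configuration -- plus a residual channel that forwards the
raw embeddings unchanged (no ReLU: BLOSUM rows are signed). Every channel
owns two context-attention layers, one per direction. For reference
features $X_1 \in \mathbb{R}^{T \times H}$ and context features
$X_2 \in \mathbb{R}^{U \times K}$,

$$u = \tanh(X_1 W_1 + W_3 (X_2 W_2))\, v, \qquad
  \alpha = \mathrm{softmax}(u),$$

with $W_1 \in \mathbb{R}^{H \times A}$, $W_2 \in \mathbb{R}^{K \times A}$,
$W_3 \in \mathbb{R}^{T \times U}$, $v \in \mathbb{R}^A$ and attention space
$A = 16$ (256 in the pretraining variant). Both modalities are projected
into the common attention space and summed, so the importance of each
reference position depends on the binding partner. The attention weights
"filter" the reference; the architecture description leaves the pooling
unstated, and we use the standard attention readout, the
$\alpha$-weighted sum over positions, giving one length-$H$ vector per
channel per stream. Each channel and direction owns its own $W_1, W_2,
W_3, v$ (whether they are shared is not documented; per-channel parameters
are the more general choice). The concatenated readouts feed a dense stack
(368 and 184 units, ReLU, dropout 0.5) ending in a single logistic output
-- the binding probability, trained with binary cross entropy, which is
what makes the logistic output the canonical choice.

The convolution filter counts $H$ and $K$ are not pinned down by the
reference description; the package defaults to 32 per channel, fully
configurable, and makes no claim that this reproduces the original
parameter count.

Training uses Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) at learning rate $10^{-4}$ and batch size 512 by
default. No early stopping or schedule is prescribed; we train a fixed
number of epochs and, when a validation set is supplied, keep the
parameters of the epoch with the best validation ROC-AUC (epoch-wise
validation tracking). With SMILES augmentation on, every epitope is
re-rendered as a fresh random SMILES each epoch.

The network, its gradients and the Adam loop are implemented in dense base
R linear algebra. Backpropagation was validated against central finite
differences on every parameter tensor during development; the context
attention layer is additionally pinned to a literal recomputation of its
defining formula in the test suite.

### Semifrozen fine-tuning

For transfer from compound-protein interaction (CPI) data, the epitope
stream can be frozen (`set_trainable_scopes(model, "semifrozen")`): its
embedding table, convolutions and the attention layer that attends *over
the epitope* stay at their pretrained values, while the TCR stream and the
dense stack adapt. The attention layer attending over the TCR belongs to
the TCR channel (its $W_2$ consumes epitope features but parameterizes the
TCR readout) and stays trainable. This protects chemistry learned from
diverse ligands against being unlearned on fine-tuning data that contains
only a few hundred distinct epitopes.

## Data pipeline

Curation keeps epitopes with at least 15 associated (deduplicated) TCRs
and uniformly downsamples epitopes above 400 TCRs -- the downsampling rule
is not further specified, and a seeded uniform draw is the neutral choice.
Negatives are generated by shuffling: each TCR is paired with exactly as
many epitopes it is *not* recorded to bind as it has positives, giving an
exact 50/50 balance; sampling is uniform over the admissible epitope set,
and a TCR with no admissible epitope (e.g. a single-epitope scope)
contributes no negatives, with a warning.

Two split protocols: the *TCR split* assigns whole TCRs to folds (shuffled
round-robin), so validation TCRs are never seen in training; the *strict
split* assigns whole epitopes to folds (greedy record-count balancing,
largest epitope first into the smallest fold -- the assignment rule is
otherwise unspecified) and then resolves TCRs spanning folds by keeping
each in the fold holding most of its records (ties to the lowest fold
index). Negatives are generated *within* folds, preserving disjointness.
CPI pretraining tables are binarized (every listed pair is a positive),
length-filtered (ligands over 250 SMILES tokens, proteins over 1028
residues dropped), balanced with random ligand-protein reassignment checked
against the positive set, and split 90/10.

## The synthetic benchmark

`generate_benchmark()` emulates the shape of curated repertoire data --
tens of epitopes (default 30, lengths 8-11), many CDR3-like TCRs per
epitope (default 100, lengths 10-18, uniform composition), balanced labels
-- with a planted, recoverable rule:

* **motif_match**: each epitope owns a unique contiguous 3-mer motif; its
  positive TCRs carry that motif at a random internal position (and no
  other epitope's motif), its negatives carry no motif at all. Labels are
  flipped with probability 0.05 by default, so a perfect rule-reader tops
  out near ROC-AUC 0.95. Learnability is verifiable: a motif-presence
  oracle scores near the ceiling, a motif-blind statistic sits at chance.
* **epitope_class_only**: labels follow a per-epitope Bernoulli base rate
  (uniform in 0.2-0.8) and the TCR carries no information. Under a strict
  split this makes chance-level performance on held-out epitopes a matter
  of construction, reproducing the unseen-epitope failure mode: a model
  can only memorize epitope identities, which are all new at test time.

What the generator does *not* emulate: V(D)J recombination statistics,
CDR3 length-composition coupling, MHC restriction, cross-reactive motifs,
class imbalance across epitopes of real repertoires. Passing the planted
benchmarks therefore certifies the pipeline mechanics and the models'
capacity to recover a clean signal at desk scale -- not performance on
real repertoire data.

## Desk-scale configuration and problem sizes

`titan_config_reduced()` / `train_control_reduced()` are the desk-scale
presets used by the package's own checks, chosen once for CPU-only
hardware: padded lengths 20 (TCR) and 13 (epitope) covering the
generator's ranges, 16 filters per channel, attention space 16, dense
stack 368/184, dropout 0.25, batch size 64, learning rate $2 \times
10^{-3}$ and up to 30 epochs. The learning rate is scaled up from the reference $10^{-4}$
in proportion to the smaller batch and much smaller model, and dropout is
lowered because the reduced network is far from the overparameterized
regime the 0.5 default targets. Verification runs use a 10-fold TCR split
of the default 30x100 benchmark with one fold held out (about 5400
training records), training three seeds with epoch-wise validation
tracking on the held-out fold and best-epoch checkpointing; the
strict-split degeneracy check uses the epitope_class_only benchmark of
the same size. At this training budget individual runs scatter by about
±0.02–0.03 ROC-AUC across seeds (optimization-trajectory noise — the
non-parametric baseline is stable on the same benchmarks), which is why
the checks average several seeds.

## Numerical choices and degenerate inputs

* ROC-AUC is the normalized Wilcoxon statistic with midranks, so tied
  scores count one half; it errors on single-class inputs. Balanced
  accuracy thresholds at 0.5 (no calibration procedure is prescribed).
* Fold summary "±" values are population standard deviations across folds
  (the estimator behind the reference "±" is not documented; the sample
  estimator is one flag away).
* Attention variance statistics default to the population estimator, with
  `estimator = "sample"` available, since the original statistic's
  estimator is likewise not documented.
* Softmax is computed with the max-subtraction trick; attention over an
  all-constant $u$ (e.g. zero embeddings) is exactly uniform.
* Epitope compression keeps residues with $\alpha$ strictly above the
  threshold; at threshold 0 it is the identity on any softmax output
  (all $\alpha > 0$).
* Training aborts with diagnostics on a non-finite loss; the BCE is
  computed in the numerically stable log1p form.
* Levenshtein distances accept empty strings ($Lev(s, "") = |s|$), but
  pair distances reject empty *query* sequences, whose lengths normalize
  the metric.
* All stochastic steps (curation downsampling, negative draws, fold
  assignment, initialization, shuffling, dropout, augmentation) run under
  explicit seeds through an RNG-state-preserving wrapper, so every result
  in the package is bit-reproducible.

## Known limitations

* Published headline numbers for models of this family (cross-validated
  ROC-AUCs on repertoire databases such as VDJdb or ImmuneCODE,
  BindingDB-pretrained transfer results, attention-variance statistics and
  compression counts on hundreds of real epitopes) require external
  database downloads and GPU-scale training; nothing in this package
  claims to reproduce them. The package reproduces the *methods* and
  their qualitative behaviour at desk scale.
* The biophysical table uses standard reference values; any source the
  original authors used would differ at most in scaling, which the
  z-scoring absorbs structurally but not numerically.
* Augmenting stereo SMILES from arbitrary external strings loses
  stereocentres (the OpenBabel SD round trip used for parsing does not
  carry them); molecules built by `peptide_to_smiles()` keep theirs, since
  augmentation rewrites the package's own graph.
* The K-NN baseline is exact (full distance matrix); no metric trees are
  used, which is appropriate for the data sizes the package targets.
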