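---
title: "Models and methods behind sbipredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sbipredict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sbipredict` predicts typed interaction events between small-molecule drugs
(SMDs, SMILES strings) and biotech drugs (BioDs, amino-acid sequences).
This vignette documents the models, the tunable parameters, the synthetic
benchmark, and the numerical and design choices a maintainer should know
about.

## The prediction problem

A corpus records positive SMD–BioD interactions as quaternaries
`(drug A, drug B, mechanism, action)`; the `(mechanism, action)` pair
defines the event class. Event ids are assigned by descending frequency
(ties broken lexicographically); every event observed no more than
`min_count = 10` times is merged into a single rare bucket placed last.
Class 0 is reserved for "no interaction", so a corpus with `K` event ids
yields a `(K + 1)`-class multi-label problem: a pair with several recorded
quaternaries has several event bits set, and an output layer neuron per
class carries a sigmoid activation. Whether a rare bucket exists is decided
by the data rather than fixed a priori — `event_catalog` objects make the
class count explicit so the output layer is always sized to the corpus.

The candidate space is the full `|SMD| x |BioD|` product. Pairs absent from
the positive set are *unlabeled*, not negative — the motivation for the PU
stage below.

## Drug representations (four modalities)

**Token channel (CNN).** Characters map to integer codes via a vocabulary
derived from the corpus (index 0 = padding, one reserved index for unseen
characters so novel drugs can still be scored). SMILES are padded/truncated
to 1000 tokens, sequences to 100. Each channel is encoded by three 1D
convolutions (kernel 8; filter counts `f`, `2f`, `3f`; ReLU) and global max
pooling; the two pooled vectors (length `3f` each) are concatenated. The
corpus-derived vocabulary is recorded with the features; on the reference
corpus the SMILES alphabet has 64 characters and the sequence alphabet 25.

**Fingerprint / embedding channel.** SMDs get a daylight-style hashed
topological fingerprint: all simple atom–bond paths of up to 7 bonds are
enumerated on the molecular graph (parsed from SMILES by OpenBabel via
ChemmineR), written as canonical element/bond-order strings (lexicographic
minimum of the two read directions), hashed with 32-bit FNV-1a, XOR-folded
to 16 bits, and mapped onto 1024 binary bits. Enumerating on the parsed
graph makes the fingerprint invariant to how the SMILES was written. It is
equivalent in kind, not bit-identical, to other toolkit implementations;
the featurizer name and version ride along with the feature matrix.
BioDs get a deterministic 1280-dimensional embedding: the sequence is
truncated to its first 1024 residues, overlapping 3-mers are counted and
hashed into 2048 bins, L2-normalized, and projected by a fixed seeded
Gaussian matrix. A pretrained protein language model can be plugged in
through the `external` backend (any function returning `n x 1280`); the
fallback keeps the package self-contained and reproducible offline.

**Topology channels.** Four prior-knowledge networks enter as edge lists:
SSI (SMD–SMD), BBI (BioD–BioD), SPI (SMD–protein), BPI (BioD–protein).
A drug's one-hot profile over a network's partner universe (the sorted
union of nodes observed in that network, persisted so inference-time
profiles align) is converted to Jaccard similarities against all same-type
drugs; the similarity row is the drug's topology feature, so its dimension
equals the drug count of its type. Two empty profiles have Jaccard 0 by
convention (0/0 in the set formula): isolated drugs share no evidence.
SMD rows are PCA-compressed to `min(512, |SMD|)` dimensions (centered,
deterministic eigendecomposition, component signs fixed by making the
largest-magnitude loading positive); BioD rows stay raw. SPI/BPI-derived
and SSI/BBI-derived blocks are separate modalities feeding separate
sub-models.

PCA is fitted on all drugs' Jaccard rows (transductive). The rows use only
network structure, never interaction labels of held-out pairs, and the four
input networks cannot contain an SMD–BioD edge by construction, so the
transform is label-disjoint from the prediction target. A strict
train-only fit is available by calling `reduce_pca()` on training rows and
`project_pca()` on the rest.

## PU undersampling

For `t = 1..T`: draw `|P|` unlabeled pairs uniformly without replacement as
temporary negatives, train one decision tree (positives = 1, draw = 0) on
the concatenated dense pair features, and score *all* unlabeled pairs with
the tree's leaf positive-class fraction (a probability, so averaging is
meaningful). A pair's mean score over the `T` repetitions is its
confidence of being a hidden positive. Selection removes pairs with mean
score ≥ θ (default 1.0: only unanimously positive-scored pairs, with θ
exposed because strict unanimity is fragile under probability averaging)
and keeps the `n = |P|` lowest-scoring pairs, ties broken by pair id.

Choices worth recording: `T` defaults to 50 (score variance decays as
`1/T`; the desk-scale harnesses use 25, which already stabilizes ranks on
3,600-pair universes); trees are `rpart` with depth 4 and ≥5 samples per
leaf ("simple" trees); every tree scores all unlabeled pairs including the
ones it trained on — at realistic `|U|` the self-scoring bias affects a
vanishing fraction of each pair's `T` evaluations. Scoring at scale walks
the fitted tree vectorized rather than through `predict.rpart`'s
model-frame machinery (verified equal in the tests).

## Sub-models, fusion, training

Every modality ends in the same head: dense 512 → 256 → `n_classes`, ReLU
on hidden layers, dropout 0.3, sigmoid outputs, mean per-class binary
cross-entropy (multi-hot targets — several event neurons may be active at
once, which rules out softmax). The ensemble is the unweighted arithmetic
mean of the sub-model outputs; ablations use any subset via an explicit
flag. Training uses Adam (default learning rate 1e-3; 0.3 is selectable
but diverges in practice with Adam), up to 100 epochs, batch size 256,
early stopping when validation loss has not decreased for 10 epochs, with
best-validation weights restored. The validation split is a stratified 10%
of each training fold. Hidden activation (ReLU), batch size, and the token
embedding width (128) are field-standard defaults where the architecture
leaves them open.

The CNN computes convolutions only out to the longest sequence in the data
plus a margin wide enough that every shorter sample retains at least one
all-padding window after the three convolutions; since all-padding windows
produce identical values, the global max pool equals the full padded-length
computation at a fraction of the cost. The padding token embeds to a frozen
zero vector. All gradients (dense, convolution, embedding, pooling) are
checked against finite differences in the test suite; fixed seeds make
training bitwise reproducible in single-threaded BLAS.

## Evaluation

Stratified 5-fold cross-validation over drug pairs (stratum = first active
event, small strata pooled), with the six-metric panel: accuracy,
precision, recall, F1 at threshold 0.5; trapezoidal ROC area; and
step-interpolated precision–recall area. The default averaging is *micro*
(per-class indicators pooled over all classes before any ratio), matching
the convention under which frequent classes dominate and reported AUCs run
close to 1; *macro* (per-class, then averaged) is available via
`average = "macro"`.

Two properties of this design deserve explicit statement, because the
package's own null-calibration harness must work around both:

- **Micro AUC has a high no-information level.** A model that learns only
  the class priors (class 0 covers half of a balanced pair set, each event
  class is rare) ranks class-0 indicators above event indicators and
  scores far above 0.5 micro AUC with zero within-class discrimination.
  The macro AUC of the same prior-only scores is 0.5, which makes macro
  the meaningful chance reference (asserted in the tests).
- **Pair-level splits leak drug-frequency information.** With drugs shared
  between folds and a balanced evaluation set, a model can memorize each
  drug's realized positive frequency; that memorization genuinely
  correlates with held-out labels even when labels are independent of all
  features. `null_calibration()` therefore evaluates on a drug-disjoint
  (`cold_split()`) test set — no drug shared between train and test — and
  checks (a) macro AUC ≈ 0.5 and (b) micro AUC ≈ its label-permutation
  reference. Signal-bearing experiments keep the standard pair-level
  protocol, which is the field's convention; cold splitting is exposed for
  users who need drug-level generalization estimates.

## The synthetic benchmark

`generate_universe()` plants a low-dimensional Gaussian latent factor per
drug and per protein. SMILES are assembled from a chain-safe fragment
grammar (alkyl/aryl/carbonyl/heteroatom fragments whose concatenations are
always valid molecules), with fragment choice biased by the drug's factor;
residue composition of BioD sequences is likewise factor-biased, so both
structure channels carry signal. Edges in all four networks are Bernoulli
draws whose logits contain latent inner products, making network
neighborhoods informative. A pair's interaction propensity combines
latent-factor affinity with its shared-protein count, with the intercept
calibrated (by root finding) so the realized positive rate matches
`positive_rate`; event classes are drawn from a multinomial whose logits
are scaled by `signal_strength`. `signal_strength = 0` yields labels
independent of every feature — the null model. A configurable fraction of
true positives is withheld from the labeled set ("hidden positives",
exchangeable with labeled ones by construction), which is exactly the
contamination PU undersampling is meant to avoid.

Defaults are desk scale: 120 SMDs, 30 BioDs, 80 proteins, 6 events,
positive rate 0.10, hidden fraction 0.10, signal strength 2 — big enough
for stratified 5-fold cross-validation, small enough that the full
acceptance harness runs in minutes. What the generator does *not* emulate:
chemically realistic molecules, homologous sequence families, scale-free
degree distributions, or corpus-level event imbalance beyond a random
per-event offset. Passing the harness therefore demonstrates that the
pipeline recovers planted multi-modal signal and that PU selection avoids
planted hidden positives — not that real-corpus accuracy magnitudes are
reproduced, which requires the licensed source data.

## Harness problem sizes

The packaged experiment drivers run single stratified 80/20 splits per
seed with reduced training schedules (≤20–30 epochs, patience 5), CNN
filter base `f = 16` with embedding width 16, and `T = 25` PU repetitions;
the sampling comparison uses the fingerprint/embedding sub-model as its
downstream classifier. These are the package's desk-scale choices — large
enough that orderings (PU > random; ensemble ≥ single modalities) are
stable across seeds, small enough for interactive use. All of them are
arguments, so paper-scale schedules (100 epochs, patience 10, `f = 64`,
`T = 50`, full 5-fold) are one call away.

## Known limitations

- The fingerprint covers linear paths only (no ring-closure or branch
  features beyond what paths capture), matching the daylight family but
  not richer circular fingerprints.
- The fallback protein embedding is a bag-of-3-mers projection; it carries
  composition, not long-range structure. The external backend exists for
  pretrained language models.
- Training is CPU BLAS; at corpus scale (hundreds of thousands of pairs)
  the CNN channel in particular would need a GPU-backed implementation.
- `rpart` trees and the dense heads assume the flat feature recipe fits in
  memory; at 287k pairs × ~2,600 features the score table is built in one
  pass but peak memory is a few GiB.
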