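---
title: "Predicting bacterial gene essentiality from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bacterial gene essentiality from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(essnet)
```

`essnet` predicts whether a bacterial gene is essential using only its
coding DNA and protein sequence. This vignette explains the model, the
assumptions behind every stage, the tunable parameters and their defaults,
what the synthetic corpus generator does and does not emulate, and the
numerical and design choices a maintainer should know about.

## The feature representation

Each gene/protein pair maps to a fixed, ordered vector of 89 values
(`feature_layout()`):

| block | values | definition |
|---|---|---|
| codon frequencies | 64 | in-frame codon counts of the gene, normalized by the gene's complete-codon total; codons ordered lexicographically AAA..TTT |
| GC content | 1 | (G+C)/(A+C+G+T), ambiguity letters excluded from both terms |
| gene length | 1 | nucleotides of the CDS, including the stop codon |
| CAI | 1 | geometric mean of relative adaptedness over the gene's codons |
| RSCU max | 1 | maximum relative synonymous codon usage over degenerate non-stop families |
| amino-acid frequencies | 20 | frequencies of the 20 standard residues, A..Y |
| protein length | 1 | standard residues, excluding a trailing stop |

Codon counting reads non-overlapping triplets from position 0: the input
is assumed to be the coding strand in frame, as curated essentiality
collections provide coding sequences directly, so no ORF search is
performed. A trailing incomplete triplet is discarded and any triplet
containing a non-ACGT character is skipped without entering the
denominator — real FASTA dialects contain ambiguity codes and erroring on
them would reject otherwise usable records.

Relative synonymous codon usage compares each codon's count with the count
expected under uniform synonymous usage: for codon $i$ in an $n$-fold
degenerate family with family total $S$,
$\mathrm{RSCU}_i = X_i / (S/n)$. A family with $S = 0$ is assigned RSCU 0
for all members — a convention, since the ratio is undefined; it keeps the
feature finite and flags absence rather than inventing uniformity. The
single-value `rscu_max` feature is taken over degenerate ($n \ge 2$)
families excluding Met, Trp and the stop family, whose RSCU is constant or
meaningless for bias measurement.

The codon adaptation index is
$\mathrm{CAI} = (\prod_{i=1}^{L} r_i)^{1/L}$ with relative adaptedness
$r_i = X_i / X_{\max}$ computed **within each amino-acid family** of a
reference count set, so each observed family's most frequent codon scores
exactly 1. The per-family reading is the standard construction of the
index; a global maximum would collapse the scores of low-usage families.
Codons absent from an observed family receive the usual pseudo-value
$0.5 / X_{\max}$ so the geometric mean can never hit an exact zero;
Met, Trp and stop codons are excluded from both the table and $L$. The
product is evaluated in log space. The reference set defaults to the
gene's own counts — matching the index's definition directly on the
gene's $X_i$ — and `feature_matrix(reference = "species")` instead pools
all genes of a species into one reference, the choice to make when a
curated highly-expressed reference set is unavailable but cross-gene
comparability matters.

## The classifier

The classifier is a fully-connected feed-forward network: input width 89,
hidden widths 128, 256, 512, 1024, 1024, 1024 with ReLU activations and
dropout, and a two-unit output layer normalized to a probability pair. A
per-unit sigmoid cannot make two outputs sum to one, so the output head is
a two-unit normalized exponential (softmax) — equivalent to a sigmoid
applied to the difference of the two logits — which honours the
probability-pair contract exactly. Training minimizes mean binary
cross-entropy with minibatches and stops early once validation loss has
failed to improve for `patience` consecutive epochs, restoring the
best-validation weights.

Tunable parameters (`mlp_config()`), with defaults:

* `hidden_dims = c(128, 256, 512, 1024, 1024, 1024)` — the selected
  architecture; smaller stacks train faster and suffice for strongly
  separable corpora.
* `dropout_rate = 0.3` — fraction of hidden units dropped per training
  batch (inverted scaling, inactive at inference).
* `max_epochs = 100`, `patience = 10` — epochs are capped and early
  stopping acts on validation loss; patience is a stability/overfitting
  trade-off and is not critical within 5–15.
* `batch_size = 256` — minibatch size (dimensionless records).
* `optimizer = "adadelta"` — adadelta needs no learning rate (its
  standard constants, decay 0.95 and epsilon 1e-6, are fixed); `sgd`,
  `adam` and `rmsprop` are available with `learning_rate` (default 0.01).
* `seed` — controls He-normal weight initialization
  (sd $\sqrt{2/\text{fan-in}}$, the standard choice for ReLU stacks),
  batch shuffling and dropout masks; identical seeds give identical
  models.

Feature standardization (train-partition mean/sd, constant features given
scale 1) is applied before training. It is an addition for optimizer
stability — raw features mix scales from ~1e-2 (frequencies) to ~1e3
(lengths) — and is fitted on the training partition only; the
`fit_standardizer()` contract rejects any other partition, because
statistics from validation or test data would leak into training.

## Balancing, splitting, and the homology leak

Curated corpora contain several-fold more non-essential than essential
genes, which biases a cross-entropy classifier toward the majority class.
The corpus is therefore balanced first — the majority class is
down-sampled uniformly at random to the minority size, globally across
species — and split afterwards, so all partitions are balanced by
construction.

`random_split()` partitions 80/10/10 (floor rule, remainder to test) with
per-class stratification; repeated evaluation (`repeated_experiment()`)
re-splits with seeds `base_seed + k`, i.e. repeated random subsampling
rather than ten-fold cross-validation, matching the repeated-selection
procedure the evaluation protocol describes. Splits are stratified by
class but not by species: class balance is what the loss is sensitive to,
and species stratification would entangle the split with the orthology
structure that the cluster-aware policy handles explicitly.

Bacterial genomes share large cores of conserved genes; two orthologs in
different species can be nearly identical in sequence. If one lands in
training and the other in testing, the classifier is partly evaluated on
memorized near-duplicates — a data leak. `cluster_aware_split()` removes
it by assigning whole orthology clusters to single partitions. Clusters
are placed largest-first (shuffled within equal sizes by the seed) into
the partition with the largest remaining deficit relative to its gene
count target, ties resolving to train. A strictly sequential fill
(train until full, then validation, then test) can leave a partition
empty whenever a large cluster arrives mid-sequence, so the deficit rule
is used instead; realized fractions can still deviate from targets —
whole clusters are indivisible — and are reported in a message. A cluster
larger than the entire train target is forced into train with a warning.
The cluster-disjointness constraint is enforced between **all** partition
pairs, not only train/test, because validation drives early stopping and
leaks there would bias model selection the same way.

Genes without a cluster assignment get singleton clusters, so the policy
degrades gracefully to a random split when no clustering is supplied.
Orthology clustering itself (e.g. reciprocal-best-hit graph clustering) is
consumed as an external two-column table; it is deliberately out of scope.

## Metrics

Essential is the positive class; probabilities at the 0.5 threshold (a
convention; ties classify positive) yield TP/FP/TN/FN and Sn, Sp, PPV and
accuracy by their standard formulas. A metric with a zero denominator is
reported as `NA` — distinct from zero — and flagged, so aggregates are
not silently skewed. The ROC curve sweeps all distinct scores with tie
groups collapsed, which makes trapezoidal integration equal the pairwise
concordance probability $P(s_+ > s_-) + \tfrac12 P(s_+ = s_-)$ exactly
(the property the test suite checks against an exhaustive pairwise
oracle). AUPR uses step-wise summation without interpolation, recorded in
the report metadata since interpolated variants differ.

## Feature ablation

Pairwise Pearson correlations over the feature table identify pairs with
$|r| > 0.9$; such pairs are merged into single ablation units (and chains
of qualifying pairs are merged transitively — overlapping pairs can occur
on arbitrary data even if a given corpus shows only disjoint ones).
Removing only one member of a correlated pair would be compensated by the
other — the very reason for grouping — so **both** members are removed
together. Each unit's importance is the drop in mean test-fold AUC under
a class-stratified 5-fold cross-validation whose fold assignment is fixed
once per study: baseline and every ablated run reuse identical folds and
identical training seeds, so deltas reflect the removed features, not
resampling noise. Ablated models are retrained with the reduced input
width rather than zero-masking the column: a masked zero is still the
standardized mean and would let the network keep weights adapted to the
feature's distribution.

## The synthetic corpus generator

No public corpus ships with the package; `generate_corpus()` creates one
with the statistical structure the method assumes:

* **Class-conditional codon usage.** A base distribution over the 61
  sense codons is drawn from a symmetric Dirichlet (shape 5, giving
  realistic non-uniform usage); the essential class is tilted by
  multiplying codon probabilities with $\exp(s \cdot d_c)$ for a fixed
  standard-normal perturbation $d$ and strength $s$
  (`codon_bias_strength`, default 0.5, producing per-codon frequency
  contrasts of the tens-of-percent magnitude seen between real classes).
* **GC offset.** `gc_shift` (default 0.3) reweights codons by their GC
  fraction in opposite directions for the two classes, giving
  non-essential genes a few percentage points more GC — the direction
  and rough size observed in curated corpora.
* **Lengths.** Gene lengths in codons are log-normal per class
  (defaults: essential median 320 codons, non-essential 280, log-sd
  0.35, floored at 30), reflecting that essential genes trend longer.
* **Orthologous families.** A fraction `ortholog_family_rate` (default
  0.3) of genes belong to families spanning ≥2 species: an ancestor is
  generated, then copied per species with per-base substitution at
  `mutation_rate` (default 0.05), biased toward third codon positions
  (where substitutions are mostly synonymous) and constrained never to
  create internal stops or destroy the start/stop; labels are shared
  within a family and the family is one cluster.
* **Label noise.** With `label_noise` q, a whole cluster unit carries the
  label opposite to the class its sequences were drawn from with
  probability q. `synthetic_leak_config()` (4 species × 600 genes,
  balanced classes, family rate 0.6, mutation 0.02, noise 0.25) uses this
  to expose the leak: flipped families are unpredictable from sequence
  composition, but under random splitting their near-identical members
  appear in both training and testing, so the network recovers their
  labels by memorization — exactly the optimism cluster-aware splitting
  removes.

Every generated record is a valid coding sequence whose protein is its
exact bacterial-code (NCBI table 11) translation. The generator emulates
only the features the classifier consumes; it does **not** reproduce
operon structure, strand asymmetries, regulatory regions, genome-wide GC
heterogeneity, pseudo-genes, or annotation noise in real curated corpora.
Passing tests on synthetic corpora therefore demonstrate that the
pipeline recovers planted signal of realistic shape and direction, not
that any particular accuracy will transfer to real genomes.

## Numerical choices and degenerate inputs

* CAI is computed in log space; exact 1 is attained (not merely
  approached) for genes using only family-maximal codons.
* Sequences with no complete unambiguous codon, proteins with no standard
  residue, references with zero counts, and single-class label vectors
  raise classed invalid-input errors naming the offending record.
* Constant features standardize to zero (scale forced to 1) and correlate
  as 0 with a warning.
* Probability ties at the classification threshold count as positive;
  score ties in ROC/PR are grouped at one threshold.
* All stochastic stages (balancing, splitting, initialization, dropout,
  generation) consume explicit seeds; a single run seed fans out to
  per-stage seeds by hashing the stage name, so stages are independently
  reproducible. Functions restore the caller's RNG state.

## Problem sizes used by the shipped checks

The test suite exercises parameter recovery on the generator's default
corpus (3 species × 2000 genes, 5 repeated splits), the leak direction on
the leak preset (2400 genes, 5 paired repetitions per policy), and
ablation sanity on a 1400-gene corpus whose only planted signal is the
length contrast (so the merged gene-length/protein-length unit must rank
first, with pure-noise units moving AUC by ≤ 0.02). The experiment
harness in these checks uses compact hidden stacks (two layers, 8–32
units), which recover planted synthetic signal as reliably as the
full-width default architecture while keeping the suite quick to run; the
default architecture itself is validated structurally and on separable
data in the classifier tests.

## Known limitations

* The CAI reference defaults to self-referential counts; against a
  curated highly-expressed reference the absolute CAI values would
  differ, though the feature remains informative either way.
* Repeated random subsampling gives overlapping test sets across
  repetitions; the reported sd understates fully independent variation.
* The ablation study retrains one model per unit and fold; with all 80+
  units and large corpora this is the most expensive operation in the
  package — restrict `units` or reduce folds for exploratory runs.
* Cluster-aware partitions cannot hit exact 80/10/10 when clusters are
  large relative to the corpus; realized fractions are reported and
  should be checked before comparing metrics across policies.
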