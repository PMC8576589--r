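---
title: "Confidence-weighted embeddings of noisy biomedical knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted embeddings of noisy biomedical knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgembed)
```

## The problem

Literature-derived biomedical knowledge graphs are built by NLP pipelines
that read abstracts and emit [subject-predicate-object] predications, e.g.
[drug A - TREATS - disease B]. The extraction step is imperfect, so a
non-trivial fraction of the stored triplets are wrong. Crucially, the
extraction pipeline also leaves behind confidence metadata for every
triplet:

* a **subject score** and an **object score** — the NLP engine's confidence
  that a text span maps to the stated concept (in SemMedDB-style stores
  these range up to 1000), and
* a **co-occurrence count** — how many times the triplet was extracted from
  the literature.

Standard graph-embedding methods (DeepWalk, TransE) treat every edge as
equally trustworthy. `kgembed` implements both methods *and* their
confidence-weighted variants, which exploit the metadata so that
representation learning leans on trustworthy triplets and leans away from
dubious ones. The learned concept vectors feed two downstream tasks:
classifying drug–disease pairs as adverse-drug-event (ADE) relationships
or not, and classifying drug–side-effect–drug polypharmacy triples as
valid or not.

## The models

### Triplet confidence scores

For a triplet with subject score $s_{v_j}$, object score $s_{v_i}$ and
co-occurrence count $c_p$, the raw weight is the product

$$W_{ijp} = (w_j s_{v_j}) \times (w_i s_{v_i}) \times (w_p c_p),$$

with user multipliers $w_j, w_i, w_p \ge 0$ (default 1 each; a grid-search
helper `tune_weights()` is available because useful non-unit values are
data-dependent). Raw weights are max-normalized over the whole graph,
$f_{ijp} = W_{ijp} / \max W$, giving scores in $(0, 1]$. Two numerical
choices matter here:

* the **normalization denominator is the global maximum**, computed once
  before walking. The raw products reach $10^{10}$ on real stores, and a
  single global constant both tames them and keeps scores comparable
  across neighbourhoods;
* a **score floor** (default $10^{-6}$) is applied inside the product so a
  zero mapping score can never produce a zero weight — Weighted TransE
  later divides by $f$.

### Weighted DeepWalk

DeepWalk starts $N$ truncated random walks of length $L$ at every vertex
and feeds the walk corpus to skip-gram negative sampling (SGNS). Plain
DeepWalk picks the next step uniformly from the neighbourhood, probability
$1/|H(v)|$. Two changes produce the weighted variant:

1. the walk traverses **(predicate, vertex) pairs**, so reaching the same
   neighbour through two predicates gives two distinct outcomes — the
   natural neighbourhood for a heterogeneous graph without metapath
   schemes; and
2. the next pair is drawn from a **softmax over the normalized scores** of
   the current neighbourhood,
   $p_k = e^{f_k/T} / \sum_m e^{f_m/T}$,
   computed with the max-shift trick. The temperature $T$ (default 1) is
   exposed for sensitivity analysis only.

Walks therefore drift toward high-confidence regions while remaining
ergodic: every entry keeps positive probability, so low-co-occurrence but
genuine relations still receive training signal through the many walks
that pass near them. Embeddings are L2-normalized after training, so
cosine similarity is a dot product.

Graphs are traversed **undirected by default** (each triplet is mirrored
into the object's adjacency). This keeps walks from stranding at sink
objects; directed traversal is available as a flag, in which case walks
that reach a sink simply stop early.

### Weighted TransE

TransE learns entity and relation vectors such that $h + l \approx t$ for
stored triplets, by minimizing the margin-ranking loss over corrupted
triplets (head *or* tail, never both, replaced by a random entity). The
energy of a triplet is $d(h + l, t)$ with $d$ the L1 or L2 norm (L2
default). The weighted variant divides each positive triplet's energy by
its confidence:

$$\mathcal{L} = \sum \left[\gamma + \frac{d(h+l,t)}{f} - d(h'+l,t')\right]_+.$$

With every $f = 1$ this is bit-for-bit the unweighted loss, a property the
test suite asserts on random batches. Confidences are clipped to
$[f_{\min}, 1]$ ($f_{\min} = 10^{-3}$ by default) before the division.

Two remarks on this formulation, both deliberate:

* Read literally, dividing by $f \in (0,1]$ *raises* the energy of
  low-confidence triplets inside the hinge, which means the optimizer
  works harder on them, not less — the opposite of what a down-weighting
  intuition suggests. We implement the division exactly as stated because
  it is the published formulation; an ablation flag
  (`weighting = "multiply"`) implements the down-weighting alternative
  for comparison and is off by default. Empirically, on our synthetic
  noisy benchmark the divided form still helps: the inflated positive
  energies of dubious triplets keep their hinges permanently active, so
  those constraints behave like unsatisfiable noise the optimizer cannot
  fit coherently, whereas unweighted TransE satisfies them at the expense
  of real structure.
* Because the positive-term gradient norm is $1/f$ (up to $1/f_{\min} =
  1000$), unclipped SGD steps of size $\alpha/f$ would destabilize
  training. **Per-example gradient steps are clipped to unit L2 norm.**
  For L2 energies the unweighted gradient norm is exactly 1, so clipping
  changes nothing in the unweighted model; it only caps the weighted
  amplification.

Other training choices follow common TransE practice where the
formulation is silent: initialization uniform in
$[-6/\sqrt{k}, 6/\sqrt{k}]$, entity vectors renormalized to unit L2 after
every update step, margin $\gamma = 1$ by default, raw (unfiltered)
negative sampling, with filtered candidate lists available for evaluation
ranks only (`tail_ranks(..., filtered = TRUE)`).

### SGNS trainer

No R implementation of word2vec-style SGNS is available in this
environment's package set, so the trainer is implemented in C++ inside the
package: one positive logistic update plus `negative_samples` noise
updates (unigram distribution raised to 0.75) per (center, context) pair,
dynamic window shrinking, linear learning-rate decay, single-threaded and
deterministic given the seed. Epochs (5) and negative samples (5) default
to standard SGNS practice; window, learning rate and dimension defaults
follow the two task profiles exposed by `profile_params()`:
drug–ADE (L = 500, N = 20, window 4, $\alpha$ = 0.025, dim 256) and
polypharmacy (N = 25, L = 500, window 10, dim 256). `min_count` defaults
to 0 so every graph vertex keeps an embedding — downstream benchmarks
remove pairs whose concepts lack vectors, and frequency pruning would
create avoidable gaps.

## Downstream evaluation

Pair features are the concatenation of the drug and disease embeddings
(length $2k$); polypharmacy features concatenate drug 1, drug 2 and the
side effect (length $3k$; 300 for $k = 100$, 768 for $k = 256$). The
classifiers are pinned to named settings so results cannot drift with
library defaults: L1-penalized logistic regression (glmnet, $\lambda =
1/n$, the glmnet-scale analogue of a unit-cost L1 penalty), k-nearest
neighbours with $k = 5$, and a random forest. The forest uses ranger with
Gini splitting — the R forest engines available offer no information-gain
criterion for classification, a small deviation from the reference
configuration — with 100 trees, and additionally a depth cap of 20 in the
polypharmacy configuration.

Cross-validation schemes: leave-one-out; stratified 5-fold (class members
dealt round-robin after a seeded shuffle, so per-fold class counts are
within one of exact proportionality); and cross-dataset (train on all of
dataset A, evaluate on dataset B's five stratified folds, so the numbers
are comparable with B's own five-fold results). Folds are seeded once per
experiment and shared across embedding methods, making every comparison
paired.

Metrics: F1 on the positive class at probability threshold 0.5 (the
reference protocol states no threshold; 0.5 is the natural choice for
probabilistic classifiers), AUC by the rank statistic with midranks for
ties, AUPRC as average precision (precision summed over recall
increments), and AP@50 $= \sum_{i \le 50} \mathrm{prec}@i \cdot
\mathrm{rel}(i) / \min(50, P)$ — the definition used by the
polypharmacy-benchmark lineage, since the metric is otherwise
underspecified. Leave-one-out folds have single-class test sets, so their
F1/AUC are computed pooled over all held-out predictions rather than per
fold.

## The synthetic benchmark

Real headline numbers require a licensed 93-million-triplet predication
store and external benchmark pair lists, so the package ships a generator
(`generate_synth_kg()`) that emulates the *structure* of the problem at
desk scale:

* drugs, diseases and filler concepts are partitioned into blocks; true
  triplets connect vertices within a block (drug–disease edges get a
  dedicated predicate), and a connectivity pass guarantees every vertex at
  least one true edge;
* spurious triplets connect uniformly random vertex pairs; their fraction
  is budgeted exactly (`round(noise_rate * n)`), not sampled, so tests can
  assert counts;
* confidence metadata is truth-correlated: true triplets draw mapping
  scores from U[600, 1000] and co-occurrence counts from 1 + Poisson(8);
  spurious ones from U[50, 400] and 1 + Poisson(1). These regimes overlap
  — confidence is informative, not an oracle;
* the labelled benchmark marks a drug–disease pair positive iff the two
  share a block (100 positives and 100 negatives by default from a
  50-drug, 10-disease, 100-filler, 5-block graph of 1280 triplets, 30%
  spurious).

What the generator does **not** emulate: the heavy-tailed degree and
predicate distributions of real predication stores, correlated extraction
errors (errors here are independent and uniform), and concept-type
semantics. Passing the synthetic comparison therefore shows the weighting
mechanism works *when confidence correlates with truth*; it does not
certify gains on any particular real store.

`run_synth_experiment()` runs the full pipeline on one generated graph
with desk-scale training settings: N = 20 walks of length 40, SGNS window
5, dimension 16, 10 epochs; TransE dimension 32, learning rate 0.01,
batch 128, 100 epochs. Two deliberate scale choices: the benchmark keeps
200 pairs and dimension stays small, because the random-forest protocol
must learn block structure from concatenated coordinates with a few
hundred training rows — sizes were chosen so the *unweighted* baselines
land mid-range (recoverable but with headroom), which is the regime in
which a weighted-vs-unweighted comparison is informative. With five
generator seeds the expected picture, asserted by the acceptance suite
and recomputed by `scripts/acceptance.R`, is: on the noisy graph both
weighted variants improve mean held-out AUC over their baselines; on the
noise-free graph the paired differences are statistically
indistinguishable from zero (the weights have nothing to fix).

## Degenerate inputs and tie-breaking

* Duplicate (subject, predicate, object) records aggregate by summing
  co-occurrence (a count) and taking the maximum of mapping scores (a
  confidence).
* All-zero raw weights are an error; the score floor makes them
  unreachable in practice.
* Ranking ties use the midrank convention throughout; unordered drug
  pairs in polypharmacy triples are canonicalized lexicographically.
* Walks from isolated vertices (directed mode) emit length-1 sequences;
  SGNS ignores sequences with no context.

## Limitations

* The confidence model trusts the scores it is given; adversarially or
  systematically wrong confidence metadata will mislead both weighted
  variants.
* The SGNS and TransE trainers are single-threaded for determinism;
  cluster-scale graphs (the `semmeddb_transe` profile) need patience or
  external tooling.
* The divided-energy TransE formulation is kept as published; its
  interaction with very small $f$ is managed by clipping, not resolved
  theoretically.
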