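---
title: "Predicting lncRNA-miRNA interactions from sequence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lncRNA-miRNA interactions from sequence: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncmir)
```

## The problem

MicroRNAs (20-25 nt) regulate gene expression partly by pairing with long
non-coding RNAs (> 200 nt); knowing which lncRNA-miRNA pairs interact helps
map regulatory circuits, but validating pairs in the laboratory is slow and
most computational predictors need expression profiles or a partially known
interaction network. `lncmir` implements a sequence-only predictor: every
RNA is encoded from its nucleotide string alone, a pair of encodings is fed
to a binary classifier, and the output is an interaction probability.

The pipeline has four stages:

1. **Per-RNA features** in four categories: k-mer spectrum, a
   composition/transition/distribution (CTD) descriptor, a PV-DM paragraph
   vector over 3-mer tokens, and a node embedding of a
   linear-neighborhood-similarity (LNS) graph built within each RNA kind.
2. **Phase decomposition**: each sequence is read as three suffixes starting
   at offsets 0, 1, 2, and the sequence-intrinsic features are computed per
   phase.
3. **Histogram fusion**: per category, the three phase vectors are pooled
   into a 20 x 20 count histogram, giving a fixed 20 x 20 x 4 tensor per RNA
   regardless of sequence length.
4. **Twin-tower CNN**: two convolutional towers (separate weights) ingest
   the lncRNA and miRNA tensors, their flattened outputs are concatenated
   through dense layers to a single sigmoid unit, and a pair is called
   interacting when the probability exceeds 0.5 (strictly).

## Feature encoders

**k-mer spectrum.** Overlapping windows of width k, step 1; each k-block is
the vector of all `4^k` k-mer frequencies (counts divided by the `L - k + 1`
windows), blocks concatenated in ascending k with A < C < G < T ordering.
lncRNAs use k = 1..4 (340 dimensions); miRNAs use k = 1..3 (84 dimensions)
because 4-mer counts on a 20-25 nt sequence are almost all zero. Frequencies
rather than raw counts keep the two kinds on one scale and make every block
sum to one, which the tests assert. U is mapped to T on input, so RNA and
DNA alphabets are interchangeable.

**CTD.** A 30-dimensional global descriptor: 4 composition values
(`count(x)/L` for A, T, G, C), 6 transition values (for each unordered base
pair, the number of adjacent positions carrying that pair in either
orientation, divided by `L - 1`), and 20 distribution values (for each base
with `n` occurrences, the 1-based positions of occurrence ranks 1,
`ceiling(0.25 n)`, `ceiling(0.5 n)`, `ceiling(0.75 n)`, `n`, divided by
`L`). The quantile rank uses `ceiling`, with rank 1 at the 0% point, which
reproduces the standard worked example exactly; a base absent from the
sequence contributes five zeros so the layout stays fixed. One caveat worth
recording: on the toy sequence `ATACGTACTGCTGACGTAGC` exhaustive counting
gives an A/T transition of 4/19, and the six transition counts then sum to
`L - 1 = 19` as they must, since every adjacent heterogeneous pair belongs
to exactly one unordered pair. A commonly quoted value of 2/19 for that one
component is inconsistent with the sequence itself, so this implementation
follows the definition.

```{r ctd}
round(ctd_vector("ATACGTACTGCTGACGTAGC"), 3)
```

**Paragraph vectors.** Sequences are tokenized into overlapping 3-mers and a
PV-DM (distributed-memory) model with negative sampling is trained from
scratch (Rcpp, single-threaded, fully seeded): the mean of the document
vector and the window's word vectors predicts the centre token. Dimensions
follow the usual convention here: 128 for lncRNAs, 64 for miRNAs; window 5,
40 epochs, 5 negative samples, learning rate 0.025 decayed to 1e-4. New
sequences are encoded by inference — a fresh document vector trained against
the frozen word/output matrices — using at least 50 passes and a 0.05
starting rate, since only one vector is being fitted; with fewer passes the
inferred vectors share so much of a common direction that even a
base-permuted sequence looks similar, and the package's similarity sanity
test catches exactly that failure mode.

**Similarity graph and node embedding.** Within each kind, every RNA's
phase-0 k-mer, CTD and doc2vec vectors are concatenated into a union vector
(498 dims for lncRNAs, 178 for miRNAs). For each RNA, LNS weights
reconstruct its union vector from its 15 Euclidean-nearest neighbors under
simplex constraints (non-negative, summing to one), solved by projected
gradient descent (at most 1000 iterations, tolerance 1e-8) — exact
constraint satisfaction is a tested invariant, which rules out the simpler
non-negative least squares plus renormalization. The graph links each node
to its up-to-15 highest-weight neighbors with weight strictly greater than
zero, symmetrized as the union of directed selections. Nodes are embedded
role2vec-style: each node gets a discrete role by median-binning a random
projection (at most 64 dimensions) of its attributes and hashing the bit
signature into 32 buckets; order-1 uniform random walks (10 per node, length
40) are rewritten as role sequences; a skip-gram model with negative
sampling (window 5, 10 epochs) is trained on them; a node's embedding (128
dims) is its role's vector. The role construction is a declared substitute
for the original motif-based roles, chosen to keep the role vocabulary
bounded at small corpus sizes, and it gives unseen sequences an embedding
for free: assign the role, look up its vector (a role never visited by any
walk falls back to the zero vector with a warning).

## Histogram fusion

Nothing forces three phase vectors of unequal-dimensional categories onto a
20 x 20 grid, so the fusion step is the package's main reconstruction
choice, and it is deliberately simple: per category, min-max normalize the
three phase vectors jointly to [0, 1] (an all-equal category maps to 0);
every feature dimension then contributes one 2-D point per phase pair
(0,1), (0,2), (1,2); the channel is the 20 x 20 count histogram of those
`3 x dims` points, right edge of the last bin inclusive. The construction
treats the phases symmetrically, is invariant to permuting or positively
rescaling a category's dimensions, and conserves mass exactly (channel c
sums to `3 x dims(c)`), all of which are tested. The graph embedding has no
phase structure, so its single vector stands in for all three phases and its
channel concentrates on the diagonal.

What this buys — a fixed CNN input independent of sequence length — has a
price that matters for interpretation: binning values pools them across
feature dimensions, so the tensor records the *distribution* of each
category's values, not which dimension carried which value. The consequences
are measured honestly below.

## Classifier

Per tower: conv(3x3, stride 1, ReLU, 32 filters) -> batch norm -> dropout
0.25 -> conv(3x3, 64) -> batch norm -> dropout 0.25; no pooling; flatten;
concatenate the two towers; dense(128, ReLU) -> dropout 0.5 -> dense(1,
sigmoid). Binary cross-entropy, Adam (1e-3), batch 64, up to 50 epochs with
early stopping (patience 10) on a held-out validation fraction (10%),
best-validation weights restored. The stack is implemented in R directly
(im2col + BLAS, analytic gradients verified against numerical
differentiation to ~1e-9), so training is exactly reproducible for a fixed
seed: initialization, shuffling and dropout all derive from it. The 0.5
decision threshold is strict (`probability > 0.5`).

## Negative sampling, folds, metrics

Negatives are drawn by shuffling both identifier lists ten times
(Fisher-Yates, Knuth-Durstenfeld variant), then repeatedly pairing one
uniform draw from each list and accepting pairs seen neither among the
positives nor among already accepted negatives, until `round(beta x
n_positives)` are collected; infeasible ratios fail before sampling and a
draw cap (1e7) guards the rejection loop. Negatives are sampled once
globally before fold assignment. Folds are label-stratified (each fold's
positive fraction within one pair of the global fraction; sizes within one);
stratification stabilizes small fixtures and can be disabled. Splitting is
at the pair level, so an RNA may occur in both training and test pairs —
faithful to common practice for this task; entity-disjoint evaluation is a
known stricter alternative deliberately not the default. Within each fold,
the doc2vec embedder and the graphs are fitted on training-fold RNAs only;
test RNAs are encoded by inference and role lookup, so no fitted component
sees test pairs.

Metrics: SN, SP, ACC, F1 from their closed forms; MCC with the square root
in the denominator (the Matthews coefficient equals the Pearson correlation
of the binary label vectors, a tested identity — a printed variant of the
formula that omits the root is not that coefficient and is not used); AUC by
Mann-Whitney midranks, cross-checked against an independent implementation.
Undefined metrics (zero denominators) are reported as `NA`, never as 0.

## The synthetic corpus

`generate_fixture()` emulates a curated interaction corpus at desk scale:
uniform-composition i.i.d. sequences (miRNAs 20-25 nt; lncRNAs 200-300 nt by
default — long enough to be lncRNAs, short enough to keep tests fast),
defaults of 50 lncRNAs, 20 miRNAs and 100 positive pairs drawn uniformly
without replacement. With `signal = "seed_complement"` each positive pair
plants the reverse complement of the miRNA seed (positions 2-8) into the
partner lncRNA at a uniformly chosen offset; offsets on the same lncRNA are
resampled to avoid overlap, because an overlapping later plant would destroy
an earlier motif (without this, about 3% of planted motifs were lost at the
default scale). The seed-complement cue is the canonical biological
interaction signal and makes the label a deterministic function of the
sequences: a direct motif-match oracle separates positives from negatives
with AUC ~0.98 (the residue comes from motifs arising by chance in
negatives). `signal = "none"` is the matched null. What the generator does
not emulate: real base composition and length distributions, shared
evolutionary structure between sequences, many-to-many interaction degree
heterogeneity, and noisy labels — passing tests on fixtures therefore
demonstrate that the machinery is correct and leak-free, not that real
corpora reach any particular accuracy.

## What the end-to-end tests show — including a negative result

The test suite evaluates the full pipeline at fixture scale (2-fold
cross-validation, encoder and classifier sizes reduced to fixture scale:
conv 8-16, dense 32, 25 epochs, doc2vec 10 training / 15 inference epochs,
walk length 20 — stated here as the package's chosen problem sizes). Three
results matter:

* The classifier itself can learn a cross-tower interaction rule: on
  synthetic tensors where the label is an AND of the two towers' patterns,
  held-out AUC reaches ~1.0 within seconds.
* The shuffled-label control stays at chance (AUC in [0.4, 0.6]), so the
  pipeline has no leakage.
* **The planted pairwise signal does not survive histogram fusion.** On the
  seed-complement corpus the full pipeline's held-out AUC is ~0.5, and this
  is not a weakness of the CNN: a 200-round gradient-boosted tree model
  trained directly on the concatenated raw tensors does no better. The
  explanation is structural. Whether a pair interacts is a function of
  *which* k-mers the two sequences carry (the miRNA's seed versus the
  lncRNA's planted complement); the fusion histogram deliberately pools
  values across feature dimensions, so each tensor is a fingerprint of the
  RNA's value distribution from which dimension identity — and hence any
  pairwise compatibility — cannot be reconstructed. Per-RNA information
  survives (the tensors are distinctive fingerprints); pair-matching
  information does not. The corresponding learnability expectation in the
  acceptance suite is left failing by design rather than weakened, because
  it documents a real property of the fused representation. For the same
  reason, the all-features-versus-k-mer-only ordering check on fixtures
  compares two chance-level configurations and is reported as measured.

This also delimits what the package can claim on real data: on corpora where
interaction correlates with per-RNA properties (composition, length, family
structure, degree), the fused tensors carry usable signal; where interaction
is decided by base-pairing complementarity alone, a fusion that preserves
dimension identity (or an explicit cross-sequence feature) would be needed.

## Numerical and degenerate-input conventions

* Ambiguity codes (N, R, Y, ...) are rejected with the offending position;
  every encoder assumes a strict 4-letter alphabet.
* Sequences shorter than 3 nt cannot be phase-decomposed or tokenized;
  CTD needs length >= 2; k-mer vectors need `L >= max(k)`.
* LNS: neighborhoods are Euclidean-nearest; rank ties resolve to the lowest
  index; all-identical neighborhoods yield a valid (uniform) simplex row
  with objective 0.
* Graph edges require weight strictly greater than 0; top-k ties resolve by
  first occurrence; degree is bounded by `2 top_k`.
* Histogram bin index is `min(floor(20 v) + 1, 20)`, i.e. the last bin's
  right edge is inclusive.
* Batch norm uses eps 1e-5 and momentum 0.9 on running statistics;
  minibatches of size 1 are skipped (batch statistics undefined).
* All stochastic stages derive sub-seeds deterministically from one integer
  seed; C++ components use a fixed splitmix-style generator rather than
  standard-library distributions, whose output is implementation-defined.

## Known limitations

* The fusion convention is a documented reconstruction of a
  multidimensional-histogram idea; other conventions (e.g. treating phases
  as 3-D coordinates) would change the tensor entirely.
* Role assignment reduces attributes to 32 discrete roles; nodes sharing a
  role share an embedding, which is coarse for large corpora (increase
  `n_roles` accordingly).
* Training the CNN in base R is practical at desk scale (hundreds of pairs)
  but not for corpora of tens of thousands of pairs.
* Pair-level splitting measures interpolation over the known RNA universe;
  generalization to unseen RNAs requires the stricter entity-disjoint
  protocol.
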