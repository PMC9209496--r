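---
title: "Methods: alignment-free protein representations and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-free protein representations and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices that were
genuinely open, and what the synthetic benchmarks do and do not demonstrate
about real data.

## The language model

`train_lm()` fits a stacked bidirectional LSTM on raw amino-acid sequences.
Each direction is an independent stack of LSTM layers over a shared token
embedding; the forward stack is trained to predict the next residue at
every position, the backward stack the previous residue, and the optimized
loss is the sum of the two mean cross-entropies. This self-supervised
objective needs no labels, which is the point: the model can absorb
arbitrarily many unannotated sequences.

Architecture and optimization defaults mirror a full-scale setting — 3
layers of 1,024 hidden units per direction, sequences clipped to 1,500
residues, AdamW at learning rate 1e-3 with an 8,000-step linear warmup,
mini-batches of 1,024 — but every quantity is configurable and the tests
and the acceptance script run a 2-layer, 64-unit configuration trained for
300 steps, which fits in minutes on one CPU. The architecture is identical
at every scale; only capacity changes. Problem sizes used throughout the
test suite (corpora of 80–200 proteins of ~84–104 residues) were chosen as
the smallest sizes at which the qualitative contrasts of interest are
stable across seeds.

Choices the objective leaves open, and what this implementation does:

* **Vocabulary.** Pad/start/stop specials, the 20 canonical residues in
  alphabetical order, then the six ambiguity letters (B, J, O, U, X, Z).
  Ambiguity letters are accepted as *inputs* (they receive their own
  embedding rows) but are excluded as prediction *targets*, since they
  carry no single ground-truth residue. The softmax layer therefore covers
  exactly the 20 canonical residues — which also makes the uniform-output
  reference score an ECE of exactly 20.
* **Loss positions.** The first residue has no backward target and the last
  none forward; both are excluded rather than wrapped or padded.
* **Hidden states.** Embeddings use the *final* recurrent layer's states,
  the standard choice, and combine directions by concatenation, giving
  `2 × hidden_units` dimensions (2,048 at full scale).
* **Pooling.** A protein's embedding is the arithmetic mean of its
  per-residue state vectors over residue positions only — no special
  tokens, and padded batch positions are masked out of both the recurrence
  (hidden and cell states forced to zero) and the mean, so embedding a
  sequence alone or inside a padded batch gives identical vectors.
* **Warmup.** A linear ramp from 0 to the configured rate over
  `warmup_steps`, constant afterwards.
* **Regularization.** Decoupled weight decay 0.01 and global gradient-norm
  clipping at 1.0; forget-gate biases initialized to 1, other weights
  uniform in ±1/sqrt(hidden).
* **Determinism.** All randomness (initialization, batch sampling) flows
  from the config seed through R's RNG; identical seed, config and corpus
  give bit-identical training logs.

Model quality is reported as exponential cross-entropy,
`ECE = exp(H)` with `H` the mean per-position cross-entropy pooled over
both directions and all prediction targets. Natural-log units are used (the
perplexity convention); the minimum is 1, and a uniform predictor scores
the output-alphabet size, 20.

## Baseline representations

The bag-of-k-mers representation counts overlapping k-length windows and
orders columns alphabetically, giving `20^k` dimensions; windows containing
ambiguity letters contribute no count, which keeps the dimension at `20^k`
exactly. Counts are reweighted by smoothed TFIDF,
`idf(t) = ln((1+n)/(1+df(t))) + 1` with L2-normalized rows — the default
convention of the widely used scikit-learn transformer, recorded here so
results are bit-reproducible. The fitting corpus is an explicit argument:
by default the transform is fitted on the represented set itself.
Amino-acid frequency vectors (counts of canonical residues normalized to
sum 1) complete the baselines.

One property of smoothed TFIDF is worth knowing when interpreting synthetic
benchmarks: k-mers unique to a single sequence receive the *highest* idf,
so in corpora whose backgrounds are i.i.d. random noise, the weighting can
emphasize exactly the unshared part of each sequence. This is visible in
the use-case analysis below.

## Dimensionality reduction

`pca_reduce()` centers columns and projects onto the leading components via
exact SVD. Exact SVD is used at every input size; desk-scale matrices
(hundreds of rows) never need a randomized solver, and exactness keeps the
covariance-eigenvalue cross-check in the test suite meaningful. Component
signs are canonicalized (largest-magnitude loading positive) so output does
not depend on the BLAS. The default of 50 components is the dimensionality
used by all downstream analyses.

`umap_project()` feeds PCA output to UMAP (`n_neighbors = 50`,
`min_dist = 0.3`, remaining parameters at library defaults) through the
Python `umap-learn` implementation, with `random_state` pinned to the
config seed. Only seed-reproducibility is promised; the layout's
orientation is arbitrary. The pipeline always projects PCA-reduced
vectors, never raw embeddings.

## Label recovery

For each ontology, evaluation restricts to proteins that carry at least one
label there, splits them into five equal folds under a derived seed, builds
an exact Euclidean kNN index on four folds and queries each held-out
protein's `max(k_values)` nearest neighbors. Ties at equal distance break
by ascending protein id. For every neighborhood size `k`, neighbor label
sets are aggregated into a prediction and scored with IoU, example-based
Precision, Recall and F1; the whole procedure is repeated with distinct
derived seeds (`fork_seed(seed, repeat)`).

The aggregation rule is per-label **majority** (> k/2 of the neighbors),
falling back to the nearest neighbor's label set when no label reaches a
majority, so predictions are never empty; `union` and `plurality` are
available as options. Majority is the standard multi-label kNN rule; union
inflates recall at the cost of precision and is the setting under which
difficulty grows most visibly with `k`.

The per-protein Recovery Error Rate is `1 − mean(IoU)` pooled over every
IoU value recorded for the protein — across ontologies, `k` values and
repeats. Pooling (rather than first averaging within each ontology) weights
ontologies by their number of recorded values; with the package's default
grids the two conventions differ only when a protein is labeled in a strict
subset of the evaluated ontologies.

The exact `k` grid is user-chosen; the default `{1, 3, 11, 51}` spans the
range up to the conventional maximum neighborhood of 51. The fivefold
protocol is equivalent to removing 20% of labels at random, five times per
repeat.

## Distance analysis

`distance_report()` compares two metrics on the same group structure:
Euclidean distance between representation vectors (typically 50 PCA
components), and sequence distance `100 − percent identity`. Percent
identity comes from a full Needleman–Wunsch/Gotoh global alignment with
BLOSUM62 scoring and affine gaps (open −10, extend −0.5); identity is
counted as identical columns over the full alignment length, gap columns
included. This is a deliberate deviation from heuristic k-tuple
approximations used by external alignment tools — the package computes the
quantity those heuristics approximate — so numeric agreement with any
particular external tool is not claimed.

Within-group means are taken over unordered distinct pairs, between-group
and group-to-background means over all cross pairs. Background proteins are
drawn with a fixed seed when not supplied explicitly; the default
background size of 500 follows the convention that a few hundred random
proteins suffice to model "everything else", and the size is configurable
because results are insensitive to it.

## The synthetic corpus generator

`generate_corpus()` creates the minimal structure the methods above are
designed to exploit: each family is defined by a set of conserved motifs;
each member is an i.i.d. random background sequence with one independently
point-mutated copy of every family motif inserted at a random position
(insertions never split a previously placed motif, so motif positions in
the ground truth are exact). The `"function"` ontology is a deterministic
function of motif content, `"domain"` carries one label per motif, and
`"taxonomy"` is drawn independently of the sequence — giving a labeled
contrast between sequence-coupled and sequence-independent ontologies with
known ground truth. `inject_shared_motif()` adds a common motif (and a
shared domain label) to several families, modelling cross-family
similarity such as enzymes with overlapping substrate ranges.

Generator defaults (5 families × 40 members, two 12-residue motifs on a
60-residue background, 10% motif substitution, uniform residue usage, 4
taxonomy labels) were fixed once as a regime where motifs are conserved
enough to define families yet backgrounds dominate sequence length —
roughly a quarter of each sequence is motif. What the generator does *not*
model: indels and length heterogeneity, positional or compositional bias,
phylogenetic correlation between background residues, and overlapping
domain architectures. Consequently, passing benchmarks on this corpus
demonstrates that the pipeline's machinery behaves as designed
(neighborhoods track motif content; taxonomy stays at chance; embeddings
separate families from background), not that any given model scale will
reach a particular accuracy on real catalogs.

## The use-case contrast

The analysis comparing embedding distance with sequence identity uses the
*language-model* embedding, not the k-mer baseline. The mechanism matters:
the LM sees each family's motifs recur across many training sequences and
its hidden states respond to them consistently, while the i.i.d.
backgrounds are unlearnable noise that pooling averages out — so family
members land close together and the family-to-background contrast exceeds
what percent identity shows. The TFIDF k-mer representation, by contrast,
up-weights each sequence's unique background k-mers (they have the highest
idf), which dilutes exactly the shared-motif signal; it separates families
from background, but less sharply than the identity metric does. Both
facts are visible in the acceptance script's
`embedding_separation_ratio` / `identity_separation_ratio` outputs.

## Degenerate inputs and numerical conventions

* Sequences shorter than `k` yield a zero k-mer vector with a logged
  warning, not an error; sequences of length 1 contribute no LM targets and
  an evaluation set consisting only of such sequences is an error.
* Empty ground-truth label sets make every set metric undefined and raise
  an error; empty *predictions* cannot occur under majority voting (the
  nearest-neighbor fallback), and are scored with precision 0 if produced
  by other means.
* `IoU ≤ Precision`, `IoU ≤ Recall` and `IoU ≤ F1` hold for all set pairs;
  the test suite verifies this exhaustively over a 4-label universe.
* PCA requires `components ≤ min(rows, cols)`; explained-variance ratios
  are relative to total variance, so a full-rank request sums to 1.
* All multi-stage seeds derive from one user seed via the fixed affine map
  `fork_seed()`, keeping every derived seed in 32-bit range.

## Known limitations

The pure-R LSTM is intended for desk-scale experiments and method
evaluation, not for catalog-scale training; at full scale the same
architecture would be trained in a GPU framework and the resulting
checkpoint imported. Approximate nearest-neighbor indexing is unnecessary
at the sizes this package targets, so the index is always exact. UMAP runs
through an external Python process and requires `umap-learn` on the
interpreter found on `PATH`.
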