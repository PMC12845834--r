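---
title: "Predicting RNA secondary structure as a contact map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA secondary structure as a contact map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnfold)
```

## The model

`attnfold` treats RNA secondary structure prediction as a dense pairwise
classification problem: given a sequence of length $L$, predict the binary
contact map $M \in \{0,1\}^{L \times L}$ with $M_{ij} = 1$ exactly when
nucleotides $i$ and $j$ are base-paired. Because the structure is a set of
pairs rather than a nested tree, pseudoknots (crossing pairs) are
representable throughout the pipeline.

The pipeline has three stages.

**1. Attention encoder.** Each residue $x_i \in \{A, U, G, C, N\}$ is
mapped to a learned embedding $e_i \in \mathbb{R}^d$ and summed with a
fixed sinusoidal positional encoding $p_i$, giving $z_i = e_i + p_i$.
Multi-head scaled dot-product self-attention is applied to
$Z = [z_1; \dots; z_L]$:
$$A_h = \mathrm{softmax}\!\left(\frac{Q_h K_h^\top}{\sqrt{d_h}}\right),
\qquad Q_h = Z W^Q_h,\; K_h = Z W^K_h,$$
and the per-head maps are averaged into a correlation map
$C = \tfrac1H \sum_h A_h$. Each row of $C$ is a probability distribution
over possible partners of residue $i$; a head can express "A attends to U
at a plausible pairing distance" through the bilinear form
$W^Q_h (W^K_h)^\top$ acting on content and position jointly. $C$ is not
symmetrised here: row-stochasticity is its defining invariant, and
symmetry is imposed downstream where the structural constraints live.

**2. U-Net refiner.** $C$ is noisy: every complementary residue pair
attracts some attention, not only true partners. The refiner is a small
U-Net over the $L \times L$ map (conv blocks, 2x max-pool down,
nearest-neighbour up, concatenation skips) that exploits the spatial
signature of real structure — stems are anti-diagonal runs of high
correlation, isolated complementary coincidences are not. The map is
padded to a multiple of $2^{\text{depth}}$, refined, cropped back,
symmetrised as $(X + X^\top)/2$ on the logit scale, and squashed through a
logistic so the output is a probability-like score map in $(0,1)$.

**3. Constraint decoder.** The refined map is thresholded with a smooth
sign gate, $\tilde C = \mathrm{softsign}(C_{\text{ref}} - s) \odot
C_{\text{ref}}$, then relaxed toward a feasible contact matrix by an
iterative min–max scheme: the relaxed matrix $A$ ascends on the score
evidence and descends where a row's total pair mass exceeds one, with a
per-row Lagrange multiplier $\lambda_i$ ascending on the rectified
violation $\max(0, \sum_j A_{ij} - 1)$. Every iterate is clipped to
$[0,1]$, masked, and re-symmetrised. Finally a greedy matcher picks
cells above the binarisation threshold in score order, skipping any cell
whose endpoints are used, so the hard guarantees — symmetry, at most one
partner per nucleotide, mask compliance — hold *unconditionally*, not
just in the limit of the relaxation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `d`, `H` | 64, 4 | embedding width and head count; `d_h = d/H` |
| `depth`, `base_channels` | 2, 16 | U-Net levels and full-resolution channels |
| `s` | 0.5 | sparsity threshold on the refined map (score units) |
| `kappa` | 10 | soft-sign sharpness (dimensionless) |
| `eta`, `eta_lambda` | 0.01 | descent/ascent step sizes of the relaxation |
| `iters` | 100 | relaxation budget |
| `min_sep` | 4 | minimum $|j - i|$, i.e. a minimum loop of 3 residues |
| `bin_threshold` | 0.5 | final cut on the relaxed scores |
| `pos_weight` | 6 | loss weight on paired cells |
| `epochs`, `learning_rate` | 20, 1e-3 | Adam training schedule |

The architecture sizes are deliberately small: the shipped configuration
trains on several hundred short sequences in a few minutes on one CPU
core. `min_sep = 4` encodes the steric minimum loop; the synthetic
generator never emits pairs below this separation, so generated truths
are always decodable. `pos_weight` counters the extreme class imbalance
(roughly $L$ paired cells among $L^2$): values that are too high make
over-prediction nearly free and the model stops using the sequence signal
to locate stem boundaries (see below); 6 balanced false positives against
false negatives in validation sweeps on held-out hairpins.

## The synthetic generator

Real structure corpora are large, license-encumbered downloads; the
package instead ships a generator whose output has the statistical
features the model must learn:

* **hairpins** — one stem of $k$ complementary pairs around a loop of
  $m \geq 3$ unpaired residues, pairs $(t, L-1-t)$;
* **cloverleafs** — a closing stem plus three inner stem-loops joined by
  short linkers (a tRNA-like multiloop), fully nested;
* **H-type pseudoknots** — two stems over regions $A < B < C < D$ with
  $A$–$C$ and $B$–$D$ pairing, so every stem-1 pair crosses every stem-2
  pair.

Stems draw Watson–Crick pairs uniformly with a configurable wobble
(G–U/U–G) fraction; loops and linkers are uniform over A, C, G, U so
composition alone carries no structural shortcut. Mutation noise is
applied to the *sequence only*, after construction; the labelled
structure remains the pre-mutation truth, which emulates an imperfect
pairing signal and makes the learning task non-trivial.

What the generator does *not* emulate: thermodynamic ensembles,
non-canonical pair geometries, covariation between homologs, family- and
length-distributions of real corpora, and structures beyond ~120 nt.
Tests passing on this generator therefore demonstrate that the
architecture can extract complementarity + geometry signals and that the
decoder's guarantees hold — not that the model is competitive on natural
RNA families.

## Numerical choices

* **Training objective.** Weighted binary cross-entropy between the
  refined map and the true contact map, over upper-triangle cells with
  $|j - i| \geq$ `min_sep` (the only cells the decoder can ever set),
  mean-reduced. Supervision sits on the refined map only; the decoder is
  non-trained post-processing. Training runs per-sequence forward/backward
  passes with gradient accumulation over mini-batches, so no padding or
  attention masking is needed for mixed-length batches.
* **The relaxation gradient.** The descent direction is
  $G = A \odot [\lambda \cdot \mathrm{softsign}(\sum_j A_{ij} - 1) -
  \tfrac12 \tilde C]$ with $\lambda$ broadcast across rows: rows over
  budget are pushed down, cells with score evidence are pushed up. The
  published description of this step is typographically ambiguous; this
  reading reproduces the stated min–max intent and is isolated in one
  internal function so an alternative can be swapped.
* **Initialisation.** He-style weights for convolutions; conv biases are
  initialised at 0.01 rather than 0 so ReLU units in zero-padded regions
  do not sit exactly on the kink (which would make finite-difference
  gradient verification ill-posed at init).
* **Ties and degenerate input.** The greedy binariser breaks score ties
  by smaller row then column index; empty score maps decode to the empty
  structure; `L = 0` maps are rejected.
* **Dot-bracket layers.** The writer canonicalises pseudoknot layer
  assignment greedily (lowest non-crossing layer, pairs in ascending
  opening index) over the four community bracket alphabets; structures
  needing more than four layers are rejected rather than silently
  mangled. Round-trips preserve the pair set, not the input layering.

## Behaviour worth knowing about

**Greedy decoding is not maximum-weight matching.** When three or more
candidate pairs conflict in a chain (e.g. $(1,2)$ at $0.95$, $(1,3)$ at
$0.85$, $(2,4)$ at $0.75$), the greedy matcher keeps only the heaviest
edge while the optimal matching takes the two lighter ones. The
exhaustive oracle in `brute_force_decode()` exists precisely to
characterise this: on instances whose conflicts are one-on-one and whose
weights are separated, greedy provably equals the oracle, and the test
suite verifies both that regime and the universal bound (oracle total
weight >= greedy total weight). Production decoding keeps the greedy rule
because it is linear-time, deterministic, and its failure mode (a
slightly lighter pair set) is benign for contact maps.

**Monotonicity in the sparsity threshold `s` holds above the noise
floor.** Raising `s` shrinks the thresholded scores pointwise, and on
prediction-like maps (strong planted signal, weak background) the decoded
pair count is non-increasing in `s`. If `s` is set *below* the background
noise level, however, the surviving noise inflates row sums, the
multipliers grow, and true pairs can be suppressed — so a larger `s` can
paradoxically recover more pairs. The default `s = 0.5` sits well above
the noise any trained refiner emits.

**Class weighting interacts with stem-boundary precision.** Hairpin
stems end where complementarity ends; the cell just past the stem end
lies on the same anti-diagonal and differs only in sequence content. With
a large `pos_weight` the cheapest policy is to over-extend stems by one
or two pairs (perfect recall, depressed precision) — observed directly in
validation: at `pos_weight = 20` the trained model and its no-attention
ablation made identical predictions, both painting the full anti-diagonal
allowed by the mask. The shipped default of 6 restores the incentive to
read the sequence.

## Design choices on open points

* The positional encoding is the standard fixed sinusoid: deterministic,
  parameter-free and length-extrapolating; only its determinism is
  specified upstream.
* The `N` residue has its own learned embedding row (it is part of the
  vocabulary); whether N may pair is a decoder policy: with
  `canonical_only = TRUE` it never pairs, otherwise the scores decide.
* The correlation map enters the refiner with two normalised coordinate
  channels ($i/L$, $j/L$), letting filters condition on pairing distance
  and position; configurable off.
* Aggregate metrics are macro-averaged (mean of per-sequence precision,
  recall, F1), and pair matching is exact — no one-position slippage
  tolerance.
* Checkpoints serialise as one JSON header line (config, shapes, loss
  history) followed by raw little-endian doubles, so a checkpoint is a
  single portable file with a human-readable head.

## Problem sizes used in the shipped tests

The test suite trains the default model (d = 64, H = 4, depth 2) on 500
synthetic hairpins (2% mutation noise) and evaluates on 100 held-out
hairpins; the ablation comparison trains three variants on 150 hairpins.
Decoder guarantee and oracle checks run on 1000 and 200 random instances
respectively; planted-structure recovery uses 100 mixed-family structures
up to 60 nt. These sizes keep a full check of every property within a few
minutes on a single CPU core while leaving each property's sample size
large enough to be meaningful.

## Limitations

* Single attention layer and a shallow U-Net: adequate for the synthetic
  families; natural RNAs with long-range multi-domain architecture would
  need stacking and larger receptive fields.
* No thermodynamic prior of any kind; the model knows only what the
  training distribution shows it.
* The Lagrangian relaxation is approximate and its iterate count is a
  fixed budget, not a convergence criterion; feasibility is guaranteed by
  the final greedy matcher, optimality is not.
* Training is CPU-bound R + BLAS with hand-written backpropagation;
  practical up to a few thousand short sequences, not for corpus-scale
  work.

## A worked example

```{r example, eval = FALSE}
spec <- family_spec("hairpin", mutation_rate = 0.02)
train <- make_dataset(500, c(hairpin = 1), list(hairpin = spec), seed = 11)
test  <- make_dataset(100, c(hairpin = 1), list(hairpin = spec), seed = 12)

ck <- train_model(train, train_config(epochs = 15, seed = 1))

pred <- predict_structure(test[[1]]$seq, ck)
evaluate_structure(pred$structure, test[[1]]$structure)

preds <- lapply(test, function(r) predict_structure(r$seq, ck)$structure)
evaluate_dataset(preds, lapply(test, `[[`, "structure"))$macro
```
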