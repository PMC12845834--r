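# attnfold

RNA secondary structure prediction as dense contact-map inference, for
people who want a small, fully inspectable, pseudoknot-capable predictor
and a test bed for constraint-enforcing decoders — not a production rival
to corpus-scale tools.

An RNA sequence folds back on itself through Watson–Crick (A–U, G–C) and
wobble (G–U) base pairs; the set of pairs is the secondary structure, and
its matrix view is the binary contact map `M ∈ {0,1}^{L×L}` with
`M[i,j] = 1` iff residues `i` and `j` pair. `attnfold` maps a sequence to
that matrix in three stages:

1. **Attention encoder** — residues are embedded (`z_i = e_i + p_i`, with
   a fixed sinusoidal positional term), passed through multi-head scaled
   dot-product self-attention, and the head-averaged attention matrix
   `C = (1/H) Σ_h softmax(Q_h K_h' / √d_h)` is read as a pairwise
   interaction propensity map.
2. **U-Net refiner** — a small encoder–decoder CNN over the L×L map
   sharpens anti-diagonal stem signatures and suppresses isolated
   complementarity coincidences, returning a symmetric score map in (0,1).
3. **Lagrangian decoder** — soft-sign sparsity thresholding
   `C̃ = softsign(C_ref − s) ⊙ C_ref`, an iterative min–max relaxation
   penalising rows whose pair mass exceeds one
   (`λ ← λ + η_λ · ReLU(Σ_j A_ij − 1)`), and a greedy matcher that makes
   the structural constraints — symmetry `M = Mᵀ`, pairing exclusivity,
   minimum loop length `|j − i| ≥ 4` — hold unconditionally.

Structures are sets of pairs, not nested trees, so crossing pairs
(pseudoknots) survive every stage, including the layered dot-bracket
writer. Scoring is standard base-pair precision/recall/F1 with exact
matching.

The package also ships a synthetic generator (hairpins, tRNA-like
cloverleafs, H-type pseudoknots, with wobble pairs and sequence-level
mutation noise), readers/writers for FASTA, CT, BPSEQ and dot-bracket,
full gradient-based training (hand-written backpropagation; the
convolution hot path is RcppArmadillo), and a brute-force maximum-weight
matching oracle used to verify the greedy decoder at small L.

## Worked example

```r
library(attnfold)

spec  <- family_spec("hairpin", mutation_rate = 0.02)
train <- make_dataset(500, c(hairpin = 1), list(hairpin = spec), seed = 11)
test  <- make_dataset(100, c(hairpin = 1), list(hairpin = spec), seed = 12)

ck <- train_model(train, train_config(epochs = 15, seed = 1))

pred <- predict_structure(test[[1]]$seq, ck)
evaluate_structure(pred$structure, test[[1]]$structure)
#> <eval_result> TP=4 FP=0 FN=0  P=1.000 R=1.000 F1=1.000

preds <- lapply(test, function(r) predict_structure(r$seq, ck)$structure)
round(evaluate_dataset(preds, lapply(test, `[[`, "structure"))$macro, 3)
#> precision    recall        f1
#>     0.867     0.990     0.919
```

Trained on 500 noisy synthetic hairpins (~3 minutes on one CPU core), the
model recovers essentially every true pair on held-out sequences
(recall ≈ 1) and occasionally extends a stem one pair too far into the
loop (precision slightly below 1). An untrained model scores F1 = 0 under
the same decoding, so the signal is learned, not decoded in.

Command-line use (`exec/attnfold` after installation):

```sh
attnfold simulate --family mix --n 100 --seed 1 --out-dir data/
attnfold train    --data data/ --out model.ckpt --epochs 15
attnfold predict  --ckpt model.ckpt --input seqs.fasta --out-dir preds/
attnfold evaluate --pred preds/ --truth data/ --out metrics.tsv
attnfold decode   --scores scores.tsv --seq seq.fasta --out pred.ct
```

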