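# mlenz

Hierarchical multi-label prediction of enzyme main classes.

## What problem this solves

An EC (Enzyme Commission) number is a four-digit code whose first digit is
one of six main classes (oxidoreductase, transferase, hydrolase, lyase,
isomerase, ligase). Annotation pipelines usually assume one EC number per
enzyme, but many enzymes are multi-functional, and their functions almost
always diverge already at the main class. `mlenz` is for computational
biologists who need that multi-functional case handled: it first decides
whether an enzyme is mono- or multi-functional (a heavily imbalanced binary
problem), and for multi-functional enzymes predicts the *subset* of the six
main classes. Digit-level annotation below the main class is delegated to
external mono-functional predictors and recorded as such in the output.

## The method

Each protein is encoded three ways: an L×20 sequence one-hot matrix, an
L×20 PSSM frequency profile (PSI-BLAST ASCII dialect; a degenerate one-hot
profile is substituted when no profile exists), and a binary Pfam
domain-presence vector. A branched network — convolutional stacks with
global pooling over the two L×20 matrices, a fully-connected layer over the
domain vector, concatenation, and a fully-connected classifier with Q
logistic outputs l(x) ∈ (0,1)^Q — is trained end to end.

The multi-label level minimizes the pairwise ranking loss (BP-MLL)

    E_i = (1 / |L||L̄|) Σ_{k∈L} Σ_{q∈L̄} exp(−(l_ik − l_iq))

which drives every true-label score above every absent-label score. Labels
are then assigned with a self-adapted threshold t(x) = wᵀl(x) + b: per
training instance the threshold minimizing the misclassified-label count
|{k∈L : l_k ≤ t}| + |{q∈L̄ : l_q ≥ t}| is computed (midpoint of the
minimizing range; for scores (0.9, 0.8, 0.3, 0.1, 0.1, 0.1) with true
classes {1,2} that is 0.55), and (w, b) is fitted by linear least squares.
Predicted labels are {j : l_j > t(x)}, with a flagged top-1 fallback so no
enzyme is left without a main class. The binary level uses the same
architecture with one logistic output and class-weighted cross-entropy
(inverse-frequency weights) against the ~20:1 mono/multi imbalance.

Evaluation covers the full multi-label suite: hamming loss, subset
accuracy, and macro-/micro-averaged precision, recall and F1.

A synthetic benchmark generator (`sim_spec()` / `generate_dataset()`)
produces sequences with one planted 6-mer motif per labeled class,
label-set patterns shaped like real multi-functional statistics, the
published mono/multi imbalance, and noisy domain-indicator bits — so every
stage is trainable and testable without external databases.

## A worked example

```r
library(mlenz)

ds   <- generate_dataset(sim_spec(n = 600, label_noise = 0, seed = 1))
data <- encode_sim_dataset(ds)
cfg  <- model_config(seed = 1, epochs = 15)

model <- build_model(cfg, domain_dim = length(ds$vocabulary))
model <- train_model(model, data, loss = "bpmll", config = cfg)
model <- calibrate_threshold(model, data)

preds <- lapply(data, function(inst) predict_main_classes(inst$x, model))
metrics_report(preds, lapply(data, `[[`, "y"), Q = 6)
```

```
<metrics_report> N=600, Q=6
  hamming_loss     0.0017
  subset_accuracy  0.9917
  macro_precision  0.9961
  macro_recall     0.9881
  macro_f1         0.9920
  micro_precision  0.9951
  micro_recall     0.9951
  micro_f1         0.9951
```

After 15 epochs the network has all but separated the planted motifs: 99.2%
of the instances get their exact label set back (subset accuracy), and only
0.17% of all instance–label decisions are wrong (hamming loss). Longer
training drives these to 1 and 0; on held-out splits or with label noise
they drop. See
`evaluate_splits()` for the repeated 70/30-split protocol that reports
mean ± sd per metric.

The same operations are scriptable through the thin CLI:

```sh
inst/scripts/mlenz simulate --n 500 --seed 1 --out bench/
inst/scripts/mlenz train    --dir bench/ --q 6 --model ml.rds
inst/scripts/mlenz calibrate --dir bench/ --model ml.rds
inst/scripts/mlenz predict  --fasta bench/sequences.fasta \
    --binary-model bin.rds --model ml.rds --out annotations.tsv
```

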