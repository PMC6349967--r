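---
title: "Hierarchical multi-label prediction of enzyme main classes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multi-label prediction of enzyme main classes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlenz)
```

## The problem

An Enzyme Commission (EC) number is a four-digit code whose first digit is
one of six *main classes* (oxidoreductase, transferase, hydrolase, lyase,
isomerase, ligase). Most computational annotation tools assume an enzyme is
mono-functional — it carries exactly one EC number — but a sizeable and
growing minority of enzymes are multi-functional, and their annotations
usually diverge already at the main class. `mlenz` implements a two-level
scheme for this situation:

1. **Binary level.** Decide whether an enzyme is mono- or multi-functional.
   The two classes are heavily imbalanced (roughly 22,000 mono vs 1,000
   multi in the curated datasets this setting models), so the classifier is
   trained with class-weighted binary cross-entropy.
2. **Multi-label level.** For multi-functional enzymes, predict the subset
   of the six main classes with a multi-label network trained with a
   pairwise ranking loss, and convert the six per-class scores into a label
   set with a per-instance adaptive threshold.

Digit-level annotation below the main class, and the upstream
enzyme/non-enzyme decision, are delegated to external mono-functional
predictors and are out of scope here; the pipeline records that delegation
in its output notes.

## Raw protein encodings

Each protein is represented three ways:

* **Sequence one-hot**: an L x 20 binary matrix over the fixed alphabetical
  residue ordering `ACDEFGHIKLMNPQRSTVWY` ('A' is column 1, 'C' column 2).
  The ordering is exported as `AA_ALPHABET` and persisted with every
  checkpoint.
* **Profile (PSSM)**: an L x 20 matrix of per-position residue frequencies
  in [0,1], parsed from the PSI-BLAST ASCII matrix dialect. We use the
  percentage columns divided by 100; the log-odds columns are parseable
  behind a flag and squashed to [0,1] by the logistic function. When no
  profile is available, `fallback_pssm()` substitutes the degenerate
  profile that puts all frequency mass on the observed residue — this keeps
  the full architecture runnable at desk scale and is tagged so consumers
  can audit which inputs carried real evolutionary information.
* **Domain presence**: a binary vector over a frozen, lexicographically
  sorted vocabulary of functional-domain identifiers (Pfam families in
  practice), 1 where a domain was hit by an HMMER search. We parse tblout
  tables or plain identifier lists; hits outside the vocabulary are counted
  and warned about, never fatal, because prediction-time sequences can
  legitimately contain domains unseen at training time.

Non-standard residue letters are rejected by default; an explicit option
maps B→D, Z→E, U→C, O→K, J→L ('X' is always an error since it carries no
residue identity). This keeps the 20-column contract exact rather than
diluting it with an ambiguity column.

## The network

Both levels share one branched topology: a convolutional stack over each
L x 20 matrix (the two sequence branches have separate weights), global
pooling over positions, a fully-connected layer over the domain vector,
concatenation, a fully-connected classifier head, and Q per-class logistic
outputs. Global pooling — max by default — is what makes the network
independent of sequence length: no padding to a fixed length is needed, and
a length-5 and a length-5,000 sequence pass through the same weights.
Per-class logistic outputs (not softmax) are essential: main classes are
not mutually exclusive.

The published architecture fixes the topology but none of the layer sizes,
so the defaults here are desk-scale choices, all overridable through
`model_config()`:

| parameter | default | why |
|---|---|---|
| conv layers | windows 4 then 8, 32 channels | receptive field 11 covers short motifs; two scales |
| pooling | global max | presence-of-feature semantics for motif detection |
| domain FC / head width | 64 / 128 | small but expressive at desk scale |
| dropout | 0.3 on the concatenated features | regularization at the fusion point |
| optimizer | Adam, learning rate 1e-3, batch 32 | robust default for small nets |
| epochs | 40 | the one training figure the published runs state |

Training is plain R with BLAS matrix operations and hand-derived
backpropagation (im2col convolution, pooling argmax routing, Adam). At the
problem sizes this package targets (hundreds to a few thousand sequences of
length ~50–120) a full 40-epoch run takes a few minutes on one CPU.
Training, initialization and dropout all draw from the configuration seed,
so runs are bit-reproducible on a fixed platform.

For the binary level we deliberately shrink and regularize the model (one
window-6 convolution with 8 channels per branch, widths 16/16, dropout 0.5,
30 epochs). With only a few dozen positive training instances, the
full-size network memorizes them — training loss collapses while held-out
recall of the rare class stays poor — whereas the small configuration is
forced toward the generalizing rule.

## The ranking loss

For instance $x_i$ with true label set $L$ and complement $\bar L$, the
per-instance training error is

$$E_i = \frac{1}{|L|\,|\bar L|} \sum_{k \in L}\sum_{q \in \bar L}
\exp\!\big(-(l_{ik} - l_{iq})\big),$$

where $l_{ij} \in (0,1)$ is the network output for class $j$. Every
(true, absent) pair whose scores are ordered the wrong way is penalized
exponentially, so minimizing the total error ranks all true labels above
all absent ones. The implementation factorizes the double sum as
$(\sum_k e^{-l_k})(\sum_q e^{l_q})$ and is checked against a literal
two-loop oracle to 1e-12 in the tests; the analytic gradient is checked
against central finite differences.

The loss is undefined when $L$ is empty or contains all Q classes (the
normalization vanishes). We treat both as hard errors rather than silently
skipping instances: the synthetic generator never emits them and the label
readers reject them with the instance id. The independent-label squared
error $\sum_j (l_{ij}-d_{ij})^2$ is provided as `squared_loss()` for
contrast, and class-weighted binary cross-entropy is used at the binary
level, with positive-class weights defaulting to inverse label frequency —
the concrete reading of "penalizing" a model to attend to a rare class.

The optimized objective is the sum of per-instance losses; the recorded
history is the per-epoch mean, which is comparable across batch sizes and
has the same optimum.

## The adaptive threshold

A label set is read off the score vector by thresholding, but a single
constant threshold ignores instance-to-instance variation. Instead, for
each training instance we compute the threshold minimizing the count

$$\big|\{k \in L : l_k \le t\}\big| + \big|\{q \in \bar L : l_q \ge t\}\big|,$$

and then fit the linear function $t(x) = w^\top l(x) + b$ to these targets
by least squares. At prediction time the labels are
$\{j : l_j > t(x)\}$ (strict inequality).

The count objective is piecewise constant, so the implementation evaluates
it only on the open intervals between consecutive distinct sorted scores
plus the two outer intervals — a threshold placed exactly at a score value
can never beat both adjacent intervals because both comparisons are
inclusive. When the minimizing set is a segment, its midpoint is returned:
for scores (0.9, 0.8, 0.3, 0.1, 0.1, 0.1) with true classes {1,2} the
objective is 0 on (0.3, 0.8) and the threshold is 0.55. Three corner cases
need conventions the printed rule does not address, and we resolve them
deterministically:

* *Unbounded minimizing intervals* (e.g. inverted rankings, or the
  tolerated degenerate empty/full label sets during calibration) are closed
  off at half the mean adjacent-score gap beyond the extreme score (0.5
  when all scores tie), so "midpoint" is always defined.
* *Multiple disjoint minimizing segments*: the widest wins, ties broken by
  the lower midpoint.
* *Empty predictions*: an enzyme at this level always has at least one
  main class, so when the strict cut excludes every class the top-scoring
  class is returned with `fallback_used = TRUE`; the pipeline reports the
  fallback frequency so this path is auditable.

The least squares system is solved through the singular value
decomposition, which yields the minimum-norm solution when the design is
rank-deficient (fewer instances than classes, duplicated rows). The
optimizer is verified against a dense-grid enumeration oracle, and exact
recovery of a planted linear threshold function is asserted to 1e-8.

## Evaluation metrics

`metrics_report()` computes the full multi-label suite: hamming loss (mean
symmetric-difference size divided by Q), subset accuracy (exact set
equality), and macro- and micro-averaged precision/recall/F1 from per-class
confusion counts. Macro-F1 is the mean of per-class harmonic means, not the
harmonic mean of the macro averages; micro metrics pool TP/FP/FN over
classes first. Zero denominators (a class never predicted or never present)
yield 0 and a per-class flag — conservative, never inflating an average.
Every metric is cross-checked in the tests against a naive per-instance,
per-class double-loop reference.

## The synthetic benchmark generator

Real training data for this problem requires UniProt-derived sequence sets,
PSI-BLAST profiles against SWISS-PROT and HMMER searches against Pfam.
To make every stage trainable and testable without downloads, `sim_spec()`
and `generate_dataset()` emulate the *statistical structure* the method
assumes:

* variable-length sequences (default 50–120 residues) with uniform
  background composition and one distinct 6-mer motif planted per class at
  non-overlapping positions — each labeled class's motif is spliced in, so
  a bag-of-motifs substring search is a perfect oracle classifier on
  noiseless data (asserted in the tests: if the model fails end to end, the
  data are not to blame);
* label sets drawn from a pattern-frequency table shaped like the real
  multi-functional statistics (pairs dominate, 2+3 and 1+3 and 3+4
  heaviest, a few triples, one quadruple), singletons shaped like the real
  mono-functional class distribution;
* mono/multi imbalance `multi_fraction = 1085/23253`, the published ratio;
* per-class domain-indicator bits set with probability 0.9 given the class
  (0.02 otherwise) over a vocabulary of 24 identifiers — informative but
  noisy, like real domain hits;
* optional label noise: with probability 0.01 per instance one label is
  flipped, never producing an empty or full set. The default is the
  curation-error scale of expert-reviewed databases; a substantially higher
  rate would make flipped-label artifacts rival the genuinely rare
  multi-functional class, which no curated corpus resembles. The mono/multi
  flags always reflect the emitted (noisy) labels, so flags and label
  cardinalities are consistent.

What the generator does **not** emulate: realistic residue composition,
evolutionary profiles (the optional PSSM fixtures are the degenerate
one-hot profile), homology between instances, or Pfam biology. Passing
end-to-end tests on this data therefore demonstrates that the machinery —
encodings, loss, optimization, threshold calibration, metrics — works and
can recover planted structure; it says nothing about accuracy on real
proteins, which depends on real profiles and much larger models.

## Problem sizes and numerical choices

The package's own test conditions are: end-to-end multi-label recovery at
n = 2000 sequences (70/30 split, 40 epochs, noiseless motifs), and the
imbalance study at n = 2000 with `multi_fraction = 0.05` (30 epochs,
weighted vs unweighted on the same seed). These sizes were chosen so a full
run is a few CPU-minutes while leaving the learning problems non-trivial.
Other numerical conventions: network scores are clamped to
[1e-12, 1 - 1e-12] so downstream logarithms are finite; pooling argmax ties
resolve to the first position; sequences shorter than a convolution window
are zero-padded to one output position; checkpoints round-trip bit-exactly
via R's native serialization and refuse to load if the stored alphabet
ordering disagrees with the package.

## Known limitations

* The mono/multi decision at the binary level uses a 0.5 cutoff by
  default; under severe imbalance the interesting operating points may lie
  elsewhere, which is why the cutoff is exposed.
* The two levels are trained independently; no feature sharing between the
  binary and multi-label models is attempted.
* Per-class thresholds, isotonic or Platt-style calibration, and
  ranking-based metrics (one-error, coverage) are out of scope.
* Running PSI-BLAST or HMMER is not part of the tested surface; the
  package parses their outputs.

## A worked example

```{r example, eval = FALSE}
library(mlenz)

# simulate a labeled benchmark and train the multi-label level
ds <- generate_dataset(sim_spec(n = 600, label_noise = 0, seed = 1))
data <- encode_sim_dataset(ds)
cfg <- model_config(seed = 1, epochs = 15)
model <- build_model(cfg, domain_dim = length(ds$vocabulary))
model <- train_model(model, data, loss = "bpmll", config = cfg)
model <- calibrate_threshold(model, data)

# predict and evaluate
preds <- lapply(data, function(inst) predict_main_classes(inst$x, model))
metrics_report(preds, lapply(data, `[[`, "y"), Q = 6)
```
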