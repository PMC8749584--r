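---
title: "Predicting hospital admission from serialized ED records: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting hospital admission from serialized ED records: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modelling idea

Emergency departments triage patients with coarse acuity scales that
concentrate most visits in the middle levels, so a score that predicts the
*outcome* of the visit — will this patient end up admitted to hospital? —
is a useful second opinion at the front door. `edtriage` implements a
dual-branch neural classifier over **serialized** visit records: every
structured EMR row (vitals, demographics, acuity, comorbidity and procedure
flags) is rendered as a short natural-language sentence,

```
age 28 years sex female arrival mode ambulance triage level 4
body temperature 37.1 degrees ... ct scan done
```

and the sentence, not the feature vector, is what the model consumes. The
attraction of this data-to-text view is that one architecture then covers
heterogeneous schemas and free-text additions without re-engineering the
input layer, and that token-level attention weights are directly
interpretable against the source record.

## Architecture

Two encoders read the same embedded token matrix $I \in \mathbb{R}^{h
\times w}$ ($h$ tokens, embedding width $w$):

* **Recurrent branch (long-range structure).** A bidirectional GRU (hidden
  width $H$ per direction, outputs concatenated to $2H$ per position) is
  pooled by a stack of $L = 2$ feed-forward attention layers. Each layer
  scores every live position with a two-sublayer ELU network and
  softmax-normalizes the scores; the first layer re-weights the sequence
  position-wise (position $t$ is scaled by $T\,\alpha_t$, so uniform
  attention is exactly the identity), and the second pools to the context
  vector $\sum_t \alpha_t v_t$. A 64-unit ELU dense layer and a softmax
  head complete the branch.
* **Convolutional branch (local phrase structure).** Three pyramid stacks
  with kernel sizes 3, 4, 5 at stride 1 — matched to the length of the
  phrase-plus-value fragments the serialization produces — each consist of
  a region convolution to $C$ channels followed by $B$ pre-activation
  residual blocks (two same-length convolutions with an identity shortcut)
  each ending in window-3 stride-2 max pooling, so $B$ blocks leave
  $\lceil h/2^B \rceil$ "keyword vectors". Each stack is pooled by the same
  attention mechanism (one layer), the three contexts are concatenated, and
  a 64-unit ELU dense layer plus softmax head follow.
* **Fusion.** After both branches are trained, their softmax heads are
  deleted, the two 64-unit penultimate layers are concatenated into a 128-d
  joint representation, dropout is applied, and a fresh softmax head is
  fine-tuned together with *all* carried-over branch weights. The reported
  training loss decomposes as $l_{total} = l_{cnn} + l_{rnn}$; during
  fine-tuning those two terms come from lightweight auxiliary readout heads
  (initialized from the deleted branch heads and discarded at export) while
  the fused head's own cross-entropy is additionally minimized. A
  `finetune_loss = "fused-only"` mode drops the auxiliary terms; both exist
  because a literal reading of the loss (per-branch terms) and of the
  synthesis step (heads deleted) cannot hold simultaneously.

All forward and backward passes are authored in this package (the GRU time
loop, the im2col convolution gather and the activation kernels in compiled
code); there is no external deep-learning runtime. Analytic gradients are
verified against central finite differences in the test suite.

## Serialization contract

Features render in fixed schema order as `display phrase + value (+ units)`
with lower-cased whitespace tokenization, point decimal marks, values at
declared schema precision, and no punctuation tokens. This makes the
rendering injective on filtered records; `parse_transcript()` is its exact
inverse, and a 1000-record round-trip property test enforces losslessness.
Records with a missing or out-of-range required feature are dropped before
rendering (no imputation — the sentence template has no "missing" form),
with per-feature drop accounting. The outcome column is configurable, so
the same pipeline retargets from hospital admission to ICU admission or
mortality.

## Training recipe

The production defaults follow the published recipe: Adam (learning rate
$10^{-5}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$),
batch 64, 60 epochs, $H = 128$, embedding width 300, kernels {3, 4, 5} at
stride 1, dropout 0.5 ahead of the fused head. Splitting is stratified
72 / 8 / 20 (train / validation / test) by largest-remainder allocation
within each class; the parameters of the best validation-AUROC epoch are
kept. `repeat_select()` re-splits and retrains (default 20 repeats) and
offers both published selection protocols: *internal* (select by hold-out
test AUROC — this leaks test information and reports say so) and *external*
(select by validation AUROC, evaluate once on the hold-out set).

Choices the recipe leaves open, fixed here and recorded in the config:

* "Iterations = 60" is read as epochs; a batch-level reading would leave
  most of the data unseen.
* The dense-64 layers use ELU, for consistency with the attention scorer.
* Attention scorer hidden width is 64.
* GRU gates follow the standard update/reset formulation with a tanh
  candidate, Glorot-uniform weights and zero biases — except the
  update-gate bias, initialized to $+1$ so the cell starts in a
  state-carrying regime. This is the recurrent analogue of the LSTM
  forget-gate-bias convention; without it the biGRU needs far longer to
  propagate credit across distant positions, and with it the long-range
  interaction benchmark below is learned within the small epoch budget.
* Gradients are clipped to global norm 5 (stabilizes the recurrent branch
  early; inert later).
* Decision threshold for the confusion metrics is 0.5; a Youden-point
  helper exists for validation-tuned operating points.
* The "combination" of the three kernel outputs is implemented as
  concatenation of the three attention contexts (3C wide) rather than
  elementwise addition, matching the architecture's description of the
  contexts being concatenated before the dense layer.
* Max pooling in the pyramid uses the window-3 / stride-2 convention of
  the pyramid architecture rather than kernel-sized windows.

## The synthetic cohort generator

No patient data ship with the package; `generate_cohort()` is a first-class
module that emulates an NHAMCS-like 15-feature schema (demographics,
arrival mode, 5-level triage acuity, six vitals, pain scale, two
comorbidity flags, two imaging flags). Features draw from declared
marginals — range-truncated normals for vitals (e.g. temperature
N(36.8, 0.7) on [34, 42] at precision 0.1), stated level probabilities for
categorical features — and the outcome follows a planted logistic model
over standardized features:

* main effects: triage acuity dominates (+1.6 log-odds at level 1 down to
  −1.6 at level 5, the clinically expected direction), with moderate
  weights on age (+0.4), pain (+0.4), oxygen saturation (−0.4) and
  diabetes (+0.4) — all *local* phrase-adjacent patterns;
* one **pure long-range interaction**: sex × CT scan with weight 1.8 on
  the product of standardized binaries, zero main effect on either, whose
  tokens render ~40 positions apart — signal that a 3–5-token convolution
  window cannot see locally, which is what makes the fusion comparison
  meaningful;
* intercept −1.1, calibrated once so prevalence ≈ 0.3 (an admission-like
  base rate).

Because the generating probability $p(x)$ is known per record, the
Bayes-optimal AUROC — `bayes_auroc()`, the ceiling for any classifier on
that cohort — is measurable with the same AUROC routine used for models.
Under the defaults (n = 20,000, seed 1) it is ≈ 0.869 at prevalence ≈ 0.30;
the frozen value ships in `inst/extdata/default_cohort_oracle.json` and a
test regenerates and matches it.

What the generator does **not** emulate: real marginal dependence between
vitals, missingness patterns, free-text chief complaints, temporal
structure, or NHAMCS's sampling design. Passing the synthetic benchmarks
therefore demonstrates that the architecture, gradients, and protocol work
and that the engine can recover planted local and long-range signal near
its information ceiling — not that it attains any particular performance
on real ED data.

## Problem sizes and the fast profile

The production hyperparameters are impractical for routine checking, so a
documented **fast profile** (`triage_config("fast")`) is used by the tests
and the acceptance script: embedding 32, H = 32, C = 16, B = 2 pyramid
blocks, learning rate $10^{-3}$, 4 branch epochs and 2 fine-tuning epochs.
On the default cohort both branches are at or past their validation plateau
within those budgets (the convolutional branch typically peaks by epoch
2–3). Test-scale experiments use n = 20,000 for the mixed-signal benchmark
and the fusion comparison, n = 8,000 (8 epochs) for the long-range
recurrent benchmark, n = 6,000 (3 epochs) for the local-pattern and
translation checks, and n = 5,000 for the null control.

## Numerical choices and degenerate inputs

* Padding is right-sided; batches are trimmed to their longest live
  sequence (outputs are provably unchanged by trailing padding, and tests
  assert it). Masked positions emit exactly zero from the biGRU, get
  attention weight exactly 0, are zeroed after every convolution, and
  enter max pooling as a −10³⁰ sentinel so they can never win a window;
  all-padding windows emit 0. The PAD embedding row is all-zero and frozen
  during training.
* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 10⁻¹².
* Attention over an all-masked sequence, an all-padding input to either
  branch, and a sequence shorter than the kernel size are errors, not
  silent degradations.
* Ties in max pooling resolve to the earliest window offset; AUROC counts
  score ties one-half (mid-rank convention), so an all-tied score vector
  scores exactly 0.5.
* The vocabulary orders tokens by frequency then lexicographically, making
  index assignment deterministic; out-of-vocabulary tokens map to UNK at
  encoding time, and the vocabulary is built on the training split only.
* Every stochastic step (cohort draw, split, initialization, shuffling,
  dropout) is seeded from the run configuration; two runs from one seed
  are bit-identical, which the protocol-determinism test asserts.

## Known limitations

* Only the English rendering path is implemented; the tokenizer hook is
  pluggable but no CJK segmentation ships.
* Numeric value tokens are atomic (one token per rendered value), so
  generalization across unseen numeric values relies on vocabulary
  coverage rather than numeracy; rare values fall back to UNK.
* Pretrained word vectors are supported (word2vec/FastText text format,
  with coverage logging) but the default path trains embeddings from
  random initialization.
* The internal-comparison selection protocol deliberately reproduces a
  test-set leak present in the published procedure; use `mode =
  "external"` for honest estimates.
* At production scale (745k visits) the pure-R-plus-kernels implementation
  is slower than a GPU framework; the architecture is desk-scale here by
  design.
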