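# edtriage

Dual-branch neural text models for emergency-department triage: predicting
hospital admission (or ICU admission, or mortality) from structured ED
visit records that are first **serialized into sentences**.

## What it does

Emergency departments assign 5-level acuity scores at the door, but those
concentrate most patients in the middle levels. A useful complement is a
model that predicts the *outcome* of the visit — admission to hospital —
from the data available at triage. `edtriage` implements such a system end
to end:

1. **Declarative schemas + filtering** (`load_schema()`, `read_visits()`,
   `filter_records()`): typed visit tables, with records missing a
   required feature (or out of physiologic range) dropped with per-feature
   accounting — no imputation.
2. **Data-to-text serialization** (`transform_records()`): each record
   becomes a sentence, `age 28 years sex female ... triage level 4 body
   temperature 37.1 degrees ... ct scan done`, rendered deterministically
   in schema order; `parse_transcript()` is the exact inverse, so the
   serialization is provably lossless.
3. **Two sentence encoders**, written from scratch (no deep-learning
   runtime; the GRU loop and convolution gather run as compiled kernels):
   - a **biGRU** (hidden width H per direction) with a 2-layer
     feed-forward ELU **attention** stack pooling the hidden sequence —
     the long-range branch;
   - a **pyramid CNN** with kernels 3/4/5 at stride 1, pre-activation
     residual blocks and stride-2 max pooling (sequence length halves per
     block, leaving ⌈h/2^B⌉ keyword vectors), attention-pooled per kernel
     — the local-phrase branch.
   Both end in a 64-unit ELU dense layer and a softmax head.
4. **Fusion** (`fuse()`, `finetune_fused()`): both heads are deleted, the
   two 64-unit penultimate layers concatenate to a 128-d joint
   representation, dropout is applied, and a fresh softmax head is
   fine-tuned with all branch weights trainable. The loss decomposes as
   `l_total = l_cnn + l_rnn` over auxiliary branch readouts, with the
   fused head's cross-entropy additionally minimized.
5. **Protocol + metrics** (`stratified_split()`, `train_branch()`,
   `repeat_select()`, `confusion_metrics()`, `auroc()`): stratified
   72/8/20 splits by largest remainder, Adam (production defaults: lr
   1e-5, batch 64, 60 epochs, H = 128), best-validation-epoch
   checkpointing, repeated model selection, and the six headline metrics
   (sensitivity, specificity, precision, F1, accuracy, AUROC; AUROC via
   the Mann-Whitney mid-rank formulation).
6. **A synthetic EMR generator** (`generate_cohort()`): NHAMCS-like
   15-feature cohorts with a planted logistic outcome — local main
   effects (triage acuity dominant) plus one pure long-range sex × CT-scan
   interaction — and a known per-record truth, so `bayes_auroc()` gives
   the exact performance ceiling for any classifier on that cohort.

## Worked example

```r
library(edtriage)

cohort <- generate_cohort(20000, seed = 1)     # synthetic study cohort
bayes_auroc(cohort)
#> [1] 0.8690473                                 # ceiling on this cohort
cohort$prevalence
#> [1] 0.3038                                    # admission-like base rate

transform_records(cohort$records[1, ], cohort$schema)
#> [1] "age 28 years sex female arrival mode ambulance triage level 4
#>      body temperature 37.1 degrees heart rate 69 beats respiratory rate
#>      13 times systolic pressure 150 mmhg diastolic pressure 65 mmhg
#>      pulse oximetry 97 percent pain index 3 diabetes present heart
#>      failure absent x ray done ct scan done"

run <- train_triage_engine(cohort, triage_config("fast", seed = 1))
round(sapply(run$metrics, `[[`, "auroc"), 4)
#>    rnn    cnn  fused
#> 0.7881 0.8551 0.8530
```

Reading the numbers: the Bayes ceiling of this cohort is 0.869. The
recurrent branch alone reaches ~0.79 (it must discover the long-range
interaction), the convolutional branch ~0.85 (the dominant signal is
phrase-local), and the fused engine matches the best branch while holding
both representations — reproducing, at desk scale, the ordering the
architecture is designed for. The null-control cohort (no
planted effect) trains to AUROC ≈ 0.5, confirming the pipeline cannot
manufacture signal.

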