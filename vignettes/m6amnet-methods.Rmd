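---
title: "m6amnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m6amnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

N6,2'-O-dimethyladenosine (m6Am) is a dual methylation — 2'-O on the
ribose, N6 on the base — of the adenosine adjacent to the mRNA 5' cap.
Experimentally mapped m6Am sites sit on an adenosine in a BCA context
(B = C, G or U immediately followed by C, then the modified A).
`m6amnet` treats site identification as binary classification of a
(2&xi;+1)-nt RNA window centered on a candidate A, with &xi; = 20
(41-nt windows) by default, and provides everything from benchmark
construction to an ensemble deep classifier and its evaluation.

A note on the window length: the data convention this package follows
describes windows via a flank parameter &xi;, and the literature this
design tracks is internally inconsistent about whether "41" names the
flank or the full window. Every dimensional statement (41 x 4 and
41 x 3 encoding matrices, 41-nt samples) implies a 41-nt window, so the
package fixes &xi; = 20 as the default and exposes it as configuration.

## Sequence encoders

Three context-based encoders map a validated RNA string (T is
normalized to U; ambiguity codes are rejected, not imputed, because no
defensible imputation rule exists for single-nucleotide site calling)
to an L x C matrix with values in [0, 1]:

* **One-hot** (4 channels, order A, C, G, U): each residue is an
  indicator row; rows sum to 1.
* **NCP** (3 binary channels): ring structure (purine A/G = 1),
  chemical functionality (amino A/C = 1) and hydrogen-bond strength
  (weak-pairing A/U = 1). A = (1,1,1), C = (0,1,0), G = (1,0,0),
  U = (0,0,1) — a bijection on the alphabet.
* **ND** (accumulated nucleotide frequency, 1 channel): entry *i* is
  the count of residue *i*'s own letter among positions 1..*i* divided
  by *i* (1-based), so "ACGACUUAGA" encodes to
  (1, 1/2, 1/3, 2/4, 2/5, 1/6, 2/7, 3/8, 2/9, 4/10).

The fusion encoder concatenates channel blocks in the fixed order
one-hot &Vert; NCP &Vert; ND (8 channels). Channel order within and
across blocks is pinned down explicitly — the convention is arbitrary
but must be stable for saved models to be portable. A "NCPD" (NCP + ND)
fusion sometimes described in the field is notationally identical to
this flat three-way concatenation, so only the flat form is
implemented.

## The base classifier

Each base classifier is a single network (implemented natively in R on
BLAS-backed matrix operations; no deep-learning backend is required):

1. **Multi-head self-attention front-end** over the L positions: the
   8-channel input is projected to `attention_model_dim` (default 64)
   and processed by `attention_heads` (default 4) scaled-dot-product
   heads with an output projection; sequence length is preserved.
   A learned input projection is added *residually* to the attention
   output. This residual is a deliberate design choice: at
   initialization softmax mixing is near-uniform across positions,
   which erases the positional information that the downstream
   branches need, and without the residual the attention variant
   measurably under-performed its own ablation on planted-motif data.
   One attention module is shared by both branches by default
   (`attention_mode = "shared"`); a per-branch mode is available.
2. **CNN branch**: two 1-D convolutions (defaults 64 filters, kernel 5,
   then 64 filters, kernel 3, valid padding, ReLU) followed by one
   temporal max-pooling layer (width 2) and flattening.
3. **BiLSTM branch**: forward and backward LSTMs (default 64 hidden
   units each) over the attention output; the two final hidden states
   feed one fully connected layer with ReLU (default width 64).
4. **Prediction head**: branch outputs concatenated into two fully
   connected layers (defaults 64, then 2), each followed by dropout
   (defaults 0.5, 0.5), and a softmax over \{non-m6Am, m6Am\}.
   The positive class is index 1 throughout and the decision threshold
   is 0.5, with ties predicted positive.

Ablation flags (`no_attention`, `cnn_only`, `bilstm_only`) remove the
corresponding component so the architecture comparisons can be
reproduced.

The original tuned layer sizes behind this family of models are not
public; the defaults above are standard values for 41 x 8 inputs, every
size is exposed in `base_classifier_spec()`, and the ensemble grid
explores a neighborhood of them. Under the defaults the model has
about 1.9e5 parameters (checked against a 1e6 budget in the tests).

**Training.** 2-class cross-entropy on the softmax outputs (only the
softmax is dictated by the design; the optimization recipe is this
package's choice), minimized by Adam (lr 1e-3, batch 64) with shuffled
mini-batches, early stopping on validation *accuracy* — the same metric
used for member selection — with patience 10, and restoration of the
best-epoch weights. All randomness (initialization, shuffling,
dropout) funnels through the spec seed, so training is exactly
reproducible; backpropagation through every layer is validated against
finite differences in the test suite (worst relative error around
1e-7).

## The ensemble

`hyperparameter_search()` trains each spec in a grid and ranks by
accuracy on a held-out validation split (selection on training
accuracy would prefer overfit members). `select_top_k()` takes the top
3 (ties broken by grid order) and fixes the aggregation rule: **soft
voting**, the arithmetic mean of member probability vectors, thresholded
at 0.5. Where the literature uses "voting" and "averaging"
interchangeably, averaging is canonical here; hard majority voting is
available behind a flag. The mean rule implies the ensemble
probability is always bounded by the member minimum and maximum, which
the tests assert.

## Benchmark construction

From a reference FASTA and a 0-based site list, the builder:

1. extracts (2&xi;+1)-nt windows (minus-strand sites are
   reverse-complemented before T&rarr;U so windows read 5'&rarr;3' on the
   transcript strand; windows overlapping sequence ends are dropped,
   not padded, and non-A centers or ambiguity codes are dropped with
   logged counts);
2. keeps windows whose center context is BCA, interpreted as positions
   (&minus;2, &minus;1, 0) = (B, C, A) relative to the candidate A — the
   standard cap-m6Am context;
3. removes redundancy per class by greedy identity clustering at 80%
   (first-seen representative retained; matches/length over the
   equal-length windows). A CD-HIT-EST backend shells out to the
   external binary when installed;
4. samples negatives uniformly without replacement to a 1:1 class
   ratio (the negative candidate universe is always explicit — a
   user-supplied region set or the synthetic generator — rather than an
   invented genomic null model);
5. plans splits: a stratified 80/20 random split (largest-remainder
   apportionment across classes), or chromosome-level hold-out groups.

**Chromosome hold-out rule.** A chromosome becomes its own test group
when it has at least `min_count = 50` records, and all smaller
chromosomes pool into one final test group. Counting is per class by
default (a chromosome qualifies only if *both* classes reach 50): on a
benchmark-shaped fixture with published per-chromosome counts, the
per-class rule reproduces exactly the known grouping in which a
chromosome with 71 total records is still pooled; a `"total"` counting
mode is provided as the alternative reading.

## Evaluation conventions

Threshold metrics are Sn = TP/(TP+FN), Sp = TN/(TN+FP),
ACC = (TP+TN)/N and the Matthews correlation coefficient with the
standard denominator sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); a published
variant of the formula groups the same four factors differently, and
the tests verify the two transcriptions agree on 1,000 random tables.
MCC is defined as 0 whenever a denominator factor vanishes. AUROC uses
the Wilcoxon rank statistic with midranks for ties (equal to the
trapezoidal ROC area, verified against an O(n&sup2;) concordant-pair
oracle); AUPR is step-wise average precision, the conservative choice,
with no PR interpolation. Repeated stratified k-fold CV (default 5
folds, 20 repeats) pools predictions within each repeat by default and
reports mean &plusmn; SD across repeats; per-fold averaging is the
alternative mode.

## The synthetic world

`synthetic_spec()` states the world once: 2,000 windows per class of
length 41, uniform background composition, the deterministic 6-mer
consensus motif CUGGAC planted 3 nt downstream of the center in 90% of
positives (&lambda; = 0.9), 8 pseudo-chromosomes assigned round-robin
within class. Both classes get the imposed (B, C, A) center context, so
the class signal is *only* the planted motif; a background window
matches the consensus with probability (1/4)^6 &asymp; 2.4e-4
(`estimate_bayes_gap()`), so a perfect detector attains AUROC
&asymp; &lambda; + (1&minus;&lambda;)/2 = 0.95 at &lambda; = 0.9.
The generator emulates the *shape* of real benchmarks — window length,
center context, balance, chromosome provenance — but none of the hard
parts of real data: positional preference gradients, composition bias
around the cap, overlapping transcript isoforms, or label noise from
the underlying assay. A green signal-recovery test therefore
establishes that the architecture, gradients and training loop work,
not that real-data accuracies are reproduced; published accuracy
tables require the original genome-derived benchmark and are treated
as directional references only.

## Numerical and runtime choices

* Glorot-uniform initialization; LSTM forget-gate bias 1.
* Softmax rows are max-shifted before exponentiation; cross-entropy
  clamps probabilities at 1e-12.
* Seeds are derived from one master seed per run and kept below 2^31;
  `with_seed()` restores the caller's RNG state.
* The acceptance run trains the default architecture with
  `max_epochs = 12, patience = 4`: signal recovery on the stated world
  saturates after a few epochs, and the cap keeps the run inside a
  10-minute single-CPU budget. The schedule is a runtime budget, not
  part of the stated data world.
* Redundancy filtering is O(n&sup2;L) in the internal backend —
  adequate for benchmark-scale inputs (thousands of windows); use the
  CD-HIT-EST backend for very large candidate pools.

## Known limitations

* No GPU or parallel training; the network is desk-scale by design.
* The negative-candidate universe must be supplied; the package does
  not construct a genomic null model.
* `repeated_kfold_cv()` with the deep recipe is expensive (k &times;
  repeats trainings); the protocol harness accepts any recipe, and
  cheap reference models are used for protocol-contract testing.
* Windows with ambiguity codes are dropped rather than scored.
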