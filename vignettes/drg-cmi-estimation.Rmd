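---
title: "Early DRG prediction and case-mix estimation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early DRG prediction and case-mix estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(drgcast)
```

# Scope

`drgcast` estimates, for an ICU population, the case-mix index (CMI) —
the mean DRG relative weight — from clinical notes available early in the
admission. It covers the whole chain: synthetic data generation, cohort
construction, text preprocessing, an attention-CNN classifier, per-subset
discrimination metrics, and the population-level CMI and payment
analyses. This vignette records the scientific choices behind each stage:
what is modelled, which parameters matter, and where the design was
genuinely open.

# The synthetic cohort generator

Real DRG-labelled ICU notes sit behind restricted-access agreements, so
the generator is a first-class, tested component, not a fixture. It
emulates the *structure* of such data:

* **Code space.** An MS-like system has flat codes; an APR-like system
  expands each clinical group into four severity-of-illness tiers, each
  with its own weight, strictly increasing in severity. Severity
  multipliers (0.55, 0.80, 1.15, 1.50 with 5% lognormal jitter) average
  one, so the severity expansion preserves the catalog-level mean weight.
* **Rank-frequency.** DRG assignment follows a Zipf law over base groups
  (`zipf_exponent`, default 1.2). Hospital DRG distributions are heavily
  top-concentrated; the Zipf default makes "top-k DRGs" subsets and
  majority-class behavior meaningful at small scale.
* **Weights.** Relative weights are lognormal, calibrated so the
  arithmetic mean and SD approach `weight_mean = 3.0` and
  `weight_sd = 2.8`, clipped below at 0.2 (real weight tables have no
  near-zero weights). The clip biases the mean upward by well under 1%.
* **Notes over time.** Note counts are Poisson per 6-hour interval over
  chart times −24 to 48 hours post-admission (HPA); negative HPA models
  the gap between hospital and ICU admission. Each note position emits
  one of the stay's DRG-specific signal n-grams with probability
  `clamp(signal_rate_slope × (chart_hpa + 24), 0, 0.5)` — zero one day
  before ICU admission, growing linearly — otherwise a Zipf-distributed
  background token. Linear accrual is the simplest mechanism that makes
  prediction error fall as the admission progresses, which is the
  qualitative phenomenon the sweep analyses measure; nothing downstream
  depends on linearity.
* **Filter bait.** Configured fractions of under-18 patients,
  multi-ICU-visit stays, and repeat patients exist only to exercise the
  cohort filters and patient-level splitting. De-identification
  placeholders use the `[** ... **]` dialect so the cleanup step faces a
  realistic pattern.

Per-note length (Poisson, mean 30 tokens, floor 5) and the note-category
mix are free parameters chosen to give 48-HPA documents of a few hundred
tokens at the default note rate; they are conventions, not calibrated
claims. What the generator does **not** attempt: real clinical language,
discharge summaries (deliberately never emitted — they would not exist at
prediction time), structured vitals/labs, or official grouper logic.
Consequently, passing tests demonstrate that the pipeline recovers
*planted, unambiguous* signal; they say nothing about the attainable
accuracy on real notes, where the signal is diffuse and confounded.

# Cohort construction and splitting

Eligibility is: age strictly over 18 (a literal reading of "over 18";
`adult_inclusive = TRUE` switches to ≥ 18), exactly one ICU visit, at
least one note charted at or before 48 HPA, and a DRG present in the
system's catalog. The label space is the *full* catalog for the system in
stable lexicographic order — payment systems define more targets than any
cohort observes, and a fixed, sorted label space keeps model indices
reproducible across runs.

Splits are by patient, never by admission, so no patient's notes can
appear on both sides. The hold-out rule assigns shuffled patients to the
test side until test *stays* reach the target fraction (default 10%);
with multi-stay patients the realized fraction can overshoot by at most
one patient's stays. Whether the 10% should count stays or patients was
open; counting stays matches the quantity the evaluation actually uses.
Cross-validation folds partition the remaining patients round-robin after
a seeded shuffle. For population analyses only each test patient's first
admission is kept; admission order is carried by stay-id order, which the
generator assigns chronologically.

# Text preprocessing

Notes up to the cutoff are sorted by chart time (stable for ties) and
concatenated, which makes the document at cutoff *t* a prefix of the
document at any later cutoff. Cleanup removes `[** ... **]` placeholders,
lowercases, and splits on non-alphanumerics. The vocabulary maps tokens
seen at least `min_count = 3` times; everything else shares one unknown
id, and a reserved padding id maps to an all-zero, never-updated embedding
row. The vocabulary is built from training-fold text only by default —
counting over the whole cohort (`vocab_scope = "cohort"`) is available but
leaks test-set token statistics into the model's input space.

Documents are truncated/padded to `max_len` (default 2000 tokens, the
order of a two-day ICU note concatenation). Truncation keeps the *head*:
in an early-prediction setting the earliest text is what is actually
available first, and head truncation keeps the encoded document monotone
in the cutoff; tail truncation is available as an option. Embeddings are
trained from random initialization rather than loaded from pretrained
clinical vectors; with planted synthetic signal, pretraining would add
nothing the task needs.

# The classifier

The model is a one-dimensional CNN over embeddings (same-length padding,
tanh), pooled by **per-label attention**: each DRG code has its own
attention vector, giving a per-label attended feature vector that a
per-label linear read-out scores, followed by a softmax across labels and
a cross-entropy objective — the single-label adaptation of the
convolutional-attention coding architecture. Attention is computed on the
post-tanh feature map. Defaults: kernel width 5 (matching the 5-token
windows reported by attention inspection), 50 filters, embedding 100,
dropout 0.2, Adam at 1e-3 — all exposed in `model_config()`, and the test
and acceptance runs use smaller widths/filter counts sized to their
problem (stated below).

Numerical and degenerate-input choices:

* Convolution runs over the true-length token sequence only, so appended
  padding can never attract attention or change a score; an empty
  document (legal at pre-admission cutoffs) is represented by a single
  padding window, and prediction falls back to what the read-out encodes
  about the label prior.
* Argmax ties break toward the lowest label index, for determinism.
* Softmaxes subtract the row maximum before exponentiation.
* Training keeps the parameters of the best validation-objective epoch;
  all shuffling, initialization and dropout derive from `config$seed`,
  and per-stage seeds derive from a global seed via a small string hash,
  so runs are reproducible at a fixed BLAS thread count.
* Gradients of every parameter were verified against central finite
  differences (agreement ~1e-10) during development.

The regression head replaces the per-label machinery with one attention
vector and a linear output trained on mean absolute error against payment
weights — the variant for settings where the weight, not the code, is the
quantity of interest.

# Evaluation

AUC is one-vs-rest per label, computed by midrank (ties count ½, equal to
pairwise concordance); macro averages over subset labels that have both a
positive and a negative stay (labels with no positive test case have no
defined AUC and are dropped, with the dropped count attached), micro
pools the (stay, label) indicators into a single ranking. F1 defines a
label with neither predictions nor positives as 0 and macro-averages over
the *full* subset list including those zeros — which is why macro-F1 runs
far below micro-F1 on large label spaces. Micro-F1 over the full label
space with single-label predictions reduces algebraically to accuracy,
and the tests assert this identity. Subsets are: all codes, each MDC,
top-30/top-50 by test frequency, and the shortest frequency-ranked prefix
covering 80% of test stays; boundary ties break by code order. Fold
models are aggregated as mean and sample SD (ddof 1).

# CMI, sweep, and bootstrap

CMI is the arithmetic mean weight; its error is `|pred − true| / true`.
The admission-time sweep re-assembles and re-encodes every population
document at each cutoff on the −24…48 h grid (step 6, 13 points) for each
fold model; stays with no note yet are predicted from an all-padding
input rather than dropped, so the population is fixed across the sweep.
The cohort-size analysis draws 20 with-replacement subgroups per model
and size (100 subpopulation estimates under five models), reports the
mean error with a percentile-bootstrap 95% CI of that mean (1000
replicates by default; the method and replicate count were open choices),
and — because it is ambiguous whether a CI should summarize subpopulation
*errors* or subpopulation *CMIs* — also emits the 2.5/97.5 percentiles of
the subpopulation CMIs. Payment is projected as
`base_rate × CMI × n_stays` (default $6000 per unit weight), deliberately
excluding wage indices, outlier and transfer adjustments.

# Problem sizes used by the test and acceptance runs

Chosen as the package's own balance of statistical resolution against
desk-scale runtime: the parameter-recovery check trains on a
2000-patient, 10-group cohort with strong signal
(`signal_rate_slope = 0.004`) and verifies held-out accuracy > 0.9 and
CMI error < 2% at 48 HPA; the fall of the error profile from −24 to
48 HPA is verified on ten independent 250-patient generator seeds. The
acceptance script runs the full five-fold pipeline on an 800-patient
cohort. Shared test fixtures use a 150-patient, 4-group world with a
once-trained model cached across test files.

# Known limitations

* Synthetic signal is unambiguous by construction; accuracy and CMI
  error here are ceilings, not forecasts for real ICU text.
* The per-label attention matrix is dense (labels × positions); at
  thousand-label catalogs with 2000-token documents, training in base R
  is minutes-per-epoch territory — appropriate to the synthetic scale
  this package targets, not to full production catalogs.
* MDC assignment, severity mix, and note-category proportions are
  plausible conventions, not estimates from data.
* Single-threaded determinism is the contract; exact reproducibility
  across differing BLAS thread counts is not guaranteed.
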