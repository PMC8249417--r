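# drgcast

Early prediction of diagnosis-related groups (DRGs) and case-mix index
(CMI) from clinical notes.

## The problem

Under prospective payment, every inpatient admission receives a single DRG
code, and each code carries a relative weight *w* expressing expected
resource use; reimbursement is approximately `base_rate × w`. DRGs are
normally assigned by human coders *after* discharge, so hospital managers
can only review their case mix retrospectively. `drgcast` implements an
early-prediction pipeline: from the clinical notes charted around ICU
admission it predicts each stay's DRG with a convolutional neural network
pooled by per-label attention, maps predictions to payment weights, and
estimates the population CMI

```
CMI = (1/n) Σᵢ wᵢ ,   relative CMI error = |CMI_pred − CMI_true| / CMI_true
```

as a function of the hours-post-admission (HPA) cutoff at which notes are
available and of the cohort size. Because individual over- and
under-predictions of *w* offset each other in the mean, population CMI can
be estimated usefully even when per-stay DRG accuracy is imperfect.

The classifier follows the convolutional-attention architecture used for
automatic clinical coding, adapted to single-label output. For a document
with embedded token matrix `X`:

```
H = tanh(Conv1d(X))                 # positions × filters, width-k kernel
αₗ = softmax(H uₗ)                  # one attention vector uₗ per DRG l
vₗ = Hᵀ αₗ                          # attended feature vector for DRG l
p  = softmax(βₗᵀ vₗ + bₗ  over l)   # per-label linear read-out
```

trained with cross-entropy (or, in the regression variant, a single
attention vector with a linear head trained on mean absolute error against
the payment weights directly). Forward, backward, and Adam optimization
are implemented in base R matrix code; attention also yields the most
informative k-token windows per prediction for inspection.

Access to real DRG-labelled ICU notes is restricted, so the package ships
a first-class synthetic generator: Zipf-distributed DRG frequencies,
lognormal relative weights, notes accruing from −24 to 48 HPA whose
planted, DRG-specific n-gram signal densifies linearly over time,
de-identification placeholders, plus under-18 patients, multi-ICU-visit
stays and repeat patients to exercise the cohort filters and patient-level
splitting.

## Worked example

```r
library(drgcast)
cfg <- gen_config(n_patients = 300, n_drg_groups = 6, system = "MS_LIKE",
                  signal_rate_slope = 0.005, seed = 42)
catalog <- make_drg_catalog(cfg)
sim     <- simulate_cohort(catalog, cfg)
cohort  <- build_cohort(sim$stays, sim$notes, catalog, "MS_LIKE")
split   <- split_train_test(cohort, test_frac = 0.10, seed = 42)
folds   <- make_cv_folds(split$train_patient_ids, k = 5, seed = 42)
fs      <- fold_stays(cohort, split, folds, 1)

corpus <- lapply(fs$train$stay_id, function(sid)
  clean_and_tokenize(assemble_document(
    cohort$notes[cohort$notes$stay_id == sid, ], 48)))
vocab <- build_vocab(corpus, min_count = 3)

enc <- function(stays) lapply(seq_len(nrow(stays)), function(i) {
  nd <- cohort$notes[cohort$notes$stay_id == stays$stay_id[i], ]
  encode(clean_and_tokenize(assemble_document(nd, 48)), vocab,
         max_len = 200, stay_id = stays$stay_id[i], cutoff_hpa = 48)
})
mcfg <- model_config(embed_dim = 24, kernel_width = 5, n_filters = 16,
                     dropout = 0.1, learning_rate = 2e-3, epochs = 10,
                     batch_size = 8, seed = 42)
model <- train_drg_model(enc(fs$train), labels = fs$train$drg_code,
                         vocab = vocab, label_space = cohort$label_space,
                         config = mcfg, val_docs = enc(fs$val),
                         val_labels = fs$val$drg_code)

tst   <- test_stays(cohort, split)
preds <- predict_stays(model, tst, cohort$notes, catalog, cutoff_hpa = 48,
                       max_len = 200)
mean(preds$pred_code == tst$drg_code)      # held-out accuracy: 1

pop   <- make_test_population(cohort, split)
sweep <- hpa_sweep(model, pop, cohort$notes, catalog, max_len = 200)
sweep$summary[, c("cutoff_hpa", "mean_error")]
```

prints the CMI error profile across the admission-time sweep:

```
 cutoff_hpa mean_error
        -24     0.1865
        -12     0.0750
         -6     0.0025
          0     0.0176
         24     0.0000
         48     0.0000
```

With no usable signal a day before ICU admission the model mis-estimates
the population CMI by ~19%; as notes (and their diagnostic n-grams)
accrue, the error collapses — here to 0 from 24 HPA on, since every
held-out stay is classified correctly. The corresponding payment
projection is `estimate_payment(cmi, n_stays)`, e.g. `$316,744` for this
27-patient population at 48 HPA. At hospital scale, a 5%
relative CMI error on a 500-stay cohort with CMI 3.15 shifts the projected
reimbursement by `estimate_payment(3.3075, 500) − estimate_payment(3.15, 500)
= $472,500`.

`run_experiment()` packages all of the above — simulation, filtering,
patient-level split, vocabulary, five cross-validation fold models,
a per-subset AUC/F1 report, the HPA sweep, and the bootstrap cohort-size
analysis — into one resumable, manifest-tracked run directory.

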