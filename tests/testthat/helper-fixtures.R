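# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# A small MS-like simulated world with strong planted signal: catalog,
# simulation, cohort, split, folds, vocabulary.
small_world <- function() {
  cached("small_world", function() {
    cfg <- gen_config(n_patients = 150, n_drg_groups = 4, system = "MS_LIKE",
                      signal_rate_slope = 0.006, note_rate = 1.0,
                      note_len_mean = 25, seed = 101)
    catalog <- make_drg_catalog(cfg)
    sim <- simulate_cohort(catalog, cfg)
    cohort <- build_cohort(sim$stays, sim$notes, catalog, "MS_LIKE")
    split <- split_train_test(cohort, 0.15, seed = 7)
    folds <- make_cv_folds(split$train_patient_ids, 5, seed = 7)
    fs <- fold_stays(cohort, split, folds, 1)
    corpus <- tokenize_population_48(fs$train, cohort$notes)
    vocab <- build_vocab(corpus, 3)
    list(cfg = cfg, catalog = catalog, sim = sim, cohort = cohort,
         split = split, folds = folds, fold1 = fs, vocab = vocab)
  })
}

tokenize_population_48 <- function(stays, notes) {
  lapply(stays$stay_id, function(sid) {
    nd <- notes[notes$stay_id == sid, , drop = FALSE]
    clean_and_tokenize(assemble_document(nd, 48))
  })
}

encode_stays_48 <- function(stays, notes, vocab, max_len = 150) {
  lapply(seq_len(nrow(stays)), function(i) {
    nd <- notes[notes$stay_id == stays$stay_id[i], , drop = FALSE]
    encode(clean_and_tokenize(assemble_document(nd, 48)), vocab,
           max_len = max_len, stay_id = stays$stay_id[i], cutoff_hpa = 48)
  })
}

# A small trained classifier on the small world, shared across model and
# CMI tests (training once keeps the suite fast).
small_model <- function() {
  cached("small_model", function() {
    w <- small_world()
    tr <- encode_stays_48(w$fold1$train, w$cohort$notes, w$vocab)
    va <- encode_stays_48(w$fold1$val, w$cohort$notes, w$vocab)
    cfg <- model_config(embed_dim = 16, kernel_width = 5, n_filters = 12,
                        dropout = 0.1, learning_rate = 3e-3, epochs = 40,
                        batch_size = 8, seed = 42)
    train_drg_model(tr, labels = w$fold1$train$drg_code, vocab = w$vocab,
                    label_space = w$cohort$label_space, config = cfg,
                    val_docs = va, val_labels = w$fold1$val$drg_code)
  })
}

# A tiny hand-buildable vocabulary for unit tests.
toy_vocab <- function(tokens = letters[1:10]) {
  build_vocab(rep(list(tokens), 3), min_count = 3)
}
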