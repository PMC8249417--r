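#' Configuration of a full experiment run
#'
#' One object drives simulate -> cohort -> split -> preprocess ->
#' train (k folds) -> evaluate -> CMI analyses. A single global seed
#' derives every stage seed, so a run is reproducible end to end.
#'
#' @param gen A [gen_config()] for the synthetic data.
#' @param model A [model_config()] for the classifier.
#' @param test_frac Hold-out stay fraction (default 0.10).
#' @param k_folds Cross-validation folds (default 5).
#' @param train_cutoff_hpa Cutoff at which training documents are
#'   assembled (default 48).
#' @param max_len Encoded sequence length (default 2000).
#' @param min_count Vocabulary minimum token count (default 3).
#' @param vocab_scope `"train"` (default; vocabulary from training-fold
#'   text only) or `"cohort"` (whole-cohort counting).
#' @param grid HPA sweep cutoffs (default `seq(-24, 48, by = 6)`).
#' @param sizes Population sizes for the bootstrap analysis (default
#'   `c(50, 100, 150)`; scale up for larger cohorts).
#' @param n_subgroups,boot_reps Bootstrap design parameters (20 / 1000).
#' @param seed Global integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(gen, model, test_frac = 0.10, k_folds = 5L,
                       train_cutoff_hpa = 48, max_len = 2000L, min_count = 3L,
                       vocab_scope = c("train", "cohort"),
                       grid = seq(-24, 48, by = 6),
                       sizes = c(50L, 100L, 150L),
                       n_subgroups = 20L, boot_reps = 1000L, seed) {
  stopifnot(inherits(gen, "gen_config"), inherits(model, "model_config"))
  vocab_scope <- match.arg(vocab_scope)
  if (missing(seed)) stop("run_config: `seed` is mandatory", call. = FALSE)
  structure(list(gen = gen, model = model, test_frac = test_frac,
                 k_folds = as.integer(k_folds),
                 train_cutoff_hpa = train_cutoff_hpa,
                 max_len = as.integer(max_len), min_count = as.integer(min_count),
                 vocab_scope = vocab_scope, grid = grid, sizes = as.integer(sizes),
                 n_subgroups = as.integer(n_subgroups),
                 boot_reps = as.integer(boot_reps), seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  strip <- function(x) {
    x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full experiment pipeline
#'
#' Executes every stage under `out_dir` and persists all inter-stage
#' artifacts: the three CSV tables, `split.json` (patient-level split and
#' folds), `vocab.tsv`, one model checkpoint per fold, `report.json`
#' (per-subset metrics aggregated over folds), `sweep.csv`, `size.csv`,
#' and `manifest.json` (config hash, seed, stage log). Re-invocation with
#' the same configuration skips stages whose outputs already exist under
#' the same config hash.
#'
#' @param config A [run_config()].
#' @param out_dir Run directory (created if needed).
#' @param verbose Log stage progress to stderr (default TRUE).
#' @return Invisibly, a list with the run artifacts (cohort, split,
#'   models, report, sweep, size analysis, manifest path).
#' @export
run_experiment <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    m <- jsonlite::read_json(manifest_path)
    if (identical(m$config_hash, hash)) m
    else list(config_hash = hash, seed = config$seed, stages = list())
  } else list(config_hash = hash, seed = config$seed, stages = list())

  log_stage <- function(stage, event, ...) {
    if (verbose)
      message(sprintf("[%s] %s %s", stage, event,
                      paste(sprintf("%s=%s", names(list(...)), list(...)),
                            collapse = " ")))
  }
  stage_done <- function(stage, files) {
    isTRUE(manifest$stages[[stage]]$done) && all(file.exists(files))
  }
  mark_done <- function(stage, files) {
    manifest$stages[[stage]] <<- list(done = TRUE, files = basename(files))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  ## stage: simulate -------------------------------------------------------
  tbl_files <- file.path(out_dir, c("notes.csv", "drg_assignments.csv", "catalog.csv"))
  catalog <- make_drg_catalog(config$gen)
  run_stage("simulate", {
    if (!stage_done("simulate", tbl_files)) {
      sim <- simulate_cohort(catalog, config$gen)
      write_tables(sim, catalog, out_dir)
      log_stage("simulate", "done", stays = nrow(sim$stays), notes = nrow(sim$notes))
      mark_done("simulate", tbl_files)
    } else log_stage("simulate", "skip")
  })
  tabs <- read_tables(out_dir)
  # planted n-grams live only in memory; reattach for downstream inspection
  tabs$catalog$signal_ngrams <- catalog$signal_ngrams[
    match(tabs$catalog$drg_code, catalog$drg_code)]

  ## stage: cohort + split -------------------------------------------------
  cohort <- run_stage("cohort", build_cohort(tabs$sim$stays, tabs$sim$notes,
                                             tabs$catalog, config$gen$system))
  split_path <- file.path(out_dir, "split.json")
  split_folds <- run_stage("split", {
    if (stage_done("split", split_path)) {
      sj <- jsonlite::read_json(split_path, simplifyVector = TRUE)
      list(split = structure(list(test_patient_ids = sj$test_patient_ids,
                                  train_patient_ids = sj$train_patient_ids,
                                  seed = sj$seed), class = "drg_split"),
           folds = sj$folds)
    } else {
      sp <- split_train_test(cohort, config$test_frac, seed = config$seed)
      fl <- make_cv_folds(sp$train_patient_ids, config$k_folds, seed = config$seed)
      jsonlite::write_json(list(test_patient_ids = sp$test_patient_ids,
                                train_patient_ids = sp$train_patient_ids,
                                folds = fl, seed = sp$seed),
                           split_path, auto_unbox = FALSE, pretty = TRUE)
      log_stage("split", "done", test_patients = length(sp$test_patient_ids))
      mark_done("split", split_path)
      list(split = sp, folds = fl)
    }
  })
  split <- split_folds$split; folds <- split_folds$folds

  ## stage: vocabulary ------------------------------------------------------
  vocab_path <- file.path(out_dir, "vocab.tsv")
  vocab <- run_stage("vocab", {
    if (stage_done("vocab", vocab_path)) read_vocab(vocab_path)
    else {
      vocab_stays <- if (config$vocab_scope == "train")
        cohort$stays[cohort$stays$patient_id %in% split$train_patient_ids, , drop = FALSE]
      else cohort$stays
      corpus <- tokenize_population(vocab_stays, cohort$notes, config$train_cutoff_hpa)
      v <- build_vocab(corpus, config$min_count)
      write_vocab(v, vocab_path)
      log_stage("vocab", "done", size = v$size, scope = config$vocab_scope)
      mark_done("vocab", vocab_path)
      v
    }
  })

  ## stage: train k fold models --------------------------------------------
  model_paths <- file.path(out_dir, sprintf("model_fold%d.rds", seq_len(config$k_folds)))
  st <- cohort$stays
  note_lookup <- cohort$notes
  models <- run_stage("train", {
    lapply(seq_len(config$k_folds), function(kk) {
      if (stage_done(paste0("train_fold", kk), model_paths[kk]))
        return(readRDS(model_paths[kk]))
      fs <- fold_stays(cohort, split, folds, kk)
      tr_docs <- encode_population(fs$train, note_lookup, vocab,
                                   config$train_cutoff_hpa, config$max_len)
      va_docs <- encode_population(fs$val, note_lookup, vocab,
                                   config$train_cutoff_hpa, config$max_len)
      mcfg <- config$model
      mcfg$seed <- derive_seed(config$seed, paste0("fold", kk))
      m <- train_drg_model(tr_docs, labels = fs$train$drg_code, vocab = vocab,
                           label_space = cohort$label_space, config = mcfg,
                           val_docs = va_docs, val_labels = fs$val$drg_code)
      saveRDS(m, model_paths[kk])
      log_stage("train", "fold done", fold = kk,
                best_val = sprintf("%.4f", m$best_val))
      mark_done(paste0("train_fold", kk), model_paths[kk])
      m
    })
  })

  ## stage: evaluate --------------------------------------------------------
  report_path <- file.path(out_dir, "report.json")
  tst <- test_stays(cohort, split)
  test_docs <- encode_population(tst, note_lookup, vocab,
                                 config$train_cutoff_hpa, config$max_len)
  report <- run_stage("evaluate", {
    subsets <- make_subsets(tst, cohort$catalog)
    reports <- lapply(models, function(m) {
      prob <- predict_prob_matrix(m, test_docs)
      preds <- do.call(rbind, lapply(test_docs, function(dc)
        predict(m, dc, cohort$catalog)))
      metric_report(prob, preds$pred_code, tst$drg_code, subsets)
    })
    agg <- aggregate_over_models(reports)
    jsonlite::write_json(agg, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    log_stage("evaluate", "done", subsets = nrow(agg))
    mark_done("evaluate", report_path)
    agg
  })

  ## stage: CMI analyses ----------------------------------------------------
  population <- make_test_population(cohort, split)
  sweep_path <- file.path(out_dir, "sweep.csv")
  sweep <- run_stage("cmi_sweep", {
    sw <- hpa_sweep(models, population, note_lookup, cohort$catalog,
                    grid = config$grid, max_len = config$max_len)
    data.table::fwrite(sw$summary, sweep_path)
    log_stage("cmi_sweep", "done", cutoffs = nrow(sw$summary))
    mark_done("cmi_sweep", sweep_path)
    sw
  })
  size_path <- file.path(out_dir, "size.csv")
  size_an <- run_stage("cmi_size", {
    sz <- population_size_analysis(models, population, note_lookup,
                                   cohort$catalog, sizes = config$sizes,
                                   n_subgroups = config$n_subgroups,
                                   boot_reps = config$boot_reps,
                                   seed = config$seed, max_len = config$max_len)
    data.table::fwrite(sz, size_path)
    log_stage("cmi_size", "done", rows = nrow(sz))
    mark_done("cmi_size", size_path)
    sz
  })

  invisible(list(catalog = tabs$catalog, cohort = cohort, split = split,
                 folds = folds, vocab = vocab, models = models,
                 report = report, sweep = sweep, size_analysis = size_an,
                 population = population, manifest = manifest_path,
                 out_dir = out_dir))
}
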