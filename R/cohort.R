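#' Build an analysis cohort by applying eligibility filters
#'
#' Retains exactly the stays that satisfy the study's inclusion rules:
#' adult patients (age strictly greater than 18 by default), a single ICU
#' visit, at least one clinical note charted at or before 48 hours
#' post-admission (HPA), and a DRG code present in the system's catalog.
#' The label space is the full catalog code list for the system in stable
#' lexicographic order — deliberately larger than the set of codes observed
#' in the cohort, mirroring how payment systems define more targets than
#' any one hospital observes.
#'
#' @param stays data.frame of stay records (`stay_id`, `patient_id`, `age`,
#'   `n_icu_visits`, `drg_system`, `drg_code`, optionally `true_weight`).
#' @param notes data.frame of note events (`stay_id`, `chart_hpa`, `text`, ...).
#' @param catalog A `drg_catalog` covering the target system.
#' @param system `"MS_LIKE"` or `"APR_LIKE"`.
#' @param adult_inclusive If `TRUE`, use age >= 18 instead of the default
#'   strict age > 18.
#' @param hpa_window Upper chart-time bound in hours for the note filter
#'   (default 48).
#' @return A `drg_cohort`: list with filtered `stays`, their `notes`
#'   (restricted to the HPA window), `catalog`, `system`, and `label_space`.
#' @export
build_cohort <- function(stays, notes, catalog, system,
                         adult_inclusive = FALSE, hpa_window = 48) {
  stopifnot(is.data.frame(stays), is.data.frame(notes))
  cat_sys <- catalog[catalog$drg_system == system, , drop = FALSE]
  if (nrow(cat_sys) == 0L)
    stop("build_cohort: catalog has no codes for system ", system, call. = FALSE)
  label_space <- sort(cat_sys$drg_code)

  noted <- unique(notes$stay_id[notes$chart_hpa <= hpa_window])
  age_ok <- if (adult_inclusive) stays$age >= 18 else stays$age > 18
  keep <- stays$drg_system == system &
    age_ok &
    stays$n_icu_visits == 1L &
    stays$stay_id %in% noted &
    stays$drg_code %in% label_space
  kept <- stays[keep, , drop = FALSE]
  if (nrow(kept) == 0L)
    stop("build_cohort: no eligible stays after filtering", call. = FALSE)
  if (is.null(kept$true_weight)) {
    wmap <- stats::setNames(cat_sys$weight, cat_sys$drg_code)
    kept$true_weight <- unname(wmap[kept$drg_code])
  }
  rownames(kept) <- NULL
  kept_notes <- notes[notes$stay_id %in% kept$stay_id &
                        notes$chart_hpa <= hpa_window, , drop = FALSE]
  rownames(kept_notes) <- NULL
  structure(list(stays = kept, notes = kept_notes, catalog = cat_sys,
                 system = system, label_space = label_space),
            class = "drg_cohort")
}

#' Split a cohort into hold-out test patients and training patients
#'
#' The split is by patient, never by admission: a patient's stays all land
#' on the same side, preventing leakage of a patient's notes between
#' training and testing. Patients are assigned to the test side in a
#' shuffled order until test stays reach `test_frac` of all stays
#' (stay-count-weighted greedy rule).
#'
#' @param cohort A `drg_cohort`.
#' @param test_frac Target fraction of stays held out (default 0.10).
#' @param seed Integer seed for the patient shuffle.
#' @return A `drg_split`: list with `test_patient_ids`,
#'   `train_patient_ids`, and the `seed`.
#' @export
split_train_test <- function(cohort, test_frac = 0.10, seed) {
  stopifnot(inherits(cohort, "drg_cohort"))
  if (test_frac <= 0 || test_frac >= 1)
    stop("split_train_test: test_frac must be in (0, 1)", call. = FALSE)
  counts <- table(cohort$stays$patient_id)
  patients <- names(counts)
  if (length(patients) < 2L)
    stop("split_train_test: need at least two patients to split", call. = FALSE)
  total <- sum(counts)
  with_seed(derive_seed(seed, "split"), {
    ord <- sample(patients)
    cum <- cumsum(as.integer(counts[ord]))
    n_test <- which(cum >= test_frac * total)[1]
    test_ids <- sort(ord[seq_len(n_test)])
    train_ids <- sort(setdiff(patients, test_ids))
    structure(list(test_patient_ids = test_ids,
                   train_patient_ids = train_ids,
                   seed = as.integer(seed)),
              class = "drg_split")
  })
}

#' Partition training patients into cross-validation folds
#'
#' @param train_patients Character vector of training patient ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` disjoint character vectors whose union is
#'   `train_patients`, with sizes differing by at most one.
#' @export
make_cv_folds <- function(train_patients, k = 5L, seed) {
  if (k < 2L) stop("make_cv_folds: k must be >= 2", call. = FALSE)
  n <- length(train_patients)
  if (n < k) stop("make_cv_folds: need at least k patients", call. = FALSE)
  with_seed(derive_seed(seed, "folds"), {
    ord <- sample(train_patients)
    # round-robin over the shuffled order: fold sizes differ by at most one
    folds <- split(ord, rep_len(seq_len(k), n))
    lapply(unname(folds), sort)
  })
}

#' Form the test population: one stay per test patient
#'
#' For population-level cost estimation only the first hospital visit of
#' each test patient is kept. Admission order is the stay-id order, which
#' the synthetic generator assigns chronologically.
#'
#' @param cohort A `drg_cohort`.
#' @param split A `drg_split` built for this cohort.
#' @return data.frame of stays, one row per test patient.
#' @export
make_test_population <- function(cohort, split) {
  stopifnot(inherits(cohort, "drg_cohort"), inherits(split, "drg_split"))
  test_stays <- cohort$stays[cohort$stays$patient_id %in% split$test_patient_ids, ,
                             drop = FALSE]
  test_stays <- test_stays[order(test_stays$patient_id, test_stays$stay_id), ,
                           drop = FALSE]
  first <- !duplicated(test_stays$patient_id)
  out <- test_stays[first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stays belonging to the test set (all admissions of test patients)
#'
#' @param cohort A `drg_cohort`.
#' @param split A `drg_split`.
#' @return data.frame of test stays.
#' @export
test_stays <- function(cohort, split) {
  out <- cohort$stays[cohort$stays$patient_id %in% split$test_patient_ids, ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stays belonging to a training fold arrangement
#'
#' Returns the stays of training patients, excluding (for validation) or
#' restricted to one held-out fold.
#'
#' @param cohort A `drg_cohort`.
#' @param split A `drg_split`.
#' @param folds Folds from [make_cv_folds()].
#' @param fold Index of the fold to hold out as validation.
#' @return list with `train` and `val` stay data.frames.
#' @export
fold_stays <- function(cohort, split, folds, fold) {
  stopifnot(fold >= 1L, fold <= length(folds))
  val_ids <- folds[[fold]]
  train_ids <- setdiff(split$train_patient_ids, val_ids)
  st <- cohort$stays
  list(train = st[st$patient_id %in% train_ids, , drop = FALSE],
       val = st[st$patient_id %in% val_ids, , drop = FALSE])
}
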