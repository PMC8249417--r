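#' Configuration for the synthetic DRG cohort generator
#'
#' Bundles every knob of the generator: catalog size and system, the Zipf
#' exponent governing DRG rank-frequency, the lognormal relative-weight
#' targets, note-arrival and note-length rates, the linear accrual rate of
#' planted diagnostic n-grams over hours post-admission (HPA), and the
#' fractions of stays that exercise the downstream cohort filters
#' (under-18 patients, multi-ICU-visit stays, repeat patients).
#'
#' @param n_patients Number of synthetic patients.
#' @param n_drg_groups Number of base DRG groups in the catalog (APR-like
#'   systems expand each group into 4 severity tiers).
#' @param system `"MS_LIKE"` (flat codes) or `"APR_LIKE"` (group x severity).
#' @param zipf_exponent Exponent of the Zipf rank-frequency law used to
#'   sample DRG assignments; larger values concentrate mass on few codes.
#' @param weight_mean,weight_sd Target mean and SD of the relative-weight
#'   distribution (lognormal, clipped below at 0.2).
#' @param background_vocab_size Number of distinct non-signal tokens.
#' @param signal_rate_slope Per-hour increase of the probability that a note
#'   token position emits one of the stay's DRG signal n-grams; the
#'   probability is `clamp(signal_rate_slope * (chart_hpa + 24), 0, 0.5)`,
#'   i.e. zero one day before ICU admission and growing linearly after.
#' @param note_rate Expected number of notes per 6-hour interval (Poisson).
#' @param note_len_mean Mean note length in tokens (Poisson, floored at 5).
#' @param signal_ngram_len Tokens per planted signal n-gram.
#' @param frac_under18 Fraction of patients younger than 18 years.
#' @param frac_multi_icu Fraction of stays with more than one ICU visit.
#' @param frac_repeat_patients Fraction of patients with a second stay.
#' @param deid_placeholder_rate Per-token rate of inserted de-identification
#'   placeholders of the form `[** ... **]`.
#' @param seed Mandatory integer seed; every generator draw derives from it.
#' @return An object of class `gen_config` (a validated list).
#' @export
gen_config <- function(n_patients = 1000L,
                       n_drg_groups = 50L,
                       system = c("MS_LIKE", "APR_LIKE"),
                       zipf_exponent = 1.2,
                       weight_mean = 3.0,
                       weight_sd = 2.8,
                       background_vocab_size = 2000L,
                       signal_rate_slope = 0.002,
                       note_rate = 1.0,
                       note_len_mean = 30L,
                       signal_ngram_len = 3L,
                       frac_under18 = 0.05,
                       frac_multi_icu = 0.05,
                       frac_repeat_patients = 0.10,
                       deid_placeholder_rate = 0.02,
                       seed) {
  system <- match.arg(system)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("gen_config: a single finite `seed` is mandatory", call. = FALSE)
  if (!is.numeric(n_drg_groups) || n_drg_groups < 2)
    stop("gen_config: `n_drg_groups` must be >= 2", call. = FALSE)
  if (n_patients < 1) stop("gen_config: `n_patients` must be >= 1", call. = FALSE)
  fracs <- c(frac_under18 = frac_under18, frac_multi_icu = frac_multi_icu,
             frac_repeat_patients = frac_repeat_patients,
             deid_placeholder_rate = deid_placeholder_rate)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("gen_config: rates must lie in [0, 1]: ",
         paste(names(fracs)[bad], collapse = ", "), call. = FALSE)
  if (weight_mean <= 0 || weight_sd <= 0)
    stop("gen_config: weight targets must be positive", call. = FALSE)
  if (signal_rate_slope < 0) stop("gen_config: `signal_rate_slope` must be >= 0", call. = FALSE)
  structure(list(
    n_patients = as.integer(n_patients),
    n_drg_groups = as.integer(n_drg_groups),
    system = system,
    zipf_exponent = zipf_exponent,
    weight_mean = weight_mean,
    weight_sd = weight_sd,
    background_vocab_size = as.integer(background_vocab_size),
    signal_rate_slope = signal_rate_slope,
    note_rate = note_rate,
    note_len_mean = note_len_mean,
    signal_ngram_len = as.integer(signal_ngram_len),
    frac_under18 = frac_under18,
    frac_multi_icu = frac_multi_icu,
    frac_repeat_patients = frac_repeat_patients,
    deid_placeholder_rate = deid_placeholder_rate,
    seed = as.integer(seed)
  ), class = "gen_config")
}

# Lognormal parameters matching a target arithmetic mean and SD.
lognormal_params <- function(m, s) {
  cv2 <- (s / m)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(m) - sdlog^2 / 2
  list(meanlog = meanlog, sdlog = sdlog)
}

# APR-style severity multipliers: mean 1 so the catalog-level weight mean is
# preserved under the 4-way severity expansion.
.apr_sev_mult <- c(0.55, 0.80, 1.15, 1.50)

#' Generate a synthetic DRG catalog
#'
#' Builds the target code space: flat codes for an MS-like system, or
#' 4 severity tiers per clinical group for an APR-like system with weight
#' strictly increasing in severity. Relative weights are lognormal draws
#' calibrated to the configured mean/SD and clipped below at 0.2. Each base
#' group receives planted signal n-grams (unique to the group) that the
#' cohort simulator will emit into note text; APR-like codes append a
#' severity marker token so severity tiers are distinguishable.
#'
#' @param config A [gen_config()].
#' @return A `drg_catalog`: a data.frame with columns `drg_code`,
#'   `drg_system`, `mdc`, `severity`, `weight`, `description` and a
#'   list-column `signal_ngrams` (character vectors of space-joined n-grams).
#' @export
make_drg_catalog <- function(config) {
  stopifnot(inherits(config, "gen_config"))
  n_groups <- config$n_drg_groups
  with_seed(derive_seed(config$seed, "catalog"), {
    lp <- lognormal_params(config$weight_mean, config$weight_sd)
    mdc_pool <- c("05", "01", "04", "06", "08", "18")
    mdc_prob <- c(0.26, 0.16, 0.12, 0.16, 0.15, 0.15)
    group_mdc <- sample(mdc_pool, n_groups, replace = TRUE, prob = mdc_prob)
    group_w <- pmax(0.2, stats::rlnorm(n_groups, lp$meanlog, lp$sdlog))

    len <- config$signal_ngram_len
    group_ngrams <- lapply(seq_len(n_groups), function(g) {
      vapply(1:2, function(k) {
        paste(sprintf("sig%03dt%d", g, (k - 1L) * len + seq_len(len)),
              collapse = " ")
      }, character(1))
    })

    if (config$system == "MS_LIKE") {
      cat_df <- data.frame(
        drg_code = sprintf("D%03d", seq_len(n_groups)),
        drg_system = "MS_LIKE",
        mdc = group_mdc,
        severity = NA_integer_,
        weight = group_w,
        description = sprintf("Synthetic condition group %03d", seq_len(n_groups)),
        stringsAsFactors = FALSE
      )
      cat_df$signal_ngrams <- group_ngrams
    } else {
      rows <- vector("list", n_groups)
      for (g in seq_len(n_groups)) {
        mult <- sort(.apr_sev_mult * exp(stats::rnorm(4, 0, 0.05)))
        w <- pmax(0.2, group_w[g] * mult)
        # enforce strict increase after the 0.2 floor
        for (s in 2:4) if (w[s] <= w[s - 1]) w[s] <- w[s - 1] * 1.05
        rows[[g]] <- data.frame(
          drg_code = sprintf("G%03d-%d", g, 1:4),
          drg_system = "APR_LIKE",
          mdc = group_mdc[g],
          severity = 1:4,
          weight = w,
          description = sprintf("Synthetic condition group %03d severity %d", g, 1:4),
          stringsAsFactors = FALSE
        )
      }
      cat_df <- do.call(rbind, rows)
      cat_df$signal_ngrams <- lapply(seq_len(nrow(cat_df)), function(i) {
        g <- (i - 1L) %/% 4L + 1L
        s <- cat_df$severity[i]
        paste(group_ngrams[[g]], sprintf("sev%d", s))
      })
    }
    rownames(cat_df) <- NULL
    class(cat_df) <- c("drg_catalog", "data.frame")
    validate_catalog(cat_df)
    cat_df
  })
}

#' Validate a DRG catalog's structural invariants
#'
#' Checks code uniqueness within a system, positivity of weights, the
#' 4-severity-per-group structure with strictly increasing weights for
#' APR-like entries, and (when planted n-grams are present) that every code
#' carries at least one signal n-gram unique to its base group.
#'
#' @param catalog A `drg_catalog`.
#' @return The catalog, invisibly; errors on violation.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  need <- c("drg_code", "drg_system", "mdc", "weight")
  if (!all(need %in% names(catalog)))
    stop("catalog missing columns: ", paste(setdiff(need, names(catalog)), collapse = ", "))
  if (anyDuplicated(catalog[c("drg_code", "drg_system")]))
    stop("catalog codes must be unique within a system")
  if (any(catalog$weight <= 0)) stop("catalog weights must all be positive")
  apr <- catalog[catalog$drg_system == "APR_LIKE", , drop = FALSE]
  if (nrow(apr)) {
    base <- sub("-[0-9]+$", "", apr$drg_code)
    for (b in unique(base)) {
      sub_df <- apr[base == b, , drop = FALSE]
      if (nrow(sub_df) != 4L || !setequal(sub_df$severity, 1:4))
        stop("APR-like group ", b, " must have exactly 4 severity entries")
      w <- sub_df$weight[order(sub_df$severity)]
      if (any(diff(w) <= 0))
        stop("APR-like group ", b, " weights must strictly increase with severity")
    }
  }
  if (!is.null(catalog$signal_ngrams)) {
    if (any(lengths(catalog$signal_ngrams) < 1L))
      stop("every code needs at least one signal n-gram")
    grp <- base_group(catalog$drg_code, catalog$drg_system)
    seen <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(catalog))) {
      for (ng in catalog$signal_ngrams[[i]]) {
        prev <- seen[[ng]]
        if (!is.null(prev) && prev != grp[i])
          stop("signal n-gram '", ng, "' shared across base groups")
        seen[[ng]] <- grp[i]
      }
    }
  }
  invisible(catalog)
}

# Base clinical group of a code: APR-like codes strip the severity suffix.
base_group <- function(code, system) {
  ifelse(system == "APR_LIKE", sub("-[0-9]+$", "", code), code)
}

# Per-token probability of emitting a signal n-gram at a given chart time.
signal_prob <- function(hpa, slope) clamp(slope * (hpa + 24), 0, 0.5)

.deid_stems <- c("Name", "Hospital", "Date", "Location", "MD Number", "Telephone")

#' Simulate a cohort of hospital stays with timestamped notes
#'
#' Samples patients and stays, assigns each stay a DRG by Zipf
#' rank-frequency over base groups, and places notes at chart times drawn in
#' \[-24, 48\] hours around ICU admission (Poisson counts per 6-h interval).
#' Note text mixes Zipf-distributed background tokens with the stay's DRG
#' signal n-grams, whose per-position emission probability grows linearly
#' with chart time (see [gen_config()]), plus de-identification placeholders
#' and sporadic upper-casing to exercise the text cleanup step. Configured
#' fractions of under-18 patients, multi-ICU-visit stays, and repeat
#' patients are realized in expectation.
#'
#' @param catalog A `drg_catalog` from [make_drg_catalog()].
#' @param config The same [gen_config()] used for the catalog.
#' @return A `drg_simulation`: list with data.frames `stays` (stay_id,
#'   patient_id, age, n_icu_visits, drg_system, drg_code, true_weight) and
#'   `notes` (stay_id, patient_id, chart_hpa, category, text). Stay ids are
#'   assigned in admission order, so per-patient lexicographic stay_id order
#'   is chronological.
#' @export
simulate_cohort <- function(catalog, config) {
  stopifnot(inherits(config, "gen_config"))
  if (!is.data.frame(catalog) || nrow(catalog) == 0L)
    stop("simulate_cohort: catalog is empty", call. = FALSE)
  with_seed(derive_seed(config$seed, "cohort"), {
    np <- config$n_patients
    patient_id <- sprintf("P%05d", seq_len(np))
    under18 <- stats::rbinom(np, 1L, config$frac_under18) == 1L
    age <- ifelse(under18,
                  sample(1:17, np, replace = TRUE),
                  pmin(95L, pmax(19L, round(stats::rnorm(np, 65, 15)))))
    n_stays <- 1L + stats::rbinom(np, 1L, config$frac_repeat_patients)

    grp_codes <- unique(base_group(catalog$drg_code, catalog$drg_system))
    n_groups <- length(grp_codes)
    zipf_p <- seq_len(n_groups)^(-config$zipf_exponent)
    zipf_p <- zipf_p / sum(zipf_p)
    is_apr <- catalog$drg_system[1] == "APR_LIKE"
    sev_p <- c(0.35, 0.30, 0.20, 0.15)

    total_stays <- sum(n_stays)
    stay_patient <- rep(patient_id, n_stays)
    stay_age <- rep(age, n_stays)
    stay_id <- sprintf("S%06d", seq_len(total_stays))
    n_icu <- 1L + stats::rbinom(total_stays, 1L, config$frac_multi_icu) *
      sample(1:2, total_stays, replace = TRUE)
    grp_idx <- sample.int(n_groups, total_stays, replace = TRUE, prob = zipf_p)
    if (is_apr) {
      sev <- sample.int(4L, total_stays, replace = TRUE, prob = sev_p)
      drg_code <- sprintf("%s-%d", grp_codes[grp_idx], sev)
    } else {
      drg_code <- grp_codes[grp_idx]
    }
    wmap <- stats::setNames(catalog$weight, catalog$drg_code)
    ngram_map <- stats::setNames(catalog$signal_ngrams, catalog$drg_code)

    stays <- data.frame(
      stay_id = stay_id, patient_id = stay_patient, age = stay_age,
      n_icu_visits = n_icu, drg_system = catalog$drg_system[1],
      drg_code = drg_code, true_weight = unname(wmap[drg_code]),
      stringsAsFactors = FALSE
    )

    bg_vocab <- sprintf("w%04d", seq_len(config$background_vocab_size))
    bg_p <- seq_along(bg_vocab)^(-1)
    bg_p <- bg_p / sum(bg_p)
    categories <- c("nursing", "physician", "radiology", "other")
    bins <- seq(-24, 42, by = 6)

    note_rows <- vector("list", total_stays)
    for (i in seq_len(total_stays)) {
      counts <- stats::rpois(length(bins), config$note_rate)
      n_notes <- sum(counts)
      if (n_notes == 0L) { note_rows[[i]] <- NULL; next }
      hpa <- rep(bins, counts) + stats::runif(n_notes, 0, 6)
      sig_ngrams <- ngram_map[[stays$drg_code[i]]]
      texts <- character(n_notes)
      for (j in seq_len(n_notes)) {
        L <- max(5L, stats::rpois(1L, config$note_len_mean))
        toks <- sample(bg_vocab, L, replace = TRUE, prob = bg_p)
        upper <- stats::runif(L) < 0.1
        toks[upper] <- toupper(toks[upper])
        p_sig <- signal_prob(hpa[j], config$signal_rate_slope)
        emit <- stats::runif(L) < p_sig
        if (any(emit))
          toks[emit] <- sample(sig_ngrams, sum(emit), replace = TRUE)
        n_deid <- stats::rbinom(1L, L, config$deid_placeholder_rate)
        if (n_deid > 0L) {
          at <- sample.int(L, n_deid)
          toks[at] <- paste0(toks[at], " [**", sample(.deid_stems, n_deid, replace = TRUE),
                             " ", sample(1000:9999, n_deid, replace = TRUE), "**]")
        }
        texts[j] <- paste(toks, collapse = " ")
      }
      note_rows[[i]] <- data.frame(
        stay_id = stays$stay_id[i], patient_id = stays$patient_id[i],
        chart_hpa = round(hpa, 3),
        category = sample(categories, n_notes, replace = TRUE,
                          prob = c(0.45, 0.25, 0.15, 0.15)),
        text = texts, stringsAsFactors = FALSE
      )
    }
    notes <- do.call(rbind, note_rows[!vapply(note_rows, is.null, logical(1))])
    if (is.null(notes))
      notes <- data.frame(stay_id = character(), patient_id = character(),
                          chart_hpa = numeric(), category = character(),
                          text = character(), stringsAsFactors = FALSE)
    rownames(notes) <- NULL
    structure(list(stays = stays, notes = notes), class = "drg_simulation")
  })
}

#' Write simulation tables to CSV
#'
#' Emits the three RFC-4180 CSV tables consumed by the readers:
#' `notes.csv`, `drg_assignments.csv`, and `catalog.csv`. Planted signal
#' n-grams are an in-memory attribute of the catalog and are not part of
#' the on-disk schema.
#'
#' @param sim A `drg_simulation`.
#' @param catalog The `drg_catalog` the simulation was drawn from.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_tables <- function(sim, catalog, out_dir) {
  stopifnot(inherits(sim, "drg_simulation"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(notes = file.path(out_dir, "notes.csv"),
             drg_assignments = file.path(out_dir, "drg_assignments.csv"),
             catalog = file.path(out_dir, "catalog.csv"))
  assign_df <- sim$stays[c("stay_id", "patient_id", "age", "n_icu_visits",
                           "drg_system", "drg_code")]
  cat_df <- as.data.frame(catalog)[c("drg_code", "drg_system", "mdc",
                                     "severity", "weight", "description")]
  for (job in list(list(paths[["notes"]], sim$notes),
                   list(paths[["drg_assignments"]], assign_df),
                   list(paths[["catalog"]], cat_df))) {
    ok <- try(data.table::fwrite(job[[2]], job[[1]], quote = TRUE), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("write_tables: failed to write ", job[[1]], call. = FALSE)
  }
  invisible(paths)
}

#' Read simulation tables back from CSV
#'
#' Inverse of [write_tables()]. The returned catalog carries no planted
#' n-grams (they are generator metadata, not on-disk schema); stays'
#' `true_weight` is re-derived by joining the catalog.
#'
#' @param dir Directory containing `notes.csv`, `drg_assignments.csv`,
#'   `catalog.csv`.
#' @return A list with `sim` (a `drg_simulation`) and `catalog`.
#' @export
read_tables <- function(dir) {
  paths <- file.path(dir, c("notes.csv", "drg_assignments.csv", "catalog.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("read_tables: missing file(s): ", paste(missing, collapse = ", "), call. = FALSE)
  notes <- as.data.frame(data.table::fread(paths[1], colClasses = list(
    character = c("stay_id", "patient_id", "category", "text"))))
  assigns <- as.data.frame(data.table::fread(paths[2], colClasses = list(
    character = c("stay_id", "patient_id", "drg_system", "drg_code"))))
  cat_df <- as.data.frame(data.table::fread(paths[3], colClasses = list(
    character = c("drg_code", "drg_system", "mdc", "description"))))
  class(cat_df) <- c("drg_catalog", "data.frame")
  wmap <- stats::setNames(cat_df$weight, paste(cat_df$drg_code, cat_df$drg_system))
  assigns$true_weight <- unname(wmap[paste(assigns$drg_code, assigns$drg_system)])
  sim <- structure(list(stays = assigns, notes = notes), class = "drg_simulation")
  list(sim = sim, catalog = cat_df)
}
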