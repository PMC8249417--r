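#' Case-mix index of a patient group
#'
#' The CMI is the arithmetic mean of the DRG relative weights of the
#' group's stays — the standard hospital-level cost-complexity indicator.
#'
#' @param weights Non-empty numeric vector of positive DRG weights.
#' @return The mean weight.
#' @export
compute_cmi <- function(weights) {
  if (length(weights) == 0L)
    stop("compute_cmi: empty weight list", call. = FALSE)
  if (any(!is.finite(weights) | weights <= 0))
    stop("compute_cmi: weights must be positive and finite", call. = FALSE)
  mean(weights)
}

#' Absolute relative CMI error
#'
#' @param predicted_cmi Predicted case-mix index.
#' @param true_cmi True case-mix index (must be positive).
#' @return `|predicted - true| / true`.
#' @export
cmi_error <- function(predicted_cmi, true_cmi) {
  if (!is.finite(true_cmi) || true_cmi <= 0)
    stop("cmi_error: true CMI must be positive", call. = FALSE)
  abs(predicted_cmi - true_cmi) / true_cmi
}

#' DRG-based payment projection
#'
#' Approximates total prospective payment as base rate x CMI x number of
#' stays, the product form under which a relative CMI error of e shifts
#' the projection by exactly `base_rate * n_stays * cmi * e` dollars.
#'
#' @param cmi Case-mix index (> 0).
#' @param n_stays Number of stays (>= 1).
#' @param base_rate Dollar amount per unit weight (default 6000).
#' @return Projected payment in dollars.
#' @export
estimate_payment <- function(cmi, n_stays, base_rate = 6000) {
  if (!is.finite(cmi) || cmi <= 0)
    stop("estimate_payment: cmi must be positive", call. = FALSE)
  if (n_stays < 1) stop("estimate_payment: n_stays must be >= 1", call. = FALSE)
  if (base_rate <= 0) stop("estimate_payment: base_rate must be positive", call. = FALSE)
  base_rate * cmi * n_stays
}

#' CMI error across admission-time cutoffs
#'
#' For every cutoff on the grid and every model, re-assembles and
#' re-encodes the population's documents at that cutoff, predicts DRG
#' weights, and compares the predicted CMI with the true CMI. Stays with
#' no note inside a window are predicted from an all-padding input rather
#' than dropped, so the population is fixed across the whole sweep.
#'
#' @param models List of trained `drg_model`s (typically the five
#'   cross-validation fold models) or [oracle_model()]s.
#' @param population data.frame of stays (one per patient), with
#'   `true_weight`.
#' @param notes data.frame of the population's notes.
#' @param catalog A `drg_catalog`.
#' @param grid Numeric cutoffs in hours (default `seq(-24, 48, by = 6)`).
#' @param max_len Encoded sequence length (default 2000).
#' @return List with `detail` (one row per cutoff x model: predicted and
#'   true CMI, absolute relative error) and `summary` (per-cutoff mean
#'   and SD of the error over models).
#' @export
hpa_sweep <- function(models, population, notes, catalog,
                      grid = seq(-24, 48, by = 6), max_len = 2000L) {
  if (nrow(population) == 0L)
    stop("hpa_sweep: empty population", call. = FALSE)
  if (inherits(models, "drg_model") || inherits(models, "drg_oracle_model"))
    models <- list(models)
  true_cmi <- compute_cmi(population$true_weight)
  detail <- list()
  for (m in seq_along(models)) {
    for (cutoff in grid) {
      preds <- predict_stays(models[[m]], population, notes, catalog,
                             cutoff_hpa = cutoff, max_len = max_len)
      pcmi <- compute_cmi(preds$pred_weight)
      detail[[length(detail) + 1L]] <- data.frame(
        cutoff_hpa = cutoff, model = m, n_stays = nrow(population),
        predicted_cmi = pcmi, true_cmi = true_cmi,
        abs_rel_error = cmi_error(pcmi, true_cmi))
    }
  }
  detail <- do.call(rbind, detail)
  summary <- do.call(rbind, lapply(split(detail, detail$cutoff_hpa), function(d)
    data.frame(cutoff_hpa = d$cutoff_hpa[1], n_models = nrow(d),
               mean_error = mean(d$abs_rel_error),
               sd_error = if (nrow(d) > 1L) stats::sd(d$abs_rel_error) else NA_real_,
               mean_predicted_cmi = mean(d$predicted_cmi),
               true_cmi = d$true_cmi[1])))
  summary <- summary[order(summary$cutoff_hpa), ]
  rownames(summary) <- NULL
  list(detail = detail, summary = summary)
}

#' CMI error across population sizes, with bootstrap confidence intervals
#'
#' For each population size, draws `n_subgroups` subgroups with
#' replacement from the population and applies each model, giving
#' `n_subgroups * length(models)` subpopulation estimates (20 x 5 = 100
#' under the defaults). Reports, per size and cutoff: the mean absolute
#' relative CMI error with a percentile-bootstrap 95% CI of that mean,
#' and the mean predicted CMI with the 2.5/97.5 percentiles of the
#' subpopulation CMIs.
#'
#' @param models List of trained models (or oracles).
#' @param population data.frame of stays (one per patient).
#' @param notes data.frame of their notes.
#' @param catalog A `drg_catalog`.
#' @param sizes Integer vector of subpopulation sizes.
#' @param n_subgroups Subgroups per model and size (default 20).
#' @param boot_reps Bootstrap replicates for the CI of the mean error
#'   (default 1000).
#' @param seed Integer seed for subgroup sampling and the bootstrap.
#' @param cutoffs Cutoffs in hours at which predictions are made
#'   (default `c(24, 48)`).
#' @param max_len Encoded sequence length.
#' @return data.frame with one row per (cutoff, size); the raw
#'   subpopulation errors and bootstrap means are attached as attribute
#'   `"raw"` (a list keyed by `"<cutoff>_<size>"`).
#' @export
population_size_analysis <- function(models, population, notes, catalog, sizes,
                                     n_subgroups = 20L, boot_reps = 1000L, seed,
                                     cutoffs = c(24, 48), max_len = 2000L) {
  if (nrow(population) == 0L)
    stop("population_size_analysis: empty population", call. = FALSE)
  if (any(sizes < 1))
    stop("population_size_analysis: sizes must be positive", call. = FALSE)
  if (inherits(models, "drg_model") || inherits(models, "drg_oracle_model"))
    models <- list(models)
  n <- nrow(population)
  true_w <- population$true_weight
  out <- list()
  raw <- list()
  with_seed(derive_seed(seed, "popsize"), {
    for (cutoff in cutoffs) {
      pred_w <- lapply(models, function(m)
        predict_stays(m, population, notes, catalog, cutoff_hpa = cutoff,
                      max_len = max_len)$pred_weight)
      for (size in sizes) {
        errs <- numeric(0); cmis <- numeric(0)
        for (m in seq_along(models)) {
          for (g in seq_len(n_subgroups)) {
            idx <- sample.int(n, size, replace = TRUE)
            pc <- mean(pred_w[[m]][idx])
            tc <- mean(true_w[idx])
            errs <- c(errs, cmi_error(pc, tc))
            cmis <- c(cmis, pc)
          }
        }
        boot_means <- vapply(seq_len(boot_reps), function(b)
          mean(errs[sample.int(length(errs), replace = TRUE)]), numeric(1))
        ci <- stats::quantile(boot_means, c(0.025, 0.975), names = FALSE)
        cmi_ci <- stats::quantile(cmis, c(0.025, 0.975), names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          cutoff_hpa = cutoff, size = size, n_estimates = length(errs),
          mean_error = mean(errs), ci_low = ci[1], ci_high = ci[2],
          mean_predicted_cmi = mean(cmis),
          cmi_ci_low = cmi_ci[1], cmi_ci_high = cmi_ci[2],
          true_cmi = mean(true_w))
        raw[[sprintf("%g_%d", cutoff, size)]] <-
          list(errors = errs, boot_means = boot_means)
      }
    }
  })
  res <- do.call(rbind, out)
  attr(res, "raw") <- raw
  res
}
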