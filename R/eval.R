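# Rank-based AUC of scores against a binary indicator, with midrank tie
# handling (equals the pairwise concordance count with ties scored 0.5).
rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro- and micro-averaged one-vs-rest AUC
#'
#' Evaluation is restricted to the stays whose true label belongs to the
#' subset. Per-label AUC is the probability that a random positive stay
#' outranks a random negative one (ties count one half). The macro score
#' is the unweighted mean over subset labels with at least one positive
#' and one negative stay; labels without a positive case are dropped (the
#' count is reported as an attribute). The micro score pools the
#' (stay, label) one-vs-rest indicators of all subset labels into a
#' single ranking. When no subset label has both a positive and a negative
#' stay (e.g. a single-code subset), the corresponding score is `NA`.
#'
#' @param prob Matrix of predicted probabilities (stays x labels), with
#'   label codes as column names; rows sum to 1.
#' @param truth Character vector of true codes, one per row of `prob`.
#' @param subset Character vector of label codes to evaluate (default:
#'   all columns).
#' @return Named numeric vector `c(macro_auc, micro_auc)` with attribute
#'   `n_dropped` (labels excluded from the macro mean).
#' @export
auc_scores <- function(prob, truth, subset = colnames(prob)) {
  stopifnot(is.matrix(prob), !is.null(colnames(prob)),
            nrow(prob) == length(truth))
  subset <- intersect(subset, colnames(prob))
  rows <- truth %in% subset
  if (!any(rows))
    stop("auc_scores: no test stay has a true label in the subset", call. = FALSE)
  P <- prob[rows, , drop = FALSE]; y <- truth[rows]
  per_label <- vapply(subset, function(l) rank_auc(P[, l], y == l), numeric(1))
  usable <- !is.na(per_label)
  pooled_scores <- as.vector(P[, subset, drop = FALSE])
  pooled_truth <- as.vector(outer(y, subset, "=="))
  # a subset whose restricted stays are all one label has no defined AUC
  out <- c(macro_auc = if (any(usable)) mean(per_label[usable]) else NA_real_,
           micro_auc = rank_auc(pooled_scores, pooled_truth))
  attr(out, "n_dropped") <- sum(!usable)
  out
}

#' Macro- and micro-averaged F1
#'
#' Restricted to stays whose true label is in the subset. Per-label F1 is
#' `2TP / (2TP + FP + FN)`, defined as 0 when a label has neither
#' predictions nor positives; the macro mean runs over every subset label,
#' including those zero-F1 absent labels. The micro score pools TP/FP/FN
#' over subset labels — with single-label predictions over the full label
#' space it reduces to plain accuracy.
#'
#' @param pred Character vector of predicted codes.
#' @param truth Character vector of true codes.
#' @param subset Character vector of label codes (default: all codes seen
#'   in `truth` or `pred`).
#' @return Named numeric vector `c(macro_f1, micro_f1)`.
#' @export
f1_scores <- function(pred, truth, subset = sort(unique(c(truth, pred)))) {
  stopifnot(length(pred) == length(truth))
  rows <- truth %in% subset
  p <- pred[rows]; y <- truth[rows]
  tp <- vapply(subset, function(l) sum(p == l & y == l), numeric(1))
  fp <- vapply(subset, function(l) sum(p == l & y != l), numeric(1))
  fn <- vapply(subset, function(l) sum(p != l & y == l), numeric(1))
  denom <- 2 * tp + fp + fn
  f1 <- ifelse(denom == 0, 0, 2 * tp / denom)
  micro_denom <- 2 * sum(tp) + sum(fp) + sum(fn)
  c(macro_f1 = mean(f1),
    micro_f1 = if (micro_denom == 0) 0 else 2 * sum(tp) / micro_denom)
}

#' Define evaluation subsets over the test stays
#'
#' Produces the DRG-code subsets used to slice model performance: all
#' codes; the codes of each major diagnostic category (MDC) present in
#' the catalog; the smallest prefix of the frequency-ranked code list
#' covering at least 80% of test stays; and the top 30 and top 50 codes
#' by test-set frequency. Ties at a frequency boundary are broken by code
#' order.
#'
#' @param stays data.frame of test stays (`drg_code`).
#' @param catalog A `drg_catalog` mapping codes to MDC.
#' @param top_k Integer vector of top-k sizes (default `c(30, 50)`).
#' @return Named list of character vectors of codes.
#' @export
make_subsets <- function(stays, catalog, top_k = c(30L, 50L)) {
  subsets <- list(all = sort(catalog$drg_code))
  for (m in sort(unique(catalog$mdc)))
    subsets[[paste0("mdc_", m)]] <- sort(catalog$drg_code[catalog$mdc == m])
  freq <- table(stays$drg_code)
  ranked <- names(freq)[order(-as.integer(freq), names(freq))]
  cum <- cumsum(as.integer(freq[ranked])) / nrow(stays)
  n80 <- which(cum >= 0.80)[1]
  subsets[["top_80pct"]] <- ranked[seq_len(n80)]
  for (k in top_k)
    subsets[[paste0("top_", k)]] <- ranked[seq_len(min(k, length(ranked)))]
  subsets
}

#' Full metric report of one model on the test stays
#'
#' One row per subset with macro/micro AUC and F1, the number of DRG
#' targets in the subset, and the number (and share) of test stays whose
#' true code falls in it.
#'
#' @param prob Probability matrix (stays x labels, named columns).
#' @param pred Predicted codes, one per stay.
#' @param truth True codes, one per stay.
#' @param subsets Named list from [make_subsets()].
#' @return data.frame with columns `subset`, `macro_auc`, `micro_auc`,
#'   `macro_f1`, `micro_f1`, `n_targets`, `n_stays`, `stay_share`.
#' @export
metric_report <- function(prob, pred, truth, subsets) {
  rows <- lapply(names(subsets), function(nm) {
    sub <- subsets[[nm]]
    covered <- sum(truth %in% sub)
    if (covered == 0L) return(NULL)
    auc <- auc_scores(prob, truth, sub)
    f1 <- f1_scores(pred, truth, sub)
    data.frame(subset = nm,
               macro_auc = unname(auc["macro_auc"]),
               micro_auc = unname(auc["micro_auc"]),
               macro_f1 = unname(f1["macro_f1"]),
               micro_f1 = unname(f1["micro_f1"]),
               n_targets = length(sub),
               n_stays = covered,
               stay_share = covered / length(truth),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Aggregate metric reports across cross-validation models
#'
#' Mean and sample standard deviation (ddof 1) of every metric across the
#' per-fold reports, per subset.
#'
#' @param reports List of data.frames from [metric_report()], one per
#'   model, with identical subset rows.
#' @return data.frame with one row per subset and `<metric>_mean` /
#'   `<metric>_sd` columns.
#' @export
aggregate_over_models <- function(reports) {
  if (length(reports) < 2L)
    stop("aggregate_over_models: need at least two reports", call. = FALSE)
  key <- reports[[1]]$subset
  for (r in reports[-1])
    if (!identical(r$subset, key))
      stop("aggregate_over_models: reports have mismatched subsets", call. = FALSE)
  metrics <- c("macro_auc", "micro_auc", "macro_f1", "micro_f1")
  out <- reports[[1]][c("subset", "n_targets", "n_stays", "stay_share")]
  for (m in metrics) {
    vals <- sapply(reports, function(r) r[[m]])
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
    out[[paste0(m, "_mean")]] <- rowMeans(vals)
    out[[paste0(m, "_sd")]] <- apply(vals, 1L, stats::sd)
  }
  out
}
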