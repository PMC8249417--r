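# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use O(n^2) pair enumeration and
# explicit confusion-matrix counting, never the package's own code paths.

# Pairwise-concordance AUC: P(score_pos > score_neg), ties 0.5.
brute_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

brute_macro_micro_auc <- function(prob, truth, subset) {
  rows <- truth %in% subset
  P <- prob[rows, , drop = FALSE]; y <- truth[rows]
  per <- sapply(subset, function(l) brute_auc(P[, l], y == l))
  pooled_s <- c(); pooled_y <- c()
  for (l in subset) {
    pooled_s <- c(pooled_s, P[, l])
    pooled_y <- c(pooled_y, y == l)
  }
  c(macro = mean(per[!is.na(per)]), micro = brute_auc(pooled_s, pooled_y))
}

brute_macro_micro_f1 <- function(pred, truth, subset) {
  rows <- truth %in% subset
  p <- pred[rows]; y <- truth[rows]
  f1s <- numeric(length(subset)); TP <- 0; FP <- 0; FN <- 0
  for (i in seq_along(subset)) {
    l <- subset[i]
    tp <- 0; fp <- 0; fn <- 0
    for (j in seq_along(p)) {
      if (p[j] == l && y[j] == l) tp <- tp + 1
      if (p[j] == l && y[j] != l) fp <- fp + 1
      if (p[j] != l && y[j] == l) fn <- fn + 1
    }
    f1s[i] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    TP <- TP + tp; FP <- FP + fp; FN <- FN + fn
  }
  c(macro = mean(f1s),
    micro = if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN))
}

# Random single-label prediction problem for metric fuzzing.
random_metric_case <- function(max_stays = 20L, max_labels = 5L) {
  n_lab <- sample(2:max_labels, 1)
  labels <- LETTERS[seq_len(n_lab)]
  n <- sample(2:max_stays, 1)
  truth <- sample(labels, n, replace = TRUE)
  prob <- matrix(stats::runif(n * n_lab), n, n_lab, dimnames = list(NULL, labels))
  # occasional exact ties to exercise the 0.5 concordance rule
  if (stats::runif(1) < 0.3) prob[] <- round(prob, 1)
  prob <- prob / rowSums(prob)
  pred <- labels[apply(prob, 1, which.max)]
  list(prob = prob, truth = truth, pred = pred, labels = labels)
}
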