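test_that("perfect ranking gives AUC 1 and random scores hover at 0.5", {
  labels <- c("A", "B")
  truth <- rep(labels, each = 50)
  prob <- rbind(matrix(rep(c(0.9, 0.1), 50), ncol = 2, byrow = TRUE),
                matrix(rep(c(0.1, 0.9), 50), ncol = 2, byrow = TRUE))
  colnames(prob) <- labels
  auc <- auc_scores(prob, truth)
  expect_equal(unname(auc["macro_auc"]), 1.0)
  expect_equal(unname(auc["micro_auc"]), 1.0)

  set.seed(3)
  n <- 2000
  prob_r <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, labels))
  prob_r <- prob_r / rowSums(prob_r)
  auc_r <- auc_scores(prob_r, sample(labels, n, replace = TRUE))
  expect_lt(abs(auc_r["macro_auc"] - 0.5), 0.05)
})

test_that("AUC matches the pairwise concordance oracle on a hand case", {
  labels <- c("A", "B", "C")
  prob <- matrix(c(0.6, 0.3, 0.1,
                   0.2, 0.5, 0.3,
                   0.3, 0.3, 0.4,
                   0.5, 0.4, 0.1,
                   0.1, 0.2, 0.7), 5, 3, byrow = TRUE,
                 dimnames = list(NULL, labels))
  truth <- c("A", "B", "A", "C", "C")
  mine <- auc_scores(prob, truth, labels)
  oracle <- brute_macro_micro_auc(prob, truth, labels)
  expect_equal(unname(mine["macro_auc"]), unname(oracle["macro"]))
  expect_equal(unname(mine["micro_auc"]), unname(oracle["micro"]))
  expect_error(auc_scores(prob, truth, "Z"), "subset")
})

test_that("evaluation restricted to a subset drops out-of-subset stays", {
  labels <- c("A", "B", "C")
  set.seed(4)
  prob <- matrix(runif(30), 10, 3, dimnames = list(NULL, labels))
  prob <- prob / rowSums(prob)
  truth <- sample(labels, 10, replace = TRUE)
  sub <- c("A", "B")
  mine <- auc_scores(prob, truth, sub)
  oracle <- brute_macro_micro_auc(prob, truth, sub)
  expect_equal(unname(mine["macro_auc"]), unname(oracle["macro"]))
  expect_equal(unname(mine["micro_auc"]), unname(oracle["micro"]))
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- round(runif(40), 2)
  y <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  prob <- cbind(A = 1 - scores, B = scores)
  # both one-vs-rest AUCs equal the binary AUC here, so macro does too
  mine <- auc_scores(prob, ifelse(y, "B", "A"), c("A", "B"))
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(unname(mine["macro_auc"]), ref, tolerance = 1e-12)
})

test_that("F1 scores match hand-computed confusion matrices", {
  truth <- c("A", "A", "B", "C")
  pred <- c("A", "B", "B", "C")
  # per label: A tp1 fp0 fn1 -> 2/3; B tp1 fp1 fn0 -> 2/3; C tp1 -> 1
  f1 <- f1_scores(pred, truth, c("A", "B", "C"))
  expect_equal(unname(f1["macro_f1"]), mean(c(2/3, 2/3, 1)))
  expect_equal(unname(f1["micro_f1"]), 2 * 3 / (2 * 3 + 1 + 1))

  all_right <- f1_scores(truth, truth, c("A", "B", "C"))
  expect_equal(unname(all_right["macro_f1"]), 1.0)
  expect_equal(unname(all_right["micro_f1"]), 1.0)

  # absent labels contribute zero F1 to the macro mean
  with_absent <- f1_scores(pred, truth, c("A", "B", "C", "D"))
  expect_equal(unname(with_absent["macro_f1"]), mean(c(2/3, 2/3, 1, 0)))
})

test_that("micro-F1 equals accuracy for single-label predictions on the full space", {
  set.seed(6)
  for (trial in 1:25) {
    case <- random_metric_case()
    f1 <- f1_scores(case$pred, case$truth, case$labels)
    expect_equal(unname(f1["micro_f1"]), mean(case$pred == case$truth))
  }
})

test_that("frequency subsets follow the cumulative-coverage rule", {
  stays <- data.frame(drg_code = rep(c("D1", "D2", "D3", "D4"),
                                     times = c(50, 30, 15, 5)))
  catalog <- data.frame(drg_code = paste0("D", 1:4), drg_system = "MS_LIKE",
                        mdc = c("05", "05", "01", "04"), weight = 1:4)
  subs <- make_subsets(stays, catalog, top_k = c(3, 30))
  expect_equal(subs$top_80pct, c("D1", "D2"))   # 50 + 30 = 80%
  expect_equal(subs$top_3, c("D1", "D2", "D3"))
  expect_equal(subs$top_30, c("D1", "D2", "D3", "D4"))  # k clipped to 4 codes
  expect_setequal(subs$mdc_05, c("D1", "D2"))
  expect_setequal(subs$all, catalog$drg_code)
  # coverage shares recount
  for (nm in names(subs)) {
    share <- sum(stays$drg_code %in% subs[[nm]]) / nrow(stays)
    brute <- 0
    for (i in seq_len(nrow(stays)))
      if (stays$drg_code[i] %in% subs[[nm]]) brute <- brute + 1
    expect_equal(share, brute / nrow(stays))
  }
})

test_that("metric reports stay within [0, 1] and count stays correctly", {
  set.seed(7)
  case <- random_metric_case(max_stays = 20, max_labels = 5)
  catalog <- data.frame(drg_code = case$labels, drg_system = "MS_LIKE",
                        mdc = "05", weight = seq_along(case$labels))
  subs <- make_subsets(data.frame(drg_code = case$truth), catalog, top_k = 2)
  rep1 <- metric_report(case$prob, case$pred, case$truth, subs)
  metrics <- as.matrix(rep1[c("macro_auc", "micro_auc", "macro_f1", "micro_f1")])
  expect_true(all(metrics >= 0 & metrics <= 1, na.rm = TRUE))
  expect_true(all(rep1$n_stays <= length(case$truth)))
  expect_equal(rep1$n_stays[rep1$subset == "all"], length(case$truth))
})

test_that("aggregation over fold models reports mean and ddof-1 SD", {
  r <- data.frame(subset = c("all", "top_2"), macro_auc = c(0.8, 0.9),
                  micro_auc = c(0.9, 0.95), macro_f1 = c(0.2, 0.3),
                  micro_f1 = c(0.4, 0.5), n_targets = c(4L, 2L),
                  n_stays = c(10L, 8L), stay_share = c(1, 0.8))
  agg_same <- aggregate_over_models(list(r, r, r))
  expect_true(all(agg_same$macro_auc_sd == 0))
  r2 <- r; r2$macro_auc <- c(0.9, 1.0)
  agg <- aggregate_over_models(list(r, r2))
  expect_equal(agg$macro_auc_mean, c(0.85, 0.95))
  expect_equal(agg$macro_auc_sd, rep(stats::sd(c(0.8, 0.9)), 2))
  expect_equal(agg$macro_auc_sd[1], 0.0707, tolerance = 1e-3)

  # independent mean/SD recomputation on random reports
  set.seed(8)
  reps <- lapply(1:5, function(i) { x <- r; x$micro_f1 <- runif(2); x })
  agg5 <- aggregate_over_models(reps)
  vals <- sapply(reps, function(x) x$micro_f1)
  expect_equal(agg5$micro_f1_mean, apply(vals, 1, mean))
  expect_equal(agg5$micro_f1_sd, apply(vals, 1, stats::sd))

  r3 <- r; r3$subset <- c("all", "other")
  expect_error(aggregate_over_models(list(r, r3)), "mismatched")
  expect_error(aggregate_over_models(list(r)), "at least two")
})

test_that("frequent-DRG subsets score at least as well as the full space on synthetic data", {
  m <- small_model()
  w <- small_world()
  tst <- test_stays(w$cohort, w$split)
  docs <- encode_stays_48(tst, w$cohort$notes, w$vocab)
  prob <- predict_prob_matrix(m, docs)
  subs <- make_subsets(tst, w$catalog, top_k = 2)
  r <- metric_report(prob, colnames(prob)[apply(prob, 1, which.max)],
                     tst$drg_code, subs)
  # tendency, not a law: asserted with slack on one seed
  expect_gte(r$micro_f1[r$subset == "top_2"] + 0.05,
             r$micro_f1[r$subset == "all"])
})
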