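test_that("forward probabilities and attention rows normalize over random models", {
  v <- toy_vocab()
  set.seed(5)
  for (trial in 1:10) {
    cfg <- model_config(embed_dim = sample(2:6, 1), kernel_width = sample(c(1, 3, 5), 1),
                        n_filters = sample(2:8, 1), dropout = 0, seed = trial)
    m <- init_drg_model(v, c("A", "B", "C"), cfg)
    toks <- sample(names(v$token_ids), sample(1:30, 1), replace = TRUE)
    out <- forward(m, encode(toks, v, 40))
    expect_equal(sum(out$prob), 1, tolerance = 1e-6)
    expect_true(all(out$prob >= 0))
    expect_equal(unname(colSums(out$attention)), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("identical feature maps receive uniform attention", {
  v <- toy_vocab()
  cfg <- model_config(embed_dim = 3, kernel_width = 1, n_filters = 4,
                      dropout = 0, seed = 1)
  m <- init_drg_model(v, c("A", "B"), cfg)
  tok <- names(v$token_ids)[1]
  out <- forward(m, encode(rep(tok, 4), v, 10))
  expect_equal(unname(out$attention),
               matrix(0.25, 4, 2), tolerance = 1e-12)
})

test_that("forward matches a hand-computed scalar chain on a 3-token doc", {
  v <- toy_vocab()
  cfg <- model_config(embed_dim = 1, kernel_width = 3, n_filters = 1,
                      dropout = 0, seed = 1)
  m <- init_drg_model(v, c("A", "B"), cfg)
  toks <- names(v$token_ids)[1:3]
  ids <- unname(v$token_ids[toks])
  x <- c(0.3, -0.5, 0.8)
  m$params$E[, 1] <- 0
  m$params$E[ids, 1] <- x
  cc <- c(0.4, -0.2, 0.7); b0 <- 0.1
  m$params$Cf[, 1] <- cc
  m$params$b_c <- b0
  u <- c(0.9, -1.1); be <- c(0.6, -0.3); bb <- c(0.05, -0.05)
  m$params$U[1, ] <- u; m$params$B[1, ] <- be; m$params$b <- bb

  # independent scalar arithmetic: same-padded windows, tanh conv,
  # per-label softmax attention, per-label linear score, output softmax
  w1 <- c(0, x[1], x[2]); w2 <- x; w3 <- c(x[2], x[3], 0)
  h <- tanh(c(sum(w1 * cc), sum(w2 * cc), sum(w3 * cc)) + b0)
  expected_p <- numeric(2)
  scores <- numeric(2)
  for (l in 1:2) {
    g <- h * u[l]
    a <- exp(g - max(g)); a <- a / sum(a)
    vl <- sum(a * h)
    scores[l] <- be[l] * vl + bb[l]
  }
  expected_p <- exp(scores - max(scores)); expected_p <- expected_p / sum(expected_p)

  out <- forward(m, encode(toks, v, 10))
  expect_equal(unname(out$prob), expected_p, tolerance = 1e-12)
})

test_that("appending padding never changes the prediction", {
  m <- small_model()
  w <- small_world()
  st <- w$cohort$stays[1:5, ]
  for (i in 1:5) {
    nd <- w$cohort$notes[w$cohort$notes$stay_id == st$stay_id[i], ]
    toks <- clean_and_tokenize(assemble_document(nd, 48))
    toks <- head(toks, 60)
    p1 <- forward(m, encode(toks, m$vocab, 60))$prob
    p2 <- forward(m, encode(toks, m$vocab, 200))$prob
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("training interpolates a linearly separable planted-signal toy set", {
  corpus <- c(rep(list(c("filler", "filler", "alpha", "marker")), 25),
              rep(list(c("filler", "filler", "beta", "marker")), 25))
  labels <- rep(c("A", "B"), each = 25)
  v <- build_vocab(corpus, 3)
  docs <- lapply(corpus, encode, vocab = v, max_len = 10)
  cfg <- model_config(embed_dim = 8, kernel_width = 3, n_filters = 6,
                      dropout = 0, learning_rate = 5e-3, epochs = 30,
                      batch_size = 8, val_frac = 0, seed = 4)
  m <- train_drg_model(docs, labels, v, c("A", "B"), cfg)
  pred <- vapply(docs, function(dc) names(which.max(forward(m, dc)$prob)),
                 character(1))
  expect_equal(mean(pred == labels), 1.0)
})

test_that("training is deterministic given the seed", {
  corpus <- lapply(1:20, function(i) sample(letters[1:6], 8, replace = TRUE))
  labels <- rep(c("A", "B"), 10)
  v <- build_vocab(corpus, 3)
  docs <- lapply(corpus, encode, vocab = v, max_len = 10)
  cfg <- model_config(embed_dim = 4, kernel_width = 3, n_filters = 3,
                      dropout = 0.2, epochs = 3, batch_size = 4, seed = 9)
  m1 <- train_drg_model(docs, labels, v, c("A", "B"), cfg)
  m2 <- train_drg_model(docs, labels, v, c("A", "B"), cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("training rejects empty input and labels outside the label space", {
  v <- toy_vocab()
  cfg <- model_config(embed_dim = 2, kernel_width = 3, n_filters = 2, seed = 1)
  expect_error(train_drg_model(list(), character(), v, c("A", "B"), cfg),
               "empty")
  doc <- encode(names(v$token_ids)[1:3], v, 5)
  expect_error(train_drg_model(list(doc), "Z", v, c("A", "B"), cfg),
               "outside label_space")
})

test_that("argmax prediction breaks ties toward the lowest label index", {
  v <- toy_vocab()
  cfg <- model_config(embed_dim = 2, kernel_width = 1, n_filters = 2,
                      dropout = 0, seed = 1)
  m <- init_drg_model(v, c("A", "B"), cfg)
  # zero read-out makes every label score equal: an exact tie
  m$params$B[] <- 0; m$params$b[] <- 0
  catalog <- data.frame(drg_code = c("A", "B"), drg_system = "MS_LIKE",
                        mdc = "05", weight = c(1.5, 2.5))
  doc <- encode(names(v$token_ids)[1:4], v, 6, stay_id = "S1", cutoff_hpa = 48)
  pr <- predict(m, doc, catalog)
  expect_equal(pr$pred_code, "A")
  expect_equal(pr$pred_weight, 1.5)
  bad_cat <- catalog[catalog$drg_code == "B", ]
  expect_error(predict(m, doc, bad_cat), "missing from catalog")
})

test_that("predicted weight always equals the catalog weight of the predicted code", {
  m <- small_model()
  w <- small_world()
  tst <- test_stays(w$cohort, w$split)
  docs <- encode_stays_48(tst, w$cohort$notes, w$vocab)
  n <- min(100L, length(docs))
  for (i in seq_len(n)) {
    pr <- predict(m, docs[[i]], w$catalog)
    expect_equal(pr$pred_weight,
                 w$catalog$weight[match(pr$pred_code, w$catalog$drg_code)])
  }
})

test_that("planted-signal model recovers held-out DRGs above 0.9 accuracy", {
  m <- small_model()
  w <- small_world()
  tst <- test_stays(w$cohort, w$split)
  preds <- predict_stays(m, tst, w$cohort$notes, w$catalog, 48, max_len = 150)
  expect_gt(mean(preds$pred_code == tst$drg_code), 0.9)
})

test_that("attention surfaces the planted n-grams on correctly classified stays", {
  m <- small_model()
  w <- small_world()
  tst <- test_stays(w$cohort, w$split)
  docs <- encode_stays_48(tst, w$cohort$notes, w$vocab)
  sig_tokens <- unique(unlist(strsplit(unlist(w$catalog$signal_ngrams), " ")))
  hits <- 0L; correct <- 0L
  for (i in seq_along(docs)) {
    pr <- predict(m, docs[[i]], w$catalog)
    if (pr$pred_code != tst$drg_code[i]) next
    correct <- correct + 1L
    top <- top_attended_ngrams(m, docs[[i]], pr$pred_code, top_n = 3)
    if (any(unlist(lapply(top, `[[`, "ngram")) %in% sig_tokens))
      hits <- hits + 1L
  }
  expect_gt(correct, 0L)
  expect_gt(hits / correct, 0.7)
})

test_that("top attended n-grams are the sorted attention row with clipped windows", {
  m <- small_model()
  w <- small_world()
  tst <- test_stays(w$cohort, w$split)
  doc <- encode_stays_48(tst[1, ], w$cohort$notes, w$vocab)[[1]]
  label <- m$label_space[1]
  out <- forward(m, doc)
  a <- out$attention[, 1]
  top <- top_attended_ngrams(m, doc, label, top_n = 5)
  weights <- vapply(top, `[[`, numeric(1), "weight")
  expect_equal(weights, sort(a, decreasing = TRUE)[1:5], tolerance = 1e-12)
  expect_true(all(diff(weights) <= 0))
  k <- m$config$kernel_width
  for (tn in top) expect_lte(length(tn$ngram), k)

  # a doc shorter than the kernel yields a clipped window, not an error
  short <- encode(names(w$vocab$token_ids)[1:2], w$vocab, 10)
  tops <- top_attended_ngrams(m, short, label, top_n = 2)
  expect_lte(length(tops[[1]]$ngram), 2L)
})

test_that("regression head converges on a constant weight target", {
  corpus <- lapply(1:40, function(i) sample(letters[1:5], 10, replace = TRUE))
  v <- build_vocab(corpus, 3)
  docs <- lapply(corpus, encode, vocab = v, max_len = 12)
  cfg <- model_config(embed_dim = 4, kernel_width = 3, n_filters = 3,
                      dropout = 0, learning_rate = 0.05, epochs = 30,
                      batch_size = 8, val_frac = 0, seed = 6, head = "regress")
  m <- train_drg_model(docs, vocab = v, label_space = character(),
                       config = cfg, weights = rep(2.5, 40))
  preds <- vapply(docs, function(dc) forward(m, dc)$yhat, numeric(1))
  expect_lt(mean(abs(preds - 2.5)), 0.25)
})

test_that("regression head beats the constant-mean weight predictor", {
  w <- small_world()
  tr_st <- w$fold1$train; va_st <- w$fold1$val
  tr <- encode_stays_48(tr_st, w$cohort$notes, w$vocab)
  va <- encode_stays_48(va_st, w$cohort$notes, w$vocab)
  cfg <- model_config(embed_dim = 16, kernel_width = 5, n_filters = 12,
                      dropout = 0.1, learning_rate = 2e-3, epochs = 8,
                      batch_size = 8, val_frac = 0, seed = 8, head = "regress")
  m <- train_drg_model(tr, vocab = w$vocab, label_space = w$cohort$label_space,
                       config = cfg, weights = tr_st$true_weight)
  pred <- vapply(va, function(dc) forward(m, dc)$yhat, numeric(1))
  mae <- mean(abs(pred - va_st$true_weight))
  baseline <- mean(abs(mean(tr_st$true_weight) - va_st$true_weight))
  expect_lt(mae, baseline)
})
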