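#' Configuration for the attention-CNN DRG model
#'
#' The classifier embeds tokens, applies a one-dimensional convolution
#' (receptive field `kernel_width` tokens, tanh activation), pools the
#' feature map with one learned attention vector per DRG label, and scores
#' each label with a per-label linear read-out followed by a softmax over
#' labels. The regression head replaces the per-label machinery with a
#' single attention vector and a linear output trained on mean absolute
#' error against DRG payment weights.
#'
#' @param embed_dim Token embedding dimension (default 100).
#' @param kernel_width Convolution width in tokens; 5 matches the 5-gram
#'   windows surfaced by attention inspection (default 5).
#' @param n_filters Number of convolution filters (default 50).
#' @param dropout Dropout probability on the convolved feature map during
#'   training (default 0.2).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Training epochs (default 15).
#' @param batch_size Documents per gradient step (default 16).
#' @param val_frac Fraction of the training documents held out internally
#'   to select the best epoch (default 0.1); ignored when an explicit
#'   validation set is passed to [train_drg_model()].
#' @param seed Mandatory integer seed covering initialization, shuffling,
#'   and dropout.
#' @param head `"classify"` (softmax cross-entropy over DRG codes) or
#'   `"regress"` (MAE on payment weights).
#' @return A `model_config` list.
#' @export
model_config <- function(embed_dim = 100L, kernel_width = 5L, n_filters = 50L,
                         dropout = 0.2, learning_rate = 1e-3, epochs = 15L,
                         batch_size = 16L, val_frac = 0.1, seed,
                         head = c("classify", "regress")) {
  head <- match.arg(head)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("model_config: a single `seed` is mandatory", call. = FALSE)
  if (kernel_width < 1L) stop("model_config: kernel_width must be >= 1", call. = FALSE)
  if (n_filters < 1L) stop("model_config: n_filters must be >= 1", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("model_config: dropout must be in [0, 1)", call. = FALSE)
  structure(list(embed_dim = as.integer(embed_dim),
                 kernel_width = as.integer(kernel_width),
                 n_filters = as.integer(n_filters),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 val_frac = val_frac, seed = as.integer(seed), head = head),
            class = "model_config")
}

#' Initialize an untrained DRG model
#'
#' Parameters are drawn from small-variance Gaussians; the padding token's
#' embedding row is all-zero and is never updated during training, so
#' padded positions contribute nothing to convolution windows.
#'
#' @param vocab A `drg_vocab`.
#' @param label_space Ordered character vector of DRG codes (the target
#'   indices of the classifier).
#' @param config A [model_config()].
#' @return A `drg_model`.
#' @export
init_drg_model <- function(vocab, label_space, config) {
  stopifnot(inherits(vocab, "drg_vocab"), inherits(config, "model_config"))
  d <- config$embed_dim; k <- config$kernel_width; nf <- config$n_filters
  L <- length(label_space)
  with_seed(derive_seed(config$seed, "init"), {
    params <- list(
      E = matrix(stats::rnorm(vocab$size * d, 0, 0.1), vocab$size, d),
      Cf = matrix(stats::rnorm(k * d * nf, 0, sqrt(1 / (k * d))), k * d, nf),
      b_c = numeric(nf)
    )
    params$E[vocab$pad_id, ] <- 0
    if (config$head == "classify") {
      params$U <- matrix(stats::rnorm(nf * L, 0, sqrt(1 / nf)), nf, L)
      params$B <- matrix(stats::rnorm(nf * L, 0, sqrt(1 / nf)), nf, L)
      params$b <- numeric(L)
    } else {
      params$u_r <- stats::rnorm(nf, 0, sqrt(1 / nf))
      params$w_r <- stats::rnorm(nf, 0, sqrt(1 / nf))
      params$b_r <- 0
    }
    structure(list(params = params, config = config, vocab = vocab,
                   label_space = label_space),
              class = "drg_model")
  })
}

# Forward pass over one document. `ids` are the true-length token ids
# (pad stripped); an empty document is represented by a single pad token.
# Returns probabilities, per-label attention, and the caches needed for
# backpropagation.
caml_forward <- function(params, ids, config, dropout_mask = NULL) {
  if (length(ids) == 0L) ids <- 1L  # pad token stands in for an empty doc
  if (max(ids) > nrow(params$E))
    stop("forward: token id exceeds embedding rows (vocab mismatch)", call. = FALSE)
  d <- ncol(params$E); k <- config$kernel_width
  n <- length(ids)
  X <- params$E[ids, , drop = FALSE]
  left <- (k - 1L) %/% 2L; right <- k - 1L - left
  Xp <- if (k > 1L) rbind(matrix(0, left, d), X, matrix(0, right, d)) else X
  W <- matrix(0, n, k * d)
  for (j in seq_len(k))
    W[, ((j - 1L) * d + 1L):(j * d)] <- Xp[j:(j + n - 1L), , drop = FALSE]
  Z <- sweep(W %*% params$Cf, 2L, params$b_c, "+")
  H <- tanh(Z)
  if (!is.null(dropout_mask)) H <- H * dropout_mask
  if (!is.null(params$U)) {
    G <- H %*% params$U                      # n x L attention logits
    A <- col_softmax(G)                      # columns sum to 1
    Vm <- crossprod(H, A)                    # F x L pooled features
    scores <- colSums(Vm * params$B) + params$b
    p <- softmax(scores)
    list(p = p, A = A, H = H, W = W, Vm = Vm, ids = ids, n = n,
         left = left, scores = scores)
  } else {
    g <- drop(H %*% params$u_r)
    a <- softmax(g)
    v <- drop(crossprod(H, a))
    yhat <- sum(params$w_r * v) + params$b_r
    list(yhat = yhat, a = a, H = H, W = W, v = v, ids = ids, n = n,
         left = left)
  }
}

# Backward pass for the softmax-classification head. `dscores` is the
# gradient of the loss w.r.t. the label scores (p - onehot for CE).
caml_backward_classify <- function(params, cache, dscores, config,
                                   dropout_mask = NULL) {
  H <- cache$H; A <- cache$A; W <- cache$W
  dB <- sweep(cache$Vm, 2L, dscores, "*")
  db <- dscores
  dV <- sweep(params$B, 2L, dscores, "*")    # F x L
  dH <- A %*% t(dV)                          # n x F, via v_l = H' a_l
  dA <- H %*% dV                             # n x L
  s <- colSums(A * dA)
  dG <- A * sweep(dA, 2L, s, "-")            # softmax-per-column backprop
  dH <- dH + dG %*% t(params$U)
  dU <- crossprod(H, dG)
  if (!is.null(dropout_mask)) dH <- dH * dropout_mask
  dZ <- dH * (1 - H * H)
  finish_conv_backward(params, cache, dZ, config,
                       extra = list(U = dU, B = dB, b = db))
}

# Backward pass for the regression head; dy is dLoss/dyhat.
caml_backward_regress <- function(params, cache, dy, config,
                                  dropout_mask = NULL) {
  H <- cache$H; a <- cache$a
  dw_r <- dy * cache$v
  db_r <- dy
  dv <- dy * params$w_r
  dH <- outer(a, dv)
  da <- drop(H %*% dv)
  dg <- a * (da - sum(a * da))
  dH <- dH + outer(dg, params$u_r)
  du_r <- drop(crossprod(H, dg))
  if (!is.null(dropout_mask)) dH <- dH * dropout_mask
  dZ <- dH * (1 - H * H)
  finish_conv_backward(params, cache, dZ, config,
                       extra = list(u_r = du_r, w_r = dw_r, b_r = db_r))
}

# Common tail of both backward passes: convolution and embedding grads.
finish_conv_backward <- function(params, cache, dZ, config, extra) {
  W <- cache$W; k <- config$kernel_width; d <- ncol(params$E)
  n <- cache$n; left <- cache$left
  dCf <- crossprod(W, dZ)
  db_c <- colSums(dZ)
  dW <- dZ %*% t(params$Cf)                  # n x (k*d)
  dXp <- matrix(0, n + k - 1L, d)
  for (j in seq_len(k))
    dXp[j:(j + n - 1L), ] <- dXp[j:(j + n - 1L), ] +
      dW[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
  dX <- dXp[(left + 1L):(left + n), , drop = FALSE]
  by_id <- rowsum(dX, group = cache$ids)
  c(list(Cf = dCf, b_c = db_c,
         E_ids = as.integer(rownames(by_id)), E_rows = by_id),
    extra)
}

# One Adam step over accumulated gradients (dense for all parameters
# except E, which is updated only on the embedding rows that were touched;
# the pad row is always skipped so its embedding stays zero).
adam_step <- function(params, grads, state, lr, pad_id,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in setdiff(names(params), "E")) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  ids <- setdiff(grads$E_ids, pad_id)
  if (length(ids)) {
    rows <- match(ids, grads$E_ids)
    g <- grads$E_rows[rows, , drop = FALSE]
    state$m$E[ids, ] <- beta1 * state$m$E[ids, , drop = FALSE] + (1 - beta1) * g
    state$v$E[ids, ] <- beta2 * state$v$E[ids, , drop = FALSE] + (1 - beta2) * g * g
    params$E[ids, ] <- params$E[ids, , drop = FALSE] -
      lr * (state$m$E[ids, , drop = FALSE] / bc1) /
        (sqrt(state$v$E[ids, , drop = FALSE] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the attention-CNN DRG model
#'
#' Minimizes softmax cross-entropy over DRG codes (or mean absolute error
#' against payment weights when `config$head == "regress"`) with Adam,
#' and returns the parameters from the epoch with the best validation
#' objective. Training is deterministic given `config$seed` and a fixed
#' BLAS thread count.
#'
#' @param docs List of `drg_encoded_doc` training documents.
#' @param labels Character vector of true DRG codes (classification head).
#' @param vocab The `drg_vocab` the documents were encoded with.
#' @param label_space Ordered DRG code vector defining the output indices.
#' @param config A [model_config()].
#' @param weights Numeric payment weights (regression head).
#' @param val_docs,val_labels,val_weights Optional explicit validation
#'   set; when absent, `config$val_frac` of `docs` is held out internally.
#' @param verbose Print per-epoch objectives.
#' @return A trained `drg_model` with a `history` data.frame attached.
#' @export
train_drg_model <- function(docs, labels = NULL, vocab, label_space, config,
                            weights = NULL, val_docs = NULL, val_labels = NULL,
                            val_weights = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  if (length(docs) == 0L) stop("train: empty training set", call. = FALSE)
  classify <- config$head == "classify"
  if (classify) {
    if (is.null(labels) || length(labels) != length(docs))
      stop("train: one label per document required", call. = FALSE)
    bad <- setdiff(unique(labels), label_space)
    if (length(bad))
      stop("train: label(s) outside label_space: ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    y <- match(labels, label_space)
  } else {
    if (is.null(weights) || length(weights) != length(docs))
      stop("train: one weight per document required", call. = FALSE)
    if (any(weights <= 0)) stop("train: weights must be positive", call. = FALSE)
    y <- weights
  }

  model <- init_drg_model(vocab, label_space, config)
  params <- model$params
  seqs <- lapply(docs, function(dc) dc$token_ids[seq_len(dc$true_length)])

  with_seed(derive_seed(config$seed, "train"), {
    if (is.null(val_docs) && config$val_frac > 0 && length(docs) >= 10L) {
      n_val <- max(1L, round(config$val_frac * length(docs)))
      vidx <- sample(length(docs), n_val)
      val_seqs <- seqs[vidx]; val_y <- y[vidx]
      seqs <- seqs[-vidx]; y <- y[-vidx]
    } else if (!is.null(val_docs)) {
      val_seqs <- lapply(val_docs, function(dc) dc$token_ids[seq_len(dc$true_length)])
      val_y <- if (classify) match(val_labels, label_space) else val_weights
    } else {
      val_seqs <- seqs; val_y <- y
    }

    state <- list(t = 0L,
                  m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))
    n_train <- length(seqs)
    best_obj <- Inf; best_params <- params
    history <- data.frame(epoch = integer(), train_obj = numeric(),
                          val_obj = numeric())

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_train)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (batch in batches) {
        acc <- NULL
        eacc <- new.env(parent = emptyenv())
        for (i in batch) {
          ids <- seqs[[i]]
          dm <- if (config$dropout > 0) {
            nr <- max(1L, length(ids))
            matrix(stats::rbinom(nr * config$n_filters, 1L, 1 - config$dropout) /
                     (1 - config$dropout), nr, config$n_filters)
          } else NULL
          cache <- caml_forward(params, ids, config, dropout_mask = dm)
          if (classify) {
            p <- cache$p
            epoch_loss <- epoch_loss - log(max(p[y[i]], 1e-12))
            ds <- p; ds[y[i]] <- ds[y[i]] - 1
            g <- caml_backward_classify(params, cache, ds, config, dropout_mask = dm)
          } else {
            r <- cache$yhat - y[i]
            epoch_loss <- epoch_loss + abs(r)
            g <- caml_backward_regress(params, cache, sign(r), config, dropout_mask = dm)
          }
          acc <- accumulate_grads(acc, g, eacc)
        }
        grads <- collect_grads(acc, eacc, scale = 1 / length(batch))
        upd <- adam_step(params, grads, state, config$learning_rate, vocab$pad_id)
        params <- upd$params; state <- upd$state
      }
      val_obj <- eval_objective(params, val_seqs, val_y, config, classify)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_obj = epoch_loss / n_train,
                                           val_obj = val_obj))
      if (verbose)
        message(sprintf("epoch %d  train %.4f  val %.4f", epoch,
                        epoch_loss / n_train, val_obj))
      if (val_obj < best_obj) { best_obj <- val_obj; best_params <- params }
    }
    model$params <- best_params
    model$history <- history
    model$best_val <- best_obj
    model
  })
}

# Sum per-document gradients; embedding rows accumulate in an environment
# keyed by token id to stay sparse.
accumulate_grads <- function(acc, g, eacc) {
  ids <- g$E_ids
  for (r in seq_along(ids)) {
    key <- as.character(ids[r])
    prev <- eacc[[key]]
    eacc[[key]] <- if (is.null(prev)) g$E_rows[r, ] else prev + g$E_rows[r, ]
  }
  g$E_ids <- NULL; g$E_rows <- NULL
  if (is.null(acc)) return(g)
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

collect_grads <- function(acc, eacc, scale) {
  for (nm in names(acc)) acc[[nm]] <- acc[[nm]] * scale
  keys <- ls(eacc)
  if (length(keys)) {
    ids <- as.integer(keys)
    rows <- do.call(rbind, lapply(keys, function(k) eacc[[k]])) * scale
    ord <- order(ids)
    acc$E_ids <- ids[ord]; acc$E_rows <- rows[ord, , drop = FALSE]
  } else {
    acc$E_ids <- integer(); acc$E_rows <- matrix(0, 0, 0)
  }
  acc
}

# Mean objective (cross-entropy or MAE) of `params` on a doc set.
eval_objective <- function(params, seqs, y, config, classify) {
  tot <- 0
  for (i in seq_along(seqs)) {
    cache <- caml_forward(params, seqs[[i]], config)
    tot <- tot + if (classify) -log(max(cache$p[y[i]], 1e-12))
                 else abs(cache$yhat - y[i])
  }
  tot / max(1L, length(seqs))
}

#' Forward pass of a trained model on one document
#'
#' @param model A `drg_model`.
#' @param doc A `drg_encoded_doc` encoded with the model's vocabulary.
#' @return For the classification head, a list with `prob` (named
#'   probability vector over the label space, summing to 1) and
#'   `attention` (positions x labels matrix; each column sums to 1). For
#'   the regression head, a list with `yhat` and `attention` (a vector).
#' @export
forward <- function(model, doc) {
  stopifnot(inherits(model, "drg_model"), inherits(doc, "drg_encoded_doc"))
  ids <- doc$token_ids[seq_len(doc$true_length)]
  cache <- caml_forward(model$params, ids, model$config)
  if (model$config$head == "classify")
    list(prob = stats::setNames(cache$p, model$label_space),
         attention = cache$A)
  else
    list(yhat = cache$yhat, attention = cache$a)
}

#' Predict the DRG and payment weight for one document
#'
#' Takes the label with the highest probability (ties broken toward the
#' lowest label index) and looks up its relative weight in the catalog;
#' with the regression head, the payment weight is the model output and no
#' code is assigned.
#'
#' @param object A trained `drg_model`.
#' @param doc A `drg_encoded_doc`.
#' @param catalog A `drg_catalog` covering the label space.
#' @param ... Unused.
#' @return A one-row data.frame: `stay_id`, `cutoff_hpa`, `pred_code`,
#'   `pred_weight`, `prob_top1`.
#' @export
predict.drg_model <- function(object, doc, catalog, ...) {
  out <- forward(object, doc)
  if (object$config$head == "classify") {
    idx <- which.max(out$prob)   # first maximum = lowest label index on ties
    code <- object$label_space[idx]
    w <- catalog$weight[match(code, catalog$drg_code)]
    if (is.na(w))
      stop("predict: code ", code, " missing from catalog", call. = FALSE)
    data.frame(stay_id = doc$stay_id, cutoff_hpa = doc$cutoff_hpa,
               pred_code = code, pred_weight = w,
               prob_top1 = unname(out$prob[idx]), stringsAsFactors = FALSE)
  } else {
    data.frame(stay_id = doc$stay_id, cutoff_hpa = doc$cutoff_hpa,
               pred_code = NA_character_, pred_weight = out$yhat,
               prob_top1 = NA_real_, stringsAsFactors = FALSE)
  }
}

#' Probability matrix of a model over a list of documents
#'
#' @param model A trained classification `drg_model`.
#' @param docs List of `drg_encoded_doc`.
#' @return Numeric matrix (documents x labels), columns named by the
#'   label space; each row sums to 1.
#' @export
predict_prob_matrix <- function(model, docs) {
  stopifnot(model$config$head == "classify")
  out <- matrix(0, length(docs), length(model$label_space),
                dimnames = list(NULL, model$label_space))
  for (i in seq_along(docs)) out[i, ] <- forward(model, docs[[i]])$prob
  out
}

#' Most-attended n-grams for a label on one document
#'
#' Reports the `top_n` convolution positions with the highest attention
#' weight for the given label, each as the `kernel_width`-token window
#' centered on the position (clipped at document boundaries), together
#' with its attention weight, in non-increasing weight order.
#'
#' @param model A trained classification `drg_model`.
#' @param doc A `drg_encoded_doc`.
#' @param label A DRG code in the model's label space.
#' @param top_n Number of windows to report (default 3).
#' @return List of lists with `ngram` (character vector of tokens) and
#'   `weight`.
#' @export
top_attended_ngrams <- function(model, doc, label, top_n = 3L) {
  stopifnot(inherits(model, "drg_model"), model$config$head == "classify")
  lidx <- match(label, model$label_space)
  if (is.na(lidx)) stop("top_attended_ngrams: label not in label space", call. = FALSE)
  out <- forward(model, doc)
  a <- out$attention[, lidx]
  toks <- decode(doc, model$vocab)
  n <- max(1L, doc$true_length)
  k <- model$config$kernel_width
  left <- (k - 1L) %/% 2L
  ord <- order(-a)
  take <- utils::head(ord, top_n)
  lapply(take, function(pos) {
    lo <- max(1L, pos - left)
    hi <- min(n, pos - left + k - 1L)
    list(ngram = if (doc$true_length == 0L) character() else toks[lo:hi],
         weight = unname(a[pos]))
  })
}

#' An oracle predictor that returns the true DRG of every stay
#'
#' Used as a reference point in population-level analyses: with perfect
#' per-stay grouping, the case-mix index error is identically zero at
#' every cutoff and cohort size.
#'
#' @param catalog A `drg_catalog`.
#' @return A `drg_oracle_model`.
#' @export
oracle_model <- function(catalog) {
  structure(list(catalog = catalog), class = "drg_oracle_model")
}

#' Predict DRGs and weights for a population of stays at one cutoff
#'
#' Assembles each stay's document at `cutoff_hpa`, encodes it with the
#' model's vocabulary, and predicts code and payment weight. Stays with no
#' note inside the window are still predicted, from an all-padding input.
#'
#' @param model A `drg_model` or [oracle_model()].
#' @param stays data.frame of stays.
#' @param notes data.frame of the stays' notes.
#' @param catalog A `drg_catalog`.
#' @param cutoff_hpa Admission-time cutoff in hours.
#' @param max_len Encoded sequence length (default 2000).
#' @return data.frame with one row per stay: `stay_id`, `cutoff_hpa`,
#'   `pred_code`, `pred_weight`, `prob_top1`.
#' @export
predict_stays <- function(model, stays, notes, catalog, cutoff_hpa,
                          max_len = 2000L) {
  UseMethod("predict_stays")
}

#' @export
predict_stays.drg_model <- function(model, stays, notes, catalog, cutoff_hpa,
                                    max_len = 2000L) {
  docs <- encode_population(stays, notes, model$vocab, cutoff_hpa, max_len)
  do.call(rbind, lapply(docs, function(dc) predict(model, dc, catalog)))
}

#' @export
predict_stays.drg_oracle_model <- function(model, stays, notes, catalog,
                                           cutoff_hpa, max_len = 2000L) {
  w <- catalog$weight[match(stays$drg_code, catalog$drg_code)]
  data.frame(stay_id = stays$stay_id, cutoff_hpa = cutoff_hpa,
             pred_code = stays$drg_code, pred_weight = w,
             prob_top1 = 1, stringsAsFactors = FALSE)
}
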