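#' Assemble a stay's document at an admission-time cutoff
#'
#' Concatenates the texts of all notes charted at or before `cutoff_hpa`,
#' in ascending chart-time order (stable for ties), joined by single
#' spaces. The result at cutoff t is always a prefix of the result at any
#' later cutoff, which is what makes the admission-time sweep well defined.
#'
#' @param notes data.frame of this stay's notes (`chart_hpa`, `text`).
#' @param cutoff_hpa Hours post-admission cutoff, in \[-24, 48\].
#' @return A single string; `""` when no note falls inside the window.
#' @export
assemble_document <- function(notes, cutoff_hpa) {
  stopifnot(is.data.frame(notes))
  if (cutoff_hpa < -24 || cutoff_hpa > 48)
    stop("assemble_document: cutoff_hpa must lie in [-24, 48]", call. = FALSE)
  sel <- notes[notes$chart_hpa <= cutoff_hpa, , drop = FALSE]
  if (nrow(sel) == 0L) return("")
  paste(sel$text[order(sel$chart_hpa)], collapse = " ")
}

#' Clean and tokenize clinical text
#'
#' Removes de-identification placeholders of the form `[** ... **]`,
#' lowercases the remainder, and splits on any non-alphanumeric run.
#'
#' @param text Character scalar.
#' @return Character vector of tokens (possibly empty).
#' @export
clean_and_tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character())
  x <- gsub("\\[\\*\\*.*?\\*\\*\\]", " ", text, perl = TRUE)
  x <- tolower(x)
  toks <- strsplit(x, "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a token vocabulary from a training corpus
#'
#' Maps every token occurring at least `min_count` times to a dense id;
#' all other tokens fall to a shared unknown id. Two ids are reserved:
#' `pad_id` (1), whose embedding row stays all-zero, and `unk_id` (2).
#' The corpus should come from training folds only so that no test text
#' influences the token inventory.
#'
#' @param corpus List of token vectors (one per training document).
#' @param min_count Minimum corpus frequency for a token to get its own id
#'   (default 3).
#' @return A `drg_vocab`: list with `token_ids` (named integer vector),
#'   `counts`, `min_count`, `pad_id`, `unk_id`, and `size` (total id count
#'   including the two reserved ids).
#' @export
build_vocab <- function(corpus, min_count = 3L) {
  if (length(corpus) == 0L)
    stop("build_vocab: empty corpus", call. = FALSE)
  all_tokens <- unlist(corpus, use.names = FALSE)
  if (length(all_tokens) == 0L)
    stop("build_vocab: corpus contains no tokens", call. = FALSE)
  counts <- table(all_tokens)
  keep <- sort(names(counts)[counts >= min_count])
  token_ids <- if (length(keep)) stats::setNames(seq_along(keep) + 2L, keep)
               else stats::setNames(integer(), character())
  structure(list(token_ids = token_ids,
                 counts = as.integer(counts[keep]),
                 min_count = as.integer(min_count),
                 pad_id = 1L, unk_id = 2L,
                 size = length(keep) + 2L),
            class = "drg_vocab")
}

#' Encode a token sequence to a fixed-length id vector
#'
#' Tokens are mapped through the vocabulary (unknowns to `unk_id`), head
#' truncated to `max_len` (the earliest text is kept — the text actually
#' available first in an early-prediction setting), and right-padded with
#' `pad_id`.
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `drg_vocab`.
#' @param max_len Sequence length (default 2000).
#' @param stay_id,cutoff_hpa Optional provenance carried on the result.
#' @param truncate `"head"` (default) keeps the first `max_len` tokens;
#'   `"tail"` keeps the last.
#' @return A `drg_encoded_doc`: list with `token_ids` (length `max_len`),
#'   `true_length`, `stay_id`, `cutoff_hpa`.
#' @export
encode <- function(tokens, vocab, max_len = 2000L,
                   stay_id = NA_character_, cutoff_hpa = NA_real_,
                   truncate = c("head", "tail")) {
  stopifnot(inherits(vocab, "drg_vocab"), max_len >= 1L)
  truncate <- match.arg(truncate)
  ids <- unname(vocab$token_ids[tokens])
  ids[is.na(ids)] <- vocab$unk_id
  n <- length(ids)
  if (n > max_len)
    ids <- if (truncate == "head") ids[seq_len(max_len)]
           else ids[(n - max_len + 1L):n]
  true_length <- length(ids)
  if (true_length < max_len)
    ids <- c(ids, rep(vocab$pad_id, max_len - true_length))
  structure(list(token_ids = as.integer(ids),
                 true_length = as.integer(true_length),
                 stay_id = stay_id, cutoff_hpa = cutoff_hpa),
            class = "drg_encoded_doc")
}

#' Decode an encoded document back to tokens
#'
#' Inverse of [encode()] for in-vocabulary inputs; unknown and pad ids
#' decode to `"<unk>"` and are dropped beyond `true_length`.
#'
#' @param doc A `drg_encoded_doc`.
#' @param vocab The `drg_vocab` used to encode it.
#' @return Character vector of tokens of length `true_length`.
#' @export
decode <- function(doc, vocab) {
  stopifnot(inherits(doc, "drg_encoded_doc"), inherits(vocab, "drg_vocab"))
  inv <- character(vocab$size)
  inv[vocab$pad_id] <- "<pad>"
  inv[vocab$unk_id] <- "<unk>"
  inv[vocab$token_ids] <- names(vocab$token_ids)
  ids <- doc$token_ids[seq_len(doc$true_length)]
  inv[ids]
}

#' Write / read a vocabulary as TSV
#'
#' @param vocab A `drg_vocab`.
#' @param path File path for the TSV (`token`, `id`, `count`).
#' @return `write_vocab`: the path, invisibly. `read_vocab`: a `drg_vocab`.
#' @export
write_vocab <- function(vocab, path) {
  df <- data.frame(token = names(vocab$token_ids),
                   id = unname(vocab$token_ids),
                   count = vocab$counts, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t",
                                        colClasses = list(character = "token")))
  structure(list(token_ids = stats::setNames(as.integer(df$id), df$token),
                 counts = as.integer(df$count),
                 min_count = NA_integer_,
                 pad_id = 1L, unk_id = 2L,
                 size = nrow(df) + 2L),
            class = "drg_vocab")
}

# Assemble + tokenize + encode every stay of a population at one cutoff.
# Returns a list of drg_encoded_doc in the row order of `stays`.
encode_population <- function(stays, notes, vocab, cutoff_hpa, max_len = 2000L) {
  note_split <- split(notes[c("chart_hpa", "text")], notes$stay_id)
  lapply(seq_len(nrow(stays)), function(i) {
    sid <- stays$stay_id[i]
    nd <- note_split[[sid]]
    txt <- if (is.null(nd)) "" else assemble_document(nd, cutoff_hpa)
    encode(clean_and_tokenize(txt), vocab, max_len = max_len,
           stay_id = sid, cutoff_hpa = cutoff_hpa)
  })
}

# Tokenized corpus for a set of stays at a cutoff (used for vocab building).
tokenize_population <- function(stays, notes, cutoff_hpa = 48) {
  note_split <- split(notes[c("chart_hpa", "text")], notes$stay_id)
  lapply(stays$stay_id, function(sid) {
    nd <- note_split[[sid]]
    if (is.null(nd)) return(character())
    clean_and_tokenize(assemble_document(nd, cutoff_hpa))
  })
}
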