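#' Train a PV-DM document embedder on tokenized RNA sequences
#'
#' Trains a distributed-memory paragraph-vector (PV-DM) model with negative
#' sampling on a corpus of token lists (typically overlapping 3-mers from
#' [tokenize_kmers()]). The context for a centre token is the mean of its
#' window word vectors and the document vector; word and output matrices are
#' learned jointly with per-document vectors. Training is single-threaded and
#' fully reproducible for a fixed `seed`.
#'
#' @param corpus List of character vectors of tokens (one per document), or a
#'   character vector of raw sequences that will be tokenized with 3-mers.
#' @param dim Embedding dimension; the conventional choices here are 128 for
#'   lncRNAs and 64 for miRNAs.
#' @param window Context half-window in tokens (default 5).
#' @param epochs Training epochs (default 40).
#' @param negative Negative samples per positive (default 5).
#' @param alpha,min_alpha Linearly decayed learning rate (defaults 0.025 to 1e-4).
#' @param seed Integer seed.
#' @return An object of class `doc2vec` with the learned matrices and the
#'   training vocabulary; use [infer_doc_vector()] to embed new sequences and
#'   `object$doc` (column per document) for the training documents.
#' @export
train_doc_embedder <- function(corpus, dim, window = 5L, epochs = 40L,
                               negative = 5L, alpha = 0.025, min_alpha = 1e-4,
                               seed = 1L) {
  if (length(corpus) == 0L) stop_input("empty corpus")
  if (is.character(corpus)) corpus <- lapply(corpus, tokenize_kmers)
  if (!all(vapply(corpus, is.character, logical(1))))
    stop_input("corpus must be a list of token character vectors")
  if (any(lengths(corpus) == 0L)) stop_input("corpus contains an empty document")
  vocab <- sort(unique(unlist(corpus, use.names = FALSE)))
  docs <- lapply(corpus, function(tk) match(tk, vocab) - 1L)
  fit <- cpp_pvdm_train(docs, length(vocab), as.integer(dim),
                        as.integer(window), as.integer(epochs),
                        as.integer(negative), alpha, min_alpha,
                        as.integer(seed))
  doc <- fit$doc
  colnames(doc) <- names(corpus)
  structure(list(vocab = vocab, dim = as.integer(dim),
                 word = fit$word, out = fit$out, counts = fit$counts,
                 doc = doc, window = as.integer(window),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 alpha = alpha, min_alpha = min_alpha,
                 seed = as.integer(seed)),
            class = "doc2vec")
}

#' Infer the document vector of a sequence from a trained embedder
#'
#' Tokenizes the sequence into 3-mers and trains a fresh document vector
#' against the frozen word/output matrices of the embedder (standard PV-DM
#' inference). Because a single vector is fitted against fixed matrices,
#' inference uses more passes and a higher starting rate than training gives
#' each document, mirroring common doc2vec practice. Deterministic for a
#' fixed embedder and seed.
#'
#' @param embedder A `doc2vec` object from [train_doc_embedder()].
#' @param seq Canonical A/C/G/T sequence (length >= 3).
#' @param epochs Inference epochs (default: at least 50, or the embedder's
#'   training epochs if larger).
#' @param alpha Starting learning rate (default: at least 0.05).
#' @param seed Integer seed (default: the embedder's seed).
#' @return Numeric vector of length `embedder$dim`.
#' @export
infer_doc_vector <- function(embedder, seq, epochs = NULL, alpha = NULL,
                             seed = NULL) {
  if (!inherits(embedder, "doc2vec")) stop_input("not a trained doc2vec embedder")
  tokens <- tokenize_kmers(seq)
  ids <- match(tokens, embedder$vocab) - 1L
  if (anyNA(ids)) {
    warning(sprintf("%d token(s) outside the training vocabulary were dropped",
                    sum(is.na(ids))), call. = FALSE)
    ids <- ids[!is.na(ids)]
    if (length(ids) == 0L) stop_input("no in-vocabulary tokens to infer from")
  }
  cpp_pvdm_infer(ids, embedder$word, embedder$out, embedder$counts,
                 embedder$window,
                 as.integer(epochs %||% max(50L, embedder$epochs)),
                 embedder$negative, alpha %||% max(0.05, embedder$alpha),
                 embedder$min_alpha, as.integer(seed %||% embedder$seed))
}

#' @export
print.doc2vec <- function(x, ...) {
  cat(sprintf("PV-DM embedder: dim %d, vocab %d, %d training docs, window %d, %d epochs\n",
              x$dim, length(x$vocab), ncol(x$doc), x$window, x$epochs))
  invisible(x)
}
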