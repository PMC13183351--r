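#' Train subword static embeddings
#'
#' Context-independent word vectors built from character n-grams, so that
#' morphologically related and unseen forms share structure. A word is the
#' bag of its boundary-marked character n-grams (plus the whole word); each
#' n-gram is assigned the pooled context co-occurrence counts of the words
#' containing it, the n-gram--context matrix is PPMI-weighted, reduced by
#' truncated SVD, and a word vector is the mean of its n-gram vectors.
#' Out-of-vocabulary words still receive a vector through their known
#' n-grams. The procedure is fully deterministic; `seed` is accepted for
#' interface symmetry and recorded.
#'
#' @param corpus An `rp_role_dataset` or list/vector of token sequences.
#' @param dim Embedding dimension.
#' @param ngram Integer pair: min and max character n-gram length.
#' @param window Symmetric context window in tokens.
#' @param min_tokens Minimum corpus size for a meaningful fit.
#' @param seed Recorded on the table (the fit itself has no randomness).
#' @return Object of class `rp_static_table`.
#' @export
train_static_embeddings <- function(corpus, dim = 32, ngram = c(3, 5),
                                    window = 2, min_tokens = 20, seed = 1) {
  seqs <- if (inherits(corpus, "rp_role_dataset"))
    lapply(corpus$utterances, `[[`, "tokens") else
      if (is.list(corpus)) corpus else strsplit(corpus, "[ \t\n]+")
  ntok <- sum(lengths(seqs))
  if (ntok == 0) rp_error("rp_empty_corpus", "cannot train on an empty corpus")
  if (ntok < min_tokens)
    rp_error("rp_corpus_too_small", "corpus has %d tokens < minimum %d", ntok, min_tokens)
  types <- sort(unique(unlist(seqs)))
  ti <- seq_along(types); names(ti) <- types
  # word x context co-occurrence within the window
  Cw <- matrix(0, length(types), length(types), dimnames = list(types, types))
  for (s in seqs) {
    n <- length(s)
    if (n < 2L) next
    id <- ti[s]
    for (off in seq_len(min(window, n - 1L))) {
      a <- id[seq_len(n - off)]; b <- id[seq.int(off + 1L, n)]
      for (k in seq_along(a)) {
        Cw[a[k], b[k]] <- Cw[a[k], b[k]] + 1
        Cw[b[k], a[k]] <- Cw[b[k], a[k]] + 1
      }
    }
  }
  grams_of <- lapply(types, word_ngrams, ngram[1], ngram[2])
  grams <- sort(unique(unlist(grams_of)))
  G <- matrix(0, length(grams), length(types), dimnames = list(grams, types))
  for (w in seq_along(types)) {
    gs <- grams_of[[w]]
    G[gs, ] <- G[gs, , drop = FALSE] + matrix(Cw[w, ], length(gs), length(types), byrow = TRUE)
  }
  tot <- sum(G)
  if (tot == 0) rp_error("rp_corpus_too_small", "no co-occurrences within the window")
  pr <- rowSums(G) / tot; pc <- colSums(G) / tot
  P <- G / tot
  M <- log2(pmax(P, 1e-12) / (pr %o% pc))
  M[M < 0 | P == 0] <- 0
  k <- min(dim, nrow(M) - 1L, ncol(M) - 1L)
  sv <- svd(M, nu = k, nv = 0)
  U <- sv$u * rep(sqrt(sv$d[seq_len(k)]), each = nrow(M))
  # fix SVD sign indeterminacy for exact reproducibility
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  if (k < dim) U <- cbind(U, matrix(0, nrow(U), dim - k))
  rownames(U) <- grams
  structure(list(ngram_vectors = U, dim = dim, ngram = ngram,
                 window = window, seed = seed, vocab = types),
            class = "rp_static_table")
}

word_ngrams <- function(word, nmin, nmax) {
  w <- paste0("<", word, ">")
  n <- nchar(w)
  out <- w
  for (len in nmin:nmax) {
    if (len > n) break
    out <- c(out, substring(w, seq_len(n - len + 1L), seq_len(n - len + 1L) + len - 1L))
  }
  unique(out)
}

#' @export
print.rp_static_table <- function(x, ...) {
  cat(sprintf("<rp_static_table> dim %d, %d n-grams (%d-%d), %d word types\n",
              x$dim, nrow(x$ngram_vectors), x$ngram[1], x$ngram[2],
              length(x$vocab)))
  invisible(x)
}

#' Static vector of one word
#'
#' Mean of the word's known character n-gram vectors; identical across all
#' contexts by construction. Words sharing no n-gram with the training
#' corpus map to the zero vector.
#'
#' @param table An `rp_static_table`.
#' @param word Surface form.
#' @return Numeric vector of length `table$dim`.
#' @export
embed_word_static <- function(table, word) {
  gs <- word_ngrams(word, table$ngram[1], table$ngram[2])
  gs <- gs[gs %in% rownames(table$ngram_vectors)]
  if (!length(gs)) return(numeric(table$dim))
  colMeans(table$ngram_vectors[gs, , drop = FALSE])
}

#' Static embedding of an argument span
#'
#' Mean of the per-word static vectors over the span tokens (the same
#' averaging convention as the contextual representation).
#'
#' @param table An `rp_static_table`.
#' @param span_tokens Character vector: the span's tokens.
#' @return Numeric vector of length `table$dim`.
#' @export
embed_argument_static <- function(table, span_tokens) {
  if (!length(span_tokens)) return(numeric(table$dim))
  rowMeans(vapply(span_tokens, function(w) embed_word_static(table, w),
                  numeric(table$dim)))
}

#' Static embeddings for every argument instance of a dataset
#' @param table An `rp_static_table`.
#' @param dataset An `rp_role_dataset`.
#' @return Numeric matrix, one row per instance.
#' @export
embed_arguments_static <- function(table, dataset) {
  ins <- dataset$instances
  out <- matrix(0, nrow(ins), table$dim)
  for (i in seq_len(nrow(ins)))
    out[i, ] <- embed_argument_static(table, strsplit(ins$surface[i], " ", fixed = TRUE)[[1]])
  out
}
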