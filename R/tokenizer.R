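#' Train a byte-pair-encoding subword tokenizer
#'
#' Standard BPE over the word types of a training corpus: the base
#' vocabulary is the character inventory plus the special tokens `<pad>`,
#' `<mask>` and `<unk>`; merges of the most frequent adjacent symbol pair
#' are added until `vocab_size` is reached or no pair repeats. Fitting uses
#' the training corpus only; unseen words at encode time fall back to
#' characters (unknown characters to `<unk>`).
#'
#' @param texts Character vector of whitespace-tokenised utterances, or a
#'   list of token vectors, or an `rp_role_dataset`.
#' @param vocab_size Maximum vocabulary size including specials.
#' @return Object of class `rp_bpe_tokenizer` with `vocab`, `merges` and the
#'   special-token ids.
#' @export
train_bpe <- function(texts, vocab_size = 512) {
  words <- corpus_words(texts)
  freq <- table(words)
  types <- names(freq)
  f <- as.numeric(freq)
  segs <- strsplit(types, "")
  chars <- sort(unique(unlist(segs)))
  specials <- c("<pad>", "<mask>", "<unk>")
  vocab <- c(specials, chars)
  merges <- character(0)
  # pair keys join the two symbols with a tab, which cannot occur in a token
  while (length(vocab) < vocab_size) {
    pair_counts <- new.env(hash = TRUE)
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      if (length(s) < 2L) next
      for (pr in unique(paste(s[-length(s)], s[-1], sep = "\t"))) {
        cur <- get0(pr, pair_counts, ifnotfound = 0)
        assign(pr, cur + f[k], pair_counts)
      }
    }
    prs <- ls(pair_counts)
    if (!length(prs)) break
    cnt <- vapply(prs, get, 0, envir = pair_counts)
    best <- prs[order(-cnt, prs)][1]  # ties broken lexicographically
    if (cnt[[best]] < 2) break
    ab <- strsplit(best, "\t", fixed = TRUE)[[1]]
    merges <- c(merges, best)
    vocab <- c(vocab, paste0(ab[1], ab[2]))
    segs <- lapply(segs, apply_merge, ab[1], ab[2])
  }
  structure(list(vocab = vocab, merges = merges,
                 pad_id = 1L, mask_id = 2L, unk_id = 3L,
                 cache = new.env(hash = TRUE)),
            class = "rp_bpe_tokenizer")
}

corpus_words <- function(texts) {
  if (inherits(texts, "rp_role_dataset"))
    return(unlist(lapply(texts$utterances, `[[`, "tokens"), use.names = FALSE))
  if (is.list(texts)) return(unlist(texts, use.names = FALSE))
  unlist(strsplit(texts, "[ \t\n]+"), use.names = FALSE)
}

apply_merge <- function(s, a, b) {
  if (length(s) < 2L) return(s)
  repeat {
    i <- which(s[-length(s)] == a & s[-1] == b)
    if (!length(i)) return(s)
    i <- i[1]
    s <- c(if (i > 1) s[1:(i - 1)], paste0(a, b),
           if (i + 1 < length(s)) s[(i + 2):length(s)])
  }
}

# Segment one word with the learned merges (greedy, in merge order).
bpe_segment <- function(tok, word) {
  hit <- get0(word, tok$cache)
  if (!is.null(hit)) return(hit)
  s <- strsplit(word, "")[[1]]
  for (m in tok$merges) {
    ab <- strsplit(m, "\t", fixed = TRUE)[[1]]
    s <- apply_merge(s, ab[1], ab[2])
    if (length(s) == 1L) break
  }
  assign(word, s, tok$cache)
  s
}

#' Encode a token sequence as subword ids
#'
#' @param tok An `rp_bpe_tokenizer`.
#' @param tokens Character vector of surface tokens (one utterance).
#' @return List with `ids` (integer subword ids) and `token_index` (0-based
#'   index of the word each subword was split from, aligning subwords back
#'   to token spans).
#' @export
bpe_encode <- function(tok, tokens) {
  ids <- integer(0); t_ix <- integer(0)
  for (w in seq_along(tokens)) {
    pieces <- bpe_segment(tok, tokens[w])
    pid <- match(pieces, tok$vocab)
    pid[is.na(pid)] <- tok$unk_id
    ids <- c(ids, pid)
    t_ix <- c(t_ix, rep.int(w - 1L, length(pid)))
  }
  list(ids = ids, token_index = t_ix)
}
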