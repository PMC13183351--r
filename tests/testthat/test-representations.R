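test_that("BPE segmentation reconstructs words and aligns subwords to tokens", {
  d <- generate_corpus(default_register_spec("russian_like"), 300, seed = 5)
  tok <- train_bpe(d, vocab_size = 120)
  words <- unique(unlist(lapply(d$utterances, `[[`, "tokens")))
  for (w in sample(words, 30)) {
    segs <- regiprobe:::bpe_segment(tok, w)
    expect_equal(paste(segs, collapse = ""), w)
  }
  enc <- bpe_encode(tok, c("mama", "vidit", "krug"))
  expect_equal(sort(unique(enc$token_index)), 0:2)
  expect_equal(length(enc$ids), length(enc$token_index))
  # unseen words fall back to known subword pieces, not failures
  enc2 <- bpe_encode(tok, "mamamama")
  expect_true(all(enc2$ids > 0))
})

test_that("masked-LM training lowers the loss and is reproducible", {
  d <- generate_corpus(default_register_spec("russian_like"), 600, seed = 8)
  cfg <- tiny_encoder_cfg()
  enc1 <- train_masked_lm(d, cfg)
  expect_lt(enc1$loss[length(enc1$loss)], enc1$loss[1])
  enc2 <- train_masked_lm(d, cfg)
  ins <- d$instances[1:5, ]
  for (i in seq_len(nrow(ins))) {
    u <- d$utterances[[ins$utterance_id[i]]]
    v1 <- embed_argument_contextual(enc1, u, c(ins$span_start[i], ins$span_end[i]))
    v2 <- embed_argument_contextual(enc2, u, c(ins$span_start[i], ins$span_end[i]))
    expect_lt(max(abs(v1 - v2)), 1e-10)
  }
  expect_error(train_masked_lm(list(), cfg), class = "rp_empty_corpus")
  expect_error(train_masked_lm(list(c("a", "b")), cfg), class = "rp_empty_corpus")
})

test_that("analytic gradients of the encoder match finite differences", {
  cfg <- encoder_config(vocab_size = 24, dim = 8, n_layers = 2, n_heads = 2,
                        ff_mult = 2, max_len = 6, epochs = 1, batch_size = 2)
  set.seed(42)
  p <- regiprobe:::init_mlm_params(cfg, 14)
  ids <- matrix(sample(4:14, 15, TRUE), 3, 5)
  padmask <- matrix(FALSE, 3, 5); padmask[2, 5] <- TRUE; ids[2, 5] <- 1L
  msk <- matrix(FALSE, 3, 5); msk[1, 2] <- msk[2, 3] <- msk[3, 5] <- TRUE
  ids_in <- ids; ids_in[msk] <- 2L
  sel <- which(as.vector(msk)); targets <- as.vector(ids)[sel]
  fwd <- function(p) {
    cache <- regiprobe:::mlm_forward(p, cfg, ids_in, padmask)
    regiprobe:::mlm_loss_backward(p, cfg, cache, sel, targets)$loss
  }
  cache <- regiprobe:::mlm_forward(p, cfg, ids_in, padmask)
  g <- regiprobe:::mlm_loss_backward(p, cfg, cache, sel, targets)$grads
  eps <- 1e-5
  for (nm in c("E", "Pm", "L1.Wq", "L1.g1", "L2.W2", "L2.bo", "b_out", "gf")) {
    ii <- sample(length(g[[nm]]), 3)
    for (i in ii) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps; fp <- fwd(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; fm <- fwd(p2)
      num <- (fp - fm) / (2 * eps)
      expect_lt(abs(num - g[[nm]][i]) / max(1e-6, abs(num) + abs(g[[nm]][i])),
                1e-4, label = sprintf("gradient of %s[%d]", nm, i))
    }
  }
})

test_that("span embeddings average subword vectors and react to context", {
  d <- generate_corpus(avp_spec(pronoun_prob = 0.5), 600, seed = 12)
  enc <- train_masked_lm(d, tiny_encoder_cfg())
  # single-token argument equals the mean over its own subwords
  ins <- d$instances[d$instances$span_end - d$instances$span_start == 1, ][1, ]
  u <- d$utterances[[ins$utterance_id]]
  e <- bpe_encode(enc$tokenizer, u$tokens)
  H <- regiprobe:::encode_ids_batch(enc, list(e$ids))[[1]]
  in_span <- e$token_index >= ins$span_start & e$token_index < ins$span_end
  expect_equal(embed_argument_contextual(enc, u, c(ins$span_start, ins$span_end)),
               colMeans(H[in_span, , drop = FALSE]), tolerance = 1e-12)
  # the same surface form in different sentences embeds differently
  prons <- d$instances[d$instances$pronoun & d$instances$head_form == "ty", ]
  if (nrow(prons) >= 2) {
    v1 <- embed_argument_contextual(enc, d$utterances[[prons$utterance_id[1]]],
                                    c(prons$span_start[1], prons$span_end[1]))
    v2 <- embed_argument_contextual(enc, d$utterances[[prons$utterance_id[2]]],
                                    c(prons$span_start[2], prons$span_end[2]))
    cosine <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    expect_lt(cosine, 1 - 1e-6)
  }
  # batch extraction agrees with single-utterance extraction
  sub <- d$instances[1:8, ]
  M <- embed_arguments_contextual(enc, d)
  for (i in 1:8) {
    v <- embed_argument_contextual(enc, d$utterances[[sub$utterance_id[i]]],
                                   c(sub$span_start[i], sub$span_end[i]))
    expect_equal(unname(M[i, ]), unname(v), tolerance = 1e-10)
  }
})

test_that("static embeddings are context-invariant, compositional and deterministic", {
  d <- generate_corpus(default_register_spec("russian_like"), 500, seed = 6)
  tab1 <- train_static_embeddings(d, dim = 24)
  tab2 <- train_static_embeddings(d, dim = 24)
  expect_identical(tab1$ngram_vectors, tab2$ngram_vectors)
  # one vector per word type regardless of context
  w <- tab1$vocab[10]
  expect_identical(embed_word_static(tab1, w), embed_word_static(tab1, w))
  # span embedding is the mean of word embeddings
  u <- embed_word_static(tab1, tab1$vocab[5])
  v <- embed_word_static(tab1, tab1$vocab[6])
  expect_equal(embed_argument_static(tab1, tab1$vocab[5:6]), (u + v) / 2,
               tolerance = 1e-12)
  # an unseen word sharing n-grams gets a finite non-zero vector
  seen <- tab1$vocab[which.max(nchar(tab1$vocab))]
  oov <- paste0(substr(seen, 1, nchar(seen) - 1), "x")
  vo <- embed_word_static(tab1, oov)
  expect_true(all(is.finite(vo)))
  expect_gt(sqrt(sum(vo^2)), 0)
  expect_error(train_static_embeddings(list(c("a", "b"))),
               class = "rp_corpus_too_small")
})
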