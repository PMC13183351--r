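#' Configuration of the contextual encoder
#'
#' Hyperparameters of the small trainable masked-language-model encoder (a
#' pre-norm transformer with tied input/output embeddings). The defaults
#' are a deliberately desk-scale profile suitable for corpora of tens of
#' thousands of tokens on one CPU; all values are recorded on the trained
#' encoder.
#'
#' @param vocab_size Subword vocabulary budget for the BPE tokenizer.
#' @param dim Hidden width (also the embedding width).
#' @param n_layers Number of transformer blocks.
#' @param n_heads Attention heads; must divide `dim`.
#' @param ff_mult Feed-forward width multiplier (inner width = `ff_mult * dim`).
#' @param max_len Maximum subword sequence length (longer inputs error).
#' @param mask_prob Per-subword masking probability during training, in (0,1).
#' @param epochs Training epochs over the corpus.
#' @param batch_size Sequences per optimisation step.
#' @param lr Adam learning rate.
#' @param seed Integer seed governing initialisation, batching and masking.
#' @return A list of class `rp_encoder_config`.
#' @export
encoder_config <- function(vocab_size = 128, dim = 32, n_layers = 2,
                           n_heads = 2, ff_mult = 4, max_len = 40,
                           mask_prob = 0.15, epochs = 16, batch_size = 128,
                           lr = 2e-3, seed = 1) {
  stopifnot(vocab_size > 4, dim > 0, n_layers > 0, n_heads > 0,
            dim %% n_heads == 0, ff_mult > 0, max_len > 1,
            mask_prob > 0, mask_prob < 1, epochs > 0, batch_size > 0, lr > 0)
  structure(list(vocab_size = vocab_size, dim = dim, n_layers = n_layers,
                 n_heads = n_heads, ff_mult = ff_mult, max_len = max_len,
                 mask_prob = mask_prob, epochs = epochs,
                 batch_size = batch_size, lr = lr, seed = seed),
            class = "rp_encoder_config")
}

## ---- parameter handling -------------------------------------------------

init_mlm_params <- function(cfg, vocab_n) {
  d <- cfg$dim; dff <- cfg$ff_mult * d
  rnorm_mat <- function(r, c) matrix(stats::rnorm(r * c, sd = 0.02), r, c)
  p <- list(E = rnorm_mat(vocab_n, d), Pm = rnorm_mat(cfg$max_len, d),
            b_out = numeric(vocab_n),
            gf = rep(1, d), bf = numeric(d))
  for (l in seq_len(cfg$n_layers)) {
    nm <- function(x) sprintf("L%d.%s", l, x)
    p[[nm("Wq")]] <- rnorm_mat(d, d); p[[nm("bq")]] <- numeric(d)
    p[[nm("Wk")]] <- rnorm_mat(d, d); p[[nm("bk")]] <- numeric(d)
    p[[nm("Wv")]] <- rnorm_mat(d, d); p[[nm("bv")]] <- numeric(d)
    p[[nm("Wo")]] <- rnorm_mat(d, d); p[[nm("bo")]] <- numeric(d)
    p[[nm("g1")]] <- rep(1, d); p[[nm("n1")]] <- numeric(d)
    p[[nm("g2")]] <- rep(1, d); p[[nm("n2")]] <- numeric(d)
    p[[nm("W1")]] <- rnorm_mat(d, dff); p[[nm("c1")]] <- numeric(dff)
    p[[nm("W2")]] <- rnorm_mat(dff, d); p[[nm("c2")]] <- numeric(d)
  }
  p
}

addb <- function(M, b) sweep(M, 2L, b, "+")

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  sd <- sqrt(rowMeans(Xc * Xc) + eps)
  Xh <- Xc / sd
  list(Y = addb(Xh * rep(1, nrow(X)) %o% g, b), Xh = Xh, sd = sd)
}

layernorm_bwd <- function(dY, cache, g) {
  Xh <- cache$Xh; sd <- cache$sd
  dg <- colSums(dY * Xh); db <- colSums(dY)
  dXh <- sweep(dY, 2L, g, "*")
  dX <- (dXh - rowMeans(dXh) - Xh * rowMeans(dXh * Xh)) / sd
  list(dX = dX, dg = dg, db = db)
}

gelu_fwd <- function(X) X * stats::pnorm(X)
gelu_bwd <- function(dY, X) dY * (stats::pnorm(X) + X * stats::dnorm(X))

## ---- forward / backward -------------------------------------------------

# Activations are (B*L) x d matrices, position-major: the rows of position i
# are ((i-1)*B+1):(i*B). `padmask` is B x L, TRUE at padding.
mlm_forward <- function(p, cfg, ids, padmask) {
  B <- nrow(ids); L <- ncol(ids); d <- cfg$dim
  nh <- cfg$n_heads; dh <- d / nh
  ps <- function(i) ((i - 1L) * B + 1L):(i * B)
  X <- p$E[as.vector(ids), , drop = FALSE] + p$Pm[rep(seq_len(L), each = B), , drop = FALSE]
  cache <- list(ids = ids, padmask = padmask, B = B, L = L, layers = vector("list", cfg$n_layers))
  for (l in seq_len(cfg$n_layers)) {
    nm <- function(x) sprintf("L%d.%s", l, x)
    ln1 <- layernorm_fwd(X, p[[nm("g1")]], p[[nm("n1")]])
    Q <- addb(ln1$Y %*% p[[nm("Wq")]], p[[nm("bq")]])
    K <- addb(ln1$Y %*% p[[nm("Wk")]], p[[nm("bk")]])
    V <- addb(ln1$Y %*% p[[nm("Wv")]], p[[nm("bv")]])
    C <- matrix(0, B * L, d)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      S <- array(0, c(B, L, L))
      for (i in seq_len(L)) {
        Qi <- Q[ps(i), hc, drop = FALSE]
        for (j in seq_len(L))
          S[, i, j] <- rowSums(Qi * K[ps(j), hc, drop = FALSE]) / sqrt(dh)
      }
      for (j in seq_len(L)) if (any(padmask[, j])) S[padmask[, j], , j] <- -1e30
      A <- array(0, c(B, L, L))
      for (i in seq_len(L)) {
        Si <- S[, i, , drop = TRUE]
        if (is.null(dim(Si))) Si <- matrix(Si, B, L)
        Si <- Si - apply(Si, 1L, max)
        Ei <- exp(Si)
        A[, i, ] <- Ei / rowSums(Ei)
      }
      for (i in seq_len(L)) {
        Ci <- matrix(0, B, dh)
        for (j in seq_len(L))
          Ci <- Ci + A[, i, j] * V[ps(j), hc, drop = FALSE]
        C[ps(i), hc] <- Ci
      }
      A_heads[[h]] <- A
    }
    O <- addb(C %*% p[[nm("Wo")]], p[[nm("bo")]])
    X2 <- X + O
    ln2 <- layernorm_fwd(X2, p[[nm("g2")]], p[[nm("n2")]])
    Z1 <- addb(ln2$Y %*% p[[nm("W1")]], p[[nm("c1")]])
    Hf <- gelu_fwd(Z1)
    Fo <- addb(Hf %*% p[[nm("W2")]], p[[nm("c2")]])
    Xout <- X2 + Fo
    cache$layers[[l]] <- list(X = X, ln1 = ln1, Q = Q, K = K, V = V,
                              A = A_heads, C = C, X2 = X2, ln2 = ln2,
                              Z1 = Z1, Hf = Hf)
    X <- Xout
  }
  lnf <- layernorm_fwd(X, p$gf, p$bf)
  cache$Xtop <- X; cache$lnf <- lnf
  cache$H <- lnf$Y
  cache
}

# Cross-entropy at the selected rows; returns loss and the full backward
# pass as a flat gradient list.
mlm_loss_backward <- function(p, cfg, cache, sel_rows, targets) {
  B <- cache$B; L <- cache$L; d <- cfg$dim
  nh <- cfg$n_heads; dh <- d / nh
  ps <- function(i) ((i - 1L) * B + 1L):(i * B)
  Hm <- cache$H[sel_rows, , drop = FALSE]
  Z <- addb(Hm %*% t(p$E), p$b_out)
  Z <- Z - apply(Z, 1L, max)
  P <- exp(Z); P <- P / rowSums(P)
  M <- length(targets)
  loss <- -mean(log(pmax(P[cbind(seq_len(M), targets)], 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(M), targets)] <- dZ[cbind(seq_len(M), targets)] - 1
  dZ <- dZ / M
  g <- list()
  g$b_out <- colSums(dZ)
  g$E <- t(dZ) %*% Hm          # head contribution (tied embeddings)
  dH <- matrix(0, B * L, d)
  dH[sel_rows, ] <- dZ %*% p$E
  lb <- layernorm_bwd(dH, cache$lnf, p$gf)
  g$gf <- lb$dg; g$bf <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    nm <- function(x) sprintf("L%d.%s", l, x)
    cl <- cache$layers[[l]]
    # FFN branch
    dFo <- dX
    g[[nm("c2")]] <- colSums(dFo)
    g[[nm("W2")]] <- t(cl$Hf) %*% dFo
    dHf <- dFo %*% t(p[[nm("W2")]])
    dZ1 <- gelu_bwd(dHf, cl$Z1)
    g[[nm("c1")]] <- colSums(dZ1)
    g[[nm("W1")]] <- t(cl$ln2$Y) %*% dZ1
    dY2 <- dZ1 %*% t(p[[nm("W1")]])
    lb2 <- layernorm_bwd(dY2, cl$ln2, p[[nm("g2")]])
    g[[nm("g2")]] <- lb2$dg; g[[nm("n2")]] <- lb2$db
    dX2 <- dX + lb2$dX
    # attention branch
    dO <- dX2
    g[[nm("bo")]] <- colSums(dO)
    g[[nm("Wo")]] <- t(cl$C) %*% dO
    dC <- dO %*% t(p[[nm("Wo")]])
    dQ <- matrix(0, B * L, d); dK <- matrix(0, B * L, d); dV <- matrix(0, B * L, d)
    for (h in seq_len(nh)) {
      hc <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cl$A[[h]]
      dA <- array(0, c(B, L, L))
      for (i in seq_len(L)) {
        dCi <- dC[ps(i), hc, drop = FALSE]
        for (j in seq_len(L)) {
          dA[, i, j] <- rowSums(dCi * cl$V[ps(j), hc, drop = FALSE])
          dV[ps(j), hc] <- dV[ps(j), hc] + A[, i, j] * dCi
        }
      }
      for (i in seq_len(L)) {
        Ai <- matrix(A[, i, ], B, L)
        dAi <- matrix(dA[, i, ], B, L)
        dSi <- Ai * (dAi - rowSums(dAi * Ai))
        dQi <- matrix(0, B, dh)
        for (j in seq_len(L)) {
          dQi <- dQi + dSi[, j] * cl$K[ps(j), hc, drop = FALSE] / sqrt(dh)
          dK[ps(j), hc] <- dK[ps(j), hc] +
            dSi[, j] * cl$Q[ps(i), hc, drop = FALSE] / sqrt(dh)
        }
        dQ[ps(i), hc] <- dQi
      }
    }
    g[[nm("bq")]] <- colSums(dQ); g[[nm("Wq")]] <- t(cl$ln1$Y) %*% dQ
    g[[nm("bk")]] <- colSums(dK); g[[nm("Wk")]] <- t(cl$ln1$Y) %*% dK
    g[[nm("bv")]] <- colSums(dV); g[[nm("Wv")]] <- t(cl$ln1$Y) %*% dV
    dY1 <- dQ %*% t(p[[nm("Wq")]]) + dK %*% t(p[[nm("Wk")]]) + dV %*% t(p[[nm("Wv")]])
    lb1 <- layernorm_bwd(dY1, cl$ln1, p[[nm("g1")]])
    g[[nm("g1")]] <- lb1$dg; g[[nm("n1")]] <- lb1$db
    dX <- dX2 + lb1$dX
  }
  # embedding lookups
  ids_vec <- as.vector(cache$ids)
  dE_emb <- rowsum(dX, ids_vec)
  idx <- as.integer(rownames(dE_emb))
  g$E[idx, ] <- g$E[idx, ] + dE_emb
  dPm <- rowsum(dX, rep(seq_len(L), each = B))
  g$Pm <- matrix(0, nrow(p$Pm), d)
  g$Pm[as.integer(rownames(dPm)), ] <- dPm
  list(loss = loss, grads = g)
}

adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^t)
    vhat <- st$v[[nm]] / (1 - beta2^t)
    p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(p = p, st = st)
}

## ---- training -----------------------------------------------------------

#' Train the masked-language-model encoder
#'
#' Fits a BPE tokenizer on the training corpus, then trains a small
#' transformer encoder with the masked-token prediction objective (a random
#' subset of subwords is replaced by `<mask>` and must be predicted from the
#' remaining context). The returned encoder is frozen: encoding is fully
#' deterministic. Training is deterministic given `config$seed`.
#'
#' @param corpus An `rp_role_dataset` or list of token vectors.
#' @param config An [encoder_config()].
#' @param quiet Suppress per-epoch loss messages.
#' @return Object of class `rp_contextual_encoder` with the tokenizer,
#'   parameters, config and per-epoch mean training `loss` trajectory.
#' @export
train_masked_lm <- function(corpus, config = encoder_config(), quiet = TRUE) {
  seqs_tok <- if (inherits(corpus, "rp_role_dataset"))
    lapply(corpus$utterances, `[[`, "tokens") else corpus
  if (!length(seqs_tok)) rp_error("rp_empty_corpus", "cannot train on an empty corpus")
  tok <- train_bpe(seqs_tok, config$vocab_size)
  seqs <- lapply(seqs_tok, function(tt) bpe_encode(tok, tt)$ids)
  seqs <- seqs[lengths(seqs) >= 2L & lengths(seqs) <= config$max_len]
  if (length(seqs) < config$batch_size)
    rp_error("rp_empty_corpus", "corpus smaller than one batch (%d usable sequences)",
             length(seqs))
  vocab_n <- length(tok$vocab)
  losses <- numeric(config$epochs)
  p <- NULL
  with_seed(config$seed, {
    p <- init_mlm_params(config, vocab_n)
    st <- list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0))
    t_step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(length(seqs))                  # shuffle, then stable
      ord <- ord[order(lengths(seqs)[ord])]            # length-sort for padding
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      bl <- 0; nmask <- 0L
      for (bix in sample(seq_along(batches))) {
        b <- batches[[bix]]
        B <- length(b)
        L <- max(lengths(seqs[b]))
        ids <- matrix(tok$pad_id, B, L)
        for (k in seq_len(B)) ids[k, seq_along(seqs[[b[k]]])] <- seqs[[b[k]]]
        padmask <- matrix(rep(seq_len(L), each = B) >
                            rep(lengths(seqs[b]), L), B, L)
        msk <- matrix(stats::runif(B * L) < config$mask_prob, B, L) & !padmask
        for (k in which(rowSums(msk) == 0L))           # at least one mask per sequence
          msk[k, sample.int(lengths(seqs[b])[k], 1L)] <- TRUE
        ids_in <- ids
        ids_in[msk] <- tok$mask_id
        sel <- which(as.vector(msk))
        targets <- as.vector(ids)[sel]
        cache <- mlm_forward(p, config, ids_in, padmask)
        out <- mlm_loss_backward(p, config, cache, sel, targets)
        t_step <- t_step + 1L
        upd <- adam_step(p, out$grads, st, config$lr, t_step)
        p <- upd$p; st <- upd$st
        bl <- bl + out$loss * length(targets)
        nmask <- nmask + length(targets)
      }
      losses[ep] <- bl / nmask  # mean masked-token cross-entropy, nats
      if (!quiet) message(sprintf("epoch %d mean loss %.4f", ep, losses[ep]))
    }
  })
  structure(list(tokenizer = tok, params = p, config = config, loss = losses),
            class = "rp_contextual_encoder")
}

#' @export
print.rp_contextual_encoder <- function(x, ...) {
  cat(sprintf("<rp_contextual_encoder> dim %d, %d layers, %d heads, vocab %d\n",
              x$config$dim, x$config$n_layers, x$config$n_heads,
              length(x$tokenizer$vocab)))
  cat(sprintf("  training loss: %.3f -> %.3f over %d epochs\n",
              x$loss[1], x$loss[length(x$loss)], length(x$loss)))
  invisible(x)
}

# Encode a batch of id sequences; returns final-layer hidden states as a
# list of (len x dim) matrices.
encode_ids_batch <- function(encoder, seqs) {
  cfg <- encoder$config; p <- encoder$params
  out <- vector("list", length(seqs))
  ord <- order(lengths(seqs))
  chunks <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
  for (ch in chunks) {
    B <- length(ch); L <- max(lengths(seqs[ch]))
    ids <- matrix(encoder$tokenizer$pad_id, B, L)
    for (k in seq_len(B)) ids[k, seq_along(seqs[[ch[k]]])] <- seqs[[ch[k]]]
    padmask <- matrix(rep(seq_len(L), each = B) > rep(lengths(seqs[ch]), L), B, L)
    cache <- mlm_forward(p, cfg, ids, padmask)
    for (k in seq_len(B)) {
      n <- lengths(seqs[ch])[k]
      rows <- (seq_len(n) - 1L) * B + k
      out[[ch[k]]] <- cache$H[rows, , drop = FALSE]
    }
  }
  out
}

#' Contextual embedding of an argument span
#'
#' Encodes the utterance with the frozen encoder and returns the arithmetic
#' mean of the final-layer vectors of all subwords belonging to the span's
#' tokens (single-level averaging; `two_level = TRUE` averages subwords
#' within each word first, then words).
#'
#' @param encoder A trained `rp_contextual_encoder`.
#' @param utt An [utterance()] (or a bare character vector of tokens).
#' @param span 0-based half-open token interval `c(start, end)`.
#' @param two_level Average per word first, then across words.
#' @return Numeric vector of length `dim`.
#' @export
embed_argument_contextual <- function(encoder, utt, span, two_level = FALSE) {
  tokens <- if (inherits(utt, "rp_utterance")) utt$tokens else utt
  enc <- bpe_encode(encoder$tokenizer, tokens)
  if (length(enc$ids) > encoder$config$max_len)
    rp_error("rp_sequence_too_long", "utterance '%s' exceeds the encoder's max length",
             if (inherits(utt, "rp_utterance")) utt$id else "<tokens>")
  H <- encode_ids_batch(encoder, list(enc$ids))[[1]]
  in_span <- enc$token_index >= span[1] & enc$token_index < span[2]
  if (!any(in_span))
    rp_error("rp_span_alignment", "no subwords align with span in utterance '%s'",
             if (inherits(utt, "rp_utterance")) utt$id else "<tokens>")
  if (!two_level) return(colMeans(H[in_span, , drop = FALSE]))
  byword <- rowsum(H[in_span, , drop = FALSE], enc$token_index[in_span])
  counts <- as.vector(table(enc$token_index[in_span]))
  colMeans(byword / counts)
}

#' Contextual embeddings for every argument instance of a dataset
#'
#' Batch-encodes each utterance once and extracts span means, row-aligned
#' with `dataset$instances`.
#'
#' @inheritParams embed_argument_contextual
#' @param dataset An `rp_role_dataset`.
#' @return Numeric matrix, one row per instance.
#' @export
embed_arguments_contextual <- function(encoder, dataset, two_level = FALSE) {
  ids <- names(dataset$utterances)
  encs <- lapply(dataset$utterances, function(u) bpe_encode(encoder$tokenizer, u$tokens))
  too_long <- lengths(lapply(encs, `[[`, "ids")) > encoder$config$max_len
  if (any(too_long))
    rp_error("rp_sequence_too_long", "utterance '%s' exceeds the encoder's max length",
             ids[too_long][1])
  H <- encode_ids_batch(encoder, lapply(encs, `[[`, "ids"))
  names(H) <- ids
  ins <- dataset$instances
  out <- matrix(0, nrow(ins), encoder$config$dim)
  for (i in seq_len(nrow(ins))) {
    e <- encs[[ins$utterance_id[i]]]
    in_span <- e$token_index >= ins$span_start[i] & e$token_index < ins$span_end[i]
    h <- H[[ins$utterance_id[i]]][in_span, , drop = FALSE]
    out[i, ] <- if (two_level) {
      byword <- rowsum(h, e$token_index[in_span])
      colMeans(byword / as.vector(table(e$token_index[in_span])))
    } else colMeans(h)
  }
  out
}
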