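# Shared fixture builders; everything is generated in code at test time.

tiny_jsonl <- function(path) {
  lines <- c(
    paste0('{"id":"u1","register":"CDS","language":"english","tokens":',
           '["why","did","he","bite","the","horse",",","Anne","?"],',
           '"instances":[{"role":"A","span":[2,3],"verb_lemma":"bite","verb_index":3},',
           '{"role":"P","span":[4,6],"verb_lemma":"bite","verb_index":3}]}'),
    paste0('{"id":"u2","register":"ADS","language":"english","tokens":',
           '["just","write","it","down"],',
           '"instances":[{"role":"P","span":[2,3],"verb_lemma":"write","verb_index":1}]}'))
  writeLines(lines, path)
  path
}

# A register whose word order is degenerate AVP with no omission: position
# fully determines the role.
avp_spec <- function(label = "R1", pronoun_prob = 0.3) {
  register_spec(default_lexicon("russian_like"), default_paradigm("russian_like"),
                c(AVP = 1.0), omission_prob = c(A = 0, P = 0),
                pronoun_prob = pronoun_prob, filler_prob = 0.2, label = label)
}

# Lexicon restricted to non-syncretic (animate-declension) nouns and
# plain accusative verbs: the case vector identifies the role exactly.
bijective_case_spec <- function(label = "R1") {
  lex <- default_lexicon("russian_like")
  lex$nouns <- lex$nouns[lex$nouns$declension == "animate", ]
  lex$verbs <- lex$verbs[lex$verbs$p_case == "ACC" & is.na(lex$verbs$p_prep), ]
  register_spec(lex, default_paradigm("russian_like"),
                c(AVP = 1 / 6, APV = 1 / 6, PAV = 1 / 6, PVA = 1 / 6,
                  VAP = 1 / 6, VPA = 1 / 6),
                omission_prob = c(A = 0, P = 0), pronoun_prob = 0,
                filler_prob = 0.2, label = label)
}

# Fully case-syncretic system: the english-like noun paradigm realises NOM
# and ACC identically, so the case vector carries no role information.
syncretic_case_spec <- function(label = "R1") {
  lex <- default_lexicon("english_like")
  lex$verbs <- lex$verbs[is.na(lex$verbs$p_prep), ]
  register_spec(lex, default_paradigm("english_like"),
                c(AVP = 0.5, PAV = 0.5),
                omission_prob = c(A = 0, P = 0), pronoun_prob = 0,
                filler_prob = 0, label = label)
}

tiny_encoder_cfg <- function(...) {
  encoder_config(vocab_size = 120, dim = 16, n_layers = 2, n_heads = 2,
                 ff_mult = 2, epochs = 3, batch_size = 64, seed = 11, ...)
}

# A hand-built hierarchical fit with fixed coefficients and zeroed random
# effects: lets closed-form contrasts be checked exactly.
fixed_logit_fit <- function(b_intercept = 1, b_register = 1, b_role = 0,
                            b_inter = 0, n_sent = 10) {
  sid <- sprintf("s%02d", seq_len(n_sent))
  rec <- data.frame(sentence_id = rep(sid, each = 2),
                    register = factor(rep(c("ADS", "CDS"), n_sent),
                                      levels = c("ADS", "CDS")),
                    role = factor("A", levels = c("A", "P")),
                    split_id = 1L,
                    correct = 1L)
  fixed <- ~ register * role
  X <- stats::model.matrix(fixed, rec)
  beta_names <- colnames(X)
  draws <- matrix(rep(c(b_intercept, b_register, b_role, b_inter), each = 2),
                  nrow = 2, dimnames = list(NULL, beta_names))
  re_cols <- c(sprintf("u_sent[%d]", seq_len(n_sent)),
               sprintf("w_sent[%d]", seq_len(n_sent)),
               "u_split[1]", "w_split[1]")
  draws <- cbind(draws, matrix(0, 2, length(re_cols),
                               dimnames = list(NULL, re_cols)))
  structure(list(draws = draws, chains = 1L, n_iter = 2L, fixed = fixed,
                 xlev = list(register = c("ADS", "CDS"), role = c("A", "P")),
                 random = "study1", beta_names = beta_names,
                 sent_levels = sid, reg_levels = c("ADS", "CDS"),
                 records = rec, seed = 1L),
            class = "rp_hier_fit")
}
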