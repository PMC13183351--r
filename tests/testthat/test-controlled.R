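test_that("controlled templates realise their intended word orders", {
  lex <- default_lexicon("english_like")
  cs <- generate_controlled_sentences(lex, default_paradigm("english_like"),
                                      condition_spec("english_like"),
                                      seed = 3, max_per_condition = 120)
  wol <- word_order_labels(cs)
  ins <- cs$instances[cs$instances$role == "A", ]
  expect_true(all(wol[ins$utterance_id] == ins$order))
  expect_true(all(ins$order[ins$condition == "fronted"] == "PAV"))
  expect_true(all(ins$order[ins$condition == "relative_clause"] == "PAV"))
  expect_true(all(ins$order[ins$condition == "passive"] == "PVA"))
  expect_true(all(ins$order[ins$condition %in%
                              c("basic", "unprototypical_animacy")] == "AVP"))
  # passives carry the agent in a by-phrase; the by is part of the span
  pas <- cs$instances[cs$instances$condition == "passive" & cs$instances$role == "A", ][1, ]
  toks <- cs$utterances[[pas$utterance_id]]$tokens
  expect_equal(toks[pas$span_start + 1L], "by")
  # animacy flip: unprototypical condition puts humans in P
  lexn <- lex$nouns
  bas <- cs$instances[cs$instances$condition == "basic", ]
  unp <- cs$instances[cs$instances$condition == "unprototypical_animacy", ]
  an_of <- function(forms) lexn$animacy[match(sub("s$", "", forms), lexn$lemma)]
  expect_true(all(an_of(bas$head_form[bas$role == "A" & !bas$pronoun]) == "human"))
  expect_true(all(an_of(unp$head_form[unp$role == "P" & !unp$pronoun]) == "human"))
  # agreement-cue flag marks exactly the number-mismatched clauses
  expect_equal(ins$agr_cue, cs$instances$number[cs$instances$role == "A"] !=
                 cs$instances$number[cs$instances$role == "P"])
})

test_that("russian controlled set crosses syncretism with word order", {
  lex <- default_lexicon("russian_like")
  par <- default_paradigm("russian_like")
  cs <- generate_controlled_sentences(lex, par, condition_spec("russian_like"),
                                      seed = 3, max_per_condition = 250)
  ins <- cs$instances
  expect_setequal(unique(ins$condition),
                  c("non_syncretic", "both_syncretic", "syncretic_A", "syncretic_P"))
  expect_setequal(unique(ins$order),
                  c("AVP", "APV", "PAV", "PVA", "VAP", "VPA"))
  # syncretism labels agree with the case encoder's bit counts
  bpar <- bind_lexicon(par, lex)
  for (i in sample(nrow(ins), 60)) {
    sync <- if (ins$role[i] == "A") ins$sync_A[i] else ins$sync_P[i]
    expect_equal(sync, sum(encode_case(ins$head_form[i], bpar)) > 1L)
  }
  # the doubly syncretic condition always keeps agreement as a cue
  both <- ins[ins$condition == "both_syncretic", ]
  expect_true(all(both$agr_cue))
  # word-order relabelling from spans matches the condition
  wol <- word_order_labels(cs)
  expect_true(all(wol[ins$utterance_id] == ins$order))
})

test_that("study-2 split composition is exact for every seed", {
  lex <- default_lexicon("russian_like")
  cs <- generate_controlled_sentences(lex, default_paradigm("russian_like"),
                                      seed = 5, max_per_condition = 250)
  for (seed in c(1, 9)) {
    sp <- compose_study2_split(cs, "russian_like", seed = seed)
    tst <- cs$instances[sp$test, ]
    counts <- table(unique(tst[, c("utterance_id", "order")])$order)
    expect_equal(as.vector(counts[c("APV", "AVP", "PAV", "PVA", "VAP", "VPA")]),
                 c(52, 24, 18, 2, 2, 2))
    expect_length(sp$train_sentences, 100)
    expect_length(sp$val_sentences, 200)
    tr <- cs$instances[sp$train, ]
    expect_setequal(unique(tr$condition), unique(cs$instances$condition))
    expect_length(intersect(sp$train_sentences, sp$test_sentences), 0)
    expect_length(intersect(sp$val_sentences, sp$test_sentences), 0)
  }
  lexE <- default_lexicon("english_like")
  csE <- generate_controlled_sentences(lexE, default_paradigm("english_like"),
                                       seed = 5, max_per_condition = 120)
  spE <- compose_study2_split(csE, "english_like", seed = 2)
  tstE <- csE$instances[spE$test, ]
  tab <- table(tstE$condition, tstE$role)
  for (cn in c("unprototypical_animacy", "fronted", "relative_clause", "passive")) {
    expect_equal(tab[cn, "A"], 2)
    expect_equal(tab[cn, "P"], 2)
  }
  trE <- csE$instances[spE$train, ]
  expect_setequal(unique(trE$condition), unique(csE$instances$condition))
})

test_that("identical encoders score controlled items identically across registers", {
  d <- generate_corpus(default_register_spec("russian_like"), 700, seed = 15)
  enc <- train_masked_lm(d, tiny_encoder_cfg())
  lex <- default_lexicon("russian_like")
  cs <- generate_controlled_sentences(lex, default_paradigm("russian_like"),
                                      seed = 6, max_per_condition = 150)
  sp <- compose_study2_split(cs, "russian_like", seed = 3)
  rec <- evaluate_generalization(list(CDS = enc, ADS = enc), cs, sp,
                                 probe_config("mlp", seed = 4))
  a <- rec[rec$register == "CDS", ]
  b <- rec[rec$register == "ADS", ]
  expect_identical(a$argument_id, b$argument_id)
  expect_identical(a$correct, b$correct)
})
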