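test_that("JSONL reading reconstructs utterances and instances", {
  f <- tiny_jsonl(withr::local_tempfile(fileext = ".jsonl"))
  d <- read_role_dataset(f)
  expect_length(d$utterances, 2)
  expect_equal(d$utterances$u1$tokens[3], "he")
  i1 <- d$instances[d$instances$utterance_id == "u1", ]
  expect_setequal(i1$role, c("A", "P"))
  expect_equal(i1$surface[i1$role == "A"], "he")
  expect_equal(i1$surface[i1$role == "P"], "the horse")
  expect_setequal(d$verb_inventory, c("bite", "write"))
})

test_that("empty input yields an empty dataset; bad records raise named errors", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), f)
  d <- read_role_dataset(f)
  expect_length(d$utterances, 0)
  expect_equal(nrow(d$instances), 0)
  expect_error(read_role_dataset(file.path(tempdir(), "nope.jsonl")),
               class = "rp_missing_file")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"id":"bad","tokens":["a","b"],"instances":',
                    '[{"role":"A","span":[1,5],"verb_lemma":"x","verb_index":0}]}'), f2)
  err <- tryCatch(read_role_dataset(f2), error = identity)
  expect_s3_class(err, "rp_span_out_of_bounds")
  expect_match(conditionMessage(err), "bad")
  f3 <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(paste0('{"id":"u9","tokens":["a","b"],"instances":',
                    '[{"role":"Q","span":[0,1],"verb_lemma":"x","verb_index":1}]}'), f3)
  expect_error(read_role_dataset(f3), class = "rp_unknown_role")
})

test_that("write then read round-trips a generated dataset record for record", {
  d <- generate_corpus(avp_spec(), 60, seed = 9)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_role_dataset(d, f)
  d2 <- read_role_dataset(f)
  expect_identical(names(d$utterances), names(d2$utterances))
  expect_identical(lapply(d$utterances, `[[`, "tokens"),
                   lapply(d2$utterances, `[[`, "tokens"))
  key <- c("utterance_id", "role", "span_start", "span_end",
           "verb_lemma", "verb_index", "surface")
  expect_equal(d$instances[key], d2$instances[key], ignore_attr = TRUE)
})

test_that("case-frame role mapping follows the frame and flags full omission", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("verb_lemma\trelation\tcase\trole",
               "videt\tnsubj\tNOM\tA",
               "videt\tobj\tACC\tP"), f)
  frames <- read_case_frames(f)
  out <- map_roles_from_frame("u1", c("kot", "videt", "sobaku"),
                              c("nsubj", NA, "obj"), c("NOM", NA, "ACC"),
                              "videt", 1L, frames)
  expect_equal(out$role[order(out$span_start)], c("A", "P"))
  # both arguments omitted: empty, flagged for exclusion
  out2 <- map_roles_from_frame("u2", "videt", NA_character_, NA_character_,
                               "videt", 0L, frames)
  expect_equal(nrow(out2), 0)
  expect_true(attr(out2, "excluded"))
  expect_error(map_roles_from_frame("u3", "x", NA, NA, "unknown", 0L, frames),
               class = "rp_verb_not_in_frames")
  # a frame must assign exactly one A and one P
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("verb_lemma\trelation\tcase\trole", "v\tnsubj\tNOM\tA"), f2)
  expect_error(read_case_frames(f2), class = "rp_bad_frame_table")
})

test_that("CoNLL-U ingestion maps roles through the frame table", {
  ff <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("verb_lemma\trelation\tcase\trole",
               "videt\tnsubj\tNOM\tA", "videt\tobj\tACC\tP"), ff)
  frames <- read_case_frames(ff)
  cu <- withr::local_tempfile(fileext = ".conllu")
  writeLines(c(
    "# sent_id = 1",
    "1\tkot\tkot\tNOUN\t_\tCase=Nom|Number=Sing\t2\tnsubj\t_\t_",
    "2\tvidit\tvidet\tVERB\t_\t_\t0\troot\t_\t_",
    "3\tsobaku\tsobaka\tNOUN\t_\tCase=Acc|Number=Sing\t2\tobj\t_\t_",
    ""), cu)
  d <- read_role_dataset(cu, format = "conllu", frames = frames, register = "ADS")
  expect_equal(nrow(d$instances), 2)
  expect_equal(sort(d$instances$role), c("A", "P"))
  expect_equal(d$instances$surface[d$instances$role == "A"], "kot")
})

test_that("dataset filters enforce the per-verb minimum and are idempotent", {
  d <- generate_corpus(default_register_spec("russian_like"), 400, seed = 2)
  counts <- tapply(d$instances$utterance_id, d$instances$verb_lemma,
                   function(u) length(unique(u)))
  thr <- sort(counts)[[3]]  # a threshold that removes some verbs, keeps others
  fd <- apply_dataset_filters(d, min_per_verb = thr)
  kept <- tapply(fd$instances$utterance_id, fd$instances$verb_lemma,
                 function(u) length(unique(u)))
  expect_true(all(kept >= thr))
  expect_true(any(counts < thr))            # something was actually removed
  fd2 <- apply_dataset_filters(fd, min_per_verb = thr)
  expect_identical(fd$instances, fd2$instances)
  # boundary: a verb with exactly the minimum survives
  expect_true(any(kept == thr) || all(kept > thr))
  # all verbs below an impossible threshold: empty dataset, no error
  fe <- apply_dataset_filters(d, min_per_verb = 1e6)
  expect_equal(nrow(fe$instances), 0)
})

test_that("word-order labeling matches the labelled examples and covers all orders", {
  u <- utterance("t1", c("why", "did", "he", "bite", "the", "horse", ",", "Anne", "?"))
  ins <- rbind(argument_instance("t1", "A", c(2, 3), "bite", 3),
               argument_instance("t1", "P", c(4, 6), "bite", 3))
  expect_equal(label_word_order(u, ins), "AVP")
  u2 <- utterance("t2", c("tak", "ty", "paket", "beri"))
  ins2 <- rbind(argument_instance("t2", "A", c(1, 2), "beri", 3),
                argument_instance("t2", "P", c(2, 3), "beri", 3))
  expect_equal(label_word_order(u2, ins2), "APV")
  u3 <- utterance("t3", c("they", "were", "cooking"))
  ins3 <- argument_instance("t3", "A", c(0, 1), "cook", 2)
  expect_equal(label_word_order(u3, ins3), "AV")
  # permutation coverage: a degenerate spec per order recovers exactly it
  for (o in c("AVP", "APV", "PAV", "PVA", "VAP", "VPA")) {
    wo <- stats::setNames(1, o)
    sp <- register_spec(default_lexicon("russian_like"),
                        default_paradigm("russian_like"), wo,
                        omission_prob = c(A = 0, P = 0), pronoun_prob = 0.2,
                        filler_prob = 0.3, label = "X")
    dd <- generate_corpus(sp, 40, seed = 4)
    expect_true(all(word_order_labels(dd) == o))
  }
  # overlapping spans are an error
  insx <- rbind(argument_instance("t1", "A", c(2, 5), "bite", 8),
                argument_instance("t1", "P", c(4, 6), "bite", 8))
  expect_error(label_word_order(u, insx), class = "rp_overlapping_spans")
})

test_that("size matching samples whole utterances to the token budget", {
  d <- generate_corpus(default_register_spec("russian_like"), 800, seed = 3)
  total <- n_tokens(d)
  maxlen <- max(vapply(d$utterances, function(u) length(u$tokens), 0L))
  budget <- floor(total / 2)
  m1 <- sample_matched_corpus(d, budget, seed = 21)
  expect_gte(n_tokens(m1), budget)
  expect_lt(n_tokens(m1), budget + maxlen)
  m2 <- sample_matched_corpus(d, budget, seed = 21)
  expect_identical(names(m1$utterances), names(m2$utterances))
  m3 <- sample_matched_corpus(d, budget, seed = 22)
  expect_gte(n_tokens(m3), budget)
  expect_false(identical(names(m1$utterances), names(m3$utterances)))
  expect_error(sample_matched_corpus(d, total + 1, seed = 1),
               class = "rp_corpus_too_small")
  # budget equal to corpus size returns the full corpus
  m4 <- sample_matched_corpus(d, total, seed = 5)
  expect_setequal(names(m4$utterances), names(d$utterances))
})
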