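make_probing_dataset <- function(n = 1200, seed = 5) {
  generate_corpus(default_register_spec("russian_like"), n, seed = seed)
}

test_that("verb-disjoint splits satisfy the protocol invariants", {
  d <- make_probing_dataset()
  sp <- make_verb_disjoint_splits(d, n_versions = 10, train_size = 100,
                                  val_range = c(100, 300), seed = 2)
  expect_length(sp, 10)
  ins <- d$instances
  partitions <- vapply(sp, function(s) paste(s$train_verbs, collapse = ","), "")
  expect_gt(length(unique(partitions)), 1)    # versions differ in verb partition
  for (s in sp) {
    expect_length(s$train, 100)
    expect_equal(sum(ins$role[s$train] == "A"), 50)
    expect_equal(sum(ins$role[s$train] == "P"), 50)
    expect_length(intersect(s$train_verbs, unique(ins$verb_lemma[c(s$val, s$test)])),
                  0)
    expect_gte(length(s$val), 100)
    expect_lte(length(s$val), 300)
    # each instance in at most one set
    all_idx <- c(s$train, s$val, s$test, s$dropped)
    expect_equal(anyDuplicated(all_idx), 0)
  }
  # deterministic given the seed
  sp2 <- make_verb_disjoint_splits(d, n_versions = 10, seed = 2)
  expect_identical(lapply(sp, `[[`, "train"), lapply(sp2, `[[`, "train"))
})

test_that("infeasible split requests raise the binding constraint", {
  d <- make_probing_dataset(150)
  one_verb <- d
  one_verb$instances$verb_lemma <- "only"
  one_verb$verb_inventory <- "only"
  expect_error(make_verb_disjoint_splits(one_verb), class = "rp_split_infeasible")
  expect_error(make_verb_disjoint_splits(d, train_size = 101),
               class = "rp_split_infeasible")
  expect_error(make_verb_disjoint_splits(d, train_size = 10000),
               class = "rp_split_infeasible")
})

test_that("probes learn separable data and stay at chance on shuffled labels", {
  set.seed(31)
  X <- matrix(stats::rnorm(600 * 4), 600, 4)
  y <- ifelse(X[, 1] + 0.5 * X[, 2] > 0, "A", "P")
  X[, 1] <- X[, 1] + ifelse(y == "A", 1.5, -1.5)
  tr <- 1:100; va <- 101:200; te <- 201:600
  for (kind in c("mlp", "svm")) {
    pr <- train_probe(X[tr, ], y[tr], X[va, ], y[va], probe_config(kind))
    expect_gte(mean(predict(pr, X[te, ]) == y[te]), 0.97)
  }
  # permutation null: shuffled labels give chance-level test accuracy
  ysh <- sample(y)
  accs <- vapply(1:3, function(s) {
    pr <- train_probe(X[tr, ], ysh[tr], X[va, ], ysh[va],
                      probe_config("mlp", seed = s))
    mean(predict(pr, X[te, ]) == ysh[te])
  }, 0)
  ci <- stats::qbinom(c(0.005, 0.995), 400, 0.5) / 400
  expect_gte(mean(accs), ci[1] - 0.05)
  expect_lte(mean(accs), ci[2] + 0.05)
  expect_error(train_probe(X[tr, ], rep("A", 100)), class = "rp_one_class")
  pr <- train_probe(X[tr, ], y[tr], config = probe_config("svm"))
  expect_error(predict(pr, X[, 1:2]), class = "rp_dim_mismatch")
})

test_that("probe selection keeps the lowest-validation-loss state", {
  set.seed(8)
  X <- matrix(stats::rnorm(300 * 3), 300, 3)
  y <- ifelse(X[, 1] > 0, "A", "P")
  pr <- train_probe(X[1:150, ], y[1:150], X[151:300, ], y[151:300],
                    probe_config("mlp", epochs = 20))
  expect_true(is.finite(pr$val_loss))
  # rerunning with identical seed reproduces the parameters exactly
  pr2 <- train_probe(X[1:150, ], y[1:150], X[151:300, ], y[151:300],
                     probe_config("mlp", epochs = 20))
  expect_identical(pr$pars, pr2$pars)
})

test_that("evaluation records preserve counts and join back to utterances", {
  d <- make_probing_dataset(600)
  sp <- make_verb_disjoint_splits(d, n_versions = 2, seed = 4)[[1]]
  M <- encode_positions(d)
  meta <- d$instances; meta$register <- "CDS"
  pr <- train_probe(M[sp$train, ], meta$role[sp$train], config = probe_config("svm"))
  rec <- evaluate_probe(pr, M[sp$test, ], meta[sp$test, ], "position", sp$split_id)
  expect_equal(nrow(rec), length(sp$test))
  expect_equal(mean(rec$correct), mean(rec$predicted == rec$role))
  expect_true(all(rec$sentence_id %in% names(d$utterances)))
  acc <- accuracy_table(rec)
  expect_equal(sum(acc$n), nrow(rec))
  # a probe that predicts everything as A is at chance on a balanced set
  bal <- c(sample(which(meta$role[sp$test] == "A"), 50),
           sample(which(meta$role[sp$test] == "P"), 50))
  constA <- structure(list(kind = "mlp",
                           pars = list(W1 = matrix(0, 3, 2), b1 = c(0, 0),
                                       W2 = matrix(0, 2, 1), b2 = -5)),
                      class = "rp_probe")
  recA <- evaluate_probe(constA, M[sp$test[bal], ], meta[sp$test[bal], ], "position", 1)
  expect_equal(mean(recA$correct), 0.5)
  expect_equal(mean(recA$correct[recA$role == "A"]), 1)
  expect_equal(mean(recA$correct[recA$role == "P"]), 0)
})

test_that("feature probes recover the designed cue structure of registers", {
  # deterministic AVP order: the position features fully determine the role
  d_avp <- generate_corpus(avp_spec(), 1200, seed = 19)
  s <- make_verb_disjoint_splits(d_avp, n_versions = 1, seed = 7)[[1]]
  M <- encode_positions(d_avp)
  meta <- d_avp$instances; meta$register <- "R"
  pr <- train_probe(M[s$train, ], meta$role[s$train], config = probe_config("svm"))
  expect_gte(mean(evaluate_probe(pr, M[s$test, ], meta[s$test, ])$correct), 0.99)
  # bijective case paradigm: the case vector determines the role
  d_bij <- generate_corpus(bijective_case_spec(), 1200, seed = 20)
  sb <- make_verb_disjoint_splits(d_bij, n_versions = 1, seed = 7)[[1]]
  par_b <- bijective_case_spec()$paradigm
  Mb <- encode_cases(d_bij, par_b)
  metab <- d_bij$instances; metab$register <- "R"
  prb <- train_probe(Mb[sb$train, ], metab$role[sb$train], config = probe_config("svm"))
  expect_gte(mean(evaluate_probe(prb, Mb[sb$test, ], metab[sb$test, ])$correct), 0.99)
  # fully syncretic paradigm: the case vector is uninformative, accuracy at chance
  d_syn <- generate_corpus(syncretic_case_spec(), 1400, seed = 21)
  ss <- make_verb_disjoint_splits(d_syn, n_versions = 1, seed = 7)[[1]]
  par_s <- syncretic_case_spec()$paradigm
  Ms <- encode_cases(d_syn, par_s)
  metas <- d_syn$instances; metas$register <- "R"
  prs <- train_probe(Ms[ss$train, ], metas$role[ss$train], config = probe_config("svm"))
  bal <- c(sample(ss$test[metas$role[ss$test] == "A"], 300),
           sample(ss$test[metas$role[ss$test] == "P"], 300))
  acc <- mean(evaluate_probe(prs, Ms[bal, ], metas[bal, ])$correct)
  band <- stats::qbinom(c(0.025, 0.975), 600, 0.5) / 600
  expect_gte(acc, band[1]); expect_lte(acc, band[2])
})

test_that("no training verb leaks into any evaluation record", {
  d <- make_probing_dataset(900)
  exper <- run_register_experiment(list(CDS = d, ADS = d),
                                   representations = "position",
                                   paradigm = NULL, n_versions = 3,
                                   split_seed = 9)
  rec <- exper$records
  verb_of <- d$instances$verb_lemma
  names(verb_of) <- paste(d$instances$utterance_id, d$instances$role, sep = ":")
  for (reg in names(exper$splits)) for (s in exper$splits[[reg]]) {
    rr <- rec[rec$register == reg & rec$split_id == s$split_id, ]
    expect_length(intersect(verb_of[rr$argument_id], s$train_verbs), 0)
  }
})
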