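test_that("generation is deterministic and respects degenerate order", {
  sp <- avp_spec()
  d1 <- generate_corpus(sp, 80, seed = 7)
  d2 <- generate_corpus(sp, 80, seed = 7)
  expect_identical(lapply(d1$utterances, `[[`, "tokens"),
                   lapply(d2$utterances, `[[`, "tokens"))
  expect_identical(d1$instances, d2$instances)
  expect_true(all(word_order_labels(d1) == "AVP"))
  expect_true(all(table(d1$instances$utterance_id) >= 1))
})

test_that("empirical order frequencies track the sampling distribution", {
  sp <- bijective_case_spec()   # uniform over the six two-argument orders
  d <- generate_corpus(sp, 6000, seed = 13)
  tab <- table(word_order_labels(d))
  p <- 1 / 6; se <- sqrt(p * (1 - p) / 6000)
  for (o in names(tab))
    expect_lt(abs(tab[[o]] / 6000 - p), 3 * se)
  # chi-square goodness of fit across seeds: reject at alpha=.01 rarely
  pass <- 0L
  for (s in 1:10) {
    dd <- generate_corpus(sp, 10000, seed = 100 + s)
    tt <- table(factor(word_order_labels(dd),
                       levels = names(sp$word_order_dist)))
    pv <- stats::chisq.test(tt, p = sp$word_order_dist)$p.value
    pass <- pass + (pv > 0.01)
  }
  expect_gte(pass, 9)
})

test_that("gold case forms are consistent with the verb frame slots", {
  sp <- default_register_spec("russian_like")
  d <- generate_corpus(sp, 500, seed = 21)
  ins <- d$instances
  verbs <- sp$lexicon$verbs
  expect_true(all(ins$case[ins$role == "A"] == "NOM"))
  expect_equal(ins$case[ins$role == "P"],
               verbs$p_case[match(ins$verb_lemma[ins$role == "P"], verbs$lemma)])
  # and every non-pronominal surface form realises its annotated cell
  nn <- ins[!ins$pronoun, ]
  par <- sp$paradigm
  for (i in sample(nrow(nn), 50)) {
    cells <- possible_cases(par, nn$head_form[i])
    expect_true(any(cells$case == nn$case[i] & cells$number == nn$number[i]))
  }
})

test_that("entropy calibration hits its target and is monotone in concentration", {
  sp <- default_register_spec("russian_like")
  sp$pronoun_prob <- 0
  cal <- calibrate_role_entropy(sp, c(A = 2.0))
  expect_lt(abs(spec_role_entropy(cal, "A") - 2.0), 0.01)
  # realised corpus entropy over A lemmas matches within the stated band
  d <- generate_corpus(cal, 6000, seed = 17)
  lem <- d$instances$head_form[d$instances$role == "A"]
  # strip inflection by mapping forms back to lemmas via the noun stems
  lemma_of <- function(forms) {
    nouns <- cal$lexicon$nouns$lemma
    hit <- lapply(forms, function(f) nouns[startsWith(f, nouns)])
    vapply(hit, function(h) h[which.max(nchar(h))], "")
  }
  Hc <- entropy_ml(table(lemma_of(lem)))
  expect_lt(abs(Hc - 2.0), 0.1)
  # zero-entropy limit: one lemma takes all mass
  cal0 <- calibrate_role_entropy(sp, c(A = 0.001), tol = 0.001)
  p <- regiprobe:::role_lemma_dist(cal0, "A")
  expect_gt(max(p), 0.999)
  # maximum-entropy limit: uniform weights
  n <- nrow(sp$lexicon$nouns)
  calU <- calibrate_role_entropy(sp, stats::setNames(log2(n), "A"))
  pU <- regiprobe:::role_lemma_dist(calU, "A")
  expect_lt(max(pU) - min(pU), 1e-3)
  # unreachable target errors
  expect_error(calibrate_role_entropy(sp, stats::setNames(log2(n) + 1, "A")),
               class = "rp_unreachable_entropy")
  # monotone: entropy non-increasing along a concentration grid
  H_grid <- vapply(c(0.25, 0.5, 1, 2, 4, 8), function(g) {
    s2 <- sp; s2$role_entropy_concentration[["A"]] <- g
    spec_role_entropy(s2, "A")
  }, 0)
  expect_true(all(diff(H_grid) <= 1e-12))
})

test_that("register pairs differ only in the named dimensions", {
  base <- default_register_spec("russian_like", label = "ADS")
  id_pair <- make_register_pair(base)
  expect_equal(id_pair$cds$role_entropy_concentration,
               id_pair$ads$role_entropy_concentration)
  pr <- make_register_pair(base, deltas = list(entropy = c(A = -0.79, P = -0.55)))
  expect_equal(spec_role_entropy(pr$ads, "A") - spec_role_entropy(pr$cds, "A"),
               0.79, tolerance = 0.02)
  expect_equal(spec_role_entropy(pr$ads, "P") - spec_role_entropy(pr$cds, "P"),
               0.55, tolerance = 0.02)
  expect_identical(pr$cds$word_order_dist, pr$ads$word_order_dist)
  # syncretism delta lowers the syncretic fraction of argument forms
  pr2 <- make_register_pair(base, deltas = list(syncretism = 0.25))
  frac_sync <- function(spec) {
    d <- generate_corpus(spec, 1200, seed = 31)
    nn <- d$instances[!d$instances$pronoun, ]
    mean(vapply(nn$head_form, function(f)
      nrow(possible_cases(spec$paradigm, f)) > 1, TRUE))
  }
  expect_lt(frac_sync(pr2$cds), frac_sync(pr2$ads))
})

test_that("invalid specifications are rejected at validation", {
  lex <- default_lexicon("russian_like")
  par <- default_paradigm("russian_like")
  expect_error(register_spec(lex, par, c(AVP = 0.7, APV = 0.2)),
               class = "rp_bad_register_spec")
  expect_error(register_spec(lex, par, c(AVP = 0.5, AV = 0.5),
                             omission_prob = c(A = 0, P = 0)),
               class = "rp_bad_register_spec")
  expect_error(register_spec(lex, par, c(AVV = 1)),
               class = "rp_bad_register_spec")
  expect_error(generate_corpus(avp_spec(), 0, seed = 1),
               class = "rp_bad_register_spec")
})

test_that("register specs survive a YAML round trip", {
  sp <- default_register_spec("russian_like", label = "CDS")
  sp$role_entropy_concentration <- c(A = 1.7, P = 0.8)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_register_spec(sp, f)
  sp2 <- read_register_spec(f)
  expect_equal(sp2$word_order_dist, sp$word_order_dist)
  expect_equal(sp2$role_entropy_concentration, sp$role_entropy_concentration)
  expect_equal(sp2$label, "CDS")
  d1 <- generate_corpus(sp, 30, seed = 2)
  d2 <- generate_corpus(sp2, 30, seed = 2)
  expect_identical(lapply(d1$utterances, `[[`, "tokens"),
                   lapply(d2$utterances, `[[`, "tokens"))
})
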