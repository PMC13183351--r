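#' Condition specification for controlled test sentences
#'
#' @param mode `"english_like"` or `"russian_like"`.
#' @param conditions English-mode conditions to generate.
#' @param orders Russian-mode overt-order strings to cross with the
#'   syncretism conditions.
#' @param pronoun Also generate variants with a pronominal A or P (English
#'   mode), including the role-ambiguous form *you*.
#' @return A list of class `rp_condition_spec`.
#' @export
condition_spec <- function(mode = c("english_like", "russian_like"),
                           conditions = c("basic", "unprototypical_animacy",
                                          "fronted", "relative_clause", "passive"),
                           orders = c("AVP", "APV", "PAV", "PVA", "VAP", "VPA"),
                           pronoun = TRUE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, conditions = conditions, orders = orders,
                 pronoun = pronoun), class = "rp_condition_spec")
}

#' Generate a controlled test set from templates
#'
#' Builds the full cross-product of templates, permitted verb--noun
#' pairings and number combinations, deduplicated. English mode realises
#' the five animacy/word-order conditions (fronting and relativisation
#' yield PAV clauses, the passive a PVA clause with the agent in a
#' *by*-phrase); Russian mode crosses the four case-syncretism conditions
#' with the requested overt orders, classifying syncretism from the
#' paradigm itself (a form counts as syncretic when [encode_case()] sets
#' more than one bit). Number is varied so that subject--verb agreement
#' disambiguates the roles in half of the variants; the doubly syncretic
#' condition keeps only agreement-cued variants, since it would otherwise
#' be globally ambiguous. Plausibility is deliberately not modelled.
#'
#' @param lexicon An [grammar_lexicon()].
#' @param paradigm The matching `rp_case_paradigm`.
#' @param spec An [condition_spec()].
#' @param pairings Optional data frame (`verb`, `noun`) restricting
#'   verb--noun combinations (applied to the P slot).
#' @param seed Seed used only for sampling among equivalent lexical
#'   choices when the cross-product is subsampled by `max_per_condition`.
#' @param max_per_condition Cap on generated sentences per condition
#'   (cross-products grow combinatorially; `Inf` keeps everything).
#' @return An `rp_role_dataset` whose instances carry `condition`, `order`,
#'   `sync_A`, `sync_P`, `agr_cue` and `pronoun` metadata columns.
#' @export
generate_controlled_sentences <- function(lexicon, paradigm,
                                          spec = condition_spec(lexicon$mode),
                                          pairings = NULL, seed = 1,
                                          max_per_condition = 400) {
  paradigm <- bind_lexicon(paradigm, lexicon)
  rows <- if (spec$mode == "english_like")
    controlled_english(lexicon, paradigm, spec, pairings)
  else controlled_russian(lexicon, paradigm, spec, pairings)
  # dedup on surface form, then cap per condition
  key <- vapply(rows, function(r) paste(r$tokens, collapse = " "), "")
  rows <- rows[!duplicated(key)]
  cond <- vapply(rows, `[[`, "", "condition")
  keep <- unlist(lapply(split(seq_along(rows), cond), function(ix) {
    if (length(ix) <= max_per_condition) ix
    else with_seed(seed, sample(ix, max_per_condition))
  }))
  rows <- rows[sort(keep)]
  utts <- vector("list", length(rows)); inst <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    id <- sprintf("ctrl_%05d", i)
    utts[[i]] <- utterance(id, r$tokens, register = "CTRL", language = spec$mode)
    ai <- rbind(
      argument_instance(id, "A", r$a_span, r$verb, r$verb_index),
      argument_instance(id, "P", r$p_span, r$verb, r$verb_index))
    ai$condition <- r$condition
    ai$order <- r$order
    ai$sync_A <- r$sync_A; ai$sync_P <- r$sync_P
    ai$agr_cue <- r$agr_cue; ai$pronoun <- r$pronoun
    ai$head_form <- c(r$a_head, r$p_head)
    ai$case <- c("NOM", "ACC")
    ai$number <- c(r$a_num, r$p_num)
    inst[[i]] <- ai
  }
  role_dataset(utts, do.call(rbind, inst))
}

# -- English templates ------------------------------------------------------

eng_np <- function(noun, num) {
  form <- if (num == "PL") paste0(noun, "s") else noun
  list(tokens = c("the", form), head = form)
}

controlled_english <- function(lexicon, paradigm, spec, pairings) {
  nouns <- lexicon$nouns
  humans <- nouns$lemma[nouns$animacy == "human"]
  others <- nouns$lemma[nouns$animacy != "human"]
  verbs <- lexicon$verbs[is.na(lexicon$verbs$p_prep), ]
  pverbs <- lexicon$verbs[!is.na(lexicon$verbs$p_prep), ]
  ok <- function(v, n) is.null(pairings) ||
    any(pairings$verb == v & pairings$noun == n)
  pron <- list(A = list(c("she", "SG"), c("they", "PL"), c("you", "SG")),
               P = list(c("her", "SG"), c("them", "PL"), c("you", "SG")))
  rows <- list()
  emit <- function(...) rows[[length(rows) + 1L]] <<- list(...)
  nums <- expand.grid(a = c("SG", "PL"), p = c("SG", "PL"), stringsAsFactors = FALSE)
  arg_variants <- function(role, lemmas, num) {
    out <- lapply(lemmas, function(l) {
      np <- eng_np(l, num)
      list(tokens = np$tokens, head = np$head, pron = FALSE, num = num)
    })
    if (spec$pronoun)
      for (pv in pron[[role]]) if (pv[2] == num)
        out[[length(out) + 1L]] <- list(tokens = pv[1], head = pv[1],
                                        pron = TRUE, num = num)
    out
  }
  for (cond in spec$conditions) {
    a_pool <- if (cond == "unprototypical_animacy") others else humans
    p_pool <- if (cond == "unprototypical_animacy") humans else others
    vset <- if (cond %in% c("basic", "unprototypical_animacy")) rbind(verbs, pverbs) else verbs
    for (vi in seq_len(nrow(vset))) {
      v <- vset[vi, ]
      for (k in seq_len(nrow(nums))) {
        an <- nums$a[k]; pn <- nums$p[k]
        for (A in arg_variants("A", a_pool, an)) for (P in arg_variants("P", p_pool, pn)) {
          if (!ok(v$lemma, P$head)) next
          vform <- inflect_verb(lexicon, v$lemma, an)
          pp <- if (!is.na(v$p_prep)) v$p_prep else character(0)
          base <- list(condition = cond, verb = v$lemma,
                       sync_A = nrow(possible_cases(paradigm, A$head)) > 1L,
                       sync_P = nrow(possible_cases(paradigm, P$head)) > 1L,
                       agr_cue = an != pn, pronoun = A$pron || P$pron,
                       a_head = A$head, p_head = P$head,
                       a_num = an, p_num = pn)
          if (cond %in% c("basic", "unprototypical_animacy")) {
            toks <- c(A$tokens, vform, pp, P$tokens, ".")
            do.call(emit, c(base, list(
              tokens = toks, order = "AVP",
              a_span = c(0L, length(A$tokens)),
              verb_index = length(A$tokens),
              p_span = c(length(A$tokens) + 1L,
                         length(A$tokens) + 1L + length(pp) + length(P$tokens)))))
          } else if (cond == "fronted") {
            # "The toys , the baby wins ."
            toks <- c(P$tokens, ",", A$tokens, vform, ".")
            do.call(emit, c(base, list(
              tokens = toks, order = "PAV",
              p_span = c(0L, length(P$tokens)),
              a_span = c(length(P$tokens) + 1L, length(P$tokens) + 1L + length(A$tokens)),
              verb_index = length(P$tokens) + 1L + length(A$tokens))))
          } else if (cond == "relative_clause") {
            # "The stories that the friend knows are good ."
            cop <- if (pn == "SG") "is" else "are"
            toks <- c(P$tokens, "that", A$tokens, vform, cop, "good", ".")
            do.call(emit, c(base, list(
              tokens = toks, order = "PAV",
              p_span = c(0L, length(P$tokens)),
              a_span = c(length(P$tokens) + 1L, length(P$tokens) + 1L + length(A$tokens)),
              verb_index = length(P$tokens) + 1L + length(A$tokens))))
          } else if (cond == "passive") {
            # "The lid is thrown by the monkeys ." ; the by-phrase heads A
            if (A$pron || P$pron) next  # nominative/accusative pronouns clash with passive frames
            cop <- if (pn == "SG") "is" else "are"
            part <- paste0(v$lemma, "ed")
            toks <- c(P$tokens, cop, part, "by", A$tokens, ".")
            do.call(emit, c(base, list(
              tokens = toks, order = "PVA",
              p_span = c(0L, length(P$tokens)),
              verb_index = length(P$tokens) + 1L,
              a_span = c(length(P$tokens) + 2L, length(P$tokens) + 3L + length(A$tokens)))))
          }
        }
      }
    }
  }
  rows
}

# -- Russian templates ------------------------------------------------------

controlled_russian <- function(lexicon, paradigm, spec, pairings) {
  # well-represented nouns only: the two highest-frequency members of each
  # declension class (keeps every syncretism profile while bounding the
  # template cross-product)
  nouns <- do.call(rbind, lapply(split(lexicon$nouns, lexicon$nouns$declension),
                                 function(g) g[order(-g$base_weight), ][seq_len(min(2, nrow(g))), ]))
  verbs <- lexicon$verbs[lexicon$verbs$p_case == "ACC" & is.na(lexicon$verbs$p_prep), ]
  ok <- function(v, n) is.null(pairings) ||
    any(pairings$verb == v & pairings$noun == n)
  nums <- expand.grid(a = c("SG", "PL"), p = c("SG", "PL"), stringsAsFactors = FALSE)
  cand <- function(case, num) {
    lapply(seq_len(nrow(nouns)), function(i) {
      form <- realize_form(paradigm, nouns$lemma[i], nouns$declension[i], case, num)
      list(lemma = nouns$lemma[i], form = form, num = num,
           sync = nrow(possible_cases(paradigm, form)) > 1L)
    })
  }
  rows <- list()
  emit <- function(...) rows[[length(rows) + 1L]] <<- list(...)
  for (k in seq_len(nrow(nums))) {
    an <- nums$a[k]; pn <- nums$p[k]
    As <- cand("NOM", an); Ps <- cand("ACC", pn)
    for (vi in seq_len(nrow(verbs))) {
      v <- verbs[vi, ]
      vform <- inflect_verb(lexicon, v$lemma, an)
      for (A in As) for (P in Ps) {
        if (A$lemma == P$lemma || !ok(v$lemma, P$lemma)) next
        cond <- if (A$sync && P$sync) "both_syncretic"
        else if (A$sync) "syncretic_A"
        else if (P$sync) "syncretic_P"
        else "non_syncretic"
        # without an agreement cue, doubly syncretic clauses are ambiguous
        if (cond == "both_syncretic" && an == pn) next
        for (ord in spec$orders) {
          syms <- strsplit(ord, "")[[1]]
          toks <- character(0); spans <- list(); vix <- NA_integer_
          for (s in syms) {
            if (s == "V") { vix <- length(toks); toks <- c(toks, vform) }
            else {
              w <- if (s == "A") A$form else P$form
              spans[[s]] <- c(length(toks), length(toks) + 1L)
              toks <- c(toks, w)
            }
          }
          emit(tokens = c(toks, "."), condition = cond, order = ord,
               verb = v$lemma, verb_index = vix,
               a_span = spans$A, p_span = spans$P,
               sync_A = A$sync, sync_P = P$sync,
               agr_cue = an != pn, pronoun = FALSE,
               a_head = A$form, p_head = P$form, a_num = an, p_num = pn)
        }
      }
    }
  }
  rows
}

#' Compose the controlled train/validation/test split
#'
#' Training (100 sentences, every generated condition represented at least
#' once), validation (200 sentences) and a test set with fixed composition:
#' in English mode each special condition (unprototypical animacy, fronted,
#' relative clause, passive) contributes exactly four test arguments, two
#' per role, and the remainder of the test sentences are basic; in Russian
#' mode the test word orders are fixed at APV 52, AVP 24, PAV 18, PVA 2,
#' VAP 2, VPA 2 sentences (syncretism conditions sampled at random within
#' each order). Counts are exact for every seed.
#'
#' @param controlled An `rp_role_dataset` from
#'   [generate_controlled_sentences()].
#' @param mode Language mode of the set.
#' @param seed Integer seed.
#' @param train_sentences,val_sentences,test_sentences Sentence counts
#'   (`test_sentences` applies to the English basic remainder; the Russian
#'   composition fixes its own total of 100).
#' @return An `rp_split_scheme` over instance rows of `controlled`.
#' @export
compose_study2_split <- function(controlled, mode = c("english_like", "russian_like"),
                                 seed = 1, train_sentences = 100,
                                 val_sentences = 200, test_sentences = 100) {
  mode <- match.arg(mode)
  ins <- controlled$instances
  sent <- unique(ins[, c("utterance_id", "condition", "order")])
  with_seed(seed, {
    if (mode == "english_like") {
      special <- c("unprototypical_animacy", "fronted", "relative_clause", "passive")
      test_sent <- character(0); test_rows <- integer(0)
      for (cn in special) {
        pool <- sent$utterance_id[sent$condition == cn]
        if (length(pool) < 4L)
          rp_error("rp_condition_insufficient",
                   "condition '%s' has %d sentences; need 4 for the test set", cn, length(pool))
        pick <- sample(pool, 4L)
        # two sentences contribute their A argument, two their P argument
        test_rows <- c(test_rows,
                       which(ins$utterance_id %in% pick[1:2] & ins$role == "A"),
                       which(ins$utterance_id %in% pick[3:4] & ins$role == "P"))
        test_sent <- c(test_sent, pick)
      }
      basic_pool <- setdiff(sent$utterance_id[sent$condition == "basic"], test_sent)
      n_basic <- test_sentences - length(test_sent)
      if (length(basic_pool) < n_basic)
        rp_error("rp_condition_insufficient",
                 "condition 'basic' has %d spare sentences; need %d", length(basic_pool), n_basic)
      basic_pick <- sample(basic_pool, n_basic)
      test_rows <- c(test_rows, which(ins$utterance_id %in% basic_pick))
      test_sent <- c(test_sent, basic_pick)
    } else {
      comp <- c(APV = 52, AVP = 24, PAV = 18, PVA = 2, VAP = 2, VPA = 2)
      test_sent <- character(0)
      for (o in names(comp)) {
        pool <- sent$utterance_id[sent$order == o]
        if (length(pool) < comp[[o]])
          rp_error("rp_condition_insufficient",
                   "word order '%s' has %d sentences; need %d", o, length(pool), comp[[o]])
        test_sent <- c(test_sent, sample(pool, comp[[o]]))
      }
      test_rows <- which(ins$utterance_id %in% test_sent)
    }
    rest <- setdiff(sent$utterance_id, test_sent)
    conds <- unique(sent$condition)
    # training must contain every condition at least once
    tr <- character(0)
    for (cn in conds) {
      pool <- intersect(rest, sent$utterance_id[sent$condition == cn])
      if (!length(pool))
        rp_error("rp_condition_insufficient",
                 "condition '%s' unavailable for the training set", cn)
      tr <- c(tr, sample(pool, 1L))
    }
    rest2 <- setdiff(rest, tr)
    if (length(rest2) < (train_sentences - length(tr)) + val_sentences)
      rp_error("rp_condition_insufficient",
               "only %d sentences left for train/validation", length(rest2))
    tr <- c(tr, sample(rest2, train_sentences - length(tr)))
    val <- sample(setdiff(rest2, tr), val_sentences)
    structure(list(split_id = 1L,
                   train = which(ins$utterance_id %in% tr),
                   val = which(ins$utterance_id %in% val),
                   test = sort(test_rows),
                   dropped = integer(0),
                   train_sentences = sort(tr), val_sentences = sort(val),
                   test_sentences = sort(unique(ins$utterance_id[test_rows]))),
              class = "rp_split_scheme")
  })
}

#' Evaluate register-trained encoders on one controlled test set
#'
#' The generalisation protocol: the same controlled sentences are embedded
#' by each register-trained encoder (contextual representation only), one
#' probe per encoder is trained on the controlled training split, and the
#' identical test items are scored under both. Records carry the condition
#' metadata needed by the hierarchical model.
#'
#' @param encoders Named list of trained `rp_contextual_encoder`s; names
#'   are the register labels (e.g. `CDS`, `ADS`).
#' @param controlled Controlled `rp_role_dataset`.
#' @param split An `rp_split_scheme` from [compose_study2_split()].
#' @param probe_cfg An [probe_config()] (mlp by default).
#' @return Record data frame (one row per register x test argument).
#' @export
evaluate_generalization <- function(encoders, controlled, split,
                                    probe_cfg = probe_config("mlp")) {
  ins <- controlled$instances
  out <- list()
  for (reg in names(encoders)) {
    X <- embed_arguments_contextual(encoders[[reg]], controlled)
    meta <- ins
    meta$register <- reg
    probe <- train_probe(X[split$train, , drop = FALSE], meta$role[split$train],
                         X[split$val, , drop = FALSE], meta$role[split$val],
                         probe_cfg)
    out[[reg]] <- evaluate_probe(probe, X[split$test, , drop = FALSE],
                                 meta[split$test, , drop = FALSE],
                                 "contextual", split$split_id)
  }
  do.call(rbind, out)
}
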