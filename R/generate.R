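#' Generate a synthetic register corpus
#'
#' Samples `n_utterances` clauses from a register specification: a verb
#' frame, an overt-order string, role-biased argument lemmas (or pronouns),
#' grammatical number, surface forms via the case paradigm (the A slot takes
#' the frame's A case, the P slot its P case), verb agreement with the
#' underlying A number, and optional clause-initial fillers. Gold argument
#' instances are attached, so generated corpora need no external annotation.
#' Deterministic given `seed`.
#'
#' @param spec An [register_spec()].
#' @param n_utterances Number of clauses to generate (> 0).
#' @param seed Integer seed.
#' @param id_prefix Prefix for utterance ids.
#' @return An `rp_role_dataset`; its `instances` carry extra metadata
#'   columns `case`, `number`, `pronoun` and `order`.
#' @export
generate_corpus <- function(spec, n_utterances, seed, id_prefix = spec$label) {
  if (n_utterances <= 0) rp_error("rp_bad_register_spec", "n_utterances must be > 0")
  with_seed(seed, {
    orders <- sample(names(spec$word_order_dist), n_utterances, replace = TRUE,
                     prob = spec$word_order_dist)
    verbs <- spec$lexicon$verbs[sample.int(nrow(spec$lexicon$verbs), n_utterances,
                                           replace = TRUE), , drop = FALSE]
    utts <- vector("list", n_utterances)
    acc <- list(utterance_id = character(), role = character(),
                span_start = integer(), span_end = integer(),
                verb_lemma = character(), verb_index = integer(),
                case = character(), number = character(), pronoun = logical(),
                head_form = character(), order = character())
    cols <- vector("list", n_utterances)
    for (i in seq_len(n_utterances)) {
      g <- realize_clause(spec, verbs[i, ], orders[i],
                          sprintf("%s_%06d", id_prefix, i))
      utts[[i]] <- g$utterance
      cols[[i]] <- g$fields
    }
    n_arg <- vapply(cols, function(z) length(z$role), 0L)
    ins <- data.frame(
      utterance_id = rep(vapply(utts, `[[`, "", "id"), n_arg),
      role = unlist(lapply(cols, `[[`, "role")),
      span_start = unlist(lapply(cols, `[[`, "span_start")),
      span_end = unlist(lapply(cols, `[[`, "span_end")),
      verb_lemma = rep(verbs$lemma, n_arg),
      verb_index = unlist(lapply(cols, `[[`, "verb_index")),
      condition = NA_character_,
      case = unlist(lapply(cols, `[[`, "case")),
      number = unlist(lapply(cols, `[[`, "number")),
      pronoun = unlist(lapply(cols, `[[`, "pronoun")),
      head_form = unlist(lapply(cols, `[[`, "head_form")),
      order = rep(orders, n_arg),
      stringsAsFactors = FALSE)
    role_dataset(utts, ins)
  })
}

# Sample one argument's lexical realisation. Returns tokens, head form and
# metadata; the span is the full token run (determiner/adposition included).
sample_argument <- function(spec, role, case) {
  lex <- spec$lexicon
  number <- sample(names(spec$number_dist), 1L, prob = spec$number_dist)
  pron <- spec$paradigm$pronouns
  use_pron <- !is.null(pron) && stats::runif(1) < spec$pronoun_prob
  if (use_pron) {
    cand <- pron[pron$case == case & pron$number == number, , drop = FALSE]
    if (nrow(cand)) {
      r <- cand[sample.int(nrow(cand), 1L), ]
      return(list(tokens = r$form, head = r$form, lemma = r$lemma,
                  case = case, number = number, pronoun = TRUE))
    }
  }
  p <- role_lemma_dist(spec, role)
  lemma <- sample(names(p), 1L, prob = p)
  decl <- lex$nouns$declension[match(lemma, lex$nouns$lemma)]
  form <- realize_form(spec$paradigm, lemma, decl, case, number)
  tokens <- if (lex$mode == "english_like") c("the", form) else form
  list(tokens = tokens, head = form, lemma = lemma,
       case = case, number = number, pronoun = FALSE)
}

inflect_verb <- function(lexicon, lemma, a_number) {
  if (lexicon$mode == "english_like") {
    if (a_number == "SG") paste0(lemma, "s") else lemma
  } else {
    paste0(lemma, if (a_number == "SG") "it" else "jat")
  }
}

# Assemble one clause for a given verb frame and overt-order string.
realize_clause <- function(spec, verb, order, id, filler = NULL) {
  syms <- strsplit(order, "")[[1]]
  args <- list(
    A = sample_argument(spec, "A", verb$a_case),
    P = sample_argument(spec, "P", verb$p_case))
  if (!is.na(verb$p_prep)) args$P$tokens <- c(verb$p_prep, args$P$tokens)
  vform <- inflect_verb(spec$lexicon, verb$lemma, args$A$number)
  if (is.null(filler) && length(spec$lexicon$fillers) &&
      stats::runif(1) < spec$filler_prob)
    filler <- sample(spec$lexicon$fillers, 1L)
  tokens <- if (is.null(filler)) character() else filler
  spans <- list()
  verb_index <- NA_integer_
  for (s in syms) {
    if (s == "V") {
      verb_index <- length(tokens)
      tokens <- c(tokens, vform)
    } else {
      spans[[s]] <- c(length(tokens), length(tokens) + length(args[[s]]$tokens))
      tokens <- c(tokens, args[[s]]$tokens)
    }
  }
  tokens <- c(tokens, ".")
  u <- utterance(id, tokens, register = spec$label,
                 language = spec$lexicon$mode, source = "synthetic")
  sn <- names(spans)
  fields <- list(
    role = sn,
    span_start = vapply(spans, `[[`, 0L, 1L),
    span_end = vapply(spans, `[[`, 0L, 2L),
    verb_index = rep(verb_index, length(sn)),
    case = vapply(sn, function(s) args[[s]]$case, ""),
    number = vapply(sn, function(s) args[[s]]$number, ""),
    pronoun = vapply(sn, function(s) args[[s]]$pronoun, TRUE),
    head_form = vapply(sn, function(s) args[[s]]$head, ""))
  list(utterance = u, fields = fields)
}
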