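#' Construct a grammar lexicon
#'
#' The generative lexicon of a synthetic register: nouns with declension
#' class, animacy and role biases; a closed pronoun inventory (taken from
#' the paradigm); verb frames naming the case each verb's A and P slot take;
#' and optional utterance-initial filler words.
#'
#' @param nouns Data frame with columns `lemma` (stem), `declension`,
#'   `animacy` (`human`/`animal`/`inanimate`), `bias_A`, `bias_P` (positive
#'   role-bias weights) and `base_weight` (positive frequency weight).
#' @param verbs Data frame with columns `lemma`, `a_case`, `p_case`, and
#'   optionally `p_prep` (adposition heading the P argument, `NA` if none).
#' @param fillers Character vector of optional clause-initial function words.
#' @param mode `"russian_like"` or `"english_like"`; controls verb
#'   morphology and determiner use at realisation time.
#' @param pairings Optional data frame (`verb`, `noun`) whitelisting
#'   verb--noun combinations; `NULL` allows all.
#' @return Object of class `rp_grammar_lexicon`.
#' @export
grammar_lexicon <- function(nouns, verbs, fillers = character(),
                            mode = c("russian_like", "english_like"),
                            pairings = NULL) {
  mode <- match.arg(mode)
  for (col in c("lemma", "declension", "animacy", "bias_A", "bias_P", "base_weight"))
    if (is.null(nouns[[col]]))
      rp_error("rp_bad_lexicon", "nouns table lacks column '%s'", col)
  for (col in c("lemma", "a_case", "p_case"))
    if (is.null(verbs[[col]]))
      rp_error("rp_bad_lexicon", "verbs table lacks column '%s'", col)
  if (is.null(verbs$p_prep)) verbs$p_prep <- NA_character_
  if (any(nouns$bias_A <= 0 & nouns$bias_P <= 0))
    rp_error("rp_bad_lexicon", "every noun needs a positive bias for at least one role")
  structure(list(nouns = nouns, verbs = verbs, fillers = fillers,
                 mode = mode, pairings = pairings),
            class = "rp_grammar_lexicon")
}

#' Built-in synthetic lexicons
#'
#' Small invented but typologically flavoured inventories. The
#' `russian_like` lexicon spreads nouns over three declension classes (one
#' with nominative/accusative syncretism) and gives verbs varied P-slot
#' cases; the `english_like` lexicon is caseless with determiner-marked
#' nouns and a few oblique (preposition-headed) P frames.
#'
#' @param mode `"russian_like"` or `"english_like"`.
#' @return An `rp_grammar_lexicon`.
#' @export
default_lexicon <- function(mode = c("russian_like", "english_like")) {
  mode <- match.arg(mode)
  if (mode == "russian_like") {
    # every declension class carries A-biased, neutral and P-biased members
    # (with graded base frequencies), so concentrating the role-conditional
    # lemma distribution leaves the case-form and syncretism profile of each
    # role unchanged: registers can differ in lexical entropy alone
    nouns <- rbind(
      noun_row("drug",   "animate",   "human",     8, 1, 8),
      noun_row("brat",   "animate",   "human",     6, 2, 5),
      noun_row("gost",   "animate",   "human",     5, 2, 3),
      noun_row("syn",    "animate",   "human",     4, 2, 2),
      noun_row("kot",    "animate",   "animal",    3, 3, 6),
      noun_row("volk",   "animate",   "animal",    3, 3, 3),
      noun_row("zhuk",   "animate",   "animal",    2, 4, 2),
      noun_row("gus",    "animate",   "animal",    1, 5, 2),
      noun_row("slon",   "animate",   "animal",    1, 6, 4),
      noun_row("krab",   "animate",   "animal",    1, 8, 5),
      noun_row("mam",    "feminine",  "human",     7, 1, 8),
      noun_row("sestr",  "feminine",  "human",     6, 2, 4),
      noun_row("dochk",  "feminine",  "human",     5, 2, 5),
      noun_row("tet",    "feminine",  "human",     4, 2, 2),
      noun_row("sobak",  "feminine",  "animal",    3, 3, 6),
      noun_row("ptic",   "feminine",  "animal",    3, 3, 3),
      noun_row("ryb",    "feminine",  "animal",    2, 4, 3),
      noun_row("knig",   "feminine",  "inanimate", 1, 5, 5),
      noun_row("lap",    "feminine",  "inanimate", 1, 6, 2),
      noun_row("lamp",   "feminine",  "inanimate", 1, 8, 5),
      noun_row("robot",  "inanimate", "inanimate", 8, 1, 6),
      noun_row("traktor","inanimate", "inanimate", 6, 2, 2),
      noun_row("avtobus","inanimate", "inanimate", 5, 2, 3),
      noun_row("kran",   "inanimate", "inanimate", 4, 2, 2),
      noun_row("dom",    "inanimate", "inanimate", 3, 3, 5),
      noun_row("stol",   "inanimate", "inanimate", 3, 3, 4),
      noun_row("krug",   "inanimate", "inanimate", 2, 4, 3),
      noun_row("paket",  "inanimate", "inanimate", 1, 5, 5),
      noun_row("sok",    "inanimate", "inanimate", 1, 6, 7),
      noun_row("hleb",   "inanimate", "inanimate", 1, 8, 6))
    verbs <- data.frame(
      lemma  = c("vid", "ljub", "ber", "derzh", "korm", "lov", "bros", "nes",
                 "pomog", "zhd", "id", "slush"),
      a_case = "NOM",
      p_case = c("ACC", "ACC", "ACC", "ACC", "ACC", "ACC", "ACC", "ACC",
                 "DAT", "GEN", "ACC", "ACC"),
      p_prep = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, "v", NA),
      stringsAsFactors = FALSE)
    grammar_lexicon(nouns, verbs, fillers = c("nu", "vot", "tak", "a"), mode = mode)
  } else {
    nouns <- rbind(
      noun_row("lady",    "common", "human",     8, 2),
      noun_row("boy",     "common", "human",     7, 2),
      noun_row("girl",    "common", "human",     7, 2),
      noun_row("baby",    "common", "human",     5, 2),
      noun_row("person",  "common", "human",     3, 2),
      noun_row("friend",  "common", "human",     3, 2),
      noun_row("monkey",  "common", "animal",    4, 3),
      noun_row("dog",     "common", "animal",    4, 4),
      noun_row("horse",   "common", "animal",    3, 4),
      noun_row("toy",     "common", "inanimate", 1, 7),
      noun_row("chair",   "common", "inanimate", 1, 5),
      noun_row("lid",     "common", "inanimate", 1, 4),
      noun_row("car",     "common", "inanimate", 2, 5),
      noun_row("ship",    "common", "inanimate", 1, 3),
      noun_row("house",   "common", "inanimate", 1, 4),
      noun_row("story",   "common", "inanimate", 1, 6),
      noun_row("biscuit", "common", "inanimate", 1, 8),
      noun_row("cake",    "common", "inanimate", 1, 6))
    verbs <- data.frame(
      lemma  = c("see", "like", "take", "hold", "feed", "catch", "throw",
                 "carry", "win", "know", "bite", "chase"),
      a_case = "NOM",
      p_case = "ACC",
      p_prep = NA_character_,
      stringsAsFactors = FALSE)
    obl <- data.frame(lemma = c("go", "run", "sit"), a_case = "NOM",
                      p_case = "ACC", p_prep = c("to", "to", "on"),
                      stringsAsFactors = FALSE)
    grammar_lexicon(nouns, rbind(verbs, obl),
                    fillers = c("why", "well", "so", "and"), mode = mode)
  }
}

noun_row <- function(lemma, declension, animacy, bias_A, bias_P,
                     base_weight = 1) {
  data.frame(lemma = lemma, declension = declension, animacy = animacy,
             bias_A = bias_A, bias_P = bias_P, base_weight = base_weight,
             stringsAsFactors = FALSE)
}

#' Construct a register specification
#'
#' A register spec is the complete generative description of one synthetic
#' speech register: the shared lexicon and case paradigm plus the
#' register-specific knobs the generator samples from.
#'
#' @param lexicon An [grammar_lexicon()].
#' @param paradigm An `rp_case_paradigm` (the form index is bound here).
#' @param word_order_dist Named probability vector over overt-order strings
#'   (subsets of \{A, P, V\} containing V, e.g. `AVP`, `APV`, `AV`, `VP`);
#'   must sum to one. Strings lacking an argument encode omission of that
#'   argument and are only admissible when the matching `omission_prob`
#'   entry is positive.
#' @param role_entropy_concentration Named positive pair `c(A=, P=)`; the
#'   exponent applied to role-biased noun weights. Larger values concentrate
#'   lexical choice and lower the role-conditional entropy.
#' @param omission_prob Named pair `c(A=, P=)` in \[0,1\] declaring whether
#'   each argument may be omitted.
#' @param number_dist Named probabilities `c(SG=, PL=)`.
#' @param pronoun_prob Probability that an overt argument is pronominal.
#' @param filler_prob Probability of a clause-initial filler word.
#' @param label Register label stamped on generated utterances (`"CDS"`,
#'   `"ADS"`, ...).
#' @return Object of class `rp_register_spec`.
#' @export
register_spec <- function(lexicon, paradigm, word_order_dist,
                          role_entropy_concentration = c(A = 1, P = 1),
                          omission_prob = c(A = 0.3, P = 0.3),
                          number_dist = c(SG = 0.75, PL = 0.25),
                          pronoun_prob = 0.3, filler_prob = 0.2,
                          label = "CDS") {
  if (abs(sum(word_order_dist) - 1) > 1e-8)
    rp_error("rp_bad_register_spec", "word_order_dist must sum to 1")
  if (is.null(names(word_order_dist)) || any(!grepl("^[APV]+$", names(word_order_dist))))
    rp_error("rp_bad_register_spec", "word_order_dist names must be strings over {A,P,V}")
  for (o in names(word_order_dist)) {
    s <- strsplit(o, "")[[1]]
    if (anyDuplicated(s) || !"V" %in% s || length(s) < 2L)
      rp_error("rp_bad_register_spec", "invalid order string '%s'", o)
    for (arg in c("A", "P"))
      if (!arg %in% s && word_order_dist[[o]] > 0 && omission_prob[[arg]] <= 0)
        rp_error("rp_bad_register_spec",
                 "order '%s' omits %s but omission_prob[%s] is 0", o, arg, arg)
  }
  if (any(role_entropy_concentration < 0))
    rp_error("rp_bad_register_spec", "concentration must be non-negative")
  stopifnot(abs(sum(number_dist) - 1) < 1e-8,
            pronoun_prob >= 0, pronoun_prob <= 1)
  structure(list(lexicon = lexicon, paradigm = bind_lexicon(paradigm, lexicon),
                 word_order_dist = word_order_dist,
                 role_entropy_concentration = role_entropy_concentration,
                 omission_prob = omission_prob, number_dist = number_dist,
                 pronoun_prob = pronoun_prob, filler_prob = filler_prob,
                 label = label),
            class = "rp_register_spec")
}

#' Built-in register specification
#'
#' Default generative settings for the two typological profiles. The
#' russian-like profile has a flexible word-order distribution with frequent
#' argument omission (A-initial orders dominant, all six two-argument orders
#' attested); the english-like profile is near-degenerate on AVP with few
#' P-initial clauses.
#'
#' @param mode `"russian_like"` or `"english_like"`.
#' @param label Register label.
#' @return An `rp_register_spec`.
#' @export
default_register_spec <- function(mode = c("russian_like", "english_like"),
                                  label = "CDS") {
  mode <- match.arg(mode)
  if (mode == "russian_like") {
    wo <- c(AV = 0.26, AVP = 0.22, APV = 0.17, VP = 0.10, PV = 0.07,
            PAV = 0.08, VAP = 0.04, PVA = 0.02, VPA = 0.02, VA = 0.02)
    register_spec(default_lexicon(mode), default_paradigm(mode), wo,
                  role_entropy_concentration = c(A = 1, P = 1),
                  omission_prob = c(A = 0.3, P = 0.4),
                  number_dist = c(SG = 0.75, PL = 0.25),
                  pronoun_prob = 0.35, filler_prob = 0.2, label = label)
  } else {
    wo <- c(AVP = 0.52, AV = 0.20, VP = 0.15, PV = 0.05, PAV = 0.04,
            PVA = 0.02, VAP = 0.01, VPA = 0.01)
    register_spec(default_lexicon(mode), default_paradigm(mode), wo,
                  role_entropy_concentration = c(A = 1, P = 1),
                  omission_prob = c(A = 0.25, P = 0.25),
                  number_dist = c(SG = 0.7, PL = 0.3),
                  pronoun_prob = 0.35, filler_prob = 0.25, label = label)
  }
}

# Role-conditional noun-lemma distribution implied by a spec. Computed in
# log space so extreme concentration exponents cannot overflow.
role_lemma_dist <- function(spec, role) {
  n <- spec$lexicon$nouns
  gamma <- spec$role_entropy_concentration[[role]]
  lw <- gamma * log(n$base_weight * n[[paste0("bias_", role)]])
  lw <- lw - max(lw)
  p <- exp(lw) / sum(exp(lw))
  names(p) <- n$lemma
  p
}

#' Closed-form role-conditional lemma entropy of a spec
#'
#' Shannon entropy (bits) of the noun-lemma distribution the generator
#' samples from for a given role; the quantity [calibrate_role_entropy()]
#' targets.
#'
#' @param spec An `rp_register_spec`.
#' @param role `"A"` or `"P"`.
#' @return Entropy in bits.
#' @export
spec_role_entropy <- function(spec, role) {
  p <- role_lemma_dist(spec, role)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Calibrate a register's role-conditional entropy
#'
#' Finds the concentration exponent for one role such that the implied
#' noun-lemma distribution has the requested Shannon entropy, by bisection
#' on the exponent (entropy is monotone non-increasing in it).
#'
#' @param spec An `rp_register_spec`.
#' @param target_H Target entropy in bits per role; named vector with any of
#'   `A`, `P`. Must lie in `[H_min, log2(n_lemmas)]` where `H_min` is the
#'   entropy at the maximal searched concentration (effectively 0).
#' @param tol Bisection tolerance on entropy, bits.
#' @return The spec with updated `role_entropy_concentration`.
#' @export
calibrate_role_entropy <- function(spec, target_H, tol = 0.005) {
  for (role in names(target_H)) {
    H <- target_H[[role]]
    n_lemmas <- nrow(spec$lexicon$nouns)
    if (H < 0 || H > log2(n_lemmas) + 1e-9)
      rp_error("rp_unreachable_entropy",
               "target %.3f bits outside [0, log2(%d) = %.3f]", H, n_lemmas, log2(n_lemmas))
    ent_at <- function(g) {
      s <- spec; s$role_entropy_concentration[[role]] <- g
      spec_role_entropy(s, role)
    }
    lo <- 0; hi <- 1
    while (ent_at(hi) > H && hi < 512) hi <- hi * 2
    if (ent_at(hi) > H + tol)
      rp_error("rp_unreachable_entropy",
               "target %.3f bits unreachable (floor %.3f at max concentration)", H, ent_at(hi))
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (ent_at(mid) > H) lo <- mid else hi <- mid
    }
    spec$role_entropy_concentration[[role]] <- (lo + hi) / 2
  }
  spec
}

#' Derive a matched register pair from one base specification
#'
#' Returns two specs sharing lexicon and paradigm, differing only in the
#' named dimensions. Defaults mirror the direction observed between
#' child-directed and adult-directed speech: the `cds`-labelled spec gets
#' *lower* role-conditional lexical entropy (and, when requested, fewer
#' syncretic forms / sharper word order) than the `ads`-labelled one.
#'
#' @param base An `rp_register_spec` (used as the ADS-like member).
#' @param deltas Named list of overrides applied to the CDS-like member:
#'   `entropy` (named vector of bit offsets per role, negative = lower
#'   entropy in CDS), `syncretism` (multiplier < 1 down-weighting nouns of
#'   syncretism-prone declension classes), `order_concentration` (exponent
#'   > 1 sharpening the word-order distribution).
#' @return List with elements `cds` and `ads`.
#' @export
make_register_pair <- function(base, deltas = list()) {
  ads <- base; ads$label <- "ADS"
  cds <- base; cds$label <- "CDS"
  if (!is.null(deltas$entropy)) {
    target <- vapply(names(deltas$entropy),
                     function(r) spec_role_entropy(base, r) + deltas$entropy[[r]], 0)
    names(target) <- names(deltas$entropy)
    cds <- calibrate_role_entropy(cds, target)
  }
  if (!is.null(deltas$syncretism)) {
    syncretic_classes <- syncretism_prone_classes(base$paradigm)
    i <- cds$lexicon$nouns$declension %in% syncretic_classes
    cds$lexicon$nouns$base_weight[i] <- cds$lexicon$nouns$base_weight[i] * deltas$syncretism
    cds$paradigm <- bind_lexicon(cds$paradigm, cds$lexicon)
  }
  if (!is.null(deltas$order_concentration)) {
    w <- cds$word_order_dist^deltas$order_concentration
    cds$word_order_dist <- w / sum(w)
  }
  list(cds = cds, ads = ads)
}

# Declension classes whose NOM and ACC suffixes coincide in some number.
syncretism_prone_classes <- function(paradigm) {
  s <- paradigm$suffixes
  out <- character()
  for (d in unique(s$declension)) for (nb in unique(s$number)) {
    nom <- s$suffix[s$declension == d & s$case == "NOM" & s$number == nb]
    acc <- s$suffix[s$declension == d & s$case == "ACC" & s$number == nb]
    if (length(nom) && length(acc) && nom == acc) out <- c(out, d)
  }
  unique(out)
}

#' Serialise / restore a register spec as YAML
#'
#' Writes the scalar knobs and tables of a spec; built-in lexicons and
#' paradigms are referenced by mode and rebuilt on read.
#'
#' @param spec An `rp_register_spec`.
#' @param path Output path.
#' @return `path` invisibly; `read_register_spec` returns the spec.
#' @export
write_register_spec <- function(spec, path) {
  obj <- list(mode = spec$lexicon$mode, label = spec$label,
              word_order_dist = as.list(spec$word_order_dist),
              role_entropy_concentration = as.list(spec$role_entropy_concentration),
              omission_prob = as.list(spec$omission_prob),
              number_dist = as.list(spec$number_dist),
              pronoun_prob = spec$pronoun_prob, filler_prob = spec$filler_prob)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_register_spec
#' @export
read_register_spec <- function(path) {
  if (!file.exists(path)) rp_error("rp_missing_file", "no such file: %s", path)
  o <- yaml::read_yaml(path)
  register_spec(default_lexicon(o$mode), default_paradigm(o$mode),
                unlist(o$word_order_dist),
                role_entropy_concentration = unlist(o$role_entropy_concentration),
                omission_prob = unlist(o$omission_prob),
                number_dist = unlist(o$number_dist),
                pronoun_prob = o$pronoun_prob, filler_prob = o$filler_prob,
                label = o$label)
}
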