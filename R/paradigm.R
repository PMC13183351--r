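#' Construct a case paradigm
#'
#' A paradigm maps cells `(declension class, case, number)` to surface
#' suffixes, plus a closed pronoun table mapping forms directly to cells. A
#' surface form is *syncretic* when it realises more than one cell: in the
#' default synthetic paradigm the inanimate class has identical nominative
#' and accusative forms (the krug/okno pattern) while the animate class
#' distinguishes them (drug vs druga).
#'
#' @param suffixes Data frame with columns `declension`, `case`, `number`,
#'   `suffix`.
#' @param pronouns Data frame with columns `form`, `lemma`, `case`, `number`.
#' @param cases Ordered case inventory; defaults to the cases present.
#' @return Object of class `rp_case_paradigm`.
#' @export
case_paradigm <- function(suffixes, pronouns = NULL,
                          cases = unique(suffixes$case)) {
  need <- c("declension", "case", "number", "suffix")
  if (!all(need %in% names(suffixes)))
    rp_error("rp_bad_paradigm", "paradigm table needs columns %s", paste(need, collapse = ", "))
  if (!all(suffixes$case %in% cases))
    rp_error("rp_bad_paradigm", "paradigm references a case outside the inventory")
  structure(list(suffixes = suffixes, pronouns = pronouns, cases = cases,
                 numbers = unique(suffixes$number), form_index = NULL),
            class = "rp_case_paradigm")
}

#' Realise a noun form
#'
#' @param paradigm An `rp_case_paradigm`.
#' @param stem Noun stem.
#' @param declension Declension class present in the paradigm.
#' @param case,number Target cell.
#' @return Surface form (stem + suffix).
#' @export
realize_form <- function(paradigm, stem, declension, case, number) {
  s <- paradigm$suffixes
  i <- which(s$declension == declension & s$case == case & s$number == number)
  if (!length(i))
    rp_error("rp_bad_paradigm", "no paradigm cell (%s, %s, %s)", declension, case, number)
  paste0(stem, s$suffix[i[1]])
}

#' Index every realisable form of a lexicon under a paradigm
#'
#' Computes the preimage of the realisation table: for each surface form, the
#' set of `(case, number)` cells it can express, pooling over the nouns in
#' `lexicon` and the pronoun table. The index is required by
#' [possible_cases()] and [encode_case()].
#'
#' @param paradigm An `rp_case_paradigm`.
#' @param lexicon An [grammar_lexicon()] whose nouns carry `lemma` (stem) and
#'   `declension` columns.
#' @return The paradigm with its `form_index` populated.
#' @export
bind_lexicon <- function(paradigm, lexicon) {
  cells <- expand.grid(case = paradigm$cases, number = paradigm$numbers,
                       stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(lexicon$nouns))) {
    n <- lexicon$nouns[i, ]
    for (j in seq_len(nrow(cells))) {
      rows[[length(rows) + 1L]] <- data.frame(
        form = realize_form(paradigm, n$lemma, n$declension, cells$case[j], cells$number[j]),
        case = cells$case[j], number = cells$number[j], stringsAsFactors = FALSE)
    }
  }
  if (!is.null(paradigm$pronouns))
    rows[[length(rows) + 1L]] <- paradigm$pronouns[, c("form", "case", "number")]
  tab <- unique(do.call(rbind, rows))
  paradigm$form_index <- split(tab[, c("case", "number")], tab$form)
  paradigm
}

#' Possible case cells of a surface form
#'
#' @param paradigm A paradigm with a bound form index (see [bind_lexicon()]).
#' @param form Surface form.
#' @return Data frame of `(case, number)` cells; more than one row means the
#'   form is syncretic.
#' @export
possible_cases <- function(paradigm, form) {
  if (is.null(paradigm$form_index))
    rp_error("rp_bad_paradigm", "paradigm has no form index; call bind_lexicon() first")
  cells <- paradigm$form_index[[form]]
  if (is.null(cells))
    rp_error("rp_form_not_in_paradigm", "form '%s' not analyzable by the paradigm", form)
  cells
}

#' Multi-hot possible-case vector of an argument form
#'
#' One bit per `(case, number)` cell of the paradigm's inventory; a bit is
#' set when the surface form can realise that cell. Exactly one set bit means
#' the form is unambiguous (like *ona*, nominative singular only); several
#' set bits mark a syncretic form (like *okno*, nominative = accusative
#' singular).
#'
#' @param form Surface form of the argument's head word.
#' @param paradigm A paradigm with a bound form index.
#' @return Named 0/1 integer vector over `case.number` cells.
#' @export
encode_case <- function(form, paradigm) {
  cells <- possible_cases(paradigm, form)
  grid <- expand.grid(case = paradigm$cases, number = paradigm$numbers,
                      stringsAsFactors = FALSE)
  lab <- paste(grid$case, grid$number, sep = ".")
  v <- as.integer(lab %in% paste(cells$case, cells$number, sep = "."))
  names(v) <- lab
  v
}

#' Is a surface form syncretic under a paradigm?
#' @inheritParams possible_cases
#' @return Logical.
#' @export
is_syncretic <- function(paradigm, form) nrow(possible_cases(paradigm, form)) > 1L

#' Built-in synthetic case paradigms
#'
#' `"russian_like"`: six cases, two numbers, three declension classes —
#' `animate` (distinct NOM/ACC throughout), `inanimate` (NOM = ACC in both
#' numbers) and `feminine` (distinct in the singular, NOM = ACC in the
#' plural) — plus a small pronoun table with both unambiguous and ambiguous
#' forms. `"english_like"`: a caseless noun system (every case shares the
#' bare/plural form, so nouns are maximally syncretic for case but mark
#' number) with the she/her, they/them, you pronoun paradigm.
#'
#' @param mode `"russian_like"` or `"english_like"`.
#' @return An `rp_case_paradigm` (form index not yet bound).
#' @export
default_paradigm <- function(mode = c("russian_like", "english_like")) {
  mode <- match.arg(mode)
  if (mode == "russian_like") {
    sfx <- rbind(
      expand_sfx("animate",
                 SG = c(NOM = "", ACC = "a", GEN = "y", DAT = "u", INS = "om", LOC = "e"),
                 PL = c(NOM = "i", ACC = "ov", GEN = "ej", DAT = "am", INS = "ami", LOC = "ax")),
      expand_sfx("inanimate",
                 SG = c(NOM = "", ACC = "", GEN = "a", DAT = "u", INS = "om", LOC = "e"),
                 PL = c(NOM = "i", ACC = "i", GEN = "ov", DAT = "am", INS = "ami", LOC = "ax")),
      expand_sfx("feminine",
                 SG = c(NOM = "a", ACC = "u", GEN = "y", DAT = "e", INS = "oj", LOC = "e"),
                 PL = c(NOM = "y", ACC = "y", GEN = "", DAT = "am", INS = "ami", LOC = "ax")))
    pro <- data.frame(
      form   = c("ja", "menja", "ty", "tebja", "ona", "ejo", "oni", "ix"),
      lemma  = c("ja", "ja", "ty", "ty", "ona", "ona", "oni", "oni"),
      case   = c("NOM", "ACC", "NOM", "ACC", "NOM", "ACC", "NOM", "ACC"),
      number = c("SG", "SG", "SG", "SG", "SG", "SG", "PL", "PL"),
      stringsAsFactors = FALSE)
    case_paradigm(sfx, pro, cases = c("NOM", "ACC", "GEN", "DAT", "INS", "LOC"))
  } else {
    sfx <- expand_sfx("common",
                      SG = c(NOM = "", ACC = ""),
                      PL = c(NOM = "s", ACC = "s"))
    pro <- data.frame(
      form   = c("she", "her", "they", "them", "you", "you", "you", "you"),
      lemma  = c("she", "she", "they", "they", "you", "you", "you", "you"),
      case   = c("NOM", "ACC", "NOM", "ACC", "NOM", "ACC", "NOM", "ACC"),
      number = c("SG", "SG", "PL", "PL", "SG", "SG", "PL", "PL"),
      stringsAsFactors = FALSE)
    case_paradigm(sfx, pro, cases = c("NOM", "ACC"))
  }
}

expand_sfx <- function(declension, SG, PL) {
  rbind(
    data.frame(declension = declension, case = names(SG), number = "SG",
               suffix = unname(SG), stringsAsFactors = FALSE),
    data.frame(declension = declension, case = names(PL), number = "PL",
               suffix = unname(PL), stringsAsFactors = FALSE))
}
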