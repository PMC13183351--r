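#' Three-feature argument-position vector
#'
#' The structural representation of an argument: (1) whether the argument
#' occupies the utterance-initial token, (2) whether it precedes the verb,
#' (3) whether the clause's other argument is overt. "First position"
#' counts every token, so a clause-initial interjection or wh-word makes the
#' following argument non-initial.
#'
#' @param instance One-row data frame (an argument instance).
#' @param utterance The housing [utterance()].
#' @param co_instance The clause's other argument instance, or `NULL` when
#'   it is omitted.
#' @return Named integer vector `(is_first, before_verb, other_present)`,
#'   each 0/1.
#' @export
encode_position <- function(instance, utterance, co_instance = NULL) {
  if (instance$utterance_id != utterance$id)
    rp_error("rp_missing_utterance", "instance does not belong to utterance '%s'", utterance$id)
  c(is_first = as.integer(instance$span_start == 0L),
    before_verb = as.integer(instance$span_start < instance$verb_index),
    other_present = as.integer(!is.null(co_instance) && nrow(co_instance) > 0L))
}

#' Position vectors for every argument instance of a dataset
#' @param dataset An `rp_role_dataset`.
#' @return Integer matrix with columns `is_first`, `before_verb`,
#'   `other_present`, one row per instance.
#' @export
encode_positions <- function(dataset) {
  ins <- dataset$instances
  per_utt <- table(ins$utterance_id)
  cbind(is_first = as.integer(ins$span_start == 0L),
        before_verb = as.integer(ins$span_start < ins$verb_index),
        other_present = as.integer(per_utt[ins$utterance_id] > 1L))
}

#' Case vectors for every argument instance of a dataset
#'
#' Applies [encode_case()] to each instance's head form (the argument's
#' content word, excluding determiners and adpositions).
#'
#' @param dataset An `rp_role_dataset` whose instances carry a `head_form`
#'   column (generated corpora do), or whose surfaces are single words.
#' @param paradigm An `rp_case_paradigm` with a bound form index.
#' @return Integer matrix, one row per instance, columns `case.number`.
#' @export
encode_cases <- function(dataset, paradigm) {
  ins <- dataset$instances
  forms <- if (!is.null(ins$head_form)) ins$head_form else ins$surface
  t(vapply(forms, function(f) encode_case(f, paradigm),
           integer(length(paradigm$cases) * length(paradigm$numbers))))
}
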