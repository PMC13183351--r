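# Distinctly classed conditions so callers can catch individual failure modes.
rp_error <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "regiprobe_error", "error", "condition")))
}

#' Construct a single utterance record
#'
#' An utterance is a tokenised clause together with its register label.
#' Punctuation counts as tokens; token indexing throughout the package is
#' 0-based with half-open spans.
#'
#' @param id Unique utterance id (string).
#' @param tokens Non-empty character vector of surface tokens.
#' @param register Register tag, e.g. `"CDS"` or `"ADS"`.
#' @param language Language tag (free string).
#' @param morph Optional list of per-token records (lemma, cases, number).
#' @param source Optional provenance string.
#' @return A list of class `rp_utterance`.
#' @export
utterance <- function(id, tokens, register = "CDS", language = "synthetic",
                      morph = NULL, source = NULL) {
  if (!is.character(tokens) || length(tokens) == 0L)
    rp_error("rp_bad_utterance", "utterance '%s': tokens must be a non-empty character vector", id)
  structure(list(id = as.character(id), register = register, language = language,
                 tokens = tokens, morph = morph, source = source),
            class = "rp_utterance")
}

#' Construct an argument instance
#'
#' One role-labelled argument span tied to a bivalent verb: the atomic datum
#' of the agent/patient classification task.
#'
#' @param utterance_id Id of the housing utterance.
#' @param role `"A"` (most agent-like) or `"P"` (most patient-like).
#' @param span Integer pair `c(start, end)`, 0-based half-open token interval.
#' @param verb_lemma Lemma of the bivalent verb.
#' @param verb_index 0-based token index of the verb; must lie outside `span`.
#' @param condition Optional condition tag (controlled datasets).
#' @return A one-row data frame.
#' @export
argument_instance <- function(utterance_id, role, span, verb_lemma, verb_index,
                              condition = NA_character_) {
  if (!role %in% c("A", "P"))
    rp_error("rp_unknown_role", "utterance '%s': unknown role label '%s'", utterance_id, role)
  span <- as.integer(span)
  if (length(span) != 2L || span[1] < 0L || span[2] <= span[1])
    rp_error("rp_bad_span", "utterance '%s': invalid span [%s)", utterance_id,
             paste(span, collapse = ","))
  if (verb_index >= span[1] && verb_index < span[2])
    rp_error("rp_bad_span", "utterance '%s': verb index %d inside argument span", utterance_id,
             as.integer(verb_index))
  data.frame(utterance_id = as.character(utterance_id), role = role,
             span_start = span[1], span_end = span[2],
             verb_lemma = verb_lemma, verb_index = as.integer(verb_index),
             condition = condition, stringsAsFactors = FALSE)
}

#' Assemble a role-annotated dataset
#'
#' Binds utterances and their argument instances into the container used by
#' every downstream stage, validating spans, role labels and referential
#' integrity.
#'
#' @param utterances List of [utterance()] records.
#' @param instances Data frame of argument instances (rows as produced by
#'   [argument_instance()], possibly with extra metadata columns).
#' @return An object of class `rp_role_dataset` with elements `utterances`
#'   (named list), `instances` (data frame with a `surface` column added) and
#'   `verb_inventory` (character vector).
#' @export
role_dataset <- function(utterances, instances) {
  ids <- vapply(utterances, `[[`, "", "id")
  if (anyDuplicated(ids))
    rp_error("rp_duplicate_id", "duplicate utterance id '%s'", ids[duplicated(ids)][1])
  names(utterances) <- ids
  if (is.null(instances) || nrow(instances) == 0L) {
    instances <- data.frame(utterance_id = character(), role = character(),
                            span_start = integer(), span_end = integer(),
                            verb_lemma = character(), verb_index = integer(),
                            condition = character(), surface = character(),
                            stringsAsFactors = FALSE)
  } else {
    bad <- setdiff(instances$utterance_id, ids)
    if (length(bad))
      rp_error("rp_missing_utterance", "instance references unknown utterance '%s'", bad[1])
    nt <- vapply(utterances, function(u) length(u$tokens), 0L)[instances$utterance_id]
    if (any(instances$span_end > nt)) {
      i <- which(instances$span_end > nt)[1]
      rp_error("rp_span_out_of_bounds", "utterance '%s': span end %d exceeds token count %d",
               instances$utterance_id[i], instances$span_end[i], nt[i])
    }
    if (any(!instances$role %in% c("A", "P")))
      rp_error("rp_unknown_role", "unknown role label '%s'",
               setdiff(unique(instances$role), c("A", "P"))[1])
    instances$surface <- vapply(seq_len(nrow(instances)), function(i) {
      u <- utterances[[instances$utterance_id[i]]]
      paste(u$tokens[(instances$span_start[i] + 1L):instances$span_end[i]], collapse = " ")
    }, "")
    if (is.null(instances$condition)) instances$condition <- NA_character_
    rownames(instances) <- NULL
  }
  structure(list(utterances = utterances, instances = instances,
                 verb_inventory = sort(unique(instances$verb_lemma))),
            class = "rp_role_dataset")
}

#' @export
print.rp_role_dataset <- function(x, ...) {
  cat(sprintf("<rp_role_dataset> %d utterances, %d argument instances, %d verbs\n",
              length(x$utterances), nrow(x$instances), length(x$verb_inventory)))
  tab <- table(x$instances$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  regs <- table(vapply(x$utterances, `[[`, "", "register"))
  cat("  registers:", paste(sprintf("%s=%d", names(regs), regs), collapse = ", "), "\n")
  invisible(x)
}

#' Total token count of a dataset
#' @param dataset An `rp_role_dataset`.
#' @return Integer number of tokens summed over utterances.
#' @export
n_tokens <- function(dataset) {
  sum(vapply(dataset$utterances, function(u) length(u$tokens), 0L))
}

#' Read a role-annotated dataset
#'
#' Reads the canonical JSONL schema (one utterance object per line with an
#' `instances` array) or a CoNLL-U file paired with a TSV case-frame table
#' (`format = "conllu"`), in which case roles are assigned with
#' [map_roles_from_frame()].
#'
#' @param path File path.
#' @param format `"jsonl"` or `"conllu"`.
#' @param frames For `"conllu"`: case-frame table from [read_case_frames()].
#' @param register,language Labels applied to CoNLL-U input (JSONL carries
#'   its own).
#' @return An `rp_role_dataset`. Unparseable records raise errors naming the
#'   offending record rather than being dropped silently.
#' @export
read_role_dataset <- function(path, format = c("jsonl", "conllu"), frames = NULL,
                              register = "CDS", language = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) rp_error("rp_missing_file", "no such file: %s", path)
  if (format == "jsonl") read_jsonl_dataset(path) else
    read_conllu_dataset(path, frames, register, language)
}

read_jsonl_dataset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(role_dataset(list(), NULL))
  utts <- vector("list", length(lines))
  inst <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    utts[[i]] <- utterance(rec$id, unlist(rec$tokens),
                           register = rec$register %||% "CDS",
                           language = rec$language %||% "unknown",
                           morph = rec$morph, source = rec$source)
    if (length(rec$instances))
      inst[[i]] <- do.call(rbind, lapply(rec$instances, function(z)
        argument_instance(rec$id, z$role, unlist(z$span), z$verb_lemma,
                          z$verb_index, z$condition %||% NA_character_)))
  }
  role_dataset(utts, do.call(rbind, inst[!vapply(inst, is.null, TRUE)]))
}

#' Write a role-annotated dataset as JSONL
#'
#' Inverse of [read_role_dataset()]; `write` then `read` reproduces the
#' dataset record for record.
#'
#' @param dataset An `rp_role_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_role_dataset <- function(dataset, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (u in dataset$utterances) {
    ins <- dataset$instances[dataset$instances$utterance_id == u$id, , drop = FALSE]
    rec <- list(id = u$id, register = u$register, language = u$language,
                tokens = as.list(u$tokens))
    if (!is.null(u$morph)) rec$morph <- u$morph
    if (!is.null(u$source)) rec$source <- u$source
    rec$instances <- lapply(seq_len(nrow(ins)), function(i) {
      z <- list(role = ins$role[i], span = c(ins$span_start[i], ins$span_end[i]),
                verb_lemma = ins$verb_lemma[i], verb_index = ins$verb_index[i])
      if (!is.na(ins$condition[i])) z$condition <- ins$condition[i]
      z
    })
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TSV case-frame table
#'
#' Columns `verb_lemma`, `relation` (nsubj/obj/obl), `case`, `role`. Each
#' verb's frame must map exactly one slot to A and one to P.
#'
#' @param path TSV file path.
#' @return Data frame of class `rp_case_frames`.
#' @export
read_case_frames <- function(path) {
  if (!file.exists(path)) rp_error("rp_missing_file", "no such file: %s", path)
  fr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("verb_lemma", "relation", "case", "role")
  if (!all(need %in% names(fr)))
    rp_error("rp_bad_frame_table", "case-frame table must have columns %s",
             paste(need, collapse = ", "))
  for (v in unique(fr$verb_lemma)) {
    r <- fr$role[fr$verb_lemma == v]
    if (sum(r == "A") != 1L || sum(r == "P") != 1L)
      rp_error("rp_bad_frame_table", "verb '%s': frame must assign exactly one A and one P slot", v)
  }
  class(fr) <- c("rp_case_frames", "data.frame")
  fr
}

#' Map grammatical relations to semantic roles via case frames
#'
#' Given a dependency-parsed clause (tokens plus per-token relation and case
#' labels relative to one bivalent verb), assigns A/P roles by looking up the
#' verb's case frame, e.g. a frame `<NOM (A), ACC (P)>` sends a nominative
#' `nsubj` to A and an accusative `obj` to P. Dependents matching no frame
#' slot yield no instance.
#'
#' @param utterance_id Id for the produced instances.
#' @param tokens Character vector of surface tokens.
#' @param relations Character vector, per token: `nsubj`/`obj`/`obl` or `NA`.
#' @param cases Character vector, per token: case label or `NA`.
#' @param verb_lemma,verb_index The clause's bivalent verb (0-based index).
#' @param frames Case-frame table from [read_case_frames()].
#' @return Data frame of argument instances; zero rows with attribute
#'   `excluded = TRUE` when both arguments are omitted.
#' @export
map_roles_from_frame <- function(utterance_id, tokens, relations, cases,
                                 verb_lemma, verb_index, frames) {
  fr <- frames[frames$verb_lemma == verb_lemma, , drop = FALSE]
  if (!nrow(fr))
    rp_error("rp_verb_not_in_frames", "verb '%s' absent from case-frame inventory", verb_lemma)
  out <- NULL
  for (i in seq_len(nrow(fr))) {
    hit <- which(!is.na(relations) & relations == fr$relation[i] &
                   !is.na(cases) & cases == fr$case[i])
    for (h in hit) {
      out <- rbind(out, argument_instance(utterance_id, fr$role[i],
                                          c(h - 1L, h), verb_lemma, verb_index))
    }
  }
  if (is.null(out)) {
    out <- argument_instance("x", "A", c(0L, 1L), verb_lemma, 2L)[0, ]
    attr(out, "excluded") <- TRUE  # both arguments omitted: flagged for exclusion
  }
  out
}

# Minimal CoNLL-U reader: one sentence block per utterance, role mapping via
# the frame table. The sentence's verb is the first token whose lemma is in
# the frame inventory; case read from the FEATS column (Case=XXX).
read_conllu_dataset <- function(path, frames, register, language) {
  if (is.null(frames))
    rp_error("rp_bad_frame_table", "conllu input requires a case-frame table")
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(lines == ""))
  utts <- list(); inst <- list(); k <- 0L
  for (b in blocks) {
    b <- b[nzchar(b) & !startsWith(b, "#")]
    if (!length(b)) next
    f <- do.call(rbind, strsplit(b, "\t", fixed = TRUE))
    if (ncol(f) < 8) rp_error("rp_bad_conllu", "malformed CoNLL-U row near '%s'", b[1])
    f <- f[grepl("^[0-9]+$", f[, 1]), , drop = FALSE]  # skip multiword ranges
    toks <- f[, 2]; lemmas <- f[, 3]; feats <- f[, 6]; rels <- f[, 8]
    cases <- ifelse(grepl("Case=", feats),
                    sub(".*Case=([A-Za-z]+).*", "\\1", feats), NA_character_)
    cases <- toupper(cases)
    vi <- which(lemmas %in% frames$verb_lemma)
    if (!length(vi)) next
    vi <- vi[1]
    k <- k + 1L
    id <- sprintf("conllu_%04d", k)
    utts[[k]] <- utterance(id, toks, register = register, language = language)
    rel <- ifelse(rels %in% c("nsubj", "obj", "obl"), rels, NA_character_)
    ai <- map_roles_from_frame(id, toks, rel, cases, lemmas[vi], vi - 1L, frames)
    if (nrow(ai)) inst[[length(inst) + 1L]] <- ai
  }
  role_dataset(utts, if (length(inst)) do.call(rbind, inst) else NULL)
}

#' Apply the standard dataset filters
#'
#' Drops verbs attested in fewer than `min_per_verb` utterances and removes
#' utterances in which both arguments are omitted (i.e. utterances that end
#' up with no argument instance). Idempotent.
#'
#' @param dataset An `rp_role_dataset`.
#' @param min_per_verb Minimum number of utterances per retained verb.
#' @param id_blocklist Optional character vector of utterance ids to exclude
#'   (stands in for manual removal of idiomatic uses).
#' @return Filtered `rp_role_dataset`; attribute `removed` carries counts.
#' @export
apply_dataset_filters <- function(dataset, min_per_verb = 10, id_blocklist = NULL) {
  ins <- dataset$instances
  n0 <- nrow(ins)
  if (length(id_blocklist)) ins <- ins[!ins$utterance_id %in% id_blocklist, , drop = FALSE]
  repeat {
    per_verb <- tapply(ins$utterance_id, ins$verb_lemma,
                       function(u) length(unique(u)))
    keep <- names(per_verb)[per_verb >= min_per_verb]
    ins2 <- ins[ins$verb_lemma %in% keep, , drop = FALSE]
    if (nrow(ins2) == nrow(ins)) break
    ins <- ins2
  }
  keep_utt <- unique(ins$utterance_id)
  out <- role_dataset(unname(dataset$utterances[keep_utt]),
                      if (nrow(ins)) ins else NULL)
  attr(out, "removed") <- c(instances = n0 - nrow(ins),
                            utterances = length(dataset$utterances) - length(keep_utt))
  out
}

#' Label the word order of a clause
#'
#' Returns the left-to-right sequence over the alphabet \{A, P, V\}: the
#' position of an overt argument is its span start, the verb is the clause's
#' bivalent verb (auxiliaries are ignored), and omitted arguments contribute
#' no symbol. `"why did he bite the horse"` labels as `"AVP"`.
#'
#' @param utterance An [utterance()] (used for bounds checking).
#' @param instances Data frame of this utterance's argument instances.
#' @return A string such as `"AVP"`, `"APV"`, `"AV"`, `"VP"`.
#' @export
label_word_order <- function(utterance, instances) {
  if (nrow(instances) == 0L) return("V")
  if (nrow(instances) == 2L) {
    o <- order(instances$span_start)
    a <- instances[o[1], ]; b <- instances[o[2], ]
    if (b$span_start < a$span_end)
      rp_error("rp_overlapping_spans", "utterance '%s': overlapping argument spans", utterance$id)
  }
  pos <- c(instances$span_start, instances$verb_index[1])
  sym <- c(instances$role, "V")
  paste(sym[order(pos)], collapse = "")
}

#' Word-order labels for every utterance in a dataset
#' @param dataset An `rp_role_dataset`.
#' @return Named character vector, one label per utterance that has at least
#'   one argument instance.
#' @export
word_order_labels <- function(dataset) {
  ins <- dataset$instances
  o1 <- order(ins$utterance_id, ins$span_start, method = "radix")
  same <- ins$utterance_id[o1][-1] == ins$utterance_id[o1][-length(o1)]
  if (any(same & ins$span_start[o1][-1] < ins$span_end[o1][-nrow(ins)]))
    rp_error("rp_overlapping_spans", "utterance '%s': overlapping argument spans",
             ins$utterance_id[o1][-1][which(same & ins$span_start[o1][-1] <
                                              ins$span_end[o1][-nrow(ins)])[1]])
  first <- !duplicated(ins$utterance_id)
  ids <- c(ins$utterance_id, ins$utterance_id[first])
  pos <- c(ins$span_start, ins$verb_index[first])
  sym <- c(ins$role, rep("V", sum(first)))
  o <- order(ids, pos, method = "radix")
  vapply(split(sym[o], ids[o]), paste, "", collapse = "")
}

#' Sample a size-matched subcorpus
#'
#' Samples whole utterances without replacement until the token budget is
#' first met or exceeded, so differently sized registers can be matched (the
#' result's token count lies in `[budget, budget + longest utterance)`).
#' Deterministic given `seed`.
#'
#' @param dataset An `rp_role_dataset`.
#' @param token_budget Target token count.
#' @param seed Integer seed.
#' @return An `rp_role_dataset` restricted to the sampled utterances.
#' @export
sample_matched_corpus <- function(dataset, token_budget, seed) {
  nt <- vapply(dataset$utterances, function(u) length(u$tokens), 0L)
  if (sum(nt) < token_budget)
    rp_error("rp_corpus_too_small", "corpus has %d tokens < budget %d", sum(nt), token_budget)
  ord <- with_seed(seed, sample.int(length(nt)))
  cum <- cumsum(nt[ord])
  take <- ord[seq_len(which(cum >= token_budget)[1])]
  ids <- names(dataset$utterances)[take]
  ins <- dataset$instances[dataset$instances$utterance_id %in% ids, , drop = FALSE]
  role_dataset(unname(dataset$utterances[take]), if (nrow(ins)) ins else NULL)
}

# Run expr under a local RNG state; never disturbs the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
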