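#' Pipeline run configuration
#'
#' One object holding every knob of the two study pipelines, with all
#' randomness derived from a single root seed via fixed per-stage offsets.
#' The defaults are a desk-scale profile: two registers of about 50K tokens
#' each, the small encoder profile, ten verb-disjoint splits and a
#' subsampled hierarchical fit.
#'
#' @param seed Root integer seed.
#' @param mode Language mode of the synthetic registers.
#' @param n_utterances Utterances generated per register.
#' @param entropy_delta Named bit offsets applied to the CDS-like member of
#'   the register pair (see [make_register_pair()]); the defaults mirror
#'   the direction and magnitude reported for Russian child-directed
#'   speech (A about 0.8 bits lower, P about 0.55).
#' @param representations Representations to probe in Study 1.
#' @param encoder [encoder_config()] shared by both registers (its seed is
#'   re-derived from `seed`).
#' @param n_versions,train_size,val_range Split protocol.
#' @param chains,n_iter,n_adapt,stat_max_records Hierarchical-model
#'   controls; records are subsampled by sentence to at most
#'   `stat_max_records` rows per representation before fitting.
#' @param controlled_test_sentences Test sentences in the Study 2 split.
#' @return A list of class `rp_run_config`.
#' @export
run_config <- function(seed = 1, mode = "russian_like", n_utterances = 10000,
                       entropy_delta = c(A = -0.79, P = -0.55),
                       representations = c("contextual", "static",
                                           "position", "case"),
                       encoder = encoder_config(),
                       n_versions = 10, train_size = 100,
                       val_range = c(100, 300),
                       chains = 2, n_iter = 2000, n_adapt = 1000,
                       stat_max_records = 6000,
                       controlled_test_sentences = 100) {
  structure(list(seed = seed, mode = mode, n_utterances = n_utterances,
                 entropy_delta = entropy_delta,
                 representations = representations, encoder = encoder,
                 n_versions = n_versions, train_size = train_size,
                 val_range = val_range, chains = chains, n_iter = n_iter,
                 n_adapt = n_adapt, stat_max_records = stat_max_records,
                 controlled_test_sentences = controlled_test_sentences),
            class = "rp_run_config")
}

# Named substreams from the root seed; keeps every stage auditable.
stage_seed <- function(config, stage) {
  offs <- c(generate_cds = 11L, generate_ads = 12L, match = 13L,
            encoder = 21L, split = 31L, probe = 32L, stats = 41L,
            controlled = 51L, study2_split = 52L)
  (config$seed * 1009L + offs[[stage]]) %% 2100000000L
}

# Thin records for the statistical stage. A sentence's records across
# splits are highly correlated (same argument, slightly different probes),
# so precision per record is maximised by capping records per argument and
# spending the budget on distinct sentences, sampled stratified by register
# so both registers keep equal sentence counts.
subsample_records <- function(records, max_records, seed, per_argument_cap = 2L) {
  if (nrow(records) <= max_records) return(records)
  with_seed(seed, {
    key <- paste(records$sentence_id, records$role)
    idx <- unlist(lapply(split(seq_len(nrow(records)), key), function(i)
      if (length(i) <= per_argument_cap) i else sample(i, per_argument_cap)),
      use.names = FALSE)
    rec <- records[sort(idx), , drop = FALSE]
    if (nrow(rec) > max_records) {
      sent_reg <- unique(rec[, c("sentence_id", "register")])
      per <- nrow(rec) / nrow(sent_reg)
      budget <- max(2L, floor(max_records / per))
      keep <- unlist(lapply(split(sent_reg$sentence_id, sent_reg$register),
                            function(s) sample(s, min(length(s), ceiling(budget / 2)))),
                     use.names = FALSE)
      rec <- rec[rec$sentence_id %in% keep, , drop = FALSE]
    }
    rec
  })
}

#' Run the register-comparison study end to end
#'
#' Generates (or accepts) a CDS-like/ADS-like register pair, size-matches
#' and filters the corpora, trains the per-register representation models,
#' runs the verb-disjoint probing protocol, computes entropy descriptives
#' and fits one hierarchical Bernoulli model per representation, ending in
#' counterfactual register contrasts (delta-P) overall and per role.
#'
#' @param config An [run_config()].
#' @param datasets Optional named list `list(CDS = , ADS = )` of prepared
#'   `rp_role_dataset`s, bypassing synthetic generation (e.g. real corpora
#'   read with [read_role_dataset()], or identity controls).
#' @param encoders Optional named list of pre-trained encoders (bypasses
#'   encoder training).
#' @param fit_stats Set `FALSE` to stop after probing (no Bayesian stage).
#' @return Object of class `rp_study1_report`: corpora summaries, entropy
#'   reports, accuracy table, per-representation fits and delta-P
#'   summaries (`overall` and per role).
#' @export
run_study1 <- function(config = run_config(), datasets = NULL,
                       encoders = NULL, fit_stats = TRUE) {
  paradigm <- bind_lexicon(default_paradigm(config$mode),
                           default_lexicon(config$mode))
  if (is.null(datasets)) {
    pair <- make_register_pair(default_register_spec(config$mode, label = "ADS"),
                               deltas = list(entropy = config$entropy_delta))
    cds <- generate_corpus(pair$cds, config$n_utterances,
                           stage_seed(config, "generate_cds"))
    ads <- generate_corpus(pair$ads, config$n_utterances,
                           stage_seed(config, "generate_ads"))
    datasets <- list(CDS = cds, ADS = ads)
    paradigm <- pair$cds$paradigm
  }
  budget <- min(vapply(datasets, n_tokens, 0L))
  datasets <- lapply(datasets, function(d)
    if (n_tokens(d) > budget)
      sample_matched_corpus(d, budget, stage_seed(config, "match")) else d)
  datasets <- lapply(datasets, apply_dataset_filters)
  enc_cfg <- config$encoder
  enc_cfg$seed <- stage_seed(config, "encoder")
  exp <- run_register_experiment(
    datasets, config$representations, enc_cfg, paradigm = paradigm,
    n_versions = config$n_versions, train_size = config$train_size,
    val_range = config$val_range, split_seed = stage_seed(config, "split"),
    probe_seed = stage_seed(config, "probe"), encoders = encoders)
  entropy <- lapply(datasets, describe_dataset, paradigm = paradigm)
  fits <- list(); delta_p <- list()
  if (fit_stats) {
    for (r in unique(exp$records$representation)) {
      rec <- subsample_records(exp$records[exp$records$representation == r, ],
                               config$stat_max_records,
                               stage_seed(config, "stats"))
      fit <- fit_hier_bernoulli(rec, random = "study1", chains = config$chains,
                                n_iter = config$n_iter, n_adapt = config$n_adapt,
                                seed = stage_seed(config, "stats"),
                                on_nonconvergence = "warn")
      fits[[r]] <- fit
      delta_p[[r]] <- list(overall = counterfactual_delta_p(fit),
                           A = counterfactual_delta_p(fit, list(role = "A")),
                           P = counterfactual_delta_p(fit, list(role = "P")))
    }
  }
  structure(list(config = config,
                 corpus_tokens = vapply(datasets, n_tokens, 0L),
                 datasets = datasets, entropy = entropy,
                 records = exp$records, accuracy = exp$accuracy,
                 encoders = exp$encoders, splits = exp$splits,
                 fits = fits, delta_p = delta_p),
            class = "rp_study1_report")
}

#' @export
print.rp_study1_report <- function(x, ...) {
  cat("<rp_study1_report>\n  corpus tokens:",
      paste(sprintf("%s=%d", names(x$corpus_tokens), x$corpus_tokens),
            collapse = ", "), "\n")
  print(x$accuracy, row.names = FALSE)
  for (r in names(x$delta_p)) {
    cat(sprintf("  delta-P [%s]: %+0.4f [%.4f, %.4f]\n", r,
                x$delta_p[[r]]$overall$mean,
                x$delta_p[[r]]$overall$ci[1], x$delta_p[[r]]$overall$ci[2]))
  }
  invisible(x)
}

#' Run the controlled generalisation study end to end
#'
#' Generates the controlled test set for the configured language mode,
#' composes the fixed-condition split, evaluates the two register-trained
#' encoders on the identical test items, and fits the Study-2 hierarchical
#' model (condition effects in English mode, syncretism and word-order
#' effects in Russian mode; sentence intercepts varying by register),
#' ending in per-condition delta-P summaries.
#'
#' @param config An [run_config()].
#' @param encoders Named list of register-trained encoders (e.g. from a
#'   [run_study1()] report's `encoders`).
#' @param fit_stats Set `FALSE` to skip the Bayesian stage.
#' @return Object of class `rp_study2_report`.
#' @export
run_study2 <- function(config = run_config(), encoders, fit_stats = TRUE) {
  mode <- config$mode
  lex <- default_lexicon(mode)
  controlled <- generate_controlled_sentences(
    lex, default_paradigm(mode), condition_spec(mode),
    seed = stage_seed(config, "controlled"))
  split <- compose_study2_split(controlled, mode,
                                seed = stage_seed(config, "study2_split"),
                                test_sentences = config$controlled_test_sentences)
  records <- evaluate_generalization(
    encoders, controlled, split,
    probe_config("mlp", seed = stage_seed(config, "probe")))
  by_cond <- accuracy_table(records, c("register", "condition", "role"))
  by_order <- accuracy_table(records, c("register", "order", "role"))
  fit <- NULL; delta_p <- NULL
  if (fit_stats) {
    fixed <- if (mode == "english_like") ~ register * role + condition
    else ~ register * role + syncretic + order
    fit <- fit_hier_bernoulli(records, fixed = fixed, random = "study2",
                              chains = config$chains, n_iter = config$n_iter,
                              n_adapt = config$n_adapt,
                              seed = stage_seed(config, "stats"),
                              on_nonconvergence = "warn")
    cells <- if (mode == "english_like") unique(records$condition)
    else unique(records$order)
    key <- if (mode == "english_like") "condition" else "order"
    delta_p <- list(overall = counterfactual_delta_p(fit))
    for (cl in cells) {
      flt <- list(cl); names(flt) <- key
      delta_p[[cl]] <- counterfactual_delta_p(fit, flt)
    }
  }
  structure(list(config = config, controlled = controlled, split = split,
                 records = records, accuracy_by_condition = by_cond,
                 accuracy_by_order = by_order, fit = fit, delta_p = delta_p),
            class = "rp_study2_report")
}

#' @export
print.rp_study2_report <- function(x, ...) {
  cat("<rp_study2_report>\n")
  print(x$accuracy_by_condition, row.names = FALSE)
  if (!is.null(x$delta_p))
    for (nm in names(x$delta_p))
      cat(sprintf("  delta-P [%s]: %+0.4f [%.4f, %.4f]\n", nm,
                  x$delta_p[[nm]]$mean, x$delta_p[[nm]]$ci[1], x$delta_p[[nm]]$ci[2]))
  invisible(x)
}
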