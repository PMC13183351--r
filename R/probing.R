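#' Verb-disjoint balanced probing splits
#'
#' Creates `n_versions` train/validation/test partitions of a dataset's
#' argument instances such that (i) the training set has exactly
#' `train_size` instances with equal A and P counts, (ii) no verb lemma
#' occurring in the training set occurs in the validation or test set, and
#' (iii) each version uses a different verb partition. Verbs are shuffled
#' and assigned greedily to the training side until the balanced quota is
#' reachable; training instances are then sampled from that side, and
#' train-side instances beyond the quota are set aside (they may not leak
#' into evaluation). Deterministic given `seed`.
#'
#' @param dataset An `rp_role_dataset`.
#' @param n_versions Number of split versions.
#' @param train_size Training instances (must be even).
#' @param val_range Closed interval for the validation-set size; the actual
#'   size is `min(val_range[2], available)` after the training allocation,
#'   and falling below `val_range[1]` is an error.
#' @param seed Integer seed.
#' @param verb_orders Optional list of pre-shuffled verb orderings, one per
#'   version. When two registers share a verb inventory, passing the same
#'   orderings to both yields (near-)matched verb partitions, pairing the
#'   register comparison and removing partition-lottery noise from the
#'   contrast.
#' @return List of `rp_split_scheme` objects, each holding instance row
#'   indices `train`, `val`, `test`, `dropped` and the verb partition.
#' @export
make_verb_disjoint_splits <- function(dataset, n_versions = 10, train_size = 100,
                                      val_range = c(100, 300), seed = 1,
                                      verb_orders = NULL) {
  ins <- dataset$instances
  if (train_size %% 2L)
    rp_error("rp_split_infeasible", "train_size must be even for exact A/P balance")
  verbs <- unique(ins$verb_lemma)
  if (length(verbs) < 2L)
    rp_error("rp_split_infeasible", "verb-disjoint splits need at least two verbs")
  half <- train_size %/% 2L
  lapply(seq_len(n_versions), function(v) with_seed(seed + v - 1L, {
    vs <- if (!is.null(verb_orders)) intersect(verb_orders[[v]], verbs)
    else sample(verbs)
    train_verbs <- character(0)
    nA <- 0L; nP <- 0L; k <- 0L
    while ((nA < half || nP < half) && k < length(vs)) {
      k <- k + 1L
      train_verbs <- c(train_verbs, vs[k])
      nA <- sum(ins$role == "A" & ins$verb_lemma %in% train_verbs)
      nP <- sum(ins$role == "P" & ins$verb_lemma %in% train_verbs)
    }
    if (nA < half || nP < half)
      rp_error("rp_split_infeasible",
               "cannot reach %d balanced training instances: only %d A / %d P available",
               train_size, nA, nP)
    if (k == length(vs))
      rp_error("rp_split_infeasible",
               "all verbs consumed by the training side; no evaluation verbs remain")
    pool <- which(ins$verb_lemma %in% train_verbs)
    tr <- c(sample(pool[ins$role[pool] == "A"], half),
            sample(pool[ins$role[pool] == "P"], half))
    dropped <- setdiff(pool, tr)
    rest <- which(!ins$verb_lemma %in% train_verbs)
    if (length(rest) < val_range[1] + 1L)
      rp_error("rp_split_infeasible",
               "only %d evaluation instances remain; need > %d for validation",
               length(rest), val_range[1])
    val_size <- min(val_range[2], length(rest) - 1L)
    val <- sample(rest, val_size)
    test <- setdiff(rest, val)
    structure(list(split_id = v, train = sort(tr), val = sort(val),
                   test = sort(test), dropped = sort(dropped),
                   train_verbs = sort(train_verbs),
                   eval_verbs = sort(setdiff(verbs, train_verbs))),
              class = "rp_split_scheme")
  }))
}

#' Probe configuration
#'
#' @param kind `"mlp"` (two-layer perceptron, hidden width 100, up to 20
#'   epochs keeping the lowest-validation-loss state) or `"svm"` (RBF
#'   kernel, default regularisation).
#' @param hidden Hidden width of the perceptron.
#' @param epochs Maximum training epochs of the perceptron.
#' @param lr Adam learning rate of the perceptron.
#' @param best_on `"val"` (default) or `"train"`: which loss selects the
#'   kept parameter state.
#' @param seed Seed for the perceptron's initialisation.
#' @return A list of class `rp_probe_config`.
#' @export
probe_config <- function(kind = c("mlp", "svm"), hidden = 100, epochs = 20,
                         lr = 0.01, best_on = c("val", "train"), seed = 1) {
  kind <- match.arg(kind)
  stopifnot(hidden > 0, epochs > 0, lr > 0)
  structure(list(kind = kind, hidden = hidden, epochs = epochs, lr = lr,
                 best_on = match.arg(best_on), seed = seed),
            class = "rp_probe_config")
}

#' Train a role probe
#'
#' Binary A/P classifier over one argument representation. The perceptron
#' path trains with full-batch Adam for up to `epochs` epochs and freezes
#' the parameter state with the lowest validation loss; the SVM path fits
#' once. Both are deterministic (given `config$seed` for the perceptron).
#'
#' @param x_train,y_train Training matrix and `"A"`/`"P"` labels.
#' @param x_val,y_val Validation matrix and labels (used by the mlp's
#'   state selection; ignored by the svm).
#' @param config An [probe_config()].
#' @return Frozen classifier of class `rp_probe`.
#' @export
train_probe <- function(x_train, y_train, x_val = NULL, y_val = NULL,
                        config = probe_config()) {
  if (length(unique(y_train)) < 2L)
    rp_error("rp_one_class", "training labels contain a single class")
  x_train <- as.matrix(x_train)
  if (config$kind == "svm") {
    fit <- e1071::svm(x_train, factor(y_train, levels = c("A", "P")),
                      kernel = "radial", scale = FALSE)
    return(structure(list(kind = "svm", fit = fit), class = "rp_probe"))
  }
  y <- as.integer(y_train == "P")
  d <- ncol(x_train); h <- config$hidden
  use_val <- config$best_on == "val" && !is.null(x_val) && length(y_val) > 0
  xv <- if (use_val) as.matrix(x_val)
  yv <- if (use_val) as.integer(y_val == "P")
  with_seed(config$seed, {
    W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h); b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(h, sd = sqrt(2 / h)), h, 1); b2 <- 0
    pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    st <- list(m = lapply(pars, function(z) z * 0), v = lapply(pars, function(z) z * 0))
    best <- list(loss = Inf, pars = pars)
    bce <- function(pars, X, yy) {
      H <- pmax(addb(X %*% pars$W1, pars$b1), 0)
      z <- drop(H %*% pars$W2) + pars$b2
      p <- stats::plogis(z)
      -mean(yy * log(pmax(p, 1e-12)) + (1 - yy) * log(pmax(1 - p, 1e-12)))
    }
    for (ep in seq_len(config$epochs)) {
      H <- pmax(addb(x_train %*% pars$W1, pars$b1), 0)
      z <- drop(H %*% pars$W2) + pars$b2
      p <- stats::plogis(z)
      dz <- (p - y) / length(y)
      g <- list(W1 = NULL, b1 = NULL, W2 = t(H) %*% dz, b2 = sum(dz))
      dH <- (dz %o% drop(pars$W2)) * (H > 0)
      g$W1 <- t(x_train) %*% dH; g$b1 <- colSums(dH)
      for (nm in names(pars)) {
        st$m[[nm]] <- 0.9 * st$m[[nm]] + 0.1 * g[[nm]]
        st$v[[nm]] <- 0.999 * st$v[[nm]] + 0.001 * g[[nm]]^2
        pars[[nm]] <- pars[[nm]] - config$lr *
          (st$m[[nm]] / (1 - 0.9^ep)) / (sqrt(st$v[[nm]] / (1 - 0.999^ep)) + 1e-8)
      }
      cur <- if (use_val) bce(pars, xv, yv) else bce(pars, x_train, y)
      if (cur < best$loss) best <- list(loss = cur, pars = pars)
    }
    structure(list(kind = "mlp", pars = best$pars, val_loss = best$loss),
              class = "rp_probe")
  })
}

#' @export
predict.rp_probe <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "svm") {
    if (ncol(newdata) != ncol(object$fit$SV))
      rp_error("rp_dim_mismatch", "probe expects %d features, got %d",
               ncol(object$fit$SV), ncol(newdata))
    return(as.character(predict(object$fit, newdata)))
  }
  if (ncol(newdata) != nrow(object$pars$W1))
    rp_error("rp_dim_mismatch", "probe expects %d features, got %d",
             nrow(object$pars$W1), ncol(newdata))
  H <- pmax(addb(newdata %*% object$pars$W1, object$pars$b1), 0)
  p <- stats::plogis(drop(H %*% object$pars$W2) + object$pars$b2)
  ifelse(p > 0.5, "P", "A")
}

#' Evaluate a frozen probe, one record per argument
#'
#' Each argument is classified independently (both arguments of a clause
#' may receive the same predicted role). The returned records carry full
#' metadata for the hierarchical model.
#'
#' @param probe An `rp_probe`.
#' @param x Representation matrix for the evaluated instances.
#' @param meta Data frame with (at least) columns `utterance_id`, `role`;
#'   `register`, `condition`, `order` are carried through when present.
#' @param representation Label of the representation kind.
#' @param split_id Split version id.
#' @return Data frame of classification records with columns `argument_id`,
#'   `sentence_id`, `register`, `role`, `representation`, `split_id`,
#'   `condition`, `order`, `predicted`, `correct`.
#' @export
evaluate_probe <- function(probe, x, meta, representation = "contextual",
                           split_id = 1L) {
  pred <- predict(probe, x)
  syncretic <- if (!is.null(meta$sync_A) && !is.null(meta$sync_P))
    ifelse(meta$role == "A", meta$sync_A, meta$sync_P) else NA
  data.frame(argument_id = paste(meta$utterance_id, meta$role, sep = ":"),
             sentence_id = meta$utterance_id,
             register = meta$register %||% NA_character_,
             role = meta$role,
             representation = representation,
             split_id = split_id,
             condition = meta$condition %||% NA_character_,
             order = meta$order %||% NA_character_,
             syncretic = syncretic,
             agr_cue = meta$agr_cue %||% NA,
             predicted = pred,
             correct = as.integer(pred == meta$role),
             stringsAsFactors = FALSE)
}

#' Accuracy table from classification records
#' @param records Record data frame from [evaluate_probe()].
#' @param by Grouping columns.
#' @return Aggregated data frame with `n` and `accuracy`.
#' @export
accuracy_table <- function(records, by = c("register", "representation", "role")) {
  by <- intersect(by, names(records))
  ag <- stats::aggregate(records$correct, records[by], function(z) c(length(z), mean(z)))
  out <- cbind(ag[by], n = ag$x[, 1], accuracy = ag$x[, 2])
  out[do.call(order, out[by]), , drop = FALSE]
}

# Representation matrices for a prepared register dataset.
build_representations <- function(dataset, representations, encoder = NULL,
                                  static_table = NULL, paradigm = NULL,
                                  two_level = FALSE) {
  out <- list()
  for (r in representations) {
    out[[r]] <- switch(r,
      contextual = embed_arguments_contextual(encoder, dataset, two_level),
      static = embed_arguments_static(static_table, dataset),
      position = encode_positions(dataset),
      case = encode_cases(dataset, paradigm),
      rp_error("rp_bad_representation", "unknown representation '%s'", r))
  }
  out
}

#' Run the register probing experiment
#'
#' The full Study-1 style protocol on a pair (or more) of prepared register
#' datasets: per register, train the encoder and static table on that
#' register's utterances, build the requested argument representations,
#' draw verb-disjoint balanced splits, train one probe per split and
#' representation (perceptron for embedding representations, RBF-SVM for
#' the feature-based ones) and collect per-argument records on the test
#' sets.
#'
#' @param datasets Named list of `rp_role_dataset` (names become register
#'   labels, e.g. `CDS`, `ADS`).
#' @param representations Subset of `c("contextual", "static", "position",
#'   "case")`.
#' @param encoder_cfg [encoder_config()] used for each register's encoder.
#' @param paradigm Case paradigm (needed for the `case` representation).
#' @param n_versions,train_size,val_range,split_seed Split protocol
#'   parameters; see [make_verb_disjoint_splits()].
#' @param probe_seed Seed for perceptron probes.
#' @param static_dim Dimension of the static table.
#' @param encoders Optional named list of pre-trained encoders, keyed like
#'   `datasets` (bypasses encoder training; used for identity controls).
#' @return List of class `rp_probe_experiment`: `records` (all test-set
#'   records), `splits`, `encoders`, `static_tables`, `accuracy`.
#' @export
run_register_experiment <- function(datasets,
                                    representations = c("contextual", "static",
                                                        "position", "case"),
                                    encoder_cfg = encoder_config(),
                                    paradigm = NULL,
                                    n_versions = 10, train_size = 100,
                                    val_range = c(100, 300), split_seed = 1,
                                    probe_seed = 1, static_dim = 32,
                                    encoders = NULL) {
  stopifnot(!is.null(names(datasets)))
  # one shuffled verb ordering per split version, shared across registers:
  # matched verb partitions pair the register comparison
  all_verbs <- sort(unique(unlist(lapply(datasets, `[[`, "verb_inventory"))))
  verb_orders <- with_seed(split_seed,
                           lapply(seq_len(n_versions), function(v) sample(all_verbs)))
  records <- list(); splits <- list(); encs <- list(); stats_tabs <- list()
  for (reg in names(datasets)) {
    ds <- datasets[[reg]]
    enc <- if (!is.null(encoders)) encoders[[reg]] else
      if ("contextual" %in% representations) train_masked_lm(ds, encoder_cfg)
    stab <- if ("static" %in% representations)
      train_static_embeddings(ds, dim = static_dim)
    reps <- build_representations(ds, representations, enc, stab, paradigm)
    sp <- make_verb_disjoint_splits(ds, n_versions, train_size, val_range,
                                    seed = split_seed, verb_orders = verb_orders)
    meta <- ds$instances
    meta$register <- reg
    for (s in sp) for (r in representations) {
      cfg <- probe_config(kind = if (r %in% c("position", "case")) "svm" else "mlp",
                          seed = probe_seed)
      probe <- train_probe(reps[[r]][s$train, , drop = FALSE], meta$role[s$train],
                           reps[[r]][s$val, , drop = FALSE], meta$role[s$val],
                           cfg)
      records[[length(records) + 1L]] <-
        evaluate_probe(probe, reps[[r]][s$test, , drop = FALSE],
                       meta[s$test, , drop = FALSE], r, s$split_id)
    }
    splits[[reg]] <- sp
    encs[[reg]] <- enc
    stats_tabs[[reg]] <- stab
  }
  records <- do.call(rbind, records)
  structure(list(records = records, splits = splits, encoders = encs,
                 static_tables = stats_tabs,
                 accuracy = accuracy_table(records)),
            class = "rp_probe_experiment")
}

#' @export
print.rp_probe_experiment <- function(x, ...) {
  cat(sprintf("<rp_probe_experiment> %d records, %d registers\n",
              nrow(x$records), length(x$splits)))
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}
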