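#' Fit the hierarchical Bernoulli model of classification outcomes
#'
#' Models per-argument correctness as Bernoulli with a logit link. Fixed
#' effects come from `fixed` (default: register, role and their
#' interaction); the random structure is either `"study1"` (random
#' intercepts for split and sentence id, each with a random slope for
#' role) or `"study2"` (a sentence-id random intercept varying by
#' register). Priors: Normal(0, `prior_sd`) on fixed effects and
#' Exponential(1) on every random-effect standard deviation. `prior_sd`
#' may be a ladder (default `c(1, 2)`): the first scale whose fit passes
#' the split-Rhat threshold on all reported parameters is kept. Sampling
#' uses JAGS with `chains` parallel-seeded chains.
#'
#' @param records Classification-record data frame (needs `correct`,
#'   `register`, `role`, `sentence_id`; `split_id` for `"study1"`).
#' @param fixed Fixed-effects formula over record columns.
#' @param random `"study1"` or `"study2"`.
#' @param prior_sd Ladder of prior standard deviations for fixed effects.
#' @param chains,n_iter,n_adapt MCMC controls (per chain; `n_iter` is the
#'   number of retained draws).
#' @param n_burn Burn-in iterations discarded after adaptation.
#' @param thin Thinning interval; `n_iter * thin` iterations are sampled
#'   and every `thin`-th retained.
#' @param seed Integer seed; chain RNGs are derived from it.
#' @param rhat_threshold Maximum admissible split-Rhat.
#' @param on_nonconvergence `"error"` (default) or `"warn"` when the last
#'   ladder step still exceeds the threshold.
#' @param quiet Suppress JAGS progress output.
#' @return Object of class `rp_hier_fit`.
#' @export
fit_hier_bernoulli <- function(records, fixed = ~ register * role,
                               random = c("study1", "study2"),
                               prior_sd = c(1, 2), chains = 2,
                               n_iter = 1000, n_adapt = 500,
                               n_burn = 0, thin = 1, seed = 1,
                               rhat_threshold = 1.01,
                               on_nonconvergence = c("error", "warn"),
                               quiet = TRUE) {
  random <- match.arg(random)
  on_nonconvergence <- match.arg(on_nonconvergence)
  if (length(unique(records$register)) < 2L)
    rp_error("rp_need_two_registers", "records cover a single register")
  if (length(unique(records$role)) < 2L)
    rp_error("rp_need_both_roles", "records cover a single role")
  rec <- records
  rec$register <- factor(rec$register)
  rec$role <- factor(rec$role, levels = c("A", "P"))
  mf <- stats::model.frame(fixed, rec)
  X <- stats::model.matrix(fixed, mf)
  if (qr(X)$rank < ncol(X))
    rp_error("rp_rank_deficient", "fixed-effect design matrix is rank deficient")
  xlev <- stats::.getXlevels(stats::terms(mf), mf)
  y <- as.integer(rec$correct)
  rp <- as.integer(rec$role == "P")
  sent_levels <- sort(unique(rec$sentence_id))
  se <- match(rec$sentence_id, sent_levels)
  reg_levels <- levels(rec$register)
  rg <- as.integer(rec$register)
  dat <- list(y = y, X = X, rp = rp, se = se,
              N = nrow(X), J = length(sent_levels))
  lp <- paste(sprintf("beta[%d]*X[n,%d]", seq_len(ncol(X)), seq_len(ncol(X))),
              collapse = " + ")
  if (random == "study1") {
    if (is.null(rec$split_id))
      rp_error("rp_bad_records", "study1 random structure needs a split_id column")
    split_levels <- sort(unique(rec$split_id))
    dat$sp <- match(rec$split_id, split_levels)
    dat$S <- length(split_levels)
    re_lp <- "u_split[sp[n]] + w_split[sp[n]]*rp[n] + u_sent[se[n]] + w_sent[se[n]]*rp[n]"
    # non-centered parameterisation: scales mix far better with binary outcomes
    re_block <- "
  for (s in 1:S) {
    z_us[s] ~ dnorm(0, 1); u_split[s] <- sd_split * z_us[s]
    z_ws[s] ~ dnorm(0, 1); w_split[s] <- sd_split_role * z_ws[s]
  }
  for (j in 1:J) {
    z_uj[j] ~ dnorm(0, 1); u_sent[j] <- sd_sent * z_uj[j]
    z_wj[j] ~ dnorm(0, 1); w_sent[j] <- sd_sent_role * z_wj[j]
  }
  sd_split ~ dexp(1)
  sd_split_role ~ dexp(1)
  sd_sent ~ dexp(1)
  sd_sent_role ~ dexp(1)"
    sd_pars <- c("sd_split", "sd_split_role", "sd_sent", "sd_sent_role")
    monitors <- c("beta", sd_pars, "u_split", "w_split", "u_sent", "w_sent")
  } else {
    dat$rg <- rg
    dat$G <- length(reg_levels)
    re_lp <- "u_sent[se[n], rg[n]]"
    re_block <- "
  for (j in 1:J) { for (g in 1:G) {
    z_uj[j,g] ~ dnorm(0, 1); u_sent[j,g] <- sd_sent[g] * z_uj[j,g]
  } }
  for (g in 1:G) { sd_sent[g] ~ dexp(1) }"
    sd_pars <- "sd_sent"
    monitors <- c("beta", "sd_sent", "u_sent")
  }
  # the glm module provides far more efficient samplers for Bernoulli-logit
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  fit_once <- function(psd) {
    code <- sprintf("model {
  for (n in 1:N) {
    logit(p[n]) <- %s + %s
    y[n] ~ dbern(p[n])
  }
  for (k in 1:K) { beta[k] ~ dnorm(0, %.8f) }%s
}", lp, re_lp, 1 / psd^2, re_block)
    dat$K <- ncol(X)
    inits <- lapply(seq_len(chains), function(ch)
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (seed * 1000L + ch) %% .Machine$integer.max))
    jm <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                            n.chains = chains, n.adapt = n_adapt,
                            quiet = quiet)
    if (n_burn > 0) stats::update(jm, n_burn, progress.bar = "none")
    rjags::coda.samples(jm, monitors, n.iter = n_iter * thin, thin = thin,
                        progress.bar = "none")
  }
  reported <- function(samp) {
    nm <- colnames(samp[[1]])
    nm[grepl("^beta\\[", nm) | nm %in% sd_pars | grepl("^sd_sent\\[", nm)]
  }
  used_sd <- NA_real_; samp <- NULL; diag_tab <- NULL
  for (psd in prior_sd) {
    samp <- fit_once(psd)
    used_sd <- psd
    rep_par <- reported(samp)
    diag_tab <- data.frame(
      parameter = rep_par,
      rhat = vapply(rep_par, function(v) split_rhat(lapply(samp, function(ch) ch[, v])), 0),
      ess = vapply(rep_par, function(v)
        sum(coda::effectiveSize(samp[, v])), 0))
    if (all(diag_tab$rhat <= rhat_threshold, na.rm = TRUE)) break
  }
  if (any(diag_tab$rhat > rhat_threshold, na.rm = TRUE)) {
    msg <- sprintf("split-Rhat above %.3f for: %s", rhat_threshold,
                   paste(diag_tab$parameter[diag_tab$rhat > rhat_threshold], collapse = ", "))
    if (on_nonconvergence == "error") rp_error("rp_nonconvergence", "%s", msg)
    warning(msg)
  }
  draws <- do.call(rbind, lapply(samp, as.matrix))
  beta_cols <- sprintf("beta[%d]", seq_len(ncol(X)))
  colnames(draws)[match(beta_cols, colnames(draws))] <- colnames(X)
  fit <- structure(list(
    draws = draws, chains = chains, n_iter = n_iter,
    fixed = fixed, xlev = xlev, random = random,
    beta_names = colnames(X),
    sd_pars = grep("^sd", diag_tab$parameter, value = TRUE),
    sent_levels = sent_levels, reg_levels = reg_levels,
    records = rec, X = X, se = se, rp = rp, rg = rg,
    sp = if (random == "study1") dat$sp,
    prior_sd = used_sd, diagnostics = diag_tab,
    seed = seed), class = "rp_hier_fit")
  fit$ppc <- posterior_predictive_check(fit)
  fit
}

# Split-Rhat: each chain halved, then the usual between/within ratio.
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    x <- as.numeric(x); n <- floor(length(x) / 2)
    list(x[1:n], x[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.rp_hier_fit <- function(x, ...) {
  cat(sprintf("<rp_hier_fit> Bernoulli-logit, random structure '%s', prior sd %g\n",
              x$random, x$prior_sd))
  cat(sprintf("  %d records, %d sentences, %d chains x %d draws\n",
              nrow(x$records), length(x$sent_levels), x$chains, x$n_iter))
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
coef.rp_hier_fit <- function(object, ...) {
  colMeans(object$draws[, object$beta_names, drop = FALSE])
}

#' @export
summary.rp_hier_fit <- function(object, ...) {
  pars <- object$diagnostics$parameter
  pars[pars %in% sprintf("beta[%d]", seq_along(object$beta_names))] <- object$beta_names
  D <- object$draws[, pars, drop = FALSE]
  data.frame(parameter = pars,
             mean = colMeans(D),
             sd = apply(D, 2, stats::sd),
             q2.5 = apply(D, 2, stats::quantile, 0.025),
             q97.5 = apply(D, 2, stats::quantile, 0.975),
             rhat = object$diagnostics$rhat,
             ess = object$diagnostics$ess,
             row.names = NULL)
}

# Per-draw logits for given records under the fitted parameters.
hier_logits <- function(fit, rec, draws_idx) {
  X <- stats::model.matrix(fit$fixed,
                           stats::model.frame(fit$fixed, rec, xlev = fit$xlev))
  D <- fit$draws[draws_idx, , drop = FALSE]
  eta <- X %*% t(D[, fit$beta_names, drop = FALSE])  # n x draws
  se <- match(rec$sentence_id, fit$sent_levels)
  rp <- as.integer(rec$role == "P")
  if (fit$random == "study1") {
    us <- t(D[, sprintf("u_sent[%d]", se), drop = FALSE])
    ws <- t(D[, sprintf("w_sent[%d]", se), drop = FALSE])
    eta <- eta + us + ws * rp
    if (!is.null(rec$split_id)) {
      spx <- match(rec$split_id, sort(unique(fit$records$split_id)))
      eta <- eta + t(D[, sprintf("u_split[%d]", spx), drop = FALSE]) +
        t(D[, sprintf("w_split[%d]", spx), drop = FALSE]) * rp
    }
  } else {
    g <- match(rec$register, fit$reg_levels)
    eta <- eta + t(D[, sprintf("u_sent[%d,%d]", se, g), drop = FALSE])
  }
  eta
}

# Observed vs replicated accuracy per register x role cell.
posterior_predictive_check <- function(fit, n_draws = 200) {
  idx <- round(seq(1, nrow(fit$draws), length.out = min(n_draws, nrow(fit$draws))))
  eta <- hier_logits(fit, fit$records, idx)
  p <- stats::plogis(eta)
  cell <- interaction(fit$records$register, fit$records$role, drop = TRUE)
  out <- lapply(levels(cell), function(cl) {
    i <- cell == cl
    rep_acc <- with_seed(fit$seed + 7919L,
                         colMeans(matrix(stats::rbinom(sum(i) * length(idx), 1,
                                                       as.vector(p[i, ])), sum(i))))
    data.frame(cell = cl, observed = mean(fit$records$correct[i]),
               rep_mean = mean(rep_acc),
               rep_q2.5 = stats::quantile(rep_acc, 0.025),
               rep_q97.5 = stats::quantile(rep_acc, 0.975))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Counterfactual register contrast (delta-P)
#'
#' For every sentence id (in the optional cell), posterior predictions of
#' correctness are computed under both register levels while holding the
#' sentence's own random effects fixed; the per-draw difference
#' P(correct | first register) - P(correct | second register) is averaged
#' over sentence ids, yielding a posterior distribution for the average
#' contrast. A positive value means classification is more probable under
#' the first register.
#'
#' @param fit An `rp_hier_fit` whose fixed effects contain `register`.
#' @param cell Optional named list filtering records (e.g.
#'   `list(role = "A")` or `list(condition = "fronted")`).
#' @param registers Length-2 character: the counterfactual register levels,
#'   first minus second. Defaults to the fit's levels in `CDS, ADS` order
#'   when present.
#' @return Object of class `rp_delta_p`: mean, 95% credible interval, the
#'   per-draw averages and the per-sentence posterior-mean differences.
#' @export
counterfactual_delta_p <- function(fit, cell = NULL, registers = NULL) {
  if (is.null(registers)) {
    registers <- fit$reg_levels
    if (all(c("CDS", "ADS") %in% registers)) registers <- c("CDS", "ADS")
    registers <- registers[1:2]
  }
  rec <- fit$records
  if (!is.null(cell)) {
    keep <- rep(TRUE, nrow(rec))
    for (nm in names(cell)) keep <- keep & rec[[nm]] %in% cell[[nm]]
    rec <- rec[keep, , drop = FALSE]
  }
  if (!nrow(rec)) rp_error("rp_empty_cell", "no records in the requested cell")
  idx <- seq_len(nrow(fit$draws))
  eta_by_reg <- lapply(registers, function(rv) {
    r2 <- rec
    r2$register <- factor(rv, levels = levels(fit$records$register))
    hier_logits(fit, r2, idx)
  })
  dif <- stats::plogis(eta_by_reg[[1]]) - stats::plogis(eta_by_reg[[2]])
  # average records within sentence id, then across sentences
  bysent <- rowsum(dif, rec$sentence_id)
  bysent <- bysent / as.vector(table(rec$sentence_id)[rownames(bysent)])
  per_draw <- colMeans(bysent)
  structure(list(mean = mean(per_draw),
                 ci = stats::quantile(per_draw, c(0.025, 0.975)),
                 per_draw = per_draw,
                 per_sentence = rowMeans(bysent),
                 registers = registers, cell = cell,
                 n_sentences = nrow(bysent)),
            class = "rp_delta_p")
}

#' @export
print.rp_delta_p <- function(x, ...) {
  cl <- if (is.null(x$cell)) "all records" else
    paste(names(x$cell), unlist(x$cell), sep = "=", collapse = ", ")
  cat(sprintf("<rp_delta_p> P(correct|%s) - P(correct|%s), %s\n",
              x$registers[1], x$registers[2], cl))
  cat(sprintf("  mean %.4f, 95%% CI [%.4f, %.4f], %d sentences\n",
              x$mean, x$ci[1], x$ci[2], x$n_sentences))
  invisible(x)
}

#' Simulate classification records from the hierarchical model
#'
#' Generates Bernoulli records under known parameters: half the sentences
#' per register, one A and one P record per sentence and split, sentence
#' and split random intercepts with role slopes. Used for calibration and
#' parameter-recovery checks of [fit_hier_bernoulli()].
#'
#' @param n_sentences Sentences per register.
#' @param n_splits Split versions.
#' @param beta Named fixed effects on the logit scale:
#'   `intercept`, `register` (added for CDS), `role` (added for P),
#'   `interaction` (CDS x P).
#' @param sd_split,sd_split_role,sd_sent,sd_sent_role Random-effect
#'   standard deviations.
#' @param seed Integer seed.
#' @return Record data frame with a `truth` attribute.
#' @export
simulate_hier_records <- function(n_sentences = 200, n_splits = 10,
                                  beta = c(intercept = 0.5, register = 1,
                                           role = 0, interaction = 0),
                                  sd_split = 0.3, sd_split_role = 0.3,
                                  sd_sent = 0.5, sd_sent_role = 0.3,
                                  seed = 1) {
  with_seed(seed, {
    sid <- sprintf("s%04d", seq_len(2 * n_sentences))
    reg <- rep(c("CDS", "ADS"), each = n_sentences)
    u_sent <- stats::rnorm(2 * n_sentences, 0, sd_sent)
    w_sent <- stats::rnorm(2 * n_sentences, 0, sd_sent_role)
    u_split <- stats::rnorm(n_splits, 0, sd_split)
    w_split <- stats::rnorm(n_splits, 0, sd_split_role)
    grid <- expand.grid(s = seq_along(sid), role = c("A", "P"),
                        split_id = seq_len(n_splits), stringsAsFactors = FALSE)
    isP <- as.integer(grid$role == "P")
    isC <- as.integer(reg[grid$s] == "CDS")
    eta <- beta[["intercept"]] + beta[["register"]] * isC + beta[["role"]] * isP +
      beta[["interaction"]] * isC * isP +
      u_sent[grid$s] + w_sent[grid$s] * isP +
      u_split[grid$split_id] + w_split[grid$split_id] * isP
    out <- data.frame(argument_id = paste(sid[grid$s], grid$role, sep = ":"),
                      sentence_id = sid[grid$s], register = reg[grid$s],
                      role = grid$role, representation = "simulated",
                      split_id = grid$split_id,
                      correct = stats::rbinom(nrow(grid), 1, stats::plogis(eta)),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- beta
    out
  })
}
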