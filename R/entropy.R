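#' Maximum likelihood (plug-in) Shannon entropy
#'
#' \eqn{H = -\sum \hat p \log_2 \hat p} with \eqn{\hat p} the observed
#' category frequencies. Zero-count categories contribute nothing. Reported
#' in bits throughout the package.
#'
#' @param counts Named (or unnamed) non-negative integer vector of category
#'   counts, or a `table`.
#' @return Entropy in bits.
#' @export
entropy_ml <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) rp_error("rp_bad_counts", "negative count")
  total <- sum(counts)
  if (total == 0) rp_error("rp_bad_counts", "all counts are zero")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Entropy descriptives of a role dataset
#'
#' The register-level variability measures: per-role entropy of argument
#' surface forms, entropy of overt word-order strings, and (when case
#' metadata or a paradigm is available) per-role entropy of case labels.
#' All maximum likelihood, in bits, with the underlying count tables.
#'
#' @param dataset An `rp_role_dataset` (typically filtered).
#' @param paradigm Optional `rp_case_paradigm` used to recover case labels
#'   when the instances carry none; generated corpora already carry a
#'   `case` column.
#' @return Object of class `rp_entropy_report`: a list with `entropy`
#'   (data frame `type`, `role`, `bits`) and `counts` (named list of count
#'   tables).
#' @export
describe_dataset <- function(dataset, paradigm = NULL) {
  ins <- dataset$instances
  rows <- list(); tabs <- list()
  for (r in c("A", "P")) {
    tab <- table(ins$surface[ins$role == r])
    tabs[[paste0("argument_", r)]] <- tab
    rows[[length(rows) + 1L]] <- data.frame(
      type = "argument", role = r,
      bits = if (length(tab)) entropy_ml(tab) else NA_real_)
  }
  wo <- table(word_order_labels(dataset))
  tabs$word_order <- wo
  rows[[length(rows) + 1L]] <- data.frame(
    type = "word order", role = "A and P",
    bits = if (length(wo)) entropy_ml(wo) else NA_real_)
  case_of <- function(idx) {
    if (!is.null(ins$case)) return(ins$case[idx])
    if (is.null(paradigm)) return(NULL)
    vapply(idx, function(i) {
      cells <- possible_cases(paradigm, ins$head_form[i] %||% ins$surface[i])
      paste(sort(unique(cells$case)), collapse = "/")
    }, "")
  }
  for (r in c("A", "P")) {
    cs <- case_of(which(ins$role == r))
    if (!is.null(cs) && length(cs)) {
      tab <- table(cs)
      tabs[[paste0("case_", r)]] <- tab
      rows[[length(rows) + 1L]] <- data.frame(type = "case", role = r,
                                              bits = entropy_ml(tab))
    }
  }
  structure(list(entropy = do.call(rbind, rows), counts = tabs),
            class = "rp_entropy_report")
}

#' @export
print.rp_entropy_report <- function(x, ...) {
  cat("<rp_entropy_report> ML entropy (bits)\n")
  print(x$entropy, row.names = FALSE)
  invisible(x)
}
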