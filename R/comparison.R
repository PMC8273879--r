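#' Group-level log-likelihood
#'
#' Sum over participants of the best-fitting parametrization's
#' log-likelihood for one model — the log of the group likelihood
#' product used by the Group Bayes Factor.
#'
#' @param fits A fit-result data frame (one best fit per participant,
#'   see [fit_cohort()]).
#' @param participants Optional character vector of required participant
#'   ids; an error lists any that are missing.
#' @return The group log-likelihood (scalar).
#' @export
group_log_likelihood <- function(fits, participants = NULL) {
  if (!is.null(participants)) {
    missing <- setdiff(participants, fits$participant)
    if (length(missing) > 0) {
      stop("missing participants: ", paste(missing, collapse = ", "))
    }
    fits <- fits[fits$participant %in% participants, , drop = FALSE]
  }
  if (anyDuplicated(fits$participant)) {
    stop("more than one fit per participant")
  }
  sum(fits$logL)
}

#' Group Bayes Factor
#'
#' `exp(logL_a - logL_b)`: the ratio of two models' group likelihoods,
#' computed in log space. Use [format_bf()] to render values outside
#' double range.
#'
#' @param logL_a,logL_b Group log-likelihoods of the two models.
#' @return The Bayes factor (possibly `Inf` when the difference exceeds
#'   double range; use the `"log"` attribute-free [format_bf()] with the
#'   difference for exact rendering).
#' @export
group_bayes_factor <- function(logL_a, logL_b) {
  stopifnot(is.finite(logL_a), is.finite(logL_b))
  exp(logL_a - logL_b)
}

#' Render a log Bayes factor in scientific notation
#'
#' Converts a natural-log Bayes factor to mantissa--exponent (base 10)
#' E-notation without ever exponentiating, so arbitrarily large factors
#' render exactly.
#'
#' @param log_bf Natural log of the Bayes factor.
#' @param digits Significant digits of the mantissa.
#' @return A character scalar like `"7.99E+25"`.
#' @export
format_bf <- function(log_bf, digits = 3) {
  l10 <- log_bf / log(10)
  e <- floor(l10)
  m <- signif(10^(l10 - e), digits)
  if (m >= 10) { # rounding pushed the mantissa over
    m <- m / 10
    e <- e + 1
  }
  sprintf("%.*gE%+03d", digits, m, e)
}

#' Interpret a Bayes factor on the conventional evidence bands
#'
#' Labels the evidence for the numerator model: `[3.2, 10)`
#' "Substantial", `[10, 100)` "Strong", `>= 100` "Decisive"; below 3.2
#' the evidence is "Not worth more than a bare mention". Band edges are
#' lower-inclusive.
#'
#' @param bf Bayes factor, > 0.
#' @return A character label.
#' @export
interpret_bf <- function(bf) {
  stopifnot(bf > 0)
  if (bf >= 100) "Decisive"
  else if (bf >= 10) "Strong"
  else if (bf >= 3.2) "Substantial"
  else "Not worth more than a bare mention"
}

#' Group-level model comparison table
#'
#' From per-model fit results, computes each model's group
#' log-likelihood and the full pairwise Bayes-factor matrix with
#' evidence labels — the shape of the study-style summary tables.
#'
#' @param fit_list Named list of fit-result data frames, one per model.
#' @return A list with `table` (data frame: model, group_logL, one
#'   `BF_vs_<model>` column per comparator) and `labels` (matrix of
#'   evidence labels for each ordered pair).
#' @export
compare_models <- function(fit_list) {
  stopifnot(length(fit_list) >= 2, !is.null(names(fit_list)))
  participants <- sort(unique(fit_list[[1]]$participant))
  gl <- vapply(fit_list, group_log_likelihood, numeric(1),
               participants = participants)
  models <- names(fit_list)
  bf <- outer(gl, gl, function(a, b) exp(a - b))
  dimnames(bf) <- list(models, models)
  labels <- matrix("", length(models), length(models),
                   dimnames = list(models, models))
  for (a in models) for (b in models) {
    labels[a, b] <- if (a == b) "-" else interpret_bf(bf[a, b])
  }
  tab <- data.frame(model = models, group_logL = as.numeric(gl),
                    stringsAsFactors = FALSE)
  for (b in models) tab[[paste0("BF_vs_", b)]] <- bf[, b]
  list(table = tab, bf = bf, labels = labels)
}
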