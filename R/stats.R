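# Recognize the two standard alternations from the prime labels, or fall
# back to sorted order with a warning.
infer_alternation <- function(primes, alternation = NULL) {
  if (!is.null(alternation)) {
    stopifnot(length(alternation) == 2L)
    return(alternation)
  }
  lv <- sort(unique(as.character(primes)))
  if (identical(lv, c("A", "P"))) return(c("A", "P"))
  if (identical(lv, c("DO", "PD"))) return(c("DO", "PD"))
  warning("unrecognized alternation {", paste(lv, collapse = ", "),
          "}; using sorted order")
  lv
}

#' Condition proportions of first-member productions
#'
#' Per structure-by-grammaticality cell and per marginal, the proportion
#' of responses that are the alternation's first member (active / DO).
#' Uncodable (`"N/A"`) responses are excluded from all denominators.
#' Proportions are reported both pooled over trials and as the mean of
#' per-participant proportions.
#'
#' @param responses A response table (see [read_responses()]).
#' @param alternation Optional two structure labels (first member
#'   first); inferred when `NULL`.
#' @return A data frame with columns `structure` (label or `"all"`),
#'   `grammatical` (`"C"`, `"I"`, or `"all"`), `pooled`,
#'   `participant_mean`, and `n` (codable trials); empty cells are
#'   flagged with `NA` proportions.
#' @export
condition_proportions <- function(responses, alternation = NULL) {
  alternation <- infer_alternation(responses$prime_structure, alternation)
  first <- alternation[[1]]
  known <- responses[responses$response != "N/A", , drop = FALSE]
  groups <- rbind(
    expand.grid(structure = c(alternation, "all"),
                grammatical = c("C", "I", "all"),
                stringsAsFactors = FALSE)
  )
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    st <- groups$structure[[i]]
    gr <- groups$grammatical[[i]]
    sel <- rep(TRUE, nrow(known))
    if (st != "all") sel <- sel & known$prime_structure == st
    if (gr != "all") sel <- sel & known$grammatical == gr
    sub <- known[sel, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(structure = st, grammatical = gr,
                        pooled = NA_real_, participant_mean = NA_real_,
                        n = 0L, stringsAsFactors = FALSE))
    }
    per <- tapply(sub$response == first, sub$participant, mean)
    data.frame(structure = st, grammatical = gr,
               pooled = mean(sub$response == first),
               participant_mean = mean(per),
               n = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Syntactic priming effect
#'
#' The proportion of first-member responses after first-member primes
#' minus the proportion after second-member primes.
#'
#' @param p_after_same Proportion of first-member responses following
#'   first-member primes.
#' @param p_after_other Proportion following second-member primes.
#' @return The difference, in [-1, 1].
#' @export
priming_effect <- function(p_after_same, p_after_other) {
  stopifnot(p_after_same >= 0, p_after_same <= 1,
            p_after_other >= 0, p_after_other <= 1)
  p_after_same - p_after_other
}

#' Grammaticality effect
#'
#' The proportion of first-member responses after ungrammatical primes
#' minus the proportion after grammatical primes.
#'
#' @param p_ungrammatical,p_grammatical Marginal first-member
#'   proportions after ungrammatical and grammatical primes.
#' @return The difference (ungrammatical minus grammatical).
#' @export
grammaticality_effect <- function(p_ungrammatical, p_grammatical) {
  stopifnot(p_ungrammatical >= 0, p_ungrammatical <= 1,
            p_grammatical >= 0, p_grammatical <= 1)
  p_ungrammatical - p_grammatical
}

#' Full priming-effect summary of a response table
#'
#' Condition proportions plus the derived effects: overall priming,
#' priming within grammatical and within ungrammatical primes, and the
#' marginal grammaticality effect — each computed from both the pooled
#' and the participant-averaged proportions.
#'
#' @inheritParams condition_proportions
#' @return A list with `proportions` (the [condition_proportions()]
#'   table) and `effects` (data frame: effect name, pooled value,
#'   participant-mean value).
#' @export
priming_summary <- function(responses, alternation = NULL) {
  alternation <- infer_alternation(responses$prime_structure, alternation)
  props <- condition_proportions(responses, alternation)
  get <- function(st, gr, col) {
    props[props$structure == st & props$grammatical == gr, col]
  }
  eff <- function(col) {
    c(
      priming_overall = priming_effect(get(alternation[[1]], "all", col),
                                       get(alternation[[2]], "all", col)),
      priming_grammatical = priming_effect(
        get(alternation[[1]], "C", col), get(alternation[[2]], "C", col)),
      priming_ungrammatical = priming_effect(
        get(alternation[[1]], "I", col), get(alternation[[2]], "I", col)),
      grammaticality = grammaticality_effect(get("all", "I", col),
                                             get("all", "C", col))
    )
  }
  pooled <- eff("pooled")
  pm <- eff("participant_mean")
  list(
    proportions = props,
    effects = data.frame(effect = names(pooled),
                         pooled = as.numeric(pooled),
                         participant_mean = as.numeric(pm),
                         stringsAsFactors = FALSE)
  )
}
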