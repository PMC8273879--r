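#' Cohort specification for the synthetic response generator
#'
#' Describes a simulated participant cohort: the trial design, the
#' per-cell probability of producing the alternation's first member, the
#' SD of a per-participant random intercept on the logit scale, and the
#' rate of uncodable responses.
#'
#' @param n_participants Number of participants.
#' @param design_name Schedule design (see [make_schedule()]).
#' @param cell_probs Named numeric vector of marginal first-member
#'   production probabilities for the four cells, named
#'   `"<structure>_<C|I>"` (e.g. `A_C`), all in (0, 1).
#' @param participant_sd SD of the participant random intercept (logit
#'   scale), >= 0.
#' @param na_rate Probability that a response is uncodable (`"N/A"`), in
#'   [0, 0.2].
#' @param alternation Two structure labels; the first member is the one
#'   whose production probability `cell_probs` states.
#' @return A list of class `"sp_cohort_spec"`.
#' @export
cohort_spec <- function(n_participants, design_name, cell_probs,
                        participant_sd = 1.0, na_rate = 0,
                        alternation = c("A", "P")) {
  stopifnot(n_participants >= 1, all(cell_probs >= 0), all(cell_probs <= 1),
            participant_sd >= 0, na_rate >= 0, na_rate <= 0.2,
            length(alternation) == 2L)
  structure(list(n_participants = as.integer(n_participants),
                 design_name = design_name,
                 cell_probs = cell_probs,
                 participant_sd = participant_sd,
                 na_rate = na_rate,
                 alternation = alternation),
            class = "sp_cohort_spec")
}

#' Default cohort calibrations for the two experiments
#'
#' The first experiment's calibration: 89 participants on the 36-trial
#' active/passive design, cell probabilities (proportion of active
#' responses) 0.872 (A-prime grammatical), 0.904 (A ungrammatical),
#' 0.702 (P grammatical), 0.745 (P ungrammatical), and a 1.42% uncodable
#' rate. The second: 125 participants on the 20-trial DO/PD design, DO
#' proportions 0.788/0.786 after DO primes (C/I) and 0.643/0.614 after
#' PD primes, 7.46% uncodable. Both use a participant random-intercept
#' SD of 1.0 on the logit scale.
#'
#' @return An [cohort_spec()] object.
#' @export
exp1_default_spec <- function() {
  cohort_spec(
    n_participants = 89, design_name = "exp1",
    cell_probs = c(A_C = 0.872, A_I = 0.904, P_C = 0.702, P_I = 0.745),
    participant_sd = 1.0, na_rate = 0.0142,
    alternation = c("A", "P")
  )
}

#' @rdname exp1_default_spec
#' @export
exp2_default_spec <- function() {
  cohort_spec(
    n_participants = 125, design_name = "exp2",
    cell_probs = c(DO_C = 0.788, DO_I = 0.786, PD_C = 0.643, PD_I = 0.614),
    participant_sd = 1.0, na_rate = 0.0746,
    alternation = c("DO", "PD")
  )
}

# Solve for the logit shift m such that E[plogis(m + sd * Z)] = p for
# Z ~ N(0,1): the mean-matching calibration that keeps cell_probs
# marginal despite the logit nonlinearity.
calibrate_logit_shift <- function(p, sd) {
  if (sd == 0 || p <= 0 || p >= 1) return(stats::qlogis(p))
  marginal <- function(m) {
    stats::integrate(function(z) stats::plogis(m + sd * z) *
                       stats::dnorm(z),
                     -Inf, Inf, rel.tol = 1e-10)$value - p
  }
  stats::uniroot(marginal, lower = stats::qlogis(p) - 4 * sd,
                 upper = stats::qlogis(p) + 4 * sd, tol = 1e-10)$root
}

#' Generate a synthetic participant cohort
#'
#' Draws one random intercept per participant on the logit scale and,
#' per trial, a response that is the alternation's first member with
#' probability `plogis(shift_cell + b_p)`, where the cell shift is
#' calibrated so the population-average proportion equals the specified
#' `cell_probs` exactly despite the logit nonlinearity. Responses are
#' replaced by `"N/A"` with probability `na_rate`. Fully reproducible
#' under `seed`.
#'
#' @param spec An [cohort_spec()] object.
#' @param seed Optional integer seed.
#' @return A response table: `participant`, `trial`, `prime_structure`,
#'   `grammatical`, `semantic_correct`, `response`.
#' @export
generate_cohort <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sched <- make_schedule(spec$design_name, seed = NULL,
                         alternation = spec$alternation)
  n_trials <- nrow(sched)
  n <- spec$n_participants
  cellkey <- paste(sched$structure, sched$grammatical, sep = "_")
  shifts <- vapply(spec$cell_probs, calibrate_logit_shift, numeric(1),
                   sd = spec$participant_sd)
  b <- stats::rnorm(n, 0, spec$participant_sd)
  tab <- data.frame(
    participant = rep(sprintf("p%03d", seq_len(n)), each = n_trials),
    trial = rep(seq_len(n_trials), n),
    prime_structure = rep(sched$structure, n),
    grammatical = rep(sched$grammatical, n),
    semantic_correct = rep(sched$semantic_correct, n),
    stringsAsFactors = FALSE
  )
  eta <- shifts[rep(cellkey, n)] + rep(b, each = n_trials)
  first <- stats::runif(nrow(tab)) < stats::plogis(eta)
  resp <- ifelse(first, spec$alternation[[1]], spec$alternation[[2]])
  if (spec$na_rate > 0) {
    resp[stats::runif(nrow(tab)) < spec$na_rate] <- "N/A"
  }
  tab$response <- resp
  tab
}
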