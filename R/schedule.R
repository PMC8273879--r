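#' Build a prime-trial schedule
#'
#' Constructs a pseudorandomized trial schedule with the cell counts of
#' one of the two experimental designs, or of the 40-trial simulation
#' protocol:
#' \describe{
#'   \item{`"exp1"`}{36 active/passive trials: 18 per structure, 12
#'     ungrammatical / 24 grammatical (balanced over structures), and a
#'     balanced semantic-correctness flag within every cell. Incorrect
#'     active primes carry a `pre_structure` error (the violation is hit
#'     before the voice is identifiable), incorrect passive primes a
#'     `post_structure` error (the auxiliary reveals the voice first).}
#'   \item{`"exp2"`}{20 DO/PD trials, 5 per structure-by-grammaticality
#'     cell; all errors are `pre_structure` by design.}
#'   \item{`"paper40"`}{40 trials, 10 per cell, over the `alternation`
#'     labels; error positions as in `"exp1"` for an A/P alternation and
#'     `pre_structure` otherwise.}
#' }
#'
#' @param design_name `"exp1"`, `"exp2"`, or `"paper40"`.
#' @param seed Optional integer seed for the order randomization; the
#'   same seed yields the identical order.
#' @param alternation Structure labels for `"paper40"` (ignored by the
#'   named designs).
#' @return A data frame with columns `structure`, `grammatical`
#'   (`"C"`/`"I"`), `semantic_correct` (`"C"`/`"I"` or `NA`), and
#'   `error_position`.
#' @export
make_schedule <- function(design_name = c("exp1", "exp2", "paper40"),
                          seed = NULL, alternation = c("A", "P")) {
  design_name <- match.arg(design_name)
  cell <- function(structure, gram, n, sem = TRUE) {
    data.frame(
      structure = rep(structure, n),
      grammatical = rep(gram, n),
      semantic_correct = if (sem)
        rep(c("C", "I"), length.out = n) else rep(NA_character_, n),
      stringsAsFactors = FALSE
    )
  }
  if (design_name == "exp1") {
    trials <- rbind(cell("A", "C", 12), cell("A", "I", 6),
                    cell("P", "C", 12), cell("P", "I", 6))
    trials$error_position <- ifelse(
      trials$grammatical == "C", "none",
      ifelse(trials$structure == "A", "pre_structure", "post_structure"))
  } else if (design_name == "exp2") {
    trials <- rbind(cell("DO", "C", 5, sem = FALSE),
                    cell("DO", "I", 5, sem = FALSE),
                    cell("PD", "C", 5, sem = FALSE),
                    cell("PD", "I", 5, sem = FALSE))
    trials$error_position <- ifelse(trials$grammatical == "C",
                                    "none", "pre_structure")
  } else {
    a <- alternation
    trials <- rbind(cell(a[[1]], "C", 10), cell(a[[1]], "I", 10),
                    cell(a[[2]], "C", 10), cell(a[[2]], "I", 10))
    if (identical(sort(a), c("A", "P"))) {
      trials$error_position <- ifelse(
        trials$grammatical == "C", "none",
        ifelse(trials$structure == "A", "pre_structure",
               "post_structure"))
    } else {
      trials$error_position <- ifelse(trials$grammatical == "C",
                                      "none", "pre_structure")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  rownames(trials) <- NULL
  trials
}

#' Simulate per-condition production proportions
#'
#' Runs the model `n_runs` times on independently seeded copies and, per
#' structure-by-grammaticality cell, summarizes the proportion of trials
#' whose produced structure matches the prime structure (congruent
#' productions). `"unknown"` outcomes are excluded from the denominators,
#' mirroring the exclusion of uncodable behavioral responses.
#'
#' @param config An [model_config()] object.
#' @param schedule A schedule from [make_schedule()].
#' @param n_runs Number of independent simulation runs (>= 2 so the SD is
#'   defined; the study protocol uses 50).
#' @param seed Integer base seed; run r uses `seed + r - 1`.
#' @param reshuffle Re-randomize the trial order independently on every
#'   run (mirroring the counterbalancing of prime orders across lists);
#'   set `FALSE` to hold the passed order fixed.
#' @return A data frame of class `"sp_condition_summary"` with one row
#'   per cell: `structure`, `grammatical`, `mean` and `sd` of the
#'   congruent-production proportion across runs, `n_runs`, and
#'   `degenerate` (TRUE when some run had an all-unknown cell).
#' @export
simulate_condition_summary <- function(config, schedule, n_runs = 50,
                                       seed = 1L, reshuffle = TRUE) {
  stopifnot(n_runs >= 2)
  cells <- unique(schedule[, c("structure", "grammatical")])
  cells <- cells[order(match(cells$structure, config$alternation),
                       cells$grammatical), , drop = FALSE]
  props <- matrix(NA_real_, nrow = n_runs, ncol = nrow(cells))
  for (r in seq_len(n_runs)) {
    set.seed(seed + r - 1L)
    sched_r <- if (reshuffle) {
      schedule[sample.int(nrow(schedule)), , drop = FALSE]
    } else {
      schedule
    }
    out <- run_schedule(config, sched_r, seed = NULL)
    known <- out[out$produced != "unknown", , drop = FALSE]
    for (i in seq_len(nrow(cells))) {
      sel <- known$prime_structure == cells$structure[[i]] &
        known$grammatical == cells$grammatical[[i]]
      if (any(sel)) {
        props[r, i] <- mean(known$produced[sel] ==
                              cells$structure[[i]])
      }
    }
  }
  res <- data.frame(
    structure = cells$structure,
    grammatical = cells$grammatical,
    mean = colMeans(props, na.rm = TRUE),
    sd = apply(props, 2, stats::sd, na.rm = TRUE),
    n_runs = n_runs,
    degenerate = apply(props, 2, anyNA),
    stringsAsFactors = FALSE
  )
  if (any(res$degenerate)) {
    warning("some runs produced an all-unknown condition cell; ",
            "summary flagged degenerate")
  }
  class(res) <- c("sp_condition_summary", "data.frame")
  res
}
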