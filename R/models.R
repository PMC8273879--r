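#' Model configuration
#'
#' Bundles everything one priming model needs: the mechanism variant, the
#' structural alternation it operates over, declarative and procedural
#' parameter sets, and the timing/bookkeeping flags shared by all
#' variants.
#'
#' Variants:
#' \describe{
#'   \item{`"activation"`}{structures live in declarative memory; priming
#'     is pure base-level recency/frequency. Grammaticality is never read
#'     (a grammatical error is not parsed), so the model is blind to it.}
#'   \item{`"associative"`}{as `"activation"`, but an ungrammatical prime
#'     places a shared error-context chunk in the buffer context, linked
#'     to the primed structure; at production time it spreads activation
#'     to the structures it has co-occurred with, attenuated by its fan.}
#'   \item{`"reinforcement"`}{structures are productions selected by
#'     utility; comprehending a prime fires the matching production and
#'     delivers `r_plus` (grammatical) or `r_minus` (ungrammatical) at
#'     the end of comprehension.}
#'   \item{`"reinforcement_sequential"`}{as `"reinforcement"`, but the
#'     feedback respects word order: when the error precedes the point at
#'     which the structure is identifiable (`pre_structure`), the negative
#'     signal cannot reach the structure production and successful
#'     completion still delivers `r_plus`; only `post_structure` errors
#'     penalize the structure production.}
#' }
#'
#' @param variant One of `"activation"`, `"associative"`,
#'   `"reinforcement"`, `"reinforcement_sequential"`.
#' @param alternation Character vector of the two structure labels, e.g.
#'   `c("A", "P")` or `c("DO", "PD")`.
#' @param declarative An [declarative_params()] object.
#' @param procedural An [utility_params()] object.
#' @param iti Inter-trial interval in simulated seconds.
#' @param prime_target_gap Simulated seconds between the end of prime
#'   comprehension and the target production attempt (verification
#'   response, waiting period, and picture encoding); sets how much the
#'   prime's recency boost has decayed when the structure is chosen.
#' @param parse_represents Add a presentation to the primed chunk when the
#'   prime is parsed.
#' @param retrieval_represents Add a further presentation on successful
#'   cued retrieval during comprehension.
#' @param production_represents Add a presentation to the chunk retrieved
#'   at production time.
#' @param reward_target_production Reinforcement variants only: also add
#'   the production fired at target production to the fired set, so it is
#'   credited by the next prime's feedback. Off by default (minimal
#'   credit assignment: only the comprehension-time production is
#'   rewarded).
#' @return A list of class `"sp_model_config"`.
#' @export
model_config <- function(variant = c("activation", "associative",
                                     "reinforcement",
                                     "reinforcement_sequential"),
                         alternation = c("A", "P"),
                         declarative = NULL,
                         procedural = utility_params(),
                         iti = 10,
                         prime_target_gap = 5,
                         parse_represents = TRUE,
                         retrieval_represents = TRUE,
                         production_represents = TRUE,
                         reward_target_production = FALSE) {
  variant <- match.arg(variant)
  if (is.null(declarative)) {
    # the associative latency-factor value set starts at 0.5; its
    # default sits mid-set like the others'
    declarative <- if (variant == "associative")
      declarative_params(lf = 0.9) else declarative_params()
  }
  stopifnot(length(alternation) == 2L, iti >= 0, prime_target_gap >= 0)
  structure(list(variant = variant, alternation = alternation,
                 declarative = declarative, procedural = procedural,
                 iti = iti, prime_target_gap = prime_target_gap,
                 parse_represents = parse_represents,
                 retrieval_represents = retrieval_represents,
                 production_represents = production_represents,
                 reward_target_production = reward_target_production),
            class = "sp_model_config")
}

# Shared error-context chunk label used by the associative variant.
ERROR_CONTEXT <- "ungrammatical"

#' Initialize model state
#'
#' Builds the per-run mutable state: one chunk per structure seeded with
#' deterministic, evenly spaced baseline presentations over the
#' pre-experiment window (encoding the empirical dominance of the first
#' alternation member), equal-utility productions, an empty buffer
#' context, and the clock at zero.
#'
#' @param config An [model_config()] object.
#' @return A list of class `"sp_model_state"`.
#' @export
sp_model_init <- function(config) {
  dp <- config$declarative
  mk_hist <- function(n) {
    if (n == 0L) return(numeric(0))
    -dp$baseline_window * (n - seq_len(n) + 0.5) / n
  }
  chunks <- list(
    chunk(config$alternation[[1]], mk_hist(dp$n0[[1]])),
    chunk(config$alternation[[2]], mk_hist(dp$n0[[2]]))
  )
  names(chunks) <- config$alternation
  utilities <- stats::setNames(config$procedural$u0, config$alternation)
  structure(list(config = config, clock = 0, chunks = chunks,
                 context = stats::setNames(numeric(0), character(0)),
                 utilities = utilities, fired = character(0),
                 fired_time = stats::setNames(numeric(0), character(0))),
            class = "sp_model_state")
}

# Mark a production as fired (pending reward) at time t.
fire_production <- function(state, label, t) {
  state$fired <- union(state$fired, label)
  state$fired_time[label] <- t
  state
}

# Deliver a reward to every pending fired production, optionally
# discounted by the time elapsed since its firing, then clear the set.
rl_credit <- function(state, reward, now) {
  up <- state$config$procedural
  if (up$discount == 0) {
    state$utilities <- deliver_reward(state$utilities, state$fired,
                                      reward, up$alpha)
  } else {
    for (p in intersect(state$fired, names(state$utilities))) {
      r_eff <- reward - up$discount * (now - state$fired_time[[p]])
      state$utilities[[p]] <- update_utility(state$utilities[[p]],
                                             up$alpha, r_eff)
    }
  }
  state$fired <- character(0)
  state$fired_time <- stats::setNames(numeric(0), character(0))
  state
}

# Append a presentation timestamp, nudging forward if the clock has not
# advanced past the last presentation (histories must stay strictly
# increasing).
add_presentation <- function(state, label, t) {
  h <- state$chunks[[label]]$history
  if (length(h) > 0L && t <= h[[length(h)]]) {
    t <- h[[length(h)]] + 1e-6
  }
  state$chunks[[label]]$history <- c(h, t)
  state
}

#' Comprehend a prime sentence
#'
#' Applies the variant-specific consequence of reading one prime: the
#' declarative variants re-present (and attempt to retrieve) the primed
#' structure's chunk; the associative variant additionally sets up the
#' error-context spreading source on ungrammatical primes; the
#' reinforcement variants fire the structure production and deliver the
#' feedback signal at the end of comprehension.
#'
#' @param state An `sp_model_state`.
#' @param stimulus A list/row with fields `structure` (one of the
#'   alternation labels), `grammatical` (`"C"` or `"I"`), and
#'   `error_position` (`"none"`, `"pre_structure"`, or
#'   `"post_structure"`). A `semantic` field may be present; no variant
#'   reads it.
#' @return The updated state, with `state$last_comprehension_latency` set.
#' @export
comprehend_prime <- function(state, stimulus) {
  cfg <- state$config
  primed <- stimulus$structure
  if (!primed %in% cfg$alternation) {
    stop("prime structure '", primed, "' is not in the alternation")
  }
  ungram <- identical(stimulus$grammatical, "I")
  latency <- 0

  if (cfg$variant %in% c("activation", "associative")) {
    dp <- cfg$declarative
    now <- state$clock
    if (cfg$parse_represents) state <- add_presentation(state, primed, now)
    # cued retrieval of the parsed structure (threshold check only)
    a <- base_level_activation(state$chunks[[primed]]$history,
                               now + 1e-9, dp$bll) +
      sample_activation_noise(dp$ans)
    if (a >= dp$rt) {
      latency <- dp$lf * exp(-a)
      if (cfg$retrieval_represents) {
        state <- add_presentation(state, primed, now + latency)
      }
    } else {
      latency <- dp$lf * exp(-dp$rt)
    }
    if (cfg$variant == "associative" && ungram) {
      # The error chunk enters the buffer context as a spreading source.
      # Its association with the primed structure is episodic: the
      # imaginal buffer holds error + this trial's structure, so only
      # that structure receives spread at production time (a permanent
      # link would eventually boost both structures equally and cancel).
      # A persistent, retrieval-ineligible episode chunk per pairing
      # makes the error chunk's fan grow with each structure it has
      # co-occurred with, so later and more promiscuous pairings spread
      # less (inverse frequency).
      state$context[ERROR_CONTEXT] <- dp$ga
      episode <- paste0("err:", primed)
      if (!episode %in% names(state$chunks)) {
        state$chunks[[episode]] <- chunk(episode, numeric(0),
                                         refs = ERROR_CONTEXT)
      }
      refs <- state$chunks[[primed]]$refs
      if (!ERROR_CONTEXT %in% refs) {
        state$chunks[[primed]]$refs <- c(refs, ERROR_CONTEXT)
      }
    }
  } else if (cfg$variant == "reinforcement") {
    up <- cfg$procedural
    state <- fire_production(state, primed, state$clock)
    reward <- if (ungram) up$r_minus else up$r_plus
    state <- rl_credit(state, reward, state$clock)
  } else if (cfg$variant == "reinforcement_sequential") {
    up <- cfg$procedural
    state <- fire_production(state, primed, state$clock)
    reward <- if (ungram &&
                  identical(stimulus$error_position, "post_structure")) {
      # structure already selected when the error is hit: penalize it
      up$r_minus
    } else {
      # grammatical, or a pre-structure error whose negative signal
      # precedes structure selection: the structure production escapes
      # punishment and successful completion still rewards it
      up$r_plus
    }
    state <- rl_credit(state, reward, state$clock)
  } else {
    stop("unknown model variant: ", cfg$variant)
  }

  state$clock <- state$clock + latency
  state$last_comprehension_latency <- latency
  state
}

#' Produce a target description
#'
#' Declarative variants retrieve over the two structure chunks (the
#' associative variant adding spreading activation from any error-context
#' source set up during comprehension) and emit the winner's label, or
#' `"unknown"` on retrieval failure. Reinforcement variants select the
#' higher-utility production under logistic utility noise. The buffer
#' context is cleared afterwards.
#'
#' @param state An `sp_model_state`.
#' @return A list with `state` (updated), `produced` (structure label or
#'   `"unknown"`), and `latency` (seconds).
#' @export
produce_description <- function(state) {
  cfg <- state$config
  if (cfg$variant %in% c("activation", "associative")) {
    ctx <- if (cfg$variant == "associative") state$context else
      stats::setNames(numeric(0), character(0))
    res <- retrieve(state$chunks, ctx, cfg$declarative, state$clock)
    produced <- if (is.null(res$chunk)) "unknown" else res$label
    if (!is.null(res$chunk) && cfg$production_represents) {
      state <- add_presentation(state, res$label,
                                state$clock + res$latency)
    }
    latency <- res$latency
  } else {
    produced <- select_production(state$utilities, cfg$procedural$egs)
    if (cfg$reward_target_production) {
      state <- fire_production(state, produced, state$clock)
    }
    latency <- 0
  }
  # the buffer context and the episodic error link last one trial
  state$context <- stats::setNames(numeric(0), character(0))
  for (lab in cfg$alternation) {
    state$chunks[[lab]]$refs <-
      setdiff(state$chunks[[lab]]$refs, ERROR_CONTEXT)
  }
  state$clock <- state$clock + latency
  list(state = state, produced = produced, latency = latency)
}

#' Run one prime-target trial
#'
#' [comprehend_prime()] then [produce_description()], advancing the clock
#' by the retrieval latencies plus the configured inter-trial interval.
#'
#' @param state An `sp_model_state`.
#' @param stimulus See [comprehend_prime()].
#' @return A list with `state` and `outcome` (a one-row data frame with
#'   the prime descriptors, the produced label, and both latencies).
#' @export
run_trial <- function(state, stimulus) {
  state <- comprehend_prime(state, stimulus)
  cl <- state$last_comprehension_latency
  state$clock <- state$clock + state$config$prime_target_gap
  prod <- produce_description(state)
  state <- prod$state
  state$clock <- state$clock + state$config$iti
  outcome <- data.frame(
    prime_structure = stimulus$structure,
    grammatical = stimulus$grammatical,
    semantic_correct = if (is.null(stimulus$semantic_correct))
      NA_character_ else stimulus$semantic_correct,
    error_position = stimulus$error_position,
    produced = prod$produced,
    comprehension_latency = cl,
    production_latency = prod$latency,
    stringsAsFactors = FALSE
  )
  list(state = state, outcome = outcome)
}

#' Generate a cohort of simulated participants from a model
#'
#' Runs the model once per participant (independently seeded, with the
#' trial order re-randomized per participant) and returns the outcomes
#' as a coded-response table, `"unknown"` productions coded as
#' uncodable (`"N/A"`). Used for model-recovery checks: a cohort born
#' from one mechanism should be won back by it in group comparison.
#'
#' @param config An [model_config()] object.
#' @param schedule A schedule from [make_schedule()].
#' @param n_participants Number of simulated participants.
#' @param seed Integer base seed; participant p uses `seed + p - 1`.
#' @return A response table (see [read_responses()] for the schema).
#' @export
generate_model_cohort <- function(config, schedule, n_participants,
                                  seed = 1L) {
  out <- lapply(seq_len(n_participants), function(p) {
    set.seed(seed + p - 1L)
    sched_p <- schedule[sample.int(nrow(schedule)), , drop = FALSE]
    run <- run_schedule(config, sched_p, seed = NULL)
    data.frame(
      participant = sprintf("m%03d", p),
      trial = run$trial,
      prime_structure = run$prime_structure,
      grammatical = run$grammatical,
      semantic_correct = run$semantic_correct,
      response = ifelse(run$produced == "unknown", "N/A", run$produced),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Run a full trial schedule
#'
#' Initializes a fresh model state and runs every trial of the schedule
#' in order.
#'
#' @param config An [model_config()] object.
#' @param schedule A schedule data frame from [make_schedule()].
#' @param seed Optional integer seed for this run's noise draws.
#' @return A data frame with one row per trial (`trial`, prime
#'   descriptors, `produced`, latencies).
#' @export
run_schedule <- function(config, schedule, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- sp_model_init(config)
  n <- nrow(schedule)
  structure_v <- schedule$structure
  gram_v <- schedule$grammatical
  errpos_v <- schedule$error_position
  sem_v <- if ("semantic_correct" %in% names(schedule))
    schedule$semantic_correct else rep(NA_character_, n)
  produced <- character(n)
  clat <- numeric(n)
  plat <- numeric(n)
  for (i in seq_len(n)) {
    stim <- list(structure = structure_v[[i]], grammatical = gram_v[[i]],
                 error_position = errpos_v[[i]],
                 semantic_correct = sem_v[[i]])
    state <- comprehend_prime(state, stim)
    clat[[i]] <- state$last_comprehension_latency
    state$clock <- state$clock + config$prime_target_gap
    prod <- produce_description(state)
    state <- prod$state
    produced[[i]] <- prod$produced
    plat[[i]] <- prod$latency
    state$clock <- state$clock + config$iti
  }
  data.frame(trial = seq_len(n), prime_structure = structure_v,
             grammatical = gram_v, semantic_correct = sem_v,
             error_position = errpos_v, produced = produced,
             comprehension_latency = clat, production_latency = plat,
             stringsAsFactors = FALSE)
}
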