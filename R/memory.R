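#' Declarative memory chunk
#'
#' A chunk is a declarative trace for one syntactic structure (or an
#' error-context tag), carrying its presentation history on the simulation
#' clock and the labels of other chunks it refers to (used for fan
#' counting in spreading activation).
#'
#' @param label Character scalar identifying the structure (e.g. `"A"`,
#'   `"P"`, `"DO"`, `"PD"`, `"ungrammatical"`).
#' @param history Numeric vector of presentation timestamps in seconds,
#'   strictly increasing. A chunk with empty history is
#'   retrieval-ineligible.
#' @param refs Character vector of labels of chunks this chunk refers to
#'   in its slots.
#' @return A list of class `"sp_chunk"`.
#' @export
chunk <- function(label, history = numeric(0), refs = character(0)) {
  stopifnot(is.character(label), length(label) == 1L)
  history <- as.numeric(history)
  if (length(history) > 1L && any(diff(history) <= 0)) {
    stop("chunk history timestamps must be strictly increasing")
  }
  structure(list(label = label, history = history, refs = refs),
            class = "sp_chunk")
}

#' Declarative parameter set
#'
#' Bundles the subsymbolic declarative parameters: activation noise scale
#' `ans` (s of the logistic noise), base-level decay `bll` (d), latency
#' factor `lf` (F, seconds), maximum associative strength `mas` (S),
#' goal-buffer source weight `ga` (W), and retrieval threshold `rt` (tau).
#'
#' @param ans Activation noise scale, >= 0.
#' @param bll Base-level decay, in (0, 1).
#' @param lf Latency factor in seconds, > 0.
#' @param mas Maximum associative strength.
#' @param ga Source activation weight for the goal/imaginal buffer.
#' @param rt Retrieval threshold in activation units.
#' @param n0 Integer vector of length 2: baseline presentation counts for
#'   the first and second alternation member.
#' @param baseline_window Width in seconds of the pre-experiment window
#'   over which baseline presentations are spread.
#' @return A list of class `"sp_declarative_params"`.
#' @export
declarative_params <- function(ans = 0.5, bll = 0.5, lf = 0.5, mas = 3.2,
                               ga = 1.0, rt = 0,
                               n0 = c(16L, 6L), baseline_window = 100) {
  stopifnot(ans >= 0, bll > 0, bll < 1, lf > 0, length(n0) == 2L,
            all(n0 >= 0), baseline_window > 0)
  structure(list(ans = ans, bll = bll, lf = lf, mas = mas, ga = ga,
                 rt = rt, n0 = as.integer(n0),
                 baseline_window = baseline_window),
            class = "sp_declarative_params")
}

#' Base-level activation
#'
#' Log power-law sum over presentation recencies,
#' \eqn{B = \ln \sum_j (now - t_j)^{-d}}, capturing frequency and recency
#' of practice.
#'
#' @param history Numeric vector of presentation timestamps (seconds),
#'   all strictly before `now`. Must be non-empty.
#' @param now Current simulation time in seconds.
#' @param d Decay exponent, in (0, 1).
#' @return Base-level activation (scalar).
#' @export
base_level_activation <- function(history, now, d) {
  if (length(history) == 0L) {
    stop("no trace: chunk has no presentation history", call. = FALSE)
  }
  if (any(history >= now)) {
    stop("all presentation timestamps must precede `now`", call. = FALSE)
  }
  log(sum((now - history)^(-d)))
}

#' Spreading activation from buffer sources
#'
#' Context boost to a target chunk from attended sources,
#' \eqn{\sum_j W_j (S - \ln fan_j)}, where the fan of source j is one plus
#' the number of chunks in the pool holding j as a slot value. Association
#' strengths are clamped at zero from below, so a very high-fan source
#' never inhibits.
#'
#' @param context Named numeric vector of source weights (names are source
#'   chunk labels, values are the W weights, all >= 0). May be empty.
#' @param target An [chunk()] object; a source spreads to it only if the
#'   source label appears among the target's `refs` or equals its label.
#' @param pool List of [chunk()] objects used for fan counting.
#' @param S Maximum associative strength.
#' @return Activation increment (scalar, >= 0).
#' @export
spreading_activation <- function(context, target, pool, S) {
  if (length(context) == 0L) return(0)
  w <- as.numeric(context)
  if (any(w < 0)) stop("source weights must be non-negative", call. = FALSE)
  src <- names(context)
  total <- 0
  for (i in seq_along(src)) {
    j <- src[[i]]
    if (!(j %in% target$refs || identical(j, target$label))) next
    fan <- 1L + sum(vapply(pool, function(ch) j %in% ch$refs, logical(1)))
    total <- total + w[[i]] * max(0, S - log(fan))
  }
  total
}

#' Activation noise draw
#'
#' One draw from a zero-mean logistic distribution with scale `s` (the
#' ACT-R instantaneous-noise convention). `s = 0` returns exactly 0.
#'
#' @param s Noise scale, >= 0.
#' @param n Number of draws.
#' @return Numeric vector of noise values.
#' @export
sample_activation_noise <- function(s, n = 1L) {
  stopifnot(s >= 0)
  if (s == 0) return(rep(0, n))
  stats::rlogis(n, location = 0, scale = s)
}

#' Noisy winner-take-all retrieval
#'
#' Computes total activation `A_i = B_i + spread_i + noise_i` for every
#' eligible chunk (non-empty history) and returns the argmax if it clears
#' the retrieval threshold, else a failure. Latency is `F * exp(-A)` of
#' the winning activation on success and `F * exp(-rt)` on failure. Ties
#' are broken uniformly at random.
#'
#' @param pool List of [chunk()] objects (may be empty).
#' @param context Named numeric vector of buffer source weights (possibly
#'   empty) for spreading activation.
#' @param params An [declarative_params()] object.
#' @param now Current simulation time (seconds).
#' @return A list with elements `chunk` (the retrieved [chunk()] or `NULL`
#'   on failure), `label` (its label or `NA_character_`), `activation`
#'   (the winning total activation, or `NA` for an empty pool), and
#'   `latency` (seconds).
#' @export
retrieve <- function(pool, context, params, now) {
  eligible <- Filter(function(ch) length(ch$history) > 0L, pool)
  fail <- list(chunk = NULL, label = NA_character_, activation = NA_real_,
               latency = params$lf * exp(-params$rt))
  if (length(eligible) == 0L) return(fail)
  now <- now + 1e-9 # presentations stamped at `now` are in the past
  a <- vapply(eligible, function(ch) {
    base_level_activation(ch$history, now, params$bll) +
      spreading_activation(context, ch, pool, params$mas)
  }, numeric(1))
  a <- a + sample_activation_noise(params$ans, length(a))
  amax <- max(a)
  if (amax < params$rt) {
    fail$activation <- amax
    return(fail)
  }
  top <- which(a == amax)
  win <- if (length(top) > 1L) top[[sample.int(length(top), 1L)]] else top
  list(chunk = eligible[[win]], label = eligible[[win]]$label,
       activation = amax, latency = params$lf * exp(-amax))
}
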