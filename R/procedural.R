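#' Utility parameter set
#'
#' Procedural (utility-learning) parameters: utility noise scale `egs`,
#' learning rate `alpha`, and the positive/negative rewards delivered
#' after comprehending a grammatical vs. ungrammatical prime.
#'
#' @param egs Utility noise scale, >= 0.
#' @param alpha Learning rate, in (0, 1].
#' @param r_plus Reward for a successfully comprehended grammatical prime.
#' @param r_minus Reward (<= 0) for an ungrammatical prime.
#' @param u0 Numeric vector of length 2: initial utilities of the first
#'   and second alternation member's production. Equal by default; an
#'   asymmetric start encodes a baseline production bias.
#' @param discount Temporal discount (reward units per second) subtracted
#'   from the reward in proportion to the time elapsed since the credited
#'   production fired. Off (0) by default: the plain update rule has no
#'   discounting.
#' @return A list of class `"sp_utility_params"`.
#' @export
utility_params <- function(egs = 0.5, alpha = 0.3, r_plus = 1,
                           r_minus = -1, u0 = c(0, 0), discount = 0) {
  stopifnot(egs >= 0, alpha > 0, alpha <= 1, r_minus <= 0,
            length(u0) == 2L, discount >= 0)
  structure(list(egs = egs, alpha = alpha, r_plus = r_plus,
                 r_minus = r_minus, u0 = as.numeric(u0),
                 discount = discount),
            class = "sp_utility_params")
}

#' Temporal-difference utility update
#'
#' \eqn{U_t = U_{t-1} + \alpha (R_t - U_{t-1})}: the utility moves a
#' fraction `alpha` of the way toward the received reward, with fixed
#' point at `U = R`. No temporal discounting is applied.
#'
#' @param u_prev Previous utility.
#' @param alpha Learning rate.
#' @param reward Received reward R.
#' @return Updated utility.
#' @export
update_utility <- function(u_prev, alpha, reward) {
  u_prev + alpha * (reward - u_prev)
}

#' Noisy production selection
#'
#' Adds an independent logistic(0, egs) draw to each candidate utility
#' and returns the index of the argmax; `egs = 0` is a deterministic
#' argmax, ties are broken uniformly at random.
#'
#' @param utilities Named numeric vector of candidate utilities
#'   (non-empty).
#' @param egs Utility noise scale.
#' @return The name (label) of the selected production.
#' @export
select_production <- function(utilities, egs) {
  if (length(utilities) == 0L) {
    stop("candidate production set is empty", call. = FALSE)
  }
  u <- utilities + sample_activation_noise(egs, length(utilities))
  top <- which(u == max(u))
  win <- if (length(top) > 1L) top[[sample.int(length(top), 1L)]] else top
  names(utilities)[[win]]
}

#' Deliver a reward to fired productions
#'
#' Applies [update_utility()] to every production that fired since the
#' last reward, then clears the fired set. Productions that did not fire
#' are untouched.
#'
#' @param utilities Named numeric vector of production utilities.
#' @param fired Character vector of labels of productions that fired.
#' @param reward Reward to deliver.
#' @param alpha Learning rate.
#' @return The updated utilities vector.
#' @export
deliver_reward <- function(utilities, fired, reward, alpha) {
  for (p in intersect(fired, names(utilities))) {
    utilities[[p]] <- update_utility(utilities[[p]], alpha, reward)
  }
  utilities
}
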