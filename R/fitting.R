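#' Parameter grids for grid-search fitting
#'
#' Returns the named parameter value sets explored for each model
#' variant. The full grids are the simulation study's sets (activation:
#' 6 x 5 x 5; associative: 6 x 5 x 4 x 4 x 3; reinforcement: 5 x 5 x 6 x
#' 6); the reduced grids subset each set to at most three values
#' (containing the package defaults) for smoke-scale fitting.
#'
#' @param variant Model variant name (the two reinforcement variants
#'   share a grid).
#' @param reduced Use the reduced grid (default) or the full grid.
#' @return A named list of numeric value vectors. Attribute `"k"` holds
#'   the free-parameter count used in the BIC (3 activation / 5
#'   associative / 4 reinforcement).
#' @export
default_parameter_grid <- function(variant, reduced = TRUE) {
  full <- list(
    activation = list(
      ans = c(0.1, 0.25, 0.5, 0.75, 1, 1.5),
      bll = c(0.1, 0.3, 0.5, 0.7, 0.9),
      lf = c(0.1, 0.3, 0.5, 0.7, 0.9)
    ),
    associative = list(
      ans = c(0.1, 0.25, 0.5, 0.75, 1, 1.5),
      bll = c(0.1, 0.3, 0.5, 0.7, 0.9),
      lf = c(0.5, 0.7, 0.9, 1),
      ga = c(0.5, 1, 1.5, 2),
      mas = c(2.8, 3.2, 3.6)
    ),
    reinforcement = list(
      egs = c(0.01, 0.1, 0.5, 0.9, 1.3),
      alpha = c(0.1, 0.3, 0.5, 0.7, 0.9),
      r_plus = c(0, 0.1, 0.5, 1, 5, 10),
      r_minus = c(-10, -5, -1, -0.5, -0.1, 0)
    )
  )
  small <- list(
    activation = list(
      ans = c(0.25, 0.5, 1),
      bll = c(0.3, 0.5, 0.7),
      lf = c(0.5, 0.9)
    ),
    associative = list(
      ans = c(0.5, 1),
      bll = c(0.5),
      lf = c(0.9),
      ga = c(0.5, 1, 2),
      mas = c(2.8, 3.2, 3.6)
    ),
    reinforcement = list(
      egs = c(0.1, 0.5, 1.3),
      alpha = c(0.3, 0.7),
      r_plus = c(0.5, 1),
      r_minus = c(-1, -0.1)
    )
  )
  key <- if (variant %in% c("reinforcement", "reinforcement_sequential"))
    "reinforcement" else variant
  if (!key %in% names(full)) stop("unknown model variant: ", variant)
  g <- if (reduced) small[[key]] else full[[key]]
  attr(g, "k") <- c(activation = 3L, associative = 5L,
                    reinforcement = 4L)[[key]]
  g
}

#' Expand a parameter grid into its Cartesian points
#'
#' @param grid A named list of parameter value vectors.
#' @return A data frame with one row per parameter combination.
#' @export
expand_parameter_grid <- function(grid) {
  expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
}

# Apply a parameter point (one row of the expanded grid) to a model
# config, routing each name to the declarative or procedural set.
apply_parameter_point <- function(config, point) {
  for (nm in names(point)) {
    v <- point[[nm]]
    if (nm %in% names(config$declarative)) {
      config$declarative[[nm]] <- v
    } else if (nm %in% names(config$procedural)) {
      config$procedural[[nm]] <- v
    } else {
      stop("parameter '", nm, "' matches no model parameter")
    }
  }
  config
}

#' Simulation-based empirical log-likelihood
#'
#' Treats the simulator's across-run mean and SD in each condition as a
#' normal predictive distribution and scores the observed proportions
#' under it: \eqn{logL = \sum_i \log \phi((x_i - \bar{x}_i)/\sigma_i) -
#' \sum_i \log \sigma_i}, a true log-density. SDs below the floor are
#' raised to it (a noise-free parameter point would otherwise yield an
#' unbounded likelihood).
#'
#' @param obs Numeric vector of observed condition proportions, in the
#'   same cell order as `summary`.
#' @param summary An `sp_condition_summary` (or any data frame with
#'   `mean` and `sd` columns matching `obs`).
#' @param sigma_floor Lower bound applied to the predictive SDs.
#' @param density If `FALSE`, drop the normalizing constant and the
#'   `-log sigma` Jacobian and sum only the `-z^2/2` terms (sensitivity
#'   analysis).
#' @param quiet Suppress the warning emitted when an SD is floored.
#' @return The log-likelihood (scalar).
#' @export
empirical_log_likelihood <- function(obs, summary, sigma_floor = 0.01,
                                     density = TRUE, quiet = FALSE) {
  stopifnot(length(obs) == nrow(summary))
  s <- summary$sd
  if (any(s < sigma_floor)) {
    if (!quiet) {
      warning("predictive SD below ", sigma_floor,
              " floored in empirical likelihood")
    }
    s <- pmax(s, sigma_floor)
  }
  if (density) {
    sum(stats::dnorm(obs, mean = summary$mean, sd = s, log = TRUE))
  } else {
    sum(-((obs - summary$mean) / s)^2 / 2)
  }
}

#' Bayesian Information Criterion
#'
#' `-2 logL + k log(n)`; lower is better.
#'
#' @param logL Log-likelihood.
#' @param k Number of free parameters.
#' @param n_obs Number of observations (here, the four fitted condition
#'   proportions per participant).
#' @return The BIC (scalar).
#' @export
bic <- function(logL, k, n_obs) {
  stopifnot(n_obs >= 1)
  -2 * logL + k * log(n_obs)
}

#' Per-participant condition proportions from a response table
#'
#' Computes, per participant and structure-by-grammaticality cell, the
#' proportion of congruent productions (response equals the prime
#' structure), excluding uncodable (`"N/A"`) responses — the observed
#' quantities the empirical likelihood scores.
#'
#' @param responses A response table (see [read_responses()]).
#' @param alternation Optional two structure labels fixing the cell
#'   order; inferred from the primes when `NULL`.
#' @return A data frame with columns `participant`, `structure`,
#'   `grammatical`, `prop` (congruent proportion), and `n` (codable
#'   trials in the cell).
#' @export
participant_data <- function(responses, alternation = NULL) {
  alternation <- infer_alternation(responses$prime_structure, alternation)
  known <- responses[responses$response != "N/A", , drop = FALSE]
  cells <- expand.grid(structure = alternation, grammatical = c("C", "I"),
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$structure, alternation),
                       cells$grammatical), , drop = FALSE]
  out <- lapply(unique(responses$participant), function(p) {
    dp <- known[known$participant == p, , drop = FALSE]
    prop <- numeric(nrow(cells))
    n <- integer(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      sel <- dp$prime_structure == cells$structure[[i]] &
        dp$grammatical == cells$grammatical[[i]]
      n[[i]] <- sum(sel)
      prop[[i]] <- if (n[[i]] > 0)
        mean(dp$response[sel] == cells$structure[[i]]) else NA_real_
    }
    data.frame(participant = p, structure = cells$structure,
               grammatical = cells$grammatical, prop = prop, n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit one model to a cohort by grid search
#'
#' Evaluates every parameter point of the grid by simulating the
#' condition summary once (summaries do not depend on the participant)
#' and scoring every participant's observed proportions against it; per
#' participant, the point with minimum BIC wins (ties broken by
#' first-in-grid order).
#'
#' @param pdata Output of [participant_data()].
#' @param config An [model_config()] template; grid parameters overwrite
#'   its declarative/procedural values point by point.
#' @param grid A grid from [default_parameter_grid()] (or a compatible
#'   named list carrying a `"k"` attribute).
#' @param schedule Trial schedule the simulations run on.
#' @param n_runs Simulation runs per parameter point.
#' @param seed Integer base seed; grid point g uses `seed + (g-1) *
#'   n_runs` so runs never overlap across points.
#' @param n_obs Observation count used in the BIC (default: the four
#'   condition proportions).
#' @param cache_dir Optional directory; when given, each point's summary
#'   is also written there as CSV.
#' @return A data frame with one row per participant: `participant`,
#'   `variant`, the best point's parameter columns, `logL`, `k`, `n_obs`,
#'   `BIC`. Attribute `"evaluations"` holds the full participant-by-point
#'   logL matrix and `"points"` the expanded grid.
#' @export
fit_cohort <- function(pdata, config, grid, schedule, n_runs = 50,
                       seed = 1L, n_obs = 4L, cache_dir = NULL) {
  points <- expand_parameter_grid(grid)
  stopifnot(nrow(points) >= 1)
  k <- attr(grid, "k")
  if (is.null(k)) k <- length(grid)
  participants <- unique(pdata$participant)
  obs <- lapply(participants, function(p) {
    pdata$prop[pdata$participant == p]
  })
  logl <- matrix(NA_real_, nrow = length(participants),
                 ncol = nrow(points))
  for (g in seq_len(nrow(points))) {
    cfg <- apply_parameter_point(config, as.list(points[g, , drop = FALSE]))
    smry <- simulate_condition_summary(cfg, schedule, n_runs = n_runs,
                                       seed = seed + (g - 1L) * n_runs)
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(smry, file.path(cache_dir,
                                       sprintf("summary_%s_%04d.csv",
                                               config$variant, g)),
                       row.names = FALSE)
    }
    for (i in seq_along(participants)) {
      logl[i, g] <- empirical_log_likelihood(obs[[i]], smry,
                                             quiet = TRUE)
    }
  }
  best <- apply(logl, 1, which.max) # min BIC == max logL at fixed k
  res <- cbind(
    data.frame(participant = participants,
               variant = config$variant, stringsAsFactors = FALSE),
    points[best, , drop = FALSE],
    data.frame(logL = logl[cbind(seq_along(participants), best)],
               k = k, n_obs = n_obs)
  )
  res$BIC <- bic(res$logL, res$k, res$n_obs)
  rownames(res) <- NULL
  attr(res, "evaluations") <- logl
  attr(res, "points") <- points
  res
}

#' Grid search for a single participant
#'
#' Convenience wrapper around [fit_cohort()] for one participant's
#' observed condition proportions.
#'
#' @param obs Numeric vector of 4 observed congruent proportions in cell
#'   order (first structure C, first I, second C, second I).
#' @param config,grid,schedule,n_runs,seed,n_obs See [fit_cohort()].
#' @return A one-row fit-result data frame (see [fit_cohort()]).
#' @export
grid_search <- function(obs, config, grid, schedule, n_runs = 50,
                        seed = 1L, n_obs = 4L) {
  alternation <- config$alternation
  pdata <- data.frame(
    participant = "p1",
    structure = rep(alternation, each = 2L),
    grammatical = rep(c("C", "I"), 2L),
    prop = obs, n = NA_integer_, stringsAsFactors = FALSE
  )
  fit_cohort(pdata, config, grid, schedule, n_runs = n_runs,
             seed = seed, n_obs = n_obs)
}
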