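mk_summary <- function(means, sds) {
  data.frame(structure = rep(c("A", "P"), each = 2),
             grammatical = rep(c("C", "I"), 2),
             mean = means, sd = sds, n_runs = 50, degenerate = FALSE)
}

test_that("empirical log-likelihood is the normal log-density of the data", {
  s <- mk_summary(rep(0.5, 4), rep(1, 4))
  expect_equal(empirical_log_likelihood(rep(0.5, 4), s),
               4 * (-0.5 * log(2 * pi)), tolerance = 1e-10)
  # moving one condition to z = 1 costs exactly 1/2
  obs <- c(1.5, 0.5, 0.5, 0.5)
  expect_equal(empirical_log_likelihood(obs, s),
               4 * (-0.5 * log(2 * pi)) - 0.5, tolerance = 1e-10)
  # maximized at the predictive mean
  set.seed(55)
  for (i in 1:10) {
    m <- runif(4); sd <- runif(4, 0.02, 0.3)
    s2 <- mk_summary(m, sd)
    at_mode <- empirical_log_likelihood(m, s2)
    expect_gt(at_mode, empirical_log_likelihood(m + runif(4, 0.01, 0.1), s2))
  }
})

test_that("empirical log-likelihood matches an explicit formula oracle", {
  set.seed(56)
  for (i in 1:20) {
    m <- runif(4); sd <- runif(4, 0.02, 0.4); x <- runif(4)
    oracle <- sum(-0.5 * log(2 * pi) - 0.5 * ((x - m) / sd)^2 - log(sd))
    expect_equal(empirical_log_likelihood(x, mk_summary(m, sd)), oracle,
                 tolerance = 1e-10)
    # z-only variant drops constant and Jacobian
    expect_equal(
      empirical_log_likelihood(x, mk_summary(m, sd), density = FALSE),
      sum(-0.5 * ((x - m) / sd)^2), tolerance = 1e-10)
  }
})

test_that("zero predictive SDs are floored with a warning", {
  s <- mk_summary(rep(0.5, 4), rep(0, 4))
  expect_warning(l <- empirical_log_likelihood(rep(0.5, 4), s), "floored")
  expect_equal(l, sum(dnorm(rep(0.5, 4), rep(0.5, 4), 0.01, log = TRUE)))
  expect_silent(empirical_log_likelihood(rep(0.5, 4), s, quiet = TRUE))
})

test_that("BIC follows -2 logL + k log(n)", {
  expect_equal(bic(-100, 3, 4), 200 + 3 * log(4), tolerance = 1e-10)
  expect_identical(bic(-100, 0, 4), 200)
  expect_equal(bic(-100, 4, 4) - bic(-100, 3, 4), log(4),
               tolerance = 1e-12)
  # at fixed k and n, BIC ranking is the -logL ranking
  ll <- c(-10, -3, -7, -1)
  expect_identical(order(bic(ll, 3, 4)), order(-ll))
})

test_that("parameter grids carry the study value sets and k", {
  g <- default_parameter_grid("activation", reduced = FALSE)
  expect_identical(attr(g, "k"), 3L)
  expect_identical(lengths(g), c(ans = 6L, bll = 5L, lf = 5L))
  expect_identical(g$ans, c(0.1, 0.25, 0.5, 0.75, 1, 1.5))
  ga <- default_parameter_grid("associative", reduced = FALSE)
  expect_identical(attr(ga, "k"), 5L)
  expect_identical(nrow(expand_parameter_grid(ga)), 6L * 5L * 4L * 4L * 3L)
  expect_identical(ga$mas, c(2.8, 3.2, 3.6))
  gr <- default_parameter_grid("reinforcement_sequential", reduced = FALSE)
  expect_identical(attr(gr, "k"), 4L)
  expect_identical(gr$r_minus, c(-10, -5, -1, -0.5, -0.1, 0))
  # reduced grids are subsets of the full sets
  for (v in c("activation", "associative", "reinforcement")) {
    red <- default_parameter_grid(v, reduced = TRUE)
    for (nm in names(red)) {
      expect_true(all(red[[nm]] %in%
                        default_parameter_grid(v, reduced = FALSE)[[nm]]))
    }
  }
  expect_error(default_parameter_grid("nonesuch"), "unknown")
})

test_that("grid search returns the dominant point", {
  sch <- make_schedule("exp1", seed = 2)
  cfg <- model_config("activation")
  single <- list(ans = 0.5, bll = 0.5, lf = 0.5)
  attr(single, "k") <- 3L
  fit <- grid_search(c(0.7, 0.7, 0.4, 0.4), cfg, single, sch,
                     n_runs = 10, seed = 3)
  expect_identical(nrow(fit), 1L)
  expect_identical(fit$ans, 0.5)
  expect_equal(fit$BIC, -2 * fit$logL + 3 * log(4), tolerance = 1e-12)

  # two-point grid: the point whose own summary generated the data wins
  two <- list(ans = c(0.25), bll = c(0.3, 0.7), lf = 0.5)
  attr(two, "k") <- 3L
  cfg1 <- model_config("activation",
                       declarative = declarative_params(ans = 0.25,
                                                        bll = 0.3))
  truth <- simulate_condition_summary(cfg1, sch, n_runs = 10, seed = 3)
  fit2 <- grid_search(truth$mean, cfg, two, sch, n_runs = 10, seed = 3)
  expect_identical(fit2$bll, 0.3)
})

test_that("refitting data from a known point recovers its predictions", {
  sch <- make_schedule("exp1", seed = 13)
  gen <- model_config("activation",
                      declarative = declarative_params(ans = 0.5,
                                                       bll = 0.5, lf = 0.5))
  truth <- simulate_condition_summary(gen, sch, n_runs = 40, seed = 900)
  grid <- default_parameter_grid("activation")
  fit <- grid_search(truth$mean, model_config("activation"), grid, sch,
                     n_runs = 40, seed = 17)
  # the chosen point can never score below the true point, which is in
  # the grid and evaluated with the same simulation machinery
  points <- attr(fit, "points")
  true_idx <- which(points$ans == 0.5 & points$bll == 0.5 &
                      points$lf == 0.5)
  expect_gte(fit$logL, attr(fit, "evaluations")[1, true_idx])
  # and its predictive distribution is indistinguishable from the
  # truth at the simulator's own run-to-run noise level (~binomial SD
  # of 36-trial proportions) -- the resolution limit of the method
  best <- model_config("activation",
                       declarative = declarative_params(ans = fit$ans,
                                                        bll = fit$bll,
                                                        lf = fit$lf))
  rec <- simulate_condition_summary(best, sch, n_runs = 40, seed = 901)
  pred_sd <- pmax(sqrt((truth$sd^2 + rec$sd^2) / 2), 0.02)
  expect_true(all(abs(rec$mean - truth$mean) <= 2 * pred_sd))
})

test_that("participant data are per-cell congruent proportions", {
  tab <- toy_responses(
    responses = c("A", "A", "P", "N/A", "P", "A", "A", "P"),
    structures = c("A", "A", "A", "A", "P", "P", "P", "P"),
    grammatical = c("C", "C", "C", "C", "C", "C", "I", "I"))
  pd <- participant_data(tab, alternation = c("A", "P"))
  expect_identical(nrow(pd), 4L)
  get <- function(st, gr) pd[pd$structure == st & pd$grammatical == gr, ]
  expect_equal(get("A", "C")$prop, 2 / 3) # N/A dropped from denominator
  expect_identical(get("A", "C")$n, 3L)
  expect_equal(get("P", "C")$prop, 1 / 2)
  expect_equal(get("P", "I")$prop, 1 / 2)
  expect_true(is.na(get("A", "I")$prop))
  expect_identical(get("A", "I")$n, 0L)
})
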