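#!/usr/bin/env Rscript
# Step 3: fit the three main mechanisms to the synthetic cohort from
# step 2 by per-participant grid search over the reduced parameter
# grids, using the simulation-based empirical likelihood and BIC.
# Summaries are simulated once per grid point and scored against every
# participant. Pass --full-grid to search the full value sets instead
# (slow: the associative grid alone is 1440 points).

suppressMessages(library(spriming))

args <- commandArgs(trailingOnly = TRUE)
full_grid <- "--full-grid" %in% args
SEED <- 20251001L
N_RUNS <- if (full_grid) 50L else 20L
N_PARTICIPANTS <- 20L # subsample for the smoke path

cohort_path <- "results/cohort_exp1.csv"
if (!file.exists(cohort_path)) {
  stop("run analysis/02_behavioral_stats.R first (missing ", cohort_path,
       ")")
}
coh <- read_responses(cohort_path)
keep <- head(unique(coh$participant), N_PARTICIPANTS)
pd <- participant_data(coh[coh$participant %in% keep, ],
                       alternation = c("A", "P"))
sch <- make_schedule("exp1", seed = SEED)

for (v in c("activation", "associative", "reinforcement")) {
  grid <- default_parameter_grid(v, reduced = !full_grid)
  n_pts <- nrow(expand_parameter_grid(grid))
  t0 <- Sys.time()
  fit <- fit_cohort(pd, model_config(v), grid, sch,
                    n_runs = N_RUNS, seed = SEED + 7L)
  message(sprintf(
    "%-13s %4d grid points, %d runs each: group logL %+.1f, median BIC %.2f (%.1fs)",
    v, n_pts, N_RUNS, group_log_likelihood(fit), median(fit$BIC),
    as.numeric(Sys.time() - t0, units = "secs")))
  write.csv(fit, file.path("results", paste0("fits_", v, ".csv")),
            row.names = FALSE)
}
writeLines(sprintf(
  '{"seed": %d, "n_runs": %d, "n_participants": %d, "full_grid": %s}',
  SEED, N_RUNS, N_PARTICIPANTS, tolower(full_grid)),
  "results/fits_provenance.json")
message("Wrote results/fits_*.csv")
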