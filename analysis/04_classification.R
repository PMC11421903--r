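#!/usr/bin/env Rscript

## Stage 4 -- the five random-forest classification experiments.
##
## Each level uses a leakage-proof hold-out (whole callers, whole core
## groups, or whole caller-dates), a majority-classifier null, and a
## one-tailed exact binomial test per iteration; medians over iterations
## are the summaries. Population is predicted from mel features and,
## separately, from the equipment-robust f1 contour statistics.

suppressMessages(library(rumblesig))

dataset <- readRDS("scratch/dataset.rds")
cfg <- dataset$config
features <- read_prov_csv("results/features.csv")
calls <- dataset$calls
mel <- mel_feature_cols(features)
f1 <- contour_feature_cols(features)
p1 <- calls[calls$population == "P1", ]
n_iter <- 300

runs <- list(
  population = run_experiment(features, calls, "population", mel,
                              n_iter = n_iter, seed = cfg$seed),
  population_f1 = run_experiment(features, calls, "population", f1,
                                 n_iter = n_iter, seed = cfg$seed + 1),
  bond = run_experiment(features, p1, "bond", mel, n_iter = n_iter,
                        seed = cfg$seed),
  core = run_experiment(features, p1, "core", mel, n_iter = n_iter,
                        seed = cfg$seed),
  individual = run_experiment(features, calls, "individual", mel,
                              n_iter = n_iter, seed = cfg$seed))

for (lv in names(runs)) {
  print(runs[[lv]])
  write_prov_csv(runs[[lv]]$iterations,
                 sprintf("results/experiment_%s.csv", lv), cfg$seed, cfg)
}
summ <- do.call(rbind, lapply(names(runs), function(lv) {
  s <- runs[[lv]]$summary
  data.frame(level = lv, median_accuracy = s$median_accuracy,
             median_baseline = s$median_baseline, median_p = s$median_p,
             test_frac_mean = s$test_frac_mean,
             test_frac_sd = s$test_frac_sd, n_calls = s$n_calls)
}))
write_prov_csv(summ, "results/experiment_summary.csv", cfg$seed, cfg)
cat("per-level summaries written to results/experiment_summary.csv\n")
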