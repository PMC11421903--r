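fake_calls <- function(counts, prefix = "P") {
  ## counts: named vector class -> n calls; one caller per 5 calls
  do.call(rbind, lapply(names(counts), function(cl) {
    n <- counts[[cl]]
    tibble::tibble(call_id = sprintf("%s_%s_%04d", prefix, cl, seq_len(n)),
                   population = cl,
                   caller_id = sprintf("%s_%s_c%02d", prefix, cl,
                                       (seq_len(n) - 1) %/% 5 + 1))
  }))
}

test_that("balancing subsamples every class down to the smallest", {
  calls <- fake_calls(c(big = 938, small = 414))
  bal <- balance_by_subsampling(calls, "population", seed = 1)
  expect_equal(unname(table(bal$population)[c("big", "small")]),
               c(414, 414), ignore_attr = TRUE)
  ## already balanced: untouched counts; seeded: reproducible membership
  calls2 <- fake_calls(c(a = 50, b = 50))
  expect_equal(nrow(balance_by_subsampling(calls2, "population", 1)), 100)
  expect_identical(balance_by_subsampling(calls, "population", 7),
                   balance_by_subsampling(calls, "population", 7))
  expect_error(balance_by_subsampling(calls[calls$population == "big", ],
                                      "population", 1), "2 non-empty")
})

test_that("caller hold-out takes 20% of eligible callers per stratum", {
  ## 10 eligible callers of 5 calls each per stratum -> 2 held out
  calls <- fake_calls(c(p1 = 50, p2 = 50))
  plan <- split_holdout_callers(calls, seed = 3)
  held_by_pop <- table(sub("_c.*", "", plan$held_units))
  expect_equal(unname(held_by_pop), c(2, 2), ignore_attr = TRUE)
  expect_equal(length(plan$test), 2 * 2 * 5)
  ## 3 eligible -> max(1, round(0.6)) = 1 held out
  small <- fake_calls(c(q = 15))
  plan2 <- split_holdout_callers(small, group_by = "population", seed = 5)
  expect_length(plan2$held_units, 1)
  ## callers never span train and test
  tr_callers <- calls$caller_id[calls$call_id %in% plan$train]
  te_callers <- calls$caller_id[calls$call_id %in% plan$test]
  expect_length(intersect(tr_callers, te_callers), 0)
  ## ineligible callers' calls stay in training
  calls3 <- rbind(calls, tibble::tibble(call_id = "x1", population = "p1",
                                        caller_id = "rare"))
  plan3 <- split_holdout_callers(calls3, seed = 3)
  expect_true("x1" %in% plan3$train)
  expect_error(split_holdout_callers(tibble::tibble(
    call_id = "a", population = "p", caller_id = "c"), seed = 1),
    "no eligible")
})

test_that("core-group hold-out takes one core per eligible bond group", {
  ds <- meta_dataset(seed = 301)   # 3 bonds x 2 cores per population
  calls <- ds$calls[ds$calls$population == "P1", ]
  plan <- split_holdout_core_groups(calls, seed = 2)
  core_of <- setNames(calls$core, calls$call_id)
  expect_length(unique(core_of[plan$test]), 3)       # one core per bond
  expect_length(intersect(unique(core_of[plan$train]),
                          unique(core_of[plan$test])), 0)
  ## each bond keeps its other core in training
  bond_of <- setNames(calls$bond, calls$call_id)
  expect_setequal(unique(bond_of[plan$train]), unique(bond_of[plan$test]))
  ## bonds without two qualifying cores are excluded, not an error
  few <- calls[calls$core != unique(calls$core)[1], ]
  ## removing one core leaves its bond with a single core -> that bond drops
  kept <- eligible_bond_calls(few)
  expect_lt(length(unique(kept$bond)), length(unique(few$bond)) + 1)
})

test_that("date hold-out keeps every test caller in training on other dates", {
  ds <- meta_dataset(seed = 302)
  plan <- split_holdout_dates(ds$calls, seed = 4)
  d <- ds$calls
  key <- paste(d$caller_id, d$date)
  tr_keys <- key[d$call_id %in% plan$train]
  te_keys <- key[d$call_id %in% plan$test]
  expect_length(intersect(tr_keys, te_keys), 0)      # caller-dates disjoint
  te_callers <- unique(d$caller_id[d$call_id %in% plan$test])
  tr_callers <- unique(d$caller_id[d$call_id %in% plan$train])
  expect_true(all(te_callers %in% tr_callers))       # same callers, new dates
  ## a caller with a single date is excluded entirely
  one_date <- tibble::tibble(call_id = c("u1", "u2", "u3"),
                             caller_id = "solo",
                             date = as.Date("2021-01-01"))
  aug <- rbind(d[, c("call_id", "caller_id", "date")], one_date)
  plan2 <- split_holdout_dates(aug, seed = 4)
  expect_false(any(c("u1", "u2", "u3") %in% c(plan2$train, plan2$test)))
  ## caller with dates {3 calls, 4 calls}: test gets exactly one whole date
  two <- tibble::tibble(
    call_id = sprintf("t%d", 1:7), caller_id = "pair",
    date = as.Date("2021-01-01") + c(0, 0, 0, 1, 1, 1, 1))
  plan3 <- split_holdout_dates(rbind(d[, names(two)], two), seed = 9)
  got <- sum(two$call_id %in% plan3$test)
  expect_true(got %in% c(3, 4))
})

test_that("majority baseline follows the training majority, not 1/k", {
  expect_equal(majority_baseline(rep(c("A", "B"), c(6, 4)),
                                 rep(c("A", "B"), c(2, 3))), 0.4)
  expect_equal(majority_baseline(rep("A", 5), c("A", "A", "B")), 2 / 3)
  ## balanced two-class data can give a baseline above or below 0.5
  hi <- majority_baseline(rep(c("A", "B"), c(7, 3)), rep("A", 10))
  lo <- majority_baseline(rep(c("A", "B"), c(7, 3)), rep("B", 10))
  expect_gt(hi, 0.5); expect_lt(lo, 0.5)
  ## seeded tie-break is deterministic
  expect_equal(majority_baseline(c("A", "B"), c("A", "B"), seed = 42),
               majority_baseline(c("A", "B"), c("A", "B"), seed = 42))
})

test_that("exact binomial upper tail matches closed forms and binom.test", {
  expect_equal(exact_binomial_p(8, 10, 0.5), 0.0546875, tolerance = 1e-12)
  expect_equal(exact_binomial_p(0, 10, 0.5), 1)
  expect_equal(exact_binomial_p(7, 7, 0.3), 0.3^7, tolerance = 1e-12)
  expect_equal(exact_binomial_p(3, 10, 0), 0)
  expect_equal(exact_binomial_p(3, 10, 1), 1)
  ## dual route: agreement with stats::binom.test across a grid
  for (k in c(1, 5, 9)) for (p0 in c(0.2, 0.5, 0.8))
    expect_equal(exact_binomial_p(k, 10, p0),
                 binom.test(k, 10, p0, alternative = "greater")$p.value,
                 tolerance = 1e-12)
  ## monotone nonincreasing in k
  ps <- vapply(0:10, exact_binomial_p, 0, n = 10, p0 = 0.4)
  expect_true(all(diff(ps) <= 0))
})

test_that("experiments are deterministic given a seed and report coherent summaries", {
  ft <- tiny_features()
  calls <- tiny_dataset()$calls
  a <- run_experiment(ft, calls, "population", mel_feature_cols(ft),
                      n_iter = 3, seed = 11)
  b <- run_experiment(ft, calls, "population", mel_feature_cols(ft),
                      n_iter = 3, seed = 11)
  expect_identical(a$iterations, b$iterations)
  expect_true(all(a$iterations$accuracy >= 0 & a$iterations$accuracy <= 1))
  expect_equal(a$iterations$accuracy,
               a$iterations$n_correct / a$iterations$n_test)
  expect_equal(a$summary$median_accuracy, median(a$iterations$accuracy))
})

test_that("median p falls as the planted population effect grows", {
  med_p <- vapply(c(0, 4), function(sig) {
    cfg <- sim_config(callers_per_population = c(8, 8),
                      bond_groups_per_population = 1, core_groups_per_bond = 1,
                      calls_per_caller = 6, calls_dispersion = Inf,
                      ensure_min_dates = FALSE, sigma_pop_hz = sig,
                      sigma_bond_hz = 0, sigma_core_hz = 0, sigma_ind_hz = 0,
                      noise_sd_hz = 1, age_slope_hz_per_year = 0,
                      duration_mean_s = 2, duration_sd_s = 0.2, n_days = 5,
                      seed = 55)
    ds <- generate_dataset(cfg)
    ft <- extract_features(ds)
    run_experiment(ft, ds$calls, "population", mel_feature_cols(ft),
                   n_iter = 30, seed = 7)$summary$median_p
  }, 0)
  expect_lt(med_p[2], med_p[1])
  expect_lt(med_p[2], 0.05)
})

test_that("population logistic regression flags the shifted contour statistic", {
  sim_stats <- function(shift, n = 120, seed) {
    set.seed(seed)
    pops <- rep(c("A", "B"), each = n / 2)
    base <- matrix(rnorm(n * 9, mean = 30, sd = 2), n, 9)
    colnames(base) <- c("f1_mean", "f1_sd", "f1_skew", "f1_kurt", "f1_p10",
                        "f1_p90", "f1_at25", "f1_at50", "f1_at75")
    base[pops == "B", "f1_mean"] <- base[pops == "B", "f1_mean"] + shift
    d <- tibble::as_tibble(base)
    d$age_years <- runif(n, 10, 50)
    d$population <- pops
    d
  }
  hits <- vapply(1:20, function(s) {
    f <- fit_population_logistic(sim_stats(3, seed = s))
    f$deviance$p[f$deviance$term == "f1_mean"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  ## null: false-positive rate of an unrelated term stays near nominal
  null_hits <- vapply(1:100, function(s) {
    f <- fit_population_logistic(sim_stats(0, n = 80, seed = 1000 + s))
    f$deviance$p[f$deviance$term == "f1_p90"] < 0.05
  }, TRUE)
  expect_lt(mean(null_hits), 0.12)     # 5% nominal + 3 binomial s.e.
  ## perfectly ordered 1-D data is flagged as separated
  sep <- sim_stats(0, n = 60, seed = 5)
  sep$f1_mean <- ifelse(sep$population == "A", 1, 100) + rnorm(60, 0, 0.01)
  expect_warning(fit_population_logistic(sep), "separation")
  expect_true(suppressWarnings(fit_population_logistic(sep))$separation)
})
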