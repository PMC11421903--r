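#' Random-forest hyperparameters
#'
#' Defaults for the classification experiments: 500 trees, six variables per
#' node, 60% of observations per tree drawn without replacement, minimum node
#' size 1, no depth limit. Proximity forests raise `num_trees` to 8000.
#'
#' @param num_trees number of trees.
#' @param mtry variables tried per node.
#' @param sample_fraction per-tree observation fraction (without replacement).
#' @param min_node_size minimum terminal node size.
#' @export
forest_spec <- function(num_trees = 500, mtry = 6, sample_fraction = 0.6,
                        min_node_size = 1) {
  list(num_trees = num_trees, mtry = mtry, sample_fraction = sample_fraction,
       min_node_size = min_node_size)
}

fit_forest <- function(x, y, spec, seed) {
  ranger::ranger(x = as.data.frame(x), y = factor(y),
                 num.trees = spec$num_trees,
                 mtry = min(spec$mtry, ncol(x)),
                 sample.fraction = spec$sample_fraction,
                 replace = FALSE,
                 min.node.size = spec$min_node_size,
                 seed = seed, num.threads = 1)
}

#' Balance classes by randomly subsampling the larger ones
#'
#' Every class is subsampled (uniformly, without replacement) down to the
#' size of the smallest class.
#'
#' @param calls data frame of calls.
#' @param class_col name of the class-label column.
#' @param seed integer seed.
#' @return the balanced subset of `calls`.
#' @export
balance_by_subsampling <- function(calls, class_col, seed) {
  labs <- calls[[class_col]]
  counts <- table(labs)
  if (any(counts == 0) || length(counts) < 2)
    stop("balancing requires at least 2 non-empty classes")
  m <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(calls)), labs), function(ix)
      if (length(ix) > m) sort(sample(ix, m)) else ix))
  })
  calls[sort(keep), , drop = FALSE]
}

#' Hold out a fraction of callers per stratum (caller-level split)
#'
#' Within each stratum, `max(1, round(frac * n_eligible))` of the callers
#' with at least `min_calls` calls are held out; all their calls form the
#' test set and the remaining calls (including those of ineligible callers)
#' the training set. No caller spans train and test.
#'
#' @param calls data frame with `call_id`, `caller_id` and the stratum column.
#' @param frac fraction of eligible callers to hold out.
#' @param min_calls eligibility threshold (calls per caller within stratum).
#' @param group_by stratum column name (e.g. `"population"`, `"core"`).
#' @param seed integer seed.
#' @return list of class `split_plan`: `train`, `test` (call ids), `level`,
#'   `held_units`.
#' @export
split_holdout_callers <- function(calls, frac = 0.2, min_calls = 5,
                                  group_by = "population", seed) {
  held <- with_seed(seed, {
    unlist(lapply(split(calls, calls[[group_by]]), function(d) {
      tab <- table(d$caller_id)
      elig <- names(tab)[tab >= min_calls]
      if (!length(elig))
        stop("no eligible callers (>= ", min_calls, " calls) in stratum '",
             d[[group_by]][1], "'")
      k <- max(1, round(frac * length(elig)))
      sample(elig, k)
    }))
  })
  test <- calls$call_id[calls$caller_id %in% held]
  structure(list(train = setdiff(calls$call_id, test), test = test,
                 level = group_by, held_units = unname(held)),
            class = "split_plan")
}

#' Restrict calls to the bond-group experiment dataset
#'
#' Keeps core groups with at least `min_calls` calls inside bond groups that
#' contain at least two such core groups.
#'
#' @param calls data frame with `core` and `bond` columns.
#' @param min_calls per-core call threshold.
#' @return the eligible subset of `calls`.
#' @export
eligible_bond_calls <- function(calls, min_calls = 5) {
  core_n <- table(calls$core)
  big_cores <- names(core_n)[core_n >= min_calls]
  d <- calls[calls$core %in% big_cores, , drop = FALSE]
  cores_per_bond <- tapply(d$core, d$bond, function(x) length(unique(x)))
  elig_bonds <- names(cores_per_bond)[cores_per_bond >= 2]
  d[d$bond %in% elig_bonds, , drop = FALSE]
}

#' Hold out one core group per bond group (core-group-level split)
#'
#' Applies [eligible_bond_calls()] first; then, per eligible bond group,
#' one core group (uniformly at random) is held out and all its calls form
#' the test set. No core group spans train and test.
#'
#' @param calls data frame with `call_id`, `core`, `bond`.
#' @param min_calls per-core eligibility threshold.
#' @param seed integer seed.
#' @return a `split_plan` (over the eligible subset only).
#' @export
split_holdout_core_groups <- function(calls, min_calls = 5, seed) {
  d <- eligible_bond_calls(calls, min_calls)
  if (length(unique(d$bond)) < 2)
    stop("need at least 2 eligible bond groups")
  held <- with_seed(seed, {
    vapply(split(d, d$bond), function(b) sample(unique(b$core), 1),
           character(1))
  })
  test <- d$call_id[d$core %in% held]
  structure(list(train = setdiff(d$call_id, test), test = test,
                 level = "bond", held_units = unname(held)),
            class = "split_plan")
}

#' Hold out one recording date per caller (individual-level split)
#'
#' Only callers with at least `min_dates` dates carrying at least
#' `min_calls_per_date` calls each are included; other callers are excluded
#' from the experiment entirely. Per eligible caller one qualifying date is
#' held out: its calls form the test set, the caller's remaining calls the
#' training set, so every test caller also appears in train (on different
#' dates).
#'
#' @param calls data frame with `call_id`, `caller_id`, `date`.
#' @param min_calls_per_date calls needed for a date to qualify.
#' @param min_dates qualifying dates needed for a caller to be eligible.
#' @param seed integer seed.
#' @return a `split_plan` (over eligible callers only).
#' @export
split_holdout_dates <- function(calls, min_calls_per_date = 3, min_dates = 2,
                                seed) {
  by_caller <- split(calls, calls$caller_id)
  elig <- Filter(function(d) {
    sum(table(as.character(d$date)) >= min_calls_per_date) >= min_dates
  }, by_caller)
  if (length(elig) < 2) stop("fewer than 2 eligible callers for the date split")
  held <- with_seed(seed, {
    lapply(elig, function(d) {
      tab <- table(as.character(d$date))
      sample(names(tab)[tab >= min_calls_per_date], 1)
    })
  })
  test <- unlist(lapply(names(elig), function(cid) {
    d <- elig[[cid]]
    d$call_id[as.character(d$date) == held[[cid]]]
  }))
  pool <- unlist(lapply(elig, function(d) d$call_id))
  structure(list(train = setdiff(pool, test), test = test,
                 level = "individual",
                 held_units = paste(names(elig), unlist(held), sep = "@")),
            class = "split_plan")
}

#' Majority (zero-rate) classifier accuracy
#'
#' Fraction of test labels equal to the most common training label; ties in
#' the training set are broken uniformly at random under `seed`.
#'
#' @param train_labels,test_labels label vectors.
#' @param seed integer seed for tie-breaking.
#' @return accuracy in `[0, 1]`.
#' @export
majority_baseline <- function(train_labels, test_labels, seed = 1) {
  stopifnot(length(train_labels) > 0, length(test_labels) > 0)
  tab <- table(train_labels)
  top <- names(tab)[tab == max(tab)]
  maj <- if (length(top) > 1) with_seed(seed, sample(top, 1)) else top
  mean(as.character(test_labels) == maj)
}

#' One-tailed exact binomial test (upper tail)
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`.
#'
#' @param k_correct observed correct count.
#' @param n test-set size.
#' @param p0 null success probability.
#' @return the upper-tail p-value.
#' @export
exact_binomial_p <- function(k_correct, n, p0) {
  stopifnot(k_correct >= 0, k_correct <= n, p0 >= 0, p0 <= 1)
  if (k_correct == 0) return(1)
  pbinom(k_correct - 1, n, p0, lower.tail = FALSE)
}

#' Run one leakage-proof classification experiment
#'
#' Implements the repeated-split protocol at one of four levels:
#' \describe{
#'   \item{population}{balance by subsampling each iteration, then hold out
#'     20% of eligible callers per population.}
#'   \item{bond}{hold out one core group per eligible bond group.}
#'   \item{core}{restrict to core groups with >= 2 callers of >= `min_calls`
#'     calls; hold out 20% of eligible callers per core group.}
#'   \item{individual}{restrict to eligible callers; hold out one date per
#'     caller.}
#' }
#' Each iteration trains a random forest on the training calls, scores the
#' test calls, and records the accuracy, the majority-classifier baseline on
#' the same test set, and the one-tailed exact binomial p-value of the
#' correct count against that baseline. Summaries are medians over
#' iterations plus the mean and s.d. of the test-set fraction.
#'
#' @param features feature table (`call_id` + numeric columns).
#' @param calls call metadata (`call_id`, `caller_id`, `population`, `core`,
#'   `bond`, `date`).
#' @param level `"population"`, `"bond"`, `"core"` or `"individual"`.
#' @param feature_cols which feature columns to use (default: all numeric).
#' @param spec a [forest_spec()].
#' @param n_iter number of repeated splits.
#' @param seed integer root seed.
#' @param frac,min_calls caller-holdout parameters.
#' @return list of class `experiment_result`: `level`, `iterations` (tibble:
#'   accuracy, baseline, n_test, n_correct, p, test_frac), `summary` (list).
#' @export
run_experiment <- function(features, calls, level, feature_cols = NULL,
                           spec = forest_spec(), n_iter = 100, seed = 1,
                           frac = 0.2, min_calls = 5) {
  level <- match.arg(level, c("population", "bond", "core", "individual"))
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(features), "call_id")
  calls <- calls[calls$call_id %in% features$call_id, , drop = FALSE]

  response_col <- switch(level, population = "population", bond = "bond",
                         core = "core", individual = "caller_id")
  ## level-specific eligibility filtering of the experiment dataset
  base <- switch(level,
    population = {
      if (length(unique(calls$population)) < 2)
        stop("population experiment needs both populations present")
      calls
    },
    bond = {
      d <- eligible_bond_calls(calls, min_calls)
      if (length(unique(d$bond)) < 2)
        stop("bond experiment needs >= 2 eligible bond groups")
      d
    },
    core = {
      by_core <- split(calls, calls$core)
      keep <- vapply(by_core, function(d)
        sum(table(d$caller_id) >= min_calls) >= 2, logical(1))
      d <- do.call(rbind, by_core[keep])
      if (is.null(d) || length(unique(d$core)) < 2)
        stop("core experiment needs >= 2 eligible core groups")
      d
    },
    individual = {
      by_caller <- split(calls, calls$caller_id)
      keep <- vapply(by_caller, function(d)
        sum(table(as.character(d$date)) >= 3) >= 2, logical(1))
      d <- do.call(rbind, by_caller[keep])
      if (is.null(d) || length(unique(d$caller_id)) < 2)
        stop("individual experiment needs >= 2 eligible callers")
      d
    })

  fx <- as.data.frame(features[, feature_cols, drop = FALSE])
  rownames(fx) <- features$call_id

  iters <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    it_seed <- substream_seed(seed, paste0(level, "_iter", i))
    d <- base
    if (level == "population")
      d <- balance_by_subsampling(d, "population", it_seed)
    plan <- switch(level,
      population = split_holdout_callers(d, frac, min_calls, "population",
                                         it_seed),
      bond = split_holdout_core_groups(d, min_calls, it_seed),
      core = split_holdout_callers(d, frac, min_calls, "core", it_seed),
      individual = split_holdout_dates(d, seed = it_seed))
    y <- setNames(d[[response_col]], d$call_id)
    fit <- fit_forest(fx[plan$train, , drop = FALSE],
                      y[plan$train], spec, it_seed)
    pred <- predict(fit, fx[plan$test, , drop = FALSE],
                    num.threads = 1)$predictions
    truth_lab <- y[plan$test]
    n_test <- length(plan$test)
    n_correct <- sum(as.character(pred) == as.character(truth_lab))
    base_acc <- majority_baseline(y[plan$train], truth_lab, it_seed)
    iters[[i]] <- c(accuracy = n_correct / n_test,
                    baseline = base_acc,
                    n_test = n_test, n_correct = n_correct,
                    p = exact_binomial_p(n_correct, n_test, base_acc),
                    test_frac = n_test / nrow(d))
  }
  iterations <- tibble::as_tibble(do.call(rbind, iters))
  structure(list(
    level = level,
    iterations = iterations,
    summary = list(
      median_accuracy = median(iterations$accuracy),
      median_baseline = median(iterations$baseline),
      median_p = median(iterations$p),
      test_frac_mean = mean(iterations$test_frac),
      test_frac_sd = sd(iterations$test_frac),
      n_iter = n_iter, n_calls = nrow(base))),
    class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<experiment_result> level=%s  n_calls=%d  n_iter=%d\n  median accuracy %.3f vs baseline %.3f (median p = %.4g)\n  test fraction %.2f +/- %.2f\n",
    x$level, s$n_calls, s$n_iter, s$median_accuracy, s$median_baseline,
    s$median_p, s$test_frac_mean, s$test_frac_sd))
  invisible(x)
}

#' Logistic regression of population on contour statistics and age
#'
#' Fits `population ~ nine contour statistics + caller age` by logistic
#' regression and reports, per regressor, the likelihood-ratio chi-square and
#' p-value from single-term deletion (analysis of deviance). Perfect
#' separation is flagged rather than silently reported.
#'
#' @param stats_table data frame with the nine contour-statistic columns, an
#'   `age_years` column, and the binary `population` column.
#' @param population_col name of the response column.
#' @return list: `coefficients` (tibble), `deviance` (tibble: term,
#'   chisq, df, p), `separation` (logical), `fit` (the `glm`).
#' @export
fit_population_logistic <- function(stats_table,
                                    population_col = "population") {
  regressors <- c(contour_feature_cols(stats_table), "age_years")
  stopifnot(length(regressors) == 10)
  d <- stats_table
  d$.y <- factor(d[[population_col]])
  if (nlevels(d$.y) != 2) stop("population response must have 2 levels")
  form <- as.formula(paste(".y ~", paste(regressors, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  ## post-hoc separation check: fitted probabilities at the boundary
  if (any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8))
    sep <- TRUE
  dev <- suppressWarnings(drop1(fit, test = "LRT"))
  dev_tbl <- tibble::tibble(
    term = rownames(dev)[-1],
    chisq = dev$LRT[-1],
    df = dev$Df[-1],
    p = dev$`Pr(>Chi)`[-1])
  coefs <- tibble::tibble(term = names(coef(fit)),
                          coefficient = unname(coef(fit)))
  if (sep)
    warning("possible perfect separation: coefficients are unreliable")
  list(coefficients = coefs, deviance = dev_tbl, separation = sep, fit = fit)
}
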