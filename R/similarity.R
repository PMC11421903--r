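#' Proximity scores from a matrix of terminal-node assignments
#'
#' `score(i, j) = (1/T) * sum over trees of [leaf_t(i) == leaf_t(j)] /
#' size_t(leaf)`, where `size_t(leaf)` is the number of observations assigned
#' to that leaf -- co-occurrence in a small (more selective) node counts for
#' more than co-occurrence in a large one. Set `adjust = FALSE` for the
#' unadjusted proportion of shared leaves.
#'
#' @param nodes integer matrix, observations x trees, of terminal-node ids.
#' @param adjust divide each co-occurrence by the leaf size.
#' @return symmetric observations x observations matrix.
#' @export
proximity_from_nodes <- function(nodes, adjust = TRUE) {
  n <- nrow(nodes); T <- ncol(nodes)
  ## global leaf index across trees, so one sparse crossproduct does all trees
  glob <- as.integer(factor(paste(rep(seq_len(T), each = n), as.vector(nodes))))
  size <- tabulate(glob)
  w <- if (adjust) 1 / sqrt(size[glob]) else 1
  Z <- Matrix::sparseMatrix(i = rep(seq_len(n), T), j = glob, x = w)
  P <- as.matrix(Matrix::tcrossprod(Z)) / T
  dimnames(P) <- list(rownames(nodes), rownames(nodes))
  P
}

#' Random-forest proximity matrix over all calls
#'
#' Trains a forest (default 8000 trees, otherwise the experiment
#' hyperparameters) on *all* observations -- no balancing, no hold-out --
#' and scores every pair of calls by node-size-adjusted terminal-node
#' co-occurrence ([proximity_from_nodes()]).
#'
#' @param features feature table (`call_id` + numeric columns).
#' @param response named vector: class label per call id (the forest
#'   identity: which response the proximities are "about").
#' @param feature_cols feature columns to use (default all numeric).
#' @param spec a [forest_spec()]; default uses 8000 trees.
#' @param seed integer seed.
#' @param adjust node-size adjustment (see [proximity_from_nodes()]).
#' @return symmetric call x call matrix with attribute `response_name`.
#' @export
proximity_matrix <- function(features, response, feature_cols = NULL,
                             spec = forest_spec(num_trees = 8000),
                             seed = 1, adjust = TRUE) {
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(features), "call_id")
  ids <- features$call_id
  if (!all(ids %in% names(response)))
    stop("response labels missing for some calls in the feature table")
  fx <- as.data.frame(features[, feature_cols, drop = FALSE])
  fit <- fit_forest(fx, response[ids], spec, seed)
  nodes <- predict(fit, fx, type = "terminalNodes",
                   num.threads = 1)$predictions
  rownames(nodes) <- ids
  P <- proximity_from_nodes(nodes, adjust = adjust)
  attr(P, "response_name") <- deparse(substitute(response))
  P
}

#' Build the call-pair table for similarity regressions
#'
#' All unordered pairs of calls with the same behavioural context and
#' different callers (and, when a `context_certain` column is present, both
#' contexts certain). The response is the proximity score plus a 0.00001
#' offset so zero proximities remain admissible under a gamma model. The
#' absolute caller age difference is z-scored across the emitted table, and
#' each pair carries a caller-dyad id ("pair ID").
#'
#' @param calls call metadata (`call_id`, `caller_id`, `age_years`,
#'   `context`, plus the grouping columns the scheme needs).
#' @param prox proximity matrix from [proximity_matrix()].
#' @param scheme `"population"` (binary same/different population),
#'   `"tier3"` (same core / same bond, different core / different bonds),
#'   `"bond_binary"` or `"core_binary"`.
#' @param relatedness optional tibble (`id_a`, `id_b`, `relatedness`) of
#'   caller-dyad relatedness; pairs without a value are dropped.
#' @param offset added to every proximity score.
#' @return tibble of class `pair_table`: call ids, `dyad`, `pair_class`
#'   (factor, most-distant class as reference), `proximity`,
#'   `proximity_off`, `age_diff`, `age_diff_z`, `context`, optionally
#'   `relatedness`.
#' @export
build_pair_table <- function(calls, prox, scheme = "population",
                             relatedness = NULL, offset = 1e-5) {
  scheme <- match.arg(scheme, c("population", "tier3", "bond_binary",
                                "core_binary"))
  ids <- intersect(calls$call_id, rownames(prox))
  d <- calls[match(ids, calls$call_id), , drop = FALSE]
  n <- length(ids)
  if (n < 2) stop("need at least 2 calls with proximity scores")
  pr <- t(utils::combn(n, 2))
  i <- pr[, 1]; j <- pr[, 2]
  keep <- d$context[i] == d$context[j] & d$caller_id[i] != d$caller_id[j]
  if ("context_certain" %in% names(d))
    keep <- keep & d$context_certain[i] & d$context_certain[j]
  i <- i[keep]; j <- j[keep]
  if (!length(i)) stop("no call pairs survive the pairing filters")

  pair_class <- switch(scheme,
    population = factor(
      ifelse(d$population[i] == d$population[j],
             "same_population", "different_population"),
      levels = c("different_population", "same_population")),
    tier3 = factor(
      ifelse(d$core[i] == d$core[j], "same_core",
             ifelse(d$bond[i] == d$bond[j], "same_bond_diff_core",
                    "different_bond")),
      levels = c("different_bond", "same_bond_diff_core", "same_core")),
    bond_binary = factor(
      ifelse(d$bond[i] == d$bond[j], "same_bond", "different_bond"),
      levels = c("different_bond", "same_bond")),
    core_binary = factor(
      ifelse(d$core[i] == d$core[j], "same_core", "different_core"),
      levels = c("different_core", "same_core")))

  age_diff <- abs(d$age_years[i] - d$age_years[j])
  out <- tibble::tibble(
    call_a = ids[i], call_b = ids[j],
    dyad = paste(pmin(d$caller_id[i], d$caller_id[j]),
                 pmax(d$caller_id[i], d$caller_id[j]), sep = ":"),
    pair_class = pair_class,
    proximity = prox[cbind(i, j)],
    proximity_off = prox[cbind(i, j)] + offset,
    age_diff = age_diff,
    age_diff_z = if (sd(age_diff) > 0) as.numeric(scale(age_diff))
                 else age_diff - mean(age_diff),
    context = d$context[i])
  if (!is.null(relatedness)) {
    key <- paste(relatedness$id_a, relatedness$id_b, sep = ":")
    out$relatedness <- relatedness$relatedness[match(out$dyad, key)]
    out <- out[!is.na(out$relatedness), , drop = FALSE]
    if (!nrow(out)) stop("no pairs with relatedness data")
  }
  class(out) <- c("pair_table", class(out))
  out
}

## gamma log-link mixed model with a dyad random intercept; ML (Laplace)
fit_gamma_glmm <- function(formula, data) {
  fit <- glmmTMB::glmmTMB(formula, family = Gamma(link = "log"), data = data,
                          REML = FALSE)
  conv <- fit$fit$convergence
  pd <- isTRUE(fit$sdr$pdHess)
  if (conv != 0 || !pd)
    stop(sprintf(
      "gamma GLMM did not converge (optimizer code %d, pdHess = %s, %s)",
      conv, pd, fit$fit$message))
  fit
}

lrt_table <- function(full, data, response, fixed_terms, lrt_terms, re_term) {
  rows <- lapply(lrt_terms, function(tm) {
    reduced_terms <- setdiff(fixed_terms, tm)
    rhs <- paste(c(if (length(reduced_terms)) reduced_terms else "1", re_term),
                 collapse = " + ")
    red <- fit_gamma_glmm(as.formula(paste(response, "~", rhs)), data)
    chi <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
    df <- attr(logLik(full), "df") - attr(logLik(red), "df")
    tibble::tibble(term = tm, chisq = chi, df = df,
                   p = pchisq(chi, df, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

glmm_result <- function(fit, deviance_tbl, diag = list()) {
  fe <- glmmTMB::fixef(fit)$cond
  vc <- glmmTMB::VarCorr(fit)$cond
  re_sd <- if (length(vc)) attr(vc$dyad, "stddev")[[1]] else NA_real_
  structure(list(
    coefficients = tibble::tibble(term = names(fe), coefficient = unname(fe)),
    dyad_sd = unname(re_sd),
    logLik = as.numeric(logLik(fit)),
    deviance = deviance_tbl,
    diagnostics = diag,
    fit = fit), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("<glmm_fit> gamma / log link, dyad random intercept sd =",
      format(x$dyad_sd, digits = 3), "\n")
  print(x$coefficients)
  if (!is.null(x$deviance)) { cat("analysis of deviance:\n"); print(x$deviance) }
  invisible(x)
}

#' Gamma mixed model of call proximity on pair class and age difference
#'
#' `proximity + offset ~ pair class + scaled |age difference| + (1 | dyad)`,
#' gamma errors with a log link, fitted by maximum likelihood (Laplace
#' approximation over the dyad intercepts). The deviance table reports
#' single-term-deletion likelihood-ratio chi-squares.
#'
#' @param pairs a `pair_table`.
#' @param lrt_terms fixed terms to test by likelihood-ratio deletion
#'   (default: both).
#' @return a `glmm_fit`: coefficient table (log-link scale), dyad
#'   random-intercept s.d., log-likelihood, deviance table.
#' @export
fit_pairclass_glmm <- function(pairs,
                               lrt_terms = c("pair_class", "age_diff_z")) {
  if (nlevels(droplevels(pairs$pair_class)) < 2)
    stop("need at least 2 pair classes present")
  if (length(unique(pairs$dyad)) < 2) stop("need at least 2 distinct dyads")
  pairs <- droplevels(pairs)
  full <- fit_gamma_glmm(
    proximity_off ~ pair_class + age_diff_z + (1 | dyad), pairs)
  dev <- if (length(lrt_terms))
    lrt_table(full, pairs, "proximity_off", c("pair_class", "age_diff_z"),
              lrt_terms, "(1 | dyad)")
  glmm_result(full, dev)
}

#' Post hoc pairwise contrasts between the three pair classes
#'
#' Tukey-adjusted pairwise contrasts of the three-state pair-class factor on
#' the link (log) scale, via `emmeans`.
#'
#' @param glmm a `glmm_fit` from a three-state (`tier3`) [fit_pairclass_glmm()].
#' @return tibble: contrast, estimate, SE, z, adjusted p.
#' @export
pairwise_contrasts <- function(glmm) {
  mf <- glmm$fit$frame
  if (nlevels(mf$pair_class) != 3)
    stop("pairwise contrasts require the three-state pair-class fit")
  emm <- emmeans::emmeans(glmm$fit, "pair_class")
  ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  tibble::tibble(contrast = as.character(ct$contrast),
                 estimate = ct$estimate, se = ct$SE,
                 z = ct$estimate / ct$SE, p = ct$p.value)
}

#' Gamma mixed model separating social from genetic effects
#'
#' `proximity + offset ~ binary pair class + scaled |age difference| +
#' relatedness + (1 | dyad)`. Reports a collinearity diagnostic (the
#' correlation between the same-group indicator and relatedness) alongside
#' the usual deviance table.
#'
#' @param pairs a `pair_table` built with a binary scheme and `relatedness`.
#' @param lrt_terms fixed terms to test by likelihood-ratio deletion.
#' @return a `glmm_fit` with `diagnostics$class_relatedness_cor`.
#' @export
fit_relatedness_glmm <- function(pairs,
                                 lrt_terms = c("pair_class", "age_diff_z",
                                               "relatedness")) {
  if (!"relatedness" %in% names(pairs))
    stop("pair table has no relatedness column")
  if (sd(pairs$relatedness) == 0) stop("relatedness column is constant")
  if (nlevels(droplevels(pairs$pair_class)) != 2)
    stop("relatedness model requires a binary pair class")
  pairs <- droplevels(pairs)
  full <- fit_gamma_glmm(
    proximity_off ~ pair_class + age_diff_z + relatedness + (1 | dyad), pairs)
  dev <- if (length(lrt_terms))
    lrt_table(full, pairs, "proximity_off",
              c("pair_class", "age_diff_z", "relatedness"), lrt_terms,
              "(1 | dyad)")
  r <- cor(as.numeric(pairs$pair_class) - 1, pairs$relatedness)
  glmm_result(full, dev, diag = list(class_relatedness_cor = r))
}
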