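#' Run the complete analysis pipeline on a synthetic dataset
#'
#' Orchestrates simulate -> features -> social-tier inference -> the five
#' classification experiments -> proximity-score similarity models, writing
#' every declared output file (CSV tables with provenance headers, WAV audio)
#' under `out_dir` and returning the in-memory results.
#'
#' Stages and outputs:
#' \describe{
#'   \item{simulate}{`calls.csv`, `callers.csv`, `truth.csv`,
#'     `sightings.csv`, `relatedness.csv`, `wav/*.wav`.}
#'   \item{features}{`features.csv` (94 mel features + 9 contour stats per
#'     call).}
#'   \item{groups}{`association.csv`, `partition.csv` (inferred core/bond
#'     groups and matriarchs).}
#'   \item{classify}{`experiment_<level>.csv` per-iteration tables and
#'     `experiment_summary.csv` (median accuracy vs majority baseline and
#'     median exact-binomial p per level).}
#'   \item{similarity}{`pairs_<scheme>.csv`, `glmm_<model>.csv`,
#'     `contrasts.csv`.}
#' }
#'
#' @param config a [sim_config()]; `desk_config()` gives a fast complete run.
#' @param out_dir output directory.
#' @param n_iter iterations per classification experiment.
#' @param levels experiment levels to run.
#' @param min_sightings sighting threshold for tier inference.
#' @param num_trees trees per proximity forest (see [run_similarity()]).
#' @param force overwrite an existing non-empty `out_dir`.
#' @param wav write per-call WAV files.
#' @param quiet suppress stage log lines.
#' @return list of class `rumble_pipeline`: `dataset`, `features`,
#'   `partition`, `experiments`, `similarity`, `out_dir`.
#' @export
run_pipeline <- function(config = desk_config(), out_dir,
                         n_iter = 300,
                         levels = c("population", "population_f1", "bond",
                                    "core", "individual"),
                         min_sightings = 20, num_trees = 8000, force = FALSE,
                         wav = TRUE, quiet = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory ", out_dir,
         " is not empty; pass force = TRUE to overwrite")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  say <- function(stage, fmt, ...) {
    if (!quiet)
      message(sprintf("[%s] (seed %d) %s", stage, seed, sprintf(fmt, ...)))
  }
  t0 <- Sys.time()

  ## --- simulate -------------------------------------------------------
  dataset <- generate_dataset(config)
  write_dataset(dataset, out_dir, wav = wav)
  say("simulate", "%d callers, %d calls, %d core groups in %d bond groups",
      nrow(dataset$truth$callers), nrow(dataset$calls),
      length(unique(dataset$truth$callers$core)),
      length(unique(dataset$truth$callers$bond)))

  ## --- features -------------------------------------------------------
  features <- extract_features(dataset)
  write_prov_csv(features, file.path(out_dir, "features.csv"), seed, config)
  say("features", "%d calls x %d features", nrow(features),
      ncol(features) - 1)

  ## --- social tiers ---------------------------------------------------
  ages <- setNames(dataset$truth$callers$age_years,
                   dataset$truth$callers$caller_id)
  assoc <- association_matrix(dataset$sightings, min_sightings)
  amat <- as.data.frame(assoc$index)
  amat <- cbind(id = assoc$ids, amat)
  write_prov_csv(amat, file.path(out_dir, "association.csv"), seed, config)
  partition <- infer_tiers(dataset$sightings, ages, min_sightings)
  write_prov_csv(partition$members, file.path(out_dir, "partition.csv"),
                 seed, config)
  say("groups", "%d core groups, %d bond groups (cut heights %.3f / %.3f)",
      length(unique(partition$members$core)),
      length(unique(partition$members$bond)),
      partition$core_cut_height, partition$bond_cut_height)

  ## --- classification experiments ------------------------------------
  calls <- dataset$calls
  mel_cols <- mel_feature_cols(features)
  f1_cols <- contour_feature_cols(features)
  main_pop <- names(sort(table(calls$population), decreasing = TRUE))[1]
  pop_calls <- calls[calls$population == main_pop, , drop = FALSE]
  experiments <- list()
  for (lv in levels) {
    res <- switch(lv,
      population = run_experiment(features, calls, "population",
                                  mel_cols, n_iter = n_iter, seed = seed),
      population_f1 = run_experiment(features, calls, "population",
                                     f1_cols, n_iter = n_iter, seed = seed + 1),
      bond = run_experiment(features, pop_calls, "bond", mel_cols,
                            n_iter = n_iter, seed = seed),
      core = run_experiment(features, pop_calls, "core", mel_cols,
                            n_iter = n_iter, seed = seed),
      individual = run_experiment(features, calls, "individual", mel_cols,
                                  n_iter = n_iter, seed = seed))
    experiments[[lv]] <- res
    write_prov_csv(res$iterations,
                   file.path(out_dir, sprintf("experiment_%s.csv", lv)),
                   seed, config)
    say("classify", "%s: median accuracy %.3f vs baseline %.3f (p %.4g)",
        lv, res$summary$median_accuracy, res$summary$median_baseline,
        res$summary$median_p)
  }
  summ <- tibble::as_tibble(do.call(rbind, lapply(names(experiments),
    function(lv) {
      s <- experiments[[lv]]$summary
      data.frame(level = lv, median_accuracy = s$median_accuracy,
                 median_baseline = s$median_baseline, median_p = s$median_p,
                 test_frac_mean = s$test_frac_mean,
                 test_frac_sd = s$test_frac_sd, n_calls = s$n_calls)
    })))
  write_prov_csv(summ, file.path(out_dir, "experiment_summary.csv"),
                 seed, config)

  ## --- similarity -----------------------------------------------------
  similarity <- run_similarity(dataset, features, num_trees = num_trees,
                               out_dir = out_dir, quiet = quiet)

  say("all", "pipeline finished in %.1f s",
      as.numeric(Sys.time() - t0, units = "secs"))
  structure(list(dataset = dataset, features = features,
                 partition = partition, experiments = experiments,
                 summary = summ, similarity = similarity, out_dir = out_dir),
            class = "rumble_pipeline")
}

#' Proximity-score similarity analyses for a dataset
#'
#' Builds full-data proximity forests (population and core-group responses),
#' the filtered pair tables, the pair-class gamma mixed models with post hoc
#' contrasts, and the social-vs-genetic relatedness model.
#'
#' @param dataset a `rumble_dataset`.
#' @param features its feature table.
#' @param num_trees trees per proximity forest.
#' @param out_dir optional directory for `pairs_*.csv`, `glmm_*.csv`,
#'   `contrasts.csv`.
#' @param quiet suppress log lines.
#' @return list: `pop_glmm`, `tier_glmm`, `contrasts`, `relatedness_glmm`,
#'   `pairs` (list of pair tables).
#' @export
run_similarity <- function(dataset, features, num_trees = 8000,
                           out_dir = NULL, quiet = FALSE) {
  config <- dataset$config
  seed <- config$seed
  calls <- dataset$calls
  mel_cols <- mel_feature_cols(features)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[similarity] (seed %d) %s", seed,
                                sprintf(fmt, ...)))
  }
  spec <- forest_spec(num_trees = num_trees)
  meta <- calls[match(features$call_id, calls$call_id), , drop = FALSE]

  ## population forest over everything
  pop_resp <- setNames(meta$population, meta$call_id)
  prox_pop <- proximity_matrix(features, pop_resp, mel_cols, spec,
                               seed = substream_seed(seed, "prox_pop"))
  pairs_pop <- build_pair_table(meta, prox_pop, "population")
  pop_glmm <- fit_pairclass_glmm(pairs_pop)
  say("population pairs: %d; pair-class coef %.3f", nrow(pairs_pop),
      pop_glmm$coefficients$coefficient[2])

  ## core-group forest within the most-sampled population
  main_pop <- names(sort(table(meta$population), decreasing = TRUE))[1]
  sub <- meta[meta$population == main_pop, , drop = FALSE]
  sub_feat <- features[features$call_id %in% sub$call_id, , drop = FALSE]
  core_resp <- setNames(sub$core, sub$call_id)
  prox_core <- proximity_matrix(sub_feat, core_resp, mel_cols, spec,
                                seed = substream_seed(seed, "prox_core"))
  pairs_tier <- build_pair_table(sub, prox_core, "tier3")
  tier_glmm <- fit_pairclass_glmm(pairs_tier)
  contrasts <- pairwise_contrasts(tier_glmm)
  say("tier pairs: %d; same-core coef %.3f", nrow(pairs_tier),
      tier_glmm$coefficients$coefficient[
        match("pair_classsame_core", tier_glmm$coefficients$term)])

  ## social vs genetic: binary core-group class + relatedness
  pairs_rel <- build_pair_table(sub, prox_core, "core_binary",
                                relatedness = dataset$relatedness)
  rel_glmm <- fit_relatedness_glmm(pairs_rel)
  say("relatedness pairs: %d; group coef %.3f, relatedness coef %.3f",
      nrow(pairs_rel), rel_glmm$coefficients$coefficient[2],
      rel_glmm$coefficients$coefficient[4])

  if (!is.null(out_dir)) {
    write_prov_csv(pairs_pop, file.path(out_dir, "pairs_population.csv"),
                   seed, config)
    write_prov_csv(pairs_tier, file.path(out_dir, "pairs_tier3.csv"),
                   seed, config)
    write_prov_csv(pairs_rel, file.path(out_dir, "pairs_core_binary.csv"),
                   seed, config)
    glmm_csv <- function(g, name) {
      tab <- merge(g$coefficients,
                   g$deviance, by = "term", all = TRUE)
      tab$dyad_sd <- g$dyad_sd
      write_prov_csv(tab, file.path(out_dir, sprintf("glmm_%s.csv", name)),
                     seed, config)
    }
    glmm_csv(pop_glmm, "population")
    glmm_csv(tier_glmm, "tier3")
    glmm_csv(rel_glmm, "relatedness")
    write_prov_csv(contrasts, file.path(out_dir, "contrasts.csv"),
                   seed, config)
  }
  list(pop_glmm = pop_glmm, tier_glmm = tier_glmm, contrasts = contrasts,
       relatedness_glmm = rel_glmm,
       pairs = list(population = pairs_pop, tier3 = pairs_tier,
                    core_binary = pairs_rel))
}
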