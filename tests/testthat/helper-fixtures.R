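## shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

## small complete dataset with audio: 2 bonds x 2 cores x 2 callers per
## population, 6 calls each -- enough structure for every analysis level
tiny_dataset <- function() cached("tiny", {
  generate_dataset(desk_config(callers_per_population = c(8, 8),
                               bond_groups_per_population = 2,
                               calls_per_caller = 6, seed = 101))
})

tiny_features <- function() cached("tiny_features", {
  extract_features(tiny_dataset())
})

## metadata-only dataset for split/leakage tests (no audio synthesis)
meta_dataset <- function(seed = 202, ...) {
  generate_dataset(desk_config(callers_per_population = c(10, 10),
                               calls_per_caller = 8, seed = seed, ...),
                   waveforms = FALSE)
}

## independent terminal-node oracle: walk each ranger tree via treeInfo
oracle_terminal_nodes <- function(fit, data) {
  out <- matrix(0L, nrow(data), fit$num.trees)
  for (tr in seq_len(fit$num.trees)) {
    ti <- ranger::treeInfo(fit, tr)
    for (i in seq_len(nrow(data))) {
      node <- 0L
      repeat {
        row <- ti[ti$nodeID == node, ]
        if (row$terminal) break
        node <- if (data[[row$splitvarName]][i] <= row$splitval)
          row$leftChild else row$rightChild
      }
      out[i, tr] <- node
    }
  }
  rownames(out) <- rownames(data)
  out
}

## brute-force proximity from a node matrix: explicit double loop over pairs
oracle_proximity <- function(nodes) {
  n <- nrow(nodes); T <- ncol(nodes)
  P <- matrix(0, n, n)
  for (tr in seq_len(T)) {
    size <- table(nodes[, tr])
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (nodes[i, tr] == nodes[j, tr])
        P[i, j] <- P[i, j] + 1 / size[[as.character(nodes[i, tr])]]
    }
  }
  P / T
}

## gamma-dyad pair simulator: proximity ~ Gamma(log link), dyad intercepts
simulate_pair_data <- function(n_pairs, n_dyads, class_effect,
                               rel_effect = 0, age_effect = 0,
                               dyad_sd = 0.5, shape = 2, intercept = -4,
                               seed = 1) {
  set.seed(seed)
  dyad <- sample(n_dyads, n_pairs, replace = TRUE)
  u <- rnorm(n_dyads, 0, dyad_sd)
  cls_dyad <- rbinom(n_dyads, 1, 0.5)          # pair class is a dyad property
  rel_dyad <- rnorm(n_dyads, 0.1, 0.15)
  age_dyad <- rnorm(n_dyads)
  mu <- exp(intercept + class_effect * cls_dyad[dyad] +
              rel_effect * rel_dyad[dyad] + age_effect * age_dyad[dyad] +
              u[dyad])
  y <- rgamma(n_pairs, shape = shape, rate = shape / mu)
  cls <- factor(ifelse(cls_dyad[dyad] == 1, "same", "different"),
                levels = c("different", "same"))
  structure(tibble::tibble(
    call_a = sprintf("a%05d", seq_len(n_pairs)),
    call_b = sprintf("b%05d", seq_len(n_pairs)),
    dyad_idx = dyad,
    dyad = sprintf("d%03d", dyad_idx),
    pair_class = cls,
    proximity = y, proximity_off = y + 1e-5,
    age_diff = age_dyad[dyad_idx], age_diff_z = age_dyad[dyad_idx],
    relatedness = rel_dyad[dyad_idx], context = "contact"),
    class = c("pair_table", class(tibble::tibble())))
}

## planted-partition sightings for tier-recovery tests
planted_sightings <- function(seed, p_within = 0.9, p_bond = 0.3,
                              p_cross = 0.02, n_days = 60, p_detect = 1) {
  cfg <- sim_config(n_populations = 1, callers_per_population = 24,
                    bond_groups_per_population = 3, core_groups_per_bond = 2,
                    n_days = n_days, p_within = p_within, p_bond = p_bond,
                    p_cross = p_cross, p_detect = p_detect, seed = seed)
  truth <- generate_ground_truth(cfg)
  list(truth = truth, sightings = generate_sightings(truth, cfg),
       ages = setNames(truth$callers$age_years, truth$callers$caller_id))
}
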