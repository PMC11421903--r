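test_that("dataset counts, nesting and age bounds match the configuration", {
  cfg <- sim_config(n_populations = 2, callers_per_population = 4,
                    bond_groups_per_population = 1, core_groups_per_bond = 2,
                    calls_per_caller = 5, calls_dispersion = Inf,
                    ensure_min_dates = FALSE, n_days = 10, seed = 3)
  ds <- generate_dataset(cfg, waveforms = FALSE)
  expect_equal(nrow(ds$calls), 40)                # 2 pops x 4 callers x 5 calls
  expect_equal(nrow(ds$truth$callers), 8)
  expect_true(all(table(ds$calls$caller_id) == 5))
  cal <- ds$truth$callers
  expect_true(all(cal$age_years >= 10))
  ## nesting: each caller one core; cores nest in bonds; bonds in populations
  expect_equal(anyDuplicated(cal$caller_id), 0)
  core_map <- unique(cal[, c("core", "bond", "population")])
  expect_equal(anyDuplicated(core_map$core), 0)
  bond_map <- unique(core_map[, c("bond", "population")])
  expect_equal(anyDuplicated(bond_map$bond), 0)
  ## matriarch is the oldest member of her core group
  for (k in split(cal, cal$core)) {
    m <- k[k$caller_id %in% ds$truth$matriarchs, ]
    expect_equal(max(k$age_years), m$age_years)
  }
})

test_that("planted f1 means collapse to one value per context when all effects vanish", {
  cfg <- sim_config(callers_per_population = c(4, 4),
                    bond_groups_per_population = 1, core_groups_per_bond = 1,
                    sigma_pop_hz = 0, sigma_bond_hz = 0, sigma_core_hz = 0,
                    sigma_ind_hz = 0, noise_sd_hz = 0,
                    age_slope_hz_per_year = 0, n_days = 5, seed = 8)
  ds <- generate_dataset(cfg, waveforms = FALSE)
  per_ctx <- tapply(ds$calls$f1_true_hz, ds$calls$context,
                    function(x) length(unique(round(x, 10))))
  expect_true(all(per_ctx == 1))
})

test_that("identical seeds reproduce metadata, waveforms, sightings and relatedness", {
  cfg <- desk_config(callers_per_population = c(3, 3), calls_per_caller = 4,
                     n_days = 10, seed = 77)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$calls, b$calls)
  expect_identical(a$waveforms, b$waveforms)
  expect_identical(a$sightings, b$sightings)
  expect_identical(a$relatedness, b$relatedness)
})

test_that("synthesized calls place their spectral ridge at f1/2 and f1", {
  fs <- 2000
  w <- synthesize_call(30, "flat", 2, fs, snr_db = 40, seed = 1)
  expect_length(w, 4000)
  ## peak-pick oracle on the generated signal: top two FFT magnitudes
  mag <- Mod(fft(as.numeric(w)))[1:2000]
  freq <- (0:1999) * fs / 4000
  top2 <- sort(freq[order(mag, decreasing = TRUE)[1:2]])
  expect_lt(abs(top2[1] - 15), fs / 4000 + 1e-9)   # within one FFT bin
  expect_lt(abs(top2[2] - 30), fs / 4000 + 1e-9)
  expect_error(synthesize_call(30, "flat", 0, fs), "duration")
  expect_error(synthesize_call(300, "flat", 1, fs), "too high")
})

test_that("sighting parties respect the configured tier probabilities", {
  ## p_within = 1, p_bond = p_cross = 0: every core group one intact unit
  cfg <- sim_config(n_populations = 1, callers_per_population = 12,
                    bond_groups_per_population = 2, core_groups_per_bond = 2,
                    p_within = 1, p_bond = 0, p_cross = 0, p_detect = 1,
                    n_days = 15, seed = 5)
  tr <- generate_ground_truth(cfg)
  sg <- generate_sightings(tr, cfg)
  core_of <- setNames(tr$callers$core, tr$callers$caller_id)
  sizes <- table(core_of)
  for (ids in sg$ids) {
    expect_equal(length(unique(core_of[ids])), 1)     # one core per party
    expect_equal(length(ids), sizes[[unique(core_of[ids])]])  # intact
  }
  ## no individual twice in one row
  expect_true(all(vapply(sg$ids, anyDuplicated, 0) == 0))
  ## n_days = 0: empty table
  cfg0 <- sim_config(n_days = 0, callers_per_population = c(3, 3), seed = 1)
  expect_equal(nrow(generate_sightings(generate_ground_truth(cfg0), cfg0)), 0)
})

test_that("equal tier probabilities equalise association indices across tiers", {
  cfg <- sim_config(n_populations = 1, callers_per_population = 12,
                    bond_groups_per_population = 2, core_groups_per_bond = 2,
                    n_days = 400, p_within = 0.4, p_bond = 0.4, p_cross = 0.4,
                    p_detect = 0.9, seed = 9)
  tr <- generate_ground_truth(cfg)
  am <- association_matrix(generate_sightings(tr, cfg), min_sightings = 20)
  cal <- tr$callers
  idx <- am$index[cal$caller_id, cal$caller_id]
  off <- upper.tri(idx)
  same_core <- outer(cal$core, cal$core, "==")
  same_bond <- outer(cal$bond, cal$bond, "==")
  w <- idx[same_core & off]
  b <- idx[!same_core & same_bond & off]
  x <- idx[!same_bond & off]
  se2 <- function(u, v) sqrt(sd(u)^2 / length(u) + sd(v)^2 / length(v))
  expect_lt(abs(mean(w) - mean(b)), 3 * se2(w, b))
  expect_lt(abs(mean(b) - mean(x)), 3 * se2(b, x))
})

test_that("relatedness reflects group structure only when dyads are coupled", {
  cfg0 <- sim_config(n_populations = 1, callers_per_population = 40,
                     rel_decouple = 0, rel_mean_within = 0.25,
                     rel_mean_cross = 0, n_days = 5, seed = 4)
  tr <- generate_ground_truth(cfg0)
  rel0 <- generate_relatedness(tr, cfg0)
  core_of <- setNames(tr$callers$core, tr$callers$caller_id)
  same <- core_of[rel0$id_a] == core_of[rel0$id_b]
  expect_lt(abs(mean(rel0$relatedness[same]) - 0.25), 0.03)
  expect_lt(abs(mean(rel0$relatedness[!same]) - 0), 0.02)
  expect_gt(mean(rel0$relatedness[same]), mean(rel0$relatedness[!same]))
  ## decoupling 1: relatedness independent of co-membership
  cfg1 <- sim_config(n_populations = 1, callers_per_population = 40,
                     rel_decouple = 1, n_days = 5, seed = 4)
  rel1 <- generate_relatedness(tr, cfg1)
  expect_gte(nrow(rel1), 500)
  expect_lt(abs(cor(as.numeric(same), rel1$relatedness)), 0.1)
  ## symmetry convention and self-exclusion
  expect_true(all(rel1$id_a < rel1$id_b))
  ## single caller: empty table
  cfg2 <- sim_config(n_populations = 1, callers_per_population = 1,
                     bond_groups_per_population = 1, core_groups_per_bond = 1,
                     n_days = 5, seed = 1)
  expect_equal(nrow(generate_relatedness(generate_ground_truth(cfg2), cfg2)), 0)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(p_within = 1.2), "p_within")
  expect_error(sim_config(contexts = letters[1:5]), "contexts")
  expect_error(sim_config(sample_rate_hz = 500), "sample_rate_hz")
  expect_error(sim_config(p_within = 0.1, p_bond = 0.5, p_cross = 0),
               "p_within")
  expect_error(sim_config(noise_sd_hz = -1), "noise_sd_hz")
})

test_that("datasets round-trip through the CSV/WAV writer", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  write_dataset(ds, dir, wav = TRUE)
  for (f in c("calls.csv", "callers.csv", "truth.csv", "sightings.csv",
              "relatedness.csv"))
    expect_true(file.exists(file.path(dir, f)))
  ## provenance header present and skipped on read
  first <- readLines(file.path(dir, "calls.csv"), n = 1)
  expect_match(first, "^# rumblesig seed=")
  calls <- read_prov_csv(file.path(dir, "calls.csv"))
  expect_equal(nrow(calls), nrow(ds$calls))
  ## one WAV per call, PCM round-trip close to the original
  id <- ds$calls$call_id[1]
  wv <- read_wav(file.path(dir, "wav", paste0(id, ".wav")))
  expect_equal(wv$sample_rate_hz, ds$config$sample_rate_hz)
  expect_equal(length(wv$samples), length(ds$waveforms[[id]]))
  expect_lt(max(abs(wv$samples - ds$waveforms[[id]])), 1e-4)
})
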