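#' Default behavioural-context labels
#'
#' Nine context categories shared across both simulated populations, loosely
#' modelled on the behavioural situations in which female elephants rumble.
#' @export
default_contexts <- function() {
  c("contact", "greeting", "departure", "dominance", "affiliative",
    "mate_attraction", "calf_reassurance", "movement", "alarm")
}

#' Simulation configuration for synthetic rumble datasets
#'
#' Defaults mirror the scale of the study system the package emulates: two
#' allopatric populations of 81 and 21 adult-female callers, hierarchically
#' nested core and bond groups, caller ages around 26 +/- 12 years (adults,
#' 10+), and low-frequency harmonic calls whose second-harmonic (f1) contour
#' carries additive population, bond-group, core-group, individual and age
#' offsets.
#'
#' @param n_populations number of populations.
#' @param callers_per_population integer vector (recycled) of adult-female
#'   callers per population.
#' @param bond_groups_per_population bond groups in each population.
#' @param core_groups_per_bond core groups nested in each bond group.
#' @param calls_per_caller mean calls per caller (negative-binomial, see
#'   `calls_dispersion`).
#' @param calls_dispersion negative-binomial size parameter; larger = less
#'   overdispersed; `Inf` gives every caller exactly
#'   `round(calls_per_caller)` calls.
#' @param contexts exactly nine behavioural-context labels.
#' @param age_mean_years,age_sd_years,age_min_years truncated-normal age
#'   distribution (adult females only).
#' @param base_f1_hz grand-mean second-harmonic frequency (Hz).
#' @param context_spread_hz half-range of per-context shifts of the f1 mean.
#' @param sigma_pop_hz between-population span of f1 offsets (Hz): with two
#'   populations they sit at -/+ `sigma_pop_hz / 2`.
#' @param sigma_bond_hz,sigma_core_hz,sigma_ind_hz s.d. of the normal
#'   bond-group / core-group / individual f1 offsets (Hz).
#' @param age_slope_hz_per_year linear effect of caller age on the f1 mean.
#' @param noise_sd_hz call-level s.d. of the planted f1 mean (Hz).
#' @param duration_mean_s,duration_sd_s,duration_min_s call duration (s);
#'   context shifts the mean deterministically.
#' @param context_duration_spread_s half-range of per-context duration shifts.
#' @param sample_rate_hz audio sampling rate (>= 2000 Hz).
#' @param snr_db signal-to-noise ratio of synthesized calls (dB).
#' @param n_days days of sighting effort.
#' @param p_within,p_bond,p_cross per-day co-sighting (edge) probabilities for
#'   within-core, cross-core-within-bond and cross-bond dyads; must satisfy
#'   `p_within >= p_bond >= p_cross`.
#' @param p_detect per-day detection probability of each individual.
#' @param rel_mean_within,rel_mean_cross mean genetic relatedness of same-core
#'   vs other dyads.
#' @param rel_sd s.d. of relatedness noise.
#' @param rel_decouple fraction of dyads whose relatedness is drawn
#'   independently of group membership (social disruption).
#' @param ensure_min_dates if TRUE every caller gets at least two dates with
#'   at least three calls each, so all callers qualify for the individual-ID
#'   experiment.
#' @param start_date first possible recording/sighting date.
#' @param seed integer root seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 2,
                       callers_per_population = c(81, 21),
                       bond_groups_per_population = 3,
                       core_groups_per_bond = 2,
                       calls_per_caller = 12,
                       calls_dispersion = 4,
                       contexts = default_contexts(),
                       age_mean_years = 26,
                       age_sd_years = 12,
                       age_min_years = 10,
                       base_f1_hz = 30,
                       context_spread_hz = 3,
                       sigma_pop_hz = 3,
                       sigma_bond_hz = 0.5,
                       sigma_core_hz = 1,
                       sigma_ind_hz = 2,
                       age_slope_hz_per_year = -0.05,
                       noise_sd_hz = 1.5,
                       duration_mean_s = 3,
                       duration_sd_s = 0.8,
                       duration_min_s = 1,
                       context_duration_spread_s = 0.8,
                       sample_rate_hz = 2000,
                       snr_db = 20,
                       n_days = 120,
                       p_within = 0.9,
                       p_bond = 0.25,
                       p_cross = 0.02,
                       p_detect = 0.9,
                       rel_mean_within = 0.25,
                       rel_mean_cross = 0,
                       rel_sd = 0.1,
                       rel_decouple = 0.5,
                       ensure_min_dates = TRUE,
                       start_date = as.Date("2021-01-01"),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$callers_per_population <-
    rep_len(callers_per_population, n_populations)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  chk(cfg$n_populations >= 1, "n_populations", "must be >= 1")
  chk(all(cfg$callers_per_population >= 1), "callers_per_population",
      "every population needs at least one caller")
  chk(cfg$bond_groups_per_population >= 1, "bond_groups_per_population", ">= 1")
  chk(cfg$core_groups_per_bond >= 1, "core_groups_per_bond", ">= 1")
  chk(length(cfg$contexts) == 9, "contexts", "exactly 9 context labels required")
  chk(!anyDuplicated(cfg$contexts), "contexts", "labels must be unique")
  for (f in c("p_within", "p_bond", "p_cross", "p_detect", "rel_decouple"))
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "probability must lie in [0, 1]")
  chk(cfg$p_within >= cfg$p_bond && cfg$p_bond >= cfg$p_cross, "p_within",
      "need p_within >= p_bond >= p_cross")
  for (f in c("age_sd_years", "sigma_pop_hz", "sigma_bond_hz", "sigma_core_hz",
              "sigma_ind_hz", "noise_sd_hz", "duration_sd_s", "rel_sd"))
    chk(cfg[[f]] >= 0, f, "s.d. must be >= 0")
  chk(cfg$sample_rate_hz >= 2000, "sample_rate_hz", "must be >= 2000 Hz")
  chk(cfg$n_days >= 0, "n_days", "must be >= 0")
  chk(cfg$duration_mean_s > 0, "duration_mean_s", "must be > 0")
  chk(cfg$calls_per_caller >= 1, "calls_per_caller", "must be >= 1")
  invisible(cfg)
}

#' A small "desk-scale" configuration for fast complete runs
#'
#' Two populations of 12 callers each, 3 bond groups of 2 core groups per
#' population, 8 calls per caller. Every downstream stage (tier inference,
#' all five classification experiments, similarity models) is exercisable in
#' minutes on one CPU.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
desk_config <- function(...) {
  args <- list(callers_per_population = c(12, 12),
               bond_groups_per_population = 3,
               core_groups_per_bond = 2,
               calls_per_caller = 8,
               duration_mean_s = 2,
               duration_sd_s = 0.4,
               n_days = 60)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
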