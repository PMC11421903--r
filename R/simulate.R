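#' Synthesize one rumble-like harmonic call
#'
#' The waveform is an additive harmonic stack on a fundamental at
#' `f1_mean_hz / 2`: the second harmonic is the target of downstream contour
#' tracing. Harmonic amplitudes decay as 1/k for k >= 2 while the fundamental
#' is attenuated to 0.4, so the second harmonic is the dominant partial --
#' rumble spectra concentrate energy above the fundamental, which is why the
#' second harmonic is the standard traced contour. A raised-cosine fade
#' (50 ms) shapes the onset/offset and white Gaussian noise is added at the
#' configured SNR.
#'
#' @param f1_mean_hz mean second-harmonic frequency (Hz); must be below an
#'   eighth of the sampling rate so at least four harmonics fit below Nyquist.
#' @param contour_shape one of `"flat"`, `"rise"`, `"fall"`, `"arch"`.
#' @param duration_s call duration in seconds (> 0).
#' @param sample_rate_hz sampling rate (Hz).
#' @param snr_db signal-to-noise ratio in dB; `Inf` = noiseless, `-Inf` = pure
#'   noise (no harmonic component at all).
#' @param seed integer seed for the noise.
#' @param depth relative modulation depth of the contour (0.15 = +/-15%).
#' @param n_harmonics number of harmonics (>= 4).
#' @param fade_s raised-cosine fade duration (s).
#' @return numeric waveform scaled to `[-0.9, 0.9]`, with attributes
#'   `sample_rate_hz` and `f1_mean_hz`.
#' @export
synthesize_call <- function(f1_mean_hz, contour_shape = "flat", duration_s,
                            sample_rate_hz = 2000, snr_db = 20, seed = NULL,
                            depth = 0.15, n_harmonics = 5, fade_s = 0.05) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0")
  if (f1_mean_hz >= sample_rate_hz / 8)
    stop("f1_mean_hz too high for sample rate: need f1 < sample_rate/8 ",
         "so at least four harmonics fit below Nyquist")
  contour_shape <- match.arg(contour_shape, c("flat", "rise", "fall", "arch"))
  n <- round(duration_s * sample_rate_hz)
  u <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  mult <- switch(contour_shape,
    flat = rep(1, n),
    rise = 1 + depth * (2 * u - 1),
    fall = 1 - depth * (2 * u - 1),
    arch = 1 + depth * (sin(pi * u) - 2 / pi))
  f1_t <- f1_mean_hz * mult
  f0_t <- f1_t / 2
  phase0 <- 2 * pi * cumsum(f0_t) / sample_rate_hz
  amps <- c(0.4, 1 / (2:n_harmonics))
  sig <- numeric(n)
  if (is.finite(snr_db) || snr_db == Inf) {
    for (k in seq_len(n_harmonics)) sig <- sig + amps[k] * sin(k * phase0)
  }
  # raised-cosine fade in/out
  nf <- min(round(fade_s * sample_rate_hz), floor(n / 2))
  if (nf > 0) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nf) - 0.5) / nf)
    sig[seq_len(nf)] <- sig[seq_len(nf)] * ramp
    sig[n + 1 - seq_len(nf)] <- sig[n + 1 - seq_len(nf)] * ramp
  }
  if (is.finite(snr_db)) {
    p_sig <- mean(sig^2)
    noise_sd <- sqrt(p_sig / 10^(snr_db / 10))
    noise <- if (is.null(seed)) rnorm(n, 0, noise_sd)
             else with_seed(seed, rnorm(n, 0, noise_sd))
    sig <- sig + noise
  } else if (snr_db == -Inf) {
    sig <- if (is.null(seed)) rnorm(n) else with_seed(seed, rnorm(n))
  }
  peak <- max(abs(sig))
  if (peak > 0) sig <- 0.9 * sig / peak
  structure(sig, sample_rate_hz = sample_rate_hz, f1_mean_hz = f1_mean_hz)
}

## deterministic context -> contour shape map (cycles the four shapes)
context_shape_map <- function(contexts) {
  shapes <- c("flat", "rise", "fall", "arch")
  setNames(shapes[(seq_along(contexts) - 1) %% 4 + 1], contexts)
}

## deterministic per-context shifts, evenly spaced over +/- half-range
context_shifts <- function(contexts, spread) {
  k <- length(contexts)
  setNames(seq(-spread, spread, length.out = k), contexts)
}

rtruncnorm_min <- function(n, mean, sd, min) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < min)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < min)
  }
  out
}

#' Generate the hierarchically nested ground truth
#'
#' Callers nest in core groups, core groups in bond groups, bond groups in
#' populations. Population f1 offsets are evenly spaced spanning
#' `sigma_pop_hz`; bond, core and individual offsets are independent normal
#' draws. The matriarch of each core group is its oldest member (ties broken
#' by lexicographic id).
#'
#' @param config a [sim_config()].
#' @return list of class `ground_truth` with elements `callers` (tibble:
#'   caller_id, population, bond, core, age_years, ind_offset_hz,
#'   f1_offset_hz, matriarch), `core_to_bond`, and `matriarchs`.
#' @export
generate_ground_truth <- function(config) {
  validate_sim_config(config)
  with_seed(substream_seed(config$seed, "truth"), {
    P <- config$n_populations
    ## evenly spaced population offsets, total span = sigma_pop_hz
    pop_off <- if (P == 1) 0 else
      (seq_len(P) - (P + 1) / 2) * config$sigma_pop_hz / (P - 1)
    rows <- list()
    for (p in seq_len(P)) {
      popid <- sprintf("P%d", p)
      n_call <- config$callers_per_population[p]
      bonds <- sprintf("%s_B%d", popid, seq_len(config$bond_groups_per_population))
      cores <- unlist(lapply(bonds, function(b)
        sprintf("%s_K%d", b, seq_len(config$core_groups_per_bond))))
      bond_of_core <- rep(bonds, each = config$core_groups_per_bond)
      core_idx <- rep_len(seq_along(cores), n_call)  # round-robin assignment
      ids <- sprintf("%s_C%02d", popid, seq_len(n_call))
      ages <- rtruncnorm_min(n_call, config$age_mean_years,
                             config$age_sd_years, config$age_min_years)
      bond_off <- setNames(rnorm(length(bonds), 0, config$sigma_bond_hz), bonds)
      core_off <- setNames(rnorm(length(cores), 0, config$sigma_core_hz), cores)
      ind_off <- rnorm(n_call, 0, config$sigma_ind_hz)
      rows[[p]] <- tibble::tibble(
        caller_id = ids,
        population = popid,
        bond = bond_of_core[core_idx],
        core = cores[core_idx],
        age_years = ages,
        ind_offset_hz = ind_off,
        f1_offset_hz = pop_off[p] + bond_off[bond_of_core[core_idx]] +
          core_off[cores[core_idx]] + ind_off +
          config$age_slope_hz_per_year * ages)
    }
    callers <- do.call(rbind, rows)
    callers <- callers[order(callers$caller_id), ]
    ## matriarch = oldest per core, lexicographic tie-break
    mat <- vapply(split(callers, callers$core), function(d) {
      d <- d[order(-d$age_years, d$caller_id), ]
      d$caller_id[1]
    }, character(1))
    callers$matriarch <- callers$caller_id %in% mat
    core_to_bond <- unique(callers[, c("core", "bond", "population")])
    structure(list(callers = callers, core_to_bond = core_to_bond,
                   matriarchs = mat),
              class = "ground_truth")
  })
}

#' Generate a complete synthetic rumble dataset
#'
#' Produces the ground-truth social hierarchy, per-call metadata and
#' waveforms, a sighting table and a genetic-relatedness table. Each call's
#' planted second-harmonic mean is
#' `base + context shift + population + bond + core + individual offsets +
#' age x slope + call-level noise`. Identical seeds give identical output.
#'
#' @param config a [sim_config()].
#' @param waveforms if FALSE, skip audio synthesis (metadata only).
#' @return list of class `rumble_dataset` with elements `calls` (tibble),
#'   `waveforms` (named list of numeric vectors), `truth`, `sightings`,
#'   `relatedness`, `config`.
#' @export
generate_dataset <- function(config, waveforms = TRUE) {
  validate_sim_config(config)
  truth <- generate_ground_truth(config)
  shapes <- context_shape_map(config$contexts)
  f_shift <- context_shifts(config$contexts, config$context_spread_hz)
  d_shift <- context_shifts(config$contexts, config$context_duration_spread_s)

  calls <- with_seed(substream_seed(config$seed, "calls"), {
    rows <- vector("list", nrow(truth$callers))
    for (i in seq_len(nrow(truth$callers))) {
      cl <- truth$callers[i, ]
      n_i <- if (is.infinite(config$calls_dispersion))
        round(config$calls_per_caller)
      else rnbinom(1, size = config$calls_dispersion,
                   mu = config$calls_per_caller)
      n_i <- max(n_i, 1L)
      if (config$ensure_min_dates) n_i <- max(n_i, 6L)
      ## dates: guarantee >= 2 dates with >= 3 calls each when required
      day_pool <- sample.int(max(config$n_days, 2), min(max(2, ceiling(n_i / 3)),
                                                        max(config$n_days, 2)))
      if (config$ensure_min_dates && n_i >= 6) {
        day_idx <- c(rep(day_pool[1], 3), rep(day_pool[2], 3),
                     sample(day_pool, n_i - 6, replace = TRUE))
      } else {
        day_idx <- sample(day_pool, n_i, replace = TRUE)
      }
      ctx <- sample(config$contexts, n_i, replace = TRUE)
      dur <- pmax(config$duration_min_s,
                  rnorm(n_i, config$duration_mean_s + d_shift[ctx],
                        config$duration_sd_s))
      f1 <- config$base_f1_hz + f_shift[ctx] + cl$f1_offset_hz +
        rnorm(n_i, 0, config$noise_sd_hz)
      f1 <- pmax(f1, 18)  # keep the whole modulated contour inside the trace band
      rows[[i]] <- tibble::tibble(
        caller_id = cl$caller_id, population = cl$population,
        bond = cl$bond, core = cl$core,
        date = config$start_date + day_idx - 1,
        context = ctx, contour_shape = unname(shapes[ctx]),
        duration_s = dur, f1_true_hz = f1,
        age_years = cl$age_years)
    }
    out <- do.call(rbind, rows)
    out$call_id <- sprintf("call%05d", seq_len(nrow(out)))
    out[, c("call_id", setdiff(names(out), "call_id"))]
  })

  wavs <- NULL
  if (waveforms) {
    wav_seed <- substream_seed(config$seed, "waveforms")
    wavs <- lapply(seq_len(nrow(calls)), function(i) {
      synthesize_call(calls$f1_true_hz[i], calls$contour_shape[i],
                      calls$duration_s[i], config$sample_rate_hz,
                      snr_db = config$snr_db,
                      seed = substream_seed(wav_seed, calls$call_id[i]))
    })
    names(wavs) <- calls$call_id
  }

  structure(list(calls = calls, waveforms = wavs, truth = truth,
                 sightings = generate_sightings(truth, config),
                 relatedness = generate_relatedness(truth, config),
                 config = config),
            class = "rumble_dataset")
}

#' Generate a sighting table with tiered association structure
#'
#' Hierarchical party model. Each day: the whole population aggregates with
#' probability `p_cross / p_within`; otherwise each bond group merges its
#' core groups with probability `(p_bond - p_cross) / (p_within - p_cross)`;
#' each detected individual joins its (core/bond/population) party with
#' probability `sqrt(p_within)` and is otherwise sighted alone. Conditional
#' on both members of a dyad being detected, the probability of co-occurring
#' in one party is then *exactly* `p_within` (same core), `p_bond` (same
#' bond, different core) or `p_cross` (different bonds): equal tier
#' probabilities give identical co-sighting behaviour across tiers, ordered
#' probabilities give ordered simple-ratio indices in expectation, and
#' `p_within = 1, p_bond = p_cross = 0` keeps every core group one intact
#' unit.
#'
#' @param truth a `ground_truth`.
#' @param config a [sim_config()].
#' @return tibble of class `sighting_table`: one row per sighting party, with
#'   `date` and a list-column `ids`.
#' @export
generate_sightings <- function(truth, config) {
  validate_sim_config(config)
  callers <- truth$callers
  n <- nrow(callers)
  out_day <- integer(0); out_ids <- list(); k <- 0
  pw <- config$p_within; pb <- config$p_bond; px <- config$p_cross
  cohesion <- sqrt(pw)
  m_pop <- if (pw > 0) px / pw else 0
  m_bond <- if (pw > px) (pb - px) / (pw - px) else 0
  bonds <- unique(callers$bond)
  if (config$n_days > 0 && n >= 1) {
    with_seed(substream_seed(config$seed, "sightings"), {
      for (d in seq_len(config$n_days)) {
        det <- runif(n) < config$p_detect
        if (!any(det)) next
        social <- runif(n) < cohesion
        pop_merge <- runif(1) < m_pop
        bond_merge <- setNames(runif(length(bonds)) < m_bond, bonds)
        party <- ifelse(!social, paste0("solo_", callers$caller_id),
                        if (pop_merge) "all" else
                          ifelse(bond_merge[callers$bond], callers$bond,
                                 callers$core))
        for (m in split(callers$caller_id[det], party[det])) {
          k <- k + 1
          out_day[k] <- d
          out_ids[[k]] <- sort(m)
        }
      }
    })
  }
  out <- if (k == 0) {
    tibble::tibble(date = config$start_date[0], ids = list())
  } else {
    tibble::tibble(date = config$start_date + out_day - 1, ids = out_ids)
  }
  class(out) <- c("sighting_table", class(out))
  out
}

#' Generate a pairwise genetic-relatedness table
#'
#' Within-population dyads only. A fraction `rel_decouple` of dyads have
#' relatedness drawn independently of group membership (emulating social
#' disruption that leaves groups containing unrelated individuals); the rest
#' centre on `rel_mean_within` for same-core dyads and `rel_mean_cross`
#' otherwise. Values are clamped to `[-0.2, 0.6]`.
#'
#' @param truth a `ground_truth`.
#' @param config a [sim_config()].
#' @return tibble: `id_a`, `id_b` (id_a < id_b), `relatedness`, plus the
#'   `decoupled` indicator.
#' @export
generate_relatedness <- function(truth, config) {
  validate_sim_config(config)
  callers <- truth$callers
  rows <- list()
  with_seed(substream_seed(config$seed, "relatedness"), {
    for (pop in unique(callers$population)) {
      d <- callers[callers$population == pop, ]
      if (nrow(d) < 2) next
      pr <- t(utils::combn(nrow(d), 2))
      same_core <- d$core[pr[, 1]] == d$core[pr[, 2]]
      dec <- runif(nrow(pr)) < config$rel_decouple
      base <- ifelse(dec,
                     sample(c(config$rel_mean_within, config$rel_mean_cross),
                            nrow(pr), replace = TRUE, prob = c(0.3, 0.7)),
                     ifelse(same_core, config$rel_mean_within,
                            config$rel_mean_cross))
      r <- pmin(0.6, pmax(-0.2, rnorm(nrow(pr), base, config$rel_sd)))
      rows[[pop]] <- tibble::tibble(
        id_a = pmin(d$caller_id[pr[, 1]], d$caller_id[pr[, 2]]),
        id_b = pmax(d$caller_id[pr[, 1]], d$caller_id[pr[, 2]]),
        relatedness = r, decoupled = dec)
    }
  })
  if (!length(rows))
    return(tibble::tibble(id_a = character(0), id_b = character(0),
                          relatedness = numeric(0), decoupled = logical(0)))
  do.call(rbind, rows)
}

#' Write a synthetic dataset to disk
#'
#' Emits `calls.csv`, `callers.csv`, `truth.csv`, `sightings.csv`
#' (semicolon-joined ids per row), `relatedness.csv`, and (optionally) one
#' PCM-16 WAV per call under `wav/`. Every CSV carries a provenance header
#' with the seed and configuration hash.
#'
#' @param dataset a `rumble_dataset`.
#' @param dir output directory (created if missing).
#' @param wav write waveform WAV files.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, wav = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- dataset$config
  calls <- dataset$calls
  calls$wav <- file.path("wav", paste0(calls$call_id, ".wav"))
  write_prov_csv(calls, file.path(dir, "calls.csv"), cfg$seed, cfg)
  cal <- dataset$truth$callers
  write_prov_csv(cal[, c("caller_id", "population", "age_years")],
                 file.path(dir, "callers.csv"), cfg$seed, cfg)
  write_prov_csv(cal, file.path(dir, "truth.csv"), cfg$seed, cfg)
  sig <- tibble::tibble(
    date = dataset$sightings$date,
    ids = vapply(dataset$sightings$ids, paste, character(1), collapse = ";"))
  write_prov_csv(sig, file.path(dir, "sightings.csv"), cfg$seed, cfg)
  write_prov_csv(dataset$relatedness, file.path(dir, "relatedness.csv"),
                 cfg$seed, cfg)
  if (wav && !is.null(dataset$waveforms)) {
    dir.create(file.path(dir, "wav"), showWarnings = FALSE)
    for (id in names(dataset$waveforms))
      write_wav(dataset$waveforms[[id]],
                file.path(dir, "wav", paste0(id, ".wav")), cfg$sample_rate_hz)
  }
  invisible(dir)
}
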