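#' Convert frequency in Hz to the mel scale
#'
#' HTK convention: `mel = 2595 * log10(1 + f/700)`.
#'
#' @param f frequency in Hz (>= 0, vectorised).
#' @return mel value(s).
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) stop("frequencies must be >= 0")
  2595 * log10(1 + f / 700)
}

#' @rdname hz_to_mel
#' @param m mel value(s).
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' STFT parameters
#'
#' Defaults follow the display settings used for rumble spectrograms: 2 kHz
#' sampling rate, Hann window of 800 samples, 90% overlap.
#'
#' @param sample_rate_hz sampling rate.
#' @param window_samples window length in samples.
#' @param overlap overlap fraction in `[0, 1)`.
#' @export
stft_params <- function(sample_rate_hz = 2000, window_samples = 800,
                        overlap = 0.9) {
  stopifnot(overlap >= 0, overlap < 1, window_samples > 1)
  list(sample_rate_hz = sample_rate_hz, window_samples = window_samples,
       overlap = overlap,
       hop = max(1L, round(window_samples * (1 - overlap))))
}

## power spectrogram: (win/2 + 1) bins x floor((N - win)/hop) + 1 frames
power_spectrogram <- function(x, stft) {
  n <- length(x)
  win <- stft$window_samples
  hop <- stft$hop
  if (n < win) stop("signal shorter than one analysis window")
  n_frames <- floor((n - win) / hop) + 1
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win - 1)) / (win - 1))  # Hann
  idx <- outer(0:(win - 1), (0:(n_frames - 1)) * hop, "+") + 1
  frames <- matrix(x[idx], nrow = win) * w
  spec <- mvfft(frames)
  n_bins <- floor(win / 2) + 1
  pow <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  list(power = pow,
       freq_hz = (seq_len(n_bins) - 1) * stft$sample_rate_hz / win,
       times = (0:(n_frames - 1)) * hop / stft$sample_rate_hz +
         win / (2 * stft$sample_rate_hz),
       n_samples = n, stft = stft)
}

## triangular mel filterbank: n_bands x n_bins matrix
mel_filterbank <- function(freq_hz, n_bands, fmin, fmax) {
  pts_mel <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_bands + 2)
  pts_hz <- mel_to_hz(pts_mel)
  fb <- matrix(0, n_bands, length(freq_hz))
  for (b in seq_len(n_bands)) {
    lo <- pts_hz[b]; mid <- pts_hz[b + 1]; hi <- pts_hz[b + 2]
    up <- (freq_hz - lo) / (mid - lo)
    down <- (hi - freq_hz) / (hi - mid)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Compute a mel spectrogram
#'
#' Short-time Fourier power spectrogram with the frequency axis collapsed
#' through a triangular mel filterbank.
#'
#' @param waveform numeric vector.
#' @param stft [stft_params()].
#' @param n_bands number of mel bands.
#' @param fmin,fmax filterbank frequency range (Hz); `fmax` must not exceed
#'   Nyquist.
#' @return list of class `mel_spectrogram`: `energy` (band x frame, >= 0),
#'   `band_hz`, `band_mel` (band centres), `times`, `n_samples`, `stft`.
#' @export
mel_spectrogram <- function(waveform, stft = stft_params(), n_bands = 22,
                            fmin = 8, fmax = 500) {
  if (!(fmin < fmax)) stop("need fmin < fmax")
  if (fmax > stft$sample_rate_hz / 2) stop("fmax exceeds Nyquist")
  ps <- power_spectrogram(as.numeric(waveform), stft)
  fb <- mel_filterbank(ps$freq_hz, n_bands, fmin, fmax)
  centres_mel <- seq(hz_to_mel(fmin), hz_to_mel(fmax),
                     length.out = n_bands + 2)[2:(n_bands + 1)]
  structure(list(energy = fb %*% ps$power,
                 band_hz = mel_to_hz(centres_mel),
                 band_mel = centres_mel,
                 times = ps$times, n_samples = ps$n_samples, stft = stft),
            class = "mel_spectrogram")
}

#' Extract the 94-dimension mel feature battery from one call
#'
#' Features describe the distribution of energy across time and frequency in
#' the mel spectrogram and are computed on per-call normalised energies, so
#' they are invariant to global amplitude scaling up to floating-point
#' rounding (recording-gain differences cannot drive classification). The inventory (94 values):
#' per-band mean, s.d., skew and excess kurtosis of normalised band energy
#' across frames (22 bands x 4 = 88); call duration (s); s.d. of the
#' time-marginal energy distribution; skew of the time-marginal energy
#' distribution (negates under time reversal); mean and s.d. of the per-frame
#' spectral centroid (mel); mean of the per-frame normalised spectral entropy.
#'
#' @param ms a [mel_spectrogram()].
#' @return named numeric vector of length 94, all finite.
#' @export
extract_mel_features <- function(ms) {
  E <- ms$energy
  if (ncol(E) < 2) stop("need at least 2 frames")
  tot <- sum(E)
  if (tot <= 0) stop("silent call: all-zero mel spectrogram")
  E <- E / tot
  n_bands <- nrow(E)
  band <- lapply(seq_len(n_bands), function(b) moment_stats(E[b, ]))
  band_feats <- unlist(lapply(seq_len(n_bands), function(b)
    setNames(band[[b]], sprintf("band%02d_%s", b, names(band[[b]])))))

  frame_e <- colSums(E)                       # time-marginal distribution
  u <- seq(0, 1, length.out = ncol(E))        # normalised time grid
  tm <- weighted_moment_stats(u, frame_e)

  ## per-frame spectral centroid (mel) and normalised entropy, energy-weighted
  ok <- frame_e > 0
  cen <- colSums(E[, ok, drop = FALSE] * ms$band_mel) / frame_e[ok]
  p <- sweep(E[, ok, drop = FALSE], 2, frame_e[ok], "/")
  ent <- apply(p, 2, function(q) {
    q <- q[q > 0]
    -sum(q * log(q)) / log(n_bands)
  })
  out <- c(band_feats,
           duration_s = ms$n_samples / ms$stft$sample_rate_hz,
           frame_energy_sd = unname(tm["sd"]),
           time_skew = unname(tm["skew"]),
           spectral_centroid_mean = mean(cen),
           spectral_centroid_sd = if (length(cen) > 1) sd(cen) else 0,
           spectral_entropy_mean = mean(ent))
  stopifnot(length(out) == 94, all(is.finite(out)))
  out
}

#' Trace the second-harmonic (f1) contour of a call
#'
#' Finds the ridge maximising summed spectral magnitude within the f1 search
#' band, subject to a frame-to-frame jump penalty (dynamic-programming path).
#' Frames where the ridge prominence (ridge magnitude over the median
#' in-band magnitude, so other harmonics in the band cannot mask a true
#' ridge) falls below `prominence` are flagged unvoiced.
#'
#' @param waveform numeric vector.
#' @param stft [stft_params()].
#' @param f1_band two-element numeric, search band in Hz (within Nyquist).
#' @param jump_penalty DP cost per bin of frame-to-frame jump, in prominence
#'   units.
#' @param prominence voiced/unvoiced threshold.
#' @param min_voiced minimum voiced frames; fewer raises an error.
#' @return list of class `f1_contour`: `freq_hz`, `voiced`, `times`,
#'   `duration_s`, `bin_width_hz`.
#' @export
trace_f1_contour <- function(waveform, stft = stft_params(),
                             f1_band = c(14, 80), jump_penalty = 0.5,
                             prominence = 4, min_voiced = 4) {
  stopifnot(length(f1_band) == 2, f1_band[1] < f1_band[2])
  if (f1_band[2] > stft$sample_rate_hz / 2) stop("f1 band exceeds Nyquist")
  ps <- power_spectrogram(as.numeric(waveform), stft)
  in_band <- which(ps$freq_hz >= f1_band[1] & ps$freq_hz <= f1_band[2])
  if (length(in_band) < 2) stop("f1 band narrower than two frequency bins")
  mag <- sqrt(ps$power[in_band, , drop = FALSE])
  n_bin <- nrow(mag); n_fr <- ncol(mag)
  med <- apply(mag, 2, median)
  prom <- sweep(mag, 2, pmax(med, .Machine$double.eps), "/")

  ## DP over frames: maximise sum of prominences minus jump penalties
  score <- prom[, 1]
  back <- matrix(0L, n_bin, n_fr)
  step <- outer(seq_len(n_bin), seq_len(n_bin),
                function(i, j) -jump_penalty * abs(i - j))
  for (t in seq_len(n_fr)[-1]) {
    cand <- sweep(step, 2, score, "+")      # cand[i, j] = score[j] + step
    back[, t] <- max.col(cand, ties.method = "first")
    score <- cand[cbind(seq_len(n_bin), back[, t])] + prom[, t]
  }
  path <- integer(n_fr)
  path[n_fr] <- which.max(score)
  for (t in rev(seq_len(n_fr)[-1])) path[t - 1] <- back[path[t], t]

  voiced <- prom[cbind(path, seq_len(n_fr))] >= prominence
  if (sum(voiced) < min_voiced)
    stop("untraceable call: fewer than ", min_voiced, " voiced frames")
  ## parabolic interpolation around the ridge bin reduces quantisation bias
  bw <- ps$freq_hz[2] - ps$freq_hz[1]
  freq <- ps$freq_hz[in_band][path]
  interior <- path > 1 & path < n_bin
  if (any(interior)) {
    ii <- which(interior)
    a <- mag[cbind(path[ii] - 1, ii)]
    b <- mag[cbind(path[ii], ii)]
    cc <- mag[cbind(path[ii] + 1, ii)]
    denom <- a - 2 * b + cc
    delta <- ifelse(abs(denom) > .Machine$double.eps,
                    0.5 * (a - cc) / denom, 0)
    freq[ii] <- freq[ii] + pmax(-0.5, pmin(0.5, delta)) * bw
  }
  structure(list(freq_hz = freq,
                 voiced = voiced,
                 times = ps$times,
                 duration_s = ps$n_samples / stft$sample_rate_hz,
                 bin_width_hz = bw),
            class = "f1_contour")
}

#' Nine summary statistics of an f1 contour
#'
#' Mean, s.d., skew, excess kurtosis, 10th and 90th percentiles
#' (linear-interpolation quantiles) of the voiced contour values, plus the
#' frequency at 25%, 50% and 75% of call duration (value at the voiced frame
#' nearest each time point). Skew and kurtosis are 0 when the s.d. is 0.
#'
#' @param contour an [trace_f1_contour()] result.
#' @return named numeric vector of length 9 (all Hz except the shape stats).
#' @export
contour_stats <- function(contour) {
  v <- contour$freq_hz[contour$voiced]
  tv <- contour$times[contour$voiced]
  if (length(v) < 4) stop("need at least 4 voiced frames")
  ms <- moment_stats(v)
  at_frac <- function(fr) v[which.min(abs(tv - fr * contour$duration_s))]
  out <- c(f1_mean = unname(ms["mean"]),
           f1_sd = if (length(v) > 1) sd(v) else 0,
           f1_skew = unname(ms["skew"]),
           f1_kurt = unname(ms["kurt"]),
           f1_p10 = unname(quantile(v, 0.1, type = 7)),
           f1_p90 = unname(quantile(v, 0.9, type = 7)),
           f1_at25 = at_frac(0.25),
           f1_at50 = at_frac(0.50),
           f1_at75 = at_frac(0.75))
  stopifnot(length(out) == 9)
  out
}

#' Extract the full per-call feature table for a dataset
#'
#' Runs [mel_spectrogram()] + [extract_mel_features()] and
#' [trace_f1_contour()] + [contour_stats()] on every call. Calls whose
#' contour is untraceable are dropped with a message (none are expected at
#' the simulator's default SNR).
#'
#' @param dataset a `rumble_dataset` (with waveforms).
#' @param stft [stft_params()].
#' @param f1_band second-harmonic search band (Hz).
#' @return tibble: `call_id`, 94 mel features, 9 contour statistics.
#' @export
extract_features <- function(dataset, stft = stft_params(),
                             f1_band = c(14, 80)) {
  stopifnot(!is.null(dataset$waveforms))
  rows <- vector("list", length(dataset$waveforms))
  keep <- logical(length(rows))
  ids <- names(dataset$waveforms)
  for (i in seq_along(rows)) {
    w <- dataset$waveforms[[i]]
    res <- tryCatch({
      mel <- extract_mel_features(mel_spectrogram(w, stft))
      cs <- contour_stats(trace_f1_contour(w, stft, f1_band))
      c(mel, cs)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      rows[[i]] <- res
      keep[i] <- TRUE
    }
  }
  if (!any(keep)) stop("no call yielded a feature vector")
  if (any(!keep))
    message(sum(!keep), " call(s) dropped as untraceable")
  out <- tibble::as_tibble(do.call(rbind, rows[keep]))
  out <- tibble::add_column(out, call_id = ids[keep], .before = 1)
  out
}

#' Names of the mel-battery and contour-statistic feature columns
#' @param features a feature table from [extract_features()].
#' @return character vector of column names.
#' @export
mel_feature_cols <- function(features) {
  setdiff(names(features), c("call_id", contour_feature_cols(features)))
}

#' @rdname mel_feature_cols
#' @export
contour_feature_cols <- function(features) {
  intersect(c("f1_mean", "f1_sd", "f1_skew", "f1_kurt", "f1_p10", "f1_p90",
              "f1_at25", "f1_at50", "f1_at75"), names(features))
}
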