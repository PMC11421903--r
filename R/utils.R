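#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' All randomness in the package flows from one root seed through named
#' substreams (calls, sightings, relatedness, ...), so that any stage can be
#' regenerated independently of the others.
#'
#' @param seed integer root seed.
#' @param stream character name of the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- seed %% 2147483647
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

## run `expr` under a local RNG state seeded with `seed`; restores global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## population moments; skew and excess kurtosis are 0 when the sd is 0
moment_stats <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v <= 0) return(c(mean = m, sd = 0, skew = 0, kurt = 0))
  s <- sqrt(v)
  c(mean = m, sd = s,
    skew = mean((x - m)^3) / s^3,
    kurt = mean((x - m)^4) / v^2 - 3)
}

## weighted moments of `x` under nonnegative weights `w` (normalised internally)
weighted_moment_stats <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  if (v <= 0) return(c(mean = m, sd = 0, skew = 0, kurt = 0))
  s <- sqrt(v)
  c(mean = m, sd = s,
    skew = sum(w * (x - m)^3) / s^3,
    kurt = sum(w * (x - m)^4) / v^2 - 3)
}

#' Write a data frame as CSV with a provenance header
#'
#' The first line is a `#`-prefixed comment recording the seed and a hash of
#' the configuration that produced the table; [read_prov_csv()] skips it.
#'
#' @param df data frame.
#' @param path output path.
#' @param seed integer seed recorded in the header.
#' @param config object hashed into the header (may be NULL).
#' @return `path`, invisibly.
#' @export
write_prov_csv <- function(df, path, seed = NA, config = NULL) {
  hash <- rlang::hash(config)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rumblesig seed=%s config_hash=%s", seed, hash), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_prov_csv
#' @export
read_prov_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Minimal mono PCM-16 WAV writer and reader
#'
#' Covers exactly the subset of the RIFF/WAVE format the simulator emits:
#' one mono channel, 16-bit signed PCM. Samples are expected in `[-1, 1]`.
#'
#' @param x numeric waveform in `[-1, 1]`.
#' @param path file path.
#' @param sample_rate_hz sampling rate in Hz.
#' @return `path` invisibly; `read_wav()` returns a list with `samples` and
#'   `sample_rate_hz`.
#' @export
write_wav <- function(x, path, sample_rate_hz) {
  stopifnot(is.numeric(x), sample_rate_hz > 0)
  pcm <- as.integer(pmax(-32767, pmin(32767, round(x * 32767))))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")   # block align
  writeBin(as.integer(16), con, size = 2, endian = "little")  # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  readChar(con, 4)  # "WAVE"
  sr <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      sr <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = sz - 8))
    } else if (identical(id, "data")) {
      samples <- readBin(con, integer(), n = sz / 2, size = 2,
                         endian = "little", signed = TRUE) / 32767
      break
    } else {
      invisible(readBin(con, "raw", n = sz))
    }
  }
  list(samples = samples, sample_rate_hz = sr)
}
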