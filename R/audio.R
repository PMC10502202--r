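#' Construct a waveform object
#' @param samples numeric vector of finite samples
#' @param sample_rate sampling rate in Hz
#' @return object of class `waveform`
#' @export
waveform <- function(samples, sample_rate = 16000) {
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples, %g Hz (%.2f s)\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

midi_to_hz <- function(pitch) 440 * 2^((pitch - 69) / 12)

#' Render a symbol sequence to audio
#'
#' Additive synthesis: each note is a tone at its equal-temperament
#' frequency (440 Hz at MIDI 69) with a 10 ms linear attack and an
#' exponential decay over the note, so note onsets are sharp in the
#' amplitude envelope.  The default timbre stacks three harmonics
#' (amplitudes 1, 0.5, 0.25); `"sine"` uses the fundamental only.  The
#' rendered duration is `(last onset + duration) * 60 / tempo` seconds and
#' the result is peak-normalized.
#'
#' @param seq a [symbol_sequence()]
#' @param sample_rate output rate in Hz (default 16000)
#' @param tempo_bpm tempo; defaults to the sequence's stored tempo
#' @param timbre `"harmonic"` (default) or `"sine"`
#' @param attack attack time in seconds (default 0.01)
#' @return a [waveform()]
#' @export
render_waveform <- function(seq, sample_rate = 16000, tempo_bpm = NULL,
                            timbre = c("harmonic", "sine"), attack = 0.01) {
  timbre <- match.arg(timbre)
  ev <- seq$events
  if (!nrow(ev)) stop("cannot render an empty sequence")
  if (is.null(tempo_bpm)) tempo_bpm <- seq$tempo_bpm
  spb <- 60 / tempo_bpm                      # seconds per beat
  total <- max(ev$onset + ev$duration) * spb
  n <- ceiling(total * sample_rate)
  out <- numeric(n)
  amps <- if (timbre == "harmonic") c(1, 0.5, 0.25) else 1
  for (i in seq_len(nrow(ev))) {
    f0 <- midi_to_hz(ev$pitch[i])
    t0 <- ev$onset[i] * spb
    dur <- ev$duration[i] * spb
    i0 <- floor(t0 * sample_rate) + 1L
    i1 <- min(n, ceiling((t0 + dur) * sample_rate))
    if (i1 < i0) next
    t <- (seq(i0, i1) - 1) / sample_rate - t0
    env <- pmin(t / attack, 1) * exp(-t / (dur / 3))
    tone <- 0
    for (h in seq_along(amps)) {
      fh <- h * f0
      if (fh < sample_rate / 2)
        tone <- tone + amps[h] * sin(2 * pi * fh * t)
    }
    out[i0:i1] <- out[i0:i1] + env * tone
  }
  peak <- max(abs(out))
  if (peak > 0) out <- out / peak * 0.99
  waveform(out, sample_rate)
}

#' Z-score normalize a waveform
#'
#' Rescales to mean 0 and standard deviation 1, the convention applied to
#' acoustic signals before amplitude demodulation so overall intensity does
#' not influence spectrotemporal modulation features.
#'
#' @param wave a [waveform()]
#' @return normalized [waveform()]
#' @export
zscore_normalize <- function(wave) {
  x <- wave$samples
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant signal")
  waveform((x - mean(x)) / s, wave$sample_rate)
}

#' Write a waveform as a PCM WAV file
#' @param wave a [waveform()]
#' @param path output path
#' @param bits 16 (integer PCM) or 32 (IEEE float)
#' @return `path`, invisibly
#' @export
write_wav <- function(wave, path, bits = 16) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32")
  x <- wave$samples
  sr <- round(wave$sample_rate)
  n <- length(x)
  bytes_per <- bits / 8
  data_len <- n * bytes_per
  u32le <- function(v) as.raw(c(v %% 256, (v %/% 256) %% 256,
                                (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
  u16le <- function(v) as.raw(c(v %% 256, v %/% 256))
  fmt_code <- if (bits == 16) 1L else 3L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("RIFF"), u32le(36 + data_len), charToRaw("WAVE"),
             charToRaw("fmt "), u32le(16), u16le(fmt_code), u16le(1),
             u32le(sr), u32le(sr * bytes_per), u16le(bytes_per),
             u16le(bits), charToRaw("data"), u32le(data_len)), con)
  if (bits == 16) {
    writeBin(as.integer(round(pmax(pmin(x, 1), -1) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a PCM WAV file
#' @param path path to a .wav file (16-bit integer or 32-bit float, mono or
#'   first channel of interleaved stereo)
#' @return a [waveform()]
#' @export
read_wav <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 44 || rawToChar(bytes[1:4]) != "RIFF" ||
      rawToChar(bytes[9:12]) != "WAVE")
    stop("not a RIFF/WAVE file: ", path)
  u <- function(i, n) sum(as.integer(bytes[i:(i + n - 1L)]) * 256^(0:(n - 1)))
  pos <- 13L
  fmt_code <- NULL
  repeat {
    if (pos + 8L > length(bytes)) stop("no data chunk in ", path)
    id <- rawToChar(bytes[pos:(pos + 3L)])
    len <- u(pos + 4L, 4)
    if (id == "fmt ") {
      fmt_code <- u(pos + 8L, 2)
      n_chan <- u(pos + 10L, 2)
      sr <- u(pos + 12L, 4)
      bits <- u(pos + 22L, 2)
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("data chunk precedes fmt chunk in ", path)
      raw_data <- bytes[(pos + 8L):(pos + 7L + len)]
      break
    }
    pos <- pos + 8L + len + len %% 2L
  }
  if (fmt_code == 1 && bits == 16) {
    x <- readBin(raw_data, "integer", n = len / 2, size = 2,
                 endian = "little") / 32767
  } else if (fmt_code == 3 && bits == 32) {
    x <- readBin(raw_data, "numeric", n = len / 4, size = 4,
                 endian = "little")
  } else {
    stop("unsupported WAV encoding (need 16-bit PCM or 32-bit float)")
  }
  if (n_chan > 1) x <- x[seq(1, length(x), by = n_chan)]
  waveform(x, sr)
}
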