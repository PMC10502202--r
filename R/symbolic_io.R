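#' Construct a monophonic symbol sequence
#'
#' The canonical symbolic container: a table of note events (MIDI pitch,
#' onset in beats, duration in beats) plus timing metadata.  Onsets must be
#' non-decreasing, durations positive, pitches in 0..127, and no two events
#' may overlap (the stream is monophonic).
#'
#' @param pitch integer MIDI note numbers (0..127)
#' @param onset onsets in beats (quarter note = 1.0), non-decreasing
#' @param duration durations in beats, positive
#' @param ticks_per_beat MIDI resolution used when writing (default 480)
#' @param tempo_bpm tempo applied only at audio rendering (default 120)
#' @return object of class `symbol_sequence`
#' @export
symbol_sequence <- function(pitch, onset, duration,
                            ticks_per_beat = 480L, tempo_bpm = 120) {
  if (length(pitch) == 0) stop("a symbol sequence needs at least one note")
  if (length(onset) != length(pitch) || length(duration) != length(pitch))
    stop("pitch, onset and duration must have the same length")
  if (any(pitch < 0 | pitch > 127)) stop("pitches must lie in 0..127")
  if (any(duration <= 0)) stop("durations must be positive")
  if (any(onset < 0)) stop("onsets must be non-negative")
  if (is.unsorted(onset)) stop("onsets must be non-decreasing")
  if (any(onset[-1] < (onset + duration)[-length(onset)] - 1e-9))
    stop("events overlap: the sequence must be monophonic")
  if (ticks_per_beat < 1) stop("ticks_per_beat must be a positive integer")
  if (tempo_bpm <= 0) stop("tempo_bpm must be positive")
  structure(list(
    events = data.frame(pitch = as.integer(pitch), onset = as.numeric(onset),
                        duration = as.numeric(duration)),
    ticks_per_beat = as.integer(ticks_per_beat),
    tempo_bpm = tempo_bpm), class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  ev <- x$events
  cat(sprintf("Monophonic symbol sequence: %d notes, %.3g beats, %g bpm\n",
              nrow(ev), max(ev$onset + ev$duration), x$tempo_bpm))
  invisible(x)
}

#' Number of notes in a symbol sequence
#' @param seq a `symbol_sequence`
#' @export
n_notes <- function(seq) nrow(seq$events)

quantize_duration <- function(d, grid = 0.25) round(d / grid) * grid

#' Tokenize a symbol sequence for the learner
#'
#' Builds the token alphabet from the distinct symbols actually observed, in
#' first-appearance order.  Under `scheme = "pitch"` a symbol is the MIDI
#' pitch; under `"pitch_duration"` it is the (pitch, quantized duration)
#' pair, so melodies with rhythm get a rhythm-bearing alphabet.
#'
#' @param seq a [symbol_sequence()]
#' @param scheme `"pitch"` (default) or `"pitch_duration"`
#' @return object of class `token_sequence`: list with `tokens` (integers in
#'   1..K), `alphabet` (data frame of symbol definitions), `scheme`.
#' @export
tokenize <- function(seq, scheme = c("pitch", "pitch_duration")) {
  scheme <- match.arg(scheme)
  ev <- seq$events
  if (!nrow(ev)) stop("cannot tokenize an empty sequence")
  key <- if (scheme == "pitch") as.character(ev$pitch)
         else paste(ev$pitch, quantize_duration(ev$duration), sep = "/")
  alpha_keys <- unique(key)
  tokens <- match(key, alpha_keys)
  if (scheme == "pitch") {
    alphabet <- data.frame(pitch = as.integer(alpha_keys),
                           duration = NA_real_)
  } else {
    parts <- strsplit(alpha_keys, "/", fixed = TRUE)
    alphabet <- data.frame(pitch = as.integer(vapply(parts, `[`, "", 1)),
                           duration = as.numeric(vapply(parts, `[`, "", 2)))
  }
  structure(list(tokens = as.integer(tokens), alphabet = alphabet,
                 scheme = scheme), class = "token_sequence")
}

#' Map tokens back to a playable symbol sequence
#'
#' Inverse of [tokenize()] for the symbol content: pitches are recovered
#' exactly; under the `pitch` scheme durations are not part of the alphabet,
#' so each note receives `default_duration` beats.  Onsets are rebuilt
#' contiguously (each note starts when the previous one ends).
#'
#' @param tokens integer token vector, or a `token_sequence`
#' @param tokseq a `token_sequence` providing alphabet and scheme (ignored
#'   if `tokens` already is one)
#' @param default_duration duration in beats for the `pitch` scheme
#' @param tempo_bpm tempo stored on the result
#' @return a [symbol_sequence()]
#' @export
detokenize <- function(tokens, tokseq = NULL, default_duration = 0.5,
                       tempo_bpm = 120) {
  if (inherits(tokens, "token_sequence")) {
    tokseq <- tokens
    tokens <- tokseq$tokens
  }
  if (is.null(tokseq)) stop("a token_sequence with the alphabet is required")
  ab <- tokseq$alphabet
  if (any(tokens < 1 | tokens > nrow(ab))) stop("token out of alphabet")
  pitch <- ab$pitch[tokens]
  duration <- if (tokseq$scheme == "pitch_duration") ab$duration[tokens]
              else rep(default_duration, length(tokens))
  onset <- c(0, cumsum(duration))[seq_along(duration)]
  symbol_sequence(pitch, onset, duration, tempo_bpm = tempo_bpm)
}

#' Alphabet size of a token sequence
#' @param tokseq a `token_sequence`
#' @export
alphabet_size <- function(tokseq) nrow(tokseq$alphabet)

# diatonic pitch set used by fixture melodies (major scale from middle C,
# extended over octaves as the alphabet grows)
.fixture_pitches <- function(K) {
  degrees <- c(0, 2, 4, 5, 7, 9, 11)
  60 + degrees[((seq_len(K) - 1) %% 7) + 1] + 12 * ((seq_len(K) - 1) %/% 7)
}

count_motif_occurrences <- function(pitch, motif) {
  L <- length(motif)
  n <- length(pitch)
  if (n < L) return(0L)
  sum(vapply(seq_len(n - L + 1L),
             function(i) all(pitch[i:(i + L - 1L)] == motif), logical(1)))
}

#' Generate a synthetic children's-song-like melody
#'
#' Produces a monophonic melody over a small diatonic pitch alphabet with a
#' fixed 3-6-note motif planted at evenly spaced, non-overlapping positions
#' and uniform-random filler notes between them — the statistical structure
#' (high-probability motif-internal transitions amid low-probability filler
#' transitions) that a chunking statistical learner is meant to discover.
#' Durations are quantized to {0.5, 1, 2} beats; motif copies share one
#' duration pattern.  Filler notes that would create an accidental extra
#' motif copy are resampled, so the output contains exactly `motif_repeats`
#' occurrences of the motif.  Deterministic for a fixed seed.
#'
#' @param n_notes total number of notes
#' @param alphabet_size number of distinct pitches available (2..30)
#' @param motif_length notes per motif (>= 2)
#' @param motif_repeats number of planted motif copies;
#'   `motif_length * motif_repeats` must not exceed `n_notes`
#' @param seed integer RNG seed
#' @param tempo_bpm stored tempo (default 120)
#' @return a [symbol_sequence()]
#' @export
make_fixture_melody <- function(n_notes = 40, alphabet_size = 8,
                                motif_length = 4, motif_repeats = 5,
                                seed = 1, tempo_bpm = 120) {
  if (motif_length < 2) stop("motif_length must be >= 2")
  if (alphabet_size < 2 || alphabet_size > 30)
    stop("alphabet_size must lie in 2..30")
  if (motif_length * motif_repeats > n_notes)
    stop("infeasible parameters: motif_length * motif_repeats > n_notes")
  pitches <- .fixture_pitches(alphabet_size)
  durs <- c(0.5, 1, 2)
  dur_p <- c(0.5, 0.35, 0.15)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  # motif: distinct-ish pitch pattern and one fixed duration pattern
  motif_pitch <- pitches[sample.int(alphabet_size, motif_length,
                                    replace = motif_length > alphabet_size)]
  motif_dur <- sample(durs, motif_length, replace = TRUE, prob = dur_p)
  # evenly spaced non-overlapping starts
  starts <- floor((seq_len(motif_repeats) - 1) * n_notes / motif_repeats) + 1L
  pitch <- integer(n_notes)
  duration <- numeric(n_notes)
  in_motif <- logical(n_notes)
  for (s in starts) {
    idx <- s:(s + motif_length - 1L)
    pitch[idx] <- motif_pitch
    duration[idx] <- motif_dur
    in_motif[idx] <- TRUE
  }
  filler <- which(!in_motif)
  pitch[filler] <- pitches[sample.int(alphabet_size, length(filler),
                                      replace = TRUE)]
  duration[filler] <- sample(durs, length(filler), replace = TRUE, prob = dur_p)
  # resample filler until no accidental extra motif copies (bounded retries)
  for (attempt in 1:200) {
    if (count_motif_occurrences(pitch, motif_pitch) == motif_repeats) break
    pitch[filler] <- pitches[sample.int(alphabet_size, length(filler),
                                        replace = TRUE)]
  }
  if (count_motif_occurrences(pitch, motif_pitch) != motif_repeats)
    stop("could not place the motif exactly; try another seed or parameters")
  onset <- c(0, cumsum(duration))[seq_len(n_notes)]
  symbol_sequence(pitch, onset, duration, tempo_bpm = tempo_bpm)
}
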