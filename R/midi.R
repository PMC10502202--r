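# Minimal Standard MIDI File (format 0/1) I/O.
# Only what monophonic melodies need: note on/off, tempo meta events,
# running status on read.  All timing converted to beats on read
# (quarter note = 1.0), written back with the sequence's ticks_per_beat.

.vlq_encode <- function(x) {
  x <- as.integer(x)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

.u32 <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                             (x %/% 256) %% 256, x %% 256))
.u16 <- function(x) as.raw(c(x %/% 256, x %% 256))

#' Write a symbol sequence as a Standard MIDI File
#'
#' Emits a format-0 file with one track: a tempo meta event followed by
#' note on/off pairs at the sequence's `ticks_per_beat` resolution.
#'
#' @param seq a [symbol_sequence()]
#' @param path output file path
#' @param velocity note-on velocity (1..127)
#' @return `path`, invisibly
#' @export
write_midi <- function(seq, path, velocity = 80L) {
  ev <- seq$events
  tpb <- seq$ticks_per_beat
  us_per_beat <- round(60e6 / seq$tempo_bpm)
  # absolute-tick event list: (tick, rank, bytes); offs sort before ons at
  # the same tick so repeated pitches retrigger cleanly
  on_t <- round(ev$onset * tpb)
  off_t <- round((ev$onset + ev$duration) * tpb)
  evs <- rbind(
    data.frame(tick = on_t, rank = 2, status = 0x90, pitch = ev$pitch, vel = velocity),
    data.frame(tick = off_t, rank = 1, status = 0x80, pitch = ev$pitch, vel = 0L))
  evs <- evs[order(evs$tick, evs$rank), ]
  track <- c(as.raw(0x00), as.raw(c(0xFF, 0x51, 0x03)),
             as.raw(c(us_per_beat %/% 65536, (us_per_beat %/% 256) %% 256,
                      us_per_beat %% 256)))
  last <- 0
  for (i in seq_len(nrow(evs))) {
    track <- c(track, .vlq_encode(evs$tick[i] - last),
               as.raw(c(evs$status[i], evs$pitch[i], evs$vel[i])))
    last <- evs$tick[i]
  }
  track <- c(track, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))  # end of track
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), .u32(6), .u16(0), .u16(1), .u16(tpb),
             charToRaw("MTrk"), .u32(length(track)), track), con)
  invisible(path)
}

.read_vlq <- function(bytes, pos) {
  val <- 0
  repeat {
    b <- as.integer(bytes[pos])
    pos <- pos + 1L
    val <- val * 128 + b %% 128L
    if (b < 128L) break
  }
  list(value = val, pos = pos)
}

#' Read a Standard MIDI File into a symbol sequence
#'
#' Supports format 0 and format 1 (tracks merged on a common tick axis).
#' Simultaneous or overlapping notes are collapsed to the monophonic
#' contract: at equal onsets the highest pitch wins; a note overlapping the
#' tail of the previous one truncates it.
#'
#' @param path path to a .mid file
#' @return a [symbol_sequence()]
#' @export
read_midi <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 14 || rawToChar(bytes[1:4]) != "MThd")
    stop("not a Standard MIDI File: ", path)
  int_at <- function(i, n) sum(as.integer(bytes[i:(i + n - 1L)]) *
                                 256^((n - 1):0))
  n_tracks <- int_at(11, 2)
  division <- int_at(13, 2)
  if (division >= 32768) stop("SMPTE time division is not supported")
  pos <- 15L
  notes <- NULL
  tempo_bpm <- 120
  for (trk in seq_len(n_tracks)) {
    if (pos + 7L > length(bytes) || rawToChar(bytes[pos:(pos + 3L)]) != "MTrk")
      stop(sprintf("malformed track %d in %s", trk, path))
    len <- int_at(pos + 4L, 4)
    end <- pos + 8L + len
    p <- pos + 8L
    tick <- 0
    status <- NULL
    active <- list()  # pitch -> start tick
    while (p < end) {
      d <- .read_vlq(bytes, p)
      tick <- tick + d$value
      p <- d$pos
      b <- as.integer(bytes[p])
      if (b >= 128L) {
        status <- b
        p <- p + 1L
      } else if (is.null(status)) {
        stop(sprintf("malformed track %d in %s: data byte with no status", trk, path))
      }
      hi <- status %/% 16L
      if (status == 255L) {            # meta event
        type <- as.integer(bytes[p]); p <- p + 1L
        d <- .read_vlq(bytes, p); p <- d$pos
        if (type == 81L && d$value == 3L) {
          us <- int_at(p, 3)
          tempo_bpm <- 60e6 / us
        }
        p <- p + d$value
      } else if (status %in% c(240L, 247L)) {  # sysex
        d <- .read_vlq(bytes, p); p <- d$pos
        p <- p + d$value
      } else if (hi %in% c(12L, 13L)) {        # program change / pressure
        p <- p + 1L
      } else {
        d1 <- as.integer(bytes[p]); d2 <- as.integer(bytes[p + 1L])
        p <- p + 2L
        if (hi == 9L && d2 > 0L) {
          active[[as.character(d1)]] <- tick
        } else if (hi == 8L || (hi == 9L && d2 == 0L)) {
          key <- as.character(d1)
          if (!is.null(active[[key]])) {
            notes <- rbind(notes, data.frame(pitch = d1,
                                             on = active[[key]],
                                             off = tick))
            active[[key]] <- NULL
          }
        }
      }
    }
    pos <- end
  }
  if (is.null(notes) || !nrow(notes))
    stop("no notes found in ", path)
  notes <- notes[notes$off > notes$on, , drop = FALSE]
  if (!nrow(notes)) stop("no notes found in ", path)
  # monophonic collapse: sort by onset then pitch (desc); same onset keeps
  # the highest pitch, later overlaps truncate the note before them
  notes <- notes[order(notes$on, -notes$pitch), ]
  keep <- notes[1, , drop = FALSE]
  if (nrow(notes) > 1) for (i in 2:nrow(notes)) {
    cur <- notes[i, ]
    lastk <- nrow(keep)
    if (cur$on == keep$on[lastk]) next          # same onset: highest kept
    if (cur$on < keep$off[lastk]) keep$off[lastk] <- cur$on
    keep <- rbind(keep, cur)
  }
  keep <- keep[keep$off > keep$on, , drop = FALSE]
  symbol_sequence(keep$pitch, keep$on / division,
                  (keep$off - keep$on) / division,
                  ticks_per_beat = division, tempo_bpm = tempo_bpm)
}
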