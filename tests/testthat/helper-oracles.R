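# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: plain loops, tables and direct formula evaluation.

# KL divergence by explicit summation
oracle_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + p[i] * log(p[i] / q[i])
  s
}

# bigram transition counts by explicit looping
oracle_counts <- function(tokens, K) {
  counts <- matrix(0, K, K)
  for (t in seq_len(length(tokens) - 1)) {
    counts[tokens[t], tokens[t + 1]] <- counts[tokens[t], tokens[t + 1]] + 1
  }
  counts
}

# full chunk pipeline recomputed from scratch for an order-1 model:
# counts -> concentrations -> marginal Beta variance -> z-scores ->
# both-positive product threshold -> maximal runs over the training walk.
# Returns the set of chunk patterns as strings.
oracle_chunks <- function(tokens, K, prior, n_passes, c_thr) {
  counts <- matrix(0, K, K)
  for (p in seq_len(n_passes)) {
    for (t in seq_len(length(tokens) - 1)) {
      counts[tokens[t], tokens[t + 1]] <- counts[tokens[t], tokens[t + 1]] + 1
    }
  }
  probs <- rels <- keys <- NULL
  for (i in 1:K) {
    for (j in 1:K) {
      if (counts[i, j] > 0) {
        a <- prior + counts[i, ]
        a0 <- sum(a)
        v <- a[j] * (a0 - a[j]) / (a0^2 * (a0 + 1))
        probs <- c(probs, a[j] / a0)
        rels <- c(rels, 1 / v)
        keys <- c(keys, paste(i, j))
      }
    }
  }
  zp <- if (length(probs) > 1 && sd(probs) > 0) (probs - mean(probs)) / sd(probs) else rep(0, length(probs))
  zr <- if (length(rels) > 1 && sd(rels) > 0) (rels - mean(rels)) / sd(rels) else rep(0, length(rels))
  good <- keys[zp > 0 & zr > 0 & zp * zr > c_thr]
  flags <- rep(FALSE, length(tokens) - 1)
  for (t in seq_len(length(tokens) - 1)) {
    flags[t] <- paste(tokens[t], tokens[t + 1]) %in% good
  }
  pats <- character(0)
  t <- 1
  while (t <= length(flags)) {
    if (flags[t]) {
      s <- t
      while (t <= length(flags) && flags[t]) t <- t + 1
      pats <- c(pats, paste(tokens[s:t], collapse = " "))
    } else t <- t + 1
  }
  sort(unique(pats))
}

# is x a contiguous subsequence of y?
is_contiguous_sub <- function(x, y) {
  lx <- length(x); ly <- length(y)
  if (lx > ly) return(FALSE)
  any(vapply(seq_len(ly - lx + 1),
             function(i) all(y[i:(i + lx - 1)] == x), logical(1)))
}

# hand-rolled format-0 SMF with explicit events (used to craft polyphonic
# and degenerate files the package writer refuses to produce)
raw_smf <- function(events, ticks_per_beat = 480) {
  u32 <- function(x) as.raw(c(x %/% 16777216, (x %/% 65536) %% 256,
                              (x %/% 256) %% 256, x %% 256))
  u16 <- function(x) as.raw(c(x %/% 256, x %% 256))
  track <- raw(0)
  for (e in events) track <- c(track, as.raw(e))
  track <- c(track, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))
  c(charToRaw("MThd"), u32(6), u16(0), u16(1), u16(ticks_per_beat),
    charToRaw("MTrk"), u32(length(track)), track)
}

default_fixture_tokens <- function(seed = 1, scheme = "pitch_duration") {
  tokenize(make_fixture_melody(40, 8, 4, 5, seed = seed), scheme)
}
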