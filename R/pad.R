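#' Parameters for probabilistic amplitude demodulation
#'
#' The modulator is modeled as the exponential of a stationary Gaussian
#' process; `modulator_timescale` sets the process correlation length in
#' seconds, equivalently a low-pass cutoff of `1/timescale` Hz on the
#' log-modulator (the default 0.1 s isolates sub-10 Hz modulation from a
#' faster carrier).  The carrier is white Gaussian with variance
#' `carrier_variance`.
#'
#' @param modulator_timescale GP correlation length in seconds (> 0)
#' @param carrier_variance variance of the white Gaussian carrier prior
#' @param max_iter maximum optimizer iterations for the MAP estimate
#' @param tol convergence tolerance on the relative change of the MAP
#'   objective
#' @param prior_variance marginal variance of the log-modulator GP
#' @return object of class `pad_params`
#' @export
pad_params <- function(modulator_timescale = 0.1, carrier_variance = 1,
                       max_iter = 200, tol = 1e-8, prior_variance = 1) {
  if (modulator_timescale <= 0) stop("modulator_timescale must be positive")
  if (tol <= 0) stop("tol must be positive")
  if (carrier_variance <= 0) stop("carrier_variance must be positive")
  structure(list(modulator_timescale = modulator_timescale,
                 carrier_variance = carrier_variance,
                 max_iter = as.integer(max_iter), tol = tol,
                 prior_variance = prior_variance), class = "pad_params")
}

# circulant GP prior eigenvalues on an n-point grid at rate fs:
# near-flat passband below the cutoff with a raised-cosine roll-off, small
# floor beyond (the prior is parameterized directly in the frequency domain)
.pad_prior_spectrum <- function(n, fs, cutoff, sigma2) {
  f <- fs * pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) / n
  hi <- cutoff * 1.3
  gain <- ifelse(f <= cutoff, 1,
                 ifelse(f >= hi, 0, 0.5 * (1 + cos(pi * (f - cutoff) / (hi - cutoff)))))
  lam <- sigma2 * (gain + 1e-6)
  lam[1] <- sigma2 * 100  # nearly-unpenalized mean level
  lam
}

#' MAP amplitude demodulation of a waveform
#'
#' Decomposes `y` into a slowly varying positive modulator `m` and a fast
#' carrier `c` with `y = m * c`.  The log-modulator carries a stationary
#' Gaussian-process prior (frequency-domain parameterized, cutoff
#' `1/modulator_timescale` Hz); the carrier is white Gaussian.
#' Marginalizing the carrier, `y_t | m_t ~ N(0, carrier_variance * m_t^2)`,
#' and the returned modulator maximizes the joint posterior over the
#' log-modulator via L-BFGS on a block-piecewise parameterization (blocks
#' much shorter than the modulator timescale, so the restriction is
#' immaterial).  The scale ambiguity of `(m, c)` is resolved by fixing
#' `mean(m)` to the RMS of the signal; the carrier is `y / m`, so
#' reconstruction is exact.
#'
#' @param wave a [waveform()], typically z-score normalized
#' @param params a [pad_params()]
#' @return object of class `demodulation`: `modulator`, `carrier`,
#'   `sample_rate`, `converged` (FALSE flags non-convergence within
#'   `max_iter`), `objective` (final negative log posterior), plus the
#'   internal coarse log-envelope used by [am_cascade()].
#' @export
demodulate <- function(wave, params = pad_params()) {
  y <- wave$samples
  sr <- wave$sample_rate
  cutoff <- 1 / params$modulator_timescale
  if (cutoff >= sr / 2) stop("modulator timescale too short for sample rate")
  fs_c <- min(sr, max(16 * cutoff, 32))
  B <- max(1L, round(sr / fs_c))
  fs_c <- sr / B
  n <- ceiling(length(y) / B)
  if (n < 4) stop("signal too short for the requested modulator timescale")
  pad_len <- n * B - length(y)
  y2 <- c(y, numeric(pad_len))^2
  S <- colSums(matrix(y2, nrow = B))
  if (max(S) < 1e-20) {   # silent signal: degenerate but well-defined
    m <- rep(1e-10, length(y))
    return(structure(list(modulator = m, carrier = y / m, sample_rate = sr,
                          converged = TRUE, objective = 0,
                          coarse = list(log_env = rep(log(1e-10), n),
                                        rate = fs_c, cutoff = cutoff)),
                     class = "demodulation"))
  }
  lam <- .pad_prior_spectrum(n, fs_c, cutoff, params$prior_variance)
  s2 <- params$carrier_variance
  Sb <- pmax(S, 1e-12)
  fn <- function(u) {
    U <- stats::fft(u)
    sum(0.5 * Sb * exp(-2 * u) / s2 + B * u) +
      0.5 * sum(Mod(U)^2 / lam) / n
  }
  gr <- function(u) {
    -Sb * exp(-2 * u) / s2 + B +
      Re(stats::fft(stats::fft(u) / lam, inverse = TRUE)) / n
  }
  u0 <- 0.5 * log(Sb / (B * s2))
  opt <- stats::optim(u0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = params$max_iter,
                                     factr = params$tol / .Machine$double.eps))
  u <- opt$par
  # upsample the block log-envelope to the full rate (block centers)
  centers <- (seq_len(n) - 0.5) * B
  x_full <- stats::approx(centers, u, xout = seq_along(y), rule = 2)$y
  m <- exp(x_full)
  m <- m * sqrt(mean(y^2)) / mean(m)
  structure(list(modulator = m, carrier = y / m, sample_rate = sr,
                 converged = opt$convergence == 0, objective = opt$value,
                 coarse = list(log_env = u + log(sqrt(mean(y^2)) / mean(exp(u))),
                               rate = fs_c, cutoff = cutoff)),
            class = "demodulation")
}

#' @export
print.demodulation <- function(x, ...) {
  cat(sprintf("PAD demodulation: %d samples at %g Hz, %s\n",
              length(x$modulator), x$sample_rate,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

.fft_lowpass <- function(x, cutoff, fs) {
  n <- length(x)
  f <- fs * pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) / n
  hi <- cutoff * 1.2
  gain <- ifelse(f <= cutoff, 1,
                 ifelse(f >= hi, 0, 0.5 * (1 + cos(pi * (f - cutoff) / (hi - cutoff)))))
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

#' Recursive AM cascade (scalogram) of a waveform
#'
#' The waveform is first demodulated into its full sub-cutoff amplitude
#' modulator.  The mean-removed log-domain modulator is then decomposed
#' recursively: at each level the current envelope is demodulated at the
#' next slower rate (a Gaussian-process MAP smoothing, which in the log
#' domain is an exact frequency-domain filter), and the component removed
#' at that level — the modulation between adjacent rate edges — is the
#' band envelope assigned to that band's nominal rate.  Band edges are the
#' geometric midpoints of the requested rates, so e.g. a 2 Hz amplitude
#' modulation lands in the band whose nominal rate is 2 Hz.  Band power is
#' the mean squared mean-removed band envelope.
#'
#' @param wave a [waveform()]
#' @param band_rates nominal band rates in Hz, strictly decreasing, all
#'   below the Nyquist rate (default `c(8, 4, 2, 1, 0.5)`, straddling the
#'   1-3 Hz phrase-rhythm range)
#' @param params a [pad_params()] for the first (nonlinear) demodulation
#' @return object of class `scalogram`: `band_rates`, `band_envelopes`
#'   (one row per band, log-domain, at the internal envelope rate
#'   `envelope_rate`), `band_power`.
#' @export
am_cascade <- function(wave, band_rates = c(8, 4, 2, 1, 0.5),
                       params = pad_params()) {
  J <- length(band_rates)
  if (J < 1) stop("need at least one band rate")
  if (J > 1 && any(diff(band_rates) >= 0))
    stop("band_rates must be strictly decreasing (fast to slow)")
  if (band_rates[1] >= wave$sample_rate / 2)
    stop("band rates must lie below the Nyquist rate")
  dm <- demodulate(wave, params)
  x <- dm$coarse$log_env
  fs_c <- dm$coarse$rate
  x <- x - mean(x)
  if (max(abs(x)) < 1e-12) {      # silent or constant input
    env <- matrix(0, J, length(x))
    return(structure(list(band_rates = band_rates, band_envelopes = env,
                          band_power = numeric(J), envelope_rate = fs_c),
                     class = "scalogram"))
  }
  edges <- numeric(J)
  for (j in seq_len(J)) {
    edges[j] <- if (j < J) sqrt(band_rates[j] * band_rates[j + 1])
                else band_rates[J] / sqrt(if (J > 1) band_rates[J - 1] / band_rates[J] else 2)
  }
  env <- matrix(0, J, length(x))
  for (j in seq_len(J)) {
    x_slow <- .fft_lowpass(x, edges[j], fs_c)
    env[j, ] <- x - x_slow
    x <- x_slow
  }
  power <- apply(env, 1, function(e) mean((e - mean(e))^2))
  structure(list(band_rates = band_rates, band_envelopes = env,
                 band_power = power, envelope_rate = fs_c),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat("AM cascade scalogram\n")
  print(data.frame(rate_hz = x$band_rates, power = x$band_power),
        row.names = FALSE)
  invisible(x)
}

#' Average AM band power over a corpus of waveforms
#'
#' Per-song band powers (from [am_cascade()]) averaged across songs.
#'
#' @param waves list of [waveform()] objects
#' @param band_rates passed to [am_cascade()]
#' @param params passed to [am_cascade()]
#' @return named numeric vector of mean band powers (names are the rates)
#' @export
corpus_band_power <- function(waves, band_rates = c(8, 4, 2, 1, 0.5),
                              params = pad_params()) {
  if (!length(waves)) stop("need at least one waveform")
  powers <- vapply(waves,
                   function(w) am_cascade(w, band_rates, params)$band_power,
                   numeric(length(band_rates)))
  out <- rowMeans(matrix(powers, nrow = length(band_rates)))
  names(out) <- paste0(band_rates, "Hz")
  out
}
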