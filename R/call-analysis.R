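#' A mono audio segment of a vocalization
#'
#' @param samples Numeric vector of finite samples (at least 0.05 s of
#'   audio).
#' @param sample_rate Sampling rate in Hz.
#' @param label Optional segment label.
#' @param airflow Phonation airflow: \code{"egressive"} (exhaled),
#'   \code{"ingressive"} (inhaled), or \code{"unknown"}.
#' @return An object of class \code{call_segment}.
#' @export
call_segment <- function(samples, sample_rate, label = NULL,
                         airflow = c("unknown", "egressive", "ingressive")) {
  airflow <- match.arg(airflow)
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    stop("'samples' must be finite numeric values", call. = FALSE)
  }
  if (sample_rate <= 0) stop("'sample_rate' must be positive", call. = FALSE)
  if (length(samples) < 0.05 * sample_rate) {
    stop("segment shorter than 0.05 s", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 sample_rate = as.numeric(sample_rate),
                 label = label, airflow = airflow),
            class = "call_segment")
}

#' Read a call segment from a WAV file
#'
#' @param path Path to a RIFF WAV file (PCM 16/24-bit or float32).
#' @param ... Passed to \code{\link{call_segment}} (\code{label},
#'   \code{airflow}).
#' @return A \code{\link{call_segment}}.
#' @export
read_call_segment <- function(path, ...) {
  w <- read_wav(path)
  call_segment(w$samples, w$sample_rate, ...)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

frame_starts <- function(n, frame_len, hop) {
  if (n <= frame_len) return(1L)
  seq(1L, n - frame_len + 1L, by = hop)
}

# Normalized autocorrelation of one frame up to lag_max, via FFT.
frame_autocorr <- function(x, lag_max) {
  x <- x - mean(x)
  nfft <- 2^ceiling(log2(2 * length(x)))
  r <- Re(stats::fft(Mod(stats::fft(c(x, numeric(nfft - length(x)))))^2,
                     inverse = TRUE))
  if (r[1] <= 0) return(numeric(lag_max + 1L))
  r[seq_len(lag_max + 1L)] / r[1]
}

#' Estimate fundamental frequency by frame-wise autocorrelation
#'
#' Each analysis frame contributes the frequency of its first strong
#' autocorrelation peak within the search range (first peak within 15% of
#' the maximum, guarding against octave errors), refined by parabolic
#' interpolation. The segment-level estimate is the median across voiced
#' frames. If fewer than half the frames are voiced (peak autocorrelation
#' below \code{voicing_threshold}), the segment is declared unvoiced.
#'
#' @param segment A \code{\link{call_segment}}.
#' @param f_min,f_max Search range in Hz (default 60-600).
#' @param frame_s Frame length in seconds (default 0.05).
#' @param hop_s Hop between frames in seconds (default 0.01).
#' @param voicing_threshold Minimum normalized autocorrelation for a frame
#'   to count as voiced (default 0.5).
#' @return Median f0 in Hz, or \code{NA_real_} when no periodicity is
#'   found ("no f0").
#' @export
estimate_f0 <- function(segment, f_min = 60, f_max = 600,
                        frame_s = 0.05, hop_s = 0.01,
                        voicing_threshold = 0.5) {
  stopifnot(inherits(segment, "call_segment"))
  x <- segment$samples
  sr <- segment$sample_rate
  frame_len <- min(length(x), round(frame_s * sr))
  hop <- max(1L, round(hop_s * sr))
  lag_min <- max(2L, floor(sr / f_max))
  lag_max <- min(frame_len - 1L, ceiling(sr / f_min))
  if (lag_max <= lag_min) stop("segment too short for the f0 search range",
                               call. = FALSE)
  starts <- frame_starts(length(x), frame_len, hop)
  f0s <- rep(NA_real_, length(starts))
  for (j in seq_along(starts)) {
    fr <- x[starts[j] + seq_len(frame_len) - 1L]
    r <- frame_autocorr(fr, lag_max)
    lags <- (lag_min + 1L):(lag_max + 1L)    # r is 1-indexed at lag 0
    rr <- r[lags]
    peaks <- local_maxima(rr)
    if (!length(peaks)) next
    best <- max(rr[peaks])
    if (best < voicing_threshold) next
    p <- peaks[which(rr[peaks] >= best - 0.15 * abs(best))[1]]
    i <- lags[p]
    denom <- r[i - 1L] - 2 * r[i] + r[i + 1L]
    delta <- if (is.finite(denom) && abs(denom) > .Machine$double.eps) {
      max(-0.5, min(0.5, 0.5 * (r[i - 1L] - r[i + 1L]) / denom))
    } else 0
    f0s[j] <- sr / (i - 1L + delta)
  }
  voiced <- f0s[!is.na(f0s)]
  if (length(voiced) < 0.5 * length(starts)) return(NA_real_)
  stats::median(voiced)
}

#' Long-term average spectrum of a call segment
#'
#' Welch-averaged power spectrum over Hann-windowed frames (25 ms window,
#' 10 ms hop by default), the working representation behind formant
#' estimation and the spectrogram-style exports.
#'
#' @param segment A \code{\link{call_segment}}.
#' @param frame_s,hop_s Frame length and hop in seconds.
#' @return An object of class \code{spectral_envelope}: a list with
#'   \code{frequencies} (Hz), \code{level_db} (dB, 0 dB at the maximum),
#'   and \code{f0_estimate} (Hz, or \code{NA} when unvoiced).
#' @export
spectral_envelope <- function(segment, frame_s = 0.025, hop_s = 0.01) {
  stopifnot(inherits(segment, "call_segment"))
  x <- segment$samples
  sr <- segment$sample_rate
  frame_len <- min(length(x), round(frame_s * sr))
  nfft <- 2^ceiling(log2(frame_len))
  hop <- max(1L, round(hop_s * sr))
  win <- hann_window(frame_len)
  starts <- frame_starts(length(x), frame_len, hop)
  acc <- numeric(nfft %/% 2L + 1L)
  for (s in starts) {
    fr <- x[s + seq_len(frame_len) - 1L] * win
    spec <- Mod(stats::fft(c(fr, numeric(nfft - frame_len))))^2
    acc <- acc + spec[seq_len(nfft %/% 2L + 1L)]
  }
  acc <- acc / length(starts)
  db <- 10 * log10(pmax(acc, .Machine$double.xmin))
  structure(list(frequencies = (seq_len(nfft %/% 2L + 1L) - 1L) * sr / nfft,
                 level_db = db - max(db),
                 f0_estimate = estimate_f0(segment)),
            class = "spectral_envelope")
}

# Sharpen an autocorrelation f0 estimate by maximizing summed harmonic
# energy of a comb at k * f over a +/- 4% interval.
refine_f0_comb <- function(x, sr, f0, n_harm = 6L) {
  n <- length(x)
  t <- (seq_len(n) - 1L) / sr
  w <- hann_window(n)
  xw <- x * w
  comb_energy <- function(f) {
    ks <- seq_len(n_harm)
    ks <- ks[ks * f < sr / 2]
    sum(vapply(ks, function(k)
      Mod(sum(xw * exp(-2i * pi * k * f * t)))^2, numeric(1)))
  }
  stats::optimize(comb_energy, lower = 0.96 * f0, upper = 1.04 * f0,
                  maximum = TRUE, tol = 0.01)$maximum
}

# Amplitudes (dB) of harmonics k * f0 up to f_max, by windowed DFT at the
# exact harmonic frequencies. The local noise floor is the mean power over
# six off-harmonic offsets (outside the analysis-window main lobe), and is
# power-subtracted from each harmonic to debias levels near the floor.
# Levels clamped 80 dB below the strongest harmonic.
harmonic_amplitudes <- function(x, sr, f0, f_max) {
  n <- length(x)
  t <- (seq_len(n) - 1L) / sr
  w <- hann_window(n)
  xw <- x * w
  freqs <- seq(f0, min(f_max, sr / 2 - f0 / 2), by = f0)
  power_at <- function(f) Mod(sum(xw * exp(-2i * pi * f * t)))^2
  offsets <- c(-0.5, -0.35, -0.2, 0.2, 0.35, 0.5) * f0
  p <- vapply(freqs, power_at, numeric(1))
  pn <- vapply(freqs, function(f)
    mean(vapply(f + offsets, power_at, numeric(1))), numeric(1))
  # robust broadband floor: the median off-harmonic power; per-harmonic
  # off-grid power next to a strong harmonic measures window leakage, not
  # noise, and would penalize exactly the informative harmonics
  p_floor <- stats::median(pn)
  corr <- 10 * log10(pmax(p - p_floor, .Machine$double.xmin))
  top <- max(corr)
  data.frame(frequency = freqs, level_db = pmax(corr, top - 80),
             floor_db = pmax(10 * log10(p_floor), top - 80))
}

# Interior local maxima of y, with topographic prominence. The left
# boundary also counts as a peak candidate when the curve falls away from
# it (an F1 at or below the first harmonic); the right boundary never does
# (a rising curve edge is a truncation artefact, not a resonance).
envelope_peaks <- function(x, y) {
  idx <- local_maxima(y)
  n <- length(y)
  if (n >= 2L && y[1] > y[2]) idx <- c(1L, idx)
  if (!length(idx)) return(data.frame(frequency = numeric(),
                                      level_db = numeric(),
                                      prominence = numeric()))
  data.frame(frequency = x[idx], level_db = y[idx],
             prominence = peak_prominences(y, idx))
}

# Analog formant-resonator magnitude (dB) at frequencies f.
resonance_db <- function(f, Fc, B) {
  num <- Fc^2 + (B / 2)^2
  20 * log10(num / sqrt(((f - Fc)^2 + (B / 2)^2) *
                          ((f + Fc)^2 + (B / 2)^2)))
}

# Analysis-by-synthesis refinement: least-squares fit of a
# cascade-resonator + spectral-tilt envelope model to the measured harmonic
# amplitudes, starting from the peak-picked estimates. Returns the fitted
# formants and the residual sum of squares (Inf when the fit could not
# run), so callers can compare alternative starts.
refine_by_synthesis <- function(harm, init_formants, bandwidths, f0,
                                tilt_db_per_octave = 12) {
  nf <- length(init_formants)
  keep <- harm$frequency <= max(init_formants) * 1.6 + 2 * f0
  h <- harm[keep, , drop = FALSE]
  # harmonics weighted by SNR above the broadband floor; at the floor they
  # drop out
  w <- pmin(1, pmax(0, (h$level_db - h$floor_db) / 20))
  n_inform <- sum(w > 0.15)
  if (n_inform < nf + 1L) {
    return(list(formants = init_formants, sse = Inf))
  }
  f_hi <- max(h$frequency[w > 0.15]) + f0  # no data beyond; keep fit inside
  lf <- log2(h$frequency / h$frequency[1])
  # with plentiful harmonics the source tilt is a free linear term; with
  # few, fix it at the assumed glottal roll-off so the fit stays well-posed
  free_tilt <- n_inform >= nf + 3L
  X <- if (free_tilt) w * cbind(1, lf) else w * cbind(rep(1, nrow(h)))
  model_db <- function(formants) {
    env <- rowSums(vapply(seq_len(nf), function(i)
      resonance_db(h$frequency, formants[i], bandwidths[i]),
      numeric(nrow(h))))
    target <- h$level_db - env
    if (!free_tilt) target <- target + tilt_db_per_octave * lf
    fit <- stats::lm.fit(X, w * target)
    sum(fit$residuals^2)
  }
  obj <- function(par) {
    formants <- par
    if (any(formants <= 0.5 * f0) || any(formants >= f_hi) ||
        any(diff(formants) < 50)) return(1e9)
    model_db(formants)
  }
  fit <- stats::optim(init_formants, obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  if (!is.finite(fit$value) || fit$value >= 1e9) {
    return(list(formants = init_formants, sse = Inf))
  }
  list(formants = sort(fit$par), sse = fit$value)
}

# Candidate (F1, F2) starting points when peak picking found fewer than two
# envelope maxima: two resonances too close to separate visually can still
# be resolved by the model fit from several displaced starts.
two_formant_starts <- function(found, harm, f0) {
  anchor <- if (length(found)) {
    found[1]
  } else {
    harm$frequency[which.max(harm$level_db)]
  }
  gap <- max(2 * f0, 300)
  starts <- list(c(anchor, anchor + gap),
                 c(max(anchor - gap, 0.6 * f0 + 25), anchor),
                 c(anchor / 1.5, anchor * 1.5),
                 c(anchor, anchor * 2))
  Filter(function(s) all(s > 0.5 * f0) && diff(s) >= 50, starts)
}

# Cepstrally smoothed envelope of the long-term average spectrum; fallback
# when no f0 can be established.
cepstral_envelope <- function(env, quefrency_cutoff_s = 0.002) {
  db <- env$level_db
  n <- length(db)
  sym <- c(db, rev(db[2:(n - 1L)]))
  ceps <- Re(stats::fft(sym, inverse = TRUE)) / length(sym)
  df <- env$frequencies[2] - env$frequencies[1]
  cut <- max(2L, round(quefrency_cutoff_s * length(sym) * df))
  lifter <- numeric(length(sym))
  lifter[seq_len(cut)] <- 1
  lifter[length(sym) - seq_len(cut - 1L) + 1L] <- 1
  smooth <- Re(stats::fft(ceps * lifter))[seq_len(n)]
  data.frame(frequency = env$frequencies, level_db = smooth)
}

#' Estimate formants from audio via harmonic spectral-envelope analysis
#'
#' Measures the amplitudes of the harmonics of the estimated f0 from the
#' long-term spectrum, interpolates a spectral envelope through them, picks
#' the most prominent envelope maxima, and (by default) refines the
#' estimates by analysis-by-synthesis: a least-squares fit of a
#' cascade-resonator plus spectral-tilt envelope model to the harmonic
#' amplitudes. This follows the visual-inspection / synthesizer-matching
#' tradition for high-f0 vocalizations and deliberately avoids linear
#' predictive coding, which mistakes harmonics for formants when f0 is high.
#'
#' When f0 overlaps F1 the envelope maximum may coincide with the first
#' harmonic; F1 is still reported there, with an \code{"f0_coincident"}
#' flag. When no f0 can be established the estimator falls back to peaks of
#' the cepstrally smoothed average spectrum (flag \code{"no_f0"}). When
#' fewer peaks than requested are found, a partial estimate is returned
#' with a warning (flag \code{"partial"}).
#'
#' @param segment A \code{\link{call_segment}}.
#' @param n_formants Number of formants requested (default 2).
#' @param f_max Upper frequency bound for the harmonic analysis in Hz
#'   (default 2600).
#' @param min_prominence_db Minimum envelope-peak prominence in dB
#'   (default 2).
#' @param refine Apply the analysis-by-synthesis refinement? Default
#'   \code{TRUE}.
#' @param bandwidths Resonator bandwidths assumed by the refinement model
#'   (defaults 60, 90, then 120 Hz).
#' @param tilt_db_per_octave Assumed source spectral slope in dB/octave,
#'   compensated before peak picking (default 12, the classic glottal
#'   -source roll-off). Without compensation the strong low harmonics mask
#'   the formant peaks.
#' @return A \code{\link{formant_estimate}} with provenance \code{"audio"}
#'   and flags as described above.
#' @export
estimate_formants <- function(segment, n_formants = 2, f_max = 2600,
                              min_prominence_db = 2, refine = TRUE,
                              bandwidths = NULL, tilt_db_per_octave = 12) {
  stopifnot(inherits(segment, "call_segment"))
  if (n_formants < 1) stop("'n_formants' must be >= 1", call. = FALSE)
  if (is.null(bandwidths)) {
    bandwidths <- c(60, 90, rep(120, max(0L, n_formants - 2L)))[
      seq_len(n_formants)]
  }
  x <- segment$samples
  sr <- segment$sample_rate
  f0 <- estimate_f0(segment)
  flags <- character()

  if (is.na(f0)) {
    env <- spectral_envelope(segment)
    sm <- cepstral_envelope(env)
    keep <- sm$frequency >= 60 & sm$frequency <= f_max
    pk <- envelope_peaks(sm$frequency[keep], sm$level_db[keep])
    flags <- "no_f0"
  } else {
    f0 <- refine_f0_comb(x, sr, f0)
    harm <- harmonic_amplitudes(x, sr, f0, f_max)
    # peak picking uses only harmonics clearly above the noise floor:
    # tilt-compensated floor-level harmonics would fabricate rising edges
    hp <- harm[harm$level_db > harm$floor_db + 6, , drop = FALSE]
    if (nrow(hp) == 0L) hp <- harm[which.max(harm$level_db), , drop = FALSE]
    comp <- hp$level_db +
      tilt_db_per_octave * log2(hp$frequency / hp$frequency[1])
    if (nrow(hp) >= 4L) {
      grid <- seq(hp$frequency[1], hp$frequency[nrow(hp)], by = 2)
      env_db <- stats::spline(hp$frequency, comp, xout = grid,
                              method = "natural")$y
    } else {
      grid <- hp$frequency
      env_db <- comp
    }
    pk <- envelope_peaks(grid, env_db)
  }

  pk <- pk[pk$prominence >= min_prominence_db, , drop = FALSE]
  if (nrow(pk) == 0L && is.na(f0)) {
    stop("0 envelope peaks found; cannot estimate formants", call. = FALSE)
  }
  pk <- pk[order(-pk$prominence), , drop = FALSE]
  sel <- sort(pk$frequency[seq_len(min(n_formants, nrow(pk)))])

  if (refine && !is.na(f0)) {
    if (length(sel) == n_formants) {
      sel <- refine_by_synthesis(harm, sel, bandwidths, f0,
                                 tilt_db_per_octave)$formants
    } else if (n_formants == 2L) {
      # merged or masked peaks: resolve by model fit from several starts
      fits <- lapply(two_formant_starts(sel, harm, f0),
                     refine_by_synthesis, harm = harm,
                     bandwidths = bandwidths, f0 = f0,
                     tilt_db_per_octave = tilt_db_per_octave)
      sse <- vapply(fits, `[[`, numeric(1), "sse")
      if (any(is.finite(sse))) {
        sel <- fits[[which.min(sse)]]$formants
        flags <- c(flags, "merged_peaks")
      }
    }
  }
  if (length(sel) == 0L) {
    if (is.na(f0)) {
      stop("0 envelope peaks found; cannot estimate formants", call. = FALSE)
    }
    sel <- harm$frequency[which.max(harm$level_db)]  # strongest harmonic
  }
  if (length(sel) < n_formants) {
    flags <- c(flags, "partial")
    warning(sprintf("only %d of %d requested formant peaks found",
                    length(sel), n_formants), call. = FALSE)
  }
  if (!is.na(f0) && length(sel) >= 1L && abs(sel[1] - f0) <= f0 / 2) {
    flags <- c(flags, "f0_coincident")
  }
  formant_estimate(sel, provenance = "audio", flags = flags)
}

#' Export a spectrogram-style matrix for a call segment
#'
#' Frame-by-frame Hann-windowed power spectra (dB), written as a CSV matrix
#' with one row per analysis frame and one column per frequency bin. The
#' default 300 Hz analysis bandwidth (about 3 ms frames) matches wide-band
#' spectrogram practice for formant display.
#'
#' @param segment A \code{\link{call_segment}}.
#' @param path Output CSV path.
#' @param analysis_bandwidth_hz Analysis bandwidth in Hz (default 300);
#'   frame length is its reciprocal.
#' @param hop_s Hop between frames in seconds (default 0.002).
#' @return \code{path}, invisibly.
#' @export
write_spectrogram_csv <- function(segment, path,
                                  analysis_bandwidth_hz = 300,
                                  hop_s = 0.002) {
  stopifnot(inherits(segment, "call_segment"))
  sr <- segment$sample_rate
  frame_len <- min(length(segment$samples),
                   max(8L, round(sr / analysis_bandwidth_hz)))
  nfft <- 2^ceiling(log2(frame_len))
  win <- hann_window(frame_len)
  starts <- frame_starts(length(segment$samples), frame_len,
                         max(1L, round(hop_s * sr)))
  mat <- t(vapply(starts, function(s) {
    fr <- segment$samples[s + seq_len(frame_len) - 1L] * win
    spec <- Mod(stats::fft(c(fr, numeric(nfft - frame_len))))^2
    10 * log10(pmax(spec[seq_len(nfft %/% 2L + 1L)], .Machine$double.xmin))
  }, numeric(nfft %/% 2L + 1L)))
  colnames(mat) <- sprintf("hz_%.1f", (seq_len(ncol(mat)) - 1L) * sr / nfft)
  df <- data.frame(time_s = (starts - 1L) / sr, mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
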