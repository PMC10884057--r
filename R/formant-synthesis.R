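#' Specification for cascade formant synthesis
#'
#' @param formants Strictly increasing formant frequencies in Hz (at least
#'   one; two for an F1-F2 vowel dispersion), all below the Nyquist
#'   frequency.
#' @param bandwidths Formant bandwidths in Hz, same length as
#'   \code{formants}. Defaults to 60 Hz for F1, 90 Hz for F2, and 120 Hz for
#'   each higher formant (typical cascade-synthesizer values).
#' @param f0 Fundamental frequency in Hz (default 100; low f0 preserves
#'   vowel quality, which degrades as the harmonics sample the envelope more
#'   sparsely).
#' @param duration Duration in seconds (default 2).
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param source \code{"tilted"} (impulse train through a -12 dB/octave
#'   spectral-tilt filter, default) or \code{"impulse"} (flat-spectrum
#'   impulse train).
#' @param seed Integer seed reserved for stochastic source components
#'   (jitter/noise); the default synthesis path is fully deterministic.
#' @return An object of class \code{synthesis_spec}.
#' @examples
#' synthesis_spec(c(358.75, 896.25))
#' @export
synthesis_spec <- function(formants, bandwidths = NULL, f0 = 100,
                           duration = 2, sample_rate = 16000,
                           source = c("tilted", "impulse"), seed = 0L) {
  source <- match.arg(source)
  if (length(formants) < 1L || any(!is.finite(formants)) ||
      any(formants <= 0)) {
    stop("'formants' must be positive finite frequencies", call. = FALSE)
  }
  if (is.unsorted(formants, strictly = TRUE)) {
    stop("'formants' must be strictly increasing", call. = FALSE)
  }
  if (any(formants >= sample_rate / 2)) {
    stop("all formants must lie below the Nyquist frequency ",
         sample_rate / 2, " Hz", call. = FALSE)
  }
  if (is.null(bandwidths)) {
    bandwidths <- c(60, 90, rep(120, max(0L, length(formants) - 2L)))
    bandwidths <- bandwidths[seq_along(formants)]
  }
  if (length(bandwidths) != length(formants) || any(bandwidths <= 0)) {
    stop("'bandwidths' must be positive and match 'formants' in length",
         call. = FALSE)
  }
  if (f0 <= 0) stop("'f0' must be positive", call. = FALSE)
  if (duration <= 0) stop("'duration' must be positive", call. = FALSE)
  if (sample_rate <= 0) stop("'sample_rate' must be positive", call. = FALSE)
  structure(list(formants = as.numeric(formants),
                 bandwidths = as.numeric(bandwidths),
                 f0 = as.numeric(f0), duration = as.numeric(duration),
                 sample_rate = as.numeric(sample_rate),
                 source = source, seed = as.integer(seed)),
            class = "synthesis_spec")
}

# Second-order digital resonator (impulse-invariant mapping of the analog
# formant resonance): y[n] = A x[n] + B y[n-1] + C y[n-2].
resonator_filter <- function(x, f, bw, sr) {
  C <- -exp(-2 * pi * bw / sr)
  B <- 2 * exp(-pi * bw / sr) * cos(2 * pi * f / sr)
  A <- 1 - B - C
  as.numeric(stats::filter(A * x, c(B, C), method = "recursive"))
}

#' Synthesize a vowel from a formant specification
#'
#' Source-filter synthesis: a glottal impulse train at \code{f0} (with a
#' -12 dB/octave spectral-tilt filter by default) passed through a cascade
#' of second-order resonators, one per formant. The output is normalized to
#' a peak amplitude of 0.9 and is deterministic for a fixed spec.
#'
#' @param spec A \code{\link{synthesis_spec}}.
#' @return A list of class \code{waveform} with \code{samples} (numeric,
#'   length \code{round(duration * sample_rate)}, peak |amplitude| 0.9) and
#'   \code{sample_rate}.
#' @examples
#' w <- synthesize_vowel(synthesis_spec(c(358.75, 896.25), duration = 0.2))
#' length(w$samples)  # 3200
#' @export
synthesize_vowel <- function(spec) {
  stopifnot(inherits(spec, "synthesis_spec"))
  sr <- spec$sample_rate
  n <- round(spec$duration * sr)
  # pulse onsets at multiples of the period, quantized to the sample grid
  pulse_idx <- unique(floor(seq(0, spec$duration, by = 1 / spec$f0) * sr)) + 1L
  pulse_idx <- pulse_idx[pulse_idx <= n]
  x <- numeric(n)
  x[pulse_idx] <- 1
  if (spec$source == "tilted") {
    # two leaky one-pole integrators: -12 dB/octave above ~100 Hz
    p <- exp(-2 * pi * 100 / sr)
    x <- as.numeric(stats::filter((1 - p) * x, p, method = "recursive"))
    x <- as.numeric(stats::filter((1 - p) * x, p, method = "recursive"))
  }
  for (i in seq_along(spec$formants)) {
    x <- resonator_filter(x, spec$formants[i], spec$bandwidths[i], sr)
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x * (0.9 / peak)
  structure(list(samples = x, sample_rate = sr), class = "waveform")
}

#' Synthesize a vowel and write it to a WAV file
#'
#' @param spec A \code{\link{synthesis_spec}}.
#' @param path Output WAV path (16-bit PCM mono).
#' @return \code{path}, invisibly.
#' @export
synthesize_to_wav <- function(spec, path) {
  w <- synthesize_vowel(spec)
  write_wav(w$samples, w$sample_rate, path)
}
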