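# Shared fixtures built in code.

# A synthesized vowel segment, optionally with additive broadband noise.
make_vowel_segment <- function(f1, f2, f0 = 100, duration = 0.5,
                               snr_db = Inf, sample_rate = 16000) {
  w <- synthesize_vowel(synthesis_spec(c(f1, f2), f0 = f0,
                                       duration = duration,
                                       sample_rate = sample_rate))
  x <- w$samples
  if (is.finite(snr_db)) {
    x <- x + stats::rnorm(length(x), 0, sqrt(mean(x^2)) * 10^(-snr_db / 20))
  }
  call_segment(x, sample_rate)
}

# First two formants, silently tolerating partial-estimate warnings.
quiet_f1f2 <- function(segment, ...) {
  est <- suppressWarnings(estimate_formants(segment, ...))
  fs <- formant_frequencies(est)
  if (length(fs) < 2) c(fs, NA_real_)[1:2] else fs[1:2]
}

# A transfer_function object with prescribed magnitudes, for peak-picker
# edge cases.
fake_tf <- function(frequencies, magnitude_db) {
  structure(list(frequencies = frequencies, magnitude_db = magnitude_db),
            f_step = frequencies[2] - frequencies[1],
            class = "transfer_function")
}
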