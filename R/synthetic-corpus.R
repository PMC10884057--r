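#' Specification for a synthetic hoo-call corpus
#'
#' Defaults reproduce the statistical structure of a small field sample of
#' chimpanzee hoo calls: 8 egressive segments from 3 individuals, mean
#' duration 0.61 s (SD 0.31), F1 358.75 Hz (SD 56.93), F2 896.25 Hz
#' (SD 133.04), with the fundamental frequency lying in the F1 region
#' (mean 300 Hz), so that f0 and F1 overlap as they do in real hoo calls.
#'
#' @param n_calls Number of calls (default 8).
#' @param n_individuals Number of callers (default 3); calls are assigned
#'   round-robin.
#' @param duration_mean,duration_sd,duration_min Call duration distribution
#'   in seconds: normal, truncated below at \code{duration_min} (defaults
#'   0.61, 0.31, 0.1).
#' @param f1_mean,f1_sd,f2_mean,f2_sd Formant-target distributions in Hz
#'   (defaults 358.75/56.93 and 896.25/133.04); per call, (F1, F2) are drawn
#'   independently and redrawn until F1 + 50 Hz < F2.
#' @param f0_mean,f0_sd Fundamental frequency in Hz (defaults 300/30). Each
#'   individual carries a shared offset and each call adds jitter; the two
#'   components split the variance 64/36 so the across-call SD is
#'   \code{f0_sd}.
#' @param noise_snr_db Broadband-noise signal-to-noise ratio in dB
#'   (default 25).
#' @param sample_rate Sampling rate in Hz (default 16000).
#' @param seed Integer seed; the corpus is fully reproducible from it.
#' @return An object of class \code{corpus_spec}.
#' @export
corpus_spec <- function(n_calls = 8, n_individuals = 3,
                        duration_mean = 0.61, duration_sd = 0.31,
                        duration_min = 0.1,
                        f1_mean = 358.75, f1_sd = 56.93,
                        f2_mean = 896.25, f2_sd = 133.04,
                        f0_mean = 300, f0_sd = 30,
                        noise_snr_db = 25, sample_rate = 16000,
                        seed = 0L) {
  s <- list(n_calls = as.integer(n_calls),
            n_individuals = as.integer(n_individuals),
            duration_mean = duration_mean, duration_sd = duration_sd,
            duration_min = duration_min,
            f1_mean = f1_mean, f1_sd = f1_sd,
            f2_mean = f2_mean, f2_sd = f2_sd,
            f0_mean = f0_mean, f0_sd = f0_sd,
            noise_snr_db = noise_snr_db, sample_rate = sample_rate,
            seed = as.integer(seed))
  if (s$n_calls < 1L) stop("'n_calls' must be >= 1", call. = FALSE)
  if (s$n_individuals < 1L) stop("'n_individuals' must be >= 1", call. = FALSE)
  for (field in c("duration_sd", "f1_sd", "f2_sd", "f0_sd")) {
    if (s[[field]] < 0) stop(sprintf("'%s' must be >= 0", field), call. = FALSE)
  }
  for (field in c("duration_mean", "duration_min", "f1_mean", "f2_mean",
                  "f0_mean", "sample_rate")) {
    if (s[[field]] <= 0) stop(sprintf("'%s' must be positive", field),
                              call. = FALSE)
  }
  numeric_fields <- setdiff(names(s), c("n_calls", "n_individuals", "seed"))
  s[numeric_fields] <- lapply(s[numeric_fields], as.numeric)
  structure(s, class = "corpus_spec")
}

#' Read a corpus specification from a YAML or JSON file
#'
#' Recognized keys match the arguments of \code{\link{corpus_spec}}.
#'
#' @param path Path to a YAML file.
#' @return A \code{\link{corpus_spec}}.
#' @export
read_corpus_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  keys <- names(formals(corpus_spec))
  unknown <- setdiff(names(cfg), keys)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(corpus_spec, cfg[intersect(names(cfg), keys)])
}

draw_truncated_normal <- function(mean, sd, lower, what, max_attempts = 1000L) {
  for (i in seq_len(max_attempts)) {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lower) return(v)
  }
  stop(sprintf(
    "could not draw %s >= %g in %d attempts; check the mean/sd fields",
    what, lower, max_attempts), call. = FALSE)
}

draw_formant_pair <- function(spec, max_attempts = 1000L) {
  for (i in seq_len(max_attempts)) {
    f1 <- stats::rnorm(1, spec$f1_mean, spec$f1_sd)
    f2 <- stats::rnorm(1, spec$f2_mean, spec$f2_sd)
    if (f1 > 0 && f1 + 50 < f2 && f2 < spec$sample_rate / 2) {
      return(c(f1, f2))
    }
  }
  stop(paste("could not draw F1 + 50 Hz < F2 in", max_attempts,
             "attempts; check f1_mean/f1_sd/f2_mean/f2_sd"), call. = FALSE)
}

#' Generate a synthetic hoo-call corpus with ground truth
#'
#' Draws per-call durations, formant targets, and fundamental frequencies
#' from the distributions in the spec, synthesizes each call as an
#' egressive vowel-like segment (cascade formant synthesis with a raised
#' -cosine onset/offset ramp), and adds broadband noise at the specified
#' SNR. All random draws derive from \code{spec$seed}, so the corpus is
#' byte-reproducible; the global RNG state is left untouched.
#'
#' Ground-truth draws are completed before any audio is rendered, so the
#' ground-truth table is identical whether or not audio is rendered.
#'
#' @param spec A \code{\link{corpus_spec}}.
#' @param render_audio Render waveforms (default \code{TRUE})? With
#'   \code{FALSE}, only the ground-truth table is produced (fast path for
#'   distributional checks on large corpora).
#' @return A list of class \code{call_corpus} with \code{ground_truth} (a
#'   data frame with columns \code{call_id}, \code{individual_id},
#'   \code{duration_s}, \code{f1_hz}, \code{f2_hz}, \code{f0_hz},
#'   \code{seed}) and \code{segments} (a list of
#'   \code{\link{call_segment}}, or \code{NULL} entries when audio is not
#'   rendered).
#' @examples
#' corpus <- generate_corpus(corpus_spec(n_calls = 2, seed = 1))
#' corpus$ground_truth
#' @export
generate_corpus <- function(spec, render_audio = TRUE) {
  stopifnot(inherits(spec, "corpus_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_calls
    individual <- rep_len(seq_len(spec$n_individuals), n)
    # shared per-individual f0 offset plus per-call jitter (0.8/0.6 split)
    offsets <- stats::rnorm(spec$n_individuals, 0, 0.8 * spec$f0_sd)
    gt <- data.frame(call_id = sprintf("call_%03d", seq_len(n)),
                     individual_id = sprintf("ind_%d", individual),
                     duration_s = NA_real_, f1_hz = NA_real_,
                     f2_hz = NA_real_, f0_hz = NA_real_,
                     seed = spec$seed, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      gt$duration_s[i] <- draw_truncated_normal(
        spec$duration_mean, spec$duration_sd, spec$duration_min, "a duration")
      ff <- draw_formant_pair(spec)
      gt$f1_hz[i] <- ff[1]
      gt$f2_hz[i] <- ff[2]
      f0 <- offsets[individual[i]] + spec$f0_mean +
        stats::rnorm(1, 0, 0.6 * spec$f0_sd)
      gt$f0_hz[i] <- max(f0, 60)
    }
    segments <- vector("list", n)
    if (render_audio) {
      for (i in seq_len(n)) {
        w <- synthesize_vowel(synthesis_spec(
          formants = c(gt$f1_hz[i], gt$f2_hz[i]), f0 = gt$f0_hz[i],
          duration = gt$duration_s[i], sample_rate = spec$sample_rate))
        x <- w$samples * amplitude_ramp(length(w$samples), spec$sample_rate)
        if (is.finite(spec$noise_snr_db)) {
          sig_rms <- sqrt(mean(x^2))
          noise_sd <- sig_rms * 10^(-spec$noise_snr_db / 20)
          x <- x + stats::rnorm(length(x), 0, noise_sd)
        }
        peak <- max(abs(x))
        if (peak > 0.9) x <- x * (0.9 / peak)
        segments[[i]] <- call_segment(x, spec$sample_rate,
                                      label = gt$call_id[i],
                                      airflow = "egressive")
      }
    }
    structure(list(ground_truth = gt, segments = segments,
                   spec = spec), class = "call_corpus")
  })
}

# Raised-cosine onset/offset ramp: 50 ms or 10% of the call, whichever is
# shorter.
amplitude_ramp <- function(n, sr) {
  ramp_len <- max(1L, min(round(0.05 * sr), floor(n / 10)))
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(ramp_len) / ramp_len)
  env <- rep(1, n)
  env[seq_len(ramp_len)] <- ramp
  env[n - seq_len(ramp_len) + 1L] <- ramp
  env
}

#' Write a corpus to disk as WAV files plus a ground-truth CSV
#'
#' One 16-bit PCM WAV per call, named after \code{call_id}, plus
#' \code{ground_truth.csv}.
#'
#' @param corpus A \code{\link{generate_corpus}} result with rendered audio.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "call_corpus"))
  if (any(vapply(corpus$segments, is.null, logical(1)))) {
    stop("corpus has unrendered audio; regenerate with render_audio = TRUE",
         call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(corpus$segments)) {
    seg <- corpus$segments[[i]]
    write_wav(seg$samples, seg$sample_rate,
              file.path(dir, paste0(corpus$ground_truth$call_id[i], ".wav")))
  }
  utils::write.csv(corpus$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
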