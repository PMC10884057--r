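#' Cylindrical tube segment
#'
#' A single cylindrical element of a vocal tract area function, described by
#' its axial length and cross-sectional area.
#'
#' @param length Segment length in centimetres (> 0).
#' @param area Cross-sectional area in square centimetres (> 0).
#' @return An object of class \code{tube_segment}: a named list with elements
#'   \code{length} and \code{area}.
#' @examples
#' tube_segment(18, 1)
#' @export
tube_segment <- function(length, area) {
  if (!is.numeric(length) || length(length) != 1L || !is.finite(length) ||
      length <= 0) {
    stop("'length' must be a single positive finite number (cm)", call. = FALSE)
  }
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) ||
      area <= 0) {
    stop("'area' must be a single positive finite number (cm^2)", call. = FALSE)
  }
  structure(list(length = as.numeric(length), area = as.numeric(area)),
            class = "tube_segment")
}

#' Ordered sequence of tube segments (discretized area function)
#'
#' Segments are ordered from the glottis (volume-velocity source) end to the
#' lip (radiating) end. The sequence is stored as a data frame with columns
#' \code{length} and \code{area}, both in CGS units (cm, cm^2).
#'
#' @param lengths Numeric vector of segment lengths in cm, glottis first;
#'   alternatively a list of \code{\link{tube_segment}} objects (then
#'   \code{areas} is ignored).
#' @param areas Numeric vector of cross-sectional areas in cm^2, same length
#'   as \code{lengths}.
#' @return An object of class \code{tube_sequence}: a data frame with columns
#'   \code{length} and \code{area} and attribute \code{total_length}.
#' @examples
#' tube_sequence(c(2, 18, 0.2), c(30, 1, 0.5))
#' @export
tube_sequence <- function(lengths, areas = NULL) {
  if (is.list(lengths) && length(lengths) > 0L &&
      all(vapply(lengths, inherits, logical(1), "tube_segment"))) {
    areas <- vapply(lengths, `[[`, numeric(1), "area")
    lengths <- vapply(lengths, `[[`, numeric(1), "length")
  }
  if (length(lengths) < 1L) {
    stop("a tube sequence needs at least one segment", call. = FALSE)
  }
  if (length(areas) != length(lengths)) {
    stop("'lengths' and 'areas' must have equal length", call. = FALSE)
  }
  if (!all(is.finite(lengths)) || any(lengths <= 0)) {
    stop("all segment lengths must be positive and finite", call. = FALSE)
  }
  if (!all(is.finite(areas)) || any(areas <= 0)) {
    stop("all segment areas must be positive and finite", call. = FALSE)
  }
  out <- data.frame(length = as.numeric(lengths), area = as.numeric(areas))
  attr(out, "total_length") <- sum(out$length)
  class(out) <- c("tube_sequence", "data.frame")
  out
}

#' Total acoustic path length of a tube sequence
#'
#' @param tubes A \code{\link{tube_sequence}}.
#' @return Total length in cm (sum of segment lengths).
#' @export
total_length <- function(tubes) {
  stopifnot(inherits(tubes, "tube_sequence"))
  sum(tubes$length)
}

#' Physical constants for tube-model simulation
#'
#' @param speed_of_sound Speed of sound in cm/s. Default 35000 (350 m/s);
#'   34300 cm/s (dry air at 20 degrees C) is the common physical alternative.
#' @param air_density Air density in g/cm^3 (default 0.00114).
#' @param damping_fraction Dimensionless propagation loss factor in [0, 0.1].
#'   Implemented as the ratio of the attenuation constant to the wavenumber,
#'   i.e. a per-segment series resistance proportional to the characteristic
#'   impedance. Default 0.005: large enough to keep all resonance peaks
#'   finite, small enough to leave peak frequencies unchanged to well below
#'   the frequency-grid resolution. Set to 0 for the lossless model.
#' @return An object of class \code{acoustic_constants}.
#' @export
acoustic_constants <- function(speed_of_sound = 35000,
                               air_density = 0.00114,
                               damping_fraction = 0.005) {
  if (!is.numeric(speed_of_sound) || speed_of_sound <= 0) {
    stop("'speed_of_sound' must be positive (cm/s)", call. = FALSE)
  }
  if (!is.numeric(air_density) || air_density <= 0) {
    stop("'air_density' must be positive (g/cm^3)", call. = FALSE)
  }
  if (!is.numeric(damping_fraction) || damping_fraction < 0 ||
      damping_fraction > 0.1) {
    stop("'damping_fraction' must lie in [0, 0.1]", call. = FALSE)
  }
  structure(list(speed_of_sound = as.numeric(speed_of_sound),
                 air_density = as.numeric(air_density),
                 damping_fraction = as.numeric(damping_fraction)),
            class = "acoustic_constants")
}

#' Read acoustic constants from a YAML or JSON configuration file
#'
#' Recognized keys: \code{speed_of_sound}, \code{air_density},
#' \code{damping_fraction}. Missing keys fall back to the defaults of
#' \code{\link{acoustic_constants}}.
#'
#' @param path Path to a YAML (or JSON; YAML is a superset) file.
#' @return An \code{\link{acoustic_constants}} object.
#' @export
read_acoustic_constants <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- acoustic_constants()
  keys <- c("speed_of_sound", "air_density", "damping_fraction")
  unknown <- setdiff(names(cfg), keys)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  args <- utils::modifyList(unclass(defaults)[keys], cfg[intersect(names(cfg), keys)])
  do.call(acoustic_constants, args)
}

#' Volume-velocity transfer function of a tube sequence
#'
#' Computes the magnitude response (lip volume velocity over glottal volume
#' velocity) of a sequence of cylindrical tube segments by cascading the
#' per-segment two-port chain (ABCD) transmission matrices of the acoustic
#' transmission line. The glottis is an ideal volume-velocity source (rigid
#' termination); the lip end is terminated by zero acoustic pressure (open
#' end) by default, or by a first-order piston-in-baffle radiation inertance.
#'
#' For a lossless uniform closed-open tube this reduces to
#' \eqn{|1/\cos(2\pi f L / c)|}, with resonances at odd multiples of
#' \eqn{c/(4L)} (the quarter-wavelength series).
#'
#' @param tubes A \code{\link{tube_sequence}}, glottis end first.
#' @param constants An \code{\link{acoustic_constants}} object.
#' @param f_min,f_max,f_step Frequency grid in Hz (\code{f_min >= 1}).
#'   Defaults 50-5000 Hz at 1 Hz.
#' @param lip_termination \code{"open"} (zero pressure, default) or
#'   \code{"piston"} (radiation inertance of a piston in an infinite baffle,
#'   end correction 0.8216 times the lip-opening radius).
#' @return An object of class \code{transfer_function}: a list with
#'   \code{frequencies} (Hz, strictly increasing), \code{magnitude_db}
#'   (normalized so the value at \code{f_min} is 0 dB), and the call
#'   parameters as attributes.
#' @examples
#' tf <- transfer_function(tube_sequence(18, 1), acoustic_constants())
#' find_formants(tf, n_formants = 2)
#' @export
transfer_function <- function(tubes, constants = acoustic_constants(),
                              f_min = 50, f_max = 5000, f_step = 1,
                              lip_termination = c("open", "piston")) {
  if (!inherits(tubes, "tube_sequence")) {
    tubes <- tube_sequence(tubes$length, tubes$area)
  }
  stopifnot(inherits(constants, "acoustic_constants"))
  lip_termination <- match.arg(lip_termination)
  if (f_min < 1) stop("'f_min' must be >= 1 Hz", call. = FALSE)
  if (f_max <= f_min) stop("'f_max' must exceed 'f_min'", call. = FALSE)
  if (f_step <= 0) stop("'f_step' must be positive", call. = FALSE)

  f <- seq(f_min, f_max, by = f_step)
  cc <- constants$speed_of_sound
  rho <- constants$air_density
  zeta <- constants$damping_fraction
  k <- 2 * pi * f / cc                       # wavenumber, rad/cm
  gamma <- complex(real = zeta * k, imaginary = k)  # propagation constant

  # cascade T = M_1 %*% ... %*% M_n, glottis-most segment first:
  # (p_g, U_g)' = T (p_l, U_l)'
  A <- rep(1 + 0i, length(f)); B <- rep(0 + 0i, length(f))
  C <- B; D <- A
  for (i in seq_len(nrow(tubes))) {
    L <- tubes$length[i]
    Zc <- rho * cc / tubes$area[i]           # characteristic impedance
    gl <- gamma * L
    ch <- cosh(gl); sh <- sinh(gl)
    A2 <- A * ch + B * sh / Zc
    B2 <- A * Zc * sh + B * ch
    C2 <- C * ch + D * sh / Zc
    D2 <- C * Zc * sh + D * ch
    A <- A2; B <- B2; C <- C2; D <- D2
  }

  if (lip_termination == "piston") {
    area_lip <- tubes$area[nrow(tubes)]
    radius <- sqrt(area_lip / pi)
    # acoustic inertance of the radiation end correction
    Z_L <- complex(imaginary = 2 * pi * f * rho * 0.8216 * radius / area_lip)
    denom <- C * Z_L + D
  } else {
    denom <- D
  }

  H <- 1 / denom
  mag <- 20 * log10(Mod(H))
  bad <- !is.finite(mag)
  if (any(bad)) {
    stop(sprintf(
      "non-finite transfer-function magnitude at %d Hz; increase damping_fraction",
      round(f[which(bad)[1]])), call. = FALSE)
  }
  structure(list(frequencies = f, magnitude_db = mag - mag[1]),
            f_step = f_step, lip_termination = lip_termination,
            constants = constants,
            class = "transfer_function")
}

#' Formant estimate
#'
#' Holds an ascending series of formant frequencies with provenance and
#' optional analysis flags.
#'
#' @param formants Numeric vector of strictly increasing positive
#'   frequencies in Hz (F1, F2, ...).
#' @param provenance One of \code{"simulated"}, \code{"synthesized"},
#'   \code{"audio"}.
#' @param flags Optional character vector of analysis flags (e.g.
#'   \code{"f0_coincident"}, \code{"partial"}).
#' @return An object of class \code{formant_estimate} with elements
#'   \code{f1}, \code{f2}, \code{higher}, \code{provenance}, \code{flags}.
#' @export
formant_estimate <- function(formants,
                             provenance = c("simulated", "synthesized", "audio"),
                             flags = character()) {
  provenance <- match.arg(provenance)
  if (length(formants) < 1L || any(!is.finite(formants)) ||
      any(formants <= 0)) {
    stop("formants must be positive finite frequencies", call. = FALSE)
  }
  if (is.unsorted(formants, strictly = TRUE)) {
    stop("formants must be strictly increasing", call. = FALSE)
  }
  structure(list(f1 = formants[1],
                 f2 = if (length(formants) >= 2L) formants[2] else NA_real_,
                 higher = if (length(formants) > 2L) formants[-(1:2)] else numeric(),
                 provenance = provenance,
                 flags = flags),
            class = "formant_estimate")
}

#' @export
print.formant_estimate <- function(x, ...) {
  fs <- c(x$f1, x$f2, x$higher)
  fs <- fs[!is.na(fs)]
  cat(sprintf("Formant estimate (%s): %s Hz%s\n", x$provenance,
              paste(sprintf("F%d = %.1f", seq_along(fs), fs), collapse = ", "),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Extract the formant frequency vector from a formant estimate
#'
#' @param x A \code{\link{formant_estimate}}.
#' @return Numeric vector of formant frequencies in Hz, ascending.
#' @export
formant_frequencies <- function(x) {
  stopifnot(inherits(x, "formant_estimate"))
  fs <- c(x$f1, x$f2, x$higher)
  fs[!is.na(fs)]
}

# Topographic prominence of local maxima in a sampled curve: height of the
# peak above its key saddle, i.e. the higher of the lowest points on the
# paths to higher terrain on each side. A side without higher terrain
# contributes no saddle; the global maximum is measured from the curve
# minimum.
peak_prominences <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p - 1L)]
    higher_left <- which(left > y[p])
    lo_left <- if (length(higher_left)) {
      min(left[(max(higher_left)):(p - 1L)])
    } else NA_real_
    right <- y[p + seq_len(length(y) - p)]
    higher_right <- which(right > y[p])
    lo_right <- if (length(higher_right)) {
      min(right[seq_len(min(higher_right))])
    } else NA_real_
    saddle <- if (is.na(lo_left) && is.na(lo_right)) {
      min(y)
    } else {
      max(lo_left, lo_right, na.rm = TRUE)
    }
    y[p] - saddle
  }, numeric(1))
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
}

#' Locate formants as prominent peaks of a transfer function
#'
#' Finds the \code{n_formants} lowest-frequency local maxima of the magnitude
#' curve whose topographic prominence exceeds \code{min_prominence_db}, and
#' refines each peak by parabolic interpolation over the three surrounding
#' grid points.
#'
#' @param tf A \code{\link{transfer_function}}.
#' @param n_formants Number of formants to return (>= 1).
#' @param min_prominence_db Minimum peak prominence in dB (default 3),
#'   rejecting grid ripple without suppressing genuine resonances.
#' @return A \code{\link{formant_estimate}} with provenance
#'   \code{"simulated"}.
#' @export
find_formants <- function(tf, n_formants = 2, min_prominence_db = 3) {
  stopifnot(inherits(tf, "transfer_function"))
  if (n_formants < 1) stop("'n_formants' must be >= 1", call. = FALSE)
  y <- tf$magnitude_db
  f <- tf$frequencies
  cand <- local_maxima(y)
  if (length(cand)) {
    prom <- peak_prominences(y, cand)
    cand <- cand[prom >= min_prominence_db]
  }
  if (length(cand) < n_formants) {
    stop(sprintf("%d peak%s found with prominence >= %g dB; %d requested",
                 length(cand), if (length(cand) == 1L) "" else "s",
                 min_prominence_db, n_formants), call. = FALSE)
  }
  cand <- sort(cand)[seq_len(n_formants)]
  step <- f[2] - f[1]
  freqs <- vapply(cand, function(i) {
    denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    delta <- if (abs(denom) > .Machine$double.eps) {
      0.5 * (y[i - 1L] - y[i + 1L]) / denom
    } else 0
    f[i] + max(-0.5, min(0.5, delta)) * step
  }, numeric(1))
  formant_estimate(freqs, provenance = "simulated")
}

#' Quarter-wavelength resonances of a uniform closed-open tube
#'
#' Analytic closed form for a uniform tube closed at the glottis (velocity
#' source) and open at the lips: resonances at odd multiples of
#' \eqn{c / (4L)}. Serves as the analytic oracle for the chain-matrix model.
#'
#' @param length Tube length in cm (> 0).
#' @param speed_of_sound Speed of sound in cm/s (default 35000).
#' @param n Number of resonances (>= 1).
#' @return Numeric vector of \code{n} resonance frequencies in Hz.
#' @examples
#' uniform_tube_resonances(18, 35000, 3)  # 486.11 1458.33 2430.56
#' @export
uniform_tube_resonances <- function(length, speed_of_sound = 35000, n = 3) {
  if (length <= 0) stop("'length' must be positive", call. = FALSE)
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  (2 * seq_len(n) - 1) * speed_of_sound / (4 * length)
}

#' Write a transfer function to CSV
#'
#' Two columns, \code{frequency_hz} and \code{magnitude_db}, with a header
#' row.
#'
#' @param tf A \code{\link{transfer_function}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_transfer_function <- function(tf, path) {
  stopifnot(inherits(tf, "transfer_function"))
  utils::write.csv(data.frame(frequency_hz = tf$frequencies,
                              magnitude_db = tf$magnitude_db),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
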