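#' Reference formants for human /u/ and chimpanzee hoo calls
#'
#' Mean and standard deviation of F1 and F2 (Hz) for the human close back
#' rounded vowel /u/ as spoken by adult males, adult females, and children
#' (the classic Peterson-Barney survey values), and for chimpanzee hoo
#' calls. Two chimpanzee fixtures are provided, reflecting the two published
#' summaries of the same call sample: \code{chimp_hoo} (F1 374.44 Hz) and
#' \code{chimp_hoo_methods} (F1 358.75 Hz). \code{chimp_hoo_methods} is the
#' default comparison target throughout the package; neither is "corrected"
#' toward the other.
#'
#' @param label Optional label to select a single reference row; one of
#'   \code{"human_male_u"}, \code{"human_female_u"}, \code{"human_child_u"},
#'   \code{"chimp_hoo"}, \code{"chimp_hoo_methods"}.
#' @return A data frame of class \code{vowel_reference} with columns
#'   \code{label}, \code{f1_mean}, \code{f1_sd}, \code{f2_mean},
#'   \code{f2_sd}; one row if \code{label} is given, all five otherwise.
#' @examples
#' vowel_references()
#' vowel_references("chimp_hoo_methods")
#' @export
vowel_references <- function(label = NULL) {
  path <- system.file("extdata", "vowel_references.csv", package = "tractsim",
                      mustWork = TRUE)
  refs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(label)) {
    if (!label %in% refs$label) {
      stop(sprintf("unknown reference label '%s'; available: %s", label,
                   paste(refs$label, collapse = ", ")), call. = FALSE)
    }
    refs <- refs[refs$label == label, , drop = FALSE]
    rownames(refs) <- NULL
  }
  class(refs) <- c("vowel_reference", "data.frame")
  refs
}

as_single_reference <- function(ref) {
  if (is.character(ref)) ref <- vowel_references(ref)
  stopifnot(is.data.frame(ref),
            all(c("label", "f1_mean", "f1_sd", "f2_mean", "f2_sd") %in%
                  names(ref)))
  if (nrow(ref) != 1L) {
    stop("expected exactly one reference row; got ", nrow(ref), call. = FALSE)
  }
  ref
}

#' Configuration closest to a reference formant pair
#'
#' Finds the non-flagged sweep row whose (F1, F2) minimizes the chosen
#' distance to the reference means. Ties are broken by smaller total tract
#' length, then by enumeration order.
#'
#' @param sweep A \code{\link{run_sweep}} result (or a data frame with its
#'   columns).
#' @param ref A single-row reference (see \code{\link{vowel_references}}) or
#'   a reference label string. Default \code{"chimp_hoo_methods"}.
#' @param metric \code{"euclidean_hz"} (Euclidean distance in Hz, default)
#'   or \code{"per_sd_normalized"} (each axis divided by the reference SD
#'   before the Euclidean distance, compensating for the unequal spread of
#'   F1 and F2).
#' @return An object of class \code{fit_result}: a list with
#'   \code{reference_label}, \code{best_row} (the winning sweep row),
#'   \code{best_f1}, \code{best_f2}, \code{distance}, and
#'   \code{within_one_sd} (named logical vector, one element per axis).
#' @export
nearest_configuration <- function(sweep, ref = "chimp_hoo_methods",
                                  metric = c("euclidean_hz",
                                             "per_sd_normalized")) {
  metric <- match.arg(metric)
  ref <- as_single_reference(ref)
  ok <- sweep$status == "ok" & is.finite(sweep$f1_hz) & is.finite(sweep$f2_hz)
  if (!any(ok)) stop("no successful configurations in sweep", call. = FALSE)
  rows <- sweep[ok, , drop = FALSE]
  d1 <- rows$f1_hz - ref$f1_mean
  d2 <- rows$f2_hz - ref$f2_mean
  dist <- if (metric == "euclidean_hz") {
    sqrt(d1^2 + d2^2)
  } else {
    sqrt((d1 / ref$f1_sd)^2 + (d2 / ref$f2_sd)^2)
  }
  ord <- order(dist, rows$total_length_cm, seq_len(nrow(rows)))
  best <- rows[ord[1L], , drop = FALSE]
  rownames(best) <- NULL
  structure(list(
    reference_label = ref$label,
    metric = metric,
    best_row = best,
    best_f1 = best$f1_hz,
    best_f2 = best$f2_hz,
    distance = dist[ord[1L]],
    within_one_sd = c(f1 = abs(best$f1_hz - ref$f1_mean) <= ref$f1_sd,
                      f2 = abs(best$f2_hz - ref$f2_mean) <= ref$f2_sd)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Best fit to %s (%s): F1 = %.1f Hz, F2 = %.1f Hz, distance = %.2f\n",
    x$reference_label, x$metric, x$best_f1, x$best_f2, x$distance))
  cat(sprintf("  within one SD: F1 %s, F2 %s\n",
              x$within_one_sd[["f1"]], x$within_one_sd[["f2"]]))
  cat(sprintf(
    "  protrusion %.1f cm, sac %.1f cm x %.0f cm^2, lip opening %.1f cm^2\n",
    x$best_row$protrusion_length_cm, x$best_row$sac_length_cm,
    x$best_row$sac_area_cm2, x$best_row$lip_area_cm2))
  invisible(x)
}

#' Overlap of a sweep with reference vowel regions
#'
#' A configuration "overlaps" a reference when both its F1 and F2 fall
#' within one SD of the reference means. Reports the overlap count and
#' fraction per reference, plus the global minimum F1 and F2 achieved by
#' the sweep.
#'
#' @param sweep A \code{\link{run_sweep}} result.
#' @param refs A \code{\link{vowel_references}} data frame (default: all
#'   five references) or a character vector of labels.
#' @return A data frame with one row per reference and columns \code{label},
#'   \code{n_within_one_sd}, \code{fraction_within_one_sd}, \code{min_f1_hz},
#'   \code{min_f2_hz}, \code{n_configurations}.
#' @export
overlap_report <- function(sweep, refs = vowel_references()) {
  if (is.character(refs)) {
    refs <- do.call(rbind, lapply(refs, vowel_references))
  }
  ok <- sweep$status == "ok" & is.finite(sweep$f1_hz) & is.finite(sweep$f2_hz)
  rows <- sweep[ok, , drop = FALSE]
  min_f1 <- if (nrow(rows)) min(rows$f1_hz) else NA_real_
  min_f2 <- if (nrow(rows)) min(rows$f2_hz) else NA_real_
  out <- data.frame(label = character(), n_within_one_sd = integer(),
                    fraction_within_one_sd = numeric(),
                    min_f1_hz = numeric(), min_f2_hz = numeric(),
                    n_configurations = integer(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(refs))) {
    r <- refs[i, ]
    hit <- abs(rows$f1_hz - r$f1_mean) <= r$f1_sd &
      abs(rows$f2_hz - r$f2_mean) <= r$f2_sd
    out <- rbind(out, data.frame(
      label = r$label,
      n_within_one_sd = sum(hit),
      fraction_within_one_sd = if (nrow(rows)) mean(hit) else NA_real_,
      min_f1_hz = min_f1, min_f2_hz = min_f2,
      n_configurations = nrow(rows), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
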