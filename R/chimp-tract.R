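#' Parameters of the five-segment chimpanzee vocal-tract simulacrum
#'
#' The simulacrum is, from glottis to lips: an optional narrow constriction,
#' a large open cavity standing in for a laryngeal air sac, a uniform main
#' tract, a lip-protrusion extension, and a short lip-opening segment whose
#' area models lip rounding.
#'
#' @param sac_length Air-sac cavity length in cm.
#' @param sac_area Air-sac cross-sectional area in cm^2 (1 = no sac, the
#'   cavity is then flush with the main tract bore).
#' @param protrusion_length Lip-protrusion length in cm.
#' @param lip_opening_area Lip-opening area in cm^2 (smaller = more rounded).
#' @param vtl Main-tract (glottis-to-teeth) length in cm, default 18
#'   (adult male chimpanzee estimate).
#' @param tract_area Main-tract area in cm^2, default 1.
#' @param protrusion_area Protrusion-segment area in cm^2; defaults to the
#'   tract bore (1 cm^2) since protrusion extends the tract and rounding is
#'   carried by the lip-opening segment.
#' @param lip_opening_length Lip-opening segment length in cm, default 0.2.
#' @param constriction_length,constriction_area Dimensions of the narrow
#'   constriction between glottis and air sac (defaults 0.125 cm and
#'   0.125 cm^2).
#' @param constriction_enabled Include the constriction segment? Default
#'   \code{TRUE}.
#' @return An object of class \code{tract_params}.
#' @examples
#' p <- tract_params(sac_length = 1.5, sac_area = 10,
#'                   protrusion_length = 2, lip_opening_area = 0.4)
#' build_tract(p)
#' @export
tract_params <- function(sac_length, sac_area, protrusion_length,
                         lip_opening_area,
                         vtl = 18, tract_area = 1,
                         protrusion_area = 1,
                         lip_opening_length = 0.2,
                         constriction_length = 0.125,
                         constriction_area = 0.125,
                         constriction_enabled = TRUE) {
  p <- list(vtl = vtl, tract_area = tract_area,
            sac_length = sac_length, sac_area = sac_area,
            protrusion_length = protrusion_length,
            protrusion_area = protrusion_area,
            lip_opening_area = lip_opening_area,
            lip_opening_length = lip_opening_length,
            constriction_length = constriction_length,
            constriction_area = constriction_area,
            constriction_enabled = isTRUE(constriction_enabled))
  for (field in setdiff(names(p), "constriction_enabled")) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", field),
           call. = FALSE)
    }
    p[[field]] <- as.numeric(v)
  }
  structure(p, class = "tract_params")
}

#' Build the tube sequence for a tract parameter set
#'
#' Segments in glottis-to-lips order: [constriction, if enabled] then air
#' sac, main tract, lip protrusion, lip opening.
#'
#' @param params A \code{\link{tract_params}} object.
#' @return A \code{\link{tube_sequence}} whose total length is the sum of
#'   the enabled segment lengths.
#' @export
build_tract <- function(params) {
  stopifnot(inherits(params, "tract_params"))
  lengths <- c(if (params$constriction_enabled) params$constriction_length,
               params$sac_length, params$vtl,
               params$protrusion_length, params$lip_opening_length)
  areas <- c(if (params$constriction_enabled) params$constriction_area,
             params$sac_area, params$tract_area,
             params$protrusion_area, params$lip_opening_area)
  tube_sequence(lengths, areas)
}

#' Simulation parameter grid
#'
#' The four swept articulatory parameters and their values. Defaults cover
#' lip protrusion 0.2-3.8 cm (step 0.2), air-sac length 1-2 cm (step 0.5),
#' air-sac area 1-30 cm^2 (step 1), and lip-opening area 0.2-1 cm^2 (step
#' 0.2): 19 x 3 x 30 x 5 = 8550 configurations.
#'
#' @param protrusion_lengths Lip-protrusion lengths in cm.
#' @param sac_lengths Air-sac lengths in cm.
#' @param sac_areas Air-sac areas in cm^2.
#' @param lip_opening_areas Lip-opening areas in cm^2.
#' @return An object of class \code{param_grid}.
#' @export
param_grid <- function(protrusion_lengths = seq(0.2, 3.8, by = 0.2),
                       sac_lengths = seq(1, 2, by = 0.5),
                       sac_areas = seq(1, 30, by = 1),
                       lip_opening_areas = seq(0.2, 1, by = 0.2)) {
  g <- list(protrusion_lengths = protrusion_lengths,
            sac_lengths = sac_lengths,
            sac_areas = sac_areas,
            lip_opening_areas = lip_opening_areas)
  for (field in names(g)) {
    v <- g[[field]]
    if (length(v) < 1L || !is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be a non-empty vector of positive values", field),
           call. = FALSE)
    }
    g[[field]] <- as.numeric(v)
  }
  structure(g, class = "param_grid")
}

#' Read a parameter grid from a YAML or JSON configuration file
#'
#' Recognized keys match the arguments of \code{\link{param_grid}}; missing
#' keys fall back to the default grid.
#'
#' @param path Path to a YAML file.
#' @return A \code{\link{param_grid}}.
#' @export
read_param_grid <- function(path) {
  cfg <- yaml::read_yaml(path)
  keys <- c("protrusion_lengths", "sac_lengths", "sac_areas",
            "lip_opening_areas")
  unknown <- setdiff(names(cfg), keys)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(param_grid, lapply(cfg[intersect(names(cfg), keys)], unlist))
}

#' Enumerate all tract configurations of a grid
#'
#' Cartesian product of the four swept lists combined with the fixed
#' parameters. Enumeration order is deterministic: protrusion length varies
#' slowest, then air-sac length, then air-sac area, with lip-opening area
#' varying fastest.
#'
#' @param grid A \code{\link{param_grid}}.
#' @param fixed A \code{\link{tract_params}} supplying the non-swept
#'   constants (its four swept fields are overwritten).
#' @return A list of \code{\link{tract_params}}, one per configuration.
#' @export
enumerate_grid <- function(grid = param_grid(), fixed = default_fixed_params()) {
  stopifnot(inherits(grid, "param_grid"), inherits(fixed, "tract_params"))
  out <- vector("list",
                length(grid$protrusion_lengths) * length(grid$sac_lengths) *
                  length(grid$sac_areas) * length(grid$lip_opening_areas))
  i <- 0L
  for (pl in grid$protrusion_lengths) {
    for (sl in grid$sac_lengths) {
      for (sa in grid$sac_areas) {
        for (la in grid$lip_opening_areas) {
          p <- fixed
          p$protrusion_length <- pl
          p$sac_length <- sl
          p$sac_area <- sa
          p$lip_opening_area <- la
          i <- i + 1L
          out[[i]] <- p
        }
      }
    }
  }
  out
}

#' Fixed tract constants used by the default sweep
#'
#' 18 cm x 1 cm^2 main tract, 0.2 cm lip opening, 0.125 cm x 0.125 cm^2
#' constriction enabled; the four swept fields carry placeholder values that
#' \code{\link{enumerate_grid}} overwrites.
#'
#' @return A \code{\link{tract_params}}.
#' @export
default_fixed_params <- function() {
  tract_params(sac_length = 1, sac_area = 1, protrusion_length = 0.2,
               lip_opening_area = 1)
}

#' Run the formant sweep over a parameter grid
#'
#' For each configuration: build the tube sequence, compute its transfer
#' function, and pick the two lowest prominent resonances. The sweep is
#' fully deterministic; configurations whose peak picking fails are recorded
#' with the failure reason in \code{status} rather than dropped.
#'
#' @param grid A \code{\link{param_grid}} (default: the full 8550-point
#'   grid).
#' @param fixed Fixed tract constants (\code{\link{tract_params}}).
#' @param constants An \code{\link{acoustic_constants}} object.
#' @param f_min,f_max,f_step Frequency grid passed to
#'   \code{\link{transfer_function}}.
#' @param min_prominence_db Peak-prominence threshold for
#'   \code{\link{find_formants}}.
#' @param progress Print a progress message every 1000 configurations?
#' @return An object of class \code{sweep_result}: a data frame with one row
#'   per configuration in enumeration order and columns
#'   \code{protrusion_length_cm}, \code{sac_length_cm}, \code{sac_area_cm2},
#'   \code{lip_area_cm2}, \code{total_length_cm}, \code{f1_hz},
#'   \code{f2_hz}, \code{status} (\code{"ok"} or the failure reason).
#' @export
run_sweep <- function(grid = param_grid(), fixed = default_fixed_params(),
                      constants = acoustic_constants(),
                      f_min = 50, f_max = 5000, f_step = 1,
                      min_prominence_db = 3, progress = FALSE) {
  configs <- enumerate_grid(grid, fixed)
  n <- length(configs)
  out <- data.frame(protrusion_length_cm = numeric(n),
                    sac_length_cm = numeric(n),
                    sac_area_cm2 = numeric(n),
                    lip_area_cm2 = numeric(n),
                    total_length_cm = numeric(n),
                    f1_hz = NA_real_, f2_hz = NA_real_,
                    status = character(n))
  for (i in seq_len(n)) {
    p <- configs[[i]]
    tubes <- build_tract(p)
    out$protrusion_length_cm[i] <- p$protrusion_length
    out$sac_length_cm[i] <- p$sac_length
    out$sac_area_cm2[i] <- p$sac_area
    out$lip_area_cm2[i] <- p$lip_opening_area
    out$total_length_cm[i] <- total_length(tubes)
    res <- tryCatch({
      tf <- transfer_function(tubes, constants, f_min, f_max, f_step)
      fe <- find_formants(tf, n_formants = 2,
                          min_prominence_db = min_prominence_db)
      list(f1 = fe$f1, f2 = fe$f2, status = "ok")
    }, error = function(e) list(f1 = NA_real_, f2 = NA_real_,
                                status = conditionMessage(e)))
    out$f1_hz[i] <- res$f1
    out$f2_hz[i] <- res$f2
    out$status[i] <- res$status
    if (progress && i %% 1000L == 0L) {
      message(sprintf("sweep: %d / %d configurations", i, n))
    }
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Write sweep results to CSV
#'
#' Byte-stable output: repeated runs of the same deterministic sweep yield
#' identical files.
#'
#' @param sweep A \code{\link{run_sweep}} result.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' Read sweep results from CSV
#'
#' @param path Path to a CSV written by \code{\link{write_sweep_csv}}.
#' @return A \code{sweep_result} data frame.
#' @export
read_sweep_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("protrusion_length_cm", "sac_length_cm", "sac_area_cm2",
                "lip_area_cm2", "total_length_cm", "f1_hz", "f2_hz", "status")
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop("sweep CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}
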