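#' Run configuration
#'
#' Central knobs for the analysis chain, with the study's defaults:
#' ring neighborhoods at 0-5, 5-15, 15-25, 25-35, 35-45 um around each
#' leukemia cell boundary; close/far proximity cutoffs of 5 and 30 um;
#' QC thresholds of 20 transcripts per cell and 300 cells per FOV;
#' 100 permutations for the density-shift background; 0.18 um/px; and an
#' IOU threshold of 0.7 for segmentation matching.
#'
#' @param ... overrides of the defaults (see fields below).
#' @return a list of class `"nichemap_config"`.
#' @export
nichemap_config <- function(...) {
  cfg <- list(
    ring_edges = c(0, 5, 15, 25, 35, 45),  # um
    contact_tolerance = 0.0,               # um
    close_cutoff = 5,                      # um
    far_cutoff = 30,                       # um
    qc_min_transcripts = 20L,
    qc_min_cells_per_fov = 300L,
    n_permutations = 100L,
    pixel_size = 0.18,                     # um / px
    iou_threshold = 0.7,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "nichemap_config"
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid config: ", paste(errs, collapse = "; "))
  cfg
}

#' Load configuration from a YAML file
#'
#' Unspecified keys take the documented defaults; all effective values are
#' logged via `message()`.
#'
#' @param path YAML file (may be empty).
#' @return a [nichemap_config()].
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  cfg <- do.call(nichemap_config, vals)
  message("config: ",
          paste(names(cfg), vapply(cfg, function(v)
            paste(format(v), collapse = ","), character(1)),
            sep = "=", collapse = " "))
  cfg
}

#' Validate a configuration
#' @param cfg a [nichemap_config()] (or plain list with the same fields).
#' @return character vector of problems; empty when valid.
#' @export
validate_config <- function(cfg) {
  errs <- character(0)
  re <- cfg$ring_edges
  if (length(re) < 2L || re[1] != 0 || any(diff(re) <= 0))
    errs <- c(errs, "ring_edges must start at 0 and be strictly increasing")
  if (!(cfg$close_cutoff > 0) || !(cfg$close_cutoff < cfg$far_cutoff))
    errs <- c(errs, "need 0 < close_cutoff < far_cutoff")
  if (cfg$contact_tolerance < 0) errs <- c(errs, "contact_tolerance < 0")
  if (cfg$pixel_size <= 0) errs <- c(errs, "pixel_size must be positive")
  if (cfg$iou_threshold <= 0 || cfg$iou_threshold > 1)
    errs <- c(errs, "iou_threshold must be in (0, 1]")
  if (cfg$n_permutations < 1) errs <- c(errs, "n_permutations must be >= 1")
  if (cfg$qc_min_transcripts < 0 || cfg$qc_min_cells_per_fov < 0)
    errs <- c(errs, "QC thresholds must be non-negative")
  errs
}

#' @export
print.nichemap_config <- function(x, ...) {
  cat("nichemap_config\n")
  for (k in names(x))
    cat(sprintf("  %-22s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}
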