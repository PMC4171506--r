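#' Analysis configuration
#'
#' Collects every tunable parameter of the segmentation/quantification
#' pipeline in one validated object. Defaults are chosen for 25x confocal
#' fields of human muscle cross-sections on the 12-bit au scale.
#'
#' @param membrane_max_thickness_um Maximum predicted sarcolemmal membrane
#'   thickness (um). Membrane pixels farther than this from a fiber interior
#'   are never claimed by that fiber; the cap drives the split of touching
#'   membranes. Default 3 um (generously above the ~1--2 um membrane band
#'   measured in healthy muscle).
#' @param min_fiber_area_um2 Fibers with cross-sectional area below this are
#'   flagged `too_small` by [qc_filter()]. Default 250 um^2 (well below the
#'   mean fiber area even of dystrophic muscle, so only debris is flagged).
#' @param min_membrane_coverage Minimum fraction of the fiber's interior
#'   boundary that must be covered by its membrane mask; below it the fiber
#'   is flagged `incomplete_membrane`. Default 0.6.
#' @param quantile_levels Quantile levels reported per fiber; ascending,
#'   each in (0,1), and 0.90 must be present (the Q90 convention).
#' @param trace_floor_au,revertant_threshold_au Intensity class boundaries
#'   (au) for [classify_fibers()]: per-fiber mean below `trace_floor_au` is
#'   `negative`, in `[trace_floor_au, revertant_threshold_au)` `trace`, at or
#'   above `revertant_threshold_au` `revertant`. Defaults 200 and 800 au,
#'   the ranges observed for trace and revertant fibers at high (7%) laser
#'   settings; they are configuration, not constants, because the au scale
#'   moves with acquisition settings.
#' @param smoothing_sigma_px Gaussian smoothing scale (pixels) applied to the
#'   spectrin channel before thresholding. Default 1.
#' @param threshold_method `"relative"` (default; Otsu on the normalised
#'   smoothed spectrin channel, invariant to global gain) or `"fixed"`.
#' @param threshold_au Fixed membrane threshold in au, used only when
#'   `threshold_method = "fixed"`.
#' @param seed_min_area_um2 Interior basins smaller than this (um^2) are not
#'   used as fiber seeds. Default 100 um^2.
#' @param random_seed Integer seed recorded in run manifests.
#'
#' @return An object of class `analysis_config` (a named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$membrane_max_thickness_um
analysis_config <- function(membrane_max_thickness_um = 3,
                            min_fiber_area_um2 = 250,
                            min_membrane_coverage = 0.6,
                            quantile_levels = c(0.25, 0.5, 0.75, 0.9),
                            trace_floor_au = 200,
                            revertant_threshold_au = 800,
                            smoothing_sigma_px = 1,
                            threshold_method = c("relative", "fixed"),
                            threshold_au = NULL,
                            seed_min_area_um2 = 100,
                            random_seed = 1L) {
  threshold_method <- match.arg(threshold_method)
  if (membrane_max_thickness_um <= 0) {
    abort("membrane_max_thickness_um must be > 0", class = "fiberquant_config_error")
  }
  if (min_fiber_area_um2 <= 0) {
    abort("min_fiber_area_um2 must be > 0", class = "fiberquant_config_error")
  }
  if (is.unsorted(quantile_levels, strictly = TRUE) ||
      any(quantile_levels <= 0) || any(quantile_levels >= 1)) {
    abort("quantile_levels must be strictly ascending and inside (0, 1)",
          class = "fiberquant_config_error")
  }
  if (!any(abs(quantile_levels - 0.9) < 1e-12)) {
    abort("quantile_levels must include 0.90 (the Q90 convention)",
          class = "fiberquant_config_error")
  }
  if (!(trace_floor_au >= 0 && trace_floor_au < revertant_threshold_au)) {
    abort("need 0 <= trace_floor_au < revertant_threshold_au",
          class = "fiberquant_config_error")
  }
  if (threshold_method == "fixed" && is.null(threshold_au)) {
    abort("threshold_au required when threshold_method = 'fixed'",
          class = "fiberquant_config_error")
  }
  structure(
    list(
      membrane_max_thickness_um = membrane_max_thickness_um,
      min_fiber_area_um2 = min_fiber_area_um2,
      min_membrane_coverage = min_membrane_coverage,
      quantile_levels = quantile_levels,
      trace_floor_au = trace_floor_au,
      revertant_threshold_au = revertant_threshold_au,
      smoothing_sigma_px = smoothing_sigma_px,
      threshold_method = threshold_method,
      threshold_au = threshold_au,
      seed_min_area_um2 = seed_min_area_um2,
      random_seed = as.integer(random_seed)
    ),
    class = "analysis_config"
  )
}

#' Read / write an analysis configuration as YAML
#'
#' The YAML mirrors the fields of [analysis_config()]; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return `read_analysis_config()` returns an `analysis_config`;
#'   `write_analysis_config()` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "fiberquant_io_error")
  }
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")),
          class = "fiberquant_config_error")
  }
  do.call(analysis_config, vals)
}

#' @param config An `analysis_config`.
#' @rdname read_analysis_config
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
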