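#' Membrane intensity statistics for one pixel set
#'
#' Computes the per-fiber intensity statistics on a vector of membrane pixel
#' intensities: arithmetic mean, minimum, maximum, nearest-rank quantiles and
#' the Q90-mean. The quantile at level p is the order statistic at rank
#' `ceiling(p * n)` -- the cut-off between the lowest p-fraction of pixels
#' and the rest -- with no interpolation, so results are reproducible
#' bit-exactly. The Q90-mean is the mean of the `ceiling(0.1 * n)` brightest
#' pixels, i.e. the mean intensity of the 10% of membrane pixels with the
#' highest intensity; it tracks what an observer reads as the bright
#' sarcolemmal rim.
#'
#' @param values Numeric vector of intensities (au) at the mask pixels;
#'   must be non-empty.
#' @param levels Quantile levels in (0, 1), ascending (default from
#'   [analysis_config()]).
#'
#' @return A one-row tibble: `mean`, `min`, `max`, one `q<level>` column per
#'   level (e.g. `q90`), and `q90_mean`.
#' @export
#' @examples
#' membrane_intensity_stats(1:10)   # mean 5.5, q90 9, q90_mean 10
membrane_intensity_stats <- function(values, levels = c(0.25, 0.5, 0.75, 0.9)) {
  if (length(values) == 0L) {
    abort("empty membrane mask: statistics undefined", class = "fiberquant_validation_error")
  }
  if (anyNA(values)) {
    abort("NA intensities in membrane mask", class = "fiberquant_validation_error")
  }
  n <- length(values)
  s <- sort(values)
  q <- s[pmax(1L, ceiling(levels * n))]
  k <- ceiling(0.1 * n)
  out <- tibble(
    mean = mean(values), min = s[1], max = s[n],
    q90_mean = mean(s[(n - k + 1L):n])
  )
  qcols <- setNames(as.list(q), paste0("q", sub("^0\\.", "", formatC(levels * 100, format = "fg"))))
  bind_cols(out[, c("mean", "min", "max")], as_tibble(qcols), out[, "q90_mean"])
}

#' Per-fiber morphometry
#'
#' Cross-sectional area (membrane plus cytoplasm, in um^2) and mean membrane
#' thickness. Thickness is estimated as membrane area divided by the length
#' of the membrane's inner contour (the cytoplasm perimeter, Crofton
#' estimate), a deterministic approximation to the medial-axis thickness.
#' For degenerate fibers without cytoplasm the full region contour is used
#' and the fiber is flagged.
#'
#' @param fibers A `fiber_set` (see [split_touching_membranes()]).
#' @param pixel_size Pixel size in um/pixel.
#'
#' @return A tibble with one row per fiber: `fiber_id`, `csa_um2`,
#'   `membrane_thickness_um`, `degenerate`.
#' @export
fiber_morphometry <- function(fibers, pixel_size) {
  stopifnot(inherits(fibers, "fiber_set"), pixel_size > 0)
  n <- nrow(fibers$fibers)
  per_inner <- crofton_perimeter(fibers$cytoplasm, n)
  per_region <- crofton_perimeter(fibers$labels, n)
  tb <- fibers$fibers
  degen <- tb$n_cytoplasm_px == 0L
  per <- ifelse(degen, per_region, per_inner)
  thickness <- ifelse(per > 0, tb$n_membrane_px * pixel_size / per, NA_real_)
  tibble(
    fiber_id = tb$fiber_id,
    csa_um2 = (tb$n_membrane_px + tb$n_cytoplasm_px) * pixel_size^2,
    membrane_thickness_um = thickness,
    degenerate = degen
  )
}

#' Quantify one section image
#'
#' Computes the full per-fiber metrics table for one image: dystrophin
#' membrane statistics (mean, min, max, quantiles, Q90-mean), mean spectrin
#' membrane intensity, and morphometry, for every QC-passing fiber. The
#' dystrophin signal inside the spectrin-defined sarcolemmal mask is taken
#' as membrane-localised dystrophin.
#'
#' @param image The [section_image()] the fibers were segmented from.
#' @param fibers A `fiber_set` with QC flags set (see [qc_filter()]).
#' @param config An [analysis_config()] (quantile levels).
#'
#' @return A tibble with one row per QC-passing fiber: identifiers
#'   (`biopsy_id`, `section_id`, `image_id`, `fiber_id`), `dys_mean`,
#'   `dys_min`, `dys_max`, `dys_q*` quantile columns, `dys_q90_mean`,
#'   `spec_mean`, `csa_um2`, `membrane_thickness_um`, `n_membrane_px`.
#'   Zero QC-passing fibers give a zero-row tibble with the same columns.
#' @export
quantify_image <- function(image, fibers, config = analysis_config()) {
  stopifnot(inherits(image, "section_image"), inherits(fibers, "fiber_set"))
  if (!identical(dim(image$dystrophin), dim(fibers$membrane))) {
    abort("image and fiber set disagree in pixel dimensions (provenance mismatch)",
          class = "fiberquant_validation_error")
  }
  if (all(is.na(fibers$fibers$qc_pass))) {
    abort("run qc_filter() before quantify_image()", class = "fiberquant_validation_error")
  }
  tb <- fibers$fibers
  morpho <- fiber_morphometry(fibers, image$pixel_size)
  pass_ids <- tb$fiber_id[tb$qc_pass]

  template <- bind_cols(
    tibble(biopsy_id = character(), section_id = character(),
           image_id = character(), fiber_id = integer()),
    membrane_intensity_stats(0, config$quantile_levels)[0, ] |>
      rename_with(~ paste0("dys_", .x)),
    tibble(spec_mean = numeric(), csa_um2 = numeric(),
           membrane_thickness_um = numeric(), n_membrane_px = integer())
  )
  if (!length(pass_ids)) return(template)

  mem <- fibers$membrane
  inmask <- mem > 0L
  lab_v <- mem[inmask]
  dys_by_fiber <- split(image$dystrophin[inmask], lab_v)
  spec_by_fiber <- split(image$spectrin[inmask], lab_v)

  rows <- map(pass_ids, function(k) {
    kk <- as.character(k)
    stats <- membrane_intensity_stats(dys_by_fiber[[kk]], config$quantile_levels) |>
      rename_with(~ paste0("dys_", .x))
    bind_cols(
      tibble(biopsy_id = image$meta$biopsy_id, section_id = image$meta$section_id,
             image_id = image$meta$image_id, fiber_id = as.integer(k)),
      stats,
      tibble(spec_mean = mean(spec_by_fiber[[kk]]))
    )
  })
  list_rbind(rows) |>
    left_join(morpho |> select("fiber_id", "csa_um2", "membrane_thickness_um"),
              by = "fiber_id") |>
    left_join(tb |> select("fiber_id", "n_membrane_px"), by = "fiber_id")
}
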