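#' Two-channel muscle section image
#'
#' A `section_image` bundles the registered dystrophin and spectrin intensity
#' grids of one imaged field of a muscle biopsy cross-section, together with
#' the pixel-size calibration and acquisition metadata. Intensities are on the
#' 12-bit arbitrary-unit (au) scale, 0--4095.
#'
#' @param dystrophin Numeric matrix of dystrophin intensities (au, 0--4095).
#' @param spectrin Numeric matrix of spectrin intensities (au, 0--4095); must
#'   have the same dimensions as `dystrophin`.
#' @param pixel_size Pixel edge length in micrometres per pixel (strictly
#'   positive). Confocal acquisition does not embed this for all export
#'   routes, so it is always supplied by the caller.
#' @param biopsy_id,section_id,image_id Character identifiers placing the
#'   field in the biopsy > section > image hierarchy.
#' @param staining_combo Label for the antibody pair used (e.g. the
#'   anti-dystrophin clone); carried into comparison reports.
#' @param is_isotype_control `TRUE` when the field comes from an
#'   isotype-control stain used for background assessment.
#' @param bead_reference_intensity Optional calibration-bead reference
#'   intensity (au) recorded for the acquisition day; carried as metadata
#'   only and never used to rescale intensities unless explicitly requested.
#'
#' @return An object of class `section_image`: a list with elements
#'   `dystrophin`, `spectrin`, `pixel_size` and `meta`.
#' @export
#' @examples
#' img <- section_image(matrix(100, 8, 8), matrix(1500, 8, 8), pixel_size = 1)
#' dim(img$dystrophin)
section_image <- function(dystrophin, spectrin, pixel_size,
                          biopsy_id = "biopsy1", section_id = "section1",
                          image_id = "image1", staining_combo = "unspecified",
                          is_isotype_control = FALSE,
                          bead_reference_intensity = NULL) {
  if (!is.matrix(dystrophin) || !is.matrix(spectrin)) {
    abort("dystrophin and spectrin must be matrices", class = "fiberquant_validation_error")
  }
  if (!identical(dim(dystrophin), dim(spectrin))) {
    abort("dystrophin and spectrin grids must have identical dimensions",
          class = "fiberquant_validation_error")
  }
  for (ch in c("dystrophin", "spectrin")) {
    x <- if (ch == "dystrophin") dystrophin else spectrin
    if (anyNA(x) || any(!is.finite(x))) {
      abort(paste0("non-finite intensities in channel '", ch, "'"),
            class = "fiberquant_validation_error")
    }
    if (min(x) < 0 || max(x) > 4095) {
      abort(paste0("channel '", ch, "' has intensities outside the 12-bit range [0, 4095]"),
            class = "fiberquant_validation_error")
    }
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    abort("pixel_size must be a single positive number (um/pixel)",
          class = "fiberquant_validation_error")
  }
  storage.mode(dystrophin) <- "double"
  storage.mode(spectrin) <- "double"
  structure(
    list(
      dystrophin = dystrophin,
      spectrin = spectrin,
      pixel_size = pixel_size,
      meta = list(
        biopsy_id = biopsy_id, section_id = section_id, image_id = image_id,
        staining_combo = staining_combo,
        is_isotype_control = isTRUE(is_isotype_control),
        bead_reference_intensity = bead_reference_intensity
      )
    ),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$dystrophin)
  cat(sprintf(
    "<section_image> %d x %d px @ %.4g um/px | biopsy=%s section=%s image=%s%s\n",
    d[1], d[2], x$pixel_size, x$meta$biopsy_id, x$meta$section_id,
    x$meta$image_id, if (x$meta$is_isotype_control) " [isotype control]" else ""
  ))
  invisible(x)
}

#' Read a two-channel section image from a multi-plane TIFF
#'
#' Reads a multi-plane (channel-interleaved) TIFF and extracts the dystrophin
#' and spectrin planes named by `channel_map`. Stored sample values are
#' interpreted directly on the 12-bit au scale: integer storage (8/12/16-bit)
#' is read as-is, while floating-point storage normalised to \eqn{[0,1]} is
#' rescaled by 65535 (the convention used by [write_section_image()]).
#'
#' @param path Path to a readable TIFF file with at least two planes.
#' @param channel_map Named list/vector giving the 0-based plane indices of
#'   the two channels, e.g. `list(dystrophin = 0, spectrin = 1)`.
#' @param pixel_size Pixel size in um/pixel.
#' @param ... Metadata passed on to [section_image()] (`biopsy_id`, ...).
#'
#' @return A [section_image()].
#' @export
load_section_image <- function(path, channel_map = list(dystrophin = 0, spectrin = 1),
                               pixel_size, ...) {
  if (!file.exists(path)) {
    abort(paste0("image file not found: ", path), class = "fiberquant_io_error")
  }
  planes <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  need <- vapply(channel_map, as.integer, integer(1))
  if (is.null(names(need)) || !all(c("dystrophin", "spectrin") %in% names(need))) {
    abort("channel_map must name 'dystrophin' and 'spectrin' plane indices",
          class = "fiberquant_format_error")
  }
  if (length(planes) <= max(need)) {
    abort(sprintf(
      "TIFF has %d plane(s) but channel_map requires plane index %d",
      length(planes), max(need)
    ), class = "fiberquant_format_error")
  }
  grab <- function(i, name) {
    p <- planes[[i + 1L]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # collapse grey RGB exports
    m <- matrix(as.numeric(p), nrow = nrow(p), ncol = ncol(p))
    if (max(m) <= 1 && !all(m == floor(m))) m <- m * 65535
    if (min(m) < 0 || max(m) > 4095) {
      abort(paste0(
        "channel '", name, "' has intensities outside the 12-bit range [0, 4095]"
      ), class = "fiberquant_validation_error")
    }
    m
  }
  section_image(
    dystrophin = grab(need[["dystrophin"]], "dystrophin"),
    spectrin = grab(need[["spectrin"]], "spectrin"),
    pixel_size = pixel_size, ...
  )
}

#' Write a section image as a two-plane 16-bit TIFF
#'
#' Values are stored losslessly for integer au intensities (written as
#' `value / 65535` in 16-bit storage, recovered exactly by
#' [load_section_image()]).
#'
#' @param image A [section_image()].
#' @param path Output path.
#' @return `path`, invisibly. Plane 0 is dystrophin, plane 1 spectrin.
#' @export
write_section_image <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  ok <- tryCatch(
    tiff::writeTIFF(
      list(image$dystrophin / 65535, image$spectrin / 65535),
      path, bits.per.sample = 16L
    ),
    error = function(e) abort(paste0("cannot write TIFF: ", conditionMessage(e)),
                              class = "fiberquant_io_error")
  )
  invisible(path)
}
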