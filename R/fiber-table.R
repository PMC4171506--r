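#' Write / read the per-fiber metrics table
#'
#' Comma-separated with a fixed column order (identifiers first, then
#' dystrophin statistics, spectrin, morphometry); missing values are written
#' as empty fields. Numeric values round-trip to at least 6 significant
#' digits.
#'
#' @param metrics Per-fiber metrics tibble from [quantify_image()] (possibly
#'   row-bound over images); an empty tibble writes a header-only file.
#' @param path Output CSV path.
#' @return `write_fiber_table()` returns `path` invisibly;
#'   `read_fiber_table()` returns the tibble.
#' @export
write_fiber_table <- function(metrics, path) {
  stopifnot(is.data.frame(metrics))
  lead <- intersect(c("biopsy_id", "section_id", "image_id", "fiber_id"),
                    names(metrics))
  metrics <- metrics[, c(lead, setdiff(names(metrics), lead))]
  tryCatch(
    readr::write_csv(metrics, path, na = ""),
    error = function(e) abort(paste0("cannot write fiber table: ", conditionMessage(e)),
                              class = "fiberquant_io_error")
  )
  invisible(path)
}

#' @rdname write_fiber_table
#' @export
read_fiber_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("fiber table not found: ", path), class = "fiberquant_io_error")
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Export a fiber label map as a 16-bit single-channel TIFF
#'
#' @param label_map A `fiber_label_map` from [segment_fibers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(label_map, path) {
  stopifnot(inherits(label_map, "fiber_label_map"))
  tiff::writeTIFF(label_map$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Per-experiment mean dystrophin intensities from a multi-experiment
#' reproducibility assessment
#'
#' Bundled example dataset: average sarcolemmal mean dystrophin intensity
#' per fiber (au) of healthy-control, Becker (BMD) and Duchenne (DMD)
#' muscle biopsies, each biopsy analysed in repeat experiments on different
#' days by different operators -- the input for inter-assay precision
#' (CV% across experiment means) and rank-concordance assessment. The
#' `cohort` column separates the control/BMD/DMD series imaged at standard
#' settings from the DMD-only series imaged at high laser settings (the au
#' scales differ). `reference_cv_percent` and `reference_rank` carry the
#' originally reported inter-assay CV (integer percent, repeated on each row
#' of a sample) and sample ranking, used to validate the implementation.
#'
#' @return Tibble with columns `cohort`, `sample`, `experiment`, `mean_au`,
#'   `reference_cv_percent`, `reference_rank`.
#' @export
#' @examples
#' d <- assay_reproducibility_means()
#' cv_percent(d$mean_au[d$sample == "Control 2"], kind = "inter")
assay_reproducibility_means <- function() {
  path <- system.file("extdata", "assay_reproducibility_means.csv",
                      package = "fiberquant", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
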