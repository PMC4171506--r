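#' Segment individual muscle fibers from the spectrin channel
#'
#' Identifies individual muscle fibers in a cross-section field using the
#' spectrin signal as a sarcolemmal mask. The spectrin channel is smoothed
#' with a Gaussian, membrane pixels are separated from fiber interiors by a
#' relative (Otsu) threshold on the normalised channel -- making the
#' segmentation invariant to global acquisition gain -- and each
#' low-intensity basin becomes a fiber seed. Membrane pixels are then grown
#' onto their geodesically nearest interior (4-connected front propagation
#' through the membrane mask), capped at the maximum predicted membrane
#' thickness, so touching membranes of adjacent fibers are split between
#' them. Ties between equally near fibers go to the lower fiber id.
#'
#' Basins qualify as fiber interiors when they are at least
#' `seed_min_area_um2` large, no larger than `max_fiber_area_um2` (the upper
#' physiological bound rejects open background regions), and adjacent to at
#' least one membrane pixel. A field with no spectrin signal therefore
#' yields zero fibers rather than an error.
#'
#' @param image A [section_image()].
#' @param config An [analysis_config()].
#' @param max_fiber_area_um2 Upper bound on plausible fiber cross-sectional
#'   area (um^2); larger candidate regions are treated as background.
#'
#' @return An object of class `fiber_label_map`: list with `labels` (integer
#'   matrix, 0 = background, k = fiber k interior + membrane), `n_fibers`,
#'   and internal matrices `interior` and `membrane` holding the per-fiber
#'   partition used by [split_touching_membranes()].
#' @seealso [split_touching_membranes()], [qc_filter()]
#' @export
segment_fibers <- function(image, config = analysis_config(),
                           max_fiber_area_um2 = 25000) {
  stopifnot(inherits(image, "section_image"), inherits(config, "analysis_config"))
  x <- image$spectrin
  if (anyNA(x) || any(!is.finite(x))) {
    abort("non-finite pixel values in spectrin channel",
          class = "fiberquant_validation_error")
  }
  ps <- image$pixel_size

  sm <- x
  if (config$smoothing_sigma_px > 0) {
    sm <- EBImage::imageData(EBImage::gblur(x, sigma = config$smoothing_sigma_px))
  }

  empty <- function() {
    z <- matrix(0L, nrow(x), ncol(x))
    structure(list(labels = z, n_fibers = 0L, interior = z, membrane = z,
                   threshold_au = NA_real_, pixel_size = ps),
              class = "fiber_label_map")
  }

  mx <- max(sm)
  if (config$threshold_method == "relative") {
    if (mx <= 0) return(empty())
    thr <- EBImage::otsu(EBImage::Image(sm / mx), range = c(0, 1)) * mx
  } else {
    thr <- config$threshold_au
  }
  membrane_mask <- sm >= thr
  if (!any(membrane_mask) || all(membrane_mask)) return(empty())

  lab <- EBImage::imageData(EBImage::bwlabel(!membrane_mask))  # 4-connected basins
  storage.mode(lab) <- "integer"
  n0 <- max(lab)
  areas <- tabulate(lab, nbins = n0)
  min_px <- max(1, round(config$seed_min_area_um2 / ps^2))
  max_px <- max_fiber_area_um2 / ps^2

  touching_mem <- sort(unique(lab[lab > 0L & any_neighbor4(membrane_mask)]))
  keep <- intersect(which(areas >= min_px & areas <= max_px), touching_mem)
  if (!length(keep)) return(empty())

  interior <- relabel_contiguous(lab, keep)
  n_fibers <- max(interior)

  # grow membrane pixels onto the nearest interior, up to the thickness cap
  # (um converted to pixel steps)
  steps <- ceiling(config$membrane_max_thickness_um / ps)
  grown <- assign_band_pixels(interior, membrane_mask, steps)

  structure(
    list(labels = grown$labels, n_fibers = n_fibers, interior = interior,
         membrane = grown$membrane, threshold_au = thr, pixel_size = ps),
    class = "fiber_label_map"
  )
}

#' @export
print.fiber_label_map <- function(x, ...) {
  cat(sprintf("<fiber_label_map> %d fibers on %d x %d px\n",
              x$n_fibers, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Split fiber regions into membrane and cytoplasm masks
#'
#' Turns the label map of [segment_fibers()] into per-fiber membrane and
#' cytoplasm masks. Every spectrin-positive boundary pixel between two
#' adjacent fibers belongs to exactly one fiber's membrane (the one whose
#' interior is geodesically nearer, low id on ties), and no membrane extends
#' beyond the configured maximum membrane thickness from its interior. The
#' cytoplasm mask is the fiber region minus its membrane; the two masks are
#' disjoint and partition the region.
#'
#' @param label_map A `fiber_label_map` from [segment_fibers()] on the same
#'   image.
#' @param spectrin The spectrin intensity grid (unused by the default
#'   geometric assignment; accepted so intensity-weighted variants can share
#'   the signature).
#' @param config The [analysis_config()] used for segmentation.
#'
#' @return An object of class `fiber_set`: list with matrices `labels`,
#'   `membrane`, `cytoplasm` (integer label maps) and `fibers`, a tibble
#'   with one row per fiber (`fiber_id`, `n_membrane_px`, `n_cytoplasm_px`,
#'   `touches_border`, `qc_pass`, `qc_reason`). QC flags are `NA` until
#'   [qc_filter()] runs.
#' @export
split_touching_membranes <- function(label_map, spectrin = NULL,
                                     config = analysis_config()) {
  stopifnot(inherits(label_map, "fiber_label_map"))
  if (config$membrane_max_thickness_um <= 0) {
    abort("membrane_max_thickness_um must be > 0", class = "fiberquant_config_error")
  }
  n <- label_map$n_fibers
  mem <- label_map$membrane
  cyt <- label_map$interior
  fibers <- tibble(
    fiber_id = seq_len(n),
    n_membrane_px = tabulate(mem, nbins = n),
    n_cytoplasm_px = tabulate(cyt, nbins = n),
    touches_border = seq_len(n) %in% border_labels(label_map$labels),
    qc_pass = NA,
    qc_reason = NA_character_
  )
  structure(
    list(labels = label_map$labels, membrane = mem, cytoplasm = cyt,
         pixel_size = label_map$pixel_size, fibers = fibers),
    class = "fiber_set"
  )
}

#' @export
print.fiber_set <- function(x, ...) {
  np <- sum(x$fibers$qc_pass, na.rm = TRUE)
  cat(sprintf("<fiber_set> %d fibers (%s qc-pass)\n", nrow(x$fibers),
              if (all(is.na(x$fibers$qc_pass))) "unflagged" else np))
  invisible(x)
}

#' Flag fibers failing quality control
#'
#' Mirrors the operator practice of avoiding section areas with artefacts:
#' fibers clipped by the image border, implausibly small fibers, and fibers
#' whose membrane covers too little of their perimeter are flagged, not
#' deleted -- downstream quantification filters on `qc_pass`. Reasons are
#' assigned with precedence `border` > `too_small` > `incomplete_membrane`.
#'
#' @param fibers A `fiber_set` from [split_touching_membranes()].
#' @param image The [section_image()] the fibers came from (supplies the
#'   pixel size).
#' @param config An [analysis_config()]; uses `min_fiber_area_um2` and
#'   `min_membrane_coverage`.
#'
#' @return The `fiber_set` with `qc_pass`/`qc_reason` filled in, and a
#'   `membrane_coverage` column (fraction of the interior boundary covered
#'   by the fiber's own membrane).
#' @export
qc_filter <- function(fibers, image, config = analysis_config()) {
  stopifnot(inherits(fibers, "fiber_set"), inherits(image, "section_image"))
  ps <- image$pixel_size
  n <- nrow(fibers$fibers)
  cyt <- fibers$cytoplasm
  mem <- fibers$membrane

  # interior boundary: cytoplasm pixels with a 4-neighbour outside their own
  # cytoplasm; covered when an 8-neighbour belongs to the same fiber's membrane
  boundary <- matrix(FALSE, nrow(cyt), ncol(cyt))
  for (s in .SHIFTS4) {
    nb <- shift_mat(cyt, s[1], s[2], fill = -1L)
    boundary <- boundary | (cyt > 0L & nb != cyt)
  }
  covered <- matrix(FALSE, nrow(cyt), ncol(cyt))
  for (s in .SHIFTS8) {
    nb <- shift_mat(mem, s[1], s[2], fill = 0L)
    covered <- covered | (boundary & nb == cyt)
  }
  nb_bound <- tabulate(cyt[boundary], nbins = n)
  nb_cov <- tabulate(cyt[covered], nbins = n)
  coverage <- ifelse(nb_bound > 0, nb_cov / nb_bound, 0)

  tb <- fibers$fibers
  area_um2 <- (tb$n_membrane_px + tb$n_cytoplasm_px) * ps^2
  reason <- dplyr::case_when(
    tb$touches_border ~ "border",
    area_um2 < config$min_fiber_area_um2 ~ "too_small",
    tb$n_membrane_px == 0 | coverage < config$min_membrane_coverage ~ "incomplete_membrane",
    TRUE ~ "pass"
  )
  fibers$fibers <- tb |>
    mutate(
      membrane_coverage = coverage,
      qc_pass = reason == "pass",
      qc_reason = reason
    )
  fibers
}

#' Match segmented fibers against ground-truth labels
#'
#' For each ground-truth fiber, finds the segmented region with the largest
#' pixel overlap and reports the Jaccard index (intersection over union).
#' Used to score segmentation recall against the synthetic generator's
#' ground truth.
#'
#' @param truth_labels Integer matrix of ground-truth fiber labels.
#' @param seg_labels Integer matrix of segmented fiber labels (same size).
#' @param min_jaccard A truth fiber counts as matched when its best Jaccard
#'   reaches this value (default 0.5).
#'
#' @return A tibble with one row per ground-truth fiber: `truth_id`,
#'   `seg_id` (0 if nothing overlaps), `jaccard`, `matched`.
#' @export
match_fibers <- function(truth_labels, seg_labels, min_jaccard = 0.5) {
  stopifnot(identical(dim(truth_labels), dim(seg_labels)))
  nt <- max(truth_labels)
  area_t <- tabulate(truth_labels, nbins = nt)
  area_s <- tabulate(seg_labels, nbins = max(seg_labels, 1))
  both <- truth_labels > 0L & seg_labels > 0L
  ov <- tibble(t = as.integer(truth_labels[both]), s = as.integer(seg_labels[both])) |>
    count(.data$t, .data$s, name = "inter") |>
    mutate(jaccard = .data$inter /
             (area_t[.data$t] + area_s[.data$s] - .data$inter)) |>
    group_by(.data$t) |>
    slice_max(.data$jaccard, n = 1, with_ties = FALSE) |>
    ungroup()
  tibble(truth_id = seq_len(nt)) |>
    left_join(ov, by = c(truth_id = "t")) |>
    transmute(
      truth_id = .data$truth_id,
      seg_id = coalesce(.data$s, 0L),
      jaccard = coalesce(.data$jaccard, 0),
      matched = .data$jaccard >= min_jaccard
    )
}
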