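#' Run the full quantification pipeline over a batch of images
#'
#' For each image: segment fibers from spectrin, split touching membranes,
#' flag QC failures, quantify QC-passing fibers; then summarise per biopsy.
#' Images are processed in batch and per-image fiber counts are logged in
#' the run manifest.
#'
#' @param images A list of [section_image()] objects, or a character vector
#'   of TIFF paths (then `pixel_size` and `channel_map` apply and metadata
#'   defaults to one biopsy/section with the file name as image id).
#' @param config An [analysis_config()].
#' @param output_dir Optional directory; when given, writes
#'   `fiber_table.csv`, `biopsy_summaries.csv`, one cumulative-curve CSV per
#'   biopsy and `run_manifest.json` there.
#' @param pixel_size,channel_map Used only when `images` are paths.
#'
#' @return List of class `quantify_run`:
#'   \describe{
#'     \item{fiber_table}{per-fiber metrics over all images;}
#'     \item{summaries}{list of [summarize_biopsy()] results, one per biopsy;}
#'     \item{summary_table}{their one-row summaries, row-bound;}
#'     \item{image_log}{tibble of per-image segmented / QC-pass fiber counts;}
#'     \item{manifest}{run manifest (config snapshot, seeds, counts,
#'       software version, timestamps, output files).}
#'   }
#' @export
run_quantify <- function(images, config = analysis_config(), output_dir = NULL,
                         pixel_size = NULL, channel_map = list(dystrophin = 0, spectrin = 1)) {
  t0 <- Sys.time()
  if (is.character(images)) {
    if (length(images) == 0L) {
      abort("no input images", class = "fiberquant_usage_error")
    }
    if (is.null(pixel_size)) {
      abort("pixel_size is required when loading images from paths",
            class = "fiberquant_usage_error")
    }
    paths <- images
    images <- map(paths, function(p) {
      load_section_image(p, channel_map = channel_map, pixel_size = pixel_size,
                         image_id = basename(p))
    })
  }
  if (length(images) == 0L) {
    abort("no input images", class = "fiberquant_usage_error")
  }
  stopifnot(all(vapply(images, inherits, logical(1), "section_image")))

  per_image <- map(images, function(img) {
    lm <- segment_fibers(img, config)
    fs <- split_touching_membranes(lm, img$spectrin, config) |>
      qc_filter(img, config)
    metrics <- quantify_image(img, fs, config)
    list(
      metrics = metrics,
      log = tibble(
        biopsy_id = img$meta$biopsy_id, section_id = img$meta$section_id,
        image_id = img$meta$image_id, n_segmented = lm$n_fibers,
        n_qc_pass = sum(fs$fibers$qc_pass)
      )
    )
  })
  fiber_table <- list_rbind(map(per_image, "metrics"))
  image_log <- list_rbind(map(per_image, "log"))

  summaries <- list()
  if (nrow(fiber_table) > 0) {
    summaries <- fiber_table |>
      group_by(.data$biopsy_id) |>
      dplyr::group_split() |>
      map(summarize_biopsy, config = config)
    names(summaries) <- vapply(summaries, function(s) s$summary$biopsy_id, character(1))
  }
  summary_table <- list_rbind(map(summaries, "summary"))

  outputs <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    f1 <- file.path(output_dir, "fiber_table.csv")
    write_fiber_table(fiber_table, f1)
    f2 <- file.path(output_dir, "biopsy_summaries.csv")
    readr::write_csv(summary_table, f2, na = "")
    outputs <- c(f1, f2)
    for (s in summaries) {
      fc <- file.path(output_dir,
                      paste0("cumulative_curve_", s$summary$biopsy_id, ".csv"))
      readr::write_csv(cumulative_distribution(s$fiber_means), fc)
      outputs <- c(outputs, fc)
    }
  }

  manifest <- list(
    software = paste0("fiberquant ", as.character(packageVersion("fiberquant"))),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    random_seed = config$random_seed,
    n_images = length(images),
    image_log = image_log,
    total_fibers_quantified = nrow(fiber_table),
    outputs = outputs
  )
  if (!is.null(output_dir)) {
    fm <- file.path(output_dir, "run_manifest.json")
    manifest$outputs <- c(manifest$outputs, fm)
    jsonlite::write_json(manifest, fm, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(fiber_table = fiber_table, summaries = summaries,
         summary_table = summary_table, image_log = image_log,
         manifest = manifest),
    class = "quantify_run"
  )
}

#' @export
print.quantify_run <- function(x, ...) {
  cat(sprintf("<quantify_run> %d images, %d fibers quantified, %d biopsies\n",
              x$manifest$n_images, nrow(x$fiber_table), length(x$summaries)))
  if (nrow(x$summary_table)) print(x$summary_table)
  invisible(x)
}

#' Run a pre/post visit comparison over two image sets
#'
#' Quantifies both arms under one configuration, builds the image-within-
#' section study design from per-image means of the per-fiber dystrophin
#' means, and bundles the percent difference, cumulative-curve shift and
#' hierarchical test into one report.
#'
#' @param pre_images,post_images Lists of [section_image()] objects (the two
#'   visits; biopsy metadata of each arm should be internally consistent).
#' @param config An [analysis_config()].
#' @param output_dir Optional directory for the report JSON and CSV tables.
#'
#' @return A `visit_comparison` (see [compare_visits()]), with the two
#'   `quantify_run`s attached as attributes `pre_run` and `post_run`.
#' @export
run_compare <- function(pre_images, post_images, config = analysis_config(),
                        output_dir = NULL) {
  if (length(pre_images) == 0L || length(post_images) == 0L) {
    abort("both pre and post image sets are required", class = "fiberquant_usage_error")
  }
  pre_run <- run_quantify(pre_images, config)
  post_run <- run_quantify(post_images, config)
  if (nrow(pre_run$fiber_table) == 0L || nrow(post_run$fiber_table) == 0L) {
    abort("no quantifiable fibers in one of the arms", class = "fiberquant_validation_error")
  }
  arm <- function(run, visit) {
    run$fiber_table |>
      mutate(visit = visit) |>
      group_by(.data$visit, .data$section_id, .data$image_id) |>
      summarise(value = mean(.data$dys_mean), .groups = "drop")
  }
  design <- study_design(bind_rows(arm(pre_run, "pre"), arm(post_run, "post")) |>
                           mutate(visit = factor(.data$visit, levels = c("pre", "post"))))
  pre_sum <- summarize_biopsy(pre_run$fiber_table |>
                                mutate(biopsy_id = "pre"), config)
  post_sum <- summarize_biopsy(post_run$fiber_table |>
                                 mutate(biopsy_id = "post"), config)
  cmp <- compare_visits(pre_sum, post_sum, design)
  attr(cmp, "pre_run") <- pre_run
  attr(cmp, "post_run") <- post_run

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      c(tidy(cmp) |> as.list(),
        list(test = if (!is.null(cmp$test)) tidy(cmp$test) |> as.list())),
      file.path(output_dir, "comparison_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    readr::write_csv(design, file.path(output_dir, "study_design.csv"))
  }
  cmp
}
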