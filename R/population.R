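#' Summarise a biopsy's fiber population
#'
#' Aggregates per-fiber metrics over all sections and images of one biopsy.
#' The biopsy average is fiber-weighted (each fiber counts once, so sections
#' contribute proportionally to the fibers they hold); per-section means are
#' retained because intra-assay precision is computed across replicate
#' sections. Summaries excluding revertant-class fibers (per-fiber mean at
#' or above `revertant_threshold_au`) are reported alongside, since very
#' bright revertants can dominate a trace-level average.
#'
#' @param metrics Per-fiber metrics tibble from [quantify_image()] (rows
#'   from several images/sections of one biopsy).
#' @param config An [analysis_config()] supplying the class thresholds.
#'
#' @return An object of class `biopsy_summary`: list with
#'   \describe{
#'     \item{summary}{one-row tibble: `biopsy_id`, `n_sections`, `n_fibers`,
#'       `avg_dys_mean`, `avg_q90_mean`, `max_dys_mean` (max over fibers of
#'       the per-fiber mean), `max_dys_max` (max over fibers of the
#'       per-fiber maximum; the two conventions are reported distinctly),
#'       `csa_mean`, `csa_sd`, `spec_mean`, `pct_revertant`,
#'       `avg_dys_mean_excl_revertant`.}
#'     \item{sections}{per-section tibble (`section_id`, `n_fibers`,
#'       `avg_dys_mean`, `avg_q90_mean`) feeding CV computations.}
#'     \item{fiber_means}{the per-fiber dystrophin means, for population
#'       curves.}
#'   }
#' @export
summarize_biopsy <- function(metrics, config = analysis_config()) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    abort("metrics must contain at least one fiber", class = "fiberquant_validation_error")
  }
  ids <- unique(metrics$biopsy_id)
  if (length(ids) != 1L) {
    abort(paste0("metrics mix biopsy_ids: ", paste(ids, collapse = ", ")),
          class = "fiberquant_validation_error")
  }
  cls <- classify_fibers(metrics, config)
  rev_mask <- cls$dys_class == "revertant"
  sections <- metrics |>
    group_by(.data$section_id) |>
    summarise(
      n_fibers = dplyr::n(),
      avg_dys_mean = mean(.data$dys_mean),
      avg_q90_mean = mean(.data$dys_q90_mean),
      .groups = "drop"
    )
  summary <- tibble(
    biopsy_id = ids,
    n_sections = nrow(sections),
    n_fibers = nrow(metrics),
    avg_dys_mean = mean(metrics$dys_mean),
    avg_q90_mean = mean(metrics$dys_q90_mean),
    max_dys_mean = max(metrics$dys_mean),
    max_dys_max = max(metrics$dys_max),
    csa_mean = mean(metrics$csa_um2),
    csa_sd = if (nrow(metrics) > 1) sd(metrics$csa_um2) else NA_real_,
    spec_mean = mean(metrics$spec_mean),
    pct_revertant = 100 * mean(rev_mask),
    avg_dys_mean_excl_revertant =
      if (all(rev_mask)) NA_real_ else mean(metrics$dys_mean[!rev_mask])
  )
  structure(
    list(summary = summary, sections = sections, fiber_means = metrics$dys_mean),
    class = "biopsy_summary"
  )
}

#' @export
print.biopsy_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<biopsy_summary> %s: %d fibers / %d sections | mean %.0f au, Q90-mean %.0f au, %.1f%% revertant\n",
    s$biopsy_id, s$n_fibers, s$n_sections, s$avg_dys_mean, s$avg_q90_mean,
    s$pct_revertant
  ))
  invisible(x)
}

#' Cumulative fiber-intensity curve
#'
#' The per-fiber intensity histogram displayed as a cumulative percentage of
#' fibers gives an S-curve: its slope reflects how homogeneous dystrophin
#' expression is across fibers, and an overall increase in dystrophin shifts
#' the whole curve to the right.
#'
#' @param values Per-fiber dystrophin means (au), at least one.
#'
#' @return A tibble of class `cumulative_curve` with columns `value` (sorted
#'   ascending) and `percent` (empirical cumulative percent of fibers,
#'   reaching 100).
#' @export
cumulative_distribution <- function(values) {
  if (length(values) == 0L) {
    abort("need at least one value", class = "fiberquant_validation_error")
  }
  s <- sort(values)
  structure(
    tibble(value = s, percent = 100 * seq_along(s) / length(s)),
    class = c("cumulative_curve", class(tibble()))
  )
}

#' Is one cumulative curve right-shifted relative to another?
#'
#' Curve B is right-shifted versus A (stochastic dominance) when B's
#' quantile function is at least A's at every probed level.
#'
#' @param curve_a,curve_b `cumulative_curve` objects (or raw value vectors).
#' @param probs Probability levels probed (default 19 evenly spaced levels).
#' @param strict Require strict inequality at every probed level.
#' @return `TRUE`/`FALSE`.
#' @export
is_right_shifted <- function(curve_a, curve_b, probs = seq(0.05, 0.95, by = 0.05),
                             strict = FALSE) {
  va <- if (is.data.frame(curve_a)) curve_a$value else curve_a
  vb <- if (is.data.frame(curve_b)) curve_b$value else curve_b
  qa <- quantile(va, probs, type = 1, names = FALSE)
  qb <- quantile(vb, probs, type = 1, names = FALSE)
  if (strict) all(qb > qa) else all(qb >= qa)
}

#' Classify fibers as negative, trace or revertant
#'
#' Classes follow the per-fiber mean dystrophin intensity with half-open
#' boundaries: below `trace_floor_au` is `negative`, from `trace_floor_au`
#' up to (excluding) `revertant_threshold_au` is `trace`, and at or above
#' `revertant_threshold_au` is `revertant`. The defaults (200, 800 au)
#' reflect the intensity ranges typically observed for trace and revertant
#' fibers at high-sensitivity acquisition settings and are deliberate
#' configuration, since the au scale moves with the acquisition.
#'
#' @param metrics Per-fiber metrics tibble (needs `dys_mean`).
#' @param config An [analysis_config()] (or anything with `trace_floor_au`
#'   and `revertant_threshold_au`).
#'
#' @return `metrics` with a `dys_class` factor column
#'   (`negative`/`trace`/`revertant`).
#' @export
classify_fibers <- function(metrics, config = analysis_config()) {
  lo <- config$trace_floor_au
  hi <- config$revertant_threshold_au
  if (!(lo >= 0 && lo < hi)) {
    abort("need 0 <= trace_floor_au < revertant_threshold_au",
          class = "fiberquant_config_error")
  }
  metrics |>
    mutate(dys_class = factor(
      dplyr::case_when(
        .data$dys_mean < lo ~ "negative",
        .data$dys_mean < hi ~ "trace",
        TRUE ~ "revertant"
      ),
      levels = c("negative", "trace", "revertant")
    ))
}

#' Count fiber classes per biopsy
#'
#' @param metrics Per-fiber metrics tibble.
#' @param config An [analysis_config()].
#' @return Tibble per biopsy: counts of each class and `pct_revertant`.
#' @export
class_counts <- function(metrics, config = analysis_config()) {
  classify_fibers(metrics, config) |>
    group_by(.data$biopsy_id) |>
    summarise(
      n_fibers = dplyr::n(),
      n_negative = sum(.data$dys_class == "negative"),
      n_trace = sum(.data$dys_class == "trace"),
      n_revertant = sum(.data$dys_class == "revertant"),
      pct_revertant = 100 * mean(.data$dys_class == "revertant"),
      .groups = "drop"
    )
}
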