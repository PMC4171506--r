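#' Tidy a hierarchical visit test
#'
#' @param x A `visit_test` from [hierarchical_visit_test()].
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate` (log scale), `std.error`,
#'   `df`, `p.value`, `ratio`, `percent_change`.
#' @method tidy visit_test
#' @export
tidy.visit_test <- function(x, ...) {
  tibble(
    term = "visit (post vs pre)",
    estimate = x$estimate,
    std.error = x$se,
    df = x$df,
    p.value = x$p_value,
    ratio = x$ratio,
    percent_change = x$percent_change
  )
}

#' @rdname tidy.visit_test
#' @return `glance()`: one-row tibble with the variance components
#'   (`var_section`, `var_image_residual`), `n_obs` and `n_sections`.
#' @method glance visit_test
#' @export
glance.visit_test <- function(x, ...) {
  tibble(
    var_section = unname(x$varcomp["section"]),
    var_image_residual = unname(x$varcomp["image_residual"]),
    n_obs = x$n_obs,
    n_sections = x$n_sections
  )
}

#' Tidy a visit comparison report
#'
#' @param x A `visit_comparison` from [compare_visits()].
#' @param ... Unused.
#' @return One-row tibble with the percent difference, right-shift flag and
#'   (when the mixed model ran) its p-value.
#' @method tidy visit_comparison
#' @export
tidy.visit_comparison <- function(x, ...) {
  tibble(
    percent_difference = x$percent_difference,
    percent_difference_rounded = x$percent_difference_rounded,
    right_shift = x$right_shift,
    p_value = if (!is.null(x$test)) x$test$p_value else NA_real_
  )
}
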