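#' Coefficient of variation (CV%) of replicate intensity means
#'
#' CV% = standard deviation / average dystrophin intensity x 100, using the
#' sample (n-1) standard deviation. Intra-assay precision applies the
#' formula to the mean intensities of replicate sections of one biopsy
#' analysed in the same experiment; inter-assay precision to the biopsy's
#' mean intensity from different experiments on different days. Table-style
#' rounding is to the nearest integer percent, half away from zero; the
#' unrounded value is always retained.
#'
#' @param values Two or more positive replicate mean intensities (au).
#' @param kind `"intra"` (across sections) or `"inter"` (across experiments).
#'
#' @return A one-row tibble of class `precision_result`: `kind`, `n`,
#'   `mean_au`, `sd_au`, `cv_percent`, `cv_rounded`.
#' @export
#' @examples
#' cv_percent(c(929, 768), kind = "inter")$cv_rounded   # 13
cv_percent <- function(values, kind = c("intra", "inter")) {
  kind <- match.arg(kind)
  if (length(values) < 2L) {
    abort("CV%% needs at least two replicate values", class = "fiberquant_validation_error")
  }
  m <- mean(values)
  if (!all(values > 0) || m <= 0) {
    abort("CV%% requires positive intensities", class = "fiberquant_validation_error")
  }
  cv <- sd(values) / m * 100
  structure(
    tibble(kind = kind, n = length(values), mean_au = m, sd_au = sd(values),
           cv_percent = cv, cv_rounded = round_half_up(cv)),
    class = c("precision_result", class(tibble()))
  )
}

#' Rank biopsies by dystrophin intensity within each experiment
#'
#' Rank 1 is the highest mean intensity. When the same biopsies are analysed
#' in several experiments, identical rank orders across experiments indicate
#' inter-assay concordance. Ties are broken deterministically by sample
#' label and flagged.
#'
#' @param data Tibble with columns `sample`, `experiment` and `mean_au`
#'   (per-experiment mean dystrophin intensity of each biopsy).
#'
#' @return List of class `sample_ranking`: `ranks` (input plus `rank`),
#'   `concordant` (`TRUE` when every experiment orders the samples common to
#'   all experiments identically), `has_ties`.
#' @export
rank_samples <- function(data) {
  stopifnot(all(c("sample", "experiment", "mean_au") %in% names(data)))
  ranks <- data |>
    group_by(.data$experiment) |>
    arrange(desc(.data$mean_au), .data$sample, .by_group = TRUE) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup()
  has_ties <- ranks |>
    group_by(.data$experiment) |>
    summarise(t = anyDuplicated(.data$mean_au) > 0, .groups = "drop") |>
    pull(.data$t) |>
    any()
  # concordant when no pair of samples is ordered differently in two
  # experiments (experiments need not all contain the same samples)
  pairs <- ranks |>
    inner_join(ranks, by = "experiment", relationship = "many-to-many",
               suffix = c("_a", "_b")) |>
    filter(.data$sample_a < .data$sample_b) |>
    mutate(a_first = .data$rank_a < .data$rank_b) |>
    group_by(.data$sample_a, .data$sample_b) |>
    summarise(consistent = dplyr::n_distinct(.data$a_first) == 1L, .groups = "drop")
  structure(
    list(ranks = ranks, concordant = all(pairs$consistent), has_ties = has_ties),
    class = "sample_ranking"
  )
}

#' @export
print.sample_ranking <- function(x, ...) {
  cat(sprintf("<sample_ranking> %d experiments, concordant: %s%s\n",
              dplyr::n_distinct(x$ranks$experiment), x$concordant,
              if (x$has_ties) " (ties broken by label)" else ""))
  print(x$ranks)
  invisible(x)
}

#' Percent dystrophin difference between two visits
#'
#' Percentage dystrophin difference = (post - pre) / pre x 100; positive
#' means higher dystrophin post-treatment.
#'
#' @param pre,post Average mean dystrophin intensity (au) of the pre- and
#'   post-treatment biopsy; `pre` must be positive.
#' @return Signed percent difference (numeric scalar).
#' @export
#' @examples
#' percent_difference(100, 130)   # +30
percent_difference <- function(pre, post) {
  if (!is.numeric(pre) || length(pre) != 1L || pre <= 0) {
    abort("pre-treatment intensity must be a single positive value",
          class = "fiberquant_validation_error")
  }
  (post - pre) / pre * 100
}

#' Assemble a study design table
#'
#' The unit of analysis of the pre/post comparison is the per-image mean of
#' the per-fiber dystrophin means, nested as images within sections within
#' visits.
#'
#' @param metrics Per-fiber metrics (from [quantify_image()]) with a `visit`
#'   column, or a ready-made tibble with `visit`, `section_id`, `image_id`,
#'   `value`.
#' @return Tibble of class `study_design` with one row per image:
#'   `visit`, `section_id`, `image_id`, `value` (au).
#' @export
study_design <- function(metrics) {
  stopifnot(is.data.frame(metrics), "visit" %in% names(metrics))
  d <- if ("value" %in% names(metrics)) {
    as_tibble(metrics)[, c("visit", "section_id", "image_id", "value")]
  } else {
    metrics |>
      group_by(.data$visit, .data$section_id, .data$image_id) |>
      summarise(value = mean(.data$dys_mean), .groups = "drop")
  }
  structure(d, class = c("study_design", class(tibble())))
}

#' Hierarchical mixed-model test of the visit effect
#'
#' Fits the pre/post comparison on the log scale with the nesting the assay
#' design implies: `log(value) ~ visit + (1 | section)`, sections nested in
#' visits as a random factor and images within sections as the residual
#' level (one per-image mean per image makes the image effect the residual).
#' Variance components are estimated by REML and the visit contrast is
#' tested with Satterthwaite denominator degrees of freedom.
#'
#' @param design A [study_design()] tibble: `visit` (two levels; the later
#'   visit is the reference shift), `section_id` (unique per section),
#'   `image_id`, positive `value` (au per-image mean).
#' @param ref Visit level treated as baseline (default the first level met).
#'
#' @return Object of class `visit_test`: list with `estimate` (log-scale
#'   visit effect, post minus pre), `se`, `df`, `p_value`, `ratio`
#'   (`exp(estimate)`), `percent_change`, `varcomp` (named vector:
#'   `section`, `image_residual` variances on the log scale), and `model`
#'   (the `lmerModLmerTest` fit).
#' @seealso [permutation_visit_test()] for a distribution-free alternative.
#' @export
hierarchical_visit_test <- function(design, ref = NULL) {
  d <- validate_design(design)
  ref <- ref %||% as.character(d$visit[1])
  d$visit <- stats::relevel(factor(d$visit), ref = ref)
  nsec <- d |> count(.data$visit, .data$section_id) |> count(.data$visit)
  if (any(nsec$n < 2)) {
    abort(paste0(
      "fewer than 2 sections in a visit: the section-level variance is not ",
      "estimable. Use permutation_visit_test(..., unit = 'image') instead ",
      "(note: image-level exchange ignores section correlation and is ",
      "anti-conservative)."
    ), class = "fiberquant_design_error")
  }
  d$log_value <- log(d$value)

  # no-noise limit: all variation is the visit contrast, REML is degenerate;
  # return the exact limit instead of a numerically unstable fit
  visit_means <- tapply(d$log_value, d$visit, mean)
  if (all(abs(d$log_value - visit_means[as.character(d$visit)]) < 1e-10)) {
    est <- unname(visit_means[setdiff(names(visit_means), ref)] - visit_means[ref])
    return(structure(
      list(estimate = est, se = 0, df = NA_real_,
           p_value = if (abs(est) > 0) 0 else 1,
           ratio = exp(est), percent_change = 100 * (exp(est) - 1),
           varcomp = c(section = 0, image_residual = 0),
           ref = ref, n_obs = nrow(d),
           n_sections = dplyr::n_distinct(d$section_id), model = NULL),
      class = "visit_test"
    ))
  }

  fit <- lmerTest::lmer(log_value ~ visit + (1 | section_id), data = d)
  co <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      estimate = co[2, "Estimate"], se = co[2, "Std. Error"],
      df = co[2, "df"], p_value = co[2, "Pr(>|t|)"],
      ratio = exp(co[2, "Estimate"]),
      percent_change = 100 * (exp(co[2, "Estimate"]) - 1),
      varcomp = c(section = vc$vcov[vc$grp == "section_id"],
                  image_residual = vc$vcov[vc$grp == "Residual"]),
      ref = ref,
      n_obs = nrow(d),
      n_sections = dplyr::n_distinct(d$section_id),
      model = fit
    ),
    class = "visit_test"
  )
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  need <- c("visit", "section_id", "image_id", "value")
  if (!all(need %in% names(design))) {
    abort(paste0("design needs columns: ", paste(need, collapse = ", ")),
          class = "fiberquant_validation_error")
  }
  if (dplyr::n_distinct(design$visit) != 2L) {
    abort("design must have exactly two visits", class = "fiberquant_design_error")
  }
  if (any(design$value <= 0)) {
    abort("all per-image means must be positive for the log transform",
          class = "fiberquant_validation_error")
  }
  nimg <- design |> count(.data$visit, .data$section_id)
  if (any(nimg$n < 2)) {
    abort("each section needs at least 2 images", class = "fiberquant_design_error")
  }
  as_tibble(design)
}

#' @export
print.visit_test <- function(x, ...) {
  cat(sprintf(
    "<visit_test> visit effect (log scale) = %.4f (ratio %.3f, %+.1f%%), SE %.4f, df %.1f, p = %.4g\n",
    x$estimate, x$ratio, x$percent_change, x$se, x$df, x$p_value
  ))
  cat(sprintf("  variance components: section %.5f, image/residual %.5f\n",
              x$varcomp["section"], x$varcomp["image_residual"]))
  invisible(x)
}

#' Hierarchical permutation test of the visit effect
#'
#' Distribution-free alternative to [hierarchical_visit_test()]: visit
#' labels are permuted at the section level (whole sections exchanged
#' between visits), respecting the correlation of images within a section.
#' The statistic is the difference between visit means of section-level
#' mean log values. With one section per visit, section-level exchange is
#' impossible; `unit = "image"` then permutes image labels instead, which
#' ignores section correlation and is anti-conservative.
#'
#' @param design A [study_design()] tibble.
#' @param n_perm Number of random permutations (default 999). When the
#'   number of distinct section-label assignments is small, all are
#'   enumerated exactly instead.
#' @param unit `"section"` (default) or `"image"` exchangeability.
#' @param ref Baseline visit (default first level met).
#'
#' @return List of class `visit_permutation`: `statistic` (observed log-mean
#'   difference, post minus pre), `p_value` (two-sided), `n_perm`, `exact`,
#'   `unit`.
#' @export
permutation_visit_test <- function(design, n_perm = 999,
                                   unit = c("section", "image"), ref = NULL) {
  unit <- match.arg(unit)
  d <- validate_design(design)
  ref <- ref %||% as.character(d$visit[1])
  d$log_value <- log(d$value)

  if (unit == "section") {
    sec <- d |>
      group_by(.data$visit, .data$section_id) |>
      summarise(m = mean(.data$log_value), .groups = "drop")
    grp <- sec$visit != ref
    vals <- sec$m
  } else {
    grp <- d$visit != ref
    vals <- d$log_value
  }
  stat <- function(g) mean(vals[g]) - mean(vals[!g])
  obs <- stat(grp)

  n <- length(vals); k <- sum(grp)
  n_assign <- choose(n, k)
  if (n_assign <= n_perm + 1) {
    idx <- utils::combn(n, k, simplify = FALSE)
    perms <- vapply(idx, function(i) stat(seq_len(n) %in% i), numeric(1))
    p <- mean(abs(perms) >= abs(obs) - 1e-12)
    exact <- TRUE
    n_used <- length(perms)
  } else {
    perms <- replicate(n_perm, stat(sample(grp)))
    p <- (1 + sum(abs(perms) >= abs(obs) - 1e-12)) / (n_perm + 1)
    exact <- FALSE
    n_used <- n_perm
  }
  structure(
    list(statistic = obs, p_value = p, n_perm = n_used, exact = exact, unit = unit),
    class = "visit_permutation"
  )
}

#' @export
print.visit_permutation <- function(x, ...) {
  cat(sprintf(
    "<visit_permutation> log-mean difference = %.4f, p = %.4g (%s, %d %s permutations)\n",
    x$statistic, x$p_value, if (x$exact) "exact" else "Monte Carlo",
    x$n_perm, x$unit
  ))
  invisible(x)
}

#' Compare pre- and post-treatment biopsies
#'
#' Bundles the three views of a paired visit comparison into one report:
#' the percent dystrophin difference of the biopsy averages, whether the
#' post-treatment cumulative fiber curve is right-shifted, and the
#' hierarchical mixed-model test on per-image means.
#'
#' @param pre_summary,post_summary [summarize_biopsy()] results for the
#'   pre- and post-treatment biopsy, analysed under one configuration.
#' @param design Optional [study_design()] covering both visits; when
#'   supplied the mixed-model test is run.
#' @param staining_combo_pre,staining_combo_post Optional antibody-pair
#'   labels; a mismatch is recorded as a warning in the report.
#'
#' @return List of class `visit_comparison`: `percent_difference`,
#'   `percent_difference_rounded`, `right_shift` (logical), `test`
#'   (a `visit_test` or `NULL`), `pre`, `post` (the summary rows),
#'   `warnings` (character).
#' @export
compare_visits <- function(pre_summary, post_summary, design = NULL,
                           staining_combo_pre = NULL, staining_combo_post = NULL) {
  stopifnot(inherits(pre_summary, "biopsy_summary"),
            inherits(post_summary, "biopsy_summary"))
  warnings <- character(0)
  if (!is.null(staining_combo_pre) && !is.null(staining_combo_post) &&
      !identical(staining_combo_pre, staining_combo_post)) {
    warnings <- c(warnings, sprintf(
      "staining combination differs between arms ('%s' vs '%s')",
      staining_combo_pre, staining_combo_post
    ))
  }
  pd <- percent_difference(pre_summary$summary$avg_dys_mean,
                           post_summary$summary$avg_dys_mean)
  shift <- is_right_shifted(pre_summary$fiber_means, post_summary$fiber_means)
  test <- if (!is.null(design)) hierarchical_visit_test(design) else NULL
  structure(
    list(
      percent_difference = pd,
      percent_difference_rounded = round_half_up(pd),
      right_shift = shift,
      test = test,
      pre = pre_summary$summary,
      post = post_summary$summary,
      warnings = warnings
    ),
    class = "visit_comparison"
  )
}

#' @export
print.visit_comparison <- function(x, ...) {
  cat(sprintf(
    "<visit_comparison> dystrophin difference %+.1f%% (post vs pre); cumulative curve right-shifted: %s\n",
    x$percent_difference, x$right_shift
  ))
  if (!is.null(x$test)) print(x$test)
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
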