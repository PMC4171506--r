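test_that("CV% uses the sample SD and reproduces table-style rounding", {
  expect_equal(cv_percent(c(929, 768))$cv_rounded, 13)
  expect_equal(cv_percent(c(306, 427, 354))$cv_rounded, 17)
  expect_equal(cv_percent(c(500, 500))$cv_percent, 0)
  expect_error(cv_percent(400), class = "fiberquant_validation_error")
  expect_error(cv_percent(c(-1, 5)), class = "fiberquant_validation_error")
})

test_that("CV% matches the two-value closed form and is scale-invariant", {
  set.seed(2)
  for (i in 1:25) {
    ab <- runif(2, 10, 2000)
    closed <- abs(ab[1] - ab[2]) / sum(ab) * sqrt(2) * 100
    expect_equal(cv_percent(ab)$cv_percent, closed)
    v <- runif(sample(2:6, 1), 10, 2000)
    g <- runif(1, 0.1, 10)
    expect_equal(cv_percent(v * g)$cv_percent, cv_percent(v)$cv_percent)
  }
})

test_that("samples rank by intensity with deterministic ties and concordance", {
  d <- tibble::tibble(sample = c("A", "B", "C"), experiment = 1,
                      mean_au = c(929, 415, 58))
  r <- rank_samples(d)
  expect_equal(r$ranks$rank[match(c("A", "B", "C"), r$ranks$sample)], 1:3)

  d2 <- dplyr::bind_rows(d, dplyr::mutate(d, experiment = 2, mean_au = mean_au * 1.1))
  expect_true(rank_samples(d2)$concordant)

  d3 <- dplyr::bind_rows(d, tibble::tibble(
    sample = c("A", "B", "C"), experiment = 2, mean_au = c(58, 415, 929)))
  expect_false(rank_samples(d3)$concordant)

  tied <- tibble::tibble(sample = c("B", "A"), experiment = 1, mean_au = c(7, 7))
  rt <- rank_samples(tied)
  expect_true(rt$has_ties)
  expect_equal(rt$ranks$sample[rt$ranks$rank == 1], "A")   # label order
})

test_that("the bundled reproducibility data reproduce reported CVs and ranking", {
  d <- assay_reproducibility_means()
  cvs <- d |>
    dplyr::group_by(cohort, sample) |>
    dplyr::summarise(got = cv_percent(mean_au, kind = "inter")$cv_rounded,
                     want = reference_cv_percent[1], .groups = "drop")
  expect_equal(cvs$got, cvs$want)

  dmd <- d |> dplyr::filter(cohort == "high_laser")
  r <- rank_samples(dmd)
  expect_true(r$concordant)
  overall <- dmd |>
    dplyr::group_by(sample) |>
    dplyr::summarise(mean_au = mean(mean_au), reference_rank = reference_rank[1]) |>
    dplyr::mutate(experiment = 1)
  ro <- rank_samples(overall)
  expect_equal(ro$ranks$rank[match(overall$sample, ro$ranks$sample)],
               overall$reference_rank)
})

test_that("percent difference has the stated sign convention and reciprocity", {
  expect_equal(percent_difference(100, 130), 30)
  expect_equal(percent_difference(250, 250), 0)
  expect_equal(percent_difference(200, 150), -25)
  expect_error(percent_difference(0, 10), class = "fiberquant_validation_error")
  set.seed(4)
  for (i in 1:20) {
    ab <- runif(2, 1, 1000)
    d1 <- percent_difference(ab[1], ab[2])
    d2 <- percent_difference(ab[2], ab[1])
    expect_equal((1 + d1 / 100) * (1 + d2 / 100), 1)
  }
})

test_that("the no-noise limit of the visit test is the exact log ratio", {
  st <- generate_study(visit_effect = log(1.3), section_sd_log = 0, image_sd_log = 0)
  expect_equal(
    dplyr::filter(st$design, visit == "post")$value,
    dplyr::filter(st$design, visit == "pre")$value * 1.3
  )
  vt <- hierarchical_visit_test(st$design)
  expect_equal(vt$estimate, log(1.3))
  expect_equal(vt$ratio, 1.3)
  expect_equal(vt$p_value, 0)
  expect_equal(unname(vt$varcomp), c(0, 0))

  null <- generate_study(visit_effect = 0, section_sd_log = 0, image_sd_log = 0)
  vt0 <- hierarchical_visit_test(null$design)
  expect_equal(vt0$estimate, 0)
  expect_equal(vt0$p_value, 1)
})

test_that("the mixed model estimates effect and variance components sensibly", {
  st <- generate_study(visit_effect = log(1.3), seed = 42)
  vt <- hierarchical_visit_test(st$design)
  expect_equal(vt$estimate, log(1.3), tolerance = 0.35)
  expect_true(all(vt$varcomp >= 0))
  expect_lt(vt$p_value, 0.05)
  td <- tidy(vt)
  expect_equal(td$estimate, vt$estimate)
  gl <- glance(vt)
  expect_equal(gl$n_obs, 40)
  expect_equal(gl$n_sections, 8)
})

test_that("degenerate designs are refused with advice, permutation test works", {
  st <- generate_study(n_sections_per_visit = 1, seed = 2)
  expect_error(hierarchical_visit_test(st$design),
               class = "fiberquant_design_error")
  pt <- permutation_visit_test(st$design, unit = "image")
  expect_true(pt$p_value > 0 && pt$p_value <= 1)

  st2 <- generate_study(visit_effect = log(2), section_sd_log = 0.05,
                        image_sd_log = 0.05, seed = 5)
  pt2 <- permutation_visit_test(st2$design)
  expect_true(pt2$exact)            # choose(8, 4) = 70 assignments enumerated
  expect_lt(pt2$p_value, 0.05)
  expect_equal(pt2$statistic, with(
    st2$design |>
      dplyr::group_by(visit, section_id) |>
      dplyr::summarise(m = mean(log(value)), .groups = "drop") |>
      dplyr::group_by(visit) |>
      dplyr::summarise(m = mean(m)),
    m[visit == "post"] - m[visit == "pre"]
  ))
})

test_that("compare_visits bundles difference, shift and test", {
  pre <- summarize_biopsy(make_metrics(rep(c(250, 350), 10), biopsy_id = "pre"))
  post <- summarize_biopsy(make_metrics(rep(c(325, 455), 10), biopsy_id = "post"))
  cmp <- compare_visits(pre, post)
  expect_equal(cmp$percent_difference, 30)
  expect_true(cmp$right_shift)
  expect_length(cmp$warnings, 0)

  same <- compare_visits(pre, pre)
  expect_equal(same$percent_difference, 0)

  cmp2 <- compare_visits(pre, post, staining_combo_pre = "MANDYS106",
                         staining_combo_post = "ab15277")
  expect_length(cmp2$warnings, 1)
  expect_match(cmp2$warnings, "staining")
})
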