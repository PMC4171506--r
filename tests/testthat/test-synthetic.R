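test_that("generation is bitwise reproducible from the seed", {
  p <- small_params(seed = 99)
  g1 <- generate_section(p)
  g2 <- generate_section(p)
  expect_identical(g1$image$dystrophin, g2$image$dystrophin)
  expect_identical(g1$image$spectrin, g2$image$spectrin)
  expect_identical(g1$truth$labels, g2$truth$labels)
  g3 <- generate_section(p, seed = 100)
  expect_false(identical(g1$image$dystrophin, g3$image$dystrophin))
})

test_that("ground-truth masks are disjoint and consistent", {
  g <- generate_section(small_params(seed = 12))
  tr <- g$truth
  # every pixel belongs to at most one fiber; membrane owner need not be the
  # covering cell at junctions, but must be a real fiber id
  expect_true(all(tr$labels >= 0 & tr$labels <= nrow(tr$fibers)))
  expect_true(all(tr$membrane[tr$membrane > 0] %in% tr$fibers$fiber_id))
  expect_equal(sum(tr$fibers$n_membrane_px), sum(tr$membrane > 0))
  expect_equal(sum(tr$fibers$csa_um2_true), prod(dim(tr$labels)) *
                 g$image$pixel_size^2)
})

test_that("noiseless rendering reproduces drawn membrane means exactly", {
  p <- generator_params("dmd_trace", n_fibers = 30, dim = c(224, 224),
                        noise_sd = 0, blur_sigma = 0, seed = 6,
                        dys_means = seq(150, by = 30, length.out = 30))
  g <- generate_section(p)
  for (k in c(1, 10, 25)) {
    mask <- g$truth$membrane == k
    if (any(mask)) {
      expect_equal(mean(g$image$dystrophin[mask]),
                   g$truth$fibers$dys_mean_true[k])
    }
  }
})

test_that("a single closed-border fiber recovers its mean exactly", {
  p <- generator_params("healthy", n_fibers = 1, dim = c(96, 96), pixel_size = 1,
                        noise_sd = 0, blur_sigma = 0, closed_border = TRUE,
                        dys_means = 600, seed = 1)
  g <- generate_section(p)
  expect_gt(sum(g$truth$membrane == 1), 0)
  st <- membrane_intensity_stats(g$image$dystrophin[g$truth$membrane == 1])
  expect_identical(st$mean, 600)
  expect_identical(st$q90_mean, 600)
})

test_that("revertant fibers appear at the preset frequency", {
  # 500 fibers over several seeded fields; binomial 95% bounds around 0.05
  classes <- unlist(lapply(1:5, function(s) {
    g <- generate_section(generator_params("dmd_trace", n_fibers = 100,
                                           dim = c(400, 400), seed = 1000 + s))
    as.character(g$truth$fibers$class)
  }))
  n <- length(classes)
  expect_equal(n, 500)
  phat <- mean(classes == "revertant")
  half <- 1.96 * sqrt(0.05 * 0.95 / n)
  expect_true(phat > 0.05 - half && phat < 0.05 + half)
  # revertant means sit in the preset range, trace means below it
  g <- generate_section(generator_params("dmd_trace", n_fibers = 100,
                                         dim = c(400, 400), seed = 77))
  tf <- g$truth$fibers
  expect_true(all(tf$dys_mean_true[tf$class == "revertant"] >= 800))
  expect_true(all(tf$dys_mean_true[tf$class == "revertant"] <= 2500))
  expect_true(all(tf$dys_mean_true[tf$class == "trace"] < 800))
})

test_that("healthy preset spans the expected per-fiber intensity range", {
  g <- generate_section(generator_params("healthy", n_fibers = 100,
                                         dim = c(480, 480), seed = 15))
  mus <- g$truth$fibers$dys_mean_true
  # ~95% of draws inside 500-1350 au by construction
  expect_gt(mean(mus >= 500 & mus <= 1350), 0.85)
  expect_equal(median(mus), sqrt(500 * 1350), tolerance = 0.1)
})

test_that("infeasible geometry is refused before rendering", {
  expect_error(
    generate_section(generator_params("dmd_trace", n_fibers = 500, dim = c(64, 64))),
    class = "fiberquant_config_error"
  )
  expect_error(generator_params("healthy", revertant_fraction = 1.5),
               class = "fiberquant_config_error")
})

test_that("study generation respects variance components and the visit effect", {
  st <- generate_study(visit_effect = log(1.3), section_sd_log = 0, image_sd_log = 0)
  d <- st$design
  expect_equal(nrow(d), 40)
  expect_equal(d$value[d$visit == "post"], d$value[d$visit == "pre"] * 1.3)

  # intra-assay CV of section means grows with the section-level SD
  cv_at <- function(ssd) {
    mean(vapply(1:30, function(r) {
      dd <- generate_study(section_sd_log = ssd, image_sd_log = 0.02,
                           seed = 500 + r)$design
      secs <- dd |>
        dplyr::filter(visit == "pre") |>
        dplyr::group_by(section_id) |>
        dplyr::summarise(m = mean(value), .groups = "drop")
      cv_percent(secs$m, kind = "intra")$cv_percent
    }, numeric(1)))
  }
  cvs <- c(cv_at(0.02), cv_at(0.08), cv_at(0.2))
  expect_true(all(diff(cvs) > 0))
  expect_gt(cvs[1], 0)
})

test_that("rendered studies carry the design into actual images", {
  st <- generate_study(visit_effect = log(1.3), n_sections_per_visit = 2,
                       n_images_per_section = 2, render = TRUE,
                       params = generator_params("dmd_trace", n_fibers = 20,
                                                 dim = c(192, 192),
                                                 noise_sd = 0, blur_sigma = 0),
                       seed = 9)
  expect_length(st$images, 8)
  img1 <- st$images[[1]]
  expect_s3_class(img1$image, "section_image")
  # rendered per-fiber means average near the image-level design value
  expect_equal(mean(img1$truth$fibers$dys_mean_true), st$design$value[1],
               tolerance = 0.25)
})
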