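test_that("intensity statistics match the brute-force sort oracle exactly", {
  expect_error(membrane_intensity_stats(numeric(0)),
               class = "fiberquant_validation_error")

  s <- membrane_intensity_stats(1:10)
  expect_equal(s$mean, 5.5)
  expect_equal(s$min, 1)
  expect_equal(s$max, 10)
  expect_equal(s$q90, 9)
  expect_equal(s$q90_mean, 10)         # top ceil(1) = 1 pixel

  s20 <- membrane_intensity_stats(1:20)
  expect_equal(s20$q90_mean, 19.5)     # (19 + 20) / 2

  sc <- membrane_intensity_stats(rep(500, 7))
  expect_equal(sc$mean, 500)
  expect_equal(sc$q90, 500)
  expect_equal(sc$q90_mean, 500)
  expect_equal(sc$max, 500)

  set.seed(101)
  for (i in 1:100) {
    n <- sample(1:1000, 1)
    v <- runif(n, 0, 4095)
    got <- membrane_intensity_stats(v)
    want <- oracle_stats(v)
    expect_equal(got$mean, want$mean)
    expect_identical(got$min, want$min)
    expect_identical(got$max, want$max)
    expect_identical(unlist(got[c("q25", "q50", "q75", "q90")], use.names = FALSE),
                     want$q)
    expect_equal(got$q90_mean, want$q90_mean)
  }
})

test_that("statistics are shift- and scale-equivariant and quantiles monotone", {
  set.seed(7)
  for (i in 1:20) {
    v <- runif(sample(5:400, 1), 0, 3000)
    base <- membrane_intensity_stats(v)
    cols <- c("mean", "min", "max", "q25", "q50", "q75", "q90", "q90_mean")
    shifted <- membrane_intensity_stats(v + 123.5)
    expect_equal(unlist(shifted[cols]), unlist(base[cols]) + 123.5)
    scaled <- membrane_intensity_stats(v * 1.3)
    expect_equal(unlist(scaled[cols]), unlist(base[cols]) * 1.3)
    qs <- unlist(base[c("q25", "q50", "q75", "q90")])
    expect_true(!is.unsorted(qs))
    expect_lte(base$q90, base$q90_mean)
    expect_lte(base$mean, base$q90_mean)
  }
})

test_that("morphometry recovers analytic disk area and ring thickness", {
  # filled disk, radius 50 px at 0.5 um/px -> csa ~ pi * 25^2 um2
  n <- 128
  d <- sqrt((row(diag(n)) - 64)^2 + (col(diag(n)) - 64)^2)
  ring <- d <= 50 & d > 47
  disk <- d <= 47
  labels <- matrix(0L, n, n); labels[ring | disk] <- 1L
  membrane <- matrix(0L, n, n); membrane[ring] <- 1L
  cyt <- matrix(0L, n, n); cyt[disk] <- 1L
  fs <- structure(list(labels = labels, membrane = membrane, cytoplasm = cyt,
                       pixel_size = 0.5,
                       fibers = tibble::tibble(fiber_id = 1L,
                                               n_membrane_px = sum(ring),
                                               n_cytoplasm_px = sum(disk),
                                               touches_border = FALSE,
                                               qc_pass = TRUE, qc_reason = "pass")),
                  class = "fiber_set")
  mo <- fiber_morphometry(fs, pixel_size = 0.5)
  expect_equal(mo$csa_um2, pi * 25^2, tolerance = 0.02)
  # 3 px wall at 0.5 um/px -> 1.5 um
  expect_equal(mo$membrane_thickness_um, 1.5, tolerance = 0.15)
  expect_false(mo$degenerate)

  # degenerate fiber: all membrane, no cytoplasm
  fs$cytoplasm[] <- 0L
  fs$membrane <- fs$labels
  fs$fibers$n_membrane_px <- sum(fs$labels)
  fs$fibers$n_cytoplasm_px <- 0L
  mo2 <- fiber_morphometry(fs, 0.5)
  expect_true(mo2$degenerate)
  expect_gt(mo2$csa_um2, 0)
  expect_gt(mo2$membrane_thickness_um, 0)
})

test_that("healthy-preset morphometry recovers the generator CSA target within 10%", {
  p <- generator_params("healthy", seed = 19)
  g <- generate_section(p)
  cfg <- analysis_config()
  lm <- segment_fibers(g$image, cfg)
  fs <- split_touching_membranes(lm, g$image$spectrin, cfg) |> qc_filter(g$image, cfg)
  met <- quantify_image(g$image, fs, cfg)
  # interior fibers only; compare to the matched ground-truth cells
  m <- match_fibers(g$truth$labels, lm$labels)
  truth_csa <- g$truth$fibers$csa_um2_true[m$seg_id %in% met$fiber_id & m$matched]
  expect_equal(mean(met$csa_um2), mean(truth_csa), tolerance = 0.1)
  expect_equal(mean(met$csa_um2) / 1e3, 4.4, tolerance = 0.25)  # low-10^3 um2 range
})

test_that("noiseless synthetic fibers are recovered exactly by the full pipeline", {
  mus <- seq(100, by = 25, length.out = 80)
  p <- generator_params("dmd_trace", noise_sd = 0, blur_sigma = 0, seed = 3,
                        dys_means = mus)
  g <- generate_section(p)
  cfg <- analysis_config(smoothing_sigma_px = 0)
  lm <- segment_fibers(g$image, cfg)
  fs <- split_touching_membranes(lm, g$image$spectrin, cfg) |> qc_filter(g$image, cfg)
  met <- quantify_image(g$image, fs, cfg)
  m <- match_fibers(g$truth$labels, lm$labels)
  mp <- m[m$seg_id %in% met$fiber_id, ]
  expect_gt(nrow(mp), 20)
  measured <- met$dys_mean[match(mp$seg_id, met$fiber_id)]
  expect_identical(measured, mus[mp$truth_id])
})

test_that("adding a constant to the dystrophin channel shifts every mean by it", {
  g <- generate_section(small_params(seed = 4))
  cfg <- analysis_config()
  lm <- segment_fibers(g$image, cfg)
  fs <- split_touching_membranes(lm, g$image$spectrin, cfg) |> qc_filter(g$image, cfg)
  met <- quantify_image(g$image, fs, cfg)
  shifted_img <- section_image(pmin(g$image$dystrophin + 100, 4095), g$image$spectrin,
                               pixel_size = g$image$pixel_size)
  met2 <- quantify_image(shifted_img, fs, cfg)
  expect_equal(met2$dys_mean, met$dys_mean + 100)
  expect_equal(met2$dys_q90_mean, met$dys_q90_mean + 100)
  expect_equal(met2$dys_q90, met$dys_q90 + 100)
})

test_that("quantify_image demands QC flags and matching provenance", {
  g <- generate_section(small_params(seed = 4))
  cfg <- analysis_config()
  lm <- segment_fibers(g$image, cfg)
  fs <- split_touching_membranes(lm, g$image$spectrin, cfg)
  expect_error(quantify_image(g$image, fs, cfg),
               class = "fiberquant_validation_error")   # QC not run
  fs <- qc_filter(fs, g$image, cfg)
  other <- section_image(matrix(0, 32, 32), matrix(0, 32, 32), pixel_size = 1)
  expect_error(quantify_image(other, fs, cfg),
               class = "fiberquant_validation_error")   # dimension mismatch

  # all fibers failing QC gives an empty, well-formed table
  fs_fail <- fs
  fs_fail$fibers$qc_pass <- FALSE
  empty <- quantify_image(g$image, fs_fail, cfg)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("dys_mean", "dys_q90_mean", "csa_um2") %in% names(empty)))
})
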