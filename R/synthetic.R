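#' Parameters for the synthetic muscle cross-section generator
#'
#' The generator emulates a transverse muscle cross-section as a seeded
#' Voronoi tessellation with Lloyd relaxation (packed convex polygons, the
#' morphology of real fiber mosaics), a membrane band of fixed physical
#' thickness along every fiber-fiber boundary positive in both channels,
#' per-fiber intensities drawn from preset distributions, then Gaussian
#' blur, noise and 12-bit quantization -- in that order, since the order
#' affects recovery tolerances.
#'
#' Presets set the per-fiber dystrophin mean distribution and the pixel size
#' (hence fiber cross-sectional area):
#' \describe{
#'   \item{healthy}{log-normal spanning ~500--1350 au (the ~3-fold per-fiber
#'     variation of healthy muscle); CSA ~4400 um^2.}
#'   \item{bmd}{intermediate levels, ~150--600 au; CSA ~6000 um^2.}
#'   \item{dmd_trace}{trace dystrophin ~200--800 au (upper-truncated), with
#'     revertant fibers drawn uniformly from 800--2500 au at
#'     `revertant_fraction`; CSA ~2500 um^2 (dystrophic fibers are
#'     smaller).}
#' }
#'
#' @param preset `"healthy"`, `"bmd"` or `"dmd_trace"`.
#' @param n_fibers Fibers per field (default 80, a typical field load).
#' @param dim Field size in pixels (rows, cols).
#' @param pixel_size um/pixel; default derived from the preset CSA target.
#' @param membrane_thickness_um Per-fiber membrane band thickness (um).
#' @param spec_membrane_mean,spec_membrane_sd Per-fiber spectrin membrane
#'   intensity distribution (au).
#' @param dys_meanlog,dys_sdlog Log-normal parameters of the per-fiber
#'   dystrophin mean; defaults from the preset.
#' @param dys_upper_trunc_au Upper truncation of the non-revertant draw
#'   (au); `Inf` disables. The `dmd_trace` preset truncates at the
#'   revertant threshold so trace and revertant populations are disjoint.
#' @param revertant_fraction Probability that a fiber is a revertant.
#' @param revertant_range Intensity range (au) revertant means are drawn
#'   uniformly from.
#' @param cytoplasm_dys_bg,cytoplasm_spec_bg Interior background levels (au).
#' @param noise_sd Additive Gaussian read-noise SD (au).
#' @param poisson Add Poisson (shot) noise before the Gaussian component.
#' @param blur_sigma Gaussian PSF sigma in pixels.
#' @param quantize Round and clip to the 12-bit range [0, 4095].
#' @param n_lloyd Lloyd relaxation iterations (more = more uniform polygons).
#' @param closed_border Treat the field edge as a fiber boundary so edge
#'   fibers get membrane there too; used for single-fiber fixtures
#'   (default `FALSE`: fibers cut by the field edge have no membrane along
#'   the cut, as in real sections).
#' @param dys_means,spec_means Optional explicit per-fiber means (au),
#'   overriding the random draws.
#' @param seed Integer seed; generation is fully reproducible from it.
#'
#' @return Object of class `generator_params` (named list).
#' @export
generator_params <- function(preset = c("healthy", "bmd", "dmd_trace"),
                             n_fibers = 80,
                             dim = c(512, 512),
                             pixel_size = NULL,
                             membrane_thickness_um = 2,
                             spec_membrane_mean = 1500,
                             spec_membrane_sd = 150,
                             dys_meanlog = NULL,
                             dys_sdlog = NULL,
                             dys_upper_trunc_au = NULL,
                             revertant_fraction = NULL,
                             revertant_range = c(800, 2500),
                             cytoplasm_dys_bg = 50,
                             cytoplasm_spec_bg = 100,
                             noise_sd = 20,
                             poisson = FALSE,
                             blur_sigma = 1,
                             quantize = TRUE,
                             n_lloyd = 2,
                             closed_border = FALSE,
                             dys_means = NULL,
                             spec_means = NULL,
                             seed = 1L) {
  preset <- match.arg(preset)
  # preset spans are central 95% intervals of the log-normal
  span <- switch(preset,
    healthy = c(500, 1350),
    bmd = c(150, 600),
    dmd_trace = c(200, 800)
  )
  csa_target <- switch(preset, healthy = 4400, bmd = 6000, dmd_trace = 2500)
  dys_meanlog <- dys_meanlog %||% log(sqrt(span[1] * span[2]))
  dys_sdlog <- dys_sdlog %||% (log(span[2] / span[1]) / (2 * stats::qnorm(0.975)))
  dys_upper_trunc_au <- dys_upper_trunc_au %||%
    if (preset == "dmd_trace") revertant_range[1] else Inf
  revertant_fraction <- revertant_fraction %||%
    if (preset == "dmd_trace") 0.05 else 0
  pixel_size <- pixel_size %||% sqrt(csa_target * n_fibers / prod(dim))
  if (revertant_fraction < 0 || revertant_fraction > 1) {
    abort("revertant_fraction must be in [0, 1]", class = "fiberquant_config_error")
  }
  for (v in list(spec_membrane_mean, revertant_range, cytoplasm_dys_bg, cytoplasm_spec_bg)) {
    if (any(v < 0) || any(v > 4095)) {
      abort("intensity parameters must lie within [0, 4095]", class = "fiberquant_config_error")
    }
  }
  structure(
    list(
      preset = preset, n_fibers = as.integer(n_fibers), dim = as.integer(dim),
      pixel_size = pixel_size, membrane_thickness_um = membrane_thickness_um,
      spec_membrane_mean = spec_membrane_mean, spec_membrane_sd = spec_membrane_sd,
      dys_meanlog = dys_meanlog, dys_sdlog = dys_sdlog,
      dys_upper_trunc_au = dys_upper_trunc_au,
      revertant_fraction = revertant_fraction, revertant_range = revertant_range,
      cytoplasm_dys_bg = cytoplasm_dys_bg, cytoplasm_spec_bg = cytoplasm_spec_bg,
      noise_sd = noise_sd, poisson = poisson, blur_sigma = blur_sigma,
      quantize = quantize, n_lloyd = as.integer(n_lloyd),
      closed_border = closed_border,
      dys_means = dys_means, spec_means = spec_means, seed = as.integer(seed)
    ),
    class = "generator_params"
  )
}

# run code under a local RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# upper-truncated log-normal draw by inverse CDF
rlnorm_trunc <- function(n, meanlog, sdlog, upper) {
  if (!is.finite(upper)) return(rlnorm(n, meanlog, sdlog))
  u <- runif(n, 0, stats::plnorm(upper, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

# nearest-seed assignment (squared Euclidean), labels in seed order
voronoi_assign <- function(seeds, nr, nc) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  best <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  for (k in seq_len(nrow(seeds))) {
    d2 <- (rr - seeds[k, 1])^2 + (cc - seeds[k, 2])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- k
  }
  lab
}

#' Generate one synthetic section image with ground truth
#'
#' Renders a two-channel field from [generator_params()]: tessellation,
#' membrane bands, per-fiber intensity draws, then blur, noise and
#' quantization last. Fully reproducible from the seed. Noiseless,
#' blur-free fields render each fiber's membrane at exactly its drawn mean
#' (up to 12-bit quantization), so ground-truth means are recovered exactly
#' by the pipeline.
#'
#' @param params A [generator_params()].
#' @param biopsy_id,section_id,image_id Metadata attached to the image.
#' @param seed Overrides `params$seed` when given.
#'
#' @return List with
#'   \describe{
#'     \item{image}{a [section_image()];}
#'     \item{truth}{list with `labels` (full fiber regions), `membrane`
#'       (membrane-band labels), and `fibers`, a tibble of per-fiber truth:
#'       `fiber_id`, `dys_mean_true`, `spec_mean_true`, `class`
#'       (trace/revertant), `csa_um2_true`, `n_membrane_px`,
#'       `touches_border`.}
#'   }
#' @export
generate_section <- function(params, biopsy_id = "sim_biopsy",
                             section_id = "sim_section", image_id = "sim_image",
                             seed = NULL) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  nr <- p$dim[1]; nc <- p$dim[2]
  t_px <- p$membrane_thickness_um / p$pixel_size
  if (prod(p$dim) / p$n_fibers < (2 * ceiling(t_px) + 3)^2) {
    abort("infeasible geometry: too many fibers for the field at this membrane thickness",
          class = "fiberquant_config_error")
  }
  with_local_seed(seed %||% p$seed, {
    seeds <- cbind(runif(p$n_fibers, 1, nr), runif(p$n_fibers, 1, nc))
    lab <- voronoi_assign(seeds, nr, nc)
    for (i in seq_len(p$n_lloyd)) {
      v <- as.vector(lab)
      sr <- tapply(as.vector(row(lab)), v, mean)
      sc <- tapply(as.vector(col(lab)), v, mean)
      idx <- as.character(seq_len(p$n_fibers))
      seeds <- cbind(sr[idx], sc[idx])
      lost <- is.na(seeds[, 1])
      if (any(lost)) {
        seeds[lost, ] <- cbind(runif(sum(lost), 1, nr), runif(sum(lost), 1, nc))
      }
      lab <- voronoi_assign(seeds, nr, nc)
    }

    # membrane: pixels within the band thickness of a fiber-fiber boundary
    boundary <- matrix(FALSE, nr, nc)
    for (s in .SHIFTS4) {
      nb <- shift_mat(lab, s[1], s[2], fill = if (p$closed_border) -1L else NA_integer_)
      boundary <- boundary | (!is.na(nb) & nb != lab)
    }
    if (any(boundary)) {
      dist_to_boundary <- EBImage::imageData(EBImage::distmap(1 - boundary))
      membrane_mask <- dist_to_boundary <= t_px
    } else {
      membrane_mask <- matrix(FALSE, nr, nc)
    }
    # membrane ownership by the same nearest-interior rule the analysis uses
    interior_lab <- lab
    interior_lab[membrane_mask] <- 0L
    grown <- assign_band_pixels(interior_lab, membrane_mask, steps = Inf)
    membrane <- grown$membrane

    # per-fiber intensity draws
    n <- p$n_fibers
    is_rev <- runif(n) < p$revertant_fraction
    mu_dys <- p$dys_means %||% {
      m <- rlnorm_trunc(n, p$dys_meanlog, p$dys_sdlog, p$dys_upper_trunc_au)
      m[is_rev] <- runif(sum(is_rev), p$revertant_range[1], p$revertant_range[2])
      pmin(m, 4095)
    }
    if (length(mu_dys) != n) {
      abort("dys_means must have one value per fiber", class = "fiberquant_config_error")
    }
    mu_spec <- p$spec_means %||%
      pmin(pmax(rnorm(n, p$spec_membrane_mean, p$spec_membrane_sd), 1), 4095)

    owned <- membrane > 0L
    dys <- matrix(p$cytoplasm_dys_bg, nr, nc)
    spec <- matrix(p$cytoplasm_spec_bg, nr, nc)
    dys[owned] <- mu_dys[membrane[owned]]
    spec[owned] <- mu_spec[membrane[owned]]

    if (p$blur_sigma > 0) {
      dys <- EBImage::imageData(EBImage::gblur(dys, sigma = p$blur_sigma))
      spec <- EBImage::imageData(EBImage::gblur(spec, sigma = p$blur_sigma))
    }
    if (p$poisson) {
      dys <- matrix(rpois(length(dys), pmax(dys, 0)), nr, nc)
      spec <- matrix(rpois(length(spec), pmax(spec, 0)), nr, nc)
    }
    if (p$noise_sd > 0) {
      dys <- dys + rnorm(length(dys), 0, p$noise_sd)
      spec <- spec + rnorm(length(spec), 0, p$noise_sd)
    }
    if (p$quantize) {
      dys <- pmin(pmax(round(dys), 0), 4095)
      spec <- pmin(pmax(round(spec), 0), 4095)
    } else {
      dys <- pmin(pmax(dys, 0), 4095)
      spec <- pmin(pmax(spec, 0), 4095)
    }

    image <- section_image(dys, spec, pixel_size = p$pixel_size,
                           biopsy_id = biopsy_id, section_id = section_id,
                           image_id = image_id)
    truth_fibers <- tibble(
      fiber_id = seq_len(n),
      dys_mean_true = mu_dys,
      spec_mean_true = mu_spec,
      class = factor(ifelse(is_rev, "revertant", "trace"),
                     levels = c("trace", "revertant")),
      csa_um2_true = tabulate(lab, nbins = n) * p$pixel_size^2,
      n_membrane_px = tabulate(membrane, nbins = n),
      touches_border = seq_len(n) %in% border_labels(lab)
    )
    list(image = image,
         truth = list(labels = lab, membrane = membrane, fibers = truth_fibers,
                      params = p))
  })
}

#' Generate a hierarchical pre/post study design
#'
#' Samples the nested structure the pre/post comparison assumes: a biopsy
#' baseline, a log-scale visit effect applied to the post visit, section
#' effects within visits, and image effects within sections. Per-image mean
#' intensities are \eqn{\exp(\log \mu + visit + section + image)}. Defaults
#' mirror a typical assay layout -- 4 sections per visit, 5 images per
#' section -- with log-scale section and image SDs of 0.10 each (intensity
#' CVs of ~10%, mid-range of observed intra-assay precision).
#'
#' With `render = TRUE` each design row is additionally rendered as a
#' synthetic section image whose per-fiber dystrophin means scatter around
#' the image-level mean, so the full pipeline can be run end to end.
#'
#' @param visit_effect Log-scale effect of the post visit (0 = null;
#'   `log(1.3)` = +30%).
#' @param n_sections_per_visit,n_images_per_section Design sizes.
#' @param baseline_mean_au Pre-visit biopsy mean (au).
#' @param section_sd_log,image_sd_log Log-scale SDs of the section and image
#'   random effects (both must be >= 0).
#' @param fiber_sd_log Log-scale SD of per-fiber means around the image mean
#'   (used only when rendering).
#' @param params [generator_params()] used when rendering images.
#' @param render Render a section image per design row.
#' @param seed Integer seed.
#'
#' @return List of class `sim_study`: `design` (a [study_design()] tibble
#'   with `visit`, `section_id`, `image_id`, `value`), `truth` (the
#'   generating parameters), and `images` (`NULL`, or a list of
#'   [generate_section()] results parallel to the design rows).
#' @export
generate_study <- function(visit_effect = 0,
                           n_sections_per_visit = 4,
                           n_images_per_section = 5,
                           baseline_mean_au = 300,
                           section_sd_log = 0.10,
                           image_sd_log = 0.10,
                           fiber_sd_log = 0.3,
                           params = generator_params("dmd_trace"),
                           render = FALSE,
                           seed = 1L) {
  if (section_sd_log < 0 || image_sd_log < 0 || fiber_sd_log < 0) {
    abort("variance components must be >= 0", class = "fiberquant_config_error")
  }
  with_local_seed(seed, {
    grid <- tidyr::expand_grid(
      visit = factor(c("pre", "post"), levels = c("pre", "post")),
      section = seq_len(n_sections_per_visit),
      image = seq_len(n_images_per_section)
    )
    sec_key <- paste(grid$visit, grid$section)
    sec_eff <- rnorm(2 * n_sections_per_visit, 0, section_sd_log)
    names(sec_eff) <- unique(sec_key)
    img_eff <- rnorm(nrow(grid), 0, image_sd_log)
    design <- grid |>
      mutate(
        section_id = paste0(.data$visit, "_s", .data$section),
        image_id = paste0(.data$section_id, "_i", .data$image),
        value = exp(log(baseline_mean_au) +
                      visit_effect * (.data$visit == "post") +
                      unname(sec_eff[sec_key]) + img_eff)
      ) |>
      select("visit", "section_id", "image_id", "value")
    design <- structure(design, class = c("study_design", class(tibble())))

    images <- NULL
    if (render) {
      img_seeds <- sample.int(.Machine$integer.max - 1L, nrow(design))
      images <- map(seq_len(nrow(design)), function(i) {
        mu_img <- design$value[i]
        n <- params$n_fibers
        # lognormal with mean exactly mu_img
        fiber_means <- with_local_seed(img_seeds[i],
          pmin(rlnorm(n, log(mu_img) - fiber_sd_log^2 / 2, fiber_sd_log), 4095))
        p2 <- params
        p2$dys_means <- fiber_means
        generate_section(
          p2,
          biopsy_id = as.character(design$visit[i]),
          section_id = design$section_id[i],
          image_id = design$image_id[i],
          seed = img_seeds[i]
        )
      })
    }
    structure(
      list(design = design,
           truth = list(visit_effect = visit_effect,
                        baseline_mean_au = baseline_mean_au,
                        section_sd_log = section_sd_log,
                        image_sd_log = image_sd_log,
                        fiber_sd_log = fiber_sd_log),
           images = images),
      class = "sim_study"
    )
  })
}
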