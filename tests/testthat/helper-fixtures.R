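# Analytic fixtures built in code: ring fibers on an empty field, a
# two-fiber wall with known split geometry, and hand-built fiber sets for
# QC edge cases.

# Three (or fewer) isolated ring fibers: disk interiors at `interior_au`,
# ring walls (width `wall` px) at `membrane_au`, empty background.
make_rings_image <- function(n = 256, centers = list(c(64, 64), c(64, 192), c(184, 128)),
                             r_out = 34, wall = 3, dys = c(600, 900, 1200),
                             membrane_au = 1500, interior_au = 100,
                             pixel_size = 1) {
  dys_img <- matrix(0, n, n)
  spec_img <- matrix(0, n, n)
  truth <- matrix(0L, n, n)
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(rep(seq_len(n), each = n), n, n)
  for (k in seq_along(centers)) {
    d <- sqrt((rr - centers[[k]][1])^2 + (cc - centers[[k]][2])^2)
    ring <- d <= r_out & d > r_out - wall
    disk <- d <= r_out - wall
    spec_img[ring] <- membrane_au
    spec_img[disk] <- interior_au
    dys_img[ring] <- dys[k]
    dys_img[disk] <- interior_au
    truth[ring | disk] <- k
  }
  list(
    image = section_image(dys_img, spec_img, pixel_size = pixel_size),
    truth = truth,
    ring_masks = lapply(seq_along(centers), function(k) {
      d <- sqrt((rr - centers[[k]][1])^2 + (cc - centers[[k]][2])^2)
      d <= r_out & d > r_out - wall
    })
  )
}

# Two rectangular fibers sharing one straight vertical wall of total
# thickness 2t, framed by membrane of thickness t on the outer rectangle.
# Returns the image plus the analytic wall column ranges.
make_wall_image <- function(nr = 60, nc = 86, t = 3, membrane_au = 1500,
                            interior_au = 100, dys = c(400, 900)) {
  spec_img <- matrix(0, nr, nc)
  dys_img <- matrix(0, nr, nc)
  frame <- matrix(FALSE, nr, nc)
  frame[1:t, ] <- TRUE; frame[(nr - t + 1):nr, ] <- TRUE
  frame[, 1:t] <- TRUE; frame[, (nc - t + 1):nc] <- TRUE
  wall_cols <- (nc %/% 2 - t + 1):(nc %/% 2 + t)   # 2t columns
  wall <- matrix(FALSE, nr, nc); wall[, wall_cols] <- TRUE
  membrane <- frame | wall
  int1 <- !membrane & col(spec_img) < min(wall_cols)
  int2 <- !membrane & col(spec_img) > max(wall_cols)
  spec_img[membrane] <- membrane_au
  spec_img[int1 | int2] <- interior_au
  left_half <- col(spec_img) <= wall_cols[t]
  dys_img[membrane & left_half] <- dys[1]
  dys_img[membrane & !left_half] <- dys[2]
  dys_img[int1 | int2] <- interior_au
  list(
    image = section_image(dys_img, spec_img, pixel_size = 1),
    wall_cols = wall_cols, t = t,
    left_cols = wall_cols[seq_len(t)], right_cols = wall_cols[t + seq_len(t)]
  )
}

# Hand-built fiber_set: one square fiber with membrane on a chosen fraction
# of its sides, away from the image border (for QC coverage tests).
make_partial_membrane_set <- function(n = 40, sides = c("left", "top")) {
  labels <- matrix(0L, n, n)
  region <- 11:30
  labels[region, region] <- 1L
  membrane <- matrix(0L, n, n)
  if ("left" %in% sides) membrane[region, 11] <- 1L
  if ("right" %in% sides) membrane[region, 30] <- 1L
  if ("top" %in% sides) membrane[11, region] <- 1L
  if ("bottom" %in% sides) membrane[30, region] <- 1L
  cytoplasm <- labels
  cytoplasm[membrane > 0L] <- 0L
  fibers <- tibble::tibble(
    fiber_id = 1L,
    n_membrane_px = sum(membrane > 0L),
    n_cytoplasm_px = sum(cytoplasm > 0L),
    touches_border = FALSE,
    qc_pass = NA, qc_reason = NA_character_
  )
  structure(list(labels = labels, membrane = membrane, cytoplasm = cytoplasm,
                 pixel_size = 1, fibers = fibers),
            class = "fiber_set")
}

# Brute-force oracle for membrane intensity statistics: sort and count.
oracle_stats <- function(values, levels = c(0.25, 0.5, 0.75, 0.9)) {
  s <- sort(values)
  n <- length(s)
  k <- ceiling(0.1 * n)
  list(
    mean = sum(values) / n,
    min = s[1], max = s[n],
    q = vapply(levels, function(p) s[max(1, ceiling(p * n))], numeric(1)),
    q90_mean = mean(sort(values, decreasing = TRUE)[seq_len(k)])
  )
}

# Minimal per-fiber metrics table built directly (no images), for
# population/comparison statistics tests.
make_metrics <- function(dys_mean, biopsy_id = "b1", section_id = "s1",
                         image_id = "i1", q90_mean = dys_mean * 2,
                         csa = 2500, spec = 1400) {
  n <- length(dys_mean)
  tibble::tibble(
    biopsy_id = biopsy_id, section_id = section_id, image_id = image_id,
    fiber_id = seq_len(n),
    dys_mean = dys_mean, dys_min = dys_mean * 0.5, dys_max = dys_mean * 2.5,
    dys_q90_mean = q90_mean, spec_mean = spec,
    csa_um2 = csa, membrane_thickness_um = 2, n_membrane_px = 500L
  )
}

# Small fast generator parameter set for pipeline-level tests.
small_params <- function(...) {
  generator_params("dmd_trace", n_fibers = 30, dim = c(224, 224), ...)
}
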