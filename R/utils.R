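# Internal matrix helpers shared by segmentation, morphometry and the
# synthetic generator. All work on plain R matrices in row/column pixel
# coordinates (0-based indices at the I/O surface, 1-based internally).

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.SHIFTS4 <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
.SHIFTS8 <- c(.SHIFTS4, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))

# First positive neighbour label under 4-connectivity in the fixed direction
# order above; 0 where none. Equally near fibers are tie-broken by direction
# priority, which depends only on geometry -- never on how fibers happen to
# be numbered -- so ownership is reproducible across relabelings.
neighbor_first_label <- function(lab) {
  acc <- matrix(0L, nrow(lab), ncol(lab))
  for (s in rev(.SHIFTS4)) {
    nb <- shift_mat(lab, s[1], s[2], fill = 0L)
    take <- nb > 0L
    acc[take] <- nb[take]
  }
  acc
}

# TRUE where any 4-neighbour satisfies `mask` (out-of-image counts as FALSE).
any_neighbor4 <- function(mask) {
  acc <- matrix(FALSE, nrow(mask), ncol(mask))
  for (s in .SHIFTS4) acc <- acc | shift_mat(mask, s[1], s[2], fill = FALSE)
  acc
}

# Crofton-corrected perimeter (pixels) per label of a label matrix: count of
# 4-neighbour crack edges between a label and anything else (image border
# included), times pi/4. Near-exact for round shapes, which is what muscle
# fiber contours are; boundary-pixel counting underestimates by 10-20%.
crofton_perimeter <- function(lab, n_labels = max(lab)) {
  if (n_labels < 1) return(numeric(0))
  cracks <- numeric(n_labels)
  for (s in .SHIFTS4) {
    nb <- shift_mat(lab, s[1], s[2], fill = -1L)  # border differs from all
    edge <- lab > 0L & nb != lab
    if (any(edge)) {
      tab <- tabulate(lab[edge], nbins = n_labels)
      cracks <- cracks + tab
    }
  }
  cracks * pi / 4
}

# Relabel positive labels contiguously 1..K in order of first occurrence
# (column-major), keeping only `keep`; everything else becomes 0.
relabel_contiguous <- function(lab, keep) {
  v <- as.vector(lab)
  firsts <- which(!duplicated(v) & v > 0L)
  old <- v[firsts][v[firsts] %in% keep]
  lut <- integer(max(v))
  lut[old] <- seq_along(old)
  out <- v
  pos <- v > 0L
  out[pos] <- lut[v[pos]]
  matrix(as.integer(out), nrow(lab), ncol(lab))
}

# Labels present on the image border.
border_labels <- function(lab) {
  b <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  sort(unique(b[b > 0L]))
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Assign membrane-band pixels to the fiber whose interior is geodesically
# nearest: grow a 4-connected front from the interior labels through the
# band mask, one step at a time, ties by fixed direction priority.
# `steps = Inf` runs to convergence (every reachable band pixel owned).
# This single rule defines membrane ownership for both the synthetic
# generator and the segmentation split, so the two agree wherever the
# interiors agree.
assign_band_pixels <- function(interior_labels, band_mask, steps = Inf) {
  assigned <- interior_labels
  membrane <- matrix(0L, nrow(interior_labels), ncol(interior_labels))
  i <- 0
  while (i < steps) {
    i <- i + 1
    nb <- neighbor_first_label(assigned)
    cand <- band_mask & assigned == 0L & nb > 0L
    if (!any(cand)) break
    assigned[cand] <- nb[cand]
    membrane[cand] <- nb[cand]
  }
  list(labels = assigned, membrane = membrane)
}
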