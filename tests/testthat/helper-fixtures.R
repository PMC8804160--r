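# Small in-code fixtures shared across test files.

# A hand-built vessel tree: one straight horizontal vessel through a frame,
# with the optic disc tucked near the left edge.
straight_tree <- function(length_px = 50, width = 5, rows = 120, cols = 160,
                          row_at = 60, col_from = 60) {
  structure(list(
    polylines = list(cbind(rep(row_at, 2), c(col_from, col_from + length_px))),
    widths = width, parent = NA_integer_, bend_amplitude = 0,
    disc_center = c(row_at, 25), disc_radius = 12,
    image_size = c(rows, cols), seed = 0L),
    class = "vessel_tree")
}

# Uniform mid-gray frame (no structure at all).
flat_image <- function(rows = 64, cols = 64, level = 128) {
  fundus_image(array(level, c(rows, cols, 3)), image_id = "flat")
}

# Random blob of <= n_px 8-connected pixels, for rectangle-fit oracles.
random_blob <- function(n_px, seed) {
  withr::with_seed(seed, {
    pts <- matrix(c(50, 50), 1, 2)
    while (nrow(pts) < n_px) {
      base <- pts[sample.int(nrow(pts), 1), ]
      cand <- base + sample(c(-1L, 0L, 1L), 2, replace = TRUE)
      pts <- unique(rbind(pts, cand))
    }
    pts
  })
}

# Brute-force minimum bounding box over a 1-degree rotation grid; pads each
# side by 1 px exactly as the fitted rectangle does.
grid_rect_area <- function(pts) {
  y <- pts[, 1]; x <- pts[, 2]
  best <- Inf
  for (deg in 0:179) {
    th <- deg * pi / 180
    u <- x * cos(th) + y * sin(th)
    v <- y * cos(th) - x * sin(th)
    a <- (diff(range(u)) + 1) * (diff(range(v)) + 1)
    if (a < best) best <- a
  }
  best
}

# Chain of segments with given long-side orientations, all
# tortuosity-qualified — exercises the angle/tortuosity layer in isolation.
make_chain_graph <- function(phis, L = 20, W = 3) {
  n <- length(phis)
  segs <- lapply(seq_len(n), function(i) {
    nbrs <- c(if (i > 1) i - 1L, if (i < n) i + 1L)
    list(id = i, rect = min_rect(c(i, i), L, W, phis[i]),
         neighbors = nbrs,
         seg_type = if (length(nbrs) == 1) "II" else "III",
         caliber_ok = TRUE, tortuosity_ok = TRUE, pixels = cbind(i, i))
  })
  structure(list(segments = segs), class = "segment_graph")
}

# Mean absolute change of heading along a polyline, in degrees.
mean_turn_deg <- function(poly) {
  d <- diff(poly)
  ang <- atan2(d[, 1], d[, 2])
  turns <- diff(ang)
  turns <- atan2(sin(turns), cos(turns))
  mean(abs(turns)) * 180 / pi
}
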