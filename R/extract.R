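#' Grayscale conversions used for fundus preprocessing
#'
#' Three channel filters with distinct roles in fundus work:
#' `hsv_value_channel()` keeps the HSV value (brightness) channel,
#' `V = max(R, G, B)`, which sharpens bright structures such as the optic
#' disc; `red_free_gray()` removes the red channel (`round((G + B) / 2)`),
#' enhancing vessel/background contrast; `green_only_gray()` keeps the green
#' channel, where vessel contrast is strongest and artery/vein brightness
#' differences are most visible.
#'
#' @param img a `fundus_image` (or a `rows x cols x 3` array).
#' @return Numeric matrix 0..255 with attribute `provenance` naming the
#'   conversion.
#' @export
hsv_value_channel <- function(img) {
  a <- .pixels(img)
  g <- pmax(a[, , 1], a[, , 2], a[, , 3])
  attr(g, "provenance") <- "hsv_value"
  g
}

#' @rdname hsv_value_channel
#' @export
red_free_gray <- function(img) {
  a <- .pixels(img)
  g <- round((a[, , 2] + a[, , 3]) / 2)
  attr(g, "provenance") <- "red_free"
  g
}

#' @rdname hsv_value_channel
#' @export
green_only_gray <- function(img) {
  a <- .pixels(img)
  g <- a[, , 2]
  attr(g, "provenance") <- "green_only"
  g
}

.pixels <- function(img) {
  if (inherits(img, "fundus_image")) img$pixels
  else { stopifnot(length(dim(img)) == 3, dim(img)[3] == 3); img }
}

#' Extraction parameters
#'
#' Tunable parameters of [extract_vessels()]. Thresholds are scale-relative
#' (percentiles of the gradient magnitude inside the ROI; the background
#' window is a fraction of the frame side) so behavior is stable across
#' frame sizes.
#'
#' @param hysteresis_low_pct,hysteresis_high_pct percentile thresholds of
#'   the ROI gradient magnitude for the weak/strong hysteresis levels.
#' @param close_radius radius (px) of the morphological closing that merges
#'   the paired edges of a vessel.
#' @param min_component_px connected components smaller than this are
#'   discarded.
#' @param window_frac background-flattening window as a fraction of
#'   `min(rows, cols)`.
#' @param require_dark fill vessel bodies by growing the detected edges
#'   through the below-background mask (vessels absorb light in the green
#'   channel) and trim anything brighter than the local background; with
#'   `FALSE` only morphological closing and hole filling are applied.
#' @param dark_thr gray-level offset from the local background below which
#'   a pixel counts as vessel-dark during body filling.
#' @return A named list of parameters.
#' @export
extract_params <- function(hysteresis_low_pct = 85, hysteresis_high_pct = 96,
                           close_radius = 2, min_component_px = 64,
                           window_frac = 1 / 8, require_dark = TRUE,
                           dark_thr = -3) {
  list(hysteresis_low_pct = hysteresis_low_pct,
       hysteresis_high_pct = hysteresis_high_pct,
       close_radius = close_radius, min_component_px = min_component_px,
       window_frac = window_frac, require_dark = require_dark,
       dark_thr = dark_thr)
}

#' Extract a binary vessel map within a region of interest
#'
#' Edge-detection-based vessel extraction: (1) green-only grayscale;
#' (2) background flattening by subtracting a large-window local average;
#' (3) Sobel gradient magnitude with hysteresis thresholding (weak edges are
#' kept only in components that contain a strong edge); (4) filling of the
#' paired vessel edges to solid bodies — the edges are grown geodesically
#' through the mask of pixels darker than the local background (a vessel
#' lumen of any width fills, while darkness stops leakage), then closed
#' morphologically, hole-filled, and trimmed to below-background pixels;
#' (5) removal of small connected components; (6) intersection with the
#' ROI.
#'
#' @param img a `fundus_image`, or a grayscale matrix 0..255.
#' @param roi logical ROI matrix, same frame size.
#' @param params see [extract_params()].
#' @return Logical vessel map (foreground strictly inside `roi`).
#' @export
extract_vessels <- function(img, roi, params = extract_params()) {
  g <- if (is.matrix(img)) img else green_only_gray(img)
  stopifnot(all(dim(g) == dim(roi)))
  if (!any(roi)) stop("ROI is empty")
  g <- g * 1.0

  w <- max(9L, as.integer(round(min(dim(g)) * params$window_frac)))
  if (w %% 2 == 0) w <- w + 1L
  box <- matrix(1 / (w * w), w, w)
  bg <- EBImage::filter2(g, box, boundary = "replicate")
  flat <- g - bg

  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(flat, sx, boundary = "replicate")
  gy <- EBImage::filter2(flat, t(sx), boundary = "replicate")
  grad <- sqrt(gx^2 + gy^2)

  gv <- grad[roi]
  hi <- quantile(gv, params$hysteresis_high_pct / 100, names = FALSE)
  lo <- quantile(gv, params$hysteresis_low_pct / 100, names = FALSE)
  if (hi <= 0) return(matrix(FALSE, nrow(g), ncol(g)))
  strong <- grad >= hi & roi
  weak <- grad >= lo & roi
  lab <- label8(weak)
  keep_ids <- unique(lab[strong & lab > 0L])
  edges <- matrix(lab %in% keep_ids, nrow(g), ncol(g)) & weak

  brush <- EBImage::makeBrush(2L * as.integer(params$close_radius) + 1L, "disc")
  if (isTRUE(params$require_dark)) {
    # fill vessel bodies by geodesic reconstruction: grow the edge seeds
    # through the below-background (dark) mask, so lumens of any width fill
    # while the darkness bound stops leakage into the background
    dark <- flat < params$dark_thr
    body <- edges & dark
    b3 <- EBImage::makeBrush(3, "box")
    repeat {
      grown <- (EBImage::dilate(body * 1, b3) > 0) & dark
      if (sum(grown) == sum(body)) break
      body <- grown
    }
    closed <- EBImage::closing((body | edges) * 1, brush) > 0
    filled <- EBImage::fillHull(closed * 1) > 0
    filled <- filled & (flat < 0)
  } else {
    closed <- EBImage::closing(edges * 1, brush) > 0
    filled <- EBImage::fillHull(closed * 1) > 0
  }

  lab2 <- label8(filled)
  if (max(lab2) > 0L) {
    sizes <- tabulate(lab2[lab2 > 0L])
    keep <- which(sizes >= params$min_component_px)
    filled <- matrix(lab2 %in% keep, nrow(g), ncol(g)) & lab2 > 0L
  }
  filled & roi
}

#' Locate the optic disc
#'
#' The optic disc is the brightest compact structure in a fundus frame; the
#' HSV value channel sharpens it. The detector thresholds the value channel
#' at a high percentile (strict `>`), takes the largest connected bright
#' component, and returns its centroid and equivalent-circle radius. A
#' manual override returns the supplied coordinates verbatim.
#'
#' @param img a `fundus_image`.
#' @param manual_center optional `(row, col)`; returned verbatim when given.
#' @param manual_radius radius to pair with `manual_center`
#'   (default `min(rows, cols) / 16`).
#' @param value_percentile brightness percentile for the threshold.
#' @return An `optic_disc`: list with `center` (row, col) and `radius` (px).
#' @export
detect_optic_disc <- function(img, manual_center = NULL, manual_radius = NULL,
                              value_percentile = 99.5) {
  if (!is.null(manual_center)) {
    stopifnot(length(manual_center) == 2)
    d <- if (inherits(img, "fundus_image")) dim(img$pixels) else dim(img)
    return(optic_disc(manual_center,
                      manual_radius %||% (min(d[1:2]) / 16)))
  }
  v <- hsv_value_channel(img)
  thr <- quantile(v, value_percentile / 100, names = FALSE)
  if (thr <= median(v) + 2)
    stop("optic disc detection failed: no region brighter than the ",
         value_percentile, "th percentile stands out; ",
         "supply manual_center = c(row, col)")
  bw <- v >= thr
  lab <- label8(bw)
  sizes <- tabulate(lab[lab > 0L])
  id <- which.max(sizes)
  px <- which(lab == id, arr.ind = TRUE)
  # the percentile component may be only the disc's brightest core; regrow
  # at a threshold halfway to the background to capture the full disc
  thr2 <- (mean(v[lab == id]) + median(v)) / 2
  lab2 <- label8(v >= thr2)
  id2 <- lab2[px[1, 1], px[1, 2]]
  if (id2 > 0L && sum(lab2 == id2) <= 0.05 * length(v)) {
    px <- which(lab2 == id2, arr.ind = TRUE)
  }
  optic_disc(c(mean(px[, 1]), mean(px[, 2])), sqrt(nrow(px) / pi))
}

#' @rdname detect_optic_disc
#' @param center,radius disc center `(row, col)` and radius in pixels.
#' @export
optic_disc <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "optic_disc")
}
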