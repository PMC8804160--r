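#' Read a fundus photograph
#'
#' Reads a PNG/TIFF/JPEG image into the package's internal representation:
#' an integer array `rows x cols x 3` with values 0..255. Grayscale inputs
#' are replicated to three channels; 16-bit inputs are rescaled to 8-bit;
#' an alpha channel, if present, is dropped.
#'
#' @param path path to an image file.
#' @param image_id identifier stored with the image; defaults to the file
#'   name without extension.
#' @param group group label, e.g. `"HC"` or `"RRD"` (optional).
#' @return A `fundus_image` object: list with `pixels` (array), `image_id`,
#'   `group`, `path`.
#' @export
read_fundus <- function(path, image_id = NULL, group = NA_character_) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read image '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 2) a <- array(rep(a[, , 1], 3), dim = c(dim(a)[1:2], 3))
  if (any(dim(a)[1:2] < 1)) stop("zero-size image: ", path)
  # EBImage stores (x = col, y = row) in [0, 1]; transpose to (row, col)
  px <- aperm(a, c(2, 1, 3))
  fundus_image(clamp8(px * 255),
               image_id = image_id %||% sub("\\.[^.]+$", "", basename(path)),
               group = group, path = path)
}

#' Construct a fundus image from pixel data
#'
#' @param pixels array `rows x cols x 3`, values 0..255.
#' @inheritParams read_fundus
#' @return A `fundus_image` object.
#' @export
fundus_image <- function(pixels, image_id = "image", group = NA_character_,
                         path = NA_character_) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            all(dim(pixels)[1:2] > 0))
  structure(list(pixels = pixels, image_id = image_id, group = group,
                 path = path),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image> %s [%d x %d], group = %s\n",
              x$image_id, d[1], d[2], x$group))
  invisible(x)
}

#' Write a fundus image as 8-bit RGB PNG
#'
#' @param img a `fundus_image`.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_fundus <- function(img, path) {
  a <- aperm(img$pixels / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask logical matrix.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' General oval region-of-interest cover
#'
#' Builds the centered elliptical "general cover" used to exclude eyelid and
#' eyelash artifacts from ultra-widefield fundus frames. The ellipse is
#' axis-aligned at the geometric frame center with semi-axes proportional to
#' the frame sides, scaled so that the included-pixel fraction matches
#' `area_fraction` (default 43% of the frame). A pixel is included iff its
#' center satisfies the closed ellipse inequality.
#'
#' @param rows,cols frame size in pixels.
#' @param area_fraction target included fraction of the frame, in
#'   `(0, pi/4]` (`pi/4` is the largest inscribed ellipse with the frame's
#'   aspect ratio).
#' @return Logical `rows x cols` matrix with attributes `center` (row, col)
#'   and `semi_axes` (row semi-axis, col semi-axis).
#' @export
make_general_cover <- function(rows, cols, area_fraction = 0.43) {
  stopifnot(rows >= 1, cols >= 1)
  if (!is.finite(area_fraction) || area_fraction <= 0 ||
      area_fraction > pi / 4 + 1e-12)
    stop("area_fraction must lie in (0, pi/4]")
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  target <- area_fraction * rows * cols
  count_at <- function(s) {
    a <- s * rows / 2; b <- s * cols / 2
    t <- 1 - ((seq_len(rows) - cr) / a)^2
    w <- b * sqrt(pmax(t, 0))
    lo <- pmax(ceiling(cc - w), 1); hi <- pmin(floor(cc + w), cols)
    sum(pmax(hi - lo + 1, 0)[t >= 0])
  }
  s0 <- sqrt(4 * area_fraction / pi)
  lo <- 0.85 * s0; hi <- min(1, 1.15 * s0)
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (count_at(mid) < target) lo <- mid else hi <- mid
  }
  s <- if (abs(count_at(lo) - target) < abs(count_at(hi) - target)) lo else hi
  a <- s * rows / 2; b <- s * cols / 2
  rr <- matrix(seq_len(rows), rows, cols)
  cm <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  mask <- ((rr - cr) / a)^2 + ((cm - cc) / b)^2 <= 1
  attr(mask, "center") <- c(cr, cc)
  attr(mask, "semi_axes") <- c(a, b)
  mask
}

#' Area of a mask
#' @param mask logical matrix.
#' @return included pixel count.
#' @export
roi_area <- function(mask) sum(mask)

#' Load a personalized RRD / non-RRD region partition
#'
#' Reads a per-image cover (as drawn by clinicians to delimit the detached
#' region) and splits the general cover into a detached (RRD) and an
#' attached (non-RRD) mask. The cover image encodes the RRD region as
#' nonzero pixels; both returned masks are intersected with the general
#' cover, so they are disjoint and their union is exactly the cover.
#'
#' @param path path to the cover image (same frame size as the fundus image).
#' @param general_cover logical matrix from [make_general_cover()].
#' @return A `roi_partition`: list with logical matrices `rrd`, `non_rrd`
#'   and the `cover` itself.
#' @export
load_region_cover <- function(path, general_cover) {
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot read cover '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), max)
  m <- t(a) > 0
  if (!all(dim(m) == dim(general_cover)))
    stop(sprintf("cover size mismatch: cover is %d x %d, frame is %d x %d",
                 nrow(m), ncol(m), nrow(general_cover), ncol(general_cover)))
  roi_partition(m, general_cover)
}

#' Build an RRD / non-RRD partition from an RRD mask
#'
#' @param rrd_mask logical matrix marking the detached region.
#' @param general_cover logical matrix; the partition lives inside it.
#' @return A `roi_partition` (see [load_region_cover()]).
#' @export
roi_partition <- function(rrd_mask, general_cover) {
  stopifnot(all(dim(rrd_mask) == dim(general_cover)))
  rrd <- rrd_mask & general_cover
  if (!any(rrd))
    warning("RRD region is empty inside the general cover")
  structure(list(rrd = rrd, non_rrd = general_cover & !rrd,
                 cover = general_cover),
            class = "roi_partition")
}

.metrics_header <- c("image_id", "group", "region", "density",
                     "caliber_avg", "caliber_median", "tort_unweighted",
                     "tort_area", "tort_length", "tort_width",
                     "tort_width_inv")

#' Write a vascular-metrics table to CSV
#'
#' Writes one row per image-region with the fixed column set
#' `image_id, group, region, density, caliber_avg, caliber_median,
#' tort_unweighted, tort_area, tort_length, tort_width, tort_width_inv`.
#' Numeric values are written at full double precision, so a read-back
#' reproduces them to well below 1e-9.
#'
#' @param metrics data.frame of metric rows (see [compute_all_metrics()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  if (!is.data.frame(metrics) || nrow(metrics) < 1)
    stop("metrics table must have at least one row")
  missing_cols <- setdiff(.metrics_header, names(metrics))
  if (length(missing_cols))
    stop("metrics table lacks columns: ", paste(missing_cols, collapse = ", "))
  df <- metrics[, .metrics_header]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  df[num] <- lapply(df[num], function(x) ifelse(x %in% c("NA", "NaN"), NA, x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vascular-metrics table written by [write_metrics_table()]
#' @param path CSV path.
#' @return data.frame with the fixed metric columns.
#' @export
read_metrics_table <- function(path) {
  read.csv(path, colClasses = c(image_id = "character", group = "character",
                                region = "character"))
}
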