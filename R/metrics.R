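#' Absolute vascular density
#'
#' Number of vessel-foreground pixels divided by the ROI pixel count — the
#' exact integer ratio, no resampling.
#'
#' @param vmap logical vessel map, a subset of `roi`.
#' @param roi logical ROI mask with at least one included pixel.
#' @return Density in `[0, 1]`.
#' @export
absolute_density <- function(vmap, roi) {
  stopifnot(all(dim(vmap) == dim(roi)))
  if (sum(roi) < 1) stop("ROI is empty; density undefined")
  if (any(vmap & !roi)) stop("vessel map has foreground outside the ROI")
  sum(vmap) / sum(roi)
}

#' Caliber statistics over qualified segments
#'
#' The caliber of a qualified segment is the width (short side) of its
#' minimum enclosing rectangle. Returns the mean and the median over all
#' `caliber_ok` segments; with an even count the median is the midpoint of
#' the two central values. With zero qualified segments both statistics are
#' `NA` — a missing metric, never coerced to 0.
#'
#' @param graph a qualified `segment_graph` (see [qualify_segments()]).
#' @return Named list `caliber_avg`, `caliber_median` (px).
#' @export
caliber_stats <- function(graph) {
  ok <- vapply(graph$segments, function(s) isTRUE(s$caliber_ok), logical(1))
  if (!any(ok)) return(list(caliber_avg = NA_real_, caliber_median = NA_real_))
  w <- vapply(graph$segments[ok], function(s) s$rect$W, numeric(1))
  list(caliber_avg = mean(w), caliber_median = median(w))
}

#' Inter-segment angles of tortuosity-qualified segments
#'
#' For a marginal (type II) segment, the inter-segment angle is the acute
#' angle between the long-side direction of its rectangle and that of its
#' unique neighbor. For an intermediate (type III) segment it is the mean
#' of the two acute angles to its two neighbors. Angles are in degrees,
#' `[0, 90]`; only `tortuosity_ok` segments appear.
#'
#' @param graph a qualified `segment_graph`.
#' @return Named numeric vector, names = segment ids.
#' @export
inter_segment_angles <- function(graph) {
  segs <- graph$segments
  ok <- vapply(segs, function(s) isTRUE(s$tortuosity_ok), logical(1))
  ids <- which(ok)
  th <- vapply(ids, function(i) {
    s <- segs[[i]]
    angs <- vapply(s$neighbors, function(j)
      acute_line_angle(s$rect$phi, segs[[j]]$rect$phi), numeric(1))
    mean(angs)
  }, numeric(1))
  names(th) <- ids
  th
}

#' Vascular tortuosity statistics
#'
#' The unweighted tortuosity is the plain mean of the inter-segment angles,
#' `T = (1/n) * sum(theta_i)`, over the `n` marginal and intermediate
#' qualified segments. The weighted variants are weighted means
#' `sum(w_i * theta_i) / sum(w_i)` with rectangle-derived weights:
#' `L*W` (area; combines length and width information), `L` (length;
#' compensates segment-size bias from the subdivision), `W` (width;
#' amplifies thick vessels), `1/W` (inverse width; reveals thin vessels).
#'
#' @param angles output of [inter_segment_angles()].
#' @param graph the same `segment_graph`.
#' @param scheme one of `"unweighted"`, `"area"`, `"length"`, `"width"`,
#'   `"width_inv"`.
#' @return Tortuosity in degrees, or `NA` when no segment qualifies.
#' @export
tortuosity <- function(angles, graph,
                       scheme = c("unweighted", "area", "length", "width",
                                  "width_inv")) {
  scheme <- match.arg(scheme)
  if (length(angles) == 0) return(NA_real_)
  ids <- as.integer(names(angles))
  L <- vapply(graph$segments[ids], function(s) s$rect$L, numeric(1))
  W <- vapply(graph$segments[ids], function(s) s$rect$W, numeric(1))
  w <- switch(scheme,
              unweighted = rep(1, length(angles)),
              area = L * W,
              length = L,
              width = W,
              width_inv = 1 / W)
  sum(w * angles) / sum(w)
}

#' Full metric configuration
#'
#' Bundles the stage parameters of the per-image pipeline.
#'
#' @param extract see [extract_params()].
#' @param qualify see [qualify_params()].
#' @param max_seg_len segment run length, see [partition_segments()].
#' @param disc_value_percentile see [detect_optic_disc()].
#' @return Named list of stage configurations.
#' @export
metric_config <- function(extract = extract_params(),
                          qualify = qualify_params(),
                          max_seg_len = 30,
                          disc_value_percentile = 99.5) {
  list(extract = extract, qualify = qualify, max_seg_len = max_seg_len,
       disc_value_percentile = disc_value_percentile)
}

#' Compute all vascular metrics of one image-region
#'
#' Runs extraction, segment partition, qualification, and the three metric
#' families for one image and one ROI: absolute density, average/median
#' caliber, and the five tortuosity statistics. Deterministic for fixed
#' inputs and configuration. Metrics that are undefined on the input (no
#' vessel foreground, no qualified segment) are `NA`.
#'
#' @param img a `fundus_image`.
#' @param roi logical ROI mask.
#' @param disc an [optic_disc()]; detected from the image when `NULL`.
#' @param config see [metric_config()].
#' @param region region label stored in the output row.
#' @return One-row data.frame with columns `image_id, group, region,
#'   density, caliber_avg, caliber_median, tort_unweighted, tort_area,
#'   tort_length, tort_width, tort_width_inv`.
#' @export
compute_all_metrics <- function(img, roi, disc = NULL,
                                config = metric_config(),
                                region = "HC-cover") {
  stopifnot(inherits(img, "fundus_image"))
  vmap <- tryCatch(extract_vessels(img, roi, config$extract),
                   error = function(e) stop("extraction stage: ",
                                            conditionMessage(e), call. = FALSE))
  density <- absolute_density(vmap, roi)
  out <- data.frame(image_id = img$image_id, group = img$group,
                    region = region, density = density,
                    caliber_avg = NA_real_, caliber_median = NA_real_,
                    tort_unweighted = NA_real_, tort_area = NA_real_,
                    tort_length = NA_real_, tort_width = NA_real_,
                    tort_width_inv = NA_real_,
                    stringsAsFactors = FALSE)
  if (!any(vmap)) return(out)
  if (is.null(disc))
    disc <- tryCatch(
      detect_optic_disc(img,
                        value_percentile = config$disc_value_percentile),
      error = function(e) stop("optic-disc stage: ", conditionMessage(e),
                               call. = FALSE))
  graph <- tryCatch(
    qualify_segments(partition_segments(vmap, config$max_seg_len),
                     disc = disc, criteria = config$qualify),
    error = function(e) stop("segment stage: ", conditionMessage(e),
                             call. = FALSE))
  cs <- caliber_stats(graph)
  out$caliber_avg <- cs$caliber_avg
  out$caliber_median <- cs$caliber_median
  th <- inter_segment_angles(graph)
  out$tort_unweighted <- tortuosity(th, graph, "unweighted")
  out$tort_area <- tortuosity(th, graph, "area")
  out$tort_length <- tortuosity(th, graph, "length")
  out$tort_width <- tortuosity(th, graph, "width")
  out$tort_width_inv <- tortuosity(th, graph, "width_inv")
  out
}
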