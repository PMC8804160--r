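#' Grow a synthetic retinal vessel tree with known geometry
#'
#' Procedural stand-in for a retinal vasculature: polylines sprout from the
#' optic-disc rim and radiate toward the periphery as bounded-turning-angle
#' random walks, with occasional binary branching and width tapering. All
#' geometry (sub-pixel centerlines, widths, topology) is returned as ground
#' truth, so downstream measurements can be checked against it.
#'
#' @param seed integer RNG seed; the tree is a pure function of it and the
#'   remaining arguments.
#' @param n_roots number of root vessels leaving the disc rim (>= 1).
#' @param bend_amplitude maximum per-step heading change in degrees
#'   (0 = perfectly straight rays).
#' @param width_root root vessel width in pixels (>= 1).
#' @param image_size `c(rows, cols)`.
#' @param disc_center,disc_radius optic-disc geometry; defaults: frame
#'   center, `min(image_size) / 14`.
#' @param p_branch per-step probability of spawning a child vessel.
#' @param step centerline step length in pixels.
#' @param width_taper child width = `max(1, taper * parent width)`.
#' @return A `vessel_tree`: list with `polylines` (list of n x 2 row/col
#'   matrices), `widths`, `parent` (NA for roots), `bend_amplitude`,
#'   `disc_center`, `disc_radius`, `image_size`, `seed`.
#' @export
grow_vessel_tree <- function(seed, n_roots = 6, bend_amplitude = 12,
                             width_root = 7, image_size = c(512, 512),
                             disc_center = NULL, disc_radius = NULL,
                             p_branch = 0.015, step = 2, width_taper = 0.75) {
  stopifnot(n_roots >= 1, bend_amplitude >= 0, width_root >= 1,
            length(image_size) == 2)
  rows <- image_size[1]; cols <- image_size[2]
  disc_radius <- disc_radius %||% (min(rows, cols) / 14)
  disc_center <- disc_center %||% c(rows / 2, cols / 2)
  if (disc_center[1] - disc_radius < 1 || disc_center[1] + disc_radius > rows ||
      disc_center[2] - disc_radius < 1 || disc_center[2] + disc_radius > cols)
    stop("image too small to contain the optic disc")
  margin <- 2
  bend_rad <- bend_amplitude * pi / 180
  withr::with_seed(seed, {
    polylines <- list(); widths <- numeric(0); parent <- integer(0)
    # queue entries: start point, heading, width, parent polyline id, depth
    queue <- lapply(seq_len(n_roots), function(i) {
      ang <- 2 * pi * (i - 1) / n_roots + runif(1, -pi / (2 * n_roots),
                                                pi / (2 * n_roots))
      list(pos = disc_center + disc_radius * c(sin(ang), cos(ang)),
           heading = ang, width = width_root, parent = NA_integer_,
           depth = 0L)
    })
    max_len <- 0.55 * min(rows, cols)
    while (length(queue) > 0 && length(polylines) < 2L * n_roots) {
      job <- queue[[1]]; queue <- queue[-1]
      pos <- job$pos; heading <- job$heading
      pts <- matrix(pos, 1, 2)
      traveled <- 0
      spawn <- list()
      while (traveled < max_len) {
        heading <- heading + runif(1, -1, 1) * bend_rad
        nxt <- pos + step * c(sin(heading), cos(heading))
        if (nxt[1] < 1 + margin || nxt[1] > rows - margin ||
            nxt[2] < 1 + margin || nxt[2] > cols - margin) break
        pos <- nxt
        pts <- rbind(pts, pos)
        traveled <- traveled + step
        if (job$depth < 2L && runif(1) < p_branch &&
            job$width * width_taper >= 1) {
          side <- sample(c(-1, 1), 1)
          spawn[[length(spawn) + 1]] <- list(
            pos = pos,
            heading = heading + side * (25 + runif(1, 0, 15)) * pi / 180,
            width = max(1, job$width * width_taper),
            depth = job$depth + 1L)
        }
      }
      if (nrow(pts) < 2) next
      polylines[[length(polylines) + 1]] <- unname(pts)
      widths <- c(widths, job$width)
      parent <- c(parent, job$parent)
      pid <- length(polylines)
      for (s in spawn)
        queue[[length(queue) + 1]] <- list(pos = s$pos, heading = s$heading,
                                           width = s$width, parent = pid,
                                           depth = s$depth)
    }
    structure(list(polylines = polylines, widths = widths, parent = parent,
                   bend_amplitude = bend_amplitude,
                   disc_center = disc_center, disc_radius = disc_radius,
                   image_size = c(rows, cols), seed = seed),
              class = "vessel_tree")
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d polylines, frame %d x %d, bend %.1f deg\n",
              length(x$polylines), x$image_size[1], x$image_size[2],
              x$bend_amplitude))
  invisible(x)
}

#' Rasterize a vessel tree to a ground-truth vessel map
#'
#' Paints every centerline dilated to its width profile: disc-shaped stamps
#' of diameter equal to the polyline width are placed along the centerline
#' at sub-pixel spacing.
#'
#' @param truth a `vessel_tree`.
#' @return Logical `rows x cols` matrix.
#' @export
rasterize_tree <- function(truth) {
  rows <- truth$image_size[1]; cols <- truth$image_size[2]
  mask <- matrix(FALSE, rows, cols)
  offs_cache <- list()
  for (i in seq_along(truth$polylines)) {
    w <- truth$widths[i]
    key <- sprintf("%.3f", w)
    if (is.null(offs_cache[[key]])) {
      rad <- w / 2
      ring <- ceiling(rad)
      d <- expand.grid(dr = -ring:ring, dc = -ring:ring)
      d <- d[d$dr^2 + d$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
      offs_cache[[key]] <- as.matrix(d)
    }
    offs <- offs_cache[[key]]
    pts <- truth$polylines[[i]]
    # resample the polyline at ~0.5 px spacing so stamps overlap
    dense <- do.call(rbind, lapply(seq_len(nrow(pts) - 1), function(k) {
      p1 <- pts[k, ]; p2 <- pts[k + 1, ]
      len <- sqrt(sum((p2 - p1)^2))
      tfrac <- seq(0, 1, length.out = max(2, ceiling(len / 0.5) + 1))
      cbind(p1[1] + tfrac * (p2[1] - p1[1]), p1[2] + tfrac * (p2[2] - p1[2]))
    }))
    ctr <- unique(round(dense))
    for (j in seq_len(nrow(offs))) {
      rr <- ctr[, 1] + offs[j, 1]; cc <- ctr[, 2] + offs[j, 2]
      keep <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
      mask[cbind(rr[keep], cc[keep])] <- TRUE
    }
  }
  mask
}

#' Render a synthetic fundus photograph from a vessel tree
#'
#' Produces an 8-bit RGB frame emulating the gross photometry of a fundus
#' capture: a bright-center background with radial falloff, vessels darker
#' than the background (most strongly in the green channel), the optic disc
#' as the brightest region, and additive Gaussian pixel noise. Returns the
#' image together with the ground-truth vessel map (the rasterized tree).
#'
#' @param truth a `vessel_tree`.
#' @param noise_sd Gaussian noise standard deviation in gray levels (>= 0).
#' @param image_id,group labels for the resulting `fundus_image`.
#' @param seed RNG seed for the noise; defaults to `truth$seed + 1`.
#' @return List with `image` (a `fundus_image`) and `vessel_map` (logical
#'   matrix).
#' @export
render_fundus <- function(truth, noise_sd = 5, image_id = "synthetic",
                          group = NA_character_, seed = NULL) {
  stopifnot(noise_sd >= 0)
  rows <- truth$image_size[1]; cols <- truth$image_size[2]
  seed <- seed %||% (truth$seed + 1L)
  vmask <- rasterize_tree(truth)
  rr <- matrix(seq_len(rows), rows, cols)
  cm <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  dc <- truth$disc_center
  dist_ctr <- sqrt((rr - (rows + 1) / 2)^2 + (cm - (cols + 1) / 2)^2)
  g <- 150 - 45 * (dist_ctr / max(dist_ctr))^2
  g[vmask] <- g[vmask] * 0.45
  disc <- sqrt((rr - dc[1])^2 + (cm - dc[2])^2) <= truth$disc_radius
  red <- 0.85 * g + 55
  blue <- 0.45 * g
  red[disc] <- 250; g[disc] <- 245; blue[disc] <- 235
  px <- array(0, c(rows, cols, 3))
  px[, , 1] <- red; px[, , 2] <- g; px[, , 3] <- blue
  if (noise_sd > 0)
    px <- px + withr::with_seed(seed,
      array(rnorm(length(px), 0, noise_sd), dim(px)))
  list(image = fundus_image(clamp8(px), image_id = image_id, group = group),
       vessel_map = vmask)
}

#' Synthetic RRD / non-RRD region partition
#'
#' Stand-in for a clinician-drawn detachment boundary: a half-plane cut of
#' the general oval cover, at a seed-chosen orientation, with the offset
#' solved so the detached (RRD) side holds the requested fraction of the
#' cover area. Both sides of a straight cut of a convex cover are simply
#' connected.
#'
#' @param image_size `c(rows, cols)`.
#' @param fraction target RRD-area / cover-area in `[0, 1]`.
#' @param seed integer seed (orientation of the cut).
#' @param cover general cover; built with [make_general_cover()] defaults
#'   when `NULL`.
#' @return A `roi_partition` (masks `rrd`, `non_rrd`, `cover`).
#' @export
make_detachment_partition <- function(image_size, fraction, seed,
                                      cover = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  rows <- image_size[1]; cols <- image_size[2]
  cover <- cover %||% make_general_cover(rows, cols)
  if (fraction == 0)
    return(suppressWarnings(roi_partition(matrix(FALSE, rows, cols), cover)))
  if (fraction == 1)
    return(roi_partition(cover, cover))
  theta <- withr::with_seed(seed, runif(1, 0, 2 * pi))
  rr <- matrix(seq_len(rows), rows, cols)
  cm <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  s <- (rr - (rows + 1) / 2) * sin(theta) + (cm - (cols + 1) / 2) * cos(theta)
  target <- fraction * sum(cover)
  lo <- min(s[cover]); hi <- max(s[cover])
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (sum(cover & s >= mid) > target) lo <- mid else hi <- mid
  }
  cut <- if (abs(sum(cover & s >= lo) - target) <
             abs(sum(cover & s >= hi) - target)) lo else hi
  rrd <- cover & s >= cut
  if (!any(rrd) || !any(cover & !rrd))
    stop("fraction ", fraction, " makes a region empty for this cover")
  roi_partition(rrd, cover)
}

#' Specification of a synthetic two-group cohort
#'
#' Describes a healthy-control-like group A and a detachment-like group B
#' whose generating parameters differ by multiplicative effects: group B
#' vessel counts, widths, and bend amplitudes are scaled by
#' `effect_density`, `effect_caliber`, `effect_tortuosity`. Per-image
#' parameters add lognormal between-image variability around the group
#' means, so with all effects at 1 the two groups are exchangeable (an
#' exact null).
#'
#' @param n_per_group images per group (>= 1).
#' @param effect_density,effect_caliber,effect_tortuosity positive group-B
#'   multipliers.
#' @param detachment_fraction RRD fraction of the cover for group-B images.
#' @param image_size `c(rows, cols)`.
#' @param seed integer master seed.
#' @param noise_sd render noise in gray levels.
#' @param base_n_roots,base_width,base_bend group-A means of the generating
#'   parameters.
#' @param cv lognormal between-image coefficient of variation (sdlog).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 20, effect_density = 1,
                        effect_caliber = 1, effect_tortuosity = 1,
                        detachment_fraction = 0.45,
                        image_size = c(256, 256), seed = 1, noise_sd = 5,
                        base_n_roots = 6, base_width = 7, base_bend = 12,
                        cv = 0.15) {
  stopifnot(n_per_group >= 1, effect_density > 0, effect_caliber > 0,
            effect_tortuosity > 0, detachment_fraction >= 0,
            detachment_fraction <= 1)
  structure(list(n_per_group = n_per_group, effect_density = effect_density,
                 effect_caliber = effect_caliber,
                 effect_tortuosity = effect_tortuosity,
                 detachment_fraction = detachment_fraction,
                 image_size = image_size, seed = seed, noise_sd = noise_sd,
                 base_n_roots = base_n_roots, base_width = base_width,
                 base_bend = base_bend, cv = cv),
            class = "cohort_spec")
}

#' Generate a synthetic two-group fundus cohort
#'
#' Draws per-image generating parameters around the group means of the
#' [cohort_spec()], grows and renders every image, builds detachment
#' partitions for group B, and returns the truth table of generating
#' parameters alongside the images. Fully reproducible from the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @param render grow and render the images (default). With
#'   `render = FALSE` only the truth table of generating parameters is
#'   produced (identical to the rendered run's, drawn from the same RNG
#'   stream) — useful for simulations over many replicate seeds.
#' @return List with `images` (list of `fundus_image`), `vessel_maps`,
#'   `partitions` (`roi_partition` for group-B images, `NULL` otherwise),
#'   `truth` (data.frame: `image_id, group, region, gen_density, gen_width,
#'   gen_bend_amplitude, seed`).
#' @export
generate_cohort <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group
  plan <- withr::with_seed(spec$seed, {
    data.frame(
      group = rep(c("HC", "RRD"), each = n),
      idx = rep(seq_len(n), 2),
      sub_seed = sample.int(.Machine$integer.max - 2L, 2 * n),
      mult_d = exp(rnorm(2 * n, 0, spec$cv)),
      mult_w = exp(rnorm(2 * n, 0, spec$cv)),
      mult_b = exp(rnorm(2 * n, 0, spec$cv)))
  })
  is_b <- plan$group == "RRD"
  truth <- data.frame(
    image_id = sprintf("%s_%03d", plan$group, plan$idx),
    group = plan$group, region = "frame",
    gen_density = pmax(1L, as.integer(round(
      spec$base_n_roots * ifelse(is_b, spec$effect_density, 1) *
        plan$mult_d))),
    gen_width = pmax(1, spec$base_width *
                       ifelse(is_b, spec$effect_caliber, 1) * plan$mult_w),
    gen_bend_amplitude = spec$base_bend *
      ifelse(is_b, spec$effect_tortuosity, 1) * plan$mult_b,
    seed = plan$sub_seed, stringsAsFactors = FALSE)
  if (!render)
    return(list(images = NULL, vessel_maps = NULL, partitions = NULL,
                truth = truth))
  images <- list(); vmaps <- list(); partitions <- list()
  for (i in seq_len(nrow(plan))) {
    id <- truth$image_id[i]
    tree <- grow_vessel_tree(truth$seed[i], n_roots = truth$gen_density[i],
                             bend_amplitude = truth$gen_bend_amplitude[i],
                             width_root = truth$gen_width[i],
                             image_size = spec$image_size)
    rend <- render_fundus(tree, noise_sd = spec$noise_sd, image_id = id,
                          group = plan$group[i])
    images[[id]] <- rend$image
    vmaps[[id]] <- rend$vessel_map
    partitions[id] <- list(if (is_b[i])
      make_detachment_partition(spec$image_size, spec$detachment_fraction,
                                seed = truth$seed[i] + 1L))
  }
  list(images = images, vessel_maps = vmaps, partitions = partitions,
       truth = truth)
}
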