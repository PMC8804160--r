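#' Minimum-area enclosing rectangle of a pixel set
#'
#' Fits the smallest-area rectangle (any orientation) containing a set of
#' pixel centers, by rotating calipers over the convex hull: the optimal
#' unpadded rectangle has a side collinear with a hull edge, so hull-edge
#' angles are scanned (a 1-degree grid is scanned as well, so the padded
#' rectangle is never larger than any 1-degree-grid axis-aligned box). Both
#' sides are extended by 1 px to account for the unit extent of a pixel; a
#' single pixel yields `L = W = 1`.
#'
#' The rectangle's width `W` is the caliber estimate of a vascular segment
#' and its long side defines the segment's direction.
#'
#' @param pts two-column matrix of pixel coordinates `(row, col)`.
#' @return A `min_rect`: list with `center` (row, col), `L` (long side, px),
#'   `W` (short side, px), `phi` (orientation of the long side versus the
#'   column axis, degrees in `[0, 180)`).
#' @export
min_enclosing_rectangle <- function(pts) {
  pts <- unique(as.matrix(pts))
  stopifnot(ncol(pts) == 2, nrow(pts) >= 1)
  y <- pts[, 1]; x <- pts[, 2]           # x along columns, y along rows
  if (nrow(pts) == 1)
    return(min_rect(c(y, x), 1, 1, 0))
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  nh <- length(h)
  edge_ang <- if (nh >= 2) {
    i2 <- c(seq_len(nh)[-1], 1)
    atan2(hy[i2] - hy, hx[i2] - hx)
  } else 0
  cand <- unique(c(edge_ang %% pi, seq(0, 179) * pi / 180))
  ct <- cos(cand); st <- sin(cand)
  u <- outer(hx, ct) + outer(hy, st)        # nh x n_angles
  v <- outer(hy, ct) - outer(hx, st)
  umin <- do.call(pmin, asplit(u, 1)); umax <- do.call(pmax, asplit(u, 1))
  vmin <- do.call(pmin, asplit(v, 1)); vmax <- do.call(pmax, asplit(v, 1))
  eu <- umax - umin; ev <- vmax - vmin
  k <- which.min((eu + 1) * (ev + 1))
  uc <- (umin[k] + umax[k]) / 2; vc <- (vmin[k] + vmax[k]) / 2
  cx <- uc * ct[k] - vc * st[k]
  cy <- uc * st[k] + vc * ct[k]
  if (eu[k] >= ev[k]) {
    L <- eu[k] + 1; W <- ev[k] + 1; phi <- cand[k]
  } else {
    L <- ev[k] + 1; W <- eu[k] + 1; phi <- cand[k] + pi / 2
  }
  min_rect(c(cy, cx), L, W, (phi * 180 / pi) %% 180)
}

#' @rdname min_enclosing_rectangle
#' @param center rectangle center `(row, col)`.
#' @param L,W long/short side lengths in px (`W <= L`).
#' @param phi orientation of the long side in degrees `[0, 180)`.
#' @export
min_rect <- function(center, L, W, phi) {
  stopifnot(W <= L + 1e-9, phi >= 0, phi < 180)
  structure(list(center = as.numeric(center), L = L, W = W, phi = phi),
            class = "min_rect")
}

#' Acute angle between two undirected lines
#'
#' @param a,b line orientations in degrees.
#' @return angle in `[0, 90]` degrees.
#' @export
acute_line_angle <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Partition a vessel map into vascular segments
#'
#' Skeletonizes the binary vessel map, cuts the skeleton at branch points
#' (crossing number >= 3), subdivides each branch-free arc into runs of at
#' most `max_seg_len` skeleton pixels, and assigns every foreground pixel to
#' the segment of its nearest skeleton pixel (by geodesic label
#' propagation). Consecutive runs of one arc are neighbors; runs meeting at
#' a branch point are not — inter-segment angles are measured along a
#' vessel, never across bifurcations. Segment types follow the neighbor
#' count: I = isolated (0), II = marginal (1), III = intermediate (2).
#'
#' @param vmap logical vessel map.
#' @param max_seg_len maximum run length in skeleton pixels (default 30).
#' @return A `segment_graph`: list with `segments` (each a list with
#'   `id`, `pixels` (n x 2 row/col), `polyline` (ordered skeleton points),
#'   `rect` ([min_rect]), `neighbors`, `seg_type`, `caliber_ok`,
#'   `tortuosity_ok`), plus `disc` (unset) and `dim`.
#' @export
partition_segments <- function(vmap, max_seg_len = 30) {
  stopifnot(is.matrix(vmap))
  if (!any(vmap)) stop("vessel map is empty; nothing to partition")
  nr <- nrow(vmap); nc <- ncol(vmap)
  skel <- skeletonize(vmap)
  cn <- crossing_number(skel)
  branch <- skel & cn >= 3L
  arcs <- skel & !branch

  seg_pixsets <- list()   # ordered skeleton runs
  seg_arc <- integer(0)   # arc id per segment, for adjacency
  if (any(arcs)) {
    idx <- which(arcs)
    key_r <- ((idx - 1L) %% nr) + 1L
    key_c <- ((idx - 1L) %/% nr) + 1L
    pos <- seq_along(idx)
    lookup <- new.env(hash = TRUE, size = length(idx))
    for (i in pos) assign(as.character(idx[i]), i, envir = lookup)
    nb_of <- function(i) {
      r <- key_r[i]; c <- key_c[i]
      out <- integer(0)
      for (k in seq_len(8)) {
        dr <- .n8[k, 1]; dc <- .n8[k, 2]
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        # a diagonal hop that merely corners around a branch point is not a
        # within-arc connection: the two pixels meet only through the branch
        if (dr != 0L && dc != 0L &&
            ((branch[r, cc] || branch[rr, c]))) next
        j <- get0(as.character((cc - 1L) * nr + rr), envir = lookup)
        if (!is.null(j)) out <- c(out, j)
      }
      out
    }
    deg <- vapply(pos, function(i) length(nb_of(i)), integer(1))
    visited <- logical(length(idx))
    arc_id <- 0L
    trace_from <- function(start) {
      path <- integer(0); cur <- start
      repeat {
        visited[cur] <<- TRUE
        path <- c(path, cur)
        nxt <- nb_of(cur)
        nxt <- nxt[!visited[nxt]]
        if (length(nxt) == 0) break
        cur <- nxt[1]
      }
      path
    }
    starts <- pos[deg <= 1L]
    for (s in c(starts, pos)) {       # endpoints first, then cycles/leftovers
      if (visited[s]) next
      arc_id <- arc_id + 1L
      path <- trace_from(s)
      n <- length(path)
      kk <- ceiling(n / max_seg_len)
      bounds <- round(seq(0, n, length.out = kk + 1))
      for (j in seq_len(kk)) {
        run <- path[(bounds[j] + 1):bounds[j + 1]]
        seg_pixsets[[length(seg_pixsets) + 1L]] <-
          cbind(key_r[run], key_c[run])
        seg_arc <- c(seg_arc, arc_id)
      }
    }
  }

  n_seg <- length(seg_pixsets)
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(n_seg)) lab[seg_pixsets[[i]]] <- i

  # attach every foreground pixel to the nearest (geodesic) skeleton run
  fg <- vmap
  repeat {
    un <- fg & lab == 0L
    if (!any(un)) break
    nbmax <- matrix(0L, nr, nc)
    for (k in seq_len(8))
      nbmax <- pmax(nbmax, shift_mat(lab, .n8[k, 1], .n8[k, 2]))
    newly <- un & nbmax > 0L
    if (!any(newly)) break
    lab[newly] <- nbmax[newly]
  }
  # components whose skeleton collapsed entirely to branch points
  leftover <- fg & lab == 0L
  if (any(leftover)) {
    ll <- label8(leftover)
    for (id in seq_len(max(ll))) {
      px <- which(ll == id, arr.ind = TRUE)
      n_seg <- n_seg + 1L
      seg_pixsets[[n_seg]] <- px
      seg_arc <- c(seg_arc, NA_integer_)
      lab[px] <- n_seg
    }
  }

  idx_all <- which(lab > 0L)
  by_seg <- split(idx_all, lab[idx_all])
  segments <- vector("list", n_seg)
  for (i in seq_len(n_seg)) {
    ii <- by_seg[[as.character(i)]]
    px <- cbind(row = ((ii - 1L) %% nr) + 1L, col = ((ii - 1L) %/% nr) + 1L)
    nbrs <- integer(0)
    if (!is.na(seg_arc[i])) {
      if (i > 1 && !is.na(seg_arc[i - 1]) && seg_arc[i - 1] == seg_arc[i])
        nbrs <- c(nbrs, i - 1L)
      if (i < length(seg_arc) && !is.na(seg_arc[i + 1]) &&
          seg_arc[i + 1] == seg_arc[i])
        nbrs <- c(nbrs, i + 1L)
    }
    segments[[i]] <- list(
      id = i, pixels = px,
      polyline = seg_pixsets[[i]],
      rect = min_enclosing_rectangle(px),
      neighbors = nbrs,
      seg_type = c("I", "II", "III")[length(nbrs) + 1L],
      caliber_ok = NA, tortuosity_ok = NA)
  }
  structure(list(segments = segments, disc = NULL, dim = c(nr, nc)),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  ty <- vapply(x$segments, `[[`, character(1), "seg_type")
  cat(sprintf("<segment_graph> %d segments (I: %d, II: %d, III: %d)\n",
              length(ty), sum(ty == "I"), sum(ty == "II"), sum(ty == "III")))
  invisible(x)
}

#' Qualification criteria for vascular segments
#'
#' The criteria select segments whose enclosing-rectangle width is a
#' trustworthy caliber reading: a well-filled rectangle (the segment is a
#' solid bar, not a blob or a corner), a long side in a working range, a
#' roughly radial course relative to the optic disc (retinal vessels sprout
#' from the disc toward the periphery), and a minimum distance from the disc
#' center (excluding the disc region itself).
#'
#' @param min_fill minimum pixel-count / rectangle-area fill ratio.
#' @param min_L,max_L bounds (px) on the rectangle long side.
#' @param max_radial_angle maximum acute angle (degrees) between the long
#'   side and the ray from the disc center through the rectangle center.
#' @param min_disc_dist_factor minimum center distance from the disc center
#'   in units of disc radius.
#' @return Named list of criteria.
#' @export
qualify_params <- function(min_fill = 0.5, min_L = 8, max_L = 60,
                           max_radial_angle = 60, min_disc_dist_factor = 1.5) {
  list(min_fill = min_fill, min_L = min_L, max_L = max_L,
       max_radial_angle = max_radial_angle,
       min_disc_dist_factor = min_disc_dist_factor)
}

#' Apply segment qualification criteria
#'
#' Sets the `caliber_ok` flag (criteria of [qualify_params()]) and the
#' `tortuosity_ok` flag (same criteria plus segment type II or III: an
#' inter-segment angle needs at least one neighbor along the vessel) on
#' every segment, and records `n_tortuosity`, the count of marginal and
#' intermediate segments entering the tortuosity statistics.
#'
#' @param graph a `segment_graph`.
#' @param disc an [optic_disc()]; defaults to the one stored in `graph`.
#' @param criteria see [qualify_params()].
#' @return The graph with flags set, `disc` stored, and `n_tortuosity`.
#' @export
qualify_segments <- function(graph, disc = graph$disc,
                             criteria = qualify_params()) {
  if (is.null(disc)) stop("optic disc required for segment qualification")
  for (i in seq_along(graph$segments)) {
    s <- graph$segments[[i]]
    r <- s$rect
    fill <- nrow(s$pixels) / (r$L * r$W)
    dvec <- r$center - disc$center
    dist <- sqrt(sum(dvec^2))
    radial <- (atan2(dvec[1], dvec[2]) * 180 / pi) %% 180
    ok <- fill >= criteria$min_fill &&
      r$L >= criteria$min_L && r$L <= criteria$max_L &&
      acute_line_angle(r$phi, radial) <= criteria$max_radial_angle &&
      dist >= criteria$min_disc_dist_factor * disc$radius
    s$caliber_ok <- ok
    s$tortuosity_ok <- ok && s$seg_type %in% c("II", "III")
    graph$segments[[i]] <- s
  }
  graph$disc <- disc
  graph$n_tortuosity <- sum(vapply(graph$segments, `[[`, logical(1),
                                   "tortuosity_ok"))
  graph
}
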