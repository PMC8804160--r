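# Low-level raster helpers shared by extraction and segment modelling.
# All operate on plain matrices in (row, col) orientation.

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) < 1 || length(cs) < 1) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Offsets of the 8-neighbourhood, clockwise from north.
.n8 <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
             dc = c(0, 1, 1, 1, 0, -1, -1, -1))

# Count of 8-neighbours that are foreground, per pixel.
neighbor_count8 <- function(mask) {
  m <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(.n8)))
    m <- m + shift_mat(mask * 1L, .n8[k, 1], .n8[k, 2])
  m
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so merge labels
# that touch diagonally via a small union-find over label ids.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (d in list(c(-1, -1), c(-1, 1))) {
    sh <- shift_mat(lab, d[1], d[2])
    sel <- lab > 0L & sh > 0L & lab != sh
    if (!any(sel)) next
    pairs <- unique(cbind(lab[sel], sh[sel]))
    for (i in seq_len(nrow(pairs))) {
      a <- find(pairs[i, 1]); b <- find(pairs[i, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- dense[lab[lab > 0L]]
  out
}

# Zhang-Suen thinning to a 1-px-wide, 8-connected skeleton.
skeletonize <- function(mask) {
  stopifnot(is.matrix(mask))
  img <- mask & TRUE
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- lapply(seq_len(8), function(k)
        shift_mat(img * 1L, -.n8[k, 1], -.n8[k, 2]))
      # p[[k]] holds the neighbour value at offset .n8[k, ] for every pixel
      b <- Reduce(`+`, p)
      a <- matrix(0L, nrow(img), ncol(img))
      for (k in seq_len(8)) {
        nxt <- if (k == 8) 1 else k + 1
        a <- a + (p[[k]] == 0L & p[[nxt]] == 1L)
      }
      # ring order: 1=N,2=NE,3=E,4=SE,5=S,6=SW,7=W,8=NW
      if (sub == 1) {
        c1 <- p[[1]] * p[[3]] * p[[5]] == 0L
        c2 <- p[[3]] * p[[5]] * p[[7]] == 0L
      } else {
        c1 <- p[[1]] * p[[3]] * p[[7]] == 0L
        c2 <- p[[1]] * p[[5]] * p[[7]] == 0L
      }
      del <- img & b >= 2L & b <= 6L & a == 1L & c1 & c2
      if (any(del)) { img[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

# Crossing number: transitions 0->1 around the 8-ring; >= 3 marks a true
# branch point (robust to staircase corners that inflate the plain
# neighbour count).
crossing_number <- function(mask) {
  p <- lapply(seq_len(8), function(k)
    shift_mat(mask * 1L, -.n8[k, 1], -.n8[k, 2]))
  a <- matrix(0L, nrow(mask), ncol(mask))
  for (k in seq_len(8)) {
    nxt <- if (k == 8) 1 else k + 1
    a <- a + (p[[k]] == 0L & p[[nxt]] == 1L)
  }
  a
}

clamp8 <- function(x) pmin(pmax(round(x), 0), 255)
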