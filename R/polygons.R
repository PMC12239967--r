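#' Polygon primitives
#'
#' Cell boundaries are simple polygons stored as n x 2 numeric matrices of
#' vertices in FOV-local micrometers (origin lower-left, y increasing
#' upward).  Vertices are kept as an *open* ring: the first vertex is not
#' repeated at the end; closure is implied everywhere.
#'
#' @name polygons
#' @keywords internal
NULL

#' Normalize a polygon vertex matrix to an open ring
#'
#' Accepts a matrix, data.frame, or list with x/y; drops a repeated closing
#' vertex and collapses consecutive duplicate vertices.
#'
#' @param poly polygon vertices (n x 2 matrix-like).
#' @return n x 2 numeric matrix, open ring.
#' @export
as_polygon <- function(poly) {
  if (is.list(poly) && !is.data.frame(poly) && all(c("x", "y") %in% names(poly)))
    poly <- cbind(poly$x, poly$y)
  m <- as.matrix(poly)
  if (ncol(m) != 2L || !is.numeric(m))
    stop("polygon must be an n x 2 numeric matrix")
  storage.mode(m) <- "double"
  n <- nrow(m)
  if (n >= 2L && all(m[1L, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  # drop consecutive duplicates
  if (nrow(m) >= 2L) {
    dup <- c(FALSE, rowSums(abs(diff(m))) == 0)
    m <- m[!dup, , drop = FALSE]
  }
  dimnames(m) <- NULL
  m
}

#' Signed and absolute shoelace area of a polygon
#' @param poly open-ring polygon matrix.
#' @return area in squared input units (absolute value).
#' @export
poly_area <- function(poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L])) / 2
}

#' Centroid of a polygon (area-weighted)
#' @param poly open-ring polygon matrix.
#' @return length-2 numeric (x, y).
#' @export
poly_centroid <- function(poly) {
  p <- as_polygon(poly)
  n <- nrow(p)
  if (n < 3L) return(colMeans(p))
  j <- c(2:n, 1L)
  cr <- p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))
  c(sum((p[, 1L] + p[j, 1L]) * cr) / (6 * a),
    sum((p[, 2L] + p[j, 2L]) * cr) / (6 * a))
}

poly_bbox <- function(poly) {
  c(xmin = min(poly[, 1L]), xmax = max(poly[, 1L]),
    ymin = min(poly[, 2L]), ymax = max(poly[, 2L]))
}

#' Test whether points fall inside or on a polygon
#'
#' Even-odd crossing rule; points exactly on an edge count as inside
#' (within a small absolute tolerance).
#'
#' @param x,y point coordinates (vectors of equal length).
#' @param poly open-ring polygon matrix.
#' @param tol absolute tolerance for the on-boundary test.
#' @return logical vector.
#' @export
point_in_polygon <- function(x, y, poly, tol = 1e-9) {
  p <- as_polygon(poly)
  n <- nrow(p)
  j <- c(2:n, 1L)
  ax <- p[, 1L]; ay <- p[, 2L]; bx <- p[j, 1L]; by <- p[j, 2L]
  inside <- logical(length(x))
  onedge <- logical(length(x))
  for (k in seq_len(n)) {
    crosses <- ((ay[k] > y) != (by[k] > y))
    if (any(crosses)) {
      xin <- (bx[k] - ax[k]) * (y[crosses] - ay[k]) / (by[k] - ay[k]) + ax[k]
      inside[crosses] <- xor(inside[crosses], x[crosses] < xin)
    }
    onedge <- onedge | (.pt_seg_dist2(x, y, ax[k], ay[k], bx[k], by[k]) <= tol^2)
  }
  inside | onedge
}

# squared distance from points (px,py) to segment (ax,ay)-(bx,by); all args
# may be vectors of equal length (or scalars for the segment)
.pt_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- ((px - ax) * dx + (py - ay) * dy) / (l2 + (l2 == 0))
  t[t < 0] <- 0; t[t > 1] <- 1
  qx <- ax + t * dx; qy <- ay + t * dy
  (px - qx)^2 + (py - qy)^2
}

# do segments (p1-p2) and (q1-q2) properly or improperly intersect?
# vectorized over pairs (all args length m)
.seg_intersect <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y) {
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  d1 <- orient(q1x, q1y, q2x, q2y, p1x, p1y)
  d2 <- orient(q1x, q1y, q2x, q2y, p2x, p2y)
  d3 <- orient(p1x, p1y, p2x, p2y, q1x, q1y)
  d4 <- orient(p1x, p1y, p2x, p2y, q2x, q2y)
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  onseg <- function(ax, ay, bx, by, cx, cy, d)
    d == 0 & cx <= pmax(ax, bx) & cx >= pmin(ax, bx) &
      cy <= pmax(ay, by) & cy >= pmin(ay, by)
  proper |
    onseg(q1x, q1y, q2x, q2y, p1x, p1y, d1) |
    onseg(q1x, q1y, q2x, q2y, p2x, p2y, d2) |
    onseg(p1x, p1y, p2x, p2y, q1x, q1y, d3) |
    onseg(p1x, p1y, p2x, p2y, q2x, q2y, d4)
}

#' Minimum edge-to-edge distance between two cell polygons
#'
#' The minimum Euclidean distance between the two boundary polylines.
#' Touching, crossing, or containment (one polygon inside the other) all
#' give 0: overlapping segmentations must not produce negative or
#' undefined separations.
#'
#' @param poly_a,poly_b polygons (open-ring matrices or anything
#'   [as_polygon()] accepts).
#' @return non-negative distance in the polygons' units (micrometers).
#' @export
edge_distance <- function(poly_a, poly_b) {
  a <- as_polygon(poly_a); b <- as_polygon(poly_b)
  if (nrow(a) < 3L || nrow(b) < 3L)
    stop("degenerate polygon: fewer than 3 vertices")
  .edge_dist_core(a, b)
}

# unvalidated workhorse; `separated = TRUE` asserts the bounding boxes do
# not overlap, letting the intersection and containment tests be skipped
.edge_dist_core <- function(a, b, separated = FALSE) {
  na <- nrow(a); nb <- nrow(b)
  ja <- c(2:na, 1L); jb <- c(2:nb, 1L)
  if (!separated) {
    ia <- rep(seq_len(na), times = nb)
    ib <- rep(seq_len(nb), each = na)
    if (any(.seg_intersect(a[ia, 1L], a[ia, 2L], a[ja, 1L][ia],
                           a[ja, 2L][ia], b[ib, 1L], b[ib, 2L],
                           b[jb, 1L][ib], b[jb, 2L][ib])))
      return(0)
    # containment (no boundary crossing, so one test point suffices)
    if (point_in_polygon(a[1L, 1L], a[1L, 2L], b) ||
        point_in_polygon(b[1L, 1L], b[1L, 2L], a))
      return(0)
  }
  # vertex-to-opposite-segment distances in both directions
  d2a <- .pt_seg_dist2(rep(a[, 1L], times = nb), rep(a[, 2L], times = nb),
                       rep(b[, 1L], each = na), rep(b[, 2L], each = na),
                       rep(b[jb, 1L], each = na), rep(b[jb, 2L], each = na))
  d2b <- .pt_seg_dist2(rep(b[, 1L], times = na), rep(b[, 2L], times = na),
                       rep(a[, 1L], each = nb), rep(a[, 2L], each = nb),
                       rep(a[ja, 1L], each = nb), rep(a[ja, 2L], each = nb))
  sqrt(min(min(d2a), min(d2b)))
}

# inward offset of a convex polygon: clip by each edge's half-plane moved
# inward by `gap`.  Returns NULL if the polygon collapses.
poly_inward_offset <- function(poly, gap) {
  p <- as_polygon(poly)
  if (gap <= 0) return(p)
  n <- nrow(p)
  if (n < 3L) return(NULL)
  # ensure counterclockwise orientation
  j <- c(2:n, 1L)
  if (sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) < 0) {
    p <- p[n:1, , drop = FALSE]
    j <- c(2:n, 1L)
  }
  out <- p
  for (k in seq_len(n)) {
    e <- p[j[k], ] - p[k, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(e[2L], -e[1L]) / len          # outward normal for CCW ring
    b <- sum(nrm * p[k, ]) - gap           # keep nrm . x <= b
    out <- clip_halfplane(out, nrm, b)
    if (is.null(out) || nrow(out) < 3L) return(NULL)
  }
  out
}

# Sutherland-Hodgman clip of polygon against half-plane {x : a.x <= b}
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0L) return(NULL)
  v <- poly %*% a - b
  keep_any <- any(v <= 1e-12)
  if (!keep_any) return(NULL)
  if (all(v <= 1e-12)) return(poly)
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    jn <- if (i == n) 1L else i + 1L
    vi <- v[i]; vj <- v[jn]
    if (vi <= 0) out <- rbind(out, poly[i, ])
    if ((vi < 0 && vj > 0) || (vi > 0 && vj < 0)) {
      t <- vi / (vi - vj)
      out <- rbind(out, poly[i, ] + t * (poly[jn, ] - poly[i, ]))
    }
  }
  if (nrow(out) < 3L) return(NULL)
  as_polygon(out)
}

#' Rasterize polygons into a label image
#'
#' A pixel belongs to a polygon when its center falls inside it; pixel
#' (r, c) covers x in ((c-1), c] * pixel_size and y in ((r-1), r] *
#' pixel_size, i.e. row index runs with y from the origin upward.
#'
#' @param polygons list of polygons (micrometer coordinates).
#' @param labels integer labels, one per polygon.
#' @param width,height raster extent in micrometers.
#' @param pixel_size micrometers per pixel.
#' @return a [label_image()] raster.
#' @export
rasterize_polygons <- function(polygons, labels, width, height,
                               pixel_size = 0.18) {
  nc <- max(1L, ceiling(width / pixel_size))
  nr <- max(1L, ceiling(height / pixel_size))
  img <- matrix(0L, nrow = nr, ncol = nc)
  skipped <- character(0)
  for (i in seq_along(polygons)) {
    p <- as_polygon(polygons[[i]])
    bb <- poly_bbox(p)
    c0 <- max(1L, floor(bb["xmin"] / pixel_size) + 1L)
    c1 <- min(nc, ceiling(bb["xmax"] / pixel_size))
    r0 <- max(1L, floor(bb["ymin"] / pixel_size) + 1L)
    r1 <- min(nr, ceiling(bb["ymax"] / pixel_size))
    if (c1 < c0 || r1 < r0) { skipped <- c(skipped, as.character(labels[i])); next }
    cs <- c0:c1; rs <- r0:r1
    cx <- (cs - 0.5) * pixel_size
    cy <- (rs - 0.5) * pixel_size
    gx <- rep(cx, each = length(rs))
    gy <- rep(cy, times = length(cs))
    inside <- point_in_polygon(gx, gy, p, tol = 0)
    if (!any(inside)) { skipped <- c(skipped, as.character(labels[i])); next }
    idx <- cbind(rep(rs, times = length(cs))[inside], rep(cs, each = length(rs))[inside])
    img[idx] <- as.integer(labels[i])
  }
  if (length(skipped))
    warning("skipped sub-pixel polygons for labels: ",
            paste(skipped, collapse = ", "))
  label_image(img, pixel_size = pixel_size)
}
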