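# Independent geometric oracles and small fixture builders.
# The oracle code is deliberately scalar and naive: plain loops over all
# segment pairs, no pruning, no shared code with the package internals.

# distance between point (px,py) and segment (ax,ay)-(bx,by), scalar
.oracle_pt_seg <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- if (l2 == 0) 0 else ((px - ax) * dx + (py - ay) * dy) / l2
  t <- min(1, max(0, t))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

.oracle_seg_seg <- function(a1, a2, b1, b2) {
  # crossing test via orientation signs
  o <- function(p, q, r) sign((q[1] - p[1]) * (r[2] - p[2]) -
                              (q[2] - p[2]) * (r[1] - p[1]))
  d1 <- o(b1, b2, a1); d2 <- o(b1, b2, a2)
  d3 <- o(a1, a2, b1); d4 <- o(a1, a2, b2)
  if (d1 * d2 < 0 && d3 * d4 < 0) return(0)
  min(.oracle_pt_seg(a1[1], a1[2], b1[1], b1[2], b2[1], b2[2]),
      .oracle_pt_seg(a2[1], a2[2], b1[1], b1[2], b2[1], b2[2]),
      .oracle_pt_seg(b1[1], b1[2], a1[1], a1[2], a2[1], a2[2]),
      .oracle_pt_seg(b2[1], b2[2], a1[1], a1[2], a2[1], a2[2]))
}

.oracle_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((poly[i, 2] > py) != (poly[j, 2] > py)) {
      xin <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) /
        (poly[j, 2] - poly[i, 2]) + poly[i, 1]
      if (px < xin) inside <- !inside
    }
    j <- i
  }
  inside
}

# brute-force min edge distance between two polygons (all segment pairs)
oracle_edge_distance <- function(pa, pb) {
  pa <- as_polygon(pa); pb <- as_polygon(pb)
  na <- nrow(pa); nb <- nrow(pb)
  best <- Inf
  for (i in seq_len(na)) {
    a1 <- pa[i, ]; a2 <- pa[if (i == na) 1 else i + 1, ]
    for (j in seq_len(nb)) {
      b1 <- pb[j, ]; b2 <- pb[if (j == nb) 1 else j + 1, ]
      best <- min(best, .oracle_seg_seg(a1, a2, b1, b2))
      if (best == 0) return(0)
    }
  }
  if (.oracle_point_in_poly(pa[1, 1], pa[1, 2], pb) ||
      .oracle_point_in_poly(pb[1, 1], pb[1, 2], pa)) return(0)
  best
}

# all-pairs brute force distance table, rows as (i, j, d) with i < j
oracle_distance_table <- function(cells, cutoff) {
  n <- nrow(cells)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- oracle_edge_distance(cells$polygon[[i]], cells$polygon[[j]])
    if (d <= cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        cell_a = cells$cell_id[i], cell_b = cells$cell_id[j], distance = d,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cell_a = character(0), cell_b = character(0),
                      distance = numeric(0)))
  do.call(rbind, rows)
}

make_square <- function(x0, y0, side = 1) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

make_hexagon <- function(cx, cy, r) {
  ang <- pi / 6 + (0:5) * pi / 3
  cbind(cx + r * cos(ang), cy + r * sin(ang))
}

# tiny cell table from a list of polygons
make_cells <- function(polys, types = NULL, fov = "F1", ...) {
  n <- length(polys)
  cell_table(data.frame(
    cell_id = sprintf("c%03d", seq_len(n)), fov_id = fov,
    sample_id = "S1", patient_id = "P1", timepoint = "baseline",
    response = "responder",
    cell_type = types %||% rep("unassigned", n),
    stringsAsFactors = FALSE, ...), polys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random disjoint-polygon FOV via the generator, small and fast
random_fov_cells <- function(n = 50, w = 200, h = 150, seed = 1) {
  sim <- simulate_fov(tissue_params(
    n_cells = as.integer(n), fov_width = w, fov_height = h,
    transcripts = FALSE, n_genes = 60L, lr_effect = NULL,
    seed = as.integer(seed)))
  sim$cells
}
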