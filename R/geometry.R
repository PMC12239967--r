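#' Pairwise edge-to-edge distance table for one FOV
#'
#' Minimum boundary-to-boundary distances between every pair of cell
#' polygons, restricted to pairs at most `cutoff` um apart.  Bounding-box
#' gaps prune pairs that cannot fall within the cutoff; the retained set
#' equals the all-pairs brute force.
#'
#' @param cells a [cell_table()] whose rows share one `fov_id`.
#' @param cutoff um; pairs farther apart are omitted (default 45).
#' @return data.frame of class `"min_distance_table"` with columns
#'   `cell_a`, `cell_b` (unordered pair, `cell_a` first in table order),
#'   `distance` (um); attributes `cutoff` and `cell_ids`.
#' @export
build_distance_table <- function(cells, cutoff = 45) {
  if (length(unique(cells$fov_id)) > 1L)
    stop("build_distance_table expects cells of a single FOV")
  n <- nrow(cells)
  polys <- cells$polygon
  ids <- cells$cell_id
  a <- character(0); b <- character(0); d <- numeric(0)
  if (n >= 2L) {
    bbs <- t(vapply(polys, poly_bbox, numeric(4)))
    res_a <- vector("list", n)
    for (i in seq_len(n - 1L)) {
      js <- (i + 1L):n
      dx <- pmax(0, pmax(bbs[i, 1L], bbs[js, 1L]) -
                    pmin(bbs[i, 2L], bbs[js, 2L]))
      dy <- pmax(0, pmax(bbs[i, 3L], bbs[js, 3L]) -
                    pmin(bbs[i, 4L], bbs[js, 4L]))
      gap2 <- dx^2 + dy^2
      keep_j <- gap2 <= cutoff^2
      js <- js[keep_j]; gap2 <- gap2[keep_j]
      if (!length(js)) next
      di <- vapply(seq_along(js), function(k)
        .edge_dist_core(polys[[i]], polys[[js[k]]],
                        separated = gap2[k] > 0), numeric(1))
      keep <- di <= cutoff
      if (any(keep)) {
        a <- c(a, rep(ids[i], sum(keep)))
        b <- c(b, ids[js[keep]])
        d <- c(d, di[keep])
      }
    }
  }
  out <- data.frame(cell_a = a, cell_b = b, distance = d,
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  attr(out, "cell_ids") <- ids
  class(out) <- c("min_distance_table", "data.frame")
  out
}

#' Per-cell counts of directly touching neighbors
#'
#' Neighbors at edge distance at most `contact_tolerance` (0 means
#' touching/overlapping boundaries).  Also reports the modal count over
#' cells.
#'
#' @param dist_table a [build_distance_table()] result built with
#'   `cutoff >= contact_tolerance`.
#' @param contact_tolerance um (default 0).
#' @return list: `counts` (named integer vector over all cells, zeros
#'   included), `mode` (modal neighbor count).
#' @export
touching_neighbors <- function(dist_table, contact_tolerance = 0) {
  if (attr(dist_table, "cutoff") < contact_tolerance)
    stop("distance table cutoff is below contact_tolerance")
  ids <- attr(dist_table, "cell_ids")
  counts <- stats::setNames(integer(length(ids)), ids)
  touch <- dist_table[dist_table$distance <= contact_tolerance, , drop = FALSE]
  if (nrow(touch)) {
    tab <- table(c(touch$cell_a, touch$cell_b))
    counts[names(tab)] <- as.integer(tab)
  }
  tt <- table(counts)
  list(counts = counts,
       mode = as.integer(names(tt)[which.max(tt)]))
}

#' Assign cells to ring neighborhoods around leukemia cells
#'
#' Half-open radial bands `[e_i, e_{i+1})` around each leukemia cell's
#' boundary (edge distance), lower-inclusive; a cell at exactly the
#' outermost edge is omitted.  The same neighbor may appear in rings of
#' several leukemia cells (overlapping neighborhoods are kept, not
#' corrected).
#'
#' @param cells a [cell_table()] of one FOV.
#' @param leukemia_ids cell ids of the leukemia population.
#' @param ring_edges strictly increasing um breaks starting at 0
#'   (default `c(0, 5, 15, 25, 35, 45)`).
#' @param exclude_types neighbor types left out of ring membership
#'   (default `"RBC"`; anucleate cells carry no usable transcriptome).
#' @param dist_table optional precomputed [build_distance_table()] with
#'   `cutoff >= max(ring_edges)`.
#' @return data.frame (`ring_assignment`): `leukemia_cell_id`,
#'   `other_cell_id`, `ring_index` (1-based), `distance`.
#' @export
assign_rings <- function(cells, leukemia_ids,
                         ring_edges = c(0, 5, 15, 25, 35, 45),
                         exclude_types = "RBC", dist_table = NULL) {
  if (length(ring_edges) < 2L || ring_edges[1] != 0 ||
      any(diff(ring_edges) <= 0))
    stop("ring_edges must start at 0 and be strictly increasing")
  if (!all(leukemia_ids %in% cells$cell_id))
    stop("leukemia_ids must be a subset of the cell table")
  if (is.null(dist_table))
    dist_table <- build_distance_table(cells, cutoff = max(ring_edges))
  if (attr(dist_table, "cutoff") < max(ring_edges))
    stop("distance table cutoff is below max(ring_edges)")
  excl <- cells$cell_id[cells$cell_type %in% exclude_types]
  # expand the unordered table into leukemia -> other directed rows
  da <- dist_table[dist_table$cell_a %in% leukemia_ids, , drop = FALSE]
  db <- dist_table[dist_table$cell_b %in% leukemia_ids, , drop = FALSE]
  leu <- c(da$cell_a, db$cell_b)
  oth <- c(da$cell_b, db$cell_a)
  dd <- c(da$distance, db$distance)
  keep <- !(oth %in% excl) & dd < max(ring_edges)
  leu <- leu[keep]; oth <- oth[keep]; dd <- dd[keep]
  ring <- findInterval(dd, ring_edges)      # [e_i, e_{i+1}) is ring i
  out <- data.frame(leukemia_cell_id = leu, other_cell_id = oth,
                    ring_index = ring, distance = dd,
                    stringsAsFactors = FALSE)
  out <- out[order(out$leukemia_cell_id, out$ring_index,
                   out$other_cell_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ring_edges") <- ring_edges
  class(out) <- c("ring_assignment", "data.frame")
  out
}

#' Minimum distance from each target-type cell to the leukemia population
#'
#' For each cell of `target_type` in the FOV, the minimum edge distance
#' over all leukemia cells (the row minimum of the full pairwise
#' distance matrix).
#'
#' @param cells a [cell_table()] of one FOV.
#' @param leukemia_ids leukemia cell ids.
#' @param target_type cell type to measure from, or `NULL` with
#'   `target_ids` given directly.
#' @param target_ids explicit target cell ids (overrides `target_type`).
#' @return named numeric vector of minimum distances (um), one per
#'   target cell; `NULL` with a warning when the FOV has no leukemia
#'   cells.
#' @export
min_distances <- function(cells, leukemia_ids, target_type = NULL,
                          target_ids = NULL) {
  if (!length(leukemia_ids)) {
    warning("FOV has no leukemia cells; skipped")
    return(NULL)
  }
  if (is.null(target_ids)) {
    if (is.null(target_type)) stop("give target_type or target_ids")
    target_ids <- cells$cell_id[cells$cell_type %in% target_type]
  }
  li <- match(leukemia_ids, cells$cell_id)
  ti <- match(target_ids, cells$cell_id)
  if (anyNA(li) || anyNA(ti)) stop("unknown cell id")
  polys <- cells$polygon
  bbs <- t(vapply(polys, poly_bbox, numeric(4)))
  out <- stats::setNames(.min_dist_to_set(polys, bbs, ti, li), target_ids)
  out
}

# min edge distance from each target polygon to a set of polygons, with
# bounding-box lower bounds pruning the candidate order
.min_dist_to_set <- function(polys, bbs, target_idx, set_idx) {
  out <- rep(Inf, length(target_idx))
  for (k in seq_along(target_idx)) {
    i <- target_idx[k]
    if (i %in% set_idx) { out[k] <- 0; next }
    dx <- pmax(0, pmax(bbs[i, 1L], bbs[set_idx, 1L]) -
                  pmin(bbs[i, 2L], bbs[set_idx, 2L]))
    dy <- pmax(0, pmax(bbs[i, 3L], bbs[set_idx, 3L]) -
                  pmin(bbs[i, 4L], bbs[set_idx, 4L]))
    gaps <- sqrt(dx^2 + dy^2)
    ord <- order(gaps)
    best <- Inf
    for (m in ord) {
      if (gaps[m] >= best) break
      best <- min(best, .edge_dist_core(polys[[i]], polys[[set_idx[m]]],
                                        separated = gaps[m] > 0))
      if (best == 0) break
    }
    out[k] <- best
  }
  out
}
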