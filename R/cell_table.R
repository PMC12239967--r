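#' Cell tables
#'
#' A cell table is a `data.frame` (class `"cell_table"`) with one row per
#' segmented cell and columns: `cell_id`, `fov_id`, `sample_id`,
#' `patient_id`, `timepoint`, `response`, `cell_type`, `area` (um^2),
#' `cx`, `cy` (centroid, um), and a list-column `polygon` of open-ring
#' vertex matrices in FOV-local micrometers.
#'
#' Timepoint labels follow the study design (`baseline`, `post_ici`,
#' `eoc2`); `response` is `responder`/`nonresponder`.  Cells not yet typed
#' carry `cell_type = "unassigned"`.
#'
#' @name cell_table
NULL

TIMEPOINT_LEVELS <- c("baseline", "post_ici", "eoc2")
RESPONSE_LEVELS <- c("responder", "nonresponder")

#' Build a validated cell table
#'
#' Validates polygons (>= 3 vertices, simple after closure), recomputes
#' area and centroid from the polygon when absent, and checks stored
#' values against recomputation when present (1e-6 relative tolerance on
#' area, 1e-6 um on centroid).
#'
#' @param df data.frame with at least `cell_id` and `fov_id`.
#' @param polygons list of polygons, one per row (or a `polygon`
#'   list-column already present in `df`).
#' @return a `cell_table` data.frame.
#' @export
cell_table <- function(df, polygons = df$polygon) {
  if (is.null(polygons)) stop("polygons are required")
  stopifnot(nrow(df) == length(polygons))
  polygons <- lapply(polygons, as_polygon)
  bad <- vapply(polygons, nrow, 1L) < 3L
  if (any(bad))
    stop("polygon with fewer than 3 vertices for cell_id: ",
         paste(df$cell_id[bad], collapse = ", "))
  selfx <- vapply(polygons, .poly_self_intersects, logical(1))
  if (any(selfx))
    stop("self-intersecting polygon for cell_id: ",
         paste(df$cell_id[selfx], collapse = ", "))
  dup <- stats::aggregate(seq_len(nrow(df)),
                          by = list(fov = df$fov_id, id = df$cell_id), length)
  if (any(dup$x > 1L))
    stop("duplicate cell_id within FOV: ",
         paste(unique(dup$id[dup$x > 1L]), collapse = ", "))
  area <- vapply(polygons, poly_area, numeric(1))
  cen <- t(vapply(polygons, poly_centroid, numeric(2)))
  if (!is.null(df$area) && !all(is.na(df$area))) {
    rel <- abs(df$area - area) / pmax(area, .Machine$double.eps)
    if (any(rel > 1e-6, na.rm = TRUE))
      stop("stored area disagrees with shoelace area for cell_id: ",
           paste(df$cell_id[which(rel > 1e-6)], collapse = ", "))
  }
  if (!is.null(df$cx) && !all(is.na(df$cx))) {
    dev <- pmax(abs(df$cx - cen[, 1L]), abs(df$cy - cen[, 2L]))
    if (any(dev > 1e-6, na.rm = TRUE))
      stop("stored centroid disagrees with polygon centroid for cell_id: ",
           paste(df$cell_id[which(dev > 1e-6)], collapse = ", "))
  }
  out <- data.frame(
    cell_id = as.character(df$cell_id),
    fov_id = as.character(df$fov_id),
    sample_id = as.character(df$sample_id %||% NA_character_),
    patient_id = as.character(df$patient_id %||% NA_character_),
    timepoint = as.character(df$timepoint %||% NA_character_),
    response = as.character(df$response %||% NA_character_),
    cell_type = as.character(df$cell_type %||% "unassigned"),
    area = area, cx = cen[, 1L], cy = cen[, 2L],
    stringsAsFactors = FALSE)
  out$polygon <- polygons
  class(out) <- c("cell_table", "data.frame")
  out
}

.poly_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  j <- c(2:n, 1L)
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    ks <- ks[!(i == 1L & ks == n)]   # skip adjacent (shared-vertex) pairs
    if (!length(ks)) next
    hit <- .seg_intersect(p[i, 1L], p[i, 2L], p[j[i], 1L], p[j[i], 2L],
                          p[ks, 1L], p[ks, 2L], p[j[ks], 1L], p[j[ks], 2L])
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Read a cell table from CSV
#'
#' Expected columns: `cell_id`, `fov_id`, `sample_id`, `patient_id`,
#' `timepoint`, `response`, `cell_type`, `polygon_wkt` (WKT POLYGON text),
#' optionally `area`, `cx`, `cy`.  Rows with malformed WKT or degenerate
#' polygons are rejected with a per-row message; duplicate `cell_id`
#' within an FOV is a hard error.  Area and centroid are recomputed from
#' the polygon when absent.
#'
#' @param path CSV file path.
#' @return a [cell_table()]; rejected rows are recorded in
#'   `attr(x, "rejected")` and counts in `attr(x, "log")`.
#' @export
read_cell_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(cell_id = "character",
                                        fov_id = "character"))
  if (!all(c("cell_id", "fov_id", "polygon_wkt") %in% names(raw)))
    stop("cell table needs columns cell_id, fov_id, polygon_wkt")
  polys <- vector("list", nrow(raw))
  ok <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    p <- tryCatch(parse_wkt_polygon(raw$polygon_wkt[i]), error = function(e) e)
    if (!inherits(p, "error") && nrow(p) >= 3L) {
      polys[[i]] <- p
      ok[i] <- TRUE
    }
  }
  reject <- raw$cell_id[!ok]
  if (length(reject))
    message("read_cell_table: rejected ", length(reject), " row(s): ",
            paste(reject, collapse = ", "))
  out <- cell_table(raw[ok, , drop = FALSE], polys[ok])
  attr(out, "rejected") <- reject
  attr(out, "log") <- c(input = nrow(raw), accepted = sum(ok),
                        rejected = length(reject))
  out
}

#' Write a cell table to CSV (WKT polygons)
#' @param cells a [cell_table()].
#' @param path output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  df <- as.data.frame(cells)[, c("cell_id", "fov_id", "sample_id",
                                 "patient_id", "timepoint", "response",
                                 "cell_type", "area", "cx", "cy")]
  df$polygon_wkt <- vapply(cells$polygon, format_wkt_polygon, character(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Parse single-ring WKT POLYGON text
#' @param wkt e.g. `"POLYGON((0 0,10 0,10 10,0 10,0 0))"`.
#' @return open-ring vertex matrix.
#' @export
parse_wkt_polygon <- function(wkt) {
  s <- trimws(wkt)
  m <- regmatches(s, regexec("^POLYGON\\s*\\(\\(([^()]*)\\)\\)$", s,
                             ignore.case = TRUE))[[1]]
  if (length(m) != 2L) stop("malformed WKT POLYGON: ", wkt)
  parts <- strsplit(trimws(strsplit(m[2], ",")[[1]]), "\\s+")
  if (any(vapply(parts, length, 1L) != 2L))
    stop("malformed WKT coordinate in: ", wkt)
  xy <- suppressWarnings(vapply(parts, as.numeric, numeric(2)))
  if (anyNA(xy)) stop("non-numeric WKT coordinate in: ", wkt)
  as_polygon(t(xy))
}

#' Format a polygon as WKT POLYGON text
#' @param poly polygon matrix.
#' @return WKT string (ring closed).
#' @export
format_wkt_polygon <- function(poly) {
  p <- as_polygon(poly)
  p <- rbind(p, p[1L, ])
  paste0("POLYGON((",
         paste(paste(format(p[, 1L], trim = TRUE, digits = 15),
                     format(p[, 2L], trim = TRUE, digits = 15)),
               collapse = ","),
         "))")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cell_table <- function(x, ...) {
  cat("cell_table:", nrow(x), "cells in", length(unique(x$fov_id)),
      "FOV(s);", sum(x$cell_type != "unassigned"), "typed\n")
  invisible(x)
}
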