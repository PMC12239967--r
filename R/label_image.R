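#' Label images
#'
#' A label image is a 2-D non-negative integer raster where value k marks
#' the pixels of object k and 0 is background.  Row index runs with y
#' from the FOV origin (lower-left) upward; `pixel_size` (um/px) converts
#' to micrometers.
#'
#' @param img integer matrix, all values >= 0.
#' @param pixel_size micrometers per pixel.
#' @return matrix of class `"label_image"` with a `pixel_size` attribute.
#' @export
label_image <- function(img, pixel_size = 0.18) {
  m <- as.matrix(img)
  if (any(m < 0)) stop("label image must be non-negative")
  if (any(m != round(m))) stop("label image must be integer-valued")
  storage.mode(m) <- "integer"
  attr(m, "pixel_size") <- pixel_size
  class(m) <- c("label_image", class(m))
  m
}

#' Number of distinct non-background labels
#' @param img a [label_image()].
#' @return integer count.
#' @export
n_labels <- function(img) length(setdiff(unique(as.vector(img)), 0L))

#' Read a label image from single-plane TIFF
#'
#' Labels are stored as 16-bit samples scaled by 65535 (exact for labels
#' below 65535); non-integer or negative pixel values are a hard error.
#'
#' @param path TIFF file path.
#' @param pixel_size micrometers per pixel to attach.
#' @return a [label_image()]; the label count is reported via `message()`.
#' @export
read_label_image <- function(path, pixel_size = 0.18) {
  r <- tiff::readTIFF(path)
  if (length(dim(r)) == 3L) {
    if (dim(r)[3] != 1L) stop("expected a single-plane TIFF")
    r <- r[, , 1L]
  }
  v <- r * 65535
  if (any(v < 0)) stop("label image contains negative pixels")
  if (max(abs(v - round(v))) > 1e-6)
    stop("label image contains non-integer pixels")
  img <- label_image(round(v), pixel_size = pixel_size)
  message("read_label_image: ", n_labels(img), " object(s) in ",
          nrow(img), "x", ncol(img), " raster")
  img
}

#' Write a label image to single-plane TIFF
#' @param img a [label_image()] (or integer matrix).
#' @param path output TIFF path.
#' @export
write_label_image <- function(img, path) {
  m <- unclass(img)
  attr(m, "pixel_size") <- NULL
  if (max(m) >= 2^16 - 1L)
    stop("labels at or above 65535 cannot be stored losslessly")
  # 16-bit samples: k/65535 quantizes back to exactly k
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @export
print.label_image <- function(x, ...) {
  cat("label_image: ", nrow(x), "x", ncol(x), " px (",
      attr(x, "pixel_size"), " um/px), ", n_labels(x), " object(s)\n",
      sep = "")
  invisible(x)
}

# per-label pixel counts, excluding background
label_areas_px <- function(img) {
  v <- as.vector(img)
  v <- v[v > 0L]
  if (!length(v)) return(integer(0))
  tab <- table(v)
  stats::setNames(as.integer(tab), names(tab))
}
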