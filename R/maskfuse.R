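#' Fusion parameters
#'
#' @param pair_overlap_min minimum fraction of a nucleus's pixels inside
#'   a membrane object for the two to pair (default 0.5).
#' @param expansion_radius um of isotropic dilation applied to nuclei
#'   without a membrane partner (default 3).
#' @param keep_orphan_membranes keep membrane objects with no nucleus
#'   (default TRUE).
#' @param min_cell_area um^2; smaller fused objects are dropped
#'   (default 10).
#' @return list of class `"fusion_params"`.
#' @export
fusion_params <- function(pair_overlap_min = 0.5, expansion_radius = 3,
                          keep_orphan_membranes = TRUE, min_cell_area = 10) {
  stopifnot(pair_overlap_min >= 0, pair_overlap_min <= 1,
            expansion_radius >= 0, min_cell_area >= 0)
  structure(list(pair_overlap_min = pair_overlap_min,
                 expansion_radius = expansion_radius,
                 keep_orphan_membranes = keep_orphan_membranes,
                 min_cell_area = min_cell_area),
            class = "fusion_params")
}

#' Fuse nucleus and membrane label images into one mask per cell
#'
#' Each nucleus pairs with the membrane object containing the largest
#' fraction of its pixels, provided that fraction reaches
#' `pair_overlap_min` (ties: larger absolute overlap, then smaller
#' membrane label).  A membrane claimed by several nuclei keeps the
#' nucleus of largest overlap; the others fall back to expansion.
#' Unpaired nuclei are dilated isotropically by `expansion_radius`,
#' clipped against every other fused object; where two expansions
#' collide, the pixel goes to the nearer nucleus (ties to the smaller
#' label).  Orphan membranes are kept as cells when requested.
#'
#' Fused labels: paired and orphan cells keep the membrane label;
#' expanded nuclei get `max(membrane label) + nucleus label`.
#'
#' @param nucleus,membrane [label_image()]s of identical dimensions.
#' @param params a [fusion_params()].
#' @return list: `fused` ([label_image()]), `provenance` (data.frame
#'   `fused_label`, `source` in paired/nucleus-expanded/orphan-membrane,
#'   `nucleus_label`, `membrane_label`).
#' @export
fuse_masks <- function(nucleus, membrane, params = fusion_params()) {
  if (!all(dim(nucleus) == dim(membrane)))
    stop("nucleus and membrane rasters must have identical dimensions")
  px <- attr(nucleus, "pixel_size") %||% 0.18
  nuc <- unclass(nucleus); mem <- unclass(membrane)
  nuc_labels <- setdiff(sort(unique(as.vector(nuc))), 0L)
  mem_labels <- setdiff(sort(unique(as.vector(mem))), 0L)
  # nucleus-membrane overlap table
  both <- nuc > 0L
  ov <- if (any(both)) {
    df <- data.frame(n = nuc[both], m = mem[both])
    stats::aggregate(cbind(npix = rep(1L, nrow(df))) ~ n + m, data = df, FUN = sum)
  } else data.frame(n = integer(0), m = integer(0), npix = integer(0))
  nuc_size <- stats::setNames(rep(0L, length(nuc_labels)),
                              nuc_labels)
  if (nrow(ov)) {
    tot <- tapply(ov$npix, ov$n, sum)
    nuc_size[names(tot)] <- as.integer(tot)
  }
  ovm <- ov[ov$m > 0L, , drop = FALSE]
  pairing <- data.frame(nucleus = integer(0), membrane = integer(0))
  if (nrow(ovm)) {
    ovm$frac <- ovm$npix / nuc_size[as.character(ovm$n)]
    # per nucleus: best membrane by fraction, then absolute overlap,
    # then smaller membrane label
    ovm <- ovm[order(ovm$n, -ovm$frac, -ovm$npix, ovm$m), , drop = FALSE]
    best <- ovm[!duplicated(ovm$n), , drop = FALSE]
    best <- best[best$frac >= params$pair_overlap_min, , drop = FALSE]
    # per membrane: keep nucleus of largest overlap (ties: smaller nucleus)
    best <- best[order(best$m, -best$npix, best$n), , drop = FALSE]
    best <- best[!duplicated(best$m), , drop = FALSE]
    pairing <- data.frame(nucleus = best$n, membrane = best$m)
  }
  fused <- matrix(0L, nrow(nuc), ncol(nuc))
  prov <- data.frame(fused_label = integer(0), source = character(0),
                     nucleus_label = integer(0), membrane_label = integer(0),
                     stringsAsFactors = FALSE)
  keep_mem <- pairing$membrane
  if (length(keep_mem)) {
    sel <- mem %in% keep_mem
    fused[sel] <- mem[sel]
    prov <- rbind(prov, data.frame(
      fused_label = pairing$membrane, source = "paired",
      nucleus_label = pairing$nucleus, membrane_label = pairing$membrane,
      stringsAsFactors = FALSE))
  }
  orphans <- setdiff(mem_labels, keep_mem)
  if (params$keep_orphan_membranes && length(orphans)) {
    sel <- mem %in% orphans
    fused[sel] <- mem[sel]
    prov <- rbind(prov, data.frame(
      fused_label = orphans, source = "orphan-membrane",
      nucleus_label = NA_integer_, membrane_label = orphans,
      stringsAsFactors = FALSE))
  }
  # nuclear-expansion fallback for unpaired nuclei
  free_nuc <- setdiff(nuc_labels, pairing$nucleus)
  if (length(free_nuc)) {
    offset <- if (length(mem_labels)) max(mem_labels) else 0L
    r_px <- params$expansion_radius / px
    dist_best <- matrix(Inf, nrow(nuc), ncol(nuc))
    claim <- matrix(0L, nrow(nuc), ncol(nuc))
    for (nl in free_nuc) {
      idx <- which(nuc == nl, arr.ind = TRUE)
      if (!nrow(idx)) next
      r0 <- max(1L, min(idx[, 1L]) - ceiling(r_px))
      r1 <- min(nrow(nuc), max(idx[, 1L]) + ceiling(r_px))
      c0 <- max(1L, min(idx[, 2L]) - ceiling(r_px))
      c1 <- min(ncol(nuc), max(idx[, 2L]) + ceiling(r_px))
      rs <- r0:r1; cs <- c0:c1
      gr <- rep(rs, times = length(cs)); gc <- rep(cs, each = length(rs))
      # distance from each window pixel to the nearest nucleus pixel
      d2 <- rep(Inf, length(gr))
      for (q in seq_len(nrow(idx)))
        d2 <- pmin(d2, (gr - idx[q, 1L])^2 + (gc - idx[q, 2L])^2)
      dpx <- sqrt(d2)
      within <- dpx <= r_px
      lin <- cbind(gr[within], gc[within])
      dv <- dpx[within]
      # nearer nucleus wins collisions; ties to the smaller label
      cur_d <- dist_best[lin]; cur_l <- claim[lin]
      take <- dv < cur_d | (dv == cur_d & (cur_l == 0L | nl < cur_l))
      if (any(take)) {
        dist_best[lin[take, , drop = FALSE]] <- dv[take]
        claim[lin[take, , drop = FALSE]] <- offset + nl
      }
      prov <- rbind(prov, data.frame(
        fused_label = offset + nl, source = "nucleus-expanded",
        nucleus_label = nl, membrane_label = NA_integer_,
        stringsAsFactors = FALSE))
    }
    free_px <- fused == 0L & claim > 0L   # never overwrite membrane cells
    fused[free_px] <- claim[free_px]
  }
  # drop fused objects below the minimum area
  areas <- label_areas_px(fused) * px^2
  small <- as.integer(names(areas)[areas < params$min_cell_area])
  if (length(small)) {
    fused[fused %in% small] <- 0L
    prov <- prov[!prov$fused_label %in% small, , drop = FALSE]
  }
  prov <- prov[order(prov$fused_label), , drop = FALSE]
  rownames(prov) <- NULL
  list(fused = label_image(fused, pixel_size = px), provenance = prov)
}

#' Assign transcripts to fused cells
#'
#' Each transcript takes the fused label at its pixel (um coordinates
#' divided by `pixel_size`); background pixels leave the transcript
#' unassigned (`NA`).  Out-of-bounds coordinates are counted, logged,
#' and left unassigned; counts are conserved.
#'
#' @param fused a [label_image()].
#' @param transcripts data.frame with `gene`, `x`, `y` (um) and
#'   optionally `cell_id`.
#' @param pixel_size um per pixel (default: the raster's).
#' @return the transcript data.frame with `cell_id` set to the fused
#'   label (as character) or `NA`; `attr(x, "log")` holds assigned /
#'   unassigned / out-of-bounds counts.
#' @export
assign_transcripts <- function(fused, transcripts,
                               pixel_size = attr(fused, "pixel_size")) {
  cc <- floor(transcripts$x / pixel_size) + 1L
  rr <- floor(transcripts$y / pixel_size) + 1L
  inb <- rr >= 1L & rr <= nrow(fused) & cc >= 1L & cc <= ncol(fused)
  lab <- rep(0L, nrow(transcripts))
  lab[inb] <- unclass(fused)[cbind(rr[inb], cc[inb])]
  out <- transcripts
  out$cell_id <- ifelse(lab > 0L, as.character(lab), NA_character_)
  n_oob <- sum(!inb)
  if (n_oob)
    message("assign_transcripts: ", n_oob, " transcript(s) out of bounds")
  attr(out, "log") <- c(input = nrow(transcripts),
                        assigned = sum(lab > 0L),
                        unassigned = sum(lab == 0L),
                        out_of_bounds = n_oob)
  out
}

#' Benchmark a segmentation against ground truth (IOU-matched F1)
#'
#' Candidate (predicted, truth) pairs with IOU at or above the threshold
#' are matched greedily in descending IOU order, one-to-one (ties:
#' smaller predicted, then truth label).  Matched pairs are true
#' positives; unmatched predictions false positives; unmatched truth
#' objects false negatives; `F1 = TP / (TP + (FP + FN)/2)`.
#'
#' @param predicted,truth [label_image()]s of identical dimensions.
#' @param iou_threshold IOU in (0, 1] required for a true positive
#'   (default 0.7).
#' @return list of class `"seg_eval"`: `tp`, `fp`, `fn`, `f1`,
#'   `iou_threshold`, `matched_pairs` (data.frame predicted/truth/iou).
#' @export
evaluate_segmentation <- function(predicted, truth, iou_threshold = 0.7) {
  if (!all(dim(predicted) == dim(truth)))
    stop("predicted and truth rasters must have identical dimensions")
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  p <- as.vector(unclass(predicted)); t <- as.vector(unclass(truth))
  ap <- label_areas_px(predicted); at <- label_areas_px(truth)
  sel <- p > 0L & t > 0L
  matched <- data.frame(predicted = integer(0), truth = integer(0),
                        iou = numeric(0))
  if (any(sel)) {
    key <- paste(p[sel], t[sel])
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), " "))
    inter <- as.integer(tab)
    pi <- as.integer(parts[, 1L]); ti <- as.integer(parts[, 2L])
    iou <- inter / (ap[as.character(pi)] + at[as.character(ti)] - inter)
    cand <- data.frame(predicted = pi, truth = ti, iou = as.numeric(iou))
    cand <- cand[cand$iou >= iou_threshold, , drop = FALSE]
    cand <- cand[order(-cand$iou, cand$predicted, cand$truth), , drop = FALSE]
    used_p <- integer(0); used_t <- integer(0)
    for (k in seq_len(nrow(cand))) {
      if (cand$predicted[k] %in% used_p || cand$truth[k] %in% used_t) next
      matched <- rbind(matched, cand[k, ])
      used_p <- c(used_p, cand$predicted[k])
      used_t <- c(used_t, cand$truth[k])
    }
    rownames(matched) <- NULL
  }
  tp <- nrow(matched)
  fp <- length(ap) - tp
  fn <- length(at) - tp
  f1 <- if (tp + fp + fn == 0) NA_real_ else tp / (tp + (fp + fn) / 2)
  structure(list(tp = tp, fp = fp, fn = fn, f1 = f1,
                 iou_threshold = iou_threshold, matched_pairs = matched),
            class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat(sprintf("seg_eval: TP=%d FP=%d FN=%d  F1=%.4f (IOU >= %.2f)\n",
              x$tp, x$fp, x$fn, x$f1, x$iou_threshold))
  invisible(x)
}
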