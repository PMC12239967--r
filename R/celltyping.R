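#' Quality-control filtering
#'
#' Removes low-quality cells (total transcript count below
#' `qc_min_transcripts`), then whole FOVs whose remaining cell count
#' falls below `qc_min_cells_per_fov`.  Thresholds follow the study
#' defaults: cells with fewer than 20 transcripts and FOVs left with
#' fewer than 300 cells are dropped.
#'
#' @param cells a [cell_table()].
#' @param counts a [count_matrix()] covering all cells.
#' @param qc_min_transcripts minimum per-cell total count (kept when
#'   `>=`; default 20).
#' @param qc_min_cells_per_fov minimum per-FOV cell count after the
#'   first stage (kept when `>=`; default 300).
#' @return the retained `cell_table`; `attr(x, "removal_log")` records
#'   both stages (removed cell ids and removed FOV ids).
#' @export
qc_filter <- function(cells, counts, qc_min_transcripts = 20L,
                      qc_min_cells_per_fov = 300L) {
  tot <- Matrix::colSums(counts)[cells$cell_id]
  if (anyNA(tot)) stop("counts do not cover all cells")
  low <- cells$cell_id[tot < qc_min_transcripts]
  kept <- cells[!(cells$cell_id %in% low), , drop = FALSE]
  fov_n <- table(kept$fov_id)
  bad_fov <- names(fov_n)[fov_n < qc_min_cells_per_fov]
  out <- kept[!(kept$fov_id %in% bad_fov), , drop = FALSE]
  class(out) <- class(cells)
  attr(out, "removal_log") <- list(
    low_count_cells = low,
    removed_fovs = bad_fov,
    input = nrow(cells), after_cell_qc = nrow(kept), kept = nrow(out))
  message("qc_filter: removed ", length(low), " low-count cell(s) and ",
          length(bad_fov), " FOV(s); ", nrow(out), "/", nrow(cells),
          " cells kept")
  out
}

#' Select reference cells from marker expression
#'
#' A cell is a reference for type t when t is the *only* type whose
#' mean marker count in that cell exceeds `min_count`; cells with zero
#' or two-plus positive types are not references.
#'
#' @param counts a [count_matrix()] (QC-passed cells).
#' @param markers named list, cell type -> marker gene vector.
#' @param min_count positivity threshold on the per-type mean marker
#'   count (default 0, i.e. any marker transcript counts).
#' @return named list, cell type -> reference cell ids; types with no
#'   reference cell are dropped with a warning.
#' @export
select_reference_cells <- function(counts, markers, min_count = 0) {
  miss <- setdiff(unlist(markers), rownames(counts))
  if (length(miss))
    stop("marker gene(s) absent from the panel: ",
         paste(miss, collapse = ", "))
  score <- vapply(markers, function(g)
    Matrix::colMeans(counts[g, , drop = FALSE]), numeric(ncol(counts)))
  pos <- score > min_count
  one <- rowSums(pos) == 1L
  type_of <- colnames(pos)[max.col(pos, ties.method = "first")]
  refs <- split(colnames(counts)[one], type_of[one])
  empty <- setdiff(names(markers), names(refs))
  if (length(empty))
    warning("no reference cells for type(s): ",
            paste(empty, collapse = ", "))
  refs[intersect(names(markers), names(refs))]
}

#' Build a reference expression profile
#'
#' Per-type mean expression of all panel genes over that type's
#' reference cells, plus the negative-control background: the mean count
#' over all negative-control probes and all cells, used to adjust the
#' Poisson rates during assignment.
#'
#' @param counts a [count_matrix()].
#' @param reference named list, type -> reference cell ids.
#' @param negctrl negative-control probe ids (default: the matrix's).
#' @return list of class `"reference_profile"`: `profile` (panel genes x
#'   types), `negctrl_mean`, `n_reference`.
#' @export
build_reference_profile <- function(counts, reference,
                                    negctrl = negctrl_genes(counts)) {
  if (!length(reference) || any(lengths(reference) == 0L))
    stop("every type needs at least one reference cell")
  panel <- setdiff(rownames(counts), negctrl)
  prof <- vapply(reference, function(ids)
    Matrix::rowMeans(counts[panel, ids, drop = FALSE]),
    numeric(length(panel)))
  rownames(prof) <- panel
  ncm <- if (length(negctrl))
    sum(counts[negctrl, , drop = FALSE]) / (length(negctrl) * ncol(counts))
  else 0
  structure(list(profile = prof, negctrl_mean = as.numeric(ncm),
                 n_reference = lengths(reference)),
            class = "reference_profile")
}

#' Likelihood-based cell-type assignment with posterior probabilities
#'
#' Counts of each cell are modeled as independent Poisson draws with
#' rate `cell_total * (profile[g, t] + negctrl_mean) / sum_g(profile[g, t]
#' + negctrl_mean)` — i.e. each type is a multinomial expression
#' signature with a flat negative-control background added to every
#' gene.  Posterior probabilities follow from the likelihood under a
#' uniform prior over types; each cell is assigned to the argmax.  An
#' optional second round re-scores cells whose broad class belongs to
#' `round2_classes` against subtype profiles only, refining the subtype
#' without changing the broad class.
#'
#' @param counts a [count_matrix()] (QC-passed; no zero-total cells).
#' @param profile a [build_reference_profile()] result (>= 2 types).
#' @param round2_profile optional `reference_profile` of subtypes.
#' @param round2_classes broad class label(s) whose cells are re-scored
#'   in round 2.
#' @return data.frame of class `"typing_result"`: `cell_id`,
#'   `broad_type`, `subtype`, `posterior_max`; `attr(x, "posterior")` is
#'   the round-1 cells x types posterior matrix (rows sum to 1).
#' @export
assign_types <- function(counts, profile, round2_profile = NULL,
                         round2_classes = NULL) {
  stopifnot(inherits(profile, "reference_profile"))
  if (ncol(profile$profile) < 2L) stop("need at least 2 profile types")
  panel <- rownames(profile$profile)
  y <- as.matrix(counts[panel, , drop = FALSE])
  tot <- colSums(as.matrix(counts))
  if (any(tot == 0))
    stop("cell(s) with zero total counts (QC should remove them): ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  post <- .poisson_posterior(y, profile)
  broad <- colnames(post)[max.col(post, ties.method = "first")]
  sub <- broad
  if (!is.null(round2_profile)) {
    if (is.null(round2_classes))
      stop("round2_classes must name the broad class(es) to refine")
    redo <- broad %in% round2_classes
    if (any(redo)) {
      post2 <- .poisson_posterior(y[, redo, drop = FALSE], round2_profile)
      sub[redo] <- colnames(post2)[max.col(post2, ties.method = "first")]
    }
  }
  out <- data.frame(cell_id = colnames(counts), broad_type = broad,
                    subtype = sub,
                    posterior_max = post[cbind(seq_len(nrow(post)),
                                               max.col(post, "first"))],
                    stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  class(out) <- c("typing_result", "data.frame")
  out
}

# cells x types posterior matrix under the Poisson signature model
.poisson_posterior <- function(y, profile) {
  lam <- profile$profile + profile$negctrl_mean
  p <- sweep(lam, 2L, colSums(lam), "/")
  # log-likelihood differs across types only through sum_g y_g log p_gt;
  # a tiny floor keeps zero-rate genes from producing 0 * -Inf
  ll <- t(y) %*% log(pmax(p, 1e-300))
  ll <- ll - apply(ll, 1L, max)
  post <- exp(ll)
  sweep(post, 1L, rowSums(post), "/")
}

#' Validate typing with cell size
#'
#' Fraction of cells larger than `area_threshold` that carry
#' `expected_type` — the megakaryocyte check (cells above 648 um^2,
#' 20,000 px at 0.18 um/px, should be megakaryocytes).
#'
#' @param cells a [cell_table()] with areas.
#' @param typing a [assign_types()] result.
#' @param area_threshold um^2 (default 648).
#' @param expected_type expected label for oversized cells.
#' @param use column of `typing` to compare (default `subtype`).
#' @return fraction in [0, 1], or `NA` with a warning when no cell
#'   exceeds the threshold.
#' @export
validate_by_size <- function(cells, typing, area_threshold = 648,
                             expected_type = "megakaryocyte",
                             use = "subtype") {
  m <- merge(as.data.frame(cells)[, c("cell_id", "area")],
             as.data.frame(typing)[, c("cell_id", use)], by = "cell_id")
  big <- m[m$area > area_threshold, , drop = FALSE]
  if (!nrow(big)) {
    warning("no cells above the area threshold")
    return(NA_real_)
  }
  mean(big[[use]] == expected_type)
}

#' Two-round typing with per-sample reference construction
#'
#' Samples from different patients and time points are heterogeneous, so
#' reference selection, profile construction, and assignment run within
#' each sample by default; `pooled = TRUE` builds one shared profile
#' instead.  Cells whose type is already fixed upstream (leukemia, RBC —
#' identified from morphology, not expression) should be excluded before
#' calling.
#'
#' @param counts a [count_matrix()] (QC-passed).
#' @param cells a [cell_table()] giving each cell's `sample_id`.
#' @param markers broad marker panel (type -> genes).
#' @param subtype_markers optional second-round panel refining
#'   `round2_classes`.
#' @param round2_classes broad classes re-scored in round 2.
#' @param pooled build one profile over all samples (default FALSE).
#' @param min_count marker positivity threshold for reference selection.
#' @return a `typing_result` data.frame over all cells (samples bound
#'   together).
#' @export
type_cells <- function(counts, cells, markers, subtype_markers = NULL,
                       round2_classes = NULL, pooled = FALSE,
                       min_count = 0) {
  groups <- if (pooled) list(all = cells$cell_id)
            else split(cells$cell_id, cells$sample_id)
  out <- lapply(groups, function(ids) {
    cm <- counts[, intersect(colnames(counts), ids), drop = FALSE]
    attr(cm, "negctrl_genes") <- negctrl_genes(counts)
    refs <- select_reference_cells(cm, markers, min_count = min_count)
    prof <- build_reference_profile(cm, refs)
    r2 <- NULL
    if (!is.null(subtype_markers)) {
      refs2 <- select_reference_cells(cm, subtype_markers,
                                      min_count = min_count)
      r2 <- build_reference_profile(cm, refs2)
    }
    assign_types(cm, prof, round2_profile = r2,
                 round2_classes = round2_classes)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("typing_result", "data.frame")
  res
}
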