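#' Read a ligand-receptor pair table
#'
#' Two-column TSV (CellTalkDB-export compatible): `ligand_gene`,
#' `receptor_gene`.  Duplicate pairs or empty gene names are errors.
#'
#' @param path TSV file path.
#' @return data.frame with `ligand_gene`, `receptor_gene`.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand_gene", "receptor_gene") %in% names(df)))
    stop("pair table needs columns ligand_gene, receptor_gene")
  df <- df[, c("ligand_gene", "receptor_gene")]
  if (any(!nzchar(df$ligand_gene)) || any(!nzchar(df$receptor_gene)))
    stop("empty gene name in pair table")
  if (anyDuplicated(df)) stop("duplicate ligand-receptor pairs")
  df
}

#' Close/far proximity groups by distance to the nearest leukemia cell
#'
#' Non-leukemia cells at minimum edge distance <= `close_cutoff` um form
#' the close group, those at >= `far_cutoff` um the far group; cells in
#' between are excluded.  FOVs without leukemia cells contribute only
#' excluded cells (with a warning).
#'
#' @param cells a [cell_table()] (one or more FOVs).
#' @param leukemia_type label of the leukemia population.
#' @param close_cutoff,far_cutoff um (defaults 5 and 30).
#' @return data.frame (`proximity_groups`): `cell_id`, `fov_id`,
#'   `min_dist`, `group` in close/far/excluded.
#' @export
proximity_groups <- function(cells, leukemia_type = "leukemia",
                             close_cutoff = 5, far_cutoff = 30) {
  stopifnot(close_cutoff > 0, close_cutoff < far_cutoff)
  out <- do.call(rbind, lapply(split(seq_len(nrow(cells)), cells$fov_id),
                               function(ix) {
    fov <- cells[ix, , drop = FALSE]
    class(fov) <- class(cells)
    leu <- fov$cell_id[fov$cell_type == leukemia_type]
    oth <- fov$cell_id[fov$cell_type != leukemia_type]
    if (!length(oth)) return(NULL)
    if (!length(leu)) {
      warning("FOV ", fov$fov_id[1], " has no leukemia cells; all excluded")
      return(data.frame(cell_id = oth, fov_id = fov$fov_id[1],
                        min_dist = NA_real_, group = "excluded",
                        stringsAsFactors = FALSE))
    }
    d <- min_distances(fov, leu, target_ids = oth)
    grp <- rep("excluded", length(d))
    grp[d <= close_cutoff] <- "close"
    grp[d >= far_cutoff] <- "far"
    data.frame(cell_id = oth, fov_id = fov$fov_id[1],
               min_dist = unname(d), group = grp, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("proximity_groups", "data.frame")
  out
}

# per-FOV, per-type mean expression of one gene over a set of cells
.fov_type_means <- function(counts, cells, gene, ids) {
  sel <- cells[cells$cell_id %in% ids, , drop = FALSE]
  if (!nrow(sel)) return(NULL)
  vapply(split(sel$cell_id, sel$fov_id, drop = TRUE), function(cid)
    mean(counts[gene, cid]), numeric(1))
}

#' Leukemia-high gene selection (2-SD rule)
#'
#' For each candidate gene on the chosen side of the pair table: the
#' per-FOV mean expression is computed for every cell type, then each
#' type's median across FOVs; the gene qualifies when leukemia's median
#' exceeds the mean of the other types' medians by more than two
#' standard deviations (dispersion taken over the non-leukemia types'
#' medians).
#'
#' @param counts a [count_matrix()].
#' @param cells a typed [cell_table()].
#' @param pairs ligand-receptor pair data.frame.
#' @param gene_side `"ligand"` or `"receptor"`: which side to screen on
#'   leukemia cells.
#' @param leukemia_type label of the leukemia population.
#' @param exclude_types types ignored as comparators (default `"RBC"`).
#' @return character vector of qualifying genes; genes absent from the
#'   panel are skipped with a message.
#' @export
leukemia_high_genes <- function(counts, cells, pairs,
                                gene_side = c("ligand", "receptor"),
                                leukemia_type = "leukemia",
                                exclude_types = "RBC") {
  gene_side <- match.arg(gene_side)
  cand <- unique(pairs[[paste0(gene_side, "_gene")]])
  absent <- setdiff(cand, rownames(counts))
  if (length(absent))
    message("leukemia_high_genes: skipping gene(s) absent from panel: ",
            paste(absent, collapse = ", "))
  cand <- setdiff(cand, absent)
  types <- setdiff(unique(cells$cell_type),
                   c(exclude_types, "unassigned"))
  out <- character(0)
  for (g in cand) {
    med <- vapply(types, function(t) {
      ids <- cells$cell_id[cells$cell_type == t]
      v <- .fov_type_means(counts, cells, g, ids)
      if (is.null(v)) NA_real_ else stats::median(v)
    }, numeric(1))
    med <- med[!is.na(med)]
    if (!leukemia_type %in% names(med)) next
    others <- med[setdiff(names(med), leukemia_type)]
    if (length(others) < 2L) next
    if (med[[leukemia_type]] > mean(others) + 2 * stats::sd(others))
      out <- c(out, g)
  }
  out
}

#' Proximity-conditioned pseudo-bulk ligand-receptor test
#'
#' For each leukemia-high gene and each complementary partner gene from
#' the pair table, and for each non-leukemia cell type and sample: the
#' per-FOV mean partner-gene expression among the type's close cells and
#' far cells, compared across FOV replicates by a two-sided
#' Mann-Whitney U test.  Benjamini-Hochberg adjustment within each
#' (orientation, sample) family.
#'
#' @param counts a [count_matrix()].
#' @param cells a typed [cell_table()] (with `sample_id`).
#' @param prox a [proximity_groups()] result.
#' @param high_genes leukemia-high genes
#'   ([leukemia_high_genes()] output).
#' @param pairs ligand-receptor pair data.frame.
#' @param orientation `"ligand-on-leukemia"` (partners are receptors
#'   tested on other types) or `"receptor-on-leukemia"`.
#' @param leukemia_type,exclude_types as elsewhere.
#' @param min_fovs minimum FOVs with both groups non-empty (default 3);
#'   below it the row is emitted with `p = NA` and a reason.
#' @return data.frame of `lr_test` results: `orientation`,
#'   `leukemia_gene`, `partner_gene`, `partner_cell_type`, `sample_id`,
#'   `n_fovs`, `mean_close`, `mean_far`, `statistic`, `p`, `p_adj`,
#'   `reason`.
#' @export
lr_test <- function(counts, cells, prox, high_genes, pairs,
                    orientation = c("ligand-on-leukemia",
                                    "receptor-on-leukemia"),
                    leukemia_type = "leukemia", exclude_types = "RBC",
                    min_fovs = 3L) {
  orientation <- match.arg(orientation)
  side <- if (orientation == "ligand-on-leukemia") "ligand" else "receptor"
  partner_side <- setdiff(c("ligand", "receptor"), side)
  types <- setdiff(unique(cells$cell_type),
                   c(leukemia_type, exclude_types, "unassigned"))
  samples <- unique(cells$sample_id)
  grp <- prox$group[match(cells$cell_id, prox$cell_id)]
  rows <- list()
  for (g in high_genes) {
    partners <- pairs[pairs[[paste0(side, "_gene")]] == g,
                      paste0(partner_side, "_gene")]
    partners <- intersect(unique(partners), rownames(counts))
    for (pg in partners) for (tt in types) for (sm in samples) {
      sel_close <- cells$cell_type == tt & cells$sample_id == sm &
        !is.na(grp) & grp == "close"
      sel_far <- cells$cell_type == tt & cells$sample_id == sm &
        !is.na(grp) & grp == "far"
      mc <- .fov_type_means(counts, cells, pg, cells$cell_id[sel_close])
      mf <- .fov_type_means(counts, cells, pg, cells$cell_id[sel_far])
      common <- intersect(names(mc), names(mf))
      row <- data.frame(orientation = orientation, leukemia_gene = g,
                        partner_gene = pg, partner_cell_type = tt,
                        sample_id = sm, n_fovs = length(common),
                        mean_close = NA_real_, mean_far = NA_real_,
                        statistic = NA_real_, p = NA_real_,
                        reason = "", stringsAsFactors = FALSE)
      if (length(common) < min_fovs) {
        row$reason <- sprintf("<%d usable FOVs", min_fovs)
      } else {
        wt <- suppressWarnings(
          stats::wilcox.test(mc[common], mf[common], exact = TRUE))
        row$mean_close <- mean(mc[common])
        row$mean_far <- mean(mf[common])
        row$statistic <- unname(wt$statistic)
        row$p <- wt$p.value
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(orientation = character(0)))
  out$p_adj <- NA_real_
  for (sm in unique(out$sample_id)) {
    sel <- out$sample_id == sm & !is.na(out$p)
    out$p_adj[sel] <- stats::p.adjust(out$p[sel], method = "BH")
  }
  rownames(out) <- NULL
  attr(out, "adjust_method") <- "BH within (orientation, sample)"
  class(out) <- c("lr_test", "data.frame")
  out
}
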