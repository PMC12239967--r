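#' Synthetic bone-marrow tissue generator
#'
#' Generates FOVs with known ground truth so every downstream stage —
#' mask fusion, transcript assignment, geometry, typing, neighborhood
#' models, density shift, ligand-receptor testing — is testable without
#' any external data.  Cells are seeded by a (minimum-separation) point
#' process, their boundaries are Voronoi cells clipped to the FOV and
#' shrunk by a small gap so polygons are disjoint; leukemia cells are
#' placed first and non-leukemia types are sampled with placement
#' probability proportional to base proportion times an enrichment
#' multiplier within `enrichment_radius` of the nearest leukemia cell.
#' Per-cell gene counts are Poisson with a log-normal per-cell size
#' factor; a receiver cell type within `lr_effect$radius` of a leukemia
#' cell has its receptor-gene rate multiplied by `lr_effect$fold`;
#' negative-control probes are flat Poisson background.
#'
#' @name synthetic_tissue
NULL

#' Default cell-type expression profiles and marker panel
#'
#' Builds a CosMx-like panel: `n_genes` panel genes (marker blocks per
#' type, a ligand/receptor block, uniform low-rate filler) plus
#' `n_negctrl` negative-control probes.  Rates are scaled so a size
#' factor of 1 gives roughly `target_depth` transcripts per cell,
#' matching sparse imaging-based data with a per-cell median near 100.
#'
#' @param n_genes panel size (default 960).
#' @param n_negctrl number of negative-control probes (default 19).
#' @param target_depth expected transcripts per cell at size factor 1.
#' @param marker_rate Poisson rate per marker gene in its own type.
#' @param n_lr_pairs number of ligand/receptor gene pairs carried by the
#'   panel (ligands high in leukemia, receptors broadly expressed).
#' @return list with `profiles` (genes x types rate matrix), `markers`
#'   (broad marker panel, type -> genes), `subtype_markers` (lymphocyte
#'   subdivision), `negctrl` (probe ids), `lr_pairs` (data.frame
#'   ligand_gene/receptor_gene).
#' @export
default_panel <- function(n_genes = 960L, n_negctrl = 19L,
                          target_depth = 100, marker_rate = 8,
                          n_lr_pairs = 12L) {
  markers <- list(
    leukemia      = c("CD34", "KIT", "MPO", "FLT3", "NPM1"),
    T_cell        = c("CD3E", "CD3D", "CD3G", "CD2", "TRAC"),
    B_cell        = c("CD19", "MS4A1", "CD79A", "CD79B", "IGHM"),
    monocyte      = c("CD14", "LYZ", "S100A8", "S100A9", "FCN1"),
    DC            = c("FCER1A", "CD1C", "CLEC9A", "ITGAX", "IRF8"),
    erythroid     = c("HBB", "HBA1", "HBA2", "ALAS2", "GYPA"),
    megakaryocyte = c("PF4", "PPBP", "ITGA2B", "VWF", "GP9"))
  lig <- c("TNFSF12", sprintf("LIGAND%02d", 2:n_lr_pairs))
  rec <- c("TNFRSF12A", sprintf("RECEPT%02d", 2:n_lr_pairs))
  named <- c(unlist(markers, use.names = FALSE), lig, rec)
  n_fill <- n_genes - length(named)
  if (n_fill < 0) stop("n_genes too small for the named genes")
  genes <- c(named, sprintf("FILLER%04d", seq_len(n_fill)))
  types <- names(markers)
  prof <- matrix(0, nrow = n_genes, ncol = length(types),
                 dimnames = list(genes, types))
  for (t in types) prof[markers[[t]], t] <- marker_rate
  prof[lig, "leukemia"] <- marker_rate        # ligands high in leukemia
  prof[rec, setdiff(types, "leukemia")] <- 1.5 # receptors broadly expressed
  used <- colSums(prof)
  base <- pmax((target_depth - used) / n_fill, 0.001)
  if (n_fill > 0)
    prof[grepl("^FILLER", genes), ] <-
      matrix(rep(base, each = n_fill), nrow = n_fill)
  list(profiles = prof,
       markers = markers[c("leukemia", "T_cell", "B_cell", "monocyte",
                           "DC", "erythroid", "megakaryocyte")],
       subtype_markers = list(T_cell = markers$T_cell,
                              B_cell = markers$B_cell),
       negctrl = sprintf("NegPrb%02d", seq_len(n_negctrl)),
       lr_pairs = data.frame(ligand_gene = lig, receptor_gene = rec,
                             stringsAsFactors = FALSE))
}

#' Parameters of the synthetic tissue generator
#'
#' Defaults emulate the study conditions: FOVs of 985 x 657 um, a
#' 960-gene panel plus 19 negative-control probes, sparse counts with a
#' per-cell median near 100, a leukemia fraction of 10%, and a
#' ligand-receptor proximity effect (receptor rate times `fold` within
#' `radius` um of a leukemia cell).
#'
#' @param ... overrides of the defaults.
#' @return list of class `"tissue_params"`.
#' @export
tissue_params <- function(...) {
  over <- list(...)
  panel <- over$panel %||% default_panel(
    n_genes = over$n_genes %||% 960L,
    n_negctrl = over$n_negctrl %||% 19L)
  p <- list(
    fov_width = 985, fov_height = 657,       # um
    n_cells = 600L,
    leukemia_fraction = 0.1,
    type_proportions = c(erythroid = 0.27, T_cell = 0.25, B_cell = 0.12,
                         monocyte = 0.18, DC = 0.08, megakaryocyte = 0.04,
                         RBC = 0.06),        # non-leukemia placement mix
    enrichment = NULL,                       # named type -> multiplier, or
                                             # list keyed by timepoint
    enrichment_radius = 25,                  # um
    expression_profiles = panel$profiles,
    negctrl_probes = panel$negctrl,
    negctrl_rate = 0.02,                     # per probe per cell
    depth_lognormal = c(mu = 0, sigma = 0.35),
    lr_effect = list(ligand = "TNFSF12", receptor = "TNFRSF12A",
                     receiver_type = "DC", fold = 3, radius = 5),
    membrane_dropout = 0,
    polygon_gap = 1.0,                       # um between neighboring cells
    fov_id = "FOV01", sample_id = "S1", patient_id = "P1",
    timepoint = "baseline", response = "responder",
    transcripts = TRUE,
    seed = 1L)
  over$panel <- NULL; over$n_genes <- NULL; over$n_negctrl <- NULL
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stop("unknown tissue_params key(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (abs(sum(p$type_proportions) - 1) > 1e-9)
    stop("type_proportions must sum to 1")
  if (!is.null(p$lr_effect) && p$lr_effect$fold <= 0) stop("lr fold must be > 0")
  if (any(p$expression_profiles < 0)) stop("expression rates must be >= 0")
  class(p) <- "tissue_params"
  p
}

# Voronoi cells of seed points inside [0,w] x [0,h] by half-plane clipping.
# Returns a list of convex open-ring polygons, one per seed.
voronoi_polygons <- function(seeds, width, height) {
  n <- nrow(seeds)
  rect <- cbind(c(0, width, width, 0), c(0, 0, height, height))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- rect
    d2 <- (seeds[, 1L] - seeds[i, 1L])^2 + (seeds[, 2L] - seeds[i, 2L])^2
    ord <- order(d2)
    for (j in ord) {
      if (j == i) next
      # half-plane can only cut if the bisector is closer than the
      # farthest current vertex
      rmax2 <- max((cell[, 1L] - seeds[i, 1L])^2 +
                   (cell[, 2L] - seeds[i, 2L])^2)
      if (d2[j] > 4 * rmax2) break
      a <- seeds[j, ] - seeds[i, ]
      b <- sum(a * (seeds[i, ] + seeds[j, ]) / 2)
      cell <- clip_halfplane(cell, a, b)
      if (is.null(cell)) break
    }
    out[[i]] <- cell
  }
  out
}

# minimum-separation uniform seed placement (dart throwing)
place_seeds <- function(n, width, height, min_sep, max_tries = 200L) {
  pts <- matrix(NA_real_, n, 2L)
  k <- 0L
  tries <- 0L
  while (k < n) {
    cand <- cbind(stats::runif(n, 0, width), stats::runif(n, 0, height))
    for (r in seq_len(nrow(cand))) {
      if (k == 0L ||
          min((pts[seq_len(k), 1L] - cand[r, 1L])^2 +
              (pts[seq_len(k), 2L] - cand[r, 2L])^2) >= min_sep^2) {
        k <- k + 1L
        pts[k, ] <- cand[r, ]
        if (k == n) break
      }
    }
    tries <- tries + 1L
    if (tries > max_tries)
      stop("n_cells too large for the FOV at the minimum polygon gap")
  }
  pts
}

#' Simulate one FOV with known ground truth
#'
#' @param params a [tissue_params()].
#' @return list with `cells` (a [cell_table()]), `transcripts`
#'   (data.frame gene/x/y/cell_id, or NULL when
#'   `params$transcripts = FALSE`), `counts` (a [count_matrix()]), and
#'   `truth` (list: `types`, `min_dist_leukemia`, `proximity_group`
#'   close/far/excluded by true edge distance, `enrichment` in force,
#'   `lr_boosted` cell ids, `seed`).
#' @export
simulate_fov <- function(params = tissue_params()) {
  p <- params
  set.seed(p$seed)
  w <- p$fov_width; h <- p$fov_height
  n <- as.integer(p$n_cells)
  min_sep <- 0.55 * sqrt(w * h / n)
  if (min_sep <= p$polygon_gap)
    stop("n_cells too large for the FOV at the minimum polygon gap")
  n_leuk <- round(n * p$leukemia_fraction)
  seeds <- place_seeds(n, w, h, min_sep)
  # leukemia cells are the first n_leuk seeds (placed first)
  leuk_idx <- seq_len(n_leuk)
  d2leuk_seed <- if (n_leuk > 0) {
    sq <- outer(seeds[, 1L], seeds[leuk_idx, 1L], "-")^2 +
          outer(seeds[, 2L], seeds[leuk_idx, 2L], "-")^2
    sqrt(apply(sq, 1L, min))
  } else rep(Inf, n)
  # type sampling for non-leukemia cells: thinning by enrichment
  enr <- p$enrichment
  if (is.list(enr) && !is.null(names(enr)) &&
      any(names(enr) %in% TIMEPOINT_LEVELS))
    enr <- enr[[p$timepoint]]
  base <- p$type_proportions / sum(p$type_proportions)
  types <- character(n)
  types[leuk_idx] <- "leukemia"
  for (i in setdiff(seq_len(n), leuk_idx)) {
    wts <- base
    if (!is.null(enr) && d2leuk_seed[i] <= p$enrichment_radius) {
      m <- enr[names(base)]
      m[is.na(m)] <- 1
      wts <- base * m
    }
    types[i] <- sample(names(base), 1L, prob = wts)
  }
  polys <- voronoi_polygons(seeds, w, h)
  polys <- lapply(polys, function(pp) {
    if (is.null(pp)) return(NULL)
    poly_inward_offset(pp, p$polygon_gap / 2)
  })
  if (any(vapply(polys, is.null, logical(1))))
    stop("n_cells too large for the FOV at the minimum polygon gap")
  ids <- sprintf("c%04d", seq_len(n))
  cells <- cell_table(data.frame(
    cell_id = ids, fov_id = p$fov_id, sample_id = p$sample_id,
    patient_id = p$patient_id, timepoint = p$timepoint,
    response = p$response, cell_type = types,
    stringsAsFactors = FALSE), polys)
  # true min edge distance to leukemia, for proximity truth and LR effect
  min_dist <- rep(Inf, n)
  if (n_leuk > 0) {
    bbs <- t(vapply(polys, poly_bbox, numeric(4)))
    nonleuk <- setdiff(seq_len(n), leuk_idx)
    min_dist[nonleuk] <- .min_dist_to_set(polys, bbs, nonleuk, leuk_idx)
    min_dist[leuk_idx] <- 0
  }
  prox <- rep("excluded", n)
  prox[min_dist <= 5] <- "close"
  prox[min_dist >= 30] <- "far"
  prox[leuk_idx] <- NA_character_
  # counts
  genes <- rownames(p$expression_profiles)
  # RBC (and any unprofiled type): anucleate, near-zero transcripts
  rate_mat <- matrix(0.0005, nrow = length(genes), ncol = n,
                     dimnames = list(genes, ids))
  have_prof <- types %in% colnames(p$expression_profiles)
  rate_mat[, have_prof] <- p$expression_profiles[, types[have_prof]]
  lr_boost <- character(0)
  if (!is.null(p$lr_effect)) {
    eff <- p$lr_effect
    hit <- which(types == eff$receiver_type & min_dist <= eff$radius)
    if (length(hit) && eff$receptor %in% genes) {
      rate_mat[eff$receptor, hit] <- rate_mat[eff$receptor, hit] * eff$fold
      lr_boost <- ids[hit]
    }
  }
  sf <- stats::rlnorm(n, p$depth_lognormal[["mu"]], p$depth_lognormal[["sigma"]])
  cnt <- matrix(stats::rpois(length(rate_mat),
                             rate_mat * rep(sf, each = length(genes))),
                nrow = length(genes), dimnames = list(genes, ids))
  neg <- matrix(stats::rpois(length(p$negctrl_probes) * n, p$negctrl_rate),
                nrow = length(p$negctrl_probes),
                dimnames = list(p$negctrl_probes, ids))
  counts <- count_matrix(rbind(cnt, neg), negctrl_genes = p$negctrl_probes)
  transcripts <- NULL
  if (isTRUE(p$transcripts)) {
    tot_all <- Matrix::colSums(counts)
    per_cell <- lapply(seq_len(n), function(i) {
      if (tot_all[i] == 0) return(NULL)
      gvec <- rep(rownames(counts), counts[, i])
      xy <- sample_in_polygon(polys[[i]], length(gvec))
      data.frame(gene = gvec, x = xy[, 1L], y = xy[, 2L],
                 cell_id = ids[i], stringsAsFactors = FALSE)
    })
    transcripts <- do.call(rbind, per_cell)
    rownames(transcripts) <- NULL
  }
  list(cells = cells, transcripts = transcripts, counts = counts,
       truth = list(types = stats::setNames(types, ids),
                    min_dist_leukemia = stats::setNames(min_dist, ids),
                    proximity_group = stats::setNames(prox, ids),
                    enrichment = enr, lr_boosted = lr_boost,
                    seed = p$seed))
}

# lower bound on edge distance from bounding boxes
bbox_gap <- function(a, b) {
  ba <- poly_bbox(a); bb <- poly_bbox(b)
  dx <- max(0, max(ba["xmin"], bb["xmin"]) - min(ba["xmax"], bb["xmax"]))
  dy <- max(0, max(ba["ymin"], bb["ymin"]) - min(ba["ymax"], bb["ymax"]))
  sqrt(dx^2 + dy^2)
}

# uniform points inside a polygon by rejection from its bounding box
sample_in_polygon <- function(poly, n) {
  bb <- poly_bbox(poly)
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    x <- stats::runif(m, bb["xmin"], bb["xmax"])
    y <- stats::runif(m, bb["ymin"], bb["ymax"])
    keep <- point_in_polygon(x, y, poly, tol = 0)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate paired nucleus / membrane / truth label images
#'
#' Truth is the rasterized cell polygons (labels are the row index of
#' `cells`); the nucleus mask is each polygon shrunk about its centroid
#' to ~40% of its area (so each nucleus is wholly inside its cell); the
#' membrane mask is the truth raster with each cell independently dropped
#' with probability `membrane_dropout`, emulating membrane-stain failure.
#'
#' @param cells a [cell_table()] with disjoint polygons.
#' @param membrane_dropout per-cell dropout probability.
#' @param seed RNG seed for the dropout draws.
#' @param pixel_size um per pixel for rasterization.
#' @return list: `nucleus`, `membrane`, `truth` ([label_image()]s),
#'   `dropped` (cell ids removed from the membrane raster), `label_map`
#'   (data.frame label/cell_id).
#' @export
simulate_mask_pair <- function(cells, membrane_dropout = 0, seed = 1L,
                               pixel_size = 0.18) {
  set.seed(seed)
  n <- nrow(cells)
  labels <- seq_len(n)
  w <- max(vapply(cells$polygon, function(p) max(p[, 1L]), numeric(1)))
  h <- max(vapply(cells$polygon, function(p) max(p[, 2L]), numeric(1)))
  truth <- rasterize_polygons(cells$polygon, labels, w, h, pixel_size)
  nuc_polys <- lapply(cells$polygon, function(p) {
    cen <- poly_centroid(p)
    # scale about the centroid so nucleus area is ~40% of the cell's
    t(cen + t(sweep(p, 2L, cen)) * sqrt(0.4))
  })
  nucleus <- rasterize_polygons(nuc_polys, labels, w, h, pixel_size)
  drop <- stats::runif(n) < membrane_dropout
  membrane <- unclass(truth)
  membrane[membrane %in% labels[drop]] <- 0L
  membrane <- label_image(membrane, pixel_size = pixel_size)
  list(nucleus = nucleus, membrane = membrane, truth = truth,
       dropped = cells$cell_id[drop],
       label_map = data.frame(label = labels, cell_id = cells$cell_id,
                              stringsAsFactors = FALSE))
}

#' Simulate a multi-FOV sample (cohort of FOVs sharing one condition)
#'
#' Runs [simulate_fov()] once per FOV with derived seeds, prefixes cell
#' ids with the FOV id so they are unique across the sample, and merges
#' cell tables and count matrices.
#'
#' @param n_fovs number of FOVs.
#' @param params a [tissue_params()]; its `fov_id` and `seed` are
#'   overridden per FOV.
#' @param seed base seed; FOV f uses `seed * 1000 + f`.
#' @return list: `cells` ([cell_table()] over all FOVs), `counts`
#'   ([count_matrix()]), `truth` (per-FOV list).
#' @export
simulate_fov_set <- function(n_fovs, params = tissue_params(), seed = 1L) {
  sims <- lapply(seq_len(n_fovs), function(f) {
    p <- params
    p$fov_id <- sprintf("F%02d", f)
    p$seed <- as.integer(seed * 1000 + f)
    simulate_fov(p)
  })
  cells <- cell_table(do.call(rbind, lapply(sims, function(s)
    as.data.frame(s$cells))))
  counts <- count_matrix(
    do.call(cbind, lapply(sims, function(s) as.matrix(s$counts))),
    negctrl_genes = negctrl_genes(sims[[1]]$counts))
  new_id <- paste(cells$fov_id, cells$cell_id, sep = ".")
  colnames(counts) <- new_id
  cells$cell_id <- new_id
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- sprintf("F%02d", seq_len(n_fovs))
  list(cells = cells, counts = counts, truth = truth)
}

#' Simulate per-cell counts straight from type expression profiles
#'
#' Draws cells of known type from the panel's Poisson rate profiles
#' without any tissue geometry — the fixture for cell-typing recovery
#' studies.  `depth` scales all rates (1 keeps the panel's target depth,
#' about 100 transcripts per cell).
#'
#' @param n_per_type cells per type.
#' @param depth rate multiplier.
#' @param seed RNG seed.
#' @param panel a [default_panel()] list.
#' @return list: `counts` ([count_matrix()]), `truth` (named type
#'   vector), `panel`.
#' @export
simulate_typing_counts <- function(n_per_type = 60L, depth = 1,
                                   seed = 1L,
                                   panel = default_panel(n_genes = 120L)) {
  set.seed(seed)
  prof <- panel$profiles
  truth <- rep(colnames(prof), each = n_per_type)
  ids <- sprintf("c%04d", seq_along(truth))
  lam <- prof[, truth] * depth
  m <- matrix(stats::rpois(length(lam), lam), nrow = nrow(prof),
              dimnames = list(rownames(prof), ids))
  neg <- matrix(stats::rpois(length(panel$negctrl) * length(ids), 0.02),
                nrow = length(panel$negctrl),
                dimnames = list(panel$negctrl, ids))
  list(counts = count_matrix(rbind(m, neg),
                             negctrl_genes = panel$negctrl),
       truth = stats::setNames(truth, ids), panel = panel)
}
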