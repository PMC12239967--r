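# counts drawn straight from known type profiles, without tissue geometry
sim_counts <- function(n_per_type = 40, depth = 1, seed = 1,
                       panel = default_panel(n_genes = 120L)) {
  set.seed(seed)
  prof <- panel$profiles
  types <- colnames(prof)
  truth <- rep(types, each = n_per_type)
  ids <- sprintf("c%04d", seq_along(truth))
  lam <- prof[, truth] * depth
  m <- matrix(rpois(length(lam), lam), nrow = nrow(prof),
              dimnames = list(rownames(prof), ids))
  neg <- matrix(rpois(19 * length(ids), 0.02), nrow = 19,
                dimnames = list(panel$negctrl, ids))
  list(counts = count_matrix(rbind(m, neg), negctrl_genes = panel$negctrl),
       truth = stats::setNames(truth, ids), panel = panel)
}

test_that("qc removes sub-threshold cells, then sub-threshold FOVs", {
  # FOV A: 4 cells, one at 19 counts; FOV B: 2 cells (below min 3)
  ids <- sprintf("q%d", 1:6)
  m <- matrix(0L, nrow = 3, ncol = 6,
              dimnames = list(c("g1", "g2", "g3"), ids))
  m[1, ] <- c(19L, 20L, 50L, 100L, 40L, 40L)
  counts <- count_matrix(m)
  cells <- make_cells(rep(list(make_square(0, 0, 5)), 6))
  cells$cell_id <- ids
  cells$fov_id <- c("A", "A", "A", "A", "B", "B")
  kept <- suppressMessages(qc_filter(cells, counts,
                                     qc_min_transcripts = 20,
                                     qc_min_cells_per_fov = 3))
  expect_setequal(kept$cell_id, c("q2", "q3", "q4"))
  lg <- attr(kept, "removal_log")
  expect_equal(lg$low_count_cells, "q1")
  expect_equal(lg$removed_fovs, "B")
  # exact boundary: 20 transcripts kept, 19 removed; 300/299-cell FOVs
  expect_true("q2" %in% kept$cell_id)    # exactly 20
  expect_false("q1" %in% kept$cell_id)   # 19
  # all-pass input returns unchanged
  kept2 <- suppressMessages(qc_filter(cells, counts,
                                      qc_min_transcripts = 0,
                                      qc_min_cells_per_fov = 0))
  expect_equal(nrow(kept2), 6L)
})

test_that("reference cells have exactly one positive marker type", {
  panel <- default_panel(n_genes = 120L)
  ids <- c("t1", "mixed", "none", "t2")
  m <- matrix(0L, nrow = nrow(panel$profiles), ncol = 4,
              dimnames = list(rownames(panel$profiles), ids))
  m["CD3E", "t1"] <- 5L                        # T only
  m["CD3E", "mixed"] <- 5L; m["CD19", "mixed"] <- 4L  # T + B
  m["CD3D", "t2"] <- 2L
  counts <- count_matrix(rbind(m, matrix(0L, 19, 4,
    dimnames = list(panel$negctrl, ids))), negctrl_genes = panel$negctrl)
  refs <- suppressWarnings(
    select_reference_cells(counts, panel$markers))
  expect_setequal(refs$T_cell, c("t1", "t2"))
  expect_false("mixed" %in% unlist(refs))
  expect_false("none" %in% unlist(refs))
})

test_that("high-depth pure cells almost all become references", {
  sc <- sim_counts(n_per_type = 50, depth = 1, seed = 3)
  refs <- suppressWarnings(
    select_reference_cells(sc$counts, sc$panel$markers))
  hit <- 0; tot <- 0
  for (t in names(refs)) {
    tot <- tot + sum(sc$truth == t)
    hit <- hit + sum(sc$truth[refs[[t]]] == t)
  }
  expect_gte(hit / tot, 0.9)
})

test_that("reference profiles recover generator rates", {
  sc <- sim_counts(n_per_type = 200, depth = 1, seed = 5)
  refs <- split(names(sc$truth), sc$truth)
  prof <- build_reference_profile(sc$counts, refs)
  # compare marker-gene means to true rates (10% relative at n = 200)
  for (t in colnames(prof$profile)) {
    g <- sc$panel$markers[[t]]
    expect_equal(unname(prof$profile[g, t]),
                 unname(sc$panel$profiles[g, t]), tolerance = 0.1)
  }
  # single reference cell: profile equals its counts
  one <- lapply(refs, `[`, 1)
  p1 <- build_reference_profile(sc$counts, one)
  expect_equal(unname(p1$profile[, "T_cell"]),
               as.numeric(sc$counts[rownames(p1$profile), one$T_cell]))
  # all-zero negative probes give zero background
  m0 <- as.matrix(sc$counts)
  m0[sc$panel$negctrl, ] <- 0L
  cm0 <- count_matrix(m0, negctrl_genes = sc$panel$negctrl)
  expect_equal(build_reference_profile(cm0, refs)$negctrl_mean, 0)
})

test_that("posteriors are proper and scale-invariant", {
  sc <- sim_counts(n_per_type = 20, depth = 1, seed = 7)
  refs <- split(names(sc$truth), sc$truth)
  prof <- build_reference_profile(sc$counts, refs)
  ty <- assign_types(sc$counts, prof)
  post <- attr(ty, "posterior")
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-9)
  expect_equal(ty$broad_type,
               colnames(post)[max.col(post, ties.method = "first")])
  # multiplying all profiles by a constant leaves assignments unchanged
  prof2 <- prof; prof2$profile <- prof$profile * 7.3
  prof2$negctrl_mean <- prof$negctrl_mean * 7.3
  ty2 <- assign_types(sc$counts, prof2)
  expect_equal(ty2$broad_type, ty$broad_type)
  expect_equal(attr(ty2, "posterior"), post, tolerance = 1e-9)
  # two identical profiles: posteriors 0.5/0.5
  prof3 <- prof
  prof3$profile <- prof$profile[, c("T_cell", "T_cell")]
  colnames(prof3$profile) <- c("A", "B")
  ty3 <- assign_types(sc$counts, prof3)
  expect_equal(unname(attr(ty3, "posterior")[, "A"]),
               rep(0.5, ncol(sc$counts)))
})

test_that("deep draws from one profile are assigned with certainty", {
  panel <- default_panel(n_genes = 120L)
  prof_rates <- panel$profiles
  set.seed(11)
  y <- matrix(rpois(nrow(prof_rates) * 5, prof_rates[, "T_cell"] * 100),
              nrow = nrow(prof_rates),
              dimnames = list(rownames(prof_rates), sprintf("d%d", 1:5)))
  counts <- count_matrix(rbind(y, matrix(0L, 19, 5,
    dimnames = list(panel$negctrl, colnames(y)))),
    negctrl_genes = panel$negctrl)
  refs <- structure(vector("list", ncol(prof_rates)),
                    names = colnames(prof_rates))
  prof <- list(profile = prof_rates, negctrl_mean = 0.02,
               n_reference = lengths(refs))
  class(prof) <- "reference_profile"
  ty <- assign_types(counts, prof)
  expect_true(all(ty$broad_type == "T_cell"))
  expect_true(all(ty$posterior_max > 0.99))
  # brute-force log-likelihood agrees with the posterior argmax
  lam <- sweep(prof_rates + 0.02, 2, colSums(prof_rates + 0.02), "/")
  ll <- vapply(colnames(lam), function(t)
    sum(dpois(y[, 1], sum(y[, 1]) * lam[, t], log = TRUE)), numeric(1))
  expect_equal(names(which.max(ll)), ty$broad_type[1])
})

test_that("round 2 refines subtypes without touching broad classes", {
  panel <- default_panel(n_genes = 120L)
  # broad profiles: lymphocyte = T+B average; round 2 separates them
  prof_rates <- panel$profiles
  lymph <- rowMeans(prof_rates[, c("T_cell", "B_cell")])
  broad_rates <- cbind(lymphocyte = lymph,
                       prof_rates[, c("monocyte", "erythroid")])
  set.seed(13)
  truth <- rep(c("T_cell", "B_cell", "monocyte"), each = 30)
  lam <- prof_rates[, truth]
  y <- matrix(rpois(length(lam), lam), nrow = nrow(lam),
              dimnames = list(rownames(prof_rates),
                              sprintf("r%03d", seq_along(truth))))
  counts <- count_matrix(rbind(y, matrix(0L, 19, length(truth),
    dimnames = list(panel$negctrl, colnames(y)))),
    negctrl_genes = panel$negctrl)
  bprof <- structure(list(profile = broad_rates, negctrl_mean = 0.02,
                          n_reference = c(1, 1, 1)),
                     class = "reference_profile")
  sprof <- structure(list(profile = prof_rates[, c("T_cell", "B_cell")],
                          negctrl_mean = 0.02, n_reference = c(1, 1)),
                     class = "reference_profile")
  ty <- assign_types(counts, bprof, round2_profile = sprof,
                     round2_classes = "lymphocyte")
  lymph_cells <- ty$broad_type == "lymphocyte"
  expect_true(all(ty$subtype[lymph_cells] %in% c("T_cell", "B_cell")))
  expect_true(all(ty$subtype[!lymph_cells] == ty$broad_type[!lymph_cells]))
  # subtype recovery among true lymphocytes
  istrue_lymph <- truth %in% c("T_cell", "B_cell")
  acc <- mean(ty$subtype[lymph_cells & istrue_lymph] ==
                truth[lymph_cells & istrue_lymph])
  expect_gte(acc, 0.9)
})

test_that("zero-count cells are rejected at assignment", {
  panel <- default_panel(n_genes = 120L)
  m <- matrix(0L, nrow(panel$profiles) + 19, 2,
              dimnames = list(c(rownames(panel$profiles), panel$negctrl),
                              c("z1", "z2")))
  m[1, 2] <- 5L
  counts <- count_matrix(m, negctrl_genes = panel$negctrl)
  prof <- structure(list(profile = panel$profiles, negctrl_mean = 0,
                         n_reference = rep(1, ncol(panel$profiles))),
                    class = "reference_profile")
  expect_error(assign_types(counts, prof), "zero total")
})

test_that("typing accuracy is high at median depth ~100 and rises with depth", {
  accs <- vapply(c(0.5, 1, 5), function(depth) {
    sc <- sim_counts(n_per_type = 60, depth = depth, seed = 17)
    refs <- suppressWarnings(
      select_reference_cells(sc$counts, sc$panel$markers))
    prof <- build_reference_profile(sc$counts, refs)
    ty <- assign_types(sc$counts, prof)
    mean(ty$broad_type == sc$truth[ty$cell_id])
  }, numeric(1))
  expect_gte(accs[2], 0.8)          # depth ~100
  expect_true(all(diff(accs) >= 0)) # non-decreasing in depth
})

test_that("size validation scores oversized cells against expectation", {
  cells <- random_fov_cells(n = 60, seed = 19)
  ty <- data.frame(cell_id = cells$cell_id,
                   broad_type = "monocyte",
                   subtype = "monocyte", stringsAsFactors = FALSE)
  big <- cells$area > median(cells$area)
  ty$subtype[big] <- "megakaryocyte"
  frac <- validate_by_size(cells, ty, area_threshold = median(cells$area),
                           expected_type = "megakaryocyte")
  expect_equal(frac, 1.0)
  # direct confusion-matrix recomputation agrees
  frac2 <- mean(ty$subtype[cells$area > median(cells$area)] ==
                  "megakaryocyte")
  expect_equal(frac, frac2)
  expect_warning(v <- validate_by_size(cells, ty, area_threshold = 1e9),
                 "no cells")
  expect_true(is.na(v))
})

test_that("per-sample typing keeps samples separate; pooled mode exists", {
  panel <- default_panel(n_genes = 120L)
  sc1 <- simulate_typing_counts(n_per_type = 25, depth = 1, seed = 23,
                                panel = panel)
  sc2 <- simulate_typing_counts(n_per_type = 25, depth = 1, seed = 24,
                                panel = panel)
  ids1 <- paste0("s1.", colnames(sc1$counts))
  ids2 <- paste0("s2.", colnames(sc2$counts))
  counts <- count_matrix(cbind(as.matrix(sc1$counts),
                               as.matrix(sc2$counts)),
                         genes = rownames(sc1$counts),
                         cells = c(ids1, ids2),
                         negctrl_genes = panel$negctrl)
  sq <- cbind(c(0, 5, 5, 0), c(0, 0, 5, 5))
  cells <- cell_table(data.frame(
    cell_id = c(ids1, ids2), fov_id = "F1",
    sample_id = rep(c("s1", "s2"), each = length(ids1)),
    stringsAsFactors = FALSE), rep(list(sq), length(ids1) * 2))
  truth <- stats::setNames(c(sc1$truth, sc2$truth), c(ids1, ids2))
  ty <- suppressWarnings(type_cells(counts, cells, panel$markers))
  expect_setequal(ty$cell_id, c(ids1, ids2))
  expect_gte(mean(ty$broad_type == truth[ty$cell_id]), 0.8)
  typ <- suppressWarnings(type_cells(counts, cells, panel$markers,
                                     pooled = TRUE))
  expect_gte(mean(typ$broad_type == truth[typ$cell_id]), 0.8)
})
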