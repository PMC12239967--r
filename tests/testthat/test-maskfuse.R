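test_that("nuclei inside membranes fuse to the membrane objects", {
  nuc <- matrix(0L, 30, 30); mem <- matrix(0L, 30, 30)
  mem[2:10, 2:10] <- 1L;  nuc[4:7, 4:7] <- 1L
  mem[15:25, 15:25] <- 2L; nuc[18:22, 18:22] <- 2L
  fz <- fuse_masks(label_image(nuc, 1), label_image(mem, 1))
  expect_identical(unclass(fz$fused)[, ], mem)
  expect_equal(sort(fz$provenance$source), c("paired", "paired"))
})

test_that("empty membranes trigger the nuclear-expansion fallback", {
  nuc <- matrix(0L, 40, 40)
  nuc[10:13, 10:13] <- 1L
  nuc[10:13, 25:28] <- 2L
  fz <- fuse_masks(label_image(nuc, pixel_size = 1),
                   label_image(matrix(0L, 40, 40), pixel_size = 1),
                   fusion_params(expansion_radius = 3))
  expect_equal(sort(unique(fz$provenance$source)), "nucleus-expanded")
  f <- unclass(fz$fused)
  # original nucleus pixels keep their (offset) labels
  expect_true(all(f[nuc == 1L] == fz$provenance$fused_label[1]))
  # expansion grew the objects but stayed within the radius
  a1 <- sum(f == fz$provenance$fused_label[1])
  expect_gt(a1, 16)            # grew beyond the 4x4 nucleus
  expect_lte(a1, sum(outer((-10:10), (-10:10), function(r, c) {
    d <- sqrt(pmax(0, (abs(r) - 2))^2 + pmax(0, (abs(c) - 2))^2)
    d <= 3.01
  })))
  # disjointness: expansions never overlap
  expect_true(all(table(f[f > 0]) > 0))
})

test_that("colliding expansions split pixels by nearest nucleus", {
  nuc <- matrix(0L, 20, 20)
  nuc[9:11, 4:6] <- 1L
  nuc[9:11, 12:14] <- 2L
  fz <- fuse_masks(label_image(nuc, 1), label_image(matrix(0L, 20, 20), 1),
                   fusion_params(expansion_radius = 5))
  f <- unclass(fz$fused)
  lab <- fz$provenance$fused_label
  # the column midway between the nuclei belongs to label 1 (tie -> smaller)
  expect_true(all(f[9:11, 9] == lab[1]))
  expect_true(all(f[9:11, 8] == lab[1]))
  expect_true(all(f[9:11, 10] == lab[2]))
})

test_that("membranes claimed by two nuclei keep the larger overlap", {
  nuc <- matrix(0L, 30, 30); mem <- matrix(0L, 30, 30)
  mem[5:20, 5:20] <- 1L
  nuc[6:12, 6:12] <- 1L      # 49 px inside membrane 1
  nuc[15:17, 15:17] <- 2L    # 9 px inside membrane 1
  fz <- fuse_masks(label_image(nuc, 1), label_image(mem, 1))
  prov <- fz$provenance
  expect_equal(prov$source[prov$nucleus_label == 1], "paired")
  expect_equal(prov$source[prov$nucleus_label == 2], "nucleus-expanded")
})

test_that("provenance matches the generator's dropout flags", {
  cells <- random_fov_cells(n = 120, w = 300, h = 200, seed = 41)
  mp <- simulate_mask_pair(cells, membrane_dropout = 0.3, seed = 3,
                           pixel_size = 0.5)
  fz <- fuse_masks(mp$nucleus, mp$membrane)
  prov <- fz$provenance
  expanded <- mp$label_map$cell_id[match(
    prov$nucleus_label[prov$source == "nucleus-expanded"],
    mp$label_map$label)]
  expect_setequal(expanded, mp$dropped)
  expect_equal(sum(prov$source == "paired"), 120 - length(mp$dropped))
})

test_that("fused masks are always pairwise disjoint rasters", {
  # a raster cannot carry two labels per pixel by construction; check
  # instead that every fused object's pixels are connected to one source
  cells <- random_fov_cells(n = 60, w = 200, h = 150, seed = 43)
  mp <- simulate_mask_pair(cells, membrane_dropout = 0.5, seed = 5,
                           pixel_size = 0.5)
  fz <- fuse_masks(mp$nucleus, mp$membrane)
  expect_equal(anyDuplicated(fz$provenance$fused_label), 0L)
  expect_true(all(unclass(fz$fused) >= 0L))
})

test_that("transcript assignment takes the label under each transcript", {
  img <- matrix(0L, 20, 20)
  img[5:10, 5:10] <- 7L
  li <- label_image(img, pixel_size = 1)
  tr <- data.frame(gene = c("A", "B", "C"),
                   x = c(7.5, 1.0, 25.0),
                   y = c(7.5, 1.0, 7.0), stringsAsFactors = FALSE)
  out <- suppressMessages(assign_transcripts(li, tr))
  expect_equal(out$cell_id, c("7", NA, NA))
  lg <- attr(out, "log")
  expect_equal(unname(lg["assigned"] + lg["unassigned"]),
               unname(lg["input"]))
  expect_equal(unname(lg["out_of_bounds"]), 1L)
})

test_that("truth-mask assignment recovers the generator's cell ids", {
  sim <- simulate_fov(tissue_params(n_cells = 100L, fov_width = 250,
                                    fov_height = 180, n_genes = 80L,
                                    seed = 17L))
  mp <- simulate_mask_pair(sim$cells, membrane_dropout = 0, seed = 1,
                           pixel_size = 0.3)
  out <- assign_transcripts(mp$truth, sim$transcripts)
  assigned <- !is.na(out$cell_id)
  truth_label <- mp$label_map$label[match(sim$transcripts$cell_id,
                                          mp$label_map$cell_id)]
  agree <- out$cell_id[assigned] == as.character(truth_label[assigned])
  expect_gte(mean(agree), 0.99)
  # most transcripts land on their cell's pixels at this resolution
  expect_gt(mean(assigned), 0.8)
})

test_that("segmentation evaluation implements the printed F1 formula", {
  # identity
  m <- matrix(0L, 30, 30); m[2:8, 2:8] <- 1L; m[12:20, 12:20] <- 2L
  t1 <- label_image(m, 1)
  ev <- evaluate_segmentation(t1, t1, 0.7)
  expect_equal(ev$f1, 1.0)
  expect_equal(ev$fp + ev$fn, 0L)
  # disjoint
  m2 <- matrix(0L, 30, 30); m2[22:28, 22:28] <- 1L
  ev2 <- evaluate_segmentation(label_image(m2, 1), t1, 0.7)
  expect_equal(ev2$f1, 0)
  # constructed tp=10 fp=5 fn=5 -> F1 = 10/15
  big <- matrix(0L, 40, 120); pred <- big; tru <- big
  k <- 0L
  for (i in 0:14) {           # 15 predicted objects in a grid
    r <- 3 + (i %% 5) * 7; c <- 3 + (i %/% 5) * 30
    pred[r:(r + 4), c:(c + 4)] <- i + 1L
    if (i < 10) tru[r:(r + 4), c:(c + 4)] <- i + 1L   # 10 matching truths
  }
  for (i in 15:19) {          # 5 truth objects nobody predicted
    r <- 3 + (i %% 5) * 7; c <- 80 + ((i - 15) %/% 5) * 10
    tru[r:(r + 4), c:(c + 4)] <- i + 1L
  }
  ev3 <- evaluate_segmentation(label_image(pred, 1), label_image(tru, 1),
                               0.7)
  expect_equal(c(ev3$tp, ev3$fp, ev3$fn), c(10L, 5L, 5L))
  expect_equal(ev3$f1, 10 / (10 + (5 + 5) / 2))
  expect_equal(round(ev3$f1, 4), 0.6667)
})

test_that("deleting one truth object gives tp=3 fp=0 fn=1, F1 = 6/7", {
  m <- matrix(0L, 20, 44)
  for (i in 0:3) m[3:9, (3 + i * 10):(9 + i * 10)] <- i + 1L
  pred <- m; pred[pred == 4L] <- 0L
  ev <- evaluate_segmentation(label_image(pred, 1), label_image(m, 1), 0.7)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(3L, 0L, 1L))
  expect_equal(ev$f1, 3 / 3.5)
})

test_that("swapping predicted and truth swaps fp/fn, keeps F1", {
  cells <- random_fov_cells(n = 50, seed = 47)
  mp <- simulate_mask_pair(cells, membrane_dropout = 0.4, seed = 9,
                           pixel_size = 0.5)
  fz <- fuse_masks(mp$nucleus, mp$membrane,
                   fusion_params(expansion_radius = 1))
  a <- evaluate_segmentation(fz$fused, mp$truth, 0.7)
  b <- evaluate_segmentation(mp$truth, fz$fused, 0.7)
  expect_equal(a$fp, b$fn)
  expect_equal(a$fn, b$fp)
  expect_equal(a$f1, b$f1)
})

test_that("F1 is non-increasing in the IOU threshold", {
  cells <- random_fov_cells(n = 50, seed = 49)
  mp <- simulate_mask_pair(cells, membrane_dropout = 0.3, seed = 11,
                           pixel_size = 0.5)
  fz <- fuse_masks(mp$nucleus, mp$membrane,
                   fusion_params(expansion_radius = 2))
  f1s <- vapply(c(0.3, 0.5, 0.7, 0.9),
                function(th) evaluate_segmentation(fz$fused, mp$truth,
                                                   th)$f1,
                numeric(1))
  expect_true(all(diff(f1s) <= 1e-12))
})

test_that("dropout-free fusion reproduces the truth exactly (F1 = 1)", {
  cells <- random_fov_cells(n = 80, w = 250, h = 180, seed = 51)
  mp <- simulate_mask_pair(cells, membrane_dropout = 0, seed = 1,
                           pixel_size = 0.5)
  fz <- fuse_masks(mp$nucleus, mp$membrane)
  ev <- evaluate_segmentation(fz$fused, mp$truth, 0.7)
  expect_equal(ev$f1, 1.0)
  expect_equal(ev$fp + ev$fn, 0L)
})

test_that("orphan membranes are kept or dropped per the flag", {
  nuc <- matrix(0L, 30, 30); mem <- matrix(0L, 30, 30)
  mem[2:10, 2:10] <- 1L; nuc[4:7, 4:7] <- 1L
  mem[15:25, 15:25] <- 2L                 # membrane with no nucleus
  fz <- fuse_masks(label_image(nuc, 1), label_image(mem, 1))
  expect_setequal(fz$provenance$source, c("paired", "orphan-membrane"))
  expect_true(2L %in% fz$provenance$fused_label)
  fz2 <- fuse_masks(label_image(nuc, 1), label_image(mem, 1),
                    fusion_params(keep_orphan_membranes = FALSE))
  expect_equal(fz2$provenance$source, "paired")
  expect_false(any(unclass(fz2$fused) == 2L))
})
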