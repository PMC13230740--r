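# Expression matrices, cosine distances and cell-type calling gates.

test_that("spots inside a nucleus are counted for that cell", {
  mask <- matrix(0L, 40, 40)
  mask[5:15, 5:15] <- 3L
  mask[25:35, 25:35] <- 7L
  spots <- data.frame(gene = c("g1", "g1", "g2"),
                      y = c(10, 30, 10), x = c(10, 30, 11))
  em <- assign_spots_to_cells(spots, mask, max_dist_um = 5,
                              pixel_size_nm = 100)
  expect_equal(unclass(em)["3", "g1"], 1L)
  expect_equal(unclass(em)["7", "g1"], 1L)
  expect_equal(unclass(em)["3", "g2"], 1L)
  expect_equal(sum(em), 3)
})

test_that("equidistant spots go to the lower label and far spots unassigned", {
  mask <- matrix(0L, 30, 60)
  mask[10:20, 5:15] <- 2L
  mask[10:20, 45:55] <- 5L
  # nucleus edges sit at x = 14 and x = 44 (0-based): x = 29 is exactly
  # 15 px from each
  mid <- data.frame(gene = "g", y = 15, x = 29)
  em <- assign_spots_to_cells(mid, mask, max_dist_um = 100,
                              pixel_size_nm = 100)
  expect_equal(attr(em, "assignment"), 2L)   # lower label wins the tie
  far <- data.frame(gene = "g", y = 15, x = 29)
  em2 <- assign_spots_to_cells(far, mask, max_dist_um = 1,
                               pixel_size_nm = 100)
  expect_true(is.na(attr(em2, "assignment")))
  expect_equal(attr(em2, "n_unassigned"), 1L)
  # no labels at all: flagged
  em3 <- assign_spots_to_cells(mid, matrix(0L, 30, 60), 5, 100)
  expect_identical(attr(em3, "flag"), "no_labels")
})

test_that("simkit spots map back to their true cells", {
  cfg <- sim_config(n_rounds = 2, n_cells = 12,
                    genes = list(A = c(T = 15), B = c(T = 15)),
                    field_shape = c(9L, 224L, 224L), drift_per_round_px = 0,
                    localization_jitter_px = 0, redetect_prob = 1, seed = 21)
  exp <- generate_experiment(cfg, render_images = FALSE)
  mask <- truth_label_mask(exp$truth$cells, c(224, 224))
  spots <- do.call(rbind, lapply(1:2, function(r) spots_from_truth(exp, r)))
  em <- assign_spots_to_cells(spots, mask, max_dist_um = 15,
                              pixel_size_nm = 100)
  assigned <- attr(em, "assignment")
  sm <- exp$truth$spots_master
  truth_cell <- sm$cell_id[match(
    do.call(paste, c(round(spots[, c("z", "y", "x")], 6))),
    do.call(paste, c(round(sm[, c("z", "y", "x")], 6))))]
  ok <- !is.na(assigned)
  expect_gte(mean(assigned[ok] == truth_cell[ok]), 0.95)
  # matrix conservation: total assigned spots = sum of entries
  expect_equal(sum(em), sum(!is.na(assigned)))
})

test_that("cosine distance has its closed-form values and scale invariance", {
  expect_equal(cosine_distance(c(2, 4, 6), c(1, 2, 3)), 0, tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1, tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 1), c(1, 0)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosine_distance(7.3 * c(1, 1), c(1, 0)),
               cosine_distance(c(1, 1), c(1, 0)), tolerance = 1e-12)
  expect_equal(as.numeric(cosine_distance(c(0, 0), c(1, 0))), 1)
  expect_error(cosine_distance(c(NA, 1), c(1, 0)), "NA")
  expect_error(cosine_distance(c(1, 1), c(0, 0)), "zero-norm")
})

test_that("typing gates are strict: d < 0.8 AND total > 10", {
  cen <- rbind(T1 = c(10, 0), T2 = c(0, 10))
  colnames(cen) <- c("g1", "g2")
  mat <- rbind(a = c(12, 0),    # clear T1
               b = c(7, 4),     # distance to T1 = 1 - 7/sqrt(65) ~ 0.13
               c = c(10, 0))    # total exactly 10: below the count gate
  colnames(mat) <- c("g1", "g2")
  calls <- call_cell_types(mat, cen, d_max = 0.8, min_rna = 10)
  expect_equal(calls$type, c("T1", "T1", "unclassified"))
  expect_equal(calls$reason[3], "count_gate")     # total exactly 10
  # total 11 with small distance: assigned
  mat2 <- rbind(y = c(11, 0)); colnames(mat2) <- c("g1", "g2")
  expect_equal(call_cell_types(mat2, cen)$type, "T1")
  # distance gate: craft distance 0.85 to the nearest centroid
  cen2 <- rbind(T1 = c(1, 0)); colnames(cen2) <- c("g1", "g2")
  # cos(theta) = 0.15 -> x = (0.15, sqrt(1-0.15^2)) scaled to counts
  v <- round(100 * c(0.15, sqrt(1 - 0.15^2)))
  mat3 <- rbind(z = v); colnames(mat3) <- c("g1", "g2")
  res3 <- call_cell_types(mat3, cen2)
  expect_gt(res3$cosine_distance, 0.8)
  expect_equal(res3$type, "unclassified")
  expect_match(res3$reason, "distance_gate")
  # every assignment satisfies both gates (programmatic audit)
  all_calls <- rbind(calls, res3)
  assigned <- all_calls[all_calls$type != "unclassified", ]
  expect_true(all(assigned$cosine_distance < 0.8 & assigned$total_rna > 10))
  expect_error(call_cell_types(mat, cen[0, , drop = FALSE]), "empty")
})

test_that("scaling a cell's counts changes neither winner nor distance", {
  set.seed(22)
  cen <- matrix(runif(15, 0, 10), 3, 5,
                dimnames = list(paste0("T", 1:3), paste0("g", 1:5)))
  mat <- matrix(rpois(25, 8), 5, 5,
                dimnames = list(NULL, paste0("g", 1:5)))
  c1 <- call_cell_types(mat, cen, min_rna = 0)
  c2 <- call_cell_types(mat * 13L, cen, min_rna = 0)
  expect_equal(c1$type, c2$type)
  expect_equal(c1$cosine_distance, c2$cosine_distance, tolerance = 1e-12)
})

test_that("reference centroids are per-type medians (vs sort oracle)", {
  set.seed(23)
  genes <- paste0("g", 1:4)
  profiles <- matrix(rpois(28, 10), 7, 4, dimnames = list(NULL, genes))
  types <- c("A", "A", "A", "B", "B", "B", "B")   # odd and even counts
  cen <- marker_centroids_from_reference(profiles, types)
  for (tt in c("A", "B")) for (g in genes) {
    v <- sort(profiles[types == tt, g])
    n <- length(v)
    med <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(unclass(cen)[tt, g], med)
  }
  # single reference cell per type: centroid equals the cell
  one <- marker_centroids_from_reference(profiles[c(1, 4), ], c("A", "B"))
  expect_equal(unclass(one)["A", ], profiles[1, ])
  # duplicating every reference cell leaves centroids unchanged
  dup <- marker_centroids_from_reference(rbind(profiles, profiles),
                                         c(types, types))
  expect_equal(unclass(dup), unclass(cen))
})

test_that("five marker-gene types are recovered from simkit expression", {
  types <- paste0("T", 1:5)
  genes <- setNames(lapply(1:5, function(g) {
    m <- setNames(rep(1.5, 5), types); m[g] <- 30; m
  }), c("Rtkn2", "Lamp3", "Pecam1", "Ptprb", "Chil3"))
  cen <- t(vapply(types, function(tt)
    vapply(genes, function(g) g[[tt]], numeric(1)), numeric(5)))
  colnames(cen) <- names(genes)
  # pairwise centroid separation as stated for the recovery simulation
  for (i in 1:4) for (j in (i + 1):5)
    expect_gte(cosine_distance(cen[i, ], cen[j, ]), 0.6)
  cfg <- sim_config(n_rounds = 5, n_cells = 40, genes = genes,
                    field_shape = c(9L, 320L, 320L), nucleus_radius_px = 9,
                    drift_per_round_px = 0, localization_jitter_px = 0,
                    redetect_prob = 1, seed = 24)
  exp <- generate_experiment(cfg, render_images = FALSE)
  spots <- do.call(rbind, lapply(1:5, function(r) spots_from_truth(exp, r)))
  mask <- truth_label_mask(exp$truth$cells, c(320, 320))
  em <- assign_spots_to_cells(spots, mask, max_dist_um = 15,
                              pixel_size_nm = 100)
  calls <- call_cell_types(em, cen)
  truth_type <- exp$truth$cells$type[as.integer(calls$cell_id)]
  cls <- calls$type != "unclassified"
  expect_gt(sum(cls), 0.5 * nrow(calls))
  expect_gte(mean(calls$type[cls] == truth_type[cls]), 0.9)
})

test_that("partial gene overlap warns and uses the intersection", {
  cen <- rbind(T1 = c(5, 1)); colnames(cen) <- c("g1", "g2")
  mat <- matrix(c(20, 3), 1, 2, dimnames = list("c1", c("g1", "g3")))
  expect_warning(res <- call_cell_types(mat, cen), "intersection")
  expect_equal(res$type, "T1")
})
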