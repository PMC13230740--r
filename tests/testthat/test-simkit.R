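# Synthetic-data generator: determinism, ground-truth structure, count
# statistics, rendering contracts.

test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_cells = 0), "zero cells")
  expect_error(sim_config(genes = list()), "zero genes")
  expect_error(sim_config(redetect_prob = 1.2), "probabilities")
  expect_error(sim_config(amplified_rounds = 99), "amplified_rounds")
  expect_error(sim_config(intensity_decay_per_round = 0), "decay")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("identical config and seed give bit-identical ground truth", {
  cfg <- small_truth_config(seed = 4)
  a <- generate_experiment(cfg, render_images = FALSE)
  b <- generate_experiment(cfg, render_images = FALSE)
  expect_identical(a$truth, b$truth)
  # and identical rendered images on a small config
  cfg2 <- sim_config(n_rounds = 1, n_cells = 4, field_shape = c(5L, 96L, 96L),
                     genes = list(G = c(A = 5)), seed = 2)
  expect_identical(generate_experiment(cfg2)$images[[1]]$G$data,
                   generate_experiment(cfg2)$images[[1]]$G$data)
})

test_that("degenerate parameters freeze spot coordinates across rounds", {
  cfg <- small_truth_config(seed = 3, jitter = 0, redetect = 1, drift = 0)
  exp <- generate_experiment(cfg, render_images = FALSE)
  sr <- exp$truth$spots_rounds
  for (g in c("XPO1", "KIF1C")) {
    rounds_g <- unique(sr$round[sr$gene == g])
    first <- sr[sr$round == rounds_g[1] & sr$gene == g, ]
    for (r in rounds_g[-1]) {
      cur <- sr[sr$round == r & sr$gene == g, ]
      expect_equal(cur[, c("z", "y", "x")], first[, c("z", "y", "x")],
                   ignore_attr = TRUE)
      expect_true(all(cur$present))
    }
  }
  expect_equal(exp$truth$drift$drift_y, rep(0, 6))
})

test_that("master spot totals follow the Poisson sum (50 cells, mean 20)", {
  totals <- vapply(1:10, function(s) {
    cfg <- sim_config(n_rounds = 1, n_cells = 50, genes = list(G = c(A = 20)),
                      field_shape = c(9L, 256L, 256L), seed = s,
                      nucleus_radius_px = 8)
    nrow(generate_experiment(cfg, render_images = FALSE)$truth$spots_master)
  }, numeric(1))
  expect_true(all(abs(totals - 1000) <= 4 * sqrt(1000)))
})

test_that("per-round present counts are binomial-stable without decay", {
  cfg <- sim_config(n_rounds = 10, n_cells = 20, genes = list(G = c(A = 40)),
                    field_shape = c(9L, 256L, 256L), redetect_prob = 0.9,
                    intensity_decay_per_round = 1, seed = 6)
  exp <- generate_experiment(cfg, render_images = FALSE)
  n_master <- nrow(exp$truth$spots_master)
  sr <- exp$truth$spots_rounds
  counts <- tapply(sr$present, sr$round, sum)
  sd3 <- 3 * sqrt(n_master * 0.9 * 0.1)
  expect_true(all(abs(counts - 0.9 * n_master) <= sd3))
})

test_that("amplified rounds scale mean amplitude by the amplification factor", {
  cfg <- sim_config(n_rounds = 4, n_cells = 20, genes = list(G = c(A = 50)),
                    field_shape = c(9L, 256L, 256L),
                    intensity_decay_per_round = 1,
                    amplification_factor = 6, amplified_rounds = c(2L, 4L),
                    seed = 8)
  exp <- generate_experiment(cfg, render_images = FALSE)
  sr <- exp$truth$spots_rounds[exp$truth$spots_rounds$present, ]
  a <- sr$amplitude[sr$round %in% c(2, 4)]
  s <- sr$amplitude[sr$round %in% c(1, 3)]
  se <- sqrt(var(a) / length(a) + 36 * var(s) / length(s))
  expect_lt(abs(mean(a) - 6 * mean(s)), 3 * se)
})

test_that("stripping residuals re-render previous-round spots at 20% amplitude", {
  cfg <- sim_config(n_rounds = 4, n_cells = 15, genes = list(G = c(A = 30)),
                    field_shape = c(9L, 192L, 192L),
                    stripping_residual_prob = 0.5, redetect_prob = 1,
                    intensity_decay_per_round = 1, seed = 9)
  exp <- generate_experiment(cfg, render_images = FALSE)
  sr <- exp$truth$spots_rounds
  res <- sr[sr$residual, ]
  expect_gt(nrow(res), 0)
  prev <- sr[!sr$residual & sr$present, ]
  m <- merge(res, prev, by.x = c("spot_id", "round"),
             by.y = c("spot_id", "round"), suffixes = c("_res", "_prev"))
  # residual amplitude is 20% of the spot's previous-round amplitude
  first <- merge(res, transform(prev, round = round + 1),
                 by = c("spot_id", "round"), suffixes = c("_res", "_prev"))
  expect_gt(nrow(first), 0)
  expect_equal(first$amplitude_res, 0.2 * first$amplitude_prev)
})

test_that("render_spots places Gaussian peaks and obeys its contracts", {
  fs <- c(7L, 64L, 64L)
  # one spot at an integer voxel, no noise: peak = background + amplitude
  stk <- render_spots(data.frame(z = 3, y = 30, x = 40), 500, c(1.5, 1),
                      fs, background_level = 50, noise_sd = 0)
  expect_equal(stk$data[4, 31, 41], 550, tolerance = 1e-6)
  expect_lt(max(stk$data[4, 31, -41]), 550)
  # empty spot list: constant background
  empty <- render_spots(matrix(0, 0, 3), numeric(0), c(1.5, 1), fs,
                        background_level = 7, noise_sd = 0)
  expect_true(all(empty$data == 7))
  # two spots 10 px apart: two local maxima
  two <- render_spots(data.frame(z = c(3, 3), y = c(20, 30), x = c(20, 20)),
                      300, c(1.5, 1), fs, 0, 0)
  pl <- two$data[4, , ]
  expect_equal(pl[21, 21], max(pl[15:25, 15:25]))
  expect_equal(pl[31, 21], max(pl[27:37, 15:25]))
  # negative amplitude and out-of-field coordinates are errors
  expect_error(render_spots(data.frame(z = 3, y = 5, x = 5), -1,
                            c(1.5, 1), fs), "negative")
  expect_error(render_spots(data.frame(z = 3, y = 999, x = 5), 10,
                            c(1.5, 1), fs), "outside")
})

test_that("render_dapi defocus model is sharpest at the stored focus plane", {
  cells <- data.frame(nucleus_y = 32, nucleus_x = 32, nucleus_radius_px = 10,
                      focus_z = 4)
  set.seed(1)
  stk <- render_dapi(cells, c(9L, 64L, 64L), defocus_rate = 1, noise_sd = 0,
                     background_level = 0, dapi_level = 300)
  # plane-to-plane variance proxies sharpness: maximal at focus_z
  v <- apply(stk$data, 1, function(p) var(as.vector(p)))
  expect_equal(which.max(v) - 1L, 4L)
  # defocus_rate = 0: all planes identical (no noise)
  set.seed(1)
  flat <- render_dapi(cells, c(5L, 64L, 64L), defocus_rate = 0, noise_sd = 0,
                      background_level = 0)
  expect_equal(flat$data[1, , ], flat$data[3, , ], tolerance = 1e-12)
})

test_that("an explicit round plan overrides the alternating default", {
  rp <- data.frame(round = 1:4, gene = c("B", "B", "A", "B"),
                   amplified = c(FALSE, TRUE, FALSE, FALSE))
  cfg <- sim_config(n_rounds = 4, n_cells = 5,
                    genes = list(A = c(T = 10), B = c(T = 10)),
                    field_shape = c(7L, 96L, 96L), round_plan = rp, seed = 1)
  exp <- generate_experiment(cfg, render_images = FALSE)
  expect_equal(exp$round_plan$gene, c("B", "B", "A", "B"))
  sr <- exp$truth$spots_rounds
  expect_setequal(unique(sr$gene[sr$round == 3]), "A")
})

test_that("written experiments round-trip through the canonical layout", {
  cfg <- sim_config(n_rounds = 2, n_cells = 4, genes = list(G = c(A = 5)),
                    field_shape = c(5L, 96L, 96L), seed = 3)
  exp <- generate_experiment(cfg)
  td <- withr::local_tempdir()
  write_experiment(exp, td)
  expect_true(all(c("r01_chG.tif", "r02_chG.tif", "dapi.tif", "cells.csv",
                    "spots_master.csv", "spots_rounds.csv", "drift.csv",
                    "sim_config.yaml") %in% list.files(td)))
  back <- read_stack_tiff(file.path(td, "r01_chG.tif"))
  expect_equal(back$data, exp$images[[1]]$G$data, tolerance = 1e-4)
})
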