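# pipeline: end-to-end orchestration — canonical file layout, the QC run
# (detection -> registration -> summaries -> colocalization) and the typing
# run (expression matrix -> cell types), with all tables persisted as CSV.

#' Analysis configuration
#'
#' @param fov_dir Directory in the canonical layout (`r{RR}_ch{GENE}.tif`,
#'   optional `dapi.tif`).
#' @param out_dir Output directory for report tables.
#' @param pixel_size_nm,z_step_nm Voxel spacing of the TIFFs.
#' @param detection [detection_params()].
#' @param registration_mode `"spots"` or `"image"`.
#' @param reference_round Registration reference round.
#' @param coloc_threshold_um Same-gene colocalization threshold (um);
#'   0.5 um suits standard rounds, 0.2 um amplified/SABER-style rounds.
#' @param cross_gene_threshold_um Cross-gene control threshold (um).
#' @param focus_window_px Window for [mean_ratio_contrast()].
#' @param d_max,min_rna,max_dist_um Typing gates and spot-to-nucleus cap.
#' @param dot_radius_px Binary-map dot radius for spot-mode registration.
#' @param seed Seed recorded in output headers (the QC path itself is
#'   deterministic).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(fov_dir, out_dir = file.path(fov_dir, "analysis"),
                            pixel_size_nm = 100, z_step_nm = 300,
                            detection = detection_params(),
                            registration_mode = c("spots", "image"),
                            reference_round = 1L,
                            coloc_threshold_um = 0.5,
                            cross_gene_threshold_um = 0.2,
                            focus_window_px = 7L,
                            d_max = 0.8, min_rna = 10L, max_dist_um = 5,
                            dot_radius_px = 2, seed = 1L) {
  stopifnot(coloc_threshold_um > 0, cross_gene_threshold_um > 0)
  structure(list(fov_dir = fov_dir, out_dir = out_dir,
                 pixel_size_nm = pixel_size_nm, z_step_nm = z_step_nm,
                 detection = detection,
                 registration_mode = match.arg(registration_mode),
                 reference_round = as.integer(reference_round),
                 coloc_threshold_um = coloc_threshold_um,
                 cross_gene_threshold_um = cross_gene_threshold_um,
                 focus_window_px = as.integer(focus_window_px),
                 d_max = d_max, min_rna = as.integer(min_rna),
                 max_dist_um = max_dist_um, dot_radius_px = dot_radius_px,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Reformat raw acquisitions into the canonical per-FOV layout
#'
#' Renames/copies TIFF stacks into `fov{F}/r{RR}_ch{GENE}.tif` under
#' `out_dir`. Files already canonical are kept as-is (idempotent). Each
#' FOV must cover rounds 1..max contiguously; gaps or name collisions are
#' errors naming the FOV and round.
#'
#' @param raw_dir Directory of raw TIFFs.
#' @param out_dir Output root (may equal `raw_dir` for an in-place check).
#' @param pattern Regex with three capture groups (fov, round, channel)
#'   matched against paths relative to `raw_dir`.
#' @return The manifest data.frame `(fov, round, channel, path)`; also
#'   written to `out_dir/manifest.csv`.
#' @export
reformat_rounds <- function(raw_dir, out_dir = raw_dir,
                            pattern = "^fov(\\d+)[_/]r(\\d+)_ch(.+)\\.tif$") {
  files <- list.files(raw_dir, pattern = "\\.tif$", recursive = TRUE)
  files <- files[!grepl("dapi", files)]
  m <- regmatches(files, regexec(pattern, files))
  ok <- lengths(m) == 4L
  if (!any(ok)) stop("no files matching the acquisition pattern")
  recs <- do.call(rbind, lapply(m[ok], function(g)
    data.frame(fov = as.integer(g[2]), round = as.integer(g[3]),
               channel = g[4], src = g[1], stringsAsFactors = FALSE)))
  key <- paste(recs$fov, recs$round, recs$channel)
  if (anyDuplicated(key))
    stop("collision: duplicate (fov, round, channel): ",
         key[duplicated(key)][1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  recs$path <- NA_character_
  for (f in unique(recs$fov)) {
    rr <- recs[recs$fov == f, ]
    missing <- setdiff(seq_len(max(rr$round)), rr$round)
    if (length(missing))
      stop(sprintf("fov%d: missing round %d", f, missing[1]))
    fov_dir <- file.path(out_dir, sprintf("fov%d", f))
    dir.create(fov_dir, showWarnings = FALSE)
    for (i in which(recs$fov == f)) {
      dst <- file.path(fov_dir, round_tiff_name(recs$round[i],
                                                recs$channel[i]))
      src <- file.path(raw_dir, recs$src[i])
      if (normalizePath(src, mustWork = TRUE) !=
          suppressWarnings(normalizePath(dst, mustWork = FALSE)))
        file.copy(src, dst, overwrite = FALSE)
      recs$path[i] <- dst
    }
  }
  manifest <- recs[order(recs$fov, recs$round, recs$channel),
                   c("fov", "round", "channel", "path")]
  rownames(manifest) <- NULL
  write_table_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

# discover rounds/genes of one canonical FOV directory
fov_inventory <- function(fov_dir) {
  files <- list.files(fov_dir, pattern = "^r\\d{2}_ch.+\\.tif$")
  if (length(files) == 0L) stop("no canonical round TIFFs in ", fov_dir)
  m <- regmatches(files, regexec("^r(\\d{2})_ch(.+)\\.tif$", files))
  data.frame(round = as.integer(vapply(m, `[`, "", 2)),
             gene = vapply(m, `[`, "", 3),
             path = file.path(fov_dir, files), stringsAsFactors = FALSE)
}

#' Round-wise quality-control run
#'
#' The analysis backbone for one field of view: detect spots in every
#' round, estimate per-round drift against the reference round, shift all
#' spot tables into the reference frame, then compute per-round summaries
#' and the same-gene colocalization series (plus the cross-gene control
#' when at least two genes are present). All tables are persisted under
#' `config$out_dir`.
#'
#' @param config An [analysis_config()].
#' @return A `qc_report`: list with `spots` (registered spot table),
#'   `drift`, `summary`, `coloc` (per gene), `cross_gene` (or NULL) and
#'   `flags`.
#' @export
run_qc <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  inv <- fov_inventory(config$fov_dir)
  inv <- inv[order(inv$round), ]
  n_rounds <- max(inv$round)
  flags <- character(0)

  stacks <- setNames(vector("list", n_rounds), seq_len(n_rounds))
  tables <- setNames(vector("list", n_rounds), seq_len(n_rounds))
  for (i in seq_len(nrow(inv))) {
    r <- inv$round[i]
    stk <- read_stack_tiff(inv$path[i], config$pixel_size_nm,
                           config$z_step_nm)
    stacks[[r]] <- stk
    tables[[r]] <- detect_spots(stk, config$detection, round = r,
                                gene = inv$gene[i])
  }

  # Drift is estimated per gene against the gene's own first round (spot
  # maps of different genes share no structure). Each gene's reference
  # round is then linked into the global reference frame by a channel-pair
  # phase-correlation estimate, applied only when its peak ratio clears a
  # confidence floor — otherwise the link stays (0, 0), flagged. Same-gene
  # colocalization is invariant to the link; it only affects the
  # cross-gene control and the shared output frame.
  shape <- dim(stacks[[config$reference_round]]$data)[2:3]
  ref_map <- spots_to_binary_map(tables[[config$reference_round]], shape,
                                 config$dot_radius_px)
  drift_rows <- vector("list", n_rounds)
  registered <- vector("list", n_rounds)
  for (g in unique(inv$gene)) {
    rounds_g <- sort(inv$round[inv$gene == g])
    est <- register_rounds(spot_tables = tables[rounds_g],
                           stacks = stacks[rounds_g],
                           reference_round = 1L,
                           mode = config$registration_mode, shape = shape,
                           dot_radius_px = config$dot_radius_px)
    link <- list(delta_y = 0, delta_x = 0, flag = "")
    if (rounds_g[1] != config$reference_round) {
      g_map <- spots_to_binary_map(tables[[rounds_g[1]]], shape,
                                   config$dot_radius_px)
      pc <- tryCatch(phase_correlation_shift(ref_map, g_map),
                     error = function(e) NULL)
      if (!is.null(pc) && pc$peak_ratio >= 1.5) {
        link <- list(delta_y = pc$delta_y, delta_x = pc$delta_x, flag = "")
      } else {
        link$flag <- "cross_gene_link_low_confidence"
      }
    }
    for (k in seq_along(rounds_g)) {
      r <- rounds_g[k]
      dy <- est$delta_y[k] + link$delta_y
      dx <- est$delta_x[k] + link$delta_x
      drift_rows[[r]] <- data.frame(
        round = r, gene = g, delta_y = dy, delta_x = dx,
        peak_ratio = est$peak_ratio[k], mode = est$mode[k],
        flags = paste_flag(est$flags[k], link$flag),
        stringsAsFactors = FALSE)
      registered[[r]] <- apply_shift(tables[[r]],
                                     list(delta_y = dy, delta_x = dx))
    }
  }
  drift <- do.call(rbind, drift_rows)

  spots_all <- do.call(rbind, registered)
  summary_tab <- round_summary(spots_all)

  coloc <- list()
  for (g in unique(inv$gene)) {
    rounds_g <- sort(inv$round[inv$gene == g])
    if (length(rounds_g) < 2L) {
      flags <- c(flags, sprintf("gene %s: single round, colocalization skipped", g))
      next
    }
    per_round <- setNames(vector("list", n_rounds), seq_len(n_rounds))
    for (r in rounds_g) per_round[[r]] <- registered[[r]]
    cs <- colocalization_series(per_round, reference_round = rounds_g[1],
                                threshold_um = config$coloc_threshold_um,
                                pixel_size_nm = config$pixel_size_nm)
    cs <- cs[cs$round %in% rounds_g, ]
    cs <- cbind(gene = g, cs, reference_round = rounds_g[1],
                threshold_um = config$coloc_threshold_um)
    coloc[[g]] <- cs
  }
  coloc_tab <- if (length(coloc)) do.call(rbind, coloc) else NULL
  if (!is.null(coloc_tab)) rownames(coloc_tab) <- NULL

  cross <- NULL
  genes <- unique(inv$gene)
  if (length(genes) >= 2L) {
    g1 <- genes[1]; g2 <- genes[2]
    r1 <- min(inv$round[inv$gene == g1]); r2 <- min(inv$round[inv$gene == g2])
    mr <- cross_gene_colocalization(registered[[r1]], registered[[r2]],
                                    config$cross_gene_threshold_um,
                                    config$pixel_size_nm)
    cross <- data.frame(gene_a = g1, gene_b = g2, round_a = r1, round_b = r2,
                        n_query = mr$n_query, n_matched = mr$n_matched,
                        percent = mr$percent_colocalized,
                        threshold_um = config$cross_gene_threshold_um,
                        stringsAsFactors = FALSE)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_csv(spots_all, file.path(config$out_dir, "spots.csv"))
  write_table_csv(drift, file.path(config$out_dir, "drift.csv"))
  write_table_csv(summary_tab, file.path(config$out_dir, "summary.csv"))
  if (!is.null(coloc_tab))
    write_table_csv(coloc_tab, file.path(config$out_dir, "coloc.csv"))
  if (!is.null(cross))
    write_table_csv(cross, file.path(config$out_dir, "cross_gene.csv"))

  structure(list(spots = spots_all, drift = drift, summary = summary_tab,
                 coloc = coloc_tab, cross_gene = cross, flags = flags,
                 config = config),
            class = "qc_report")
}

#' Cell-typing run
#'
#' Builds the gene-by-cell expression matrix from registered spots and a
#' nucleus label mask, calls cell types against reference centroids, and
#' writes the matrix, assignments and a spatial map (cell centroids with
#' called types) under `config$out_dir`.
#'
#' @param config An [analysis_config()].
#' @param spots Registered spot table (e.g. `run_qc(config)$spots`).
#' @param label_mask 2D integer nucleus label mask.
#' @param centroids A `centroid_set` (types x genes).
#' @return List with `expression` (matrix), `assignments` (data.frame) and
#'   `spatial_map` (data.frame `cell_id, y, x, type`).
#' @export
run_typing <- function(config, spots, label_mask, centroids) {
  stopifnot(inherits(config, "analysis_config"))
  if (missing(centroids) || is.null(centroids)) stop("missing centroids")
  mat <- assign_spots_to_cells(spots, label_mask,
                               max_dist_um = config$max_dist_um,
                               pixel_size_nm = config$pixel_size_nm,
                               genes = colnames(centroids))
  calls <- call_cell_types(mat, centroids, d_max = config$d_max,
                           min_rna = config$min_rna)
  labels <- as.integer(rownames(mat))
  cy <- vapply(labels, function(l) mean(which(label_mask == l,
                                              arr.ind = TRUE)[, 1]) - 1,
               numeric(1))
  cx <- vapply(labels, function(l) mean(which(label_mask == l,
                                              arr.ind = TRUE)[, 2]) - 1,
               numeric(1))
  spatial <- data.frame(cell_id = as.character(labels), y = cy, x = cx,
                        type = calls$type, stringsAsFactors = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  em <- data.frame(cell_id = rownames(mat), unclass(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table_csv(em, file.path(config$out_dir, "expression_matrix.csv"))
  write_table_csv(calls, file.path(config$out_dir, "type_assignments.csv"))
  write_table_csv(spatial, file.path(config$out_dir, "spatial_map.csv"))
  if (sum(calls$type != "unclassified") == 0L)
    warning("no cell passed the typing gates")
  list(expression = mat, assignments = calls, spatial_map = spatial)
}

#' Read / write 16-bit integer label masks as TIFF
#'
#' @param mask Integer matrix (labels 0..65535).
#' @param path TIFF path.
#' @return `write_label_mask` returns `path` invisibly; `read_label_mask`
#'   an integer matrix.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(max(mask) <= 65535)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
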