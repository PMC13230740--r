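# simkit: synthetic multi-round smFISH datasets with known ground truth.
#
# The generator emulates the statistical structure of a sequential smFISH
# experiment on cultured cells: per-cell Poisson RNA counts, diffraction-
# limited spots rendered as 3D Gaussians on a noisy constant background,
# per-round redetection dropout, lateral stage drift, slight intensity decay
# across wash cycles, optional amplification rounds, and a defocused DAPI
# stack with a known best-focus plane per nucleus.

#' Configuration of a synthetic sequential smFISH experiment
#'
#' Defaults emulate a desk-scale 20-round two-gene experiment in cultured
#' cells: alternating hybridization of two genes, ~95% per-round
#' redetection, small random stage drift, and a slight intensity decay per
#' wash cycle.
#'
#' @param field_shape Integer triple `(nz, ny, nx)`.
#' @param pixel_size_nm,z_step_nm Voxel spacing in nanometres.
#' @param n_rounds Number of hybridization rounds.
#' @param n_cells Number of cells in the field.
#' @param genes Named list: gene name -> named numeric vector of mean RNA
#'   counts per cell type (names are cell-type labels). All genes must use
#'   the same type labels. A bare numeric is taken as a single type "A".
#' @param type_proportions Optional named numeric of cell-type frequencies
#'   (defaults to uniform over the types named in `genes`).
#' @param psf_sigma_px PSF sigma `(lateral, axial)` in pixels/planes.
#' @param spot_amplitude Lognormal amplitude parameters `c(meanlog, sdlog)`.
#' @param background_level,noise_sd Constant background and additive
#'   Gaussian noise SD (camera counts).
#' @param redetect_prob Probability that a master spot is re-detected
#'   (rendered) in a round imaging its gene.
#' @param drift_per_round_px Lateral drift: a single number `s` samples each
#'   round's drift uniformly in `[-s, s]` per axis (round 1 fixed at 0); a
#'   pair `c(dy, dx)` applies that drift to every round after the first; an
#'   `n_rounds x 2` matrix gives absolute per-round drifts.
#' @param drift_integer Round sampled drifts to whole pixels (default TRUE).
#' @param intensity_decay_per_round Multiplicative amplitude decay per
#'   round, in `(0, 1]`.
#' @param amplification_factor Amplitude multiplier for amplified rounds
#'   (>= 1), emulating concatemer-based signal amplification.
#' @param amplified_rounds Integer vector of amplified rounds.
#' @param stripping_residual_prob Probability that a spot present in round
#'   r-1 leaves a 20%-amplitude residual in round r (tests false-positive
#'   behaviour of downstream analysis).
#' @param localization_jitter_px SD of Gaussian jitter added to each
#'   rendered spot coordinate per round.
#' @param defocus_rate DAPI blur sigma per z-plane of defocus (px/plane).
#' @param nucleus_radius_px,dapi_level Nucleus disk radius and mean DAPI
#'   intensity above background.
#' @param round_plan Optional explicit plan: data.frame with columns
#'   `round`, `gene` and optionally `amplified`. Default: genes alternate
#'   in the order listed (`round r` images gene `(r-1) %% n_genes + 1`).
#' @param seed Integer RNG seed; the same config + seed reproduces the
#'   experiment bit-identically.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(field_shape = c(9L, 192L, 192L),
                       pixel_size_nm = 100,
                       z_step_nm = 300,
                       n_rounds = 20L,
                       n_cells = 25L,
                       genes = list(XPO1 = c(A = 20), KIF1C = c(A = 20)),
                       type_proportions = NULL,
                       psf_sigma_px = c(1.5, 1.0),
                       spot_amplitude = c(meanlog = log(200), sdlog = 0.2),
                       background_level = 100,
                       noise_sd = 20,
                       redetect_prob = 0.95,
                       drift_per_round_px = 5,
                       drift_integer = TRUE,
                       intensity_decay_per_round = 0.98,
                       amplification_factor = 1,
                       amplified_rounds = integer(0),
                       stripping_residual_prob = 0,
                       localization_jitter_px = 0.1,
                       defocus_rate = 1.0,
                       nucleus_radius_px = 10,
                       dapi_level = 400,
                       round_plan = NULL,
                       seed = 1L) {
  if (length(field_shape) != 3L || any(field_shape < 1))
    stop("field_shape must be positive (nz, ny, nx)")
  if (n_rounds < 1L) stop("n_rounds must be positive")
  if (n_cells < 1L) stop("configuration error: zero cells")
  if (is.numeric(genes) && !is.list(genes)) genes <- lapply(genes, function(m) c(A = m))
  if (length(genes) == 0L) stop("configuration error: zero genes")
  if (is.null(names(genes)) || any(names(genes) == ""))
    stop("genes must be a named list")
  genes <- lapply(genes, function(m) {
    if (is.null(names(m))) names(m) <- paste0("T", seq_along(m))
    m
  })
  types <- names(genes[[1]])
  for (g in genes) {
    if (!identical(names(g), types)) stop("all genes must share cell-type labels")
    if (any(g < 0)) stop("mean counts must be nonnegative")
  }
  if (is.null(type_proportions))
    type_proportions <- setNames(rep(1 / length(types), length(types)), types)
  if (!identical(sort(names(type_proportions)), sort(types)))
    stop("type_proportions must name the same types as genes")
  probs <- c(redetect_prob, stripping_residual_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (intensity_decay_per_round <= 0 || intensity_decay_per_round > 1)
    stop("intensity_decay_per_round must be in (0, 1]")
  if (amplification_factor < 1) stop("amplification_factor must be >= 1")
  if (length(amplified_rounds) && !all(amplified_rounds %in% seq_len(n_rounds)))
    stop("amplified_rounds must be a subset of 1..n_rounds")
  if (any(psf_sigma_px <= 0)) stop("psf_sigma_px must be positive")
  if (background_level < 0 || noise_sd < 0 || localization_jitter_px < 0 ||
      defocus_rate < 0)
    stop("levels, noise, jitter and defocus_rate must be nonnegative")
  if (!is.null(round_plan)) {
    stopifnot(is.data.frame(round_plan),
              all(c("round", "gene") %in% names(round_plan)))
    if (!all(round_plan$gene %in% names(genes)))
      stop("round_plan references unknown genes")
    if (!all(round_plan$round %in% seq_len(n_rounds)))
      stop("round_plan round out of range")
  }
  structure(list(
    field_shape = as.integer(field_shape), pixel_size_nm = pixel_size_nm,
    z_step_nm = z_step_nm, n_rounds = as.integer(n_rounds),
    n_cells = as.integer(n_cells), genes = genes,
    type_proportions = type_proportions, psf_sigma_px = psf_sigma_px,
    spot_amplitude = spot_amplitude, background_level = background_level,
    noise_sd = noise_sd, redetect_prob = redetect_prob,
    drift_per_round_px = drift_per_round_px, drift_integer = drift_integer,
    intensity_decay_per_round = intensity_decay_per_round,
    amplification_factor = amplification_factor,
    amplified_rounds = as.integer(amplified_rounds),
    stripping_residual_prob = stripping_residual_prob,
    localization_jitter_px = localization_jitter_px,
    defocus_rate = defocus_rate, nucleus_radius_px = nucleus_radius_px,
    dapi_level = dapi_level, round_plan = round_plan, seed = as.integer(seed)
  ), class = "sim_config")
}

# Default round plan: genes alternate in listed order (odd rounds gene 1,
# even rounds gene 2 for the two-gene case).
resolve_round_plan <- function(config) {
  if (!is.null(config$round_plan)) {
    rp <- config$round_plan
    if (is.null(rp$amplified))
      rp$amplified <- rp$round %in% config$amplified_rounds
    return(rp[order(rp$round), c("round", "gene", "amplified")])
  }
  gn <- names(config$genes)
  data.frame(
    round = seq_len(config$n_rounds),
    gene = gn[((seq_len(config$n_rounds) - 1L) %% length(gn)) + 1L],
    amplified = seq_len(config$n_rounds) %in% config$amplified_rounds,
    stringsAsFactors = FALSE
  )
}

# Dart-throwing placement of non-overlapping nucleus disks, with a border
# margin; errors out if the field cannot host n_cells at the separation.
place_nuclei <- function(n_cells, ny, nx, radius, max_tries = 20000L) {
  min_sep <- 2.6 * radius
  margin <- radius + 2
  ys <- xs <- numeric(0)
  tries <- 0L
  while (length(ys) < n_cells && tries < max_tries) {
    tries <- tries + 1L
    y <- runif(1, margin, ny - 1 - margin)
    x <- runif(1, margin, nx - 1 - margin)
    if (length(ys) == 0L || min(sqrt((ys - y)^2 + (xs - x)^2)) >= min_sep) {
      ys <- c(ys, y); xs <- c(xs, x)
    }
  }
  if (length(ys) < n_cells)
    stop("could not place ", n_cells, " non-overlapping nuclei; ",
         "enlarge the field or reduce n_cells/nucleus_radius_px")
  cbind(y = ys, x = xs)
}

# Uniform spot positions within each cell's Voronoi region (nearest nucleus
# center), clipped to a PSF border margin, by batch rejection sampling.
sample_positions_in_cells <- function(counts, centers, nz, ny, nx,
                                      margin_yx, margin_z) {
  need <- counts
  out <- vector("list", length(counts))
  for (i in seq_along(out)) out[[i]] <- matrix(0, 0, 3)
  lo_z <- margin_z; hi_z <- nz - 1 - margin_z
  if (hi_z < lo_z) { lo_z <- 0; hi_z <- nz - 1 }
  guard <- 0L
  while (any(need > 0) && guard < 1000L) {
    guard <- guard + 1L
    n_batch <- max(2000L, 30L * sum(need))
    y <- runif(n_batch, margin_yx, ny - 1 - margin_yx)
    x <- runif(n_batch, margin_yx, nx - 1 - margin_yx)
    d2 <- outer(y^2 + x^2, rep(1, nrow(centers))) -
      2 * cbind(y, x) %*% t(centers) +
      outer(rep(1, n_batch), rowSums(centers^2))
    cell <- max.col(-d2, ties.method = "first")
    for (i in which(need > 0)) {
      idx <- which(cell == i)
      if (length(idx) == 0L) next
      take <- head(idx, need[i])
      z <- runif(length(take), lo_z, hi_z)
      out[[i]] <- rbind(out[[i]], cbind(z, y[take], x[take]))
      need[i] <- need[i] - length(take)
    }
  }
  if (any(need > 0)) stop("failed to sample spot positions in cells")
  out
}

#' Render spots as 3D Gaussians on a noisy background
#'
#' Each spot adds a separable 3D Gaussian of the given amplitude at its
#' subpixel position; an additive Gaussian noise field of SD `noise_sd`
#' sits on top of a constant background. Uses the current RNG state.
#'
#' @param coords Numeric matrix or data.frame with columns `z, y, x`
#'   (0-based, inside the field).
#' @param amplitudes Nonnegative per-spot peak amplitudes.
#' @param psf_sigma_px PSF sigma `(lateral, axial)`.
#' @param field_shape `(nz, ny, nx)`.
#' @param background_level,noise_sd Background level and noise SD.
#' @param pixel_size_nm,z_step_nm Spacing metadata for the output stack.
#' @return An [image_stack()].
#' @export
render_spots <- function(coords, amplitudes, psf_sigma_px, field_shape,
                         background_level = 0, noise_sd = 0,
                         pixel_size_nm = 100, z_step_nm = 300) {
  coords <- as.data.frame(coords)
  if (all(c("z", "y", "x") %in% names(coords))) {
    coords <- as.matrix(coords[, c("z", "y", "x")])
  } else {
    coords <- as.matrix(coords)
    if (ncol(coords) != 3L && nrow(coords) > 0L)
      stop("coords must have columns z, y, x")
    colnames(coords) <- c("z", "y", "x")[seq_len(ncol(coords))]
  }
  nz <- field_shape[1]; ny <- field_shape[2]; nx <- field_shape[3]
  n <- nrow(coords)
  if (length(amplitudes) == 1L) amplitudes <- rep(amplitudes, n)
  if (n > 0 && any(amplitudes < 0)) stop("negative amplitude")
  if (n > 0 && (any(coords[, 1] < 0) || any(coords[, 1] > nz - 1) ||
                any(coords[, 2] < 0) || any(coords[, 2] > ny - 1) ||
                any(coords[, 3] < 0) || any(coords[, 3] > nx - 1)))
    stop("spot coordinates outside the field")
  sl <- psf_sigma_px[1]; sa <- psf_sigma_px[2]
  rl <- ceiling(4 * sl); ra <- ceiling(4 * sa)
  arr <- array(0, dim = c(nz, ny, nx))
  for (i in seq_len(n)) {
    z0 <- coords[i, 1]; y0 <- coords[i, 2]; x0 <- coords[i, 3]
    zi <- max(0, floor(z0) - ra):min(nz - 1, ceiling(z0) + ra)
    yi <- max(0, floor(y0) - rl):min(ny - 1, ceiling(y0) + rl)
    xi <- max(0, floor(x0) - rl):min(nx - 1, ceiling(x0) + rl)
    gz <- exp(-(zi - z0)^2 / (2 * sa^2))
    gy <- exp(-(yi - y0)^2 / (2 * sl^2))
    gx <- exp(-(xi - x0)^2 / (2 * sl^2))
    arr[zi + 1, yi + 1, xi + 1] <- arr[zi + 1, yi + 1, xi + 1] +
      amplitudes[i] * (gz %o% gy %o% gx)
  }
  arr <- arr + background_level
  if (noise_sd > 0) arr <- arr + array(rnorm(nz * ny * nx, 0, noise_sd),
                                       dim = c(nz, ny, nx))
  image_stack(pmax(arr, 0), pixel_size_nm, z_step_nm)
}

#' Render a defocused DAPI stack from nucleus ground truth
#'
#' Nuclei are disks carrying a granular multiplicative texture. Each plane
#' of each nucleus is blurred with `sigma = defocus_rate * |z - focus_z|`,
#' so the plane at the nucleus's own `focus_z` is sharpest.
#'
#' @param cells Data frame with columns `nucleus_y`, `nucleus_x`,
#'   `nucleus_radius_px`, `focus_z` (0-based plane index per nucleus).
#' @param field_shape `(nz, ny, nx)`.
#' @param defocus_rate Blur sigma per plane of defocus (px/plane).
#' @param noise_sd Additive Gaussian noise SD.
#' @param background_level,dapi_level Background and mean nuclear signal.
#' @param pixel_size_nm,z_step_nm Spacing metadata.
#' @return An [image_stack()].
#' @export
render_dapi <- function(cells, field_shape, defocus_rate = 1, noise_sd = 0,
                        background_level = 50, dapi_level = 400,
                        pixel_size_nm = 100, z_step_nm = 300) {
  nz <- field_shape[1]; ny <- field_shape[2]; nx <- field_shape[3]
  if (any(cells$focus_z < 0) || any(cells$focus_z > nz - 1))
    stop("focus_z outside stack")
  arr <- array(background_level, dim = c(nz, ny, nx))
  for (i in seq_len(nrow(cells))) {
    cy <- cells$nucleus_y[i]; cx <- cells$nucleus_x[i]
    r <- cells$nucleus_radius_px[i]
    pad <- ceiling(r + 4 * defocus_rate * max(nz, 1) + 2)
    y0 <- max(0, floor(cy - pad)); y1 <- min(ny - 1, ceiling(cy + pad))
    x0 <- max(0, floor(cx - pad)); x1 <- min(nx - 1, ceiling(cx + pad))
    yy <- y0:y1; xx <- x0:x1
    disk <- outer((yy - cy)^2, (xx - cx)^2, "+") <= r^2
    tex <- matrix(runif(length(yy) * length(xx), 0.3, 1.7),
                  length(yy), length(xx))
    patch0 <- dapi_level * tex * disk
    for (z in 0:(nz - 1)) {
      sig <- defocus_rate * abs(z - cells$focus_z[i])
      patch <- if (sig > 0) gauss_blur2d(patch0, sig) else patch0
      arr[z + 1, yy + 1, xx + 1] <- arr[z + 1, yy + 1, xx + 1] + patch
    }
  }
  if (noise_sd > 0) arr <- arr + array(rnorm(nz * ny * nx, 0, noise_sd),
                                       dim = c(nz, ny, nx))
  image_stack(pmax(arr, 0), pixel_size_nm, z_step_nm)
}

#' Generate a complete synthetic multi-round experiment
#'
#' Draws cells, master spots and per-round presence/drift/jitter, then
#' (optionally) renders one image stack per round for the gene scheduled in
#' that round plus a DAPI stack. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param render_images Render image stacks (set `FALSE` to generate only
#'   ground-truth tables, e.g. for coordinate-level studies).
#' @return An object of class `fish_experiment`: list with `config`,
#'   `round_plan`, `truth` (tables `cells`, `spots_master`, `spots_rounds`,
#'   `drift`), `images` (per-round list named by gene) and `dapi`.
#' @export
generate_experiment <- function(config, render_images = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  nz <- config$field_shape[1]; ny <- config$field_shape[2]
  nx <- config$field_shape[3]
  types <- names(config$type_proportions)
  plan <- resolve_round_plan(config)

  centers <- place_nuclei(config$n_cells, ny, nx, config$nucleus_radius_px)
  cells <- data.frame(
    cell_id = seq_len(config$n_cells),
    type = sample(types, config$n_cells, replace = TRUE,
                  prob = config$type_proportions),
    nucleus_y = centers[, "y"], nucleus_x = centers[, "x"],
    nucleus_radius_px = config$nucleus_radius_px,
    focus_z = sample(0:(nz - 1), config$n_cells, replace = TRUE),
    stringsAsFactors = FALSE
  )

  margin_yx <- ceiling(2 * config$psf_sigma_px[1])
  margin_z <- min(ceiling(2 * config$psf_sigma_px[2]), floor((nz - 1) / 2))
  master <- list()
  for (g in names(config$genes)) {
    mu <- config$genes[[g]][cells$type]
    counts <- rpois(config$n_cells, mu)
    pos <- sample_positions_in_cells(counts, centers, nz, ny, nx,
                                     margin_yx, margin_z)
    for (i in seq_len(config$n_cells)) {
      if (counts[i] == 0) next
      master[[length(master) + 1L]] <- data.frame(
        gene = g, cell_id = i, z = pos[[i]][, 1], y = pos[[i]][, 2],
        x = pos[[i]][, 3], stringsAsFactors = FALSE
      )
    }
  }
  spots_master <- if (length(master)) do.call(rbind, master) else
    data.frame(gene = character(0), cell_id = integer(0),
               z = numeric(0), y = numeric(0), x = numeric(0))
  spots_master <- cbind(spot_id = seq_len(nrow(spots_master)), spots_master)

  # Per-round drift (absolute, vs round 1).
  dp <- config$drift_per_round_px
  if (is.matrix(dp)) {
    stopifnot(nrow(dp) == config$n_rounds, ncol(dp) == 2)
    drift <- dp
  } else if (length(dp) == 2L) {
    drift <- cbind(rep(dp[1], config$n_rounds), rep(dp[2], config$n_rounds))
    drift[1, ] <- 0
  } else {
    drift <- cbind(runif(config$n_rounds, -dp, dp),
                   runif(config$n_rounds, -dp, dp))
    if (config$drift_integer) drift <- round(drift)
    drift[1, ] <- 0
  }
  drift_df <- data.frame(round = seq_len(config$n_rounds),
                         drift_y = drift[, 1], drift_x = drift[, 2])

  jit <- config$localization_jitter_px
  rounds_rows <- list()
  prev_present <- NULL   # rows rendered in the previous round (residuals)
  for (r in seq_len(config$n_rounds)) {
    g <- plan$gene[plan$round == r]
    amp_mult <- config$intensity_decay_per_round^(r - 1) *
      ifelse(plan$amplified[plan$round == r], config$amplification_factor, 1)
    sm <- spots_master[spots_master$gene == g, , drop = FALSE]
    present <- rbinom(nrow(sm), 1, config$redetect_prob) == 1
    zyx <- cbind(sm$z, sm$y + drift[r, 1], sm$x + drift[r, 2])
    if (jit > 0 && nrow(sm) > 0)
      zyx <- zyx + matrix(rnorm(3 * nrow(sm), 0, jit), ncol = 3)
    amp <- rlnorm(nrow(sm), config$spot_amplitude[1],
                  config$spot_amplitude[2]) * amp_mult
    rows <- data.frame(
      round = r, spot_id = sm$spot_id, gene = g, present = present,
      z = ifelse(present, zyx[, 1], NA_real_),
      y = ifelse(present, zyx[, 2], NA_real_),
      x = ifelse(present, zyx[, 3], NA_real_),
      amplitude = ifelse(present, amp, NA_real_),
      residual = FALSE, stringsAsFactors = FALSE
    )
    if (config$stripping_residual_prob > 0 && !is.null(prev_present) &&
        nrow(prev_present) > 0) {
      keep <- rbinom(nrow(prev_present), 1,
                     config$stripping_residual_prob) == 1
      if (any(keep)) {
        res <- prev_present[keep, , drop = FALSE]
        res$round <- r
        res$y <- res$y - drift[r - 1, 1] + drift[r, 1]
        res$x <- res$x - drift[r - 1, 2] + drift[r, 2]
        res$amplitude <- 0.2 * res$amplitude
        res$residual <- TRUE
        rows <- rbind(rows, res)
      }
    }
    prev_present <- rows[rows$present & !rows$residual, , drop = FALSE]
    rounds_rows[[r]] <- rows
  }
  spots_rounds <- do.call(rbind, rounds_rows)
  rownames(spots_rounds) <- NULL

  images <- NULL; dapi <- NULL
  if (render_images) {
    images <- vector("list", config$n_rounds)
    for (r in seq_len(config$n_rounds)) {
      g <- plan$gene[plan$round == r]
      rr <- spots_rounds[spots_rounds$round == r & spots_rounds$present, ,
                         drop = FALSE]
      # clamp residual/jittered coordinates into the field for rendering
      rr$z <- pmin(pmax(rr$z, 0), nz - 1)
      rr$y <- pmin(pmax(rr$y, 0), ny - 1)
      rr$x <- pmin(pmax(rr$x, 0), nx - 1)
      stk <- render_spots(rr[, c("z", "y", "x")], rr$amplitude,
                          config$psf_sigma_px, config$field_shape,
                          config$background_level, config$noise_sd,
                          config$pixel_size_nm, config$z_step_nm)
      images[[r]] <- setNames(list(stk), g)
    }
    dapi <- render_dapi(cells, config$field_shape, config$defocus_rate,
                        config$noise_sd, config$background_level,
                        config$dapi_level, config$pixel_size_nm,
                        config$z_step_nm)
  }

  structure(list(config = config, round_plan = plan,
                 truth = list(cells = cells, spots_master = spots_master,
                              spots_rounds = spots_rounds, drift = drift_df),
                 images = images, dapi = dapi),
            class = "fish_experiment")
}

#' Ground-truth spot table for one round
#'
#' Returns the rendered (drifted + jittered) coordinates of the spots
#' present in a round as a spot table, usable wherever detected spots are
#' (e.g. coordinate-level registration/colocalization studies).
#'
#' @param experiment A `fish_experiment` (or its `truth` list).
#' @param round Round number.
#' @param include_residuals Include stripping-residual spots.
#' @return A spot-table data.frame (see [detect_spots()] for columns).
#' @export
spots_from_truth <- function(experiment, round, include_residuals = FALSE) {
  truth <- if (inherits(experiment, "fish_experiment")) experiment$truth else experiment
  sr <- truth$spots_rounds
  sel <- sr$round == round & sr$present
  if (!include_residuals) sel <- sel & !sr$residual
  sr <- sr[sel, , drop = FALSE]
  data.frame(round = sr$round, gene = sr$gene, z = sr$z, y = sr$y, x = sr$x,
             intensity = sr$amplitude, background_mean = NA_real_,
             background_sd = NA_real_, snr = NA_real_, flags = "",
             stringsAsFactors = FALSE)
}

#' Write a synthetic experiment to disk in the canonical layout
#'
#' Writes per-round TIFF stacks named `r{round:02d}_ch{gene}.tif` plus
#' `dapi.tif` under a FOV directory, ground truth as CSV tables
#' (`spots_master.csv`, `spots_rounds.csv`, `cells.csv`, `drift.csv`) and
#' the configuration as YAML.
#'
#' @param experiment A `fish_experiment` with rendered images.
#' @param dir Output FOV directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "fish_experiment"))
  if (is.null(experiment$images))
    stop("experiment was generated with render_images = FALSE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plan <- experiment$round_plan
  for (r in plan$round) {
    g <- plan$gene[plan$round == r]
    write_stack_tiff(experiment$images[[r]][[g]],
                     file.path(dir, round_tiff_name(r, g)))
  }
  write_stack_tiff(experiment$dapi, file.path(dir, "dapi.tif"))
  tr <- experiment$truth
  write_table_csv(tr$cells, file.path(dir, "cells.csv"))
  write_table_csv(tr$spots_master, file.path(dir, "spots_master.csv"))
  write_table_csv(tr$spots_rounds, file.path(dir, "spots_rounds.csv"))
  write_table_csv(tr$drift, file.path(dir, "drift.csv"))
  cfg <- experiment$config
  cfg$round_plan <- if (!is.null(cfg$round_plan)) as.list(cfg$round_plan)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}
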