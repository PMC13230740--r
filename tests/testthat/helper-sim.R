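# Shared fixtures: small synthetic configurations used across test files.
# Everything is generated in code at test time; no stored binary data.

# A small two-gene alternating experiment (fast to generate, no rendering).
small_truth_config <- function(seed = 1, n_rounds = 6, jitter = 0.1,
                               redetect = 0.95, drift = 5) {
  sim_config(n_rounds = n_rounds, n_cells = 15,
             genes = list(XPO1 = c(A = 30), KIF1C = c(A = 30)),
             field_shape = c(9L, 192L, 192L),
             drift_per_round_px = drift, redetect_prob = redetect,
             localization_jitter_px = jitter, seed = seed)
}

# A sparse rendered field for detection tests: the well-separated
# single-molecule regime (the real experiments are sparser still).
sparse_field_config <- function(seed = 1, n_rounds = 2) {
  sim_config(n_rounds = n_rounds, n_cells = 10,
             genes = list(XPO1 = c(A = 6), KIF1C = c(A = 6)),
             field_shape = c(13L, 192L, 192L), seed = seed)
}

# Fourier translation of a 2D image by a (possibly subpixel) shift; the
# independent reference used to construct registration test inputs.
fourier_shift2d <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  fy <- roundfish:::fft_freq_idx(ny); fx <- roundfish:::fft_freq_idx(nx)
  ph <- exp(-2i * pi * (outer(fy, rep(1, nx)) * dy / ny +
                          outer(rep(1, ny), fx) * dx / nx))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (ny * nx)
}

# Circular integer roll of a matrix (content moves by +dy, +dx).
roll2d <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
}

# Minimal valid fluidic run spec (text), parameterized on rounds.
minimal_spec_text <- function(n_rounds = 3) {
  sprintf("
n_rounds: %d
buffers:
  wash: {kind: syringe, address: 1}
  hyb:  {kind: plate,   address: \"A{round}\"}
steps:
  - {id: hyb,  action: flush, buffer: hyb, volume_ml: 0.5, rate_ml_per_min: 0.5}
  - {id: wash, action: flush, buffer: wash, volume_ml: 1.0, rate_ml_per_min: 1.0}
  - {id: image, action: image}
", n_rounds)
}

# Disk label mask from simkit cells (ground-truth segmentation).
truth_label_mask <- function(cells, shape) {
  ny <- shape[1]; nx <- shape[2]
  mask <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    r <- cc$nucleus_radius_px
    yy <- max(1, floor(cc$nucleus_y - r)):min(ny, ceiling(cc$nucleus_y + r + 2))
    xx <- max(1, floor(cc$nucleus_x - r)):min(nx, ceiling(cc$nucleus_x + r + 2))
    d2 <- outer((yy - 1 - cc$nucleus_y)^2, (xx - 1 - cc$nucleus_x)^2, "+")
    sub <- mask[yy, xx]
    sub[d2 <= r^2 & sub == 0L] <- i
    mask[yy, xx] <- sub
  }
  mask
}
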