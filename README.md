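# roundfish

Sequential single-molecule FISH (smFISH) multiplexes RNA species over
time: each hybridization round reveals one gene as diffraction-limited
spots, images it, and strips the signal before the next round. Running
such experiments unattended requires a fluidic program executor that
exchanges buffers and triggers the microscope, and a round-wise analysis
pipeline that verifies — while the experiment runs — that spots are still
detected, rounds stay registered, the same molecules reappear, and image
quality holds.

`roundfish` implements the computational core of such a platform in R,
end to end, for method developers and platform builders who need every
stage scoreable against ground truth:

* **simkit** — a synthetic multi-round image generator (Gaussian-PSF
  spots, per-round redetection dropout, stage drift, intensity decay,
  amplified rounds, defocused nuclear stacks) with complete ground-truth
  tables.
* **detection** — Laplacian-of-Gaussian spot detection with an automatic
  elbow threshold, subpixel localization, and per-spot
  intensity/background/SNR metrics (`snr = (peak − bg) / sd(bg)` from a
  local annulus).
* **registration** — per-round drift by phase cross-correlation on binary
  spot maps or intensity projections, with upsampled-DFT subpixel
  refinement.
* **colocalization** — optimal one-to-one spot matching across rounds
  (Hungarian algorithm on distance costs saturated at a cap), reported as
  the percentage of a round's spots matched within a threshold (0.5 µm or
  0.2 µm by convention).
* **focus** — Helmli–Scherer mean-ratio contrast `max(I/μ, μ/I)` per
  plane, per-nucleus best-plane selection, and best-focus composites.
* **typing** — gene-by-cell expression matrices (nearest-nucleus spot
  assignment) and cell-type calls by cosine distance to reference
  centroids, gated at distance < 0.8 and > 10 detected RNAs.
* **fluidics** — a fully simulated rig (valve, peristaltic pump, flow
  sensor with anomaly detection, 96-well plate robot) executing
  declarative YAML run specifications in simulated time, with
  file-synchronization and TTL acquisition-trigger handshakes and
  JSON-lines event logs.
* **pipeline** — canonical file layouts, the `run_qc()` / `run_typing()`
  orchestrators, and a command-line interface (`exec/roundfish`).

The methods vignette (`vignettes/roundfish-methods.Rmd`) documents the
models, parameter defaults and numerical choices in detail.

## Worked example

Simulate a 6-round, two-gene experiment (alternating rounds, known drift,
95% per-round redetection), write it in the canonical per-FOV layout, and
run the round-wise QC:

```r
library(roundfish)

cfg <- sim_config(n_rounds = 6, n_cells = 10,
                  genes = list(XPO1 = c(A = 6), KIF1C = c(A = 6)),
                  field_shape = c(13L, 192L, 192L), seed = 11)
exp <- generate_experiment(cfg)
fov <- file.path(tempdir(), "fov1")
write_experiment(exp, fov)

config <- analysis_config(fov_dir = fov,
                          detection = detection_params(min_separation_px = 2))
report <- run_qc(config)

report$summary[, c("gene", "round", "n_spots", "median_intensity", "median_snr")]
#>    gene round n_spots median_intensity median_snr
#> 1 KIF1C     2      58              167       7.90
#> 2 KIF1C     4      59              171       8.41
#> 3 KIF1C     6      61              178       8.78
#> 4  XPO1     1      56              192       8.62
#> 5  XPO1     3      55              166       7.78
#> 6  XPO1     5      57              171       7.72

report$coloc[, c("gene", "round", "n_query", "n_matched", "percent")]
#>    gene round n_query n_matched percent
#> 1  XPO1     1      56        56   100.0
#> 2  XPO1     3      55        51    92.7
#> 3  XPO1     5      57        53    93.0
#> 4 KIF1C     2      58        58   100.0
#> 5 KIF1C     4      59        52    88.1
#> 6 KIF1C     6      61        55    90.2

report$cross_gene[, c("gene_a", "gene_b", "percent", "threshold_um")]
#>   gene_a gene_b percent threshold_um
#> 1   XPO1  KIF1C       0          0.2
```

Reading the output: spot counts per round are stable (~55–61 per gene)
and the median SNR holds near 8 across rounds — detection efficiency is
not degrading. Around 90% of each later round's spots colocalize within
0.5 µm with the gene's first round, consistent with the configured 95%
redetection probability compounded with detection losses, while
cross-gene colocalization is 0% — different genes are not cross-detected.
The estimated drift for the reference gene's rounds matches the injected
truth to subpixel accuracy:

```r
report$drift[report$drift$gene == "XPO1", c("round", "delta_y", "delta_x")]
#>   round delta_y delta_x
#> 1     1       0    0.00
#> 3     3       2    0.95
#> 5     5       1   -4.95
exp$truth$drift[c(1, 3, 5), ]   # injected (negated = expected delta)
#>   round drift_y drift_x
#> 1     1       0       0
#> 3     3      -2      -1
#> 5     5      -1       5
```

(The second gene's deltas are expressed in that gene's own
reference-round frame; see the vignette on cross-gene linking.)

A fluidic run works the same way from a declarative spec:

```r
spec <- parse_run_spec(system.file("extdata", "example_run_spec.yaml",
                                   package = "roundfish"))
rig <- simulated_rig(seed = 9)
log <- run_experiment(rig, spec, ttl_trigger_mock(delay_s = 3))
nrow(log); max(log$t)
#> [1] 42
#> [1] 2349
attr(log, "dispensed_ml")
#>     hyb    wash    dapi imaging
#>     1.5     3.0     0.3     2.4
```

42 events over 2,349 simulated seconds; dispensed volumes are the exact
per-buffer sums of `rate × pump interval` — the simulated clock advances
by step durations, nothing sleeps.

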