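---
title: "Round-wise analysis of sequential smFISH: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Round-wise analysis of sequential smFISH: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roundfish)
```

Sequential single-molecule FISH (smFISH) multiplexes genes over time:
each hybridization round reveals one RNA species as diffraction-limited
fluorescent spots, images it, and strips the signal before the next round.
An automated platform doing this unattended needs two things working in
lock-step: a fluidic program executor that exchanges buffers and triggers
the microscope, and a round-wise analysis pipeline that verifies — while
the experiment runs — that spots are still being detected, that rounds
stay registered, that the same molecules reappear, and that image quality
holds. `roundfish` implements both halves against a synthetic data
generator with complete ground truth, so every stage can be scored
quantitatively.

This vignette explains the models behind each module, the tunable
parameters (with units and defaults), the numerical choices, and what the
synthetic tests do and do not establish about real data.

## The synthetic experiment (`sim_config`, `generate_experiment`)

The generator emulates the statistical structure of a multi-round
experiment on cultured cells:

* **Cells.** `n_cells` nuclei are placed by dart-throwing with a
  minimum-separation rejection rule (2.6 nucleus radii) inside a border
  margin; cell territories are the Voronoi regions of the nucleus centers.
  Nuclei are disks of radius `nucleus_radius_px` (default 10 px at
  100 nm/px, i.e. a 2 µm nuclear radius at desk scale).
* **Spots.** Per cell and gene, RNA counts are Poisson with a per-cell-type
  mean (`genes`); positions are uniform within the cell territory,
  excluding a 2σ PSF margin at the field border so no rendered spot is
  edge-truncated. Spots are rendered as separable 3D Gaussians
  (`psf_sigma_px`, default 1.5 px lateral / 1.0 plane axial) with
  lognormal peak amplitudes (`spot_amplitude`, default meanlog `log(200)`,
  sdlog 0.2) on a constant background (default 100 counts) with additive
  Gaussian read noise (`noise_sd`, default 20). The default
  amplitude/noise ratio of 10 is the "configured SNR" referred to
  throughout the tests.
* **Rounds.** A round plan maps each round to a gene; by default genes
  alternate in the order listed (two genes → odd/even rounds), and an
  explicit `round_plan` table overrides this, including per-round
  amplification flags for concatemer-amplified (SABER-style) rounds, which
  multiply amplitudes by `amplification_factor`. Per round, each master
  spot of the scheduled gene is re-detected with probability
  `redetect_prob` (default 0.95), displaced by the round's global drift,
  jittered by `localization_jitter_px` (default 0.1 px, the localization
  reproducibility of a well-behaved fitter), and its amplitude decays by
  `intensity_decay_per_round` (default 0.98 — the magnitude of the decay
  over wash cycles is a free parameter of the generator, not a published
  value). With `stripping_residual_prob > 0` a previous-round spot can
  re-appear at 20% amplitude, emulating incomplete stripping so that
  false-positive behaviour downstream can be probed.
* **Drift.** A scalar `drift_per_round_px = s` samples each round's
  absolute lateral drift uniformly in `[-s, s]` per axis (round 1 pinned
  at zero), rounded to whole pixels by default; a pair applies a fixed
  drift, and a full matrix specifies arbitrary per-round trajectories
  (e.g. a random walk). Per-round absolute drift was chosen over a random
  walk as the default because it bounds the total excursion at any round
  count, which is what a stage with closed-loop XY control produces.
* **DAPI.** The nuclear channel is rendered once: disks carrying a
  granular multiplicative texture (uniform 0.3–1.7), blurred per plane
  with `sigma = defocus_rate × |z − focus_z|` where each nucleus has its
  own, known best-focus plane. `defocus_rate` (default 1 px/plane) is the
  blur growth per plane of defocus.

Everything derives from a single seed: the same `sim_config` reproduces
images and ground-truth tables bit-identically. The ground truth —
`cells`, `spots_master`, `spots_rounds` (with rendered coordinates and
presence flags), `drift` — is the scoring reference for every downstream
module.

What the generator deliberately does **not** model: optical aberrations
and chromatic shift, tissue autofluorescence structure, Poisson shot
noise (additive Gaussian noise is sufficient for SNR-controlled tests and
keeps detection thresholds analytically predictable; a shot-noise switch
would be the natural extension point), 3D nucleus shapes, and cell
crowding/overlap. Passing tests therefore demonstrate algorithmic
correctness under controlled statistics — not robustness to every
pathology of real tissue.

## Spot detection (`detect_spots`)

Detection is the classic matched-filter path for diffraction-limited
spots: a Laplacian-of-Gaussian (LoG) filter tuned to the PSF, local-maxima
selection, and per-spot quality metrics.

* **LoG filter.** The stack is smoothed with an anisotropic separable
  Gaussian (lateral σ in y/x, axial σ in z) and a negated 6-neighbour
  discrete Laplacian scaled by σ² is applied, so spots become positive
  peaks. Convolution kernels are truncated at 4σ and renormalized at the
  borders; a constant image maps exactly to a zero response, and the
  filter is linear — both are asserted in tests.
* **Local maxima.** 26-connected maxima with `-Inf` beyond the borders;
  plateau ties break toward the lexicographically earlier voxel so
  detection is deterministic.
* **Automatic threshold.** The candidate count as a function of threshold
  falls steeply through the noise maxima and plateaus at the true-spot
  count. The threshold is the point of that curve farthest below the
  chord between its endpoints, computed on a 100-point log-spaced grid
  with the threshold axis normalized to its range and the count axis
  normalized on a log scale (raw counts would let the noise population
  dwarf the plateau), then advanced to the low edge of the plateau (steps
  continue while a grid step still sheds ≥1% of candidates, within 2.5×
  the elbow). The whole rule is homogeneous: scaling the image scales the
  threshold exactly. Degenerate curves — fewer than two candidates, a
  flat curve, or no plateau (pure noise, recognized by the count
  collapsing between the elbow and twice the elbow) — fall back to the
  99.99th percentile of the candidate maxima, flagged; on pure Gaussian
  noise this admits on the order of one false call per megavoxel.
* **Subpixel refinement.** A 3-point parabolic fit per axis on the LoG
  response, clamped to ±0.5 px. Noise-free localization error is ~0.01 px;
  at configured SNR 10 the RMSE is ~0.15 px. Full 3D Gaussian fitting
  would be the higher-accuracy extension; it is not needed for the
  round-wise QC this package targets.
* **Metrics.** The evidence for round-wise QC is per-spot: local
  background mean and SD from an annulus (inner/outer radii default
  3σ–5σ, with signal inside 2σ excluded by construction) in the spot's
  central z-plane, `intensity = raw peak − background mean`, and
  `snr = intensity / background SD`. The annulus geometry is an explicit,
  configurable definition (reported in the output), since background
  estimation conventions differ between tools; measuring on the central
  plane avoids axial annulus truncation in thin stacks. A flat background
  (SD 0) yields an `Inf` SNR plus a `snr_infinite` flag rather than a
  number, and spots whose annulus leaves the image are flagged
  `annulus_clipped`.

`round_summary()` aggregates per (gene, round): spot count, median and
interquartile range of intensity, background and SNR — the trend curves
an operator watches across a 20-round run to decide whether detection
efficiency is drifting.

## Drift registration (`register_rounds`)

Mechanical stage drift between rounds is modeled as a global 2D
translation. Both registration paths — binary spot maps (spots rasterized
as disks at their rounded positions, z collapsed) and maximum-intensity
projections — feed the same phase cross-correlation estimator: the
normalized cross-power spectrum's inverse transform peaks at the
translation; an upsampled matrix-multiply DFT evaluated in a 1.5 px
neighbourhood of the peak refines it to subpixel precision
(`upsample = 20` by default, i.e. a 0.05 px grid; the factor is a package
default and is reported in the output metadata). Integer circular shifts
are recovered exactly up to
a quarter of the field; subpixel shifts to within 0.1 px (verified
against a brute-force shifted-difference-energy oracle). The sign
convention is fixed throughout: the returned `(delta_y, delta_x)` is
**added** to the moving round's spot coordinates to land them in the
reference frame, and deltas are stored to 3 decimals.

The estimator also returns `peak_ratio`, the correlation peak over the
strongest secondary peak outside a 5×5 exclusion zone — a confidence
score. It is noisy per image pair; its median over replicates decreases
monotonically as rotation (which violates the translation-only model) is
injected. Translation-only is a deliberate limitation: rotation, scale
and non-rigid deformation are out of scope, as is axial drift (assumed
handled by hardware autofocus).

Rounds imaging different genes share no spot structure, so `run_qc()`
registers each gene's rounds against the gene's own first round. The
gene-reference rounds are then linked into the global frame by a
channel-pair phase-correlation estimate, applied only when its peak ratio
clears a confidence floor (1.5) — otherwise the link stays `(0, 0)` and
is flagged. Same-gene colocalization is mathematically invariant to this
link (a common offset cancels in pair distances); only the cross-gene
control and the shared output frame depend on it. On synthetic data,
where different genes' spot maps are independent point sets, the link is
typically unidentifiable and correctly falls back, mirroring the fact
that on real data this step needs either shared image structure or a
manual alignment.

## Cross-round colocalization (`match_spots`)

Whether the *same molecules* reappear across rounds is the platform's
central fidelity statistic. Registered spot tables from two rounds are
matched by an optimal one-to-one assignment (Hungarian algorithm, via
`clue::solve_LSAP`) on the (y, x) Euclidean cost matrix; z is ignored
because drift correction is lateral. Costs are **saturated** at
`cost_cap_factor × threshold` (default 4×): every pair beyond the cap is
equally expensive, so a spot without a near partner "spends" the cap
instead of displacing genuine sub-threshold pairs along augmenting
chains. This bounded-loss formulation matters: with unbounded distances
(or a huge "forbidden" cost) the solver sacrifices true sub-pixel pairs
to shorten far ones, and measured colocalization drops by several points
at realistic densities. On fields where every spot is either near a
unique partner or far from all of them, the result is provably
cap-invariant (tested). The distance threshold (strict `<`) is applied
*after* assignment; matched pairs at or beyond it are discarded.

The colocalization percentage uses the query round's spot count as the
denominator by default ("percentage of total spots identified in that
round"); the reference-round denominator is available as an option.
Default thresholds are 0.5 µm for standard rounds and 0.2 µm for
amplified experiments — both plain configuration values, converted
through `pixel_size_nm`. `colocalization_series()` reports every round of
one gene against the gene's first round (the reference reports 100 by
definition); `cross_gene_colocalization()` runs the same machinery across
genes as a specificity control, whose expectation for independent point
processes is `100·(1 − exp(−λπt²))` at density λ and threshold t — the
package's tests verify this calibration.

With 95% per-round redetection, 0.1 px jitter and up to 5 px/round drift,
the per-round percentage sits in the 99% CI of 95% for every round — the
CI carries two binomial terms (`2.576·sqrt(2·0.95·0.05/n)`) because each
round's percentage is computed against the same reference-round presence
realization. With perfect redetection and zero jitter every round reports
exactly 100%.

## Focus scoring (`nucleus_focus_curves`)

Image sharpness of the nuclear stain is scored with the Helmli–Scherer
mean-ratio contrast: per pixel, with μ the local mean over a `window_px`
square (default 7 px, edge-truncated; the window size is a package
default, configurable and reported), the measure is
`R = max(I/μ, μ/I)`, with `R = 1` where both are zero and a documented
cap of 1e6 where one of them alone is zero. The measure is ≥ 1
everywhere, exactly 1 on constants, invariant to multiplying the image by
a positive constant (so illumination scaling cannot masquerade as
sharpness), and strictly decreasing under Gaussian blur of textured
content — all asserted as exact or monotonicity tests.

Per nucleus (from a label mask — external masks are accepted everywhere;
`segment_nuclei_fallback()` provides an Otsu + hole-fill + connected
components + size-filter baseline for tests and demos), the contrast map
is averaged over the nucleus **bounding box** per z-plane; the best plane
is the argmax of this focus curve (ties to the lowest z). A
mask-restricted scoring variant is available (`use_mask = TRUE`). The
best-focus composite takes each nucleus's pixels from its own best plane
and fills the background from the plane at the **median of the
per-nucleus best-z values** (rounded to nearest, ties to the lower plane)
— of the possible readings of a "median z-index" fill, the median over
nuclei is the one that keeps the background near the tissue's dominant
focal plane. `condition_summary()` reduces each condition to boxplot
statistics of the per-nucleus best focus measure, the comparison used to
rank sample-preparation protocols.

On synthetic stacks with `defocus_rate = 1` px/plane and moderate noise,
best-plane recovery is ≥ 95% over 200 nuclei (in practice 100%).

## Cell typing (`call_cell_types`)

The gene-by-cell expression matrix is built by nearest-nucleus
assignment: each spot goes to the label whose nucleus interior or
boundary is nearest in (y, x) — per-label Euclidean distance transforms,
ties to the lower label — provided the distance is at most `max_dist_um`
(default 5 µm). This is a deliberately simple, documented baseline for
cell attribution without a membrane marker; point-cloud segmentation
methods that infer cell boundaries from the RNA distribution itself are a
separate problem and out of scope here.

Cell types are called against reference centroids (per-type median
expression vectors, e.g. from scRNA-seq reduced to the panel genes):
nearest centroid by cosine distance, assigned iff the distance is
strictly below `d_max = 0.8` **and** the cell's total RNA count strictly
exceeds `min_rna = 10` (so ≥ 11 detected RNAs; both strict readings are
implemented as stated, with the `<` vs `≤` boundary noted as convention).
Cosine distance is scale-invariant, so sampling depth does not change a
cell's nearest type. Unclassifiable cells are retained with reason codes
(`distance_gate`, `count_gate`) for audit. On a 5-type simulation with
marker-gene centroids separated by cosine distance ≥ 0.6 and ~30
RNAs/cell, recovery among classified cells exceeds 90% (in practice
100%).

## The simulated fluidics rig (`run_experiment`)

A run specification is a YAML document (schema version 1; an example
ships under `inst/extdata/example_run_spec.yaml`): `n_rounds`, a `buffers`
map (each `kind: syringe` with a valve-port address or `kind: plate` with
a well address, where `{round}` templates resolve per round — single-use
hybridization buffers live in per-round wells, washing buffers in
syringes), and an ordered `steps` list. Steps are `flush` (buffer +
volume or duration + rate), `incubate`, `pause`, or `image`, each with an
optional `rounds` condition (`all` or an explicit list) — this is how a
DAPI stain runs only in round 1 or an extra amplification-hybridization
step runs only in selected rounds. Validation is eager and errors name
the offending step.

The rig is simulated at the level of observable behaviour: a selector
valve, a peristaltic pump whose flow sensor samples at a fixed period
(default 1 s) with relative noise (default 2%), syringe reservoirs, a
96-well plate (2.0 mL capacity per well, enforced: over-aspirating emits
an `error` event and halts the run cleanly), and a monotone simulated
clock — time advances by step durations only, nothing sleeps, and a
20-round program executes in milliseconds. Every action is an event
(`valve_select`, `aspirate`, `pump_start/stop`, `incubate`,
`trigger_armed`, `acquisition_done`, `anomaly`, `error`) with a simulated
timestamp; logs serialize deterministically as JSON lines, and identical
seeds give byte-identical files. Volume bookkeeping is exact to 1e−9 mL
and the clock to floating-point precision of the step-duration sum.

Acquisition handshakes follow two trigger protocols: a shared
synchronization file (content mode: arm writes "1", the microscope
writes "0" when done; existence mode: arm creates the file, deletion
signals completion) and a TTL line-level mock (out-pulse arms, in-pulse
completes, strictly alternating). Mock acquirers with configurable
delays play the microscope in tests; a missing response times out and
aborts with the log intact. Bubble traps and vacuum pumps are modeled
only through their failure effect: scheduled flow anomalies multiply the
measured flow, and `detect_flow_anomaly()` flags maximal intervals whose
relative deviation exceeds a tolerance (default 20%) for at least a
minimum duration (default 5 s), with pump-off samples excluded — at 2%
sensor noise this produces zero false alarms over hundreds of clean
traces while catching a 10 s bubble to within one sample.

## Orchestration and formats (`run_qc`, `run_typing`, CLI)

`reformat_rounds()` normalizes raw acquisitions into the canonical layout
`fov{F}/r{RR}_ch{GENE}.tif` (idempotent, with a manifest and hard errors
on gaps or collisions). `run_qc()` chains detection → per-gene
registration → round summaries → colocalization series (+ cross-gene
control when two genes are present) and persists every table as RFC-4180
CSV with '.' decimals; it is a pure function of its inputs and
configuration — reruns are byte-identical. `run_typing()` adds the
expression matrix, type assignments and a spatial cell map. Image stacks
travel as multi-page 32-bit-float TIFF (intensities scaled by 1/65536 to
fit the TIFF writer's unit range; 16-bit camera counts round-trip
losslessly), label masks as 16-bit TIFF, logs as JSON lines. The
`exec/roundfish` script exposes `simulate`, `reformat`, `qc`, `focus`,
`type` and `run-experiment` as a thin command-line layer over these
functions, with exit codes 0/1/2 for ok / user error / data error.

## Problem sizes and what the tests establish

The test and acceptance simulations run at desk scale, chosen to finish a
full suite in minutes while keeping every statistical check
well-powered: calibration experiments use 20 rounds with 1,000 spots per
gene on 320×320 px fields (truth-level, no rendering); rendered detection
fields are 192×192 px × 13 planes with ~60–90 spots per round — roughly
4× the spot density of a typical real field of view, i.e. conservative
for merge-related recall losses; focus scoring uses 200 nuclei across
four fields; typing uses 40 cells across 5 types. Two spots closer than
about 2σ laterally merge into a single LoG maximum — a physical
resolution limit, not an implementation artifact — which is why recall
criteria are stated for the well-separated single-molecule regime that
real smFISH (one gene per round, no spatial crowding) is designed to
operate in.

## Known limitations

Translation-only registration; 2D matching (z ignored); no dense-spot
deconvolution or transcription-site decomposition; nearest-nucleus cell
attribution rather than boundary inference; additive-Gaussian noise
model; no real hardware drivers (the rig interfaces are simulation-only
by design, though the event/trigger contracts are written so a serial
backend could be slotted in); FOVs are processed independently (no
mosaic stitching).
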