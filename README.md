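# holoflow

In-flow holographic detection and enumeration of circulating tumor cells
(CTCs).

CTCs are tumor-derived cells in peripheral blood — roughly 1–10 per
millilitre even in late-stage disease, against ~10⁶ white and ~10⁹ red blood
cells per millilitre. `holoflow` implements the computational pipeline of a
dual-modality detection platform for researchers developing label-free
liquid-biopsy instrumentation: in-line (Gabor) digital holographic
microscopy frames recorded at 450 fps are scored by a compact
keypoint-heatmap neural network, while two photomultiplier (PMT) channels
record immunofluorescence (IF) pulses from PSMA and EpCAM staining; the two
streams are fused on a shared clock and a cell is enumerated as a CTC only
if its holographic confidence reaches the operating threshold θ = 0.5 **and**
it is PSMA-positive (EpCAM is phenotyping-only — it is often downregulated
during epithelial–mesenchymal transition and would gate out real CTCs).

The package provides, as separately usable modules:

* **holosim** — a seeded physics simulator of the instrument: cells as
  cosine-tapered phase objects, band-limited angular-spectrum propagation,
  Poisson/read-noise camera model, drifting background, Poisson arrivals,
  and PMT pulses whose FWHM equals the field-of-view transit time.
  (`optical_config`, `cell_model`, `sim_config`, `simulate_run`)
* **preprocess** — causal exponential-moving-average background
  subtraction, fixed-mean/σ normalization, and an offset-invariant focus
  score. (`preprocess_stack`, `focus_metric`)
* **keypoint model** — a small three-branch high-resolution conv-net
  (hand-rolled forward/backward over Rcpp kernels) trained with the
  asymmetric pixel-wise loss
  `L = −A·[y·log p + (1−y)·log(1−p)]`, A = 0.1 for false positives on
  positive (cell-line) samples and A = 1 otherwise; Adam at lr 0.01 with
  0.85 decay per epoch; session-level hard-sample mining; pseudo-labeling
  restricted to buffer sessions; leakage-free 80:20 session splits.
  (`build_model`, `train_detector`, `asymmetric_bce`, `render_targets`,
  `mine_hard_sessions`, `split_by_session`, `pseudo_label`)
* **detect** — heatmap peak extraction with non-maximum suppression, track
  linking across the repeated captures of each flowing cell, matching to
  reference keypoints, recovery curves. (`detect_frames`, `link_tracks`,
  `match_to_reference`, `recovery_curve`)
* **if_signal** — rolling-median/MAD baseline, transit-width-gated pulse
  detection, exact cross-channel matching. (`trace_peaks`,
  `detect_pmt_peaks`, `match_channels`)
* **fuse/enumerate** — DHM×IF fusion, CTC gating, per-mL enumeration,
  PPV/FPR/depletion/enrichment arithmetic, cohort summaries.
  (`align_events`, `classify_ctc`, `enumerate_per_ml`, `ppv`,
  `depletion_stats`, `cohort_summary`)

A thin CLI (`inst/cli/holoflow`) wraps simulation, detection, IF peak
extraction and enumeration; frames travel as 16-bit multi-page TIFF, traces
and events as CSV, manifests and reports as JSON with content hashes.

## Worked example

```r
library(holoflow)

# a short "spiked" acquisition on a reduced 256 x 128 px field of view
oc <- optical_config(roi = c(256L, 128L))
sc <- sim_config(optical = oc, flow_speed_um_s = 8000,
                 cell_rate_per_s = c(ctc_like = 6, blood_like = 10),
                 duration_s = 1, volume_ml_equiv = 0.6, seed = 42)
run <- simulate_run(sc, cohort = "patient")
table(run$truth$class_label)
#> blood_like   ctc_like
#>          7          6

# train a small detector on simulated sessions (abridged: 480 frames)
sessions <- simulate_session_set(n_pos = 4, n_neg = 4,
                                 frames_per_session = 60, seed = 7)
fit <- train_detector(sessions,
                      train_config(epochs = 5, batch_size = 8,
                                   steps_per_epoch = 60, seed = 5))
round(fit$metrics[, c("epoch", "lr", "pos_loss", "neg_loss")], 5)
#>   epoch      lr pos_loss neg_loss
#> 1     0 0.01000  0.01251  0.00356
#> 2     1 0.00850  0.00510  0.00026
#> 3     2 0.00722  0.00514  0.00006
#> 4     3 0.00614  0.00428  0.00001
#> 5     4 0.00522  0.00387  0.00001

# full pipeline: preprocess, detect, PMT pulses, fuse, gate, enumerate
cfg <- pipeline_config(preprocess = list(norm_sd = sqrt(2000)),
                       output_dir = tempfile())
run_pipeline(run$frames, run$traces, run$manifest, cfg, fit$model,
             flow_speed_um_s = 8000)
#> enumeration_report sample-001: 4 CTC in 0.6 mL -> 6.67 CTC/mL (theta = 0.5)
#>   EpCAM+ fraction among PSMA+ CTCs: 0.75
```

The learning rate follows the 0.01·0.85ᵉ schedule; both stream losses fall
as the detector learns to fire on CTC-like fringe patterns and stay silent
on blood-like ones. The enumeration report counts each flowing cell once
(tracks, not per-frame detections), keeps only tracks with confidence ≥ 0.5
that fused with a PSMA-positive IF event, and normalizes by the declared
whole-blood volume. Of the six planted CTC-like cells, four pass the joint
gate in this short run — the rest fall to the confidence threshold or PSMA
expression sampling, which is exactly the TPR-vs-θ trade-off the recovery
curve quantifies.

Diagnostic arithmetic at the validation operating point (recovery 0.60,
assumed abundance 10 cells/mL, 5 false events across 55 mL):

```r
ppv(tpr = 0.60, abundance_per_ml = 10, fpr_per_ml = 5 / 55)
#> [1] 0.9850746
```

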