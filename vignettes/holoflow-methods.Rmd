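---
title: "Methods: in-flow holographic CTC detection with holoflow"
author: "holoflow authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-flow holographic CTC detection with holoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Circulating tumor cells (CTCs) occur at roughly one to ten cells per
millilitre of blood against a background of about 10^6 white and 10^9 red
blood cells per millilitre. `holoflow` models the computational half of an
in-flow detection platform: after inertial microfluidic enrichment, cells
stream through a channel where an in-line (Gabor) digital holographic
microscope records defocused interference patterns at 450 frames per second,
while two photomultiplier tubes (PMTs) record immunofluorescence (IF) from
PSMA and EpCAM conjugates excited co-linearly. A compact keypoint-heatmap
network scores every cell morphologically; IF pulses gate the final call. A
cell is enumerated as a CTC only if its holographic confidence reaches the
model threshold (0.5) *and* it is PSMA-positive. EpCAM is recorded but never
gates, because EpCAM is frequently downregulated during
epithelial-to-mesenchymal transition and gating on it would discard a
clinically important CTC subset.

The package contains a physics-based simulator of the instrument (no
external dataset exists for this geometry), the full training and inference
stack for the detector, the PMT signal chain, and the fusion/enumeration
arithmetic, each exposed as composable functions plus a thin `holoflow`
command-line wrapper (`inst/cli/holoflow`).

## Hologram simulation

Cells are modelled as pure phase objects: a cosine-tapered phase bump of
radius $R$ and peak phase $\varphi_{\max} = 2\pi\,t/\lambda$, where $t$ is
the peak optical thickness (refractive-index excess times physical
thickness) and $\lambda = 405$ nm. The taper avoids the edge ringing a hard
disc would produce under coherent propagation. Two stock populations differ
only in radius and optical thickness: blood-like cells (3.5 µm radius, 60 nm
peak thickness) emulate the residual nucleated background after enrichment,
CTC-like cells (9 µm, 150 nm) are larger and optically denser. These values
are package choices in the physiological range for leukocytes and epithelial
tumor cells, not instrument measurements.

The transmission field is propagated to the sensor by band-limited
angular-spectrum propagation with evanescent components suppressed; when the
requested distance exceeds the aliasing-free limit of the sampled grid, the
transfer function is band-limited further (with a warning from the public
API; the simulator muffles it because the limit is intended behaviour
there). Cells sit 30 µm from the focal plane by default — the channel depth
is not a published quantity, so the defocus is a configurable placeholder
chosen to produce a few clearly resolved fringes at the 0.345 µm
object-space pixel (3.45 µm sensor pitch through a 10×/0.30 NA objective).
Intensity frames apply the per-pixel photon budget (default 2000 photons),
Poisson shot noise, Gaussian read noise (sd 5 counts), and a smooth
background pattern drifting on a 5 s timescale.

Arrivals are independent Poisson processes per population; cells transit the
long (1440 px, 496.8 µm) ROI axis at the flow speed, and the configuration
refuses flows whose transit is shorter than two frame periods so every cell
is captured at least twice. Every expressed marker adds a Gaussian pulse to
its PMT channel with FWHM equal to the field-of-view transit time, centred
at mid-transit; frames and traces share one clock. All randomness flows
through one master seed with fixed per-component sub-streams (arrivals,
expression, camera noise, PMT noise), so any component can be reproduced in
isolation and identical configurations give bit-identical outputs.

What the simulator deliberately omits: Mie scattering, red-cell
biconcavity and polydispersity, hydrodynamic focusing imperfections, camera
MTF, spectral cross-talk, photobleaching. Passing tests on synthetic data
therefore demonstrate that the algorithms are correct and well-calibrated
under the stated noise model — not that the detector would transfer to
instrument data unchanged.

## Preprocessing

Raw frames are referenced against an exponential moving average of the
preceding frames of the same session (`bg <- (1-α)·bg + α·frame`,
α = 0.02 by default: slow enough that a transiting cell, present for a
handful of frames, barely biases the estimate — no cell masking is
performed). The update is strictly causal; the first 10 frames only seed the
background. Frames are then scaled by one fixed mean and standard deviation
rather than per-frame statistics, so inter-frame contrast differences — which
carry signal — survive normalization. In the simulation-driven tests the
fixed scale is the shot-noise standard deviation `sqrt(photon_budget)`,
which puts blank frames at approximately unit variance.

The focus score is the ratio of gradient energy to centred signal energy,
$\sum |\nabla f|^2 / \sum (f - \bar f)^2$. In the frequency domain this is
the signal-power-weighted mean squared spatial frequency, so it is invariant
to additive offsets and affine gain, zero for constant frames, and provably
strictly decreasing under Gaussian blur — the property the test suite checks
across five blur levels. (A variance-of-gradient metric normalized by mean
intensity is not offset-invariant once the background has been subtracted
and the mean sits near zero, which is why this form was chosen.)

## The detector

The detector is a deliberately small three-branch high-resolution network: a
stride-2 stem keeps a half-resolution feature stream alive end to end, while
1/4- and 1/8-resolution branches (doubling channel width per level) supply
context and are fused back by 1×1 convolutions and nearest-neighbour
upsampling. There is no fourth, coarser pyramid level — pruning the coarsest
levels bounds the receptive field (measured at construction by a
gradient-impulse probe; about 43 input px at the defaults, bound 96 px) so
the model attends to the scale of single cells rather than frame-level
context, and keeps inference cheap. The head emits a sigmoid heatmap at half
the input resolution; peaks are extracted after bilinear upsampling. With
the default width (6 high-resolution channels) the model has ~10.7k
parameters. Weights are seeded He-normal draws — a pretrained initialization
is deliberately not used, so builds are reproducible offline; the logit
head's bias starts at −3 so an untrained model is near-silent.

Supervision renders each labelled centroid as a Gaussian keypoint with
σ = 2.8 µm (8.12 px at the default pixel size); overlapping blobs combine by
elementwise maximum, keeping the target interpretable as a per-pixel
probability. Negative (healthy-blood) frames get blank targets.

The pixel-wise loss is the asymmetric binary cross-entropy
$L = -A\,[\,y \log p + (1-y) \log(1-p)\,]$ with $A = 0.1$ exactly when the
frame comes from the positive (cell-line-in-buffer) stream *and* the pixel
is unlabeled ($y < 0.05$, i.e. no keypoint nearby), and $A = 1$ otherwise.
Positive-stream labels come from a pseudo-labeler, which can miss cells;
down-weighting apparent false positives there stops real-but-unlabelled
cells from teaching the detector to stay silent. The 0.05 cutoff is a
package choice: the asymmetry is defined at the false-positive level and a
low threshold approximates "no keypoint nearby" without touching blob
shoulders. With $A \equiv 1$ the loss reduces exactly to textbook BCE, which
the tests verify against an independent implementation.

Training uses Adam at learning rate 0.01 decayed by 0.85 each epoch. Each
batch draws half its frames from positive sessions uniformly and half from
negative sessions weighted by the previous epoch's per-session mean loss
(plus a floor of 1% of the maximum so no session's probability vanishes) —
hard-sample mining at session granularity, which resurfaces the healthy
backgrounds the detector currently finds hardest. Augmentation jitters the
gain by ±10%; horizontal flips along the flow axis are off by default
because defocused fringes have a chirality.

Two protocol rules are enforced as hard errors, not conventions: the
pseudo-labeler refuses blood-medium sessions (in buffer runs every nucleated
object is a target, so labelling is a pure detection task; on blood frames
unlabelled true cells would poison the negative supervision), and
train/validation splits operate at session granularity so repeated captures
of one cell can never straddle the split. The splitter enumerates session
subsets exactly (up to 16 sessions) to get the frame ratio as close to 80:20
as the session sizes allow, falling back to a seeded greedy pass beyond
that.

## Detection, tracking and scoring

Peaks are strict 8-neighbour local maxima at or above the confidence
threshold, followed by greedy non-maximum suppression within a 16 px radius
(about 2σ of the keypoint blob); ties break toward the lowest (y, x).
Because a cell is captured in several consecutive frames, detections are
linked greedily using the known along-flow displacement per frame, with a
25 px gate; a track's representative confidence is the maximum over its
members — one confident capture suffices for candidacy. Detections are
matched to reference keypoints one-to-one, greedily by descending
confidence with a 15 µm default radius (the production radius is unstated;
15 µm is about 1.7 cell radii). The test suite checks this greedy matcher
against an exact maximum-bipartite-matching oracle on a thousand small
random instances at detection-realistic density, where the two agree.

## PMT signal chain

The baseline of each PMT trace is a rolling median over a window of 50
expected pulse widths, with the noise scale from the scaled median absolute
deviation (1.4826·MAD) of the residual — both robust to ~10% pulse
contamination. Candidate excursions above half the acceptance threshold are
merged across gaps shorter than 0.2 expected widths, then accepted if the
apex reaches `k_sigma = 6` noise units and the FWHM lies within [0.3, 3]×
the expected transit width. The width gate is what distinguishes cellular
pulses (FWHM = field-of-view transit time) from electronic spikes; the
6σ amplitude gate holds the false-pulse rate on pure noise far below one
per simulated millilitre-equivalent. Amplitude is measured at the apex
above baseline rather than integrated — simpler, and monotone in the
integral at fixed width. The published system's exact scoring statistic is
not public; these defaults define a compatible contract, all exposed in
configuration.

Cross-channel matching pairs pulse centre times within half a transit time.
Because pulse times live on a line, a non-crossing dynamic program gives the
exact maximum one-to-one matching (ties resolved toward the smallest total
offset); matched pairs are dual-positive events, unmatched pulses singleton
events, so `events = peaks1 + peaks2 − matched`. The same matcher aligns
holographic track mid-times with IF event times during fusion. Tracks with
no IF partner stay marker-negative; IF events with no track are logged but
never enumerated — holography is the cell-presence channel.

## Enumeration and performance arithmetic

Counts are normalized to the whole-blood volume each run represents
(simulations declare their millilitre-equivalent in the configuration).
The threshold comparison is inclusive (`confidence >= 0.5`); the platform's
description says "exceeded", so a `strict_greater` flag preserves the
strict reading — at float confidences the distinction is immaterial but it
is documented rather than hidden. Diagnostic arithmetic follows the usual
definitions: PPV = TPR·c/(TPR·c + FPR) at an assumed abundance c;
per-stage depletion 1 − out/in from mean counts; enrichment fold =
target retention ÷ background survival, multiplicative across stages;
cohort medians are ordinary sample medians (even n: mean of the middle
two).

## Numerical choices and degenerate inputs

* Predicted probabilities are clipped to [1e−7, 1 − 1e−7] inside the loss;
  the training gradient is taken directly on logits, `A·(p − y)/N`, which is
  the clipped-BCE gradient without the catastrophic cancellation.
* Propagation suppresses evanescent components always and band-limits
  beyond the grid's aliasing-free distance; `distance = 0` is an exact
  identity.
* Sub-resolution cells (radius < 2 object pixels), non-positive photon
  budgets, flows faster than a two-frame transit, zero-truth recovery
  curves, empty cohorts, and negative depletion all raise errors instead of
  returning quietly wrong numbers.
* All matchers are deterministic with documented tie-breaks; all stochastic
  components consume a stated seed.

## Problem sizes used by the shipped tests

The end-to-end suite trains the default-width detector on 2000 simulated
frames (8 positive and 8 negative sessions of 125 frames) at a reduced
256 × 128 px field of view, 8 epochs of 125 Adam steps at batch 8, then
evaluates recovery on a held-out positive session (150 frames), false
tracks on 210 blank frames, and patient-like versus healthy-like
enumeration on 1.5 s runs declared as 1.5 mL-equivalents (CTC-like rate
10/s ≈ 10 cells/mL at 90% PSMA expression). These sizes were chosen so the
whole suite trains and evaluates a real detector from scratch in minutes on
one CPU while leaving the statistical margins (recovery ≥ 80% at the 0.5
threshold, ≤ 1 false track per 100 blank frames, healthy ≤ 1 per
mL-equivalent) comfortably testable.

## Known limitations

The simulator's two-population phase-object world is far simpler than
patient blood; recovery numbers measured on it say nothing quantitative
about clinical recovery. The detector here is a faithful small-scale
realization of the architecture family, not a reproduction of any
production network or its weights; the published architecture's exact
branch widths and augmentation protocol are not public. Track linking is
single-hypothesis and will fragment under heavy occlusion. Only two
fluorescence channels are modelled, without spectral unmixing.
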