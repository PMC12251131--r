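---
title: "Motion compensation for fluorescence lifetime image sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion compensation for fluorescence lifetime image sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(flimreg)
```

## The problem

Fibre-bundle optical endomicroscopy (OEM) of the distal lung acquires
fluorescence intensity and lifetime (FLIm) image sequences at a few frames per
second, nominally 128 x 128 pixels. Breathing and probe manipulation displace
the imaged scene between frames, and a substantial fraction of frames —
sometimes a quarter of a dataset — carry no usable content at all (motion
blur, noise bursts, signal dropout). Downstream analyses such as frame fusion
and thresholded detection of fluorescent reporters need the surviving frames
aligned to a common reference; naive alignment fails in characteristic ways
that this package is built around.

`flimreg` implements the full chain: lifetime reconstruction, removal of
uninformative frames, scene-consistency splitting, motion-model
characterisation, translation registration with a peak-tracking correlation
method, fusion, detection, and an ablation harness, plus a synthetic-sequence
generator so that every stage is testable without clinical data.

## Lifetime reconstruction

Two time-gated intensity measurements per pixel, $D_0$ (early) and $D_1$
(late), separated by a gate interval $\Delta t$, give the classical two-gate
rapid lifetime determination estimate
$$\tau = \frac{\Delta t}{\ln(D_0 / D_1)},$$
assuming a mono-exponential decay and equal gate widths. Pixels where the
estimate is undefined ($D_1 \ge D_0$ or a non-positive gate) are masked
invalid rather than raised as errors, preserving the frame geometry. The gate
interval is instrument-specific and always user-supplied.

For display and registration, lifetime maps are *alpha-weighted*: clipped to a
display range (default $[0,\, 2\,\mathrm{median}(\tau)]$, configurable) and
multiplied by the intensity image rescaled to $[0, 1]$, so that structural
contrast comes from intensity while colour scale comes from lifetime.

```{r rld-example}
tau <- matrix(2, 32, 32)                       # 2 ns everywhere
gates <- make_two_bin(matrix(1e4, 32, 32), tau, delta_t = 2,
                      poisson = TRUE, seed = 1)
fit <- rld_lifetime(gates$bin0, gates$bin1, delta_t = 2)
median(fit$tau[fit$valid_mask])
```

## Alignment quality and scene consistency

All similarity computations use the normalised cross-correlation with the
*root-sum-of-squares* deviation convention
$$\mathrm{NCC}(A, B) =
  \frac{\sum_{(x,y)} (A - \mu_A)(B - \mu_B)}{\sigma_A\,\sigma_B},
  \qquad \sigma_A = \sqrt{\textstyle\sum_{(x,y)} (A - \mu_A)^2},$$
(no $1/N$), so that $\mathrm{NCC}(A, A) = 1$ exactly. The *quality of
alignment* $QA_{[K+1,K]}$ is this statistic for consecutive frames, and its
rate of change
$$\mathrm{RoC}_{[K]} = \frac{|QA_{[K+1,K]} - QA_{[K,K-1]}|}{QA_{[K,K-1]}}
  \times 100\%$$
flags scene transitions when it reaches a threshold, 30% by default — the
level that in practice separates scene changes from ordinary drift. The
denominator convention deserves a note: a single-indexed $QA_{[K]}$ is
ambiguous, and we adopt the *preceding* pair's QA (the only single-valued QA
available at $K$), with the alternative exposed via
`roc_series(denominator = "current")`.

`split_scenes()` runs a *sequential scan with post-break reset*: once a break
fires, the cross-scene QA value is discarded and the RoC baseline restarts
inside the new segment. Without the reset, the QA recovery after a genuine
break always fires a second, spurious break, because the next RoC denominator
is the near-zero cross-scene QA. Entries with a non-positive denominator are
marked unusable and fire only when the absolute QA change also exceeds 0.3.
Segments shorter than 2 frames are merged into a neighbour — a one-frame
scene cannot be registered.

## Removing uninformative frames

Each frame is summarised by grey-level co-occurrence (GLCM) texture features
(32 grey levels; offsets $(0,1), (1,0), (1,1), (1,-1)$; symmetric, normalised,
averaged) plus global mean and variance. In unsupervised mode a two-component
Gaussian mixture is fitted to standardised *corruption-sensitive* features:
contrast, correlation, homogeneity and log-variance. The raw mean and GLCM
energy are excluded from clustering because they track scene identity — with
them, multi-scene sequences cluster by scene and an entire scene gets flagged.

The *minority* cluster is labelled uninformative. An earlier rule — "the
cluster with lower GLCM correlation" — is provably wrong for blur artefacts,
which *raise* GLCM correlation; corrupted frames being a minority is the
premise of the removal step itself, so cluster size is the robust label, with
low correlation kept as the tie-break. Two guards prevent false alarms on
clean sequences: the standardised cluster separation must exceed 1.5, and the
split must move at least one feature by a texturally meaningful amount
(correlation by 0.1, log-variance by 0.5, homogeneity by 0.05, or contrast by
50% relatively). A supervised mode (`fit_frame_classifier()`) is available
when labelled frames exist.

Known limitation: intensity-dropout artefacts in *multi-scene* sequences are
the hardest case — the GLCM features are scale-free by construction
(quantisation is per-frame), so dropout is visible only through log-variance,
which also varies between scenes. On single-scene sequences all three
artefact families are detected reliably.

## Motion characterisation

Before registering, the motion model is checked with a dense two-frame
optical flow — a pyramidal, iteratively re-warped Lucas–Kanade estimator
(3 levels, 15-pixel windows, 3 iterations per level), implemented in the
package. The flow field is summarised by its median vector, magnitude
percentiles and a *translation-consistency score*: the fraction of pixels
whose flow lies within 1 px of the median vector (1 px matching the integer
translation model downstream). A pair with score at or above 0.8 is
recommended for translation-only registration; lower scores indicate
non-rigid content. Only these summary statistics feed downstream decisions,
which is why a robust classical estimator suffices here.

## The correlation map and its failure mode

The full NCC surface over all integer displacements is computed in the
Fourier domain:
$$\mathbf{C}_{map} = \frac{\mathcal{F}^{-1}\!\left[\,\mathcal{F}(I_{ref})^{*}
  \times \mathcal{F}(I_{mov})\,\right]}{\sigma_{ref}\,\sigma_{mov}},$$
with both mean-subtracted frames zero-padded to $(2H-1) \times (2W-1)$, so
the map has a well-defined zero-shift origin at its centre and no circular
aliasing. The surface equals the direct spatial-domain evaluation of the NCC
at every shift to machine precision (this equivalence is asserted against a
brute-force oracle in the test suite). Normalisation is global (whole-frame
$\mu, \sigma$), faithful to the definition above, not per-shift windowed
normalisation.

Two registration baselines come directly from this map:

* **`register_translate()`** — the offset is the global argmax of the map
  against the segment's reference frame (the first frame). Ties break toward
  the smaller displacement, then row-major.
* **`register_powell()`** — maximises the NCC over continuous translation
  with a derivative-free local optimiser (Nelder–Mead) started at zero shift,
  rounded to integer pixels. (A direction-set optimiser in the Powell family
  would behave equivalently here; none is available in the supporting
  libraries, and the optimiser's identity is immaterial to the failure mode
  below.)

Both fail on *repetitive texture*. A scene with period-$p$ structure yields a
correlation surface with near-equal maxima $p$ pixels apart, and under global
normalisation with zero padding, the alias closer to zero shift enjoys a
larger overlap and can outscore the true displacement peak. The argmax then
errs by exactly one period; the local optimiser converges to whichever alias
owns the starting basin. `find_local_peaks()` (3 x 3 non-maximum suppression,
95% of the global maximum, 3 px minimum separation) makes this multi-peak
ambiguity measurable.

## Peak-tracked registration

The package's core registration method treats the sequence of correlation
maps as a tracking problem: the *true* displacement peak moves smoothly
across maps, while aliases jump. A reliability-weighted discriminative
correlation filter (DCF) follows it.

Per feature channel $c$ extracted from the map region around the tracked peak
(raw values, gradient magnitude, Gaussian-smoothed copy; each standardised to
zero mean, unit norm), a filter is learned by minimising
$$\Big\|\,\mathbf{S} \odot \big(\rho - \textstyle\sum_c \xi_c \ast
  \mathrm{DCF}_c\big)\Big\|^2 + \lambda \sum_c R_c \|\mathrm{DCF}_c\|^2,$$
where $\rho$ is a Gaussian desired response centred on the peak, $\mathbf{S}$
is the Gaussian *spatial reliability map*
$S(i,j) = \exp\!\big(-\tfrac{(i-i_0)^2 + (j-j_0)^2}{2\sigma_s^2}\big)$
centred on the tracked peak, and $R_c$ is the per-channel reliability
$R_c = \exp\!\big(-\|\mathbf{d}_c\|^2 / 2\sigma_c^2\big)$ driven by the
change $\mathbf{d}_c$ of a unit-normalised 11 x 11 descriptor patch at the
peak between consecutive maps. The objective is solved per channel in closed
form in the frequency domain,
$$\mathrm{DCF}_c = \frac{\mathcal{F}(\xi_c)^{*}\, \mathcal{F}(\rho)}
  {\mathcal{F}(\xi_c)^{*}\mathcal{F}(\xi_c) + \lambda R_c},$$
with $\mathbf{S}$ applied as a multiplicative feature mask — a deterministic
ridge solution adequate for peak-shaped inputs (the original tracker
literature uses an iterative constrained solver; nothing downstream depends
on that refinement). The frequency-domain solution is verified in the tests
against a dense linear-algebra solve of the same least-squares problem.

Tracking a segment: the tracker initialises on the reference frame's
auto-correlation map, whose dominant peak is the zero-shift origin. For each
moving frame, the response $\mathbf{S} \odot \sum_c R_c (x_c \ast
\mathrm{DCF}_c)$ is evaluated on a region centred at the previous peak and
its argmax *within a search window* becomes the new peak, which is then
snapped to the nearest local maximum of the raw correlation surface (a 3 x 3
hill-climb). The snap matters: the Gaussian spatial prior otherwise biases
broad peaks by about a pixel toward the previous track position. Offsets are
decoded relative to the map origin; with frame 1 as the reference this
coincides with decoding relative to the initial peak. Filters update by an
exponential moving average after each confident frame; a frame whose response
maximum falls below 0.2 times the running median of previous maxima is
flagged low-confidence and carries the previous offset forward. The tracker
is re-initialised at the start of every scene segment.

Why this defeats aliasing: the search window (±15 px) and the spatial
reliability $\mathbf{S}$ ($\sigma_s = 10$ px) confine the decision to the
neighbourhood of the previous track, where the true peak is the only
candidate as long as per-frame drift stays well inside the window — even when
a periodic alias elsewhere on the map is absolutely higher.

Registered frames are produced by integer translation with vacated borders
masked invalid (`warp_translate()`); there is no interpolation and no
sub-pixel refinement, matching the integer-translation motion model.

### Tracker parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.01 | ridge weight of the filter objective |
| `sigma_s` | 10 px | spatial-reliability width around the tracked peak |
| `sigma_c` | 0.5 | channel-reliability decay on unit-norm descriptors |
| `sigma_rho` | 2 px | width of the Gaussian desired response |
| `eta` | 0.2 | filter learning rate (EMA) |
| `roi_size` | 63 px | filter region cut from the map |
| `search_size` | 31 px | acceptance window around the previous peak |
| `conf_floor` | 0.2 | low-confidence fraction of the running median response |

The search window bounds the maximum trackable per-frame displacement
(±15 px); `sigma_s` trades alias suppression (smaller) against tolerance to
fast drift (larger). All are exposed via `tracker_config()` and fixed in the
test fixtures.

## Fusion, detection, evaluation

`fuse_mean()` averages registered frames per pixel over the frames whose
validity mask covers it, recording the support count; for i.i.d. noise the
fused variance falls as $1/n$. `nap_detect()` thresholds the fused image and
removes connected components below `min_area` (default 4 px) — the threshold
itself is application-specific and always user-supplied. Detection is scored
pixel-wise by precision, recall and F1 (= Dice); when prediction and truth
are both empty the score is 1 by convention.

Registration quality is scored on consecutive registered pairs over their
mutual valid region: QA, SSIM (standard constants $k_1 = 0.01$, $k_2 = 0.03$,
Gaussian window $\sigma = 1.5$) and NRMSE (RMSE divided by the reference's
intensity range; range- rather than mean-normalisation, stated here because
both conventions exist). The overlap pixel count is always reported alongside
so a shrinking overlap cannot silently inflate scores. `run_ablation()`
crosses datasets x stages (unprocessed, after frame removal, after removal
plus scene splitting) x methods and reports means, standard deviations and
stage-over-stage improvement percentages; NRMSE improvements are sign-flipped
so positive always means better.

## The synthetic generator

`simulate_sequence()` emulates four acquisition scenarios: (1) a homogeneous
scene; (2) a drifting scene with occasional corrupted frames (default rate
25% of the sequence, the level motivating the removal step); (3) one scene
change; (4) multiple scene changes. Frames are 128 x 128 crops of a larger
texture canvas at scripted offsets, plus 1% additive Gaussian noise, with
ground-truth shifts, corruption flags and scene ids recorded for every frame.

Generator design choices worth stating explicitly:

* **Two-scale smooth texture.** The smooth canvas is a sum of two
  band-limited fields (Gaussian-blurred white noise at $\sigma = 5$ and
  $\sigma = 1.5$, the fine one at 0.45 relative amplitude). Tissue scenes
  carry both coarse structure and fine texture; numerically, the coarse part
  keeps consecutive-frame QA high under drift (so within-scene RoC stays well
  below the 30% transition threshold), while the fine part makes the
  correlation peak decay faster per pixel than the zero-padding overlap
  grows, so the true displacement peak dominates the map.
* **Procedural brick texture.** A periodic mortar grid (default period 16 px)
  with per-cell intensity jitter and a faint aperiodic component. The
  periodicity guarantees multi-peak correlation surfaces; the jitter and the
  aperiodic component make the *true* peak a genuine local maximum. The
  aliasing fixture (`alias_fixture()`) scripts a drift crossing one full
  period and asserts at generation time that the global argmax actually fails
  by a period on at least one frame, retrying derived seeds deterministically
  if a draw happens not to.
* **Isolated corruption.** Corrupted frames are planted never adjacent to
  each other or to a scene start: adjacent corruptions would leave a
  post-removal temporal gap whose accumulated drift mimics a transition.
  Severities are fixed per mode (noise at 5 x scene SD, blur at
  $\sigma = 8$ px, dropout to 5% intensity) so the detection task is
  well-posed.
* **Drift.** Integer random-walk steps of at most ±2 px per axis per frame
  (±1 px in multi-scene scenarios), cumulative bound ±12 px. At the nominal
  8 fps this corresponds to drift speeds of a few pixels per second.
* **Blob scenes.** Bright Gaussian blobs (amplitude 2, $\sigma = 3$ px) on a
  smooth or brick base with the truth mask recorded, feeding the fused-image
  detection experiment.

What the generator does **not** emulate: fibre-bundle core patterns,
photon-level FLIm physics beyond the two-gate decay model, non-rigid tissue
deformation, rotation or scale changes, and illumination drift. Passing tests
therefore demonstrate the pipeline's behaviour under its stated motion model
(integer translation, abrupt scene changes, gross frame corruption) — they do
not certify performance on clinical data, where deformation and subtler
artefacts occur.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at the study's native frame size
(128 x 128) with sequences of 14–24 frames, 10–20 seeds per property; oracle
comparisons (spatial-domain NCC, dense ridge solve) use frames up to 32 x 32
and a 9 x 9 filter instance, where brute force is exact and fast. All
computation is in double precision; FFT padding is exact (no size rounding);
offsets are integers end to end. Degenerate inputs (constant frames,
zero-sigma regions) raise informative errors at the boundary of each stage,
except where masking is the contract (lifetime estimation, RoC entries with
non-positive denominators).

## Known limitations

* Translation-only: rotation, scaling and deformation are out of scope; the
  motion characterisation stage exists precisely to detect when that
  assumption fails (`recommended = "non-rigid"`).
* The tracker assumes per-frame drift within its search window; faster motion
  needs a larger window or a lower frame-to-reference strategy.
* Global (not overlap-aware) NCC normalisation biases large-displacement
  comparisons toward small offsets on weakly textured scenes; the tracked
  method compensates by locality, the argmax baseline does not.
* Dropout corruption in multi-scene sequences is detected less reliably than
  noise and blur (see above).
* Fusion by averaging can wash out small dynamic objects; alternatives are
  out of scope.
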