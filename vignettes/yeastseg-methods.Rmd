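---
title: "Automated seeding, segmentation and backwards tracking of budding yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated seeding, segmentation and backwards tracking of budding yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Single-cell time-lapse microscopy of budding yeast needs every cell
segmented in every frame and followed over hours, without dedicating a
fluorescent channel or dye to segmentation. Two properties of yeast make
a particular strategy attractive. First, colonies are essentially
immobile: a cell present at frame $t$ is present, slightly smaller, at
frame $t-1$. Second, cells only ever appear by budding. Segmenting the
movie *backwards* therefore removes the hard detection problem: every
cell already exists in the segmentation of the later frame, and a bud is
found the moment it disappears going back — that frame is its birth.

What backwards tracking does need is a segmentation of the *last* frame
(the seed). `yeastseg` produces that seed fully automatically and then
tracks it back, with explicit self-correction steps for the mistakes a
watershed-based seeding makes.

## Pipeline overview

For one frame the preparation (`prep_frame()`) computes three things:

1. **Contour evidence.** Phase-contrast frames are used directly (the
   phase halo makes boundaries bright); bright-field frames are
   complemented and filtered with a white top-hat
   (`brightfield_preprocess()`), which lifts the thin dark boundary
   rings and flattens slow illumination gradients; optionally a
   cytoplasmic fluorescent channel is blended in
   (`make_composite()`: $(1-w)\,\mathrm{phase} + w\,(1-\mathrm{fluor})$)
   to darken interiors. The result is lightly smoothed (Gaussian,
   `blur_sigma`) and robustly rescaled to $[0,1]$.
2. **A coarse colony mask** (`coarse_cell_mask()`): the local standard
   deviation of the evidence separates textured colony regions from flat
   background (Otsu threshold), gaps are closed, enclosed interiors
   filled, debris below `min_colony_area` dropped. Every label the
   pipeline ever emits lies inside this mask.
3. **Contour pixels** (`detect_contour_pixels()`): pixel $p$ is boundary
   material when
   $I(p) > \mu_w(p) + k\,\sigma_w(p)$, with local mean and standard
   deviation over `mean_window`/`std_window` pixels, plus an absolute
   floor `min_contrast` so that pure noise in flat regions (where
   $\sigma_w$ *is* the noise) is never marked. Wide bright interstices
   between packed cells are plateaus with no local contrast; pixels
   above `barrier_evidence_min` near the colony are added, and a
   radius-1 closing seals one-pixel gaps. This closed network is both
   the watershed input and the hard boundary ("barrier") of the scoring
   subroutine.

Automated seeding of the last frame (`autoseed()`) then runs:

* **Watershed** (`make_topography()`, `watershed_partition()`): the
  distance of every colony pixel to the nearest contour-or-background
  pixel is negated, so each contour-enclosed interior holds one deep
  minimum. Flooding uses a basin-depth tolerance `h` (default 1 distance
  unit): basins shallower than `h` merge into their neighbor, which
  suppresses spurious shallow minima without a separate reconstruction
  pass. Contour-plateau pixels are attached to the nearest basin so the
  labels partition the colony mask exactly.
* **Under-segmentation splitting** (`split_undersegmented()`): each
  watershed region is re-examined with several contour thresholds
  (`vote_thresholds`, bracketing the default $k$); each threshold votes
  every region pixel cell/non-cell, and the majority-voted mask's
  connected components become separate putative cells. A region whose
  voted mask stays in one piece is kept unchanged.
* **Iterative fine-tuning** (`compute_score()`, `refine_once()`,
  `iterate_subroutine()`): per putative cell, inside a subimage around
  its seed, a per-pixel score in $[0,1]$ mixes three terms —
  $w_b\,(1-\text{evidence})$, $w_s\,\max(0, 1 - d(p,\text{seed})/\text{reach})$,
  and $w_i\,[\,p\text{ connected to the seed through low-evidence
  pixels}\,]$ (defaults $0.5/0.3/0.2$, threshold $0.5$ inclusive, reach
  15 px). Detected contour pixels count as maximal evidence whatever
  their raw intensity. The thresholded score is reduced to the component
  carrying the seed — specifically the component holding the
  seed-connected interior, so a tiny bud is never traded for its big
  mother next door — holes are filled, the boundary smoothed (disk
  closing/opening, radius `smooth_radius`, skipped when it would erase a
  small cell), and the mask feeds back as the next round's seed. Five
  rounds (with an early stop at a fixed point) converge coarse watershed
  regions, damaged seeds, and stale seeds from a neighboring time point
  onto the cell boundary.
* **Cell acceptance.** A converged mask is accepted as a cell only if
  (a) its mean *self-score* — the score of the mask used as its own
  seed, which saturates the proximity term and so measures only
  boundary evidence and interior connectedness — reaches
  `cell_score_min` (default 0.7), and (b) at least `enclosure_min`
  (default 0.9) of its boundary lies on detected contours. Real
  interiors self-score near 1 and are fully enclosed; basins in
  interstices or at the colony margin fail one or both tests. In
  tracking, failing these tests *is* the birth criterion: going
  backwards, a bud whose seed no longer finds an enclosed interior has
  just been born.
* **Over-segmentation merging** (`merge_oversegmented()`): fragments of
  one cell each converge toward the whole cell and therefore overlap
  heavily; any pair with $|A\cap B| / \min(|A|,|B|) > \theta$ (default
  0.5) is unioned, transitively.
* **Overlap distribution** (`distribute_overlaps()`): remaining disputed
  pixels (fused halos make neighbors claim the same boundary pixels) go
  to the cell with the higher score; exact ties go to the lower label
  id, which in tracking is the older, established cell. No disputed
  pixel is discarded, so per-cell area never falls below what discarding
  overlaps would leave — the basis of the area-gain and
  periphery-quantification comparisons in `pct_area_gain()` and
  `pct_quant_difference()`.

Backwards tracking (`track_backwards()`) segments frame $t-1$ from frame
$t$'s labels, cell by cell in independent subimages (`pad` = 10 px
margin covers one-frame boundary motion), reconciles with the same
score distribution, and declares a cell born when it is absent
(`min_cell_area`, cell tests above) for `lost_patience` consecutive
backward steps (default 1: buds vanish abruptly). When a converged mask
fails the cell tests, the tracker retries once from a dilated seed:
between distant frames, colony expansion can shift a rim cell most of a
cell diameter off its seed, and the widened search recovers it, while a
genuinely absent bud gains nothing because the rightful owner wins the
score distribution. Large inter-frame movement beyond that is out of
scope: the method assumes the near-immobility of yeast colonies.

## The synthetic benchmark

`simulate_geometry()` and the renderers generate the ground-truthed
colonies every quantitative claim in this package is measured on.

Cells are ellipses (axis ratio 1.05–1.35) whose area grows exponentially
with a 90-minute doubling time, the textbook rate for budding yeast in
glucose. Buds appear on mothers at `bud_rate` (default 0.46 events per
cell per hour, consistent with that doubling time), at an initial
effective radius of 4.5 px — at the default 40X-like scale (mother radii
8–15 px) that is the size at which a newborn bud is a scoreable object.
Buds are placed in the least crowded of eight candidate directions, so
inserting one shoves the neighborhood as little as possible. Crowding is
resolved by pairwise centroid repulsion using the exact ellipse radii
along the center line plus a 2 px rest gap; colonies spread laterally as
they grow, as real colonies do. Because true boundaries never touch,
the 2 px gap between neighbors renders as one *fused* bright ridge — the
classic phase-contrast false boundary the overlap-distribution step
exists for — while keeping the ground truth unambiguous. Disputed
pixels during rasterization go to the cell with the smaller normalized
ellipse radius, so true labels never overlap.

The phase render places the halo (width 2 px) just outside each
boundary over a mid-grey background, with interiors darker than
background and Gaussian pixel noise (default sd 0.03 on a 0–1 scale).
The bright-field render uses thin (1 px) rings only mildly darker than
the field, plus a linear illumination gradient. The fluorescence render
gives each cell a bright interior with a per-track intensity jitter and
shot-like noise scaling with $\sqrt{\text{intensity}}$.

What the generator deliberately does *not* model: optics (no point
spread function — boundaries are sharp before the pipeline's own blur),
focus drift, cell death, irregular morphologies (pheromone-arrested or
sporulating cells), and cell migration. Passing the synthetic benchmark
therefore demonstrates the correction logic — splitting, merging,
distribution, recovery, birth detection — under controlled conditions;
it does not certify performance on real images, where the
contour-detection constants typically need recalibration per objective
and modality.

## Numerical choices

* Coordinates are 0-free R conventions: matrices indexed `[row, col]`
  from 1; all masks share the frame's shape.
* Contour defaults (`mean_window = std_window = 11`, `contour_k = 0.5`)
  are calibrated on the renderer at the 40X-like scale: they give ~99%
  halo coverage with sealed ridges between touching cells. All such
  constants are exposed in `prep_params()` and round-trip through the
  YAML configuration.
* Score threshold ties are inclusive (`score >= threshold` keeps the
  pixel); distribution ties go to the lower label id; component
  selection ties go to the larger piece, then the lower component id.
  Every operation is deterministic — the only RNG in the package is the
  scene generator and `perturb_seed()`, both driven by explicit seeds.
* Degenerate inputs: constant images yield empty masks; an empty contour
  set yields a flat topography with no basins (and a warning from
  `autoseed()`); an empty threshold set propagates an empty mask, which
  callers interpret as cell loss; labels above 65535 are refused by the
  16-bit TIFF writer.
* `interval_robustness_experiment()` scores, by default, the cohort of
  cells already alive at the largest tested interval, so the
  accuracy-versus-interval curve is a paired comparison; otherwise
  newborn buds enter only the short intervals and, being tiny, are the
  hardest objects to score at pixel precision, which can invert the
  trend. Per-interval populations remain available via
  `cohort = "per_interval"`.
* `seed_perturbation_study()` perturbs only cells whose reference track
  survives at least five backward frames; recovery is unobservable for
  a cell that is born (disappears) almost immediately behind the seed
  frame.
* Study sizes: the perturbation study uses four 512×512 fields of
  55-cell colonies over 10 frames (≥200 eligible cells); the interval
  study two fields of 60-cell colonies, intervals 3/12/24 min; the
  seeding-quality study one 55-cell final frame. These sizes give
  stable percentages while keeping a full run in a few minutes on one
  core.

## Known limitations

* Bright-field seeding at the default (phase-calibrated) constants finds
  essentially all cells but with boundaries about one pixel tight
  (median Jaccard ≈ 0.87 on the renderer) and extra candidate regions:
  the 1 px rings blur into the evidence with an inward bias, and the
  top-hat's rectified noise pedestal makes interiors and background
  locally indistinguishable. Phase or composite input is preferred for
  the automated seeding step; bright-field tracking from a good seed is
  unaffected.
* Labels are capped at 65535 by the 16-bit label TIFF format.
* The tracker has no motion model; fields with substantial inter-frame
  displacement (flowing cells, loose mounts) are outside the method's
  assumptions.
* `perturb_seed()` guarantees a connected remainder only for the
  convex-ish masks it is meant for (a directional cut of a crescent can
  disconnect).

## Worked example

```{r, eval = FALSE}
library(yeastseg)

sp <- scene_params(n_initial_cells = 20, frames = 10,
                   frame_dim = c(320L, 320L), rng_seed = 5, bud_rate = 1.5)
truth <- simulate_geometry(sp)
stack <- render_phase(truth, sp)

seed <- autoseed(stack[[10]], "phase")       # automated last-frame seeding
tracks <- track_backwards(stack, seed$labels)
head(tracks$table)
tracks$birth_frame                            # 1 = present from the start
```
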