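---
title: "Methods: droplet cytotoxicity image analysis and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet cytotoxicity image analysis and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropcyto)
```

## The assay and what the package computes

In a droplet cytotoxicity assay, effector cells (e.g. primary NK cells) and
target cells (e.g. K562 leukaemia cells) are co-encapsulated at random into
picolitre water-in-oil droplets, the droplets are immobilised in an
observation chamber, and the chamber is imaged hourly over ~10 h in four
channels: brightfield, one tracker dye per cell type, and a viability dye
that is dark in live cells and turns bright — and stays bright — when a cell
dies. Because each droplet isolates one cell pair, every target death can be
attributed to its co-encapsulated effector, turning a bulk killing assay
into thousands of parallel single-cell experiments.

`dropcyto` implements the complete analysis chain:

1. **Droplet detection** — circular-Hough detection on each brightfield
   frame.
2. **Tracking** — linking detections across hourly frames and removing
   droplets that move too far.
3. **Cell counting** — per-droplet, per-channel segmentation and counting,
   giving each droplet an effector:target (E:T) occupancy class.
4. **Death calling and kinetics** — per-droplet viability traces, death
   times, killer fraction, fast/slow killer split, serial killers.
5. **A Poisson co-encapsulation model** and **a ground-truthed synthetic
   image generator**, so that every stage can be validated quantitatively
   without access to experimental images.

## Poisson co-encapsulation

Cells arrive at the droplet-forming junction at random, so the number of
cells of one species per droplet is Poisson with mean

$$\lambda = c \cdot d \cdot V,$$

where $c$ is the feed concentration (cells/mL), $V$ the droplet volume
(70 pL by default), and $d$ the dilution factor — the fraction of droplet
volume contributed by that cell stream. The default $d = 0.5$ reflects two
aqueous inlets run at equal flow rates; it is exposed as a parameter because
the effective in-droplet concentration depends on the chip and flow
configuration. The two species load independently, so the joint occupancy
probability is a product of Poissons. At the default concentrations
(7×10⁶ and 10×10⁶ cells/mL) this gives $\lambda_E = 0.245$,
$\lambda_T = 0.35$, and a 1:1 pairing probability of ≈ 4.7%.

```{r}
p <- encapsulation_params(7e6, 10e6, 70, 0.5)
occupancy_pmf(p, 1, 1)
```

Observed pairing rates in real devices run below this naive prediction
(reported 1:1 fractions are nearer 3%): sedimentation, clumping and inlet
effects thin out multi-cell droplets. `compare_observed_predicted()` reports
this gap per class; the package deliberately makes no attempt to fit or
explain it. Normalisation checks truncate the support at $k = 50$ per
species, where the residual mass at assay densities is far below 10⁻¹⁰.

## What the synthetic generator emulates — and what it does not

`generate_experiment()` renders tiled, multi-channel, hourly image stacks
with full per-droplet and per-cell ground truth:

* ~50 µm droplets (radius jittered per droplet, constant over time),
  hex-packed with a safety margin so droplets never touch tile borders;
  92% of lattice sites are filled, the vacancies serving as landing spots
  for movers.
* Brightfield shows each droplet as a dark rim (Gaussian radial profile) on
  a light background — the minimum structure circle detection needs.
* Cells are 2-D Gaussian spots with full width ≈ one cell diameter (10 µm).
  The target tracker is stable; the effector tracker decays exponentially
  with a 10 h half-life (calcein-like: "detectable but fading"); the
  viability channel switches from background to a bright stable spot at the
  cell's death hour. A live cell's viability signal is background, not
  literally zero — the pipeline must background-correct, as on real images.
* Per-frame droplet jitter (sd 0.5 px) and, for a 2% minority of "movers",
  a single jump to a vacant lattice site at a random frame — a planted
  removal case for the tracker.
* Fates: each target sharing a droplet with ≥ 1 effector dies with
  probability `killer_prob` (default 0.2, the reported scale of the killer
  fraction among NK cells). Death hours follow a discretised exponential
  with rate 0.5/h over hours 1–10, chosen so that ≈ 87% of kills fall
  within 4 h and ≈ 39% within the first hour — matching the reported
  fast-killer kinetics. Targets in effector-free droplets (the negative
  control stratum) die spontaneously with probability 0.05 over the window,
  in the late hours, consistent with ~95% control viability.
* Additive Gaussian noise (sd 0.01) on every frame.

Deliberate non-realism, and what it implies: there is no point-spread
function, no bleed-through, no illumination gradient, no droplet shrinkage,
and — most importantly — **cells are rendered resolvable**: within a droplet,
cells are placed with a minimum mutual separation of ≈ 2 cell diameters
(falling back to a maximally separated ring in crowded droplets) and
per-frame cell jitter is redrawn when it would push two cells below ≈ 1.9
diameters. Touching or overlapping cells merge into one connected component
after thresholding, and declumping (watershed) is out of scope here, as it
is in the original analysis. Passing the validation bound therefore
demonstrates that the pipeline is accurate *when cells are resolvable at
the rendered contrast* — it says nothing about clumped cells, debris, or
focus drift in real data. Cell division is never simulated; occupancy is a
t = 0 property.

`simulate_cohort()` is the table-level twin of the image generator: the same
occupancy, fate and trace model without pixels, used to study the kinetics
estimators at cohort sizes (tens of thousands of droplets) where rendering
images would be pointless.

## Numerical choices in the pipeline

**Detection.** The brightfield is contrast-stretched between its 1st and
99th percentiles (constant frames are returned unchanged and flagged),
inverted, and convolved (FFT) with ring-minus-interior templates over a
radius grid of 0.8–1.2× the nominal radius in 0.5 px steps. The template
score is the mean intensity on an annulus minus the mean on the interior
disk, so structureless noise scores ≈ 0 regardless of the stretch. On
rendered data true droplets score ≥ 0.6 and clutter ≤ 0.31; the default
acceptance threshold of 0.45 sits midway with a wide margin on both sides.
Candidate centres are accepted greedily in descending score order with a
minimum separation of one minimum radius, and any disk touching the tile
border is dropped (partial droplets corrupt counts; tiles are analysed as
disjoint fields, with no stitching). Detection is fully deterministic.

**Tracking.** Links between consecutive frames use greedy globally-nearest
matching under an allowed movement of 0.5× the droplet radius — safely
below the radius, beyond which a neighbouring droplet could be mistaken for
the same one. Greedy global matching cannot assign one detection to two
tracks and coincides with optimal assignment when spacing ≫ jitter, which
the immobilised-chamber geometry guarantees. Tracks with a gap are flagged
`removed_gap`; broken tracks whose break coincides with unmatched
detections on the far side are flagged `removed_mover`. Removed tracks
never enter downstream analysis but are retained, with reasons, for audit.

**Counting.** Per droplet and channel, the processing order is fixed: crop
(radius + 2 px margin), white top-hat with a disk of 1.5× the cell radius,
zero all non-droplet pixels, threshold. The threshold is Otsu computed over
in-disk top-hat intensities, guarded by a contrast floor (0.1): a droplet
whose in-disk maximum is below the floor binarises to empty rather than
letting Otsu split background noise. Components are labelled with
8-connectivity (Gaussian spots binarise to blobs where diagonal adjacency
is routine) and filtered to 0.25–4× the nominal cell area.

**Attribution and death calling.** Each viability object is attributed to
the cell type whose nearest tracker centroid lies within one cell diameter,
falling back to t = 0 tracker positions when the tracker signal has
decayed; otherwise it counts as `dead_unknown`. Viability traces are
background-corrected by the droplet's median in-disk viability intensity at
t = 0, making the "alive = 0" convention literal. A death is called at the
first frame the corrected intensity exceeds θ = 0.1 and stays above it for
`persistence` frames (default 1 — hourly sampling is coarse and the dye is
stable; raise it for noisy data).

**Kinetics.** The killing analysis uses complete tracks with occupancy
exactly 1:1 and no dead cell at t = 0; every exclusion is logged, and
eligible + excluded equals the 1:1 complete-track count exactly. The killer
fraction is the fraction of eligible pairs whose *target* dies in the
window (effector deaths are recorded but not killer events). Killers are
split at `t_fast` = 4 h into fast and slow killers. Serial killers are
single effectors with ≥ 2 targets and ≥ 2 target deaths, read from the
census dead-count step function.

## Validation against ground truth

`validate_against_truth()` reproduces a script-vs-manual comparison with
the generator's truth standing in for manual counts. Pipeline tracks are
matched to truth droplets by t = 0 centre proximity (within one radius);
at t = 3, 4 and 10 h it compares, over the matched droplets: total droplet
count, the distribution of droplets over total-cell-count bins (0, 1, 2, 3,
4+), the 1:1 pairing count, and the cumulative dead-cell count. Deviation is
$100\,|obs - truth| / \max(truth, 1)$ — the guard keeps empty strata
finite — and the report's headline is the maximum over all metrics,
timepoints and strata. Matching-by-position (rather than comparing against
all droplets) keeps the audited mover/gap exclusions from masquerading as
counting error, which is what the bound is meant to measure.

Problem sizes were chosen as a realistic desk-scale instance of the assay:
the default validation experiment uses six 512×512 px tiles at 2 µm/px
(≈ 1,200 droplets — the spatial density of the real chamber, two orders of
magnitude fewer fields), 11 hourly timepoints, and the default dye/noise
settings. Cohort-level estimator checks use ≈ 42,000 table-level droplets,
giving ≈ 2,000 eligible 1:1 pairs per seed.

## Known limitations

* The detector assumes near-circular droplets; deformed or coalesced
  droplets are out of scope.
* Touching cells of the same type merge into one count (no declumping).
* Dead-cell attribution can fail (`dead_unknown`) if both trackers decay
  below detectability and t = 0 positions are ambiguous — with the default
  half-life the effector tracker stays detectable over 10 h.
* Tracking allows no gaps: a droplet missed at one frame is excluded rather
  than re-identified later. This is conservative and auditable.
* The Poisson model treats species independently and ignores the
  sedimentation/clumping effects that depress observed pairing below the
  prediction; the comparison function reports that gap rather than
  modelling it.
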