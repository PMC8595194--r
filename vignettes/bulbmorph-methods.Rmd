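---
title: "Models and methods behind bulbmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bulbmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bulbmorph)
```

`bulbmorph` measures four aspects of olfactory-bulb reorganisation during
anuran metamorphosis: the relative growth and bilateral fusion of the dorsal
projection field, the stability of odor-response maps in the ventral field,
the tuft-level morphology of projection neurons, and odor-guided side
preference in a two-area choice tank. This vignette explains the models and
conventions each analysis relies on, why the defaults are what they are, and
what the synthetic validation data do and do not demonstrate.

## Coordinate and data conventions

Voxel arrays are stored as (y, x, z) with any extra dimension (channel,
time) last; the x axis is the left–right (medial–lateral) axis. Voxel
indices are 1-based, physical positions are voxel centers in micrometers.
Normalized bulb coordinates put the lateral edge at ML = 0, the medial edge
at ML = 1, and the anterior edge at AP = 0; these conventions are recorded
in every output file. All threshold comparisons in the package are strict
inequalities, and wherever an optimisation over thresholds ties, the
smallest optimizer wins. Every stochastic generator draws from a private
seeded stream and leaves the caller's RNG state untouched, so a fixed seed
fixes outputs bit-exactly.

## Volumetry and bilateral overlap

Volume shares are pure voxel-count ratios of two disjoint masks, so they
are invariant to voxel-size rescaling; hemispheres are pooled. Channel
shares are computed on maximum-intensity projections and use the union
convention: each channel's share is relative to pixels labeled in *either*
channel, so shares can sum to more than 100 when the two sources co-occupy
pixels (the alternative — excluding doubly labeled pixels — is not adopted,
and the convention is flagged in the output). Bilateral overlap is
100·|L ∩ R| / |L ∪ R| over the full 3D stack with a per-plane breakdown.

Two global threshold criteria are implemented exactly on 256-bin
histograms (integer 8-bit data get one bin per gray level, other data 256
equal-width bins over the observed range): Kapur–Sahoo–Wong maximum
entropy, and Huang's minimum fuzziness with membership attraction to the
class means and the fuzziness constant C set to the full gray-level range.
A property-based test suite checks both against exhaustive-search oracles
on random histograms. Foreground is strictly above the threshold. Note one
consequence of the tie rule: on a histogram with an extended plateau of
optimizers (for instance two well-separated modes, where every split
between the modes produces the same partition), the reported threshold is
the plateau's left edge; the induced binarization is identical across the
plateau.

The median filter used before binarization is a per-z-plane square window
with reflection padding; even window sizes are centered by the lower-left
convention (offsets −size/2 … size/2 − 1). Axis profiles bin labeled
voxels into 100 equal bins across the landmark-defined span; in dMOB mode
positions are mirrored about the interhemispheric midline.

Trends over development are summarised by a least-squares cubic
(R² reported by definition, defined as 0 with a warning for a
zero-variance response) and by RANSAC: 1000 two-point samples, inliers
within a residual threshold defaulting to the MAD scale of an initial
least-squares fit, final line refit on the largest consensus set, seed
mandatory.

## Calcium response analysis

A stimulus difference map is the voxelwise mean of a 3-frame peak window
minus the mean of the 5 frames immediately before onset. The peak window is
placed data-driven: the 3 consecutive frames maximizing the frame-averaged
fluorescence between onset and stimulus offset plus a 10-s decay margin
(slow indicators peak after offset). Negative deflections are preserved.
Because window placement only uses the argmax of a frame-mean trace, the
map is linear in the movie for positive scalings.

Responsive regions must satisfy three criteria: (i) area strictly greater
than 100 pixels on the z-projected, repeat-averaged per-stimulus map;
(ii) maximal amplitude strictly above the dataset threshold, defined as the
mean over candidate regions of each region's median per-presentation
amplitude — computed per recording by default (pooling across recordings is
a caller-side choice); (iii) centroid inside the glomerular-cluster
boundary polygon when one is supplied (points on the boundary count as
inside; without a polygon the filter passes everything with a warning).
Supra-noise pixels are delineated before connected components by the larger
of an Otsu threshold and a robust noise floor (median + 5 MAD of the map).
The floor is load-bearing: a pure Otsu split on a map without any response
(the Ringer control, or any untuned stimulus) falls inside the noise
distribution, and with 8-connectivity the supra-threshold noise percolates
into pseudo-components larger than 100 px that bridge genuine regions.
Candidates found under different stimuli are merged when they share pixels.

Region traces (mean over region pixels and z) are baseline-corrected with
an asymmetric least-squares Whittaker smoother: minimize
Σ wᵢ(yᵢ − zᵢ)² + λ Σ(Δ²z)ᵢ² with wᵢ = p where yᵢ > zᵢ and 1 − p otherwise,
λ = 10⁴, p = 0.01, 10 reweighting iterations. These defaults flatten
minute-scale drift while attenuating 5-s transients by well under 10 %.
Since the second-difference penalty's null space is affine, the stiff limit
(λ → ∞) of the baseline is the iteratively reweighted least-squares *line*,
which the tests verify in closed form. Corrected traces are normalized to
baseline 0 / maximum 1, and the tuning set is the set of stimuli whose
repeat-averaged amplitude in the expected peak interval strictly exceeds
12.5 % of the trace maximum. Repeats are averaged, not maxed — the
conservative aggregation. The Ringer negative control and the odor-mixture
positive control are measured but never enter the tuning set. A region is
fsk+ iff forskolin is in its tuning set. An SNR sanity check
(peak over baseline-sd of the corrected trace ≥ 2) replaces the
deconvolution-based quality control of upstream toolchains, which is out of
scope here along with motion correction: the pipeline expects
motion-corrected movies.

Spatial maps use a product-Gaussian KDE with per-axis Scott bandwidths
(σ̂ · n^(−1/(d+4)), d = 2 for joint maps) scaled by the number of
contributing regions; margins are independent 1D estimates (d = 1) rather
than marginalized 2D ones. Collinear positions trigger a documented 1D
fallback.

## Neuron morphometry

Critical points are branching nodes (≥ 2 children) and endpoints of the
reconstruction tree, excluding the soma. Tufts are detected with DBSCAN
semantics: ε = 15 µm on pairwise distance (strict <), minimum cluster size
6 ("more than 5 points"), border points attached to the first claiming core
point in node-id order so the clustering is deterministic. Whether the
15-µm rule is a neighbor-distance or cluster-diameter bound is a genuine
ambiguity; the neighbor-distance (DBSCAN ε) reading is used and exposed as
a parameter. Tuft volume is the 3D convex hull of the member points
(an in-package incremental hull; degenerate clusters report volume 0 with a
flag instead of failing the cell). The soma→tuft distance is summed edge
length to the cluster's attachment node — the member with minimal path
distance, since the measurement endpoint inside a tuft is otherwise
undefined — and is always at least the Euclidean soma–attachment distance.
Inter-tuft distance is the mean pairwise distance of tuft centroids,
reported only for multi-tufted cells; per-tuft volumes are averaged per
cell (not summed). Branches are maximal unbranched segments classified as
primary iff they originate at the soma and tufted iff their distal node
lies on a soma→tuft path or inside a tuft arbor. Population comparisons run
two-sided Mann–Whitney U tests per descriptor and report uni/bi/tri+
shares.

## Behavioral assay

Visits are maximal runs of samples inside one area, with entry at the first
inside sample (no sub-sample interpolation — the tracker's sampling grid is
the resolution), so visit time plus neutral time equals record time
exactly. Visits straddling the analysis window are clipped, not dropped,
conserving measured time; no debouncing is applied by default (minimum
visit = one sample). Animals that do not enter either area within 40 min
of stimulus application are excluded (closed bound: entry exactly at
40 min is included); the 20-min analysis window starts at the first entry.
Habituation comparisons default to the final 20 min of the habituation
period so both conditions use equal window lengths. The cohort test is the
two-sided Wilcoxon signed-rank on per-animal (area 2 − area 1) mean time
per visit; zero differences are dropped, exact for n ≤ 25 without ties.
With nine animals the smallest attainable two-sided p is 2/2⁹ ≈ 0.0039,
and the achievable rejection level at α = 0.05 is 3.9 % — the test is
slightly conservative by discreteness, which the 1000-cohort null
calibration reflects.

## The synthetic generators

The generators exist so that every analysis can be validated against
planted truth; their defaults are the study conditions, not tuning knobs.

* **Bilateral stacks** (80×80×64 voxels at 1 µm, two blob pairs of 8-µm
  half-max radius, peak 100 a.u., autofluorescence 5 a.u.): each left/right
  blob pair is separated by the distance at which the sphere–sphere lens
  volume yields the requested overlap fraction, solved analytically, so the
  planted fraction is recovered within ~2 points before noise. Blobs are
  flat-core supergaussians, intensity = peak·exp(−(d²/2σ²)³), with the
  half-maximum surface exactly at the planted radius. The flat core and
  steep shoulder make the voxel footprint insensitive to the exact
  binarization threshold — with a pure Gaussian profile no global
  histogram threshold recovers the half-max footprint, and the measured
  overlap drifts systematically with the threshold value, which would
  conflate generator and analysis errors. The 20 %-of-peak noise condition
  is analysed with a 3-px median (matching, relative to the 80-px grid,
  the 10-px window used on 512-px planes) followed by maximum-entropy
  binarization; Huang's criterion, although appropriate for real bulb
  stacks, collapses onto the background mode on these strongly
  background-dominated synthetic histograms (under 5 % foreground voxels
  plus a zero-clamped background spike) and is therefore exercised by its
  oracle tests rather than by the recovery check.
* **Calcium recordings** (128×128×2 voxels, 2-s frames, 5-s stimuli at
  60-s intervals, two repeats of MIX/Ringer/AA/AM/BA/FSK, baseline
  100 a.u.): responses are steps of the planted amplitude for the stimulus
  duration followed by exponential decay (τ = 4 s), so the 3-frame peak
  average equals the planted amplitude exactly in the noise-free case while
  keeping window placement non-trivial. The default scene plants twelve
  circular regions (~180 px) spanning six tuning profiles — {AA}, {AM},
  {AA,AM}, {FSK}, {AM,FSK}, {AA,FSK} — with fsk+ regions medial
  (ML ≥ 0.7) and fsk− regions lateral (ML ≤ 0.3), mirroring the two
  processing streams. Validation uses amplitude 30 with noise sd 6
  (SNR 5) and a 3-a.u. sinusoidal drift. Overlapping planted regions are
  rejected so ground truth stays unambiguous.
* **Neurons**: tuft centers sit on fixed directions at a radius derived
  from the requested separation; each tuft is a star of points-per-tuft
  critical points within the tuft spread (6 µm default, well under the
  15-µm clustering radius); basal neurites end bluntly far from any tuft.
  Unambiguous-recovery fixtures require separation > 2ε by construction.
* **Trajectories**: a two-state semi-Markov process — exponential neutral
  dwell (rate = visit rate, 0.05 s⁻¹), then a fair choice of area with
  exponential dwell of mean 13 s in area 1 (the observed habituation
  median) and preference-odds × 13 s in area 2 — sampled at 1 Hz with
  positions uniform in the current zone. The expected time-per-visit ratio
  equals the planted odds.

What passing these checks shows — and what it does not: the synthetic data
have no point-spread function, no motion or focus drift beyond a global
sinusoid, no autofluorescence structure, no reconstruction errors and no
tracking dropouts. Recovery there validates the *computational* pipeline
(definitions, estimators, conventions, determinism), not robustness to
every artifact of real recordings; the rigid-shift registration fallback
and the SNR guard are the only concessions to imperfect input.

## Problem sizes and runtime choices

The validation suite uses 100 random histograms for the threshold oracles,
10 seeds per overlap fraction ({0, 0.10, 0.25, 0.40}), 10 seeded
recordings (12 regions each) for tuning recovery, 50 random point sets (up
to 200 points) for the clustering oracle, a 34-cell population (11/12/11
uni/bi/tri), and 1000 nine-animal null cohorts of 1600-s trajectories for
the type-I calibration — sizes chosen so the whole suite completes in a few
minutes on a single core while keeping every estimate's Monte-Carlo error
well inside the tolerances tested.

## Known limitations

Tiled-acquisition stitching, manual volume annotation, image-based neuron
reconstruction and video tracking are out of scope: masks, SWC files and
trajectory tables are inputs. The amplitude criterion's "dataset" is one
recording by default; cross-animal pooling changes the threshold and is
left to the caller. Huang thresholding of histograms with extreme class
imbalance returns background-adjacent thresholds by design of its
criterion; inspect the recorded threshold value in the mask provenance
before trusting masks from such data. The hull volume of nearly coplanar
tufts is numerically 0 and flagged rather than estimated.
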