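# bulbmorph

Quantitative analysis of olfactory-bulb rewiring during amphibian
metamorphosis.

During metamorphosis of *Xenopus laevis*, the main olfactory bulb (MOB) is
rebuilt while the animal keeps smelling: axonal projections from the larval
principal nasal cavity to the ventral bulb (vMOB, the "water" field) are
replaced by projections from the newly formed middle cavity, while a dorsal
projection field (dMOB, the "air" field) forms de novo as a single unpaired
structure in which axons from the left and right epithelia increasingly
overlap across the interhemispheric midline. `bulbmorph` provides the full
measurement pipeline for studying this process, for researchers working with
multiphoton image stacks, volumetric calcium recordings, neuron
reconstructions and behavioral tracking data:

* **Projection-field volumetry** — relative volume shares of the vMOB/dMOB
  fields, per-source innervation shares on maximum-intensity projections,
  bilateral innervation overlap
  (100·|L ∩ R| / |L ∪ R| per stack and per plane), and labeled-pixel
  profiles along the left–right axis. Binarization by Kapur–Sahoo–Wong
  maximum-entropy thresholding (maximize H_bg(t) + H_fg(t)) or Huang's
  minimum-fuzziness thresholding (minimize Σ_g S(μ_t(g))·h(g) with
  μ_t(g) = 1/(1 + |g − m_class(t)|/C)), both exact on 256-bin histograms.
  Trend fits by least-squares cubic regression and RANSAC robust lines;
  group comparison by Mann–Whitney U.
* **Glomerular odor responses** — stimulus difference maps (3-frame peak
  minus 5-frame baseline), responsive-region selection (area > 100 px,
  dataset amplitude criterion, cluster-boundary filter), asymmetric
  least-squares (Whittaker) baseline correction, max-normalized traces,
  tuning profiles by the strict 12.5 % amplitude rule, forskolin (cAMP
  pathway) classification, landmark-normalized (ML, AP) positions and
  Gaussian kernel density maps with Scott's-rule bandwidths
  (h_j = σ̂_j · n^(−1/(d+4))).
* **Projection-neuron morphometry** — branching/endpoint extraction from
  SWC trees, dendritic-tuft detection by density clustering (more than 5
  critical points within < 15 µm, DBSCAN semantics), convex-hull tuft
  volumes, soma→tuft path distances along the dendrites, inter-tuft
  Euclidean distances, primary/secondary × tufted/basal branch
  classification, and population comparisons with uni/bi/tri+ shares.
* **Behavioral choice assay** — visit segmentation of two-area tank
  trajectories, average time per visit, the 40-min exclusion rule and
  20-min analysis window, and the paired Wilcoxon signed-rank preference
  test.
* **Synthetic data** — seeded generators for every input with planted,
  recoverable ground truth (overlap fractions, tuning profiles, tuft
  memberships, side-preference odds), used by the test suite to validate
  the whole pipeline end to end.

## Worked example

Plant a 25 % bilateral innervation overlap, push the stack through the
measurement pipeline (autofluorescence subtraction, median filtering,
maximum-entropy binarization), and recover it:

```r
library(bulbmorph)

sim <- simulateBilateralStack(overlap = 0.25, noiseSd = 20, seed = 42)
st  <- removeAutofluorescence(sim$stack, "left", "blue")
st  <- removeAutofluorescence(st, "right", "blue")
st  <- medianFilter2D(st, 3)
maskL <- binarizeChannel(st, "left",  "max_entropy")
maskR <- binarizeChannel(st, "right", "max_entropy")
ov <- bilateralOverlap(maskL, maskR, compartment = "dmob")
maskL
#> BinaryMask: 80 x 80 x 64 voxels, 5935 labeled (1.45%)
#>   provenance: channel=left; method=max_entropy; threshold=25.7574
sprintf("planted overlap: 25%%   measured: %.1f%%", ov$percent)
#> "planted overlap: 25%   measured: 25.9%"
```

The measured 25.9 % is the share of doubly labeled voxels among all labeled
voxels, recovered from the noisy stack within one percentage point of the
planted fraction.

Morphometry of a simulated bi-tufted projection neuron:

```r
cell <- simulateNeuron(nTufts = 2, seed = 7)
cell$tree
#> NeuronTree: 35 nodes, root id 1, 16 endpoints, 2 branching points
morphometricProfile(cell$tree)
#> n_tufts 2; mean tuft volume 31.1 um^3; mean soma-tuft path 150 um;
#> mean inter-tuft distance 211.7 um; 2 primary tufted dendrites,
#> 2 primary basal neurites, 14 secondary tufted, 0 secondary basal
```

The profile says the cell reaches two glomeruli (two detected tuft
clusters), each tuft sits 150 µm of dendritic path from the soma, and the
two tufts are 212 µm apart — the descriptors used to compare ventral
against dorsal projection-neuron populations.

An end-to-end synthetic run of all four analyses (deterministic under the
seed, writes CSV reports plus a JSON manifest):

```r
runPipeline(list(seed = 1, out_dir = "demo-out"))
```

or from a shell: `Rscript inst/scripts/run-pipeline.R --seed 1 --out-dir demo-out`.

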