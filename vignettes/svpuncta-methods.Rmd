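---
title: "Methods: segmentation and quantification of presynaptic clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and quantification of presynaptic clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpuncta)
```

## The measurement model

`svpuncta` quantifies cue-induced presynaptic assembly in co-cultures of
primary neurons and heterologous partner cells. The biological signal is
the clustering of synaptic vesicles (SVs) in axonal segments that touch a
cue-presenting cell; everything the package computes reduces to set
operations on three binary masks derived from the neuron, partner-cell and
SV-marker channels.

Two statistics summarize a field. Writing $a_i$ for the pixel area of
contact zone $i$ (a size-gated connected component of the intersection of
the neuronal-process mask with the dilated partner mask) and $s_i$ for the
SV-mask area inside it,

* **frequency** $= \#\{i : s_i > 0\}/n$ — the probability that a contact
  zone developed at least one SV cluster;
* **density** $= \tfrac1n\sum_i s_i/a_i$ (headline, the unweighted mean of
  per-region coverage) and pooled density $= \sum_i s_i / \sum_i a_i$.

Both density readings are reported because the averaging semantics of
"fraction of overlap area occupied" are ambiguous: the mean of fractions
weights every contact zone equally, the pooled ratio weights by area. They
diverge when coverage correlates with region size; downstream analyses
should pick one and keep it fixed. The same ambiguity exists for frequency
across fields (average of per-field frequencies vs. pooling all regions);
the batch summary emits per-field rows so either aggregate can be formed.

SV puncta outside every contact zone are ignored by construction: they are
not attributable to the presented cue.

## Thresholding

Binarization uses a single global threshold per channel, with foreground
defined by strict inequality (intensity > threshold); the strictness
convention matters only at exact threshold values and is documented so
fixed thresholds are interpretable. `auto_threshold()` implements the
classic Otsu criterion on a 256-bin histogram of the [0, 1] intensity
range — the 8-bit-style binning makes its levels comparable to manual
picks — with ties between equally good splits resolved by averaging, and a
typed error on constant (degenerate-histogram) images rather than an
arbitrary level.

Otsu's split is unreliable when the signal occupies a tiny pixel fraction,
as a punctate vesicle stain does (well under 1% of a field): both classes
of the optimal split then sit inside the background mode and the threshold
collapses onto background. `suggest_threshold()` therefore emulates what a
user does on the histogram: background level = median, spread = MAD,
signal = pixels above median + 4·MAD, threshold = midpoint of background
and median signal. It falls back to Otsu when no appreciable signal
exists. For batch analysis the package deliberately requires *fixed*
thresholds chosen once (e.g. with `suggest_threshold()` or the
`render_threshold_preview()` panels on a trial field): per-field automatic
thresholds make segmentation output a function of each field's histogram
and inflate between-field variance.

Load-time normalization divides by the bit-depth maximum (255 or 65535),
never by the observed maximum, precisely so that one fixed threshold means
the same thing in every field of an experiment.

## Morphology and labeling

Structuring elements are Euclidean disks: the set of pixel centers at
distance ≤ r from the origin. Erosion and dilation are computed through
the exact Euclidean distance transform (dilation: distance-to-foreground
≤ r; erosion: distance-to-background > r), which realizes the disk
definition without kernel rasterization artifacts. Boundary convention:
outside the image counts as foreground for erosion and as background for
dilation, so objects are not eaten at the frame and dilation never invents
off-frame support. Distances compare against r with a 10⁻⁷ slack; since
pixel distances are square roots of integers, this resolves exact ties
(e.g. distance exactly 2 at r = 2 is inside) without ever admitting a
strictly larger offset.

Cell-body removal subtracts the opening of the neuron mask from the neuron
mask. Structures that contain the disk anywhere (somata) are segmented by
the opening and removed; structures thinner than the disk in every
direction (neurites) are untouched. On rasterized disks a few isolated
boundary pixels can survive the subtraction — the opening of a discrete
disk does not always cover its own outermost rasterization ring — which is
harmless downstream (such residue is speck-sized and far smaller than the
overlap gate).

Clean-up order is fixed: area-open all three masks, then remove cell
bodies from the neuron mask, then dilate the partner mask. The order of
the first two steps on the neuron channel is not uniquely determined by
the narrative it mirrors; opening-first was chosen and frozen so that
speckle never seeds the cell-body opening. The "slight" partner dilation
radius defaults to 2 px at 20×.

Connected components use 4- or 8-connectivity (default 8) and are labeled
1..n in raster-scan order (top-to-bottom, left-to-right) of each
component's first pixel, making labels — and therefore per-region tables —
deterministic and platform-independent. The implementation builds the
foreground pixel-adjacency graph and takes its components (igraph); an
independent flood-fill oracle and EBImage's `bwlabel` serve as
cross-checks in the test suite, never as the implementation.

## Default parameters (20×)

| parameter | default | unit | why |
|---|---|---|---|
| `min_area_neuron` | 20 | px | speckle floor below any neurite fragment of interest |
| `min_area_partner` | 50 | px | partner cells are large blobs; kills antibody debris |
| `min_area_sv` | 4 | px | ≈1 µm² at 20×, the smallest resolvable SV cluster at that power |
| `cellbody_disk_radius` | 8 | px | the scale of a soma, ≫ neurite half-width |
| `partner_dilation_radius` | 2 | px | captures edge-hugging SV clusters without bridging cells |
| `min_overlap_area` | 10 | px | discards grazing contacts with no room for a cluster |
| `min_synapse_area` | 3 | px | smallest credible pre/post colocalization at 63× |
| `connectivity` | 8 | — | diagonal neurite steps stay connected |

The 63× preset scales linear sizes ×3 and pixel-count gates ×9. All values
are honest engineering defaults for the stated optics, overridable in
`seg_config()` and echoed into every batch manifest. Pixel size (µm/px) has
no default: it is a required calibration input.

Synapse-mode density is reported per 100 µm² of neuronal-process area. No
standard unit exists for this quantity; area-normalization was chosen over
per-field counts (which depend on how much dendrite is in frame) and
per-dendrite-length density (which requires tracing, out of scope), and
the unit is spelled out in the output header.

## The synthetic generator

`generate_cocult_field()` emulates the assay's geometry, not its optics:
correlated-random-walk neurites of ~3 px width plus disk somata, elliptical
partner blobs, and hard-disk SV puncta placed inside contact zones. Ground
truth is defined on the noiseless masks with the same contact-zone geometry
the pipeline uses (dilation 2 px, gate 10 px, 8-connectivity); each true
region is marked cluster-bearing by an independent Bernoulli draw with the
target frequency — the simplest generative model matching the frequency
statistic — and marked regions receive puncta, clipped to the region, until
coverage reaches the target density greedily; the realized coverage is
recorded, as rasterized disks overshoot targets slightly. Rendering is
constant foreground over constant background plus additive Gaussian noise,
clipped to [0, 1].

Default conditions are the 20× benchmark regime: 512×512 fields dense
enough to carry ≥15 gated contact regions (40 neurites, 18 partner blobs),
target frequency 0.6 and density 0.2 — the magnitude of manually scored
values in this assay — and noise σ = 0.1 against channel contrasts of
0.5/0.6/0.7, i.e. a worst-channel SNR of 5. Partner blobs are kept clear
of somata so that contact zones involve processes only, as axon/partner
contacts do.

What the generator does *not* emulate: the microscope's point-spread
function (an optional Gaussian blur would stand in for the ~300 nm/1 µm
resolvability discussion, but is off by default), photon shot noise,
uneven illumination, astrocyte background, and out-of-focus light.
Passing the recovery benchmarks therefore demonstrates that the
segmentation and bookkeeping are correct and noise-robust under an
idealized image-formation model — not that any particular threshold will
transfer to a given microscope. On real data, thresholds must be chosen
per experiment on trial fields.

`generate_synapse_field()` plants colocalized pre/post punctum pairs on the
neurite mask plus pre-only/post-only decoys, all mutually separated by more
than twice the punctum diameter, so the true synapse count is exact by
construction.

## Numerical and degenerate-case choices

* Empty fields are *flagged*, never zero-filled: a field without contact
  regions yields `empty = TRUE` with `NA` statistics, and an empty neuron
  mask in synapse mode yields an `NA` density. Silent zeros would bias
  condition averages downward.
* `sv_mean_intensity` is `NA` for cluster-free regions (mean over an empty
  set), and is computed from raw, pre-binarization marker intensities —
  binarized means would all be 1.
* A cluster straddling two regions counts once in each region it touches;
  its pixels are attributed to the region containing them, so region SV
  areas always sum to the total in-zone SV area.
* CSV export rounds floats to 6 significant digits; the round-trip is
  exact at that precision. Excel-free CSV keeps the hand-off scriptable.
* The pipeline draws no random numbers; identical configuration and input
  give byte-identical outputs (asserted by file hash in the tests). All
  generator randomness derives from a single integer seed.

## Problem sizes used in validation

The test suite validates every mask operation against brute-force
pixel-set oracles on one hundred random 32×32 instances per operation;
ground-truth recovery runs on twenty 512×512 noisy fields (accuracy ≥87%
per field for frequency and pooled density, against realized truth);
noiseless round-trips on ten 256×256 fields recover frequency exactly and
pooled density within the disk-rasterization slack of 0.01; the Bernoulli
marking model is checked over 200 seeded 96×96 fields against a 3-standard-
error band. These sizes were chosen to exercise every code path at full
fidelity while keeping the suite fast enough to run habitually.

## Known limitations

* Global thresholding cannot rescue fields with strong illumination
  gradients; no local/adaptive mode is provided.
* Touching SV clusters are not split (no watershed); counts are of
  connected clusters, not vesicle pools.
* Colocalization in synapse mode is pixel overlap after clean-up, not
  centroid distance; sub-pixel apposition without mask overlap is missed.
* z-stacks are not projected or registered; each field is a single plane
  of three registered channels.
* Native Zeiss `.lsm` files are not parsed; convert to TIFF.
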