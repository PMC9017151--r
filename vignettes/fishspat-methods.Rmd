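---
title: "Methods: quantifying subcellular spatial distributions with fishspat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying subcellular spatial distributions with fishspat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishspat)
```

# Scope and data model

`fishspat` quantifies where molecules sit inside single cells. Two signal
modalities are supported throughout: single-molecule FISH, where each mRNA
is a diffraction-limited spot with a position `(x, y, z)`, and
immunofluorescence, where protein abundance is a continuous intensity image
`I(x, y)` (the sum over z-slices). The unit of analysis is the
`cell_record`: the cell and nucleus masks, the manually annotated MTOC
position, the signal, and optionally a height map giving the number of
z-slices the cell occupies above each pixel. Records sharing gene, molecule
and condition form an `acquisition_series`; series are stored in a
hierarchical HDF5 repository
(`/{molecule}/{gene}/{condition}/{timepoint}/{image_id}`) with one dataset
per descriptor, so expensive segmentation runs once and every statistic can
be recomputed from the descriptors alone.

Coordinates are 0-based with `x` the column and `y` the row; z counts
slices from the physical bottom of the stack. All geometric statistics are
anchored at the nucleus centroid and oriented by the MTOC, the cell's
polarity landmark; "clockwise" is defined in image coordinates (y pointing
down), where it coincides with increasing `atan2` angle.

# Primary descriptors

**Vignetting and contrast.** Wide-field images lose intensity toward the
corners. The correction multiplies each pixel by the radially symmetric
gain `exp(-d / s)` with `d` the Euclidean distance from the image centre
and `s = sqrt((w/2)^2 (h/2)^2)` by default (the scale is a parameter).
Contrast is then stretched linearly onto `[0, 255]`.

**Cell mask.** The tubulin channel's maximum projection is passed through a
local entropy filter: the Shannon entropy (bits) of the intensity histogram
in a square window (default 30 × 30 px, the value appropriate for
full-resolution acquisitions; small synthetic fixtures use a window scaled
to their feature size). Textured cytoplasm scores high, smooth background
low. The entropy image is binarized before edge detection. The default
level is the midpoint between the low and high entropy plateaus *plus one
bit*: a window straddling the boundary half-and-half gains exactly one bit
of mixture entropy, so the half-coverage contour — the unbiased boundary
estimate — sits one bit above the plateau midpoint. (Running the edge
detector on the raw entropy image instead localizes on the outer slope of
the entropy halo, which we measured to displace the contour by roughly an
eighth of the window and push the disk-fixture Jaccard from ~0.93 down to
~0.70.) A caller-supplied percentile threshold overrides this level for
noisy series. Canny edge detection (Gaussian smoothing, Sobel gradients,
non-maximum suppression, hysteresis at 0.1/0.3 of the maximum magnitude)
traces the contour; dilation and closing bridge gaps, holes are filled, the
mask is eroded back, and the largest connected component is kept — one cell
per image is assumed.

**Nucleus mask.** Same skeleton, but an Otsu threshold on the stretched
DAPI projection replaces the entropy/Canny steps (the entropy pipeline
remains available for poor DAPI signal). Morphology neighborhoods default
to 16–20 px.

**Zero level and height map.** The zero level is the index of the slice
with the maximum summed tubulin intensity (ties resolve to the lowest
index) — the bottom in-focus slice. Each slice at or above it is segmented
(by default with the cheap per-slice Otsu threshold; the full entropy
pipeline is available via `method = "full"` since the choice is not
determined by the procedure description) and the height map records, per
pixel, the highest covering slice. The cell volume is
`sum(h) * pixel_size^2 * z_step` with defaults `1/9.75` µm/px and `0.3` µm
per slice.

**Spot detection.** Per slice: Gaussian smoothing, background subtraction
(the background is a wide Gaussian blur, σ = 10 px), white top-hat
enhancement with a disc (radius 4 px), then Laplacian-of-Gaussian filtering
at the PSF scale (σ = 1.5 px). Local maxima are kept if they exceed both a
relative threshold (0.25 of the maximum response) and a significance floor
of 15 robust standard deviations (MAD) of the response. The two thresholds
are both scale-free, so rescaling the image intensities leaves the spot set
unchanged, while a blank noise image yields no detections (noise maxima
reach ~8–9 MAD; matched-filter responses of real spots exceed ~90 MAD at
peak SNR 10). Two spots closer than about the LoG scale merge into one
detection. Spots below the zero level are discarded when one is supplied.

**Z-line masks.** Myofiber sarcomere boundaries are vertical stripes:
a vertical Sobel operator followed by Gaussian smoothing and Otsu
binarization per slice.

# Quantization

**Peripheral distance map.** One ray per degree is cast from the nucleus
centroid; each ray is split into 100 equidistant points between the nucleus
contour and the first cell-boundary crossing (the first-crossing rule makes
the construction deterministic on non-star-convex masks). Joining the k-th
points yields 100 nested isoline polygons; `D(x, y)` is the deepest polygon
containing the pixel — 100 at the nucleus envelope, 0 at the cell edge.
Because the polygons are star-shaped around the centroid, containment
reduces to comparing the pixel's radius with the polygon's crossing radius
along the pixel's direction, which is monotone in the isoline index; the
implementation bisects that index (30 iterations, i.e. well below one
isoline of resolution) instead of running 100 point-in-polygon tests, and
the test suite checks exact agreement with an even–odd containment oracle
(boundary-tie pixels may differ by one isoline). Cumulative peripheral
regions use `D <= i`, so the region at i = 100 is exactly the cytoplasm;
the strict peripheral mask `{D < p}` is also provided.

**Quadrants.** Two orthogonal axes centred at the nucleus centroid are
rotated over all 360 integer orientations. Pixels and spots are assigned to
integer-degree bins (a 10⁻⁷-degree nudge keeps points lying exactly on a
boundary stable under floating-point perturbations such as an exact 90°
image rotation; the centroid pixel itself, whose angle is undefined, is
excluded). Because quadrant boundaries sit at integer degrees, per-quadrant
counts come exactly from circular sums of the degree histograms, and the
orientation search is a vectorized equivalent of the 360-way brute force.
Two orientation rules are available:

* `max_signal` — retain the orientation maximizing the signal inside the
  MTOC-containing quadrant; quadrants are renumbered Q1 = MTOC quadrant,
  then clockwise. This is the alignment used for distribution profiles,
  where cells must be registered to a common frame. Ties are broken by the
  smallest rotation relative to the MTOC direction; a lowest-absolute-degree
  rule would violate rotation covariance, because the lowest element of a
  tie plateau does not rotate with the image.
* `mtoc_bisect` — anchor the axes so the MTOC direction bisects Q1. This
  orientation does not look at the signal, so quadrant densities remain
  exchangeable under spatial randomness. The MTOC polarity index uses it:
  a signal-maximized Q1 density is inflated by selection even for uniform
  signal (we measured MPI ≈ 0.8 on uniform fixtures under the maximizing
  rule), which would destroy the calibration of any subsequent test.

Relative densities are `c_i = (t_i / a_i) / (T / A)` (signal per area over
mean signal per area), so `sum(c_i a_i) = A` holds as an algebraic
identity, asserted to 1e-9 in the tests. The 3D variant replaces areas by
voxel volumes from the height map.

**Fine-grained segments.** Each quadrant is halved into 45° sectors
(anchored at the MTOC sector) and crossed with `p` isoline bands of equal
isoline count (equal-count rather than equal-volume bands: the former is
determined by the distance map alone and keeps segments comparable across
cells). Segments are ordered concentrically from the nucleus outward,
`segment = (band - 1) * 8 + sector`, giving aligned 8 × p density vectors.

# Statistics

**Peripheral fraction.** Per cell, cumulative peripheral signal divided by
cumulative peripheral volume, normalized by the whole-cytoplasm density;
the series profile is the per-isoline median. The i = 100 entry is exactly
1, a useful internal check. Enrichment against a reference gene is the
elementwise ratio of profiles.

**Volume-corrected noise.**
`Nm = (sd(N)/E(N))^2 − (b·E(V)/(a + b·E(V))) · (Cov(N,V)/(E(N)·E(V)))`,
with `(a, b)` from the least-squares regression of transcript count N on
volume V. When N is exactly proportional to V the terms cancel and Nm = 0
(to rounding); Nm is also invariant to rescaling V, since the regression
absorbs the units. Sample (n−1) moments are used consistently so the
cancellation is exact.

**Cytoplasmic spread.** Centrality is the mean of `(100 − D)/100` over
cytoplasmic spots (1 = all signal at the edge); for protein the same
average runs over cytoplasm pixels whose intensity exceeds the cytoplasmic
mean (the whole-image mean is the documented alternative; the cytoplasmic
mean avoids dependence on how much background the frame contains). Spread
entropy is the Kozachenko–Leonenko k-nearest-neighbour estimate
(`k = 4` by default, the common bias/variance compromise; estimates are in
nats and normalized per series by the maximum). On 2000 uniform points in
the unit square the estimate sits within 0.05 of the closed-form 0; the
residual positive bias (~0.03) is the square's boundary effect on
nearest-neighbour distances.

**MTOC polarity index.** Per cell, the MTOC-quadrant density is compared
with the median of the cell's three non-MTOC densities;
`MPI = 2 · (#exceedances)/n − 1 ∈ [−1, 1]`. For four exchangeable densities
the first exceeds the median of the other three with probability exactly
1/2, and per-image medians make the n events independent, so the two-sided
binomial test is exact. (Pooling one median across the series — the other
reading of the definition — correlates the events through the shared
median and inflated the measured null rejection rate to ~15% at n = 30, so
the per-image median is used.) Uncertainty is a bootstrap over cells (100
resamples by default).

**Distribution profiles and colocalization.** The profile at a time point
is the elementwise median of the aligned 8 × p density vectors. Density
category maps classify segments against the mean ± one standard deviation
of all segment densities. The colocalization score compares mRNA and
protein profiles across time: each pair `(t1, t2)` gets a similarity
`γ'` — the Pearson correlation of the two profiles, optionally after
neighborhood smoothing (each segment averaged with its adjacent sectors in
the same band and adjacent bands in the same sector, which damps
single-segment noise before correlating). The score is the Vargha–Delaney
`A12 = P(α > β) + ½P(α = β)` comparing the similarities of forward-leading
pairs (`t1 < t2`, mRNA observed before protein) against the rest, computed
from ranks and therefore invariant under monotone transforms of γ'.
Degenerate (zero-variance) profiles are excluded with a log message. The
optional permutation test reassigns which pairs count as forward-leading
(pair-label permutation, the choice among the under-determined permutation
groups that needs no extra structure), Monte-Carlo sampled.

**Degree of clustering.** For point patterns, Ripley's
`K(r) = (1/(λ²ν(w))) Σᵢ Nᵢ(r)` with no edge correction — faithful to the
printed estimator; its boundary bias is shared by the permutation null,
which lives in the same window, and cancels in the normalized index. For
continuous intensities the convolution estimator
`Kc(r) = (1/(λ²V)) Σ_{|lag| ≤ r} (I ⋆ I)(lag) − 1/λ` (autocorrelation via
FFT on the pixel lattice; a 3D stack is approximated by its 2D sum
projection, justified by the low axial extent of adherent cells). On a
binarized point pattern the two estimators agree exactly, which the tests
assert. The CSR null redraws the observed number of points uniformly in the
window (literally permuting coordinates would change nothing) or permutes
intensity values among within-mask pixels; 100 permutations by default.
`H(r) = sqrt(K/π) − r` (2D) or `(3K/4π)^(1/3) − r` (3D) — the
normalizations with zero CSR expectation. Envelopes are exact order
statistics (5th largest/smallest of the 100 null curves), so the observed
curve exceeds an envelope with probability exactly 5/101 per radius under
exchangeability. The clustering index is `H* = H/H95` for `H ≥ 0` and
`−H/H5` otherwise (`|H*| > 1` exactly when H leaves the central 90% band);
radii where the dividing percentile has the wrong sign are masked. The
degree of clustering `δ` is the trapezoidal integral of `max(H* − 1, 0)` —
the index is integrated, not H itself, because only H* is normalized to 1
at the envelope. The default radius grid is 60 radii up to 30% of the
equivalent window radius.

Because the envelopes are pointwise, the event `δ > 0` is a union over ~60
correlated radii: under CSR it occurs in roughly a quarter of replicates
(small spurious areas of order 10⁻³), not 5%. A simultaneous envelope
would shrink this, but is not part of the procedure; consumers comparing
conditions should compare δ distributions (as the Thomas-vs-Poisson power
check does) rather than treating any positive δ as significant.

**Reproducibility curve.** For each pool size k, k cells plus one held-out
cell are drawn repeatedly; the deviation is the mean absolute difference
between the held-out density vector and the pooled average, averaged over
draws — decreasing in k for reproducible populations.

**Muscle statistics.** Z-line spacing Z is the median distance between
leading edges of consecutive stripes over all rows, slices and fibers
(centroid-to-centroid is available). Per spot, the distance to the nearest
Z-line pixel in its own slice (0 inside a stripe), computed from a
Euclidean distance transform; slices with ≤ 25 spots are dropped along
with their spots, and spots with no Z-line within radius Z are excluded
(including them at a censored value would distort the profile; the
exclusion is logged). Counts at integer distances (rounding half-up) are
normalized per image by the number of retained spots, and the fiber
profile is the elementwise median — no second normalization after the
median. Internuclear regions are cropped between consecutive nuclei
centroids and split into n half-open vertical bands (n = 20 or 80; integer
break positions differ by at most 1 px), with the same relative-density
normalization as quadrants.

# Synthetic fixtures and what they do (not) show

Every generator is a pure function of its parameters and an explicit seed,
and emits the ground truth needed to compute its expected statistic
independently. The crossbow cell is approximated as a disk plus a
rectangular stem (the statistics under test are shape-agnostic); spots are
uniform (CSR), Thomas-clustered (25 parents, σ = 0.02 of the window side,
mean 12 offspring — the clustered alternative for power checks), or
MTOC-polarized by rejection sampling at a chosen density ratio. Rendered
spot images use Gaussian PSFs (σ = 1.5 px) with Gaussian read noise at
peak SNR 10; striated fibers use a 15-px stripe period by default, the
spacing reported for real myofiber data, with spots either uniform or
stripe-anchored at 2 px jitter.

The fixtures emulate geometry, counting statistics and noise — not optics.
No aberration, depth attenuation, autofluorescence, segmentation ambiguity
between touching cells, or chromatic misregistration is simulated, so
passing tests certify the estimators and their calibration, not
end-to-end robustness on raw microscope data.

Problem sizes in the test suite and acceptance script: 200 CSR fixtures of
300 points with 100 permutations each for the Ripley calibration; 50
Thomas and 50 matched Poisson replicates for power; 100 null and 100
polarized series of 30 cells for the MPI; 1000 random similarity matrices
for the A12 oracle; 20 images of 20 spots for detection; cohorts of 8
fibers of 2000 spots for the muscle checks. These sizes put the
Monte-Carlo error of each reported fraction near or below one percentage
point.

# Known limitations

* No edge correction in K: absolute K values are biased low near the
  boundary (about 4–5% at r = 0.05 in the unit square); only
  envelope-normalized quantities should be compared across windows.
* The isoline construction assumes the nucleus centroid sees the boundary
  in every direction; on strongly concave masks the first-crossing rule
  truncates the map to the near part of the cell, and isoline polygons may
  self-intersect.
* Pointwise envelopes make `δ > 0` anti-conservative as a significance
  statement (see above).
* Protein "peaks" for spread statistics are pixels above the cytoplasmic
  mean intensity; no sub-pixel peak fitting is attempted.
* The HDF5 layout is this package's own normative layout; externally
  produced descriptor files need their spot-coordinate convention checked
  (this package stores voxel units).
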