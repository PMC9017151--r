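# fishspat

Spatial statistics for subcellular distributions of mRNA and protein in
single cells.

Single-molecule FISH resolves individual transcripts as diffraction-limited
spots; immunofluorescence gives the corresponding protein as a continuous
intensity field. `fishspat` turns multichannel 3D stacks of micropatterned
cells (or precomputed descriptors in a hierarchical HDF5 repository) into
quantitative answers to where molecules sit: are they peripheral, are they
clustered, are they polarized toward the MTOC, and do mRNA and protein
distributions track each other over time? A myofiber module asks the same
questions relative to sarcomere Z-lines, and a fully seeded synthetic-cell
generator makes every statistic testable without any imaging data.

## What it computes

For each cell the package extracts primary descriptors — cell, nucleus and
cytoplasm masks (entropy-filter/Canny and Otsu pipelines), the zero level
(bottom in-focus slice), a per-pixel height map and cell volume, mRNA spot
positions (top-hat + Laplacian-of-Gaussian detection) or summed protein
intensity. Cells are then quantized around the nucleus centroid: a
peripheral distance map of 100 isolines between the nucleus envelope and
the cell edge, MTOC-anchored quadrants, and fine-grained 8 × p segments.
On top of these it provides:

* **Peripheral fraction** `F(i)`: median relative signal density in
  cumulative regions from the cell edge to isoline i, with enrichment
  ratios against a reference gene.
* **Volume-corrected noise**
  `Nm = (σ_N/E[N])² − (b·E[V]/(a + b·E[V])) · Cov(N,V)/(E[N]·E[V])` —
  transcript-count variability not explained by cell volume (a, b from the
  regression of N on V).
* **Cytoplasmic spread**: centrality (mean normalized distance from the
  nucleus envelope) and Kozachenko–Leonenko k-NN entropy.
* **MTOC polarity index** `MPI = 2·|{cells: c_MTOC > m}|/n − 1 ∈ [−1, 1]`
  with an exact binomial test and bootstrap spread.
* **Distribution profiles** (median 8 × p density vectors), density
  category maps, and the **colocalization score** — the Vargha–Delaney
  `A12 = P(α > β) + ½P(α = β)` comparing profile correlations of
  forward-leading time pairs (mRNA before protein) against the rest.
* **Degree of clustering** for both modalities: Ripley's
  `K(r) = (1/(λ²ν(w))) Σᵢ Nᵢ(r)` for spots and a convolution
  (autocorrelation) estimator `Kc` for intensities, normalized to
  `H* = H/H₉₅` against 100-permutation CSR envelopes;
  `δ = ∫ max(H*−1, 0) dr` is a scalar clustering strength comparable
  across molecules.
* **Muscle statistics**: Z-line spacing, per-spot Z-line distance
  profiles, internuclear vertical quantization (n = 20/80 bands) and local
  density striation profiles.

## Worked example

Twenty synthetic crossbow cells with a 3-fold spot enrichment in the
MTOC-facing quadrant, plus one Thomas-clustered pattern:

```r
library(fishspat)

skel <- make_crossbow_cell(radius = 60, nucleus_radius = 15, mtoc_angle = 40)
cells <- lapply(1:20, function(i) {
  sp <- make_polarized_spots(skel$cell_mask, skel$nucleus_centroid, skel$mtoc,
                             quadrant_ratio = 3, n = 80, seed = i)
  synthetic_cell_record(skel, spots = sp, id = sprintf("cell%02d", i))
})
series <- acquisition_series(cells, condition = "simulated")
series
#> <acquisition_series> synthGene mRNA (simulated): 20 cell(s), t = 2 h

mpi(series, n_boot = 100, seed = 1)
#> <mpi_result> MPI = 1.000 (p = 1.91e-06, boot sd = 0.000, n = 20, cytoplasmic)
```

Every one of the 20 cells has a higher relative density in its MTOC
quadrant than in its other quadrants, so the polarity index sits at its
upper bound of 1 and the binomial test is decisive — the generator's
enrichment is recovered. Clustering separates just as cleanly:

```r
cyto <- cytoplasm_mask(skel$cell_mask, skel$nucleus_mask)
clustered <- sample_thomas_spots(skel$cell_mask, n_parents = 15, sigma = 2,
                                 mean_offspring = 15, seed = 3)
ripley_clustering(points = clustered[, 1:2], window = win_mask(cyto),
                  n_permutations = 100, seed = 1)
#> <clustering_result> point mode (2D), 60 radii <= 17.7, degree = 798.8

# the same number of uniform spots:
#> CSR degree: 0
```

The clustered pattern's H* curve leaves the permutation envelope over the
cluster-scale radii, integrating to a large degree of clustering, while
uniform spots stay inside the band (`δ = 0`). Peripheral fractions of the
(radially uniform) polarized cells sit at 1 across isolines, as they
should:

```r
dm <- peripheral_distance_map(cyto, skel$nucleus_mask, skel$nucleus_centroid)
prof <- peripheral_fraction_profile(series, dmaps = rep(list(dm), 20))
prof[c(10, 50, 100), ]
#> # A tibble: 3 × 2
#>   isoline     F
#>     <int> <dbl>
#> 1      10 0.996
#> 2      50 0.998
#> 3     100 1
```

Result objects are tidyverse-friendly: `tidy()` and `glance()` return
tibbles, `autoplot()` draws the standard figure for each result type
(H* curves with envelopes, peripheral profiles, Z-line histograms), and a
thin command-line wrapper (`inst/cli/fishspat`) exposes `simulate`,
`stats` and `muscle` subcommands.

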