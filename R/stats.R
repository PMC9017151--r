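# Statistics over acquisition series: peripheral fraction, volume-corrected
# noise, cytoplasmic spread, MTOC polarity index, distribution profiles,
# colocalization score, pooled-deviation reproducibility.

#' Per-record peripheral relative density vector
#'
#' For each isoline index i (1..100), the density of cytoplasmic signal in
#' the cumulative peripheral region `{D <= i}`, divided by the region's
#' measure and normalized by the total cytoplasmic density:
#' `c_i = (N_i / V_i) / (N / V_cyt)`. The full-cytoplasm entry (i = 100) is
#' 1 by construction.
#'
#' @param record a [cell_record()].
#' @param dmap the record's [peripheral_distance_map()].
#' @return Numeric vector of length 100.
#' @export
peripheral_density_vector <- function(record, dmap) {
  V <- dmap$peripheral_volumes
  if (record$molecule == "mRNA") {
    cyto <- cytoplasm_mask(record$cell_mask, record$nucleus_mask)
    sp <- record$spots
    keep <- .inside_mask(cyto, sp[, 1], sp[, 2])
    D <- dmap_lookup(dmap, sp[keep, 1], sp[keep, 2])
    counts <- cumsum(tabulate(pmin(pmax(D, 1L), 100L), nbins = 100))
  } else {
    Dpix <- dmap$D
    vals <- record$intensity
    tot <- vapply(1:100, function(i) sum(vals[!is.na(Dpix) & Dpix <= i]), numeric(1))
    counts <- tot
  }
  N <- counts[100]
  if (N <= 0) return(rep(NA_real_, 100))
  dens <- ifelse(V > 0, counts / V, 0)
  dens / (N / V[100])
}

#' Peripheral fraction profile of a series
#'
#' Median over records of the per-record peripheral relative density
#' vectors. Records without a distance map are skipped (logged).
#'
#' @param series an [acquisition_series()].
#' @param dmaps list of [peripheral_distance_map()] parallel to
#'   `series$records` (`NULL` entries are skipped).
#' @return An object of class `peripheral_profile`: a tibble with columns
#'   `isoline` and `F`, plus gene/molecule attributes.
#' @export
peripheral_fraction_profile <- function(series, dmaps) {
  vecs <- list()
  for (i in seq_along(series$records)) {
    if (is.null(dmaps[[i]])) {
      message(sprintf("record %s has no distance map; skipped", series$records[[i]]$id))
      next
    }
    vecs[[length(vecs) + 1L]] <- peripheral_density_vector(series$records[[i]], dmaps[[i]])
  }
  if (!length(vecs)) abort("no record has a distance map")
  M <- do.call(rbind, vecs)
  out <- tibble(isoline = 1:100, F = apply(M, 2, median, na.rm = TRUE))
  structure(out, gene = series$gene, molecule = series$molecule,
            n_records = length(vecs),
            class = c("peripheral_profile", class(out)))
}

#' Peripheral enrichment relative to a reference profile
#'
#' Elementwise ratio of two peripheral fraction profiles (e.g. a gene of
#' interest over a uniform reference gene).
#'
#' @param profile,reference [peripheral_fraction_profile()] results.
#' @return Tibble with columns `isoline` and `enrichment`.
#' @export
peripheral_enrichment <- function(profile, reference) {
  tibble(isoline = profile$isoline, enrichment = profile$F / reference$F)
}

#' @rdname peripheral_fraction_profile
#' @param object a `peripheral_profile`.
#' @param ... unused.
#' @export
autoplot.peripheral_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$isoline, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "isoline (cell edge → nucleus)",
                  y = "median relative density") +
    ggplot2::theme_minimal()
}

#' Volume-corrected expression noise
#'
#' Cell-to-cell variability in transcript count that cannot be explained by
#' cell volume:
#' `Nm = (sd(N)/E(N))^2 - (b E(V) / (a + b E(V))) * (Cov(N,V) / (E(N) E(V)))`
#' with `(a, b)` the intercept and slope of the least-squares regression of
#' N on V. When N is exactly proportional to V the two terms cancel and
#' `Nm = 0`.
#'
#' @param summaries a data frame with columns `total_cytoplasmic` (N) and
#'   `volume_um3` (V), e.g. rows of [signal_summary()].
#' @return Scalar `Nm`.
#' @export
volume_corrected_noise <- function(summaries) {
  N <- summaries$total_cytoplasmic
  V <- summaries$volume_um3
  if (length(N) < 3) abort("need at least 3 cells")
  if (any(V <= 0) || var(V) == 0)
    abort("degenerate volumes: regression of N on V is undefined",
          class = "fishspat_degenerate_error")
  fit <- coef(lm(N ~ V))
  a <- fit[[1]]; b <- fit[[2]]
  (sd(N) / mean(N))^2 -
    (b * mean(V) / (a + b * mean(V))) * (cov(N, V) / (mean(N) * mean(V)))
}

#' Cytoplasmic centrality
#'
#' Mean peripheral position of the cytoplasmic signal: for each spot (or,
#' for protein, each cytoplasm pixel whose intensity exceeds the cytoplasmic
#' mean), `(100 - D) / 100`. 1 means all signal at the cell edge, 0 all at
#' the nucleus envelope.
#'
#' @param record a [cell_record()].
#' @param dmap the record's [peripheral_distance_map()].
#' @return Scalar in `[0, 1]`.
#' @export
centrality <- function(record, dmap) {
  cyto <- cytoplasm_mask(record$cell_mask, record$nucleus_mask)
  if (record$molecule == "mRNA") {
    sp <- record$spots
    keep <- .inside_mask(cyto, sp[, 1], sp[, 2])
    if (!any(keep)) abort("no cytoplasmic spots", class = "fishspat_undefined_error")
    D <- dmap_lookup(dmap, sp[keep, 1], sp[keep, 2])
  } else {
    vals <- record$intensity[unclass(cyto)]
    thr <- mean(vals)
    sel <- unclass(cyto) & record$intensity > thr
    if (!any(sel)) abort("no above-mean pixels", class = "fishspat_undefined_error")
    D <- dmap$D[sel]
    D <- D[!is.na(D)]
  }
  mean((100 - D) / 100)
}

#' Kozachenko-Leonenko entropy of a point set
#'
#' k-nearest-neighbour differential entropy estimate (in nats):
#' `H = psi(n) - psi(k) + log(c_d) + (d/n) sum_i log(eps_i)` with `eps_i`
#' the distance from point i to its k-th neighbour and `c_d` the unit-ball
#' volume. For 2000 uniform points on the unit square the estimate is close
#' to the closed-form value 0.
#'
#' @param points n x d matrix (d = 2 or 3).
#' @param k neighbour order.
#' @return Scalar entropy estimate, nats.
#' @export
spread_entropy <- function(points, k = 4) {
  points <- as.matrix(points)
  n <- nrow(points); d <- ncol(points)
  if (n < k + 1) abort("need at least k + 1 points")
  eps <- FNN::knn.dist(points, k = k)[, k]
  if (any(eps == 0))
    abort("duplicate points make the entropy estimate degenerate",
          class = "fishspat_degenerate_error")
  cd <- if (d == 2) pi else 4 * pi / 3
  digamma(n) - digamma(k) + log(cd) + d * mean(log(eps))
}

#' Normalize entropies across a series
#'
#' Divides by the maximum so the most spread cell scores 1.
#'
#' @param h vector of entropy estimates.
#' @return Vector of the same length with maximum 1.
#' @export
normalize_entropy <- function(h) h / max(h)

# per-record quadrant densities, optionally restricted to the peripheral
# region {D < p}
.quadrant_densities <- function(record, geom = NULL, dmap = NULL, p = NULL) {
  q <- quadrantize(record, geom, orientation = "mtoc_bisect")
  if (is.null(p)) return(q$parts$c)
  if (is.null(dmap)) abort("peripheral MPI needs distance maps")
  labels <- q$quadrant_labels
  region <- !is.na(dmap$D) & dmap$D < p
  a_i <- vapply(1:4, function(k) sum(region & labels == k, na.rm = TRUE), numeric(1))
  if (record$molecule == "mRNA") {
    sp <- q$signal$spots
    D <- dmap_lookup(dmap, sp[, 1], sp[, 2])
    lab <- q$label_of_bin[q$signal$spot_bin + 1L]
    t_i <- vapply(1:4, function(k) sum(lab == k & D < p), numeric(1))
  } else {
    t_i <- vapply(1:4, function(k) sum(record$intensity[region & labels == k], na.rm = TRUE), numeric(1))
  }
  TT <- sum(t_i); A <- sum(a_i)
  ifelse(a_i > 0 & TT > 0, (t_i / a_i) / (TT / A), 0)
}

#' MTOC polarity index
#'
#' For each quantized cell the MTOC quadrant density is compared against
#' `m`, the median of the cell's three non-MTOC quadrant densities, and
#' `MPI = 2 |{cells with MTOC density > m}| / |S| - 1`, in `[-1, 1]`.
#' Significance comes from a two-sided binomial test of the exceedance
#' count against probability 1/2; with the per-image median the exceedance
#' events are independent fair coin flips under quadrant exchangeability
#' (for four exchangeable densities, the first exceeds the median of the
#' other three with probability exactly 1/2), so the binomial reference
#' distribution is exact. The spread is estimated by bootstrap over cells.
#'
#' @param series an [acquisition_series()].
#' @param region `"cytoplasmic"` (whole cytoplasm) or `"peripheral"`
#'   (restricted to `{D < p}`).
#' @param p peripheral percent when `region = "peripheral"`.
#' @param dmaps list of distance maps (needed for the peripheral region).
#' @param geoms optional list of precomputed [quadrant_geometry()] objects.
#' @param n_boot bootstrap resamples.
#' @param seed optional seed for the bootstrap.
#' @return An object of class `mpi_result` with elements `mpi`, `p_value`,
#'   `boot_sd`, `n_images`.
#' @export
mpi <- function(series, region = c("cytoplasmic", "peripheral"), p = 30,
                dmaps = NULL, geoms = NULL, n_boot = 100, seed = NULL) {
  region <- match.arg(region)
  recs <- series$records
  if (!length(recs)) abort("empty series")
  pp <- if (region == "peripheral") p else NULL
  dens <- map(seq_along(recs), function(i) {
    .quadrant_densities(recs[[i]],
                        geom = if (!is.null(geoms)) geoms[[i]] else NULL,
                        dmap = if (!is.null(dmaps)) dmaps[[i]] else NULL,
                        p = pp)
  })
  exceed <- map_lgl(dens, ~ .x[1] > median(.x[2:4]))
  stat <- function(idx) 2 * mean(exceed[idx]) - 1
  cnt <- sum(exceed)
  n <- length(recs)
  boot <- function() {
    vapply(seq_len(n_boot), function(b) stat(sample.int(n, n, replace = TRUE)),
           numeric(1))
  }
  bs <- if (!is.null(seed)) withr::with_seed(seed, boot()) else boot()
  structure(
    list(mpi = 2 * cnt / n - 1,
         p_value = binom.test(cnt, n, 0.5)$p.value,
         boot_sd = sd(bs), n_images = n, region = region),
    class = "mpi_result"
  )
}

#' @export
print.mpi_result <- function(x, ...) {
  cat(sprintf("<mpi_result> MPI = %.3f (p = %.3g, boot sd = %.3f, n = %d, %s)\n",
              x$mpi, x$p_value, x$boot_sd, x$n_images, x$region))
  invisible(x)
}

#' @rdname mpi
#' @param x an `mpi_result`.
#' @param ... unused.
#' @export
tidy.mpi_result <- function(x, ...) {
  tibble(mpi = x$mpi, p_value = x$p_value, boot_sd = x$boot_sd,
         n_images = x$n_images, region = x$region)
}

#' @rdname mpi
#' @export
glance.mpi_result <- function(x, ...) tidy(x)

#' Median spatial distribution profile
#'
#' Elementwise median of aligned fine-grained density vectors over the
#' records of one time point.
#'
#' @param quants list of fine-grained [fine_grained_segments()] results with
#'   identical segment dimensions.
#' @return An object of class `distribution_profile`: tibble `segment`,
#'   `sector`, `band`, `c_bar`.
#' @export
distribution_profile <- function(quants) {
  ps <- unique(map_int(quants, ~ as.integer(.x$n_bands)))
  if (length(ps) != 1)
    abort("records quantized with different band counts", class = "fishspat_parameter_error")
  M <- do.call(rbind, map(quants, ~ .x$parts$c))
  out <- quants[[1]]$parts[, c("segment", "sector", "band")]
  out$c_bar <- apply(M, 2, median)
  structure(out, n_bands = ps, class = c("distribution_profile", class(out)))
}

#' Density categories of a median profile
#'
#' Classifies each segment as `high` (above mean + sd), `low` (below
#' mean - sd) or `mid` (within one standard deviation of the mean of all
#' segment densities).
#'
#' @param c_bar numeric vector of segment densities (or a
#'   `distribution_profile`).
#' @return Factor vector with levels `low`, `mid`, `high`.
#' @export
density_category_map <- function(c_bar) {
  if (inherits(c_bar, "distribution_profile")) c_bar <- c_bar$c_bar
  mu <- mean(c_bar); s <- sd(c_bar)
  if (is.na(s)) s <- 0
  out <- rep("mid", length(c_bar))
  out[c_bar > mu + s] <- "high"
  out[c_bar < mu - s] <- "low"
  factor(out, levels = c("low", "mid", "high"))
}

#' Vargha-Delaney A12 effect size
#'
#' `P(alpha > beta) + 0.5 P(alpha = beta)` for a value drawn from `x1`
#' against one drawn from `x2`, computed from ranks (so it is invariant to
#' any strictly monotone transform).
#'
#' @param x1,x2 numeric vectors.
#' @return Scalar in `[0, 1]`.
#' @export
vd_a12 <- function(x1, x2) {
  m <- length(x1); n <- length(x2)
  if (!m || !n) abort("both groups must be non-empty")
  r <- rank(c(x1, x2))
  (sum(r[seq_len(m)]) / m - (m + 1) / 2) / n
}

# neighborhood smoothing on the 8 x p sector/band lattice: each segment
# averaged with its adjacent sectors (same band) and adjacent bands (same
# sector)
smooth_segments <- function(c_vec, n_sectors = 8) {
  p <- length(c_vec) / n_sectors
  M <- matrix(c_vec, nrow = n_sectors) # [sector, band]
  out <- M
  for (s in seq_len(n_sectors)) {
    for (b in seq_len(p)) {
      nb <- c(M[s, b],
              M[(s %% n_sectors) + 1, b],
              M[((s - 2) %% n_sectors) + 1, b],
              if (b > 1) M[s, b - 1],
              if (b < p) M[s, b + 1])
      out[s, b] <- mean(nb)
    }
  }
  as.vector(out)
}

#' Colocalization score
#'
#' Measures the interdependence of mRNA and protein spatial distributions
#' across time. For every time-point pair `(t1, t2)` the similarity
#' `gamma'(t1, t2)` is the Pearson correlation of the two (optionally
#' neighborhood-smoothed) density profiles. The score is the Vargha-Delaney
#' A12 effect size of the similarities of the forward-leading pairs
#' `S1 = {t1 < t2}` (mRNA observed before protein) against all other pairs.
#' Pairs with a degenerate (zero-variance) profile are excluded with a log
#' message. An optional Monte-Carlo permutation test reassigns pair labels.
#'
#' @param mrna_profiles named list of mRNA density vectors, names are time
#'   points (numeric, hours).
#' @param protein_profiles named list of protein density vectors.
#' @param smoothing apply neighborhood smoothing on the 8-sector lattice.
#' @param n_sectors sectors per band (for smoothing).
#' @param n_perm optional number of label permutations for a p-value.
#' @param seed optional seed for the permutation test.
#' @param region free-text label (`"global"` or `"peripheral"`) carried in
#'   the result.
#' @return An object of class `cs_result` with elements `a12`,
#'   `similarity` (|T1| x |T2| matrix), `permutation_p`, `region`.
#' @export
colocalization_score <- function(mrna_profiles, protein_profiles,
                                 smoothing = TRUE, n_sectors = 8,
                                 n_perm = NULL, seed = NULL,
                                 region = "global") {
  t1 <- as.numeric(names(mrna_profiles))
  t2 <- as.numeric(names(protein_profiles))
  if (anyNA(t1) || anyNA(t2)) abort("profile lists must be named by numeric time points")
  prep <- function(v) if (smoothing) smooth_segments(v, n_sectors) else v
  P1 <- map(mrna_profiles, prep)
  P2 <- map(protein_profiles, prep)
  sim <- matrix(NA_real_, length(t1), length(t2), dimnames = list(t1, t2))
  for (i in seq_along(t1)) for (j in seq_along(t2)) {
    a <- P1[[i]]; b <- P2[[j]]
    if (sd(a) == 0 || sd(b) == 0) {
      message(sprintf("degenerate profile pair (t1=%g, t2=%g) excluded", t1[i], t2[j]))
      next
    }
    sim[i, j] <- cor(a, b)
  }
  fwd <- outer(t1, t2, `<`)
  ok <- !is.na(sim)
  s1 <- sim[fwd & ok]; s2 <- sim[!fwd & ok]
  if (!length(s1) || !length(s2))
    abort("need non-empty forward-leading and backward pair sets")
  a12 <- vd_a12(s1, s2)
  perm_p <- NULL
  if (!is.null(n_perm)) {
    vals <- sim[ok]; n1 <- length(s1)
    run <- function() {
      stats <- vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(length(vals), n1)
        vd_a12(vals[idx], vals[-idx])
      }, numeric(1))
      mean(stats >= a12)
    }
    perm_p <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  }
  structure(list(a12 = a12, similarity = sim, permutation_p = perm_p,
                 region = region),
            class = "cs_result")
}

#' @export
print.cs_result <- function(x, ...) {
  cat(sprintf("<cs_result> A12 = %.3f (%s)%s\n", x$a12, x$region,
              if (!is.null(x$permutation_p)) sprintf(", perm p = %.3g", x$permutation_p) else ""))
  invisible(x)
}

#' @rdname colocalization_score
#' @param x a `cs_result`.
#' @param ... unused.
#' @export
tidy.cs_result <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$similarity))) |>
    setNames(c("t_mrna", "t_protein", "gamma")) |>
    mutate(t_mrna = as.numeric(as.character(.data$t_mrna)),
           t_protein = as.numeric(as.character(.data$t_protein)),
           forward = .data$t_mrna < .data$t_protein)
}

#' @rdname colocalization_score
#' @export
glance.cs_result <- function(x, ...) {
  tibble(a12 = x$a12, region = x$region,
         permutation_p = x$permutation_p %||% NA_real_)
}

#' Pooled-deviation reproducibility curve
#'
#' For each pool size k, repeatedly draws k cells plus one held-out cell and
#' measures the mean absolute difference between the held-out density vector
#' and the pooled (averaged) vector; reports the mean over draws. On
#' reproducible (e.g. micropatterned) cells the curve decreases with k.
#'
#' @param vectors list of per-cell density vectors of equal length (e.g.
#'   circular-isoline quantized distributions).
#' @param pool_sizes vector of pool sizes (each < number of cells).
#' @param n_draws random draws per pool size.
#' @param seed optional seed.
#' @return Tibble with columns `pool_size` and `deviation`.
#' @export
pooled_deviation_profile <- function(vectors, pool_sizes = 1:20, n_draws = 50,
                                     seed = NULL) {
  n <- length(vectors)
  if (any(pool_sizes >= n))
    abort("pool sizes must be smaller than the number of cells",
          class = "fishspat_parameter_error")
  M <- do.call(rbind, vectors)
  run <- function() {
    map_dbl(pool_sizes, function(k) {
      devs <- vapply(seq_len(n_draws), function(d) {
        idx <- sample.int(n, k + 1)
        held <- M[idx[1], ]
        pooled <- colMeans(M[idx[-1], , drop = FALSE])
        mean(abs(held - pooled))
      }, numeric(1))
      mean(devs)
    })
  }
  dev <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  tibble(pool_size = pool_sizes, deviation = dev)
}

#' Render mRNA spots as a continuous intensity image
#'
#' For continuous-signal analyses of mRNA (e.g. translation-inhibition
#' series), spots are convolved with a Gaussian kernel into an intensity
#' image so the immunofluorescence code paths apply; 2D only.
#'
#' @param record an mRNA [cell_record()].
#' @param sigma Gaussian kernel width, px.
#' @return A protein-mode [cell_record()] with the rendered intensity.
#' @export
spots_to_intensity <- function(record, sigma = 2) {
  if (record$molecule != "mRNA") abort("expected an mRNA record", class = "fishspat_type_error")
  d <- dim(record$cell_mask)
  img <- matrix(0, d[1], d[2])
  sp <- record$spots
  if (nrow(sp)) {
    at <- .xy_to_idx(sp[, 1:2, drop = FALSE], d)
    at[, 1] <- pmin(pmax(at[, 1], 1L), d[1])
    at[, 2] <- pmin(pmax(at[, 2], 1L), d[2])
    for (i in seq_len(nrow(at))) img[at[i, 1], at[i, 2]] <- img[at[i, 1], at[i, 2]] + 1
    img <- EBImage::gblur(img, sigma, boundary = "replicate")
    img <- pmax(img, 0)
  }
  cell_record(paste0(record$id, "_cont"), "protein", record$gene,
              record$timepoint_h, record$cell_mask, record$nucleus_mask,
              record$mtoc, intensity = img,
              nucleus_centroid = record$nucleus_centroid,
              pixel_size_xy = record$pixel_size_xy, z_step = record$z_step)
}
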