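# Ground-truthed synthetic cells, intensity fields and myofibers. Every
# generator is a pure function of its parameters and seed (randomness is
# scoped with withr::with_seed; no global state is consumed or left behind),
# and each fixture carries the truth needed to compute its expected
# statistics independently.

.with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

disk_mask <- function(size, cx, cy, r) {
  x <- matrix(rep(0:(size - 1), each = size), size)
  y <- matrix(rep(0:(size - 1), times = size), size)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

#' Synthetic crossbow-shaped cell skeleton
#'
#' Emulates a cell polarized on a crossbow micropattern: a disk body with a
#' rectangular stem, a centred nucleus, and an MTOC placed on a mid-radius
#' ring at a chosen angle. The crossbow is approximated as disk plus stem;
#' the statistics under test are shape-agnostic.
#'
#' @param radius cell body radius, px.
#' @param nucleus_radius nucleus radius, px (must be smaller).
#' @param mtoc_angle MTOC angle in degrees (image convention, y down).
#' @param stem add the stem rectangle.
#' @param n_slices when given, a dome-shaped height map with this many
#'   slices is attached.
#' @param seed accepted for interface uniformity (the skeleton is
#'   deterministic).
#' @return List with `cell_mask`, `nucleus_mask`, `nucleus_centroid`,
#'   `mtoc`, and optionally `height_map`.
#' @export
make_crossbow_cell <- function(radius = 80, nucleus_radius = 20,
                               mtoc_angle = 0, stem = TRUE, n_slices = NULL,
                               seed = NULL) {
  if (nucleus_radius >= radius)
    abort("nucleus_radius must be smaller than radius", class = "fishspat_geometry_error")
  size <- 2L * ceiling(radius * 1.35) + 1L
  cx <- (size - 1) / 2; cy <- (size - 1) / 2
  cell <- disk_mask(size, cx, cy, radius)
  if (stem) {
    x <- matrix(rep(0:(size - 1), each = size), size)
    y <- matrix(rep(0:(size - 1), times = size), size)
    cell <- cell | (abs(x - cx) <= 0.18 * radius & y >= cy & y <= cy + 1.25 * radius)
  }
  nuc <- disk_mask(size, cx, cy, nucleus_radius)
  th <- mtoc_angle * pi / 180
  mtoc <- c(cx + 0.6 * radius * cos(th), cy + 0.6 * radius * sin(th))
  hm <- NULL
  if (!is.null(n_slices)) {
    x <- matrix(rep(0:(size - 1), each = size), size)
    y <- matrix(rep(0:(size - 1), times = size), size)
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    hm <- matrix(0L, size, size)
    inside <- cell
    rel <- pmin(r / (radius * 1.3), 1)
    hm[inside] <- pmax(1L, round(n_slices * sqrt(pmax(1 - rel[inside]^2, 0))))
  }
  list(cell_mask = binary_mask(cell, "cell"),
       nucleus_mask = binary_mask(nuc, "nucleus"),
       nucleus_centroid = c(cx, cy), mtoc = mtoc, height_map = hm,
       radius = radius)
}

#' Assemble a cell record from a skeleton and a signal
#'
#' @param skel a [make_crossbow_cell()] skeleton.
#' @param spots spot matrix (mRNA) or `NULL`.
#' @param intensity intensity matrix (protein) or `NULL`.
#' @param id,gene,timepoint_h metadata.
#' @return A [cell_record()].
#' @export
synthetic_cell_record <- function(skel, spots = NULL, intensity = NULL,
                                  id = "synthetic", gene = "synthGene",
                                  timepoint_h = 2) {
  cell_record(id, molecule = if (is.null(intensity)) "mRNA" else "protein",
              gene = gene, timepoint_h = timepoint_h,
              cell_mask = skel$cell_mask, nucleus_mask = skel$nucleus_mask,
              mtoc = skel$mtoc, spots = spots, intensity = intensity,
              nucleus_centroid = skel$nucleus_centroid,
              height_map = skel$height_map)
}

#' Uniform (CSR) spots inside a mask
#'
#' n points uniform over the mask footprint (pixel plus sub-pixel jitter);
#' z uniform within the local height when a height map is given.
#'
#' @param mask a [binary_mask()].
#' @param n number of spots.
#' @param seed integer seed.
#' @param height_map optional height map for 3D z-coordinates.
#' @return n x 3 spot matrix.
#' @export
sample_poisson_spots <- function(mask, n, seed = 1, height_map = NULL) {
  .with_seed(seed, {
    idx <- which(unclass(mask), arr.ind = TRUE)
    prob <- if (is.null(height_map)) NULL else height_map[idx]
    i <- sample.int(nrow(idx), n, replace = TRUE, prob = prob)
    x <- idx[i, 2] - 1 + runif(n, -0.499, 0.499)
    y <- idx[i, 1] - 1 + runif(n, -0.499, 0.499)
    z <- if (is.null(height_map)) rep(0, n) else runif(n, 0, height_map[idx][i])
    cbind(x = x, y = y, z = z)
  })
}

#' Thomas-process (clustered) spots inside a mask
#'
#' Uniform parent points; offspring displaced by isotropic Gaussian noise,
#' discarded if they leave the mask. The returned matrix carries the truth
#' (`parents`, `parent_of`) as attributes.
#'
#' @param mask a [binary_mask()].
#' @param n_parents number of cluster parents.
#' @param sigma offspring displacement sd, px.
#' @param mean_offspring Poisson mean offspring per parent.
#' @param seed integer seed.
#' @return m x 3 spot matrix with truth attributes.
#' @export
sample_thomas_spots <- function(mask, n_parents = 25, sigma = 2,
                                mean_offspring = 12, seed = 1) {
  .with_seed(seed, {
    idx <- which(unclass(mask), arr.ind = TRUE)
    pi_ <- sample.int(nrow(idx), n_parents, replace = TRUE)
    px <- idx[pi_, 2] - 1; py <- idx[pi_, 1] - 1
    counts <- rpois(n_parents, mean_offspring)
    ox <- rep(px, counts) + rnorm(sum(counts), 0, sigma)
    oy <- rep(py, counts) + rnorm(sum(counts), 0, sigma)
    parent <- rep(seq_len(n_parents), counts)
    keep <- .inside_mask(mask, ox, oy)
    out <- cbind(x = ox[keep], y = oy[keep], z = 0)
    attr(out, "parents") <- cbind(x = px, y = py)
    attr(out, "parent_of") <- parent[keep]
    out
  })
}

#' MTOC-polarized spots
#'
#' Spot density inside the MTOC-containing quadrant is `quadrant_ratio`
#' times the density elsewhere (rejection sampling; `ratio = 1` is
#' uniform). The quadrant is centred on the MTOC direction.
#'
#' @param mask a [binary_mask()].
#' @param centroid nucleus centroid `(x, y)` anchoring the quadrant axes.
#' @param mtoc MTOC `(x, y)`.
#' @param quadrant_ratio density ratio (>= 1).
#' @param n number of spots.
#' @param seed integer seed.
#' @return n x 3 spot matrix; the anchoring orientation is attached as the
#'   `orientation_deg` attribute.
#' @export
make_polarized_spots <- function(mask, centroid, mtoc, quadrant_ratio = 3,
                                 n = 100, seed = 1) {
  th_m <- .angle_deg(mtoc[1], mtoc[2], centroid[1], centroid[2])
  d0 <- (floor(th_m) - 45) %% 360
  .with_seed(seed, {
    acc <- matrix(numeric(), ncol = 3)
    idx <- which(unclass(mask), arr.ind = TRUE)
    while (nrow(acc) < n) {
      m <- max(2L * (n - nrow(acc)), 64L)
      i <- sample.int(nrow(idx), m, replace = TRUE)
      x <- idx[i, 2] - 1 + runif(m, -0.499, 0.499)
      y <- idx[i, 1] - 1 + runif(m, -0.499, 0.499)
      th <- .angle_deg(x, y, centroid[1], centroid[2])
      in_q <- ((th - d0) %% 360) < 90
      p <- ifelse(in_q, 1, 1 / quadrant_ratio)
      keep <- runif(m) < p
      acc <- rbind(acc, cbind(x[keep], y[keep], 0))
    }
    out <- acc[seq_len(n), , drop = FALSE]
    colnames(out) <- c("x", "y", "z")
    attr(out, "orientation_deg") <- d0
    out
  })
}

#' Render spots into a noisy image
#'
#' Gaussian point-spread kernels at the spot positions plus Gaussian read
#' noise, clipped at zero.
#'
#' @param spots spot matrix (x, y used; z selects the slice for multi-slice
#'   stacks).
#' @param dim image size `c(rows, cols)`.
#' @param psf_sigma PSF width, px.
#' @param peak peak intensity per spot.
#' @param noise_sd Gaussian read-noise sd.
#' @param n_slices number of slices.
#' @param seed integer seed.
#' @return An [image_stack()] (signal channel).
#' @export
render_spot_image <- function(spots, dim = c(128, 128), psf_sigma = 1.5,
                              peak = 10, noise_sd = 1, n_slices = 1,
                              seed = 1) {
  h <- dim[1]; w <- dim[2]
  vox <- array(0, dim = c(h, w, n_slices))
  r <- ceiling(4 * psf_sigma)
  for (i in seq_len(nrow(spots))) {
    sx <- spots[i, 1]; sy <- spots[i, 2]
    z <- if (n_slices > 1) round(spots[i, 3]) else 0
    if (z < 0 || z >= n_slices) next
    cxs <- max(0, floor(sx - r)):min(w - 1, ceiling(sx + r))
    rys <- max(0, floor(sy - r)):min(h - 1, ceiling(sy + r))
    g <- peak * exp(-(outer((rys - sy)^2, (cxs - sx)^2, `+`)) / (2 * psf_sigma^2))
    vox[rys + 1, cxs + 1, z + 1] <- vox[rys + 1, cxs + 1, z + 1] + g
  }
  .with_seed(seed, {
    vox <- vox + array(rnorm(length(vox), 0, noise_sd), dim = dim(vox))
  })
  image_stack(pmax(vox, 0), "signal")
}

#' Synthetic continuous intensity field
#'
#' Constant background plus Gaussian hotspots inside the mask; zero
#' outside. Hotspot centres are returned as the `hotspots` attribute.
#'
#' @param mask a [binary_mask()].
#' @param n_hotspots number of hotspots (0 for a flat field).
#' @param hotspot_sigma hotspot width, px.
#' @param hotspot_amplitude peak amplitude above background.
#' @param background background level inside the mask.
#' @param seed integer seed.
#' @return Intensity matrix.
#' @export
make_intensity_field <- function(mask, n_hotspots = 10, hotspot_sigma = 3,
                                 hotspot_amplitude = 20, background = 1,
                                 seed = 1) {
  .with_seed(seed, {
    h <- nrow(mask); w <- ncol(mask)
    img <- matrix(0, h, w)
    img[unclass(mask)] <- background
    centers <- NULL
    if (n_hotspots > 0) {
      idx <- which(unclass(mask), arr.ind = TRUE)
      i <- sample.int(nrow(idx), n_hotspots, replace = TRUE)
      centers <- cbind(x = idx[i, 2] - 1, y = idx[i, 1] - 1)
      x <- matrix(rep(0:(w - 1), each = h), h)
      y <- matrix(rep(0:(h - 1), times = w), h)
      for (j in seq_len(n_hotspots)) {
        img <- img + hotspot_amplitude *
          exp(-((x - centers[j, 1])^2 + (y - centers[j, 2])^2) / (2 * hotspot_sigma^2))
      }
      img[!unclass(mask)] <- 0
    }
    attr(img, "hotspots") <- centers
    img
  })
}

#' Synthetic striated myofiber
#'
#' Rectangular fiber with vertical Z-line stripes at a fixed period,
#' evenly spaced nuclei along the fiber axis, and spots either uniform or
#' anchored to stripe centres with Gaussian jitter.
#'
#' @param length,width fiber size, px.
#' @param period stripe period, px.
#' @param stripe_width stripe thickness, px.
#' @param n_nuclei number of nuclei (>= 2).
#' @param n_spots number of spots.
#' @param spot_mode `"uniform"` or `"on_stripe"`.
#' @param jitter_sd Gaussian jitter of stripe-anchored spots, px.
#' @param seed integer seed.
#' @return A [fiber_record()]; the stripe truth is attached as attributes
#'   `stripe_x` (leading-edge x positions) and `period`.
#' @export
make_striated_fiber <- function(length = 600, width = 120, period = 15,
                                stripe_width = 3, n_nuclei = 3, n_spots = 2000,
                                spot_mode = c("uniform", "on_stripe"),
                                jitter_sd = 2, seed = 1) {
  spot_mode <- match.arg(spot_mode)
  mask <- binary_mask(matrix(TRUE, width, length), "cell")
  stripe_x <- seq(period, length - stripe_width - 1, by = period)
  zmask <- matrix(FALSE, width, length)
  for (s in stripe_x) zmask[, (s:(s + stripe_width - 1)) + 1] <- TRUE
  cent <- cbind(x = round(seq(length * 0.1, length * 0.9, length.out = n_nuclei)),
                y = width / 2)
  spots <- .with_seed(seed, {
    if (spot_mode == "uniform") {
      cbind(x = runif(n_spots, 0, length - 1), y = runif(n_spots, 0, width - 1), z = 0)
    } else {
      centers <- stripe_x + (stripe_width - 1) / 2
      sx <- sample(centers, n_spots, replace = TRUE) + rnorm(n_spots, 0, jitter_sd)
      cbind(x = pmin(pmax(sx, 0), length - 1),
            y = runif(n_spots, 0, width - 1), z = 0)
    }
  })
  fib <- fiber_record("synthetic_fiber", mask, cent, spots,
                      list(binary_mask(zmask, "zline")))
  attr(fib, "stripe_x") <- stripe_x
  attr(fib, "period") <- period
  fib
}
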