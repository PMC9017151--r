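# Primary image descriptors: corrected projections, masks, zero level,
# height map, cell volume, spot detection, Z-line masks.

#' Segmentation parameters
#'
#' @param entropy_window side of the square neighborhood for the local
#'   entropy filter, in pixels (cell mask).
#' @param nucleus_window morphology neighborhood for the nucleus mask,
#'   in pixels.
#' @param percentile_threshold optional fraction in (0,1); when set, the
#'   entropy image is binarized at this percentile before edge detection
#'   (useful for noisy series).
#' @param use_otsu_for_nucleus use an Otsu threshold for the nucleus (the
#'   default); when `FALSE` the entropy filter pipeline is used instead.
#' @param morphology_radius radius of the disc structuring element used to
#'   bridge broken edges, in pixels.
#' @param canny_sigma,canny_low,canny_high Gaussian pre-smoothing and
#'   hysteresis thresholds (fractions of the stretched range) for the Canny
#'   step.
#' @param vignetting_scale optional fall-off scale of the vignetting gain;
#'   defaults to `sqrt((w/2)^2 * (h/2)^2)`.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(entropy_window = 30, nucleus_window = 18,
                                percentile_threshold = NULL,
                                use_otsu_for_nucleus = TRUE,
                                morphology_radius = 7,
                                canny_sigma = 2, canny_low = 0.1, canny_high = 0.3,
                                vignetting_scale = NULL) {
  if (entropy_window < 3 || nucleus_window < 3) abort("windows must be >= 3 px")
  if (!is.null(percentile_threshold) &&
      (percentile_threshold <= 0 || percentile_threshold >= 1))
    abort("percentile_threshold must lie in (0, 1)")
  structure(as.list(environment()), class = "segmentation_params")
}

#' Spot detection parameters
#'
#' @param smoothing_sigma Gaussian pre-smoothing, px.
#' @param bg_sigma background estimation scale (Gaussian blur), px.
#' @param tophat_radius radius of the white top-hat structuring disc, px.
#' @param log_sigma Laplacian-of-Gaussian blob scale, px (matched to the
#'   spot PSF width).
#' @param log_threshold relative peak threshold, fraction of the maximum LoG
#'   response.
#' @param noise_floor_sd significance floor: a peak must also exceed this
#'   many robust standard deviations (MAD) of the LoG response. Pure-noise
#'   maxima reach about 8-9 MAD, matched-filter responses of real spots are
#'   an order of magnitude higher, so the floor rejects noise while keeping
#'   the whole pipeline invariant to intensity rescaling.
#' @param min_slice_spots minimum spots per slice for muscle analyses.
#' @return A list of class `spot_detection_params`.
#' @export
spot_detection_params <- function(smoothing_sigma = 1, bg_sigma = 10,
                                  tophat_radius = 4, log_sigma = 1.5,
                                  log_threshold = 0.25, noise_floor_sd = 15,
                                  min_slice_spots = 25) {
  vals <- c(smoothing_sigma, bg_sigma, tophat_radius, log_sigma, log_threshold,
            noise_floor_sd)
  if (any(vals <= 0)) abort("spot detection parameters must be positive")
  structure(as.list(environment())[1:7], class = "spot_detection_params")
}

#' Vignetting correction
#'
#' Multiplies each pixel by a radially symmetric exponential gain centred at
#' the image centre, compensating the fall-off of illumination towards the
#' image corners: `gain(x, y) = exp(-d / s)` with `d` the Euclidean distance
#' from the centre and `s = sqrt((w/2)^2 * (h/2)^2)` by default.
#'
#' @param image 2D numeric matrix.
#' @param scale optional fall-off scale `s`.
#' @return The corrected matrix (same dimensions).
#' @export
vignetting_correct <- function(image, scale = NULL) {
  if (!is.matrix(image) || !length(image)) abort("`image` must be a non-empty matrix")
  h <- nrow(image); w <- ncol(image)
  s <- scale %||% sqrt((w / 2)^2 * (h / 2)^2)
  x <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  y <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  d <- sqrt((x - w / 2)^2 + (y - h / 2)^2)
  image * exp(-d / s)
}

#' Histogram stretching to the 0-255 range
#'
#' Linear normalization mapping the minimum to 0 and the maximum to 255. A
#' constant image cannot be stretched and yields an all-zero image with a
#' warning.
#'
#' @param image 2D numeric matrix.
#' @return Matrix with values in `[0, 255]`.
#' @export
stretch_contrast <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) {
    warn("constant image cannot be contrast-stretched; returning zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - rng[1]) / diff(rng) * 255
}

#' Local entropy filter
#'
#' Per-pixel Shannon entropy (bits) of the intensity histogram over a square
#' window. The window covers `window` x `window` pixels centred on each pixel
#' (for an even window the extra row/column falls on the low-index side) and
#' is clipped at the image border. Images with more than `max_levels`
#' distinct integer values are re-binned.
#'
#' @param image 2D matrix of integer-valued intensities.
#' @param window neighborhood side in pixels.
#' @param max_levels maximum number of histogram levels before re-binning.
#' @return Matrix of entropies in bits.
#' @export
local_entropy_filter <- function(image, window = 30, max_levels = 64) {
  h <- nrow(image); w <- ncol(image)
  if (window > h || window > w)
    abort("entropy window exceeds the image size", class = "fishspat_parameter_error")
  vals <- round(image)
  lv <- sort(unique(as.vector(vals)))
  if (length(lv) > max_levels) {
    vals <- as.integer(cut(as.vector(vals), breaks = max_levels, labels = FALSE))
    vals <- matrix(vals, h, w)
    lv <- sort(unique(as.vector(vals)))
  }
  lo <- ceiling((window - 1) / 2); hi <- floor((window - 1) / 2)
  r1 <- pmax(seq_len(h) - lo, 1L); r2 <- pmin(seq_len(h) + hi, h)
  c1 <- pmax(seq_len(w) - lo, 1L); c2 <- pmin(seq_len(w) + hi, w)
  nlogn <- matrix(0, h, w)
  ntot <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  for (l in lv) {
    ii <- matrix(0, h + 1L, w + 1L)
    ii[-1, -1] <- t(apply(apply(vals == l, 2, cumsum), 1, cumsum))
    cnt <- ii[r2 + 1L, c2 + 1L] - ii[r1, c2 + 1L] - ii[r2 + 1L, c1] + ii[r1, c1]
    nz <- cnt > 0
    nlogn[nz] <- nlogn[nz] + cnt[nz] * log2(cnt[nz])
  }
  log2(ntot) - nlogn / ntot
}

sobel_gradients <- function(image) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # d/dx (x = column)
  ky <- t(kx)                                                # d/dy (y = row)
  list(gx = EBImage::filter2(image, kx, boundary = "replicate"),
       gy = EBImage::filter2(image, ky, boundary = "replicate"))
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression and
#' hysteresis thresholding (thresholds are fractions of the maximum gradient
#' magnitude).
#'
#' @param image 2D matrix.
#' @param sigma pre-smoothing Gaussian sigma, px.
#' @param low,high hysteresis thresholds as fractions of the maximum
#'   magnitude.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(image, sigma = 2, low = 0.1, high = 0.3) {
  sm <- EBImage::gblur(image, sigma = sigma, boundary = "replicate")
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(image), ncol(image)))
  ang <- atan2(g$gy, g$gx)
  sector <- (round(ang / (pi / 4)) %% 4) # 0: E-W, 1: NE-SW, 2: N-S, 3: NW-SE
  h <- nrow(image); w <- ncol(image)
  pad <- matrix(0, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- mag
  off <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  nms <- matrix(FALSE, h, w)
  rows <- row(mag); cols <- col(mag)
  for (s in 0:3) {
    o <- off[[as.character(s)]]
    sel <- sector == s
    r <- rows[sel]; c <- cols[sel]
    m0 <- mag[sel]
    m1 <- pad[cbind(r + 1 + o[1], c + 1 + o[2])]
    m2 <- pad[cbind(r + 1 - o[1], c + 1 - o[2])]
    nms[sel] <- m0 >= m1 & m0 >= m2
  }
  mx <- max(mag)
  strong <- nms & mag >= high * mx
  weak <- nms & mag >= low * mx
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  weak & (lab %in% keep)
}

.disc <- function(r) EBImage::makeBrush(2 * floor(r) + 1, shape = "disc")

.largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(NULL)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

.close_and_fill <- function(edges, radius) {
  m <- EBImage::dilate(edges * 1, .disc(radius))
  m <- EBImage::closing(m, .disc(radius))
  m <- EBImage::fillHull(m)
  m <- EBImage::erode(m, .disc(radius))
  m > 0
}

#' Detect the cell mask from the tubulin channel
#'
#' Maximum projection, vignetting correction, histogram stretching, local
#' entropy filtering, optional percentile thresholding, Canny edge detection,
#' then dilation/closing/erosion to bridge gaps, hole filling and retention
#' of the largest connected component. One cell per image is assumed.
#'
#' @param tubulin_stack an [image_stack()] (tubulin channel).
#' @param params a [segmentation_params()].
#' @return A [binary_mask()] with role `"cell"`.
#' @export
detect_cell_mask <- function(tubulin_stack, params = segmentation_params()) {
  proj <- apply(tubulin_stack$voxels, c(1, 2), max)
  segment_projection(proj, params)
}

segment_projection <- function(proj, params = segmentation_params()) {
  corr <- vignetting_correct(proj, params$vignetting_scale)
  st <- stretch_contrast(corr)
  ent <- local_entropy_filter(st, params$entropy_window)
  # Binarize the entropy image before edge detection. The level is either a
  # caller-supplied percentile or the midpoint between the low/high entropy
  # plateaus plus 1 bit: a window straddling the boundary 50/50 gains exactly
  # one bit of mixture entropy, so the half-coverage contour sits one bit
  # above the plateau midpoint. This keeps the traced contour centred on the
  # true boundary instead of on the outer slope of the entropy halo.
  thr <- if (!is.null(params$percentile_threshold)) {
    quantile(ent, params$percentile_threshold)
  } else {
    (quantile(ent, 0.10) + quantile(ent, 0.90)) / 2 + 1
  }
  work <- (ent >= thr) * 255
  edges <- canny_edges(work, params$canny_sigma, params$canny_low, params$canny_high)
  if (!any(edges))
    abort(sprintf("segmentation failure: no edges found (entropy range %.3g-%.3g bits)",
                  min(ent), max(ent)),
          class = "fishspat_segmentation_error")
  m <- .close_and_fill(edges, params$morphology_radius)
  comp <- .largest_component(m)
  if (is.null(comp) || sum(comp) < 9)
    abort("segmentation failure: no closed contour survived morphology",
          class = "fishspat_segmentation_error")
  binary_mask(comp, "cell")
}

#' Detect the nucleus mask from the DAPI channel
#'
#' As [detect_cell_mask()] but with an Otsu threshold on the stretched
#' projection in place of the entropy/Canny pipeline (the default; set
#' `use_otsu_for_nucleus = FALSE` in the parameters to fall back to the
#' entropy pipeline for poor-quality DAPI signal).
#'
#' @param dapi_stack an [image_stack()] (nucleus channel).
#' @param params a [segmentation_params()].
#' @return A [binary_mask()] with role `"nucleus"`.
#' @export
detect_nucleus_mask <- function(dapi_stack, params = segmentation_params()) {
  proj <- apply(dapi_stack$voxels, c(1, 2), max)
  if (!params$use_otsu_for_nucleus) {
    m <- segment_projection(proj, params)
    return(binary_mask(unclass(m), "nucleus"))
  }
  st <- stretch_contrast(vignetting_correct(proj, params$vignetting_scale))
  thr <- otsu_threshold(st)
  bin <- st > thr
  if (!any(bin))
    abort("segmentation failure: empty Otsu foreground",
          class = "fishspat_segmentation_error")
  r <- max(2, round(params$nucleus_window / 6))
  m <- EBImage::closing(bin * 1, .disc(r))
  m <- EBImage::fillHull(m)
  comp <- .largest_component(m > 0)
  if (is.null(comp))
    abort("segmentation failure: no nucleus component",
          class = "fishspat_segmentation_error")
  binary_mask(comp, "nucleus")
}

#' Otsu threshold of an intensity image
#'
#' Exhaustively maximizes the between-class variance over a 256-bin
#' histogram of the image.
#'
#' @param image numeric matrix.
#' @param levels number of histogram bins.
#' @return The threshold on the intensity scale; pixels strictly above it
#'   are foreground.
#' @export
otsu_threshold <- function(image, levels = 256) {
  rng <- range(image)
  if (diff(rng) == 0) return(rng[1])
  sc <- (image - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1), levels = levels)
  thr01 * diff(rng) + rng[1]
}

#' Cytoplasm mask
#'
#' `cytoplasm = cell AND NOT nucleus`.
#'
#' @param cell,nucleus [binary_mask()] objects of identical shape.
#' @return A [binary_mask()] with role `"cytoplasm"`.
#' @export
cytoplasm_mask <- function(cell, nucleus) {
  if (!all(dim(cell) == dim(nucleus))) abort("mask shapes differ")
  binary_mask(unclass(cell) & !unclass(nucleus), "cytoplasm")
}

#' Zero level of a stack
#'
#' Index (0-based) of the slice with the maximum summed intensity — the
#' bottom in-focus slice of the tubulin stack. Ties are broken towards the
#' lowest index.
#'
#' @param tubulin_stack an [image_stack()].
#' @return Integer slice index.
#' @export
compute_zero_level <- function(tubulin_stack) {
  sums <- apply(tubulin_stack$voxels, 3, sum)
  which.max(sums) - 1L
}

#' Height map from per-slice segmentation
#'
#' Segments each slice at or above the zero level and assigns to every pixel
#' the highest slice (counted from the zero level, starting at 1) whose mask
#' covers it; 0 where no slice does. The per-slice mask is obtained either by
#' a cheap Otsu threshold (`method = "threshold"`, the default) or by the
#' full entropy/Canny pipeline (`method = "full"`).
#'
#' @param tubulin_stack an [image_stack()].
#' @param zero_level bottom in-focus slice (0-based).
#' @param params a [segmentation_params()].
#' @param method per-slice segmentation flavor.
#' @return 2D integer matrix of slice counts.
#' @export
compute_height_map <- function(tubulin_stack, zero_level = compute_zero_level(tubulin_stack),
                               params = segmentation_params(),
                               method = c("threshold", "full")) {
  method <- match.arg(method)
  nz <- n_slices(tubulin_stack)
  if (zero_level < 0 || zero_level >= nz)
    abort("zero_level outside the stack", class = "fishspat_parameter_error")
  d <- dim(tubulin_stack$voxels)
  h <- matrix(0L, d[1], d[2])
  any_ok <- FALSE
  for (z in zero_level:(nz - 1L)) {
    sl <- slice_of(tubulin_stack, z)
    mz <- tryCatch({
      if (method == "threshold") {
        if (diff(range(sl)) == 0) NULL else {
          bin <- sl > otsu_threshold(sl)
          comp <- .largest_component(EBImage::fillHull(bin * 1) > 0)
          comp
        }
      } else {
        unclass(segment_projection(sl, params))
      }
    }, error = function(e) NULL)
    if (is.null(mz) || !any(mz)) next
    any_ok <- TRUE
    val <- z - zero_level + 1L
    h[mz] <- pmax(h[mz], val)
  }
  if (!any_ok)
    abort("height map failure: no slice could be segmented",
          class = "fishspat_segmentation_error")
  h
}

#' Cell volume from a height map
#'
#' `V = sum_z |M_z| * pixel_size_xy^2 * z_step`, reconstructing the slice
#' masks as `{h >= z}`.
#'
#' @param height_map 2D matrix of non-negative integers.
#' @param pixel_size_xy,z_step voxel geometry in micrometres.
#' @return Volume in cubic micrometres.
#' @export
cell_volume <- function(height_map, pixel_size_xy = DEFAULT_PIXEL_SIZE,
                        z_step = DEFAULT_Z_STEP) {
  if (any(height_map < 0))
    abort("height map entries must be non-negative", class = "fishspat_validation_error")
  sum(height_map) * pixel_size_xy^2 * z_step
}

#' Sum-intensity projection
#'
#' `I(x, y) = sum_z voxels`, the protein intensity descriptor.
#'
#' @param signal_stack an [image_stack()].
#' @return 2D matrix.
#' @export
sum_intensity_projection <- function(signal_stack) {
  apply(signal_stack$voxels, c(1, 2), sum)
}

#' Detect mRNA spots
#'
#' Per-slice pipeline: background subtraction (Gaussian-blurred background
#' after Sobel-guided smoothing), white top-hat enhancement, then
#' Laplacian-of-Gaussian peak detection with a threshold relative to the
#' maximum response. Spots below `zero_level` are removed when one is
#' provided. Two spots closer than about the LoG scale may merge into a
#' single detection.
#'
#' @param signal_stack an [image_stack()] (mRNA channel).
#' @param params a [spot_detection_params()].
#' @param zero_level optional bottom in-focus slice; detections below it are
#'   discarded.
#' @return n x 3 matrix with columns `x`, `y`, `z` (possibly zero rows).
#' @export
detect_spots <- function(signal_stack, params = spot_detection_params(),
                         zero_level = NULL) {
  out <- list()
  for (z in seq_len(n_slices(signal_stack)) - 1L) {
    if (!is.null(zero_level) && z < zero_level) next
    sl <- slice_of(signal_stack, z)
    pk <- .detect_spots_2d(sl, params)
    if (nrow(pk)) out[[length(out) + 1L]] <- cbind(pk, z = z)
  }
  if (!length(out)) return(matrix(numeric(), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  res <- do.call(rbind, out)
  colnames(res) <- c("x", "y", "z")
  res
}

.log_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  x <- outer(rep(1, 2 * r + 1), -r:r)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2))
  k <- (x^2 + y^2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)
}

.detect_spots_2d <- function(sl, params) {
  empty <- matrix(numeric(), ncol = 2)
  if (diff(range(sl)) == 0) return(empty)
  sm <- EBImage::gblur(sl, params$smoothing_sigma, boundary = "replicate")
  bg <- EBImage::gblur(sm, params$bg_sigma, boundary = "replicate")
  resid <- pmax(sm - bg, 0)
  th <- EBImage::whiteTopHat(resid, .disc(params$tophat_radius))
  resp <- -EBImage::filter2(th, .log_kernel(params$log_sigma), boundary = "replicate")
  mx <- max(resp)
  if (mx <= 0) return(empty)
  h <- nrow(resp); w <- ncol(resp)
  pad <- matrix(-Inf, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- resp
  ismax <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & resp >= pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  # robust noise scale: MAD is insensitive to the sparse spot responses
  floor_ <- max(params$log_threshold * mx,
                params$noise_floor_sd * stats::mad(resp))
  sel <- which(ismax & resp >= floor_, arr.ind = TRUE)
  if (!nrow(sel)) return(empty)
  cbind(x = sel[, 2] - 1, y = sel[, 1] - 1)
}

#' Detect Z-line stripes in a myofiber slice
#'
#' Vertical Sobel operator (responding to vertical edges), Gaussian
#' smoothing, then Otsu binarization. The fiber axis is assumed horizontal
#' (x).
#'
#' @param phalloidin_slice 2D matrix.
#' @param sigma Gaussian smoothing after the Sobel step, px.
#' @return A [binary_mask()] with role `"zline"` (empty, with a warning, for
#'   a constant image).
#' @export
detect_zline_mask <- function(phalloidin_slice, sigma = 2) {
  if (diff(range(phalloidin_slice)) == 0) {
    warn("constant image: no Z-lines detected")
    return(binary_mask(matrix(FALSE, nrow(phalloidin_slice), ncol(phalloidin_slice)), "zline"))
  }
  g <- sobel_gradients(phalloidin_slice)
  resp <- EBImage::gblur(abs(g$gx), sigma, boundary = "replicate")
  thr <- otsu_threshold(resp)
  binary_mask(resp > thr, "zline")
}
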