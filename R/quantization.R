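# MTOC-anchored geometric quantization: peripheral distance map (100
# isolines), rotational quadrant maximization, fine-grained 8 x p segments,
# and relative density vectors.
#
# Angular conventions: rays are cast at one per degree (0..359); a pixel or
# spot belongs to the integer-degree bin floor(angle). Quadrant/sector
# boundaries always sit at integer degrees, so degree-binned histograms give
# exact per-part counts. "Clockwise" is in image coordinates (y down), where
# it coincides with increasing angle.

#' Peripheral distance map
#'
#' Casts one ray per degree from the nucleus centroid, splits each ray into
#' 100 equidistant points between the nucleus contour and the cell border,
#' and joins the k-th points into isoline polygons. `D(x, y)` is the isoline
#' index: 100 at the nucleus envelope, 0 at the cell edge, `NA` outside the
#' cytoplasm. On non-star-convex masks a ray uses its first boundary
#' crossing from the centroid.
#'
#' @param cytoplasm,nucleus [binary_mask()] objects of equal shape.
#' @param nucleus_centroid `(x, y)`; must lie inside the nucleus.
#' @param height_map optional height map; when present, cumulative 3D
#'   peripheral volumes are attached.
#' @param pixel_size_xy,z_step voxel geometry in micrometres.
#' @return An object of class `peripheral_distance_map` with elements `D`
#'   (integer matrix), `peripheral_volumes` (cumulative measure of
#'   `{D <= i}`, i = 1..100), ray radii and the centroid.
#' @export
peripheral_distance_map <- function(cytoplasm, nucleus, nucleus_centroid = NULL,
                                    height_map = NULL,
                                    pixel_size_xy = DEFAULT_PIXEL_SIZE,
                                    z_step = DEFAULT_Z_STEP) {
  if (is.null(nucleus_centroid)) nucleus_centroid <- mask_centroid(nucleus)
  cx <- nucleus_centroid[1]; cy <- nucleus_centroid[2]
  if (!.inside_mask(nucleus, cx, cy))
    abort("nucleus centroid lies outside the nucleus mask",
          class = "fishspat_geometry_error")
  cell <- unclass(cytoplasm) | unclass(nucleus)
  rays <- .cast_rays(cell, unclass(nucleus), cx, cy)

  obj <- structure(
    list(rn = rays$rn, rc = rays$rc, centroid = c(cx, cy),
         isoline_count = 100L, dim = dim(cytoplasm)),
    class = "peripheral_distance_map"
  )
  idx <- which(unclass(cytoplasm), arr.ind = TRUE)
  px <- idx[, 2] - 1; py <- idx[, 1] - 1
  Dv <- dmap_lookup(obj, px, py)
  D <- matrix(NA_integer_, nrow(cytoplasm), ncol(cytoplasm))
  D[idx] <- Dv
  obj$D <- D

  voxvol <- if (!is.null(height_map)) {
    height_map[idx] * pixel_size_xy^2 * z_step
  } else {
    rep(pixel_size_xy^2, nrow(idx))
  }
  # cumulative measure of {D <= i} from the cell edge inwards
  tab <- vapply(0:100, function(i) sum(voxvol[Dv == i]), numeric(1))
  obj$peripheral_volumes <- cumsum(tab)[-1] # V_1..V_100 (V_i covers D <= i)
  obj$volumes_3d <- !is.null(height_map)
  obj
}

# per-degree first-crossing radii out of the nucleus (rn) and cell (rc)
.cast_rays <- function(cell, nucleus, cx, cy, step = 0.25) {
  h <- nrow(cell); w <- ncol(cell)
  maxR <- sqrt(h^2 + w^2)
  t <- seq(0, maxR, by = step)
  th <- (0:359) * pi / 180
  X <- outer(cos(th), t) + cx
  Y <- outer(sin(th), t) + cy
  r <- round(Y) + 1L; c <- round(X) + 1L
  ok <- r >= 1L & r <= h & c >= 1L & c <= w
  inside_cell <- matrix(FALSE, 360, length(t))
  inside_cell[ok] <- cell[cbind(r[ok], c[ok])]
  inside_nuc <- matrix(FALSE, 360, length(t))
  inside_nuc[ok] <- nucleus[cbind(r[ok], c[ok])]
  first_exit <- function(inside) {
    # first column where the ray has left the region (after being inside)
    apply(inside, 1, function(v) {
      i <- which(!v)[1]
      if (is.na(i)) length(v) else i
    })
  }
  en <- first_exit(inside_nuc)
  ec <- first_exit(inside_cell)
  rn <- pmax(t[pmax(en - 1L, 1L)] + step / 2, step / 2)
  rc <- pmax(t[pmax(ec - 1L, 1L)] + step / 2, rn + step)
  list(rn = rn, rc = rc)
}

#' Isoline index at arbitrary positions
#'
#' Evaluates the peripheral distance map at continuous `(x, y)` positions
#' (e.g. spot coordinates) by locating the nested isoline polygon containing
#' each point.
#'
#' @param dmap a [peripheral_distance_map()].
#' @param x,y coordinate vectors.
#' @return Integer vector of isoline indices in `[0, 100]`.
#' @export
dmap_lookup <- function(dmap, x, y) {
  cx <- dmap$centroid[1]; cy <- dmap$centroid[2]
  dx <- x - cx; dy <- y - cy
  r <- sqrt(dx^2 + dy^2)
  th <- (atan2(dy, dx) * 180 / pi + 360) %% 360
  a <- floor(th) %% 360
  b <- (a + 1L) %% 360
  sinA <- sin((th - a) * pi / 180)
  sinB <- sin((a + 1 - th) * pi / 180)
  rho_at <- function(s) {
    r0 <- dmap$rc[a + 1L] - (s / 100) * (dmap$rc[a + 1L] - dmap$rn[a + 1L])
    r1 <- dmap$rc[b + 1L] - (s / 100) * (dmap$rc[b + 1L] - dmap$rn[b + 1L])
    den <- r0 * sinA + r1 * sinB
    tt <- ifelse(den > 0, r0 * sinA / den, 0)
    p0x <- r0 * cos(a * pi / 180); p0y <- r0 * sin(a * pi / 180)
    p1x <- r1 * cos(b * pi / 180); p1y <- r1 * sin(b * pi / 180)
    ix <- p0x + tt * (p1x - p0x); iy <- p0y + tt * (p1y - p0y)
    sqrt(ix^2 + iy^2)
  }
  lo <- rep(0, length(r)); hi <- rep(100, length(r))
  out <- rep(NA_real_, length(r))
  at_edge <- r >= rho_at(lo)
  at_nuc <- r <= rho_at(hi)
  out[at_edge] <- 0
  out[at_nuc & is.na(out)] <- 100
  todo <- is.na(out)
  if (any(todo)) {
    for (it in 1:30) {
      mid <- (lo + hi) / 2
      # rho decreasing in s: point inside polygon mid iff r <= rho(mid)
      inside <- r <= rho_at(mid)
      upd <- todo & inside
      lo[upd] <- mid[upd]
      dwn <- todo & !inside
      hi[dwn] <- mid[dwn]
    }
    out[todo] <- floor(lo[todo] + 1e-9)
  }
  as.integer(pmin(pmax(out, 0), 100))
}

#' Peripheral mask at a given percent
#'
#' `{D < p}`: a strip at the cell edge whose width is a fixed proportion of
#' the radial distance.
#'
#' @param dmap a [peripheral_distance_map()].
#' @param p percent in `[0, 100]`.
#' @return A [binary_mask()] with role `"periphery"`.
#' @export
peripheral_mask <- function(dmap, p) {
  m <- !is.na(dmap$D) & dmap$D < p
  binary_mask(m, "periphery")
}

# ---- quadrant machinery ----------------------------------------------------

#' Precompute quadrant geometry for a cell mask
#'
#' Per-degree area (and, with a height map, volume) histograms around the
#' nucleus centroid, reusable across records that share a mask.
#'
#' @param cell_mask a [binary_mask()].
#' @param nucleus_centroid `(x, y)`.
#' @param height_map optional height map for 3D volumes.
#' @param pixel_size_xy,z_step voxel geometry.
#' @return An object of class `quadrant_geometry`.
#' @export
quadrant_geometry <- function(cell_mask, nucleus_centroid, height_map = NULL,
                              pixel_size_xy = DEFAULT_PIXEL_SIZE,
                              z_step = DEFAULT_Z_STEP) {
  idx <- which(unclass(cell_mask), arr.ind = TRUE)
  # the pixel at the centroid has no angle; its quadrant is undefined, so it
  # is excluded from the histograms
  r0 <- sqrt((idx[, 2] - 1 - nucleus_centroid[1])^2 +
               (idx[, 1] - 1 - nucleus_centroid[2])^2)
  idx <- idx[r0 > 1e-9, , drop = FALSE]
  bin <- .angle_bin(idx[, 2] - 1, idx[, 1] - 1,
                    nucleus_centroid[1], nucleus_centroid[2])
  area_hist <- tabulate(bin + 1L, nbins = 360)
  vol_hist <- NULL
  if (!is.null(height_map)) {
    voxvol <- height_map[idx] * pixel_size_xy^2 * z_step
    vol_hist <- vapply(split(voxvol, factor(bin, levels = 0:359)), sum, numeric(1))
  }
  structure(list(idx = idx, bin = bin, area_hist = area_hist,
                 vol_hist = vol_hist, centroid = nucleus_centroid,
                 dim = dim(cell_mask)),
            class = "quadrant_geometry")
}

.circular_window_sum <- function(hist, starts, len) {
  cs <- c(0, cumsum(c(hist, hist)))
  cs[starts + len + 1L] - cs[starts + 1L]
}

# signal histogram: per-degree spot counts (mRNA) or intensity sums
# restricted to the cytoplasm
.signal_histogram <- function(record, centroid) {
  cyto <- cytoplasm_mask(record$cell_mask, record$nucleus_mask)
  if (record$molecule == "mRNA") {
    sp <- record$spots
    keep <- .inside_mask(cyto, sp[, 1], sp[, 2])
    sp <- sp[keep, , drop = FALSE]
    bin <- .angle_bin(sp[, 1], sp[, 2], centroid[1], centroid[2])
    list(hist = tabulate(bin + 1L, nbins = 360), spots = sp, spot_bin = bin)
  } else {
    idx <- which(unclass(cyto), arr.ind = TRUE)
    bin <- .angle_bin(idx[, 2] - 1, idx[, 1] - 1, centroid[1], centroid[2])
    vals <- record$intensity[idx]
    hist <- vapply(split(vals, factor(bin, levels = 0:359)), sum, numeric(1))
    list(hist = unname(hist), spots = NULL, spot_bin = NULL)
  }
}

#' MTOC-anchored quadrant quantization (2D)
#'
#' Rotates two orthogonal axes centred at the nucleus centroid over all 360
#' integer orientations and retains the orientation that maximizes the
#' cytoplasmic signal (spot count or summed intensity) inside the quadrant
#' containing the MTOC. Quadrants are renumbered so Q1 is the MTOC quadrant,
#' then clockwise. Ties are broken towards the lowest orientation.
#'
#' Per-quadrant relative concentrations are
#' `c_i = (t_i / a_i) / (T / A)` with `T` the total cytoplasmic signal and
#' `A` the cell mask area, so that `sum(c_i a_i) = A`.
#'
#' The axis orientation can be chosen in two ways. `"max_signal"` (the
#' alignment used for distribution profiles) retains the orientation
#' maximizing the signal in the MTOC quadrant. `"mtoc_bisect"` anchors the
#' axes so the MTOC direction bisects Q1; this orientation is independent of
#' the signal, which preserves the exchangeability of quadrant densities
#' under spatial randomness — the MTOC polarity index uses it so its
#' binomial null is calibrated (a signal-maximized Q1 density is inflated by
#' selection even for uniform signal).
#'
#' @param record a [cell_record()].
#' @param geom optional precomputed [quadrant_geometry()].
#' @param orientation `"max_signal"` or `"mtoc_bisect"` (see Details).
#' @return An object of class `quantization_result`; its `parts` element is
#'   a tibble with columns `part`, `t`, `a`, `c` (and `v`, `c3d` after
#'   [quadrantize_3d()]).
#' @export
quadrantize <- function(record, geom = NULL,
                        orientation = c("max_signal", "mtoc_bisect")) {
  orientation <- match.arg(orientation)
  ctr <- record$nucleus_centroid
  if (sqrt(sum((record$mtoc - ctr)^2)) < 1e-9)
    abort("MTOC coincides with the nucleus centroid: quadrant undefined",
          class = "fishspat_geometry_error")
  if (is.null(geom)) geom <- quadrant_geometry(record$cell_mask, ctr)
  sig <- .signal_histogram(record, ctr)
  mtoc_bin <- .angle_bin(record$mtoc[1], record$mtoc[2], ctr[1], ctr[2])

  if (orientation == "max_signal") {
    d <- 0:359
    qm <- ((mtoc_bin - d) %% 360) %/% 90
    starts <- (d + 90 * qm) %% 360
    tm <- .circular_window_sum(sig$hist, starts, 90)
    # ties broken by the smallest rotation relative to the MTOC direction,
    # which makes the chosen partition covariant under image rotation
    ties <- d[tm == max(tm)]
    best <- ties[which.min((ties - mtoc_bin) %% 360)]
  } else {
    best <- (mtoc_bin - 45L) %% 360L
  }

  qm_best <- ((mtoc_bin - best) %% 360) %/% 90
  quad_of_bin <- (((0:359 - best) %% 360) %/% 90)
  label_of_bin <- ((quad_of_bin - qm_best) %% 4) + 1L

  t_i <- vapply(1:4, function(k) sum(sig$hist[label_of_bin == k]), numeric(1))
  a_i <- vapply(1:4, function(k) sum(geom$area_hist[label_of_bin == k]), numeric(1))
  TT <- sum(t_i); A <- sum(a_i)
  c_i <- ifelse(a_i > 0 & TT > 0, (t_i / a_i) / (TT / A), 0)

  labels <- matrix(NA_integer_, geom$dim[1], geom$dim[2])
  labels[geom$idx] <- label_of_bin[geom$bin + 1L]

  structure(
    list(orientation_deg = best, mtoc_bin = mtoc_bin,
         quadrant_labels = labels,
         parts = tibble(part = 1:4, t = t_i, a = a_i, c = c_i),
         total = TT, area = A, molecule = record$molecule,
         label_of_bin = label_of_bin, geom = geom, signal = sig),
    class = "quantization_result"
  )
}

#' @export
print.quantization_result <- function(x, ...) {
  kind <- if (!is.null(x$sectors)) sprintf("fine-grained 8 x %d", x$n_bands) else "quadrant"
  cat(sprintf("<quantization_result> %s, orientation %d deg\n", kind, x$orientation_deg))
  print(x$parts)
  invisible(x)
}

#' MTOC-anchored quadrant quantization (3D)
#'
#' Reuses the 2D orientation and computes per-quadrant volumes from the
#' height map; `c_i = (t_i / v_i) / (T / V)`.
#'
#' @inheritParams quadrantize
#' @return A `quantization_result` whose `parts` tibble gains `v` (µm³) and
#'   `c3d` columns.
#' @export
quadrantize_3d <- function(record, geom = NULL) {
  if (!has_height_map(record))
    abort("3D quantization needs a height map", class = "fishspat_capability_error")
  if (is.null(geom) || is.null(geom$vol_hist))
    geom <- quadrant_geometry(record$cell_mask, record$nucleus_centroid,
                              height_map = record$height_map,
                              pixel_size_xy = record$pixel_size_xy,
                              z_step = record$z_step)
  q <- quadrantize(record, geom)
  v_i <- vapply(1:4, function(k) sum(geom$vol_hist[q$label_of_bin == k]), numeric(1))
  V <- sum(v_i)
  q$parts$v <- v_i
  q$parts$c3d <- ifelse(v_i > 0 & q$total > 0, (q$parts$t / v_i) / (q$total / V), 0)
  q$volume <- V
  q
}

#' Fine-grained quantization into 8 x p segments
#'
#' Halves each quadrant into 45-degree sectors (anchored at the MTOC
#' sector, clockwise) and crosses them with `p` isoline bands of the
#' peripheral distance map (bands of equal isoline count). Segments are
#' ordered concentrically from the nucleus outward:
#' `segment = (band - 1) * 8 + sector`. Relative densities use the same
#' normalization as quadrants, with areas (or, in 3D, voxel volumes)
#' restricted to the cytoplasm where `D` is defined.
#'
#' @param record a [cell_record()].
#' @param dmap a [peripheral_distance_map()] for the record.
#' @param p number of isoline bands (3 for the standard 8 x 3 profile).
#' @param quant optional [quadrantize()] result to reuse the orientation.
#' @param use_3d use voxel volumes (needs the dmap built with a height map).
#' @return A `quantization_result` with a `parts` tibble of 8 x p rows
#'   (`segment`, `sector`, `band`, `t`, `a`, `c`) and a `segment_labels`
#'   matrix.
#' @export
fine_grained_segments <- function(record, dmap, p = 3, quant = NULL,
                                  use_3d = FALSE) {
  if (p < 1) abort("p must be >= 1", class = "fishspat_parameter_error")
  if (is.null(quant)) quant <- quadrantize(record)
  ctr <- record$nucleus_centroid
  best <- quant$orientation_deg
  sm <- ((quant$mtoc_bin - best) %% 360) %/% 45
  sector_of_bin <- ((((0:359 - best) %% 360) %/% 45 - sm) %% 8) + 1L

  band_of_D <- function(D) p - pmin(pmax(ceiling(D * p / 100), 1L), p) + 1L

  cyto <- cytoplasm_mask(record$cell_mask, record$nucleus_mask)
  idx <- which(unclass(cyto), arr.ind = TRUE)
  pbin <- .angle_bin(idx[, 2] - 1, idx[, 1] - 1, ctr[1], ctr[2])
  psec <- sector_of_bin[pbin + 1L]
  pD <- dmap$D[idx]
  pband <- band_of_D(pD)
  pseg <- (pband - 1L) * 8L + psec

  measure <- if (use_3d) {
    if (is.null(record$height_map))
      abort("3D fine-grained quantization needs a height map",
            class = "fishspat_capability_error")
    record$height_map[idx] * record$pixel_size_xy^2 * record$z_step
  } else rep(1, nrow(idx))

  nseg <- 8L * p
  a_i <- vapply(seq_len(nseg), function(s) sum(measure[pseg == s]), numeric(1))

  if (record$molecule == "mRNA") {
    sp <- record$spots
    keep <- .inside_mask(cyto, sp[, 1], sp[, 2])
    sp <- sp[keep, , drop = FALSE]
    sbin <- .angle_bin(sp[, 1], sp[, 2], ctr[1], ctr[2])
    ssec <- sector_of_bin[sbin + 1L]
    sD <- dmap_lookup(dmap, sp[, 1], sp[, 2])
    sseg <- (band_of_D(sD) - 1L) * 8L + ssec
    t_i <- vapply(seq_len(nseg), function(s) sum(sseg == s), numeric(1))
  } else {
    vals <- record$intensity[idx]
    t_i <- vapply(seq_len(nseg), function(s) sum(vals[pseg == s]), numeric(1))
  }

  TT <- sum(t_i); A <- sum(a_i)
  c_i <- ifelse(a_i > 0 & TT > 0, (t_i / a_i) / (TT / A), 0)
  labels <- matrix(NA_integer_, nrow(cyto), ncol(cyto))
  labels[idx] <- pseg
  structure(
    list(orientation_deg = best, mtoc_bin = quant$mtoc_bin,
         segment_labels = labels, n_bands = p,
         parts = tibble(segment = seq_len(nseg),
                        sector = rep(1:8, times = p),
                        band = rep(seq_len(p), each = 8),
                        t = t_i, a = a_i, c = c_i),
         sectors = 8L, total = TT, area = A, molecule = record$molecule),
    class = "quantization_result"
  )
}

#' @rdname quadrantize
#' @param x a `quantization_result`.
#' @param ... unused.
#' @export
tidy.quantization_result <- function(x, ...) x$parts
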