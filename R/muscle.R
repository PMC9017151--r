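# Myofiber analyses: Z-line spacing, per-spot Z-line distance profiles,
# internuclear vertical quantization, local density striation profiles.
# The fiber axis is assumed horizontal (x).

#' Create a fiber record
#'
#' A multinucleated myofiber with per-slice Z-line masks.
#'
#' @param id identifier.
#' @param cell_mask fiber [binary_mask()].
#' @param nuclei_centroids list/matrix of `(x, y)` centroids (at least 2),
#'   ordered along the fiber axis.
#' @param spots n x 3 spot matrix `(x, y, z)`.
#' @param zline_masks named or ordered list of per-slice Z-line
#'   [binary_mask()] objects; element i corresponds to slice `z = i - 1`.
#' @param gene gene symbol.
#' @return An object of class `fiber_record`.
#' @export
fiber_record <- function(id, cell_mask, nuclei_centroids, spots, zline_masks,
                         gene = "gene") {
  if (!is_binary_mask(cell_mask)) cell_mask <- binary_mask(cell_mask, "cell")
  cent <- as.matrix(nuclei_centroids)
  if (nrow(cent) < 2) abort("a fiber needs at least 2 nuclei")
  cent <- cent[order(cent[, 1]), , drop = FALSE]
  spots <- as.matrix(spots)
  if (ncol(spots) == 2L) spots <- cbind(spots, 0)
  colnames(spots) <- c("x", "y", "z")
  structure(
    list(id = as.character(id), gene = gene, cell_mask = cell_mask,
         nuclei_centroids = cent, spots = spots,
         zline_masks = zline_masks),
    class = "fiber_record"
  )
}

#' @export
print.fiber_record <- function(x, ...) {
  cat(sprintf("<fiber_record> %s: %d nuclei, %d spots, %d slice(s)\n",
              x$id, nrow(x$nuclei_centroids), nrow(x$spots), length(x$zline_masks)))
  invisible(x)
}

# leading-edge x positions of Z-line stripes along one row
.stripe_leading_edges <- function(rowvals) {
  d <- diff(c(FALSE, rowvals))
  which(d == 1) - 1L # 0-based x of the first pixel of each stripe
}

#' Z-line spacing
#'
#' For each slice and each row y, collects the distances between the
#' leading edges of consecutive Z-line stripes; the spacing `Z` is the
#' median of all pooled distances. Masks from several fibers can be pooled
#' by concatenating their mask lists.
#'
#' @param zline_masks list of per-slice Z-line [binary_mask()] objects.
#' @param edge `"leading"` (first stripe pixel along +x, the default) or
#'   `"centroid"` (stripe centre-to-centre).
#' @return Median spacing in pixels.
#' @export
zline_spacing <- function(zline_masks, edge = c("leading", "centroid")) {
  edge <- match.arg(edge)
  dists <- numeric()
  for (m in zline_masks) {
    mm <- unclass(m)
    for (r in seq_len(nrow(mm))) {
      pos <- if (edge == "leading") {
        .stripe_leading_edges(mm[r, ])
      } else {
        runs <- rle(mm[r, ])
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1
        (starts[runs$values] + ends[runs$values]) / 2 - 1
      }
      if (length(pos) >= 2) dists <- c(dists, diff(pos))
    }
  }
  if (!length(dists))
    abort("fewer than 2 Z-line stripes everywhere", class = "fishspat_degenerate_error")
  median(dists)
}

#' Z-line mRNA distance profile of one fiber
#'
#' Slices with no more than `min_slice_spots` spots are excluded (their
#' spots too). Each remaining spot gets distance 0 if it falls inside its
#' slice's Z-line mask, otherwise the minimal Euclidean distance to a
#' Z-line pixel; spots with no Z-line within radius `Z` are excluded
#' (logged). Distances are binned at integer pixels (rounding half-up) and
#' counts are normalized by the number of retained spots.
#'
#' @param fiber a [fiber_record()].
#' @param Z Z-line spacing (profile length is `Z + 1`, distances 0..Z);
#'   defaults to [zline_spacing()] of the fiber's masks.
#' @param min_slice_spots slice inclusion threshold.
#' @return Numeric vector `delta` of length `Z + 1` (normalized counts at
#'   distances 0..Z), with attribute `n_excluded`.
#' @export
zline_distance_profile <- function(fiber, Z = NULL, min_slice_spots = 25) {
  Z <- Z %||% zline_spacing(fiber$zline_masks)
  Z <- as.integer(round(Z))
  sp <- fiber$spots
  zs <- round(sp[, 3])
  keep_slice <- vapply(seq_along(fiber$zline_masks) - 1L,
                       function(z) sum(zs == z) > min_slice_spots, logical(1))
  if (!any(keep_slice))
    abort("all slices excluded by the spot-count threshold",
          class = "fishspat_degenerate_error")
  dists <- numeric()
  n_excluded <- 0L
  for (z in which(keep_slice) - 1L) {
    m <- unclass(fiber$zline_masks[[z + 1L]])
    if (!any(m)) next
    dm <- .distance_to_mask(m)
    here <- sp[zs == z, , drop = FALSE]
    at <- cbind(pmin(pmax(round(here[, 2]) + 1L, 1L), nrow(m)),
                pmin(pmax(round(here[, 1]) + 1L, 1L), ncol(m)))
    d <- dm[at]
    far <- d > Z
    n_excluded <- n_excluded + sum(far)
    dists <- c(dists, d[!far])
  }
  if (n_excluded > 0)
    message(sprintf("%s: %d spot(s) with no Z-line within Z excluded",
                    fiber$id, n_excluded))
  bins <- floor(dists + 0.5)
  delta <- tabulate(bins + 1L, nbins = Z + 1L) / length(dists)
  names(delta) <- 0:Z
  attr(delta, "n_excluded") <- n_excluded
  delta
}

# Euclidean distance from every pixel to the nearest TRUE pixel of `mask`
.distance_to_mask <- function(mask) {
  EBImage::distmap(1 - mask, metric = "euclidean")
}

#' Median Z-line distance profile over fibers
#'
#' Elementwise median of the per-fiber normalized distance profiles.
#'
#' @param fibers list of [fiber_record()] objects.
#' @param Z shared Z-line spacing; defaults to [zline_spacing()] pooled over
#'   all fibers.
#' @param min_slice_spots slice inclusion threshold.
#' @return An object of class `zline_profile`: tibble with columns
#'   `distance_px` (0..Z) and `delta_bar`.
#' @export
zline_profile <- function(fibers, Z = NULL, min_slice_spots = 25) {
  Z <- Z %||% zline_spacing(unlist(map(fibers, "zline_masks"), recursive = FALSE))
  M <- do.call(rbind, map(fibers, ~ zline_distance_profile(.x, Z, min_slice_spots)))
  out <- tibble(distance_px = 0:round(Z), delta_bar = apply(M, 2, median))
  structure(out, Z = Z, n_fibers = length(fibers),
            class = c("zline_profile", class(out)))
}

#' @rdname zline_profile
#' @param object a `zline_profile`.
#' @param ... unused.
#' @export
autoplot.zline_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance_px, y = .data$delta_bar)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "distance to nearest Z-line (px)",
                  y = "normalized median count") +
    ggplot2::theme_minimal()
}

#' Internuclear vertical quantization
#'
#' Restricts the fiber mask to the x-range between each pair of consecutive
#' nuclei centroids and splits it into `n` near-equal-width vertical bands
#' (band widths differ by at most one pixel; integer break positions are
#' obtained by rounding the equal-width grid).
#'
#' @param fiber a [fiber_record()].
#' @param n_segments number of bands (20 or 80 in the reference protocol).
#' @return List of regions (one per internuclear interval), each with
#'   `x_range`, `breaks`, `areas` (band pixel areas) and `labels` (band
#'   index matrix, `NA` outside).
#' @export
vertical_quantization <- function(fiber, n_segments = 20) {
  if (n_segments < 2) abort("n_segments must be >= 2", class = "fishspat_parameter_error")
  cent <- fiber$nuclei_centroids
  mask <- unclass(fiber$cell_mask)
  out <- list()
  for (i in seq_len(nrow(cent) - 1)) {
    x0 <- cent[i, 1]; x1 <- cent[i + 1, 1]
    breaks <- round(seq(x0, x1, length.out = n_segments + 1))
    cols <- col(mask) - 1L
    lab <- matrix(NA_integer_, nrow(mask), ncol(mask))
    for (b in seq_len(n_segments)) { # half-open bands [break_b, break_{b+1})
      lab[cols >= breaks[b] & cols < breaks[b + 1] & mask] <- b
    }
    areas <- vapply(seq_len(n_segments), function(b) sum(lab == b, na.rm = TRUE), numeric(1))
    if (any(areas == 0))
      abort("zero-area vertical band", class = "fishspat_degenerate_error")
    out[[i]] <- list(x_range = c(x0, x1), breaks = breaks, areas = areas,
                     labels = lab, n_segments = n_segments)
  }
  out
}

#' Local mRNA density along a quantized fiber
#'
#' Relative concentration `c_i = (t_i / a_i) / (T / A)` per vertical band,
#' for each internuclear region.
#'
#' @param fiber a [fiber_record()].
#' @param segments result of [vertical_quantization()].
#' @return Tibble with columns `region`, `band`, `t`, `a`, `c`.
#' @export
muscle_local_density <- function(fiber, segments) {
  sp <- fiber$spots
  rows <- list()
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    n <- seg$n_segments
    inx <- sp[, 1] >= seg$breaks[1] & sp[, 1] < seg$breaks[n + 1]
    here <- sp[inx, , drop = FALSE]
    b <- pmin(pmax(findInterval(here[, 1], seg$breaks), 1L), n)
    inmask <- .inside_mask(fiber$cell_mask, here[, 1], here[, 2])
    t_i <- vapply(seq_len(n), function(k) sum(b == k & inmask), numeric(1))
    TT <- sum(t_i); A <- sum(seg$areas)
    c_i <- ifelse(seg$areas > 0 & TT > 0, (t_i / seg$areas) / (TT / A), 0)
    rows[[i]] <- tibble(region = i, band = seq_len(n), t = t_i,
                        a = seg$areas, c = c_i)
  }
  bind_rows(rows)
}
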