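# Domain containers: image stacks, masks, cell records, acquisition series.

DEFAULT_PIXEL_SIZE <- 1 / 9.75 # micrometres per pixel
DEFAULT_Z_STEP <- 0.3          # micrometres per z-slice

#' Create an image stack
#'
#' A multi-slice fluorescence image for a single channel. Voxels are stored as
#' an array indexed `[y, x, z]`; 2D images are promoted to a single-slice
#' stack.
#'
#' @param voxels 2D matrix or 3D array of non-negative intensities.
#' @param channel_role one of `"nucleus"`, `"pattern"`, `"signal"`,
#'   `"tubulin"`.
#' @param pixel_size_xy lateral pixel size in micrometres per pixel.
#' @param z_step axial distance between consecutive slices in micrometres.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels,
                        channel_role = c("signal", "nucleus", "pattern", "tubulin"),
                        pixel_size_xy = DEFAULT_PIXEL_SIZE,
                        z_step = DEFAULT_Z_STEP) {
  channel_role <- match.arg(channel_role)
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L) abort("`voxels` must be a 2D matrix or 3D array")
  if (!is.numeric(voxels)) abort("`voxels` must be numeric", class = "fishspat_format_error")
  if (anyNA(voxels) || any(voxels < 0)) abort("intensities must be non-negative")
  if (pixel_size_xy <= 0 || z_step <= 0) abort("geometry parameters must be positive")
  structure(
    list(voxels = voxels, channel_role = channel_role,
         pixel_size_xy = pixel_size_xy, z_step = z_step),
    class = "image_stack"
  )
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %s, %d x %d px, %d slice(s)\n",
              x$channel_role, d[2], d[1], d[3]))
  invisible(x)
}

n_slices <- function(stack) dim(stack$voxels)[3]

slice_of <- function(stack, z) stack$voxels[, , z + 1L]

#' Create a binary mask
#'
#' @param grid logical (or 0/1) matrix, `TRUE` inside the region.
#' @param role one of `"cell"`, `"nucleus"`, `"cytoplasm"`, `"periphery"`,
#'   `"zline"`.
#' @return An object of class `binary_mask` (a logical matrix with a role
#'   attribute).
#' @export
binary_mask <- function(grid, role = c("cell", "nucleus", "cytoplasm", "periphery", "zline")) {
  role <- match.arg(role)
  if (!is.matrix(grid)) abort("`grid` must be a matrix")
  m <- matrix(as.logical(grid), nrow = nrow(grid))
  structure(m, role = role, class = c("binary_mask", "matrix", "array"))
}

mask_area <- function(mask) sum(mask)

is_binary_mask <- function(x) inherits(x, "binary_mask")

#' Load a TIFF file as an image stack
#'
#' Multi-page TIFFs become multi-slice stacks; single-page (2D) files are
#' promoted to stacks with one slice.
#'
#' @inheritParams image_stack
#' @param path path to a 2D or 3D TIFF file.
#' @return An [image_stack()].
#' @export
load_tiff_stack <- function(path,
                            channel_role = c("signal", "nucleus", "pattern", "tubulin"),
                            pixel_size_xy = DEFAULT_PIXEL_SIZE,
                            z_step = DEFAULT_Z_STEP) {
  channel_role <- match.arg(channel_role)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "fishspat_io_error")
  slices <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                     error = function(e) abort(sprintf("cannot read TIFF %s: %s", path, conditionMessage(e)),
                                               class = "fishspat_io_error"))
  if (!is.list(slices)) slices <- list(slices)
  slices <- lapply(slices, function(s) if (length(dim(s)) == 3L) s[, , 1] else s)
  vox <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]
  image_stack(vox, channel_role, pixel_size_xy, z_step)
}

#' Write an image stack to a TIFF file
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  vox <- stack$voxels
  mx <- max(vox, 1e-12)
  pages <- lapply(seq_len(dim(vox)[3]), function(z) vox[, , z] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Create a cell record
#'
#' The unit of analysis: one segmented cell with its masks, MTOC annotation,
#' and either mRNA spot positions (smFISH) or a projected protein intensity
#' image (IF). Spots lying below the zero level (out-of-focus slices) are
#' removed at construction time and the removal is recorded.
#'
#' @param id image identifier.
#' @param molecule `"mRNA"` or `"protein"`.
#' @param gene gene symbol.
#' @param timepoint_h acquisition time point in hours.
#' @param cell_mask,nucleus_mask [binary_mask()] objects of equal size.
#' @param mtoc length-2 numeric `(x, y)` MTOC position in pixels.
#' @param spots n x 3 matrix `(x, y, z)` of spot positions (mRNA only).
#' @param intensity 2D non-negative matrix `I(x, y)` (protein only).
#' @param nucleus_centroid optional `(x, y)`; computed from the nucleus mask
#'   when missing.
#' @param height_map optional 2D integer matrix of per-pixel slice counts.
#' @param zero_level optional index of the bottom in-focus slice.
#' @param pixel_size_xy,z_step voxel geometry in micrometres.
#' @return An object of class `cell_record`.
#' @export
cell_record <- function(id, molecule = c("mRNA", "protein"), gene = "gene",
                        timepoint_h = 0,
                        cell_mask, nucleus_mask, mtoc,
                        spots = NULL, intensity = NULL,
                        nucleus_centroid = NULL,
                        height_map = NULL, zero_level = NULL,
                        pixel_size_xy = DEFAULT_PIXEL_SIZE,
                        z_step = DEFAULT_Z_STEP) {
  molecule <- match.arg(molecule)
  if (!is_binary_mask(cell_mask)) cell_mask <- binary_mask(cell_mask, "cell")
  if (!is_binary_mask(nucleus_mask)) nucleus_mask <- binary_mask(nucleus_mask, "nucleus")
  if (!all(dim(cell_mask) == dim(nucleus_mask))) abort("mask shapes differ")
  if (molecule == "mRNA") {
    if (is.null(spots) || !is.null(intensity))
      abort("mRNA records carry `spots` and no `intensity`", class = "fishspat_type_error")
    spots <- as.matrix(spots)
    if (length(spots) && ncol(spots) == 2L) spots <- cbind(spots, 0)
    if (length(spots) && ncol(spots) != 3L) abort("`spots` must have columns x, y, z")
    colnames(spots) <- c("x", "y", "z")
  } else {
    if (is.null(intensity) || !is.null(spots))
      abort("protein records carry `intensity` and no `spots`", class = "fishspat_type_error")
    if (any(intensity < 0)) abort("intensity must be non-negative")
  }
  if (length(mtoc) != 2L) abort("`mtoc` must be (x, y)")
  if (!.inside_mask(cell_mask, mtoc[1], mtoc[2]))
    abort("MTOC must lie inside the cell mask", class = "fishspat_validation_error")
  if (is.null(nucleus_centroid)) nucleus_centroid <- mask_centroid(nucleus_mask)

  n_removed <- 0L
  if (molecule == "mRNA" && nrow(spots)) {
    inside <- .inside_mask(cell_mask, spots[, 1], spots[, 2])
    if (!all(inside))
      abort(sprintf("%d spot(s) outside the cell mask", sum(!inside)),
            class = "fishspat_validation_error")
    if (!is.null(zero_level)) {
      keep <- spots[, 3] >= zero_level
      n_removed <- sum(!keep)
      spots <- spots[keep, , drop = FALSE]
    }
  }
  if (!is.null(height_map)) {
    if (!all(dim(height_map) == dim(cell_mask))) abort("height_map shape differs from masks")
    if (any(height_map[!cell_mask] != 0))
      abort("height_map must be 0 outside the cell mask", class = "fishspat_validation_error")
  }
  rec <- structure(
    list(id = as.character(id), molecule = molecule, gene = gene,
         timepoint_h = timepoint_h,
         cell_mask = cell_mask, nucleus_mask = nucleus_mask,
         nucleus_centroid = as.numeric(nucleus_centroid),
         mtoc = as.numeric(mtoc),
         spots = if (molecule == "mRNA") spots else NULL,
         intensity = if (molecule == "protein") intensity else NULL,
         height_map = height_map, zero_level = zero_level,
         pixel_size_xy = pixel_size_xy, z_step = z_step,
         n_spots_below_zero = n_removed),
    class = "cell_record"
  )
  rec
}

#' @export
print.cell_record <- function(x, ...) {
  sig <- if (x$molecule == "mRNA") sprintf("%d spots", nrow(x$spots)) else "intensity image"
  cat(sprintf("<cell_record> %s | %s %s t=%gh | %s | %s\n", x$id, x$gene, x$molecule,
              x$timepoint_h, sig, if (is.null(x$height_map)) "2D" else "3D"))
  invisible(x)
}

.inside_mask <- function(mask, x, y) {
  r <- round(y) + 1L; c <- round(x) + 1L
  ok <- r >= 1L & r <= nrow(mask) & c >= 1L & c <= ncol(mask)
  out <- logical(length(x))
  out[ok] <- mask[cbind(r[ok], c[ok])]
  out
}

#' Geometric centroid of a mask (0-based x, y)
#' @param mask a [binary_mask()].
#' @return numeric `(x, y)`.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) abort("empty mask has no centroid")
  c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)
}

has_height_map <- function(record) !is.null(record$height_map)

#' Create an acquisition series
#'
#' A set of cell records sharing gene, molecule type and condition.
#'
#' @param records list of [cell_record()] objects (at least one).
#' @param gene,molecule,condition shared metadata; defaults taken from the
#'   first record.
#' @return An object of class `acquisition_series`.
#' @export
acquisition_series <- function(records, gene = NULL, molecule = NULL,
                               condition = "micropattern") {
  if (!length(records)) abort("a series needs at least one record")
  gene <- gene %||% records[[1]]$gene
  molecule <- molecule %||% records[[1]]$molecule
  ok <- map_lgl(records, ~ .x$gene == gene && .x$molecule == molecule)
  if (!all(ok)) abort("all records must share gene and molecule")
  structure(
    list(gene = gene, molecule = molecule, condition = condition,
         timepoints = sort(unique(map_dbl(records, "timepoint_h"))),
         records = records),
    class = "acquisition_series"
  )
}

#' @export
length.acquisition_series <- function(x) length(x$records)

#' @export
print.acquisition_series <- function(x, ...) {
  cat(sprintf("<acquisition_series> %s %s (%s): %d cell(s), t = %s h\n",
              x$gene, x$molecule, x$condition, length(x$records),
              paste(x$timepoints, collapse = "/")))
  invisible(x)
}

#' Per-cell signal summary
#'
#' Total cytoplasmic signal (spot count for mRNA, summed intensity for
#' protein), cell area and, when a height map is present, cell volume.
#'
#' @param record a [cell_record()].
#' @return A one-row tibble with columns `id`, `total_cytoplasmic`,
#'   `area_px`, `volume_um3`.
#' @export
signal_summary <- function(record) {
  cyto <- cytoplasm_mask(record$cell_mask, record$nucleus_mask)
  if (record$molecule == "mRNA") {
    total <- sum(.inside_mask(cyto, record$spots[, 1], record$spots[, 2]))
  } else {
    total <- sum(record$intensity[cyto])
  }
  vol <- if (has_height_map(record)) {
    cell_volume(record$height_map, record$pixel_size_xy, record$z_step)
  } else NA_real_
  tibble(id = record$id, total_cytoplasmic = total,
         area_px = mask_area(record$cell_mask), volume_um3 = vol)
}

#' Drop mRNA records with too few spots
#'
#' Low-count cells are unreliable for spatial statistics and are removed
#' before analysis (default threshold 10 spots; noisier probes may need a
#' higher cut such as 100).
#'
#' @param series an mRNA [acquisition_series()].
#' @param min_spots minimum spot count a record must have to be kept.
#' @param quiet suppress the per-record log of discarded ids.
#' @return The filtered [acquisition_series()].
#' @export
filter_low_count_cells <- function(series, min_spots = 10, quiet = FALSE) {
  if (series$molecule != "mRNA")
    abort("filter_low_count_cells applies to mRNA series only",
          class = "fishspat_type_error")
  counts <- map_int(series$records, ~ nrow(.x$spots))
  keep <- counts >= min_spots
  if (!quiet && any(!keep)) {
    ids <- map_chr_safe(series$records[!keep], "id")
    message(sprintf("discarding %d low-count cell(s): %s",
                    sum(!keep), paste(ids, collapse = ", ")))
  }
  series$records <- series$records[keep]
  if (!length(series$records))
    warn("all records filtered out")
  series
}

map_chr_safe <- function(x, field) vapply(x, function(e) as.character(e[[field]]), character(1))
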