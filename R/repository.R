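# Hierarchical HDF5 repository of primary/secondary image descriptors.
#
# Layout (normative for this package):
#   /{molecule}/{gene}/{condition}/{timepoint}/{image_id}/
#     cell_mask (uint8 2D), nucleus_mask (uint8 2D),
#     nucleus_centroid (2 float), mtoc_position (2 float),
#     spots (n x 3 float, mRNA) or IF (2D float, protein),
#     height_map (2D int, optional), zero_level (scalar int, optional)
#   attributes on the image group: pixel_size_xy, z_step
# Spot coordinates are stored in voxel units (pixels / slice index).

#' Write acquisition series to an HDF5 descriptor repository
#'
#' Stores every record of every series under
#' `/{molecule}/{gene}/{condition}/{timepoint}/{image_id}`. Overwrites any
#' existing file at `h5_path` (idempotent). All records are validated before
#' anything is written.
#'
#' @param series_list list of [acquisition_series()] (a bare series is
#'   accepted).
#' @param h5_path output file path.
#' @return `h5_path`, invisibly.
#' @export
write_repository <- function(series_list, h5_path) {
  if (inherits(series_list, "acquisition_series")) series_list <- list(series_list)
  for (s in series_list) {
    if (!inherits(s, "acquisition_series")) abort("expected acquisition_series objects")
    for (r in s$records) .validate_record(r)
  }
  if (file.exists(h5_path)) file.remove(h5_path)
  rhdf5::h5createFile(h5_path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (s in series_list) {
    for (r in s$records) {
      grp <- sprintf("/%s/%s/%s/%s/%s", s$molecule, s$gene, s$condition,
                     format(r$timepoint_h), r$id)
      .h5_mkdirs(h5_path, grp)
      h5w <- function(obj, name) rhdf5::h5write(obj, h5_path, paste0(grp, "/", name))
      h5w(matrix(as.integer(r$cell_mask), nrow(r$cell_mask)), "cell_mask")
      h5w(matrix(as.integer(r$nucleus_mask), nrow(r$nucleus_mask)), "nucleus_mask")
      h5w(as.numeric(r$nucleus_centroid), "nucleus_centroid")
      h5w(as.numeric(r$mtoc), "mtoc_position")
      if (r$molecule == "mRNA") {
        h5w(unname(r$spots), "spots")
      } else {
        h5w(r$intensity, "IF")
      }
      if (!is.null(r$height_map)) h5w(matrix(as.integer(r$height_map), nrow(r$height_map)), "height_map")
      if (!is.null(r$zero_level)) h5w(as.integer(r$zero_level), "zero_level")
      fid <- rhdf5::H5Fopen(h5_path)
      gid <- rhdf5::H5Gopen(fid, grp)
      rhdf5::h5writeAttribute(r$pixel_size_xy, gid, "pixel_size_xy")
      rhdf5::h5writeAttribute(r$z_step, gid, "z_step")
      rhdf5::H5Gclose(gid); rhdf5::H5Fclose(fid)
    }
  }
  invisible(h5_path)
}

.h5_mkdirs <- function(h5_path, grp) {
  parts <- strsplit(sub("^/", "", grp), "/")[[1]]
  acc <- ""
  existing <- rhdf5::h5ls(h5_path)
  have <- if (nrow(existing)) paste(sub("^/$", "", existing$group), existing$name, sep = "/") else character()
  for (p in parts) {
    acc2 <- paste0(acc, "/", p)
    if (!(acc2 %in% have)) rhdf5::h5createGroup(h5_path, acc2)
    have <- c(have, acc2)
    acc <- acc2
  }
}

.validate_record <- function(r) {
  if (!inherits(r, "cell_record")) abort("expected cell_record")
  cell_record(r$id, r$molecule, r$gene, r$timepoint_h, r$cell_mask, r$nucleus_mask,
              r$mtoc, spots = r$spots, intensity = r$intensity,
              nucleus_centroid = r$nucleus_centroid, height_map = r$height_map,
              zero_level = r$zero_level, pixel_size_xy = r$pixel_size_xy,
              z_step = r$z_step)
  invisible(TRUE)
}

#' Read acquisition series from an HDF5 descriptor repository
#'
#' @param h5_path repository written by [write_repository()] (or following
#'   the same layout).
#' @param molecule,gene,condition,timepoint optional selector filters; `NULL`
#'   matches everything.
#' @return A list of [acquisition_series()], one per
#'   molecule/gene/condition combination with at least one matching record.
#'   An empty list when nothing matches.
#' @export
read_repository <- function(h5_path, molecule = NULL, gene = NULL,
                            condition = NULL, timepoint = NULL) {
  if (!file.exists(h5_path)) abort(sprintf("no such file: %s", h5_path), class = "fishspat_io_error")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(h5_path)
  if (!nrow(ls)) return(list())
  grp_depth <- lengths(strsplit(sub("^/", "", paste(ls$group, ls$name, sep = "/")), "/"))
  image_groups <- ls[ls$otype == "H5I_GROUP" & grp_depth == 5, ]
  if (!nrow(image_groups)) return(list())
  out <- list()
  for (i in seq_len(nrow(image_groups))) {
    full <- paste(image_groups$group[i], image_groups$name[i], sep = "/")
    parts <- strsplit(sub("^/", "", full), "/")[[1]]
    mol <- parts[1]; gn <- parts[2]; cond <- parts[3]; tp <- as.numeric(parts[4]); id <- parts[5]
    if (!is.null(molecule) && !(mol %in% molecule)) next
    if (!is.null(gene) && !(gn %in% gene)) next
    if (!is.null(condition) && !(cond %in% condition)) next
    if (!is.null(timepoint) && !(tp %in% timepoint)) next
    members <- ls[ls$group == full, "name"]
    for (need in c("cell_mask", "nucleus_mask", "mtoc_position")) {
      if (!(need %in% members))
        abort(sprintf("repository group %s is missing dataset %s", full, need),
              class = "fishspat_schema_error")
    }
    if (!any(c("spots", "IF") %in% members))
      abort(sprintf("repository group %s has neither spots nor IF", full),
            class = "fishspat_schema_error")
    rd <- function(name) rhdf5::h5read(h5_path, paste0(full, "/", name))
    attrs <- rhdf5::h5readAttributes(h5_path, full)
    spots <- if ("spots" %in% members) {
      sp <- rd("spots")
      if (is.null(dim(sp))) sp <- matrix(sp, ncol = 3)
      sp
    } else NULL
    rec <- cell_record(
      id = id, molecule = if (is.null(spots)) "protein" else "mRNA",
      gene = gn, timepoint_h = tp,
      cell_mask = binary_mask(rd("cell_mask") != 0, "cell"),
      nucleus_mask = binary_mask(rd("nucleus_mask") != 0, "nucleus"),
      mtoc = as.numeric(rd("mtoc_position")),
      spots = spots,
      intensity = if ("IF" %in% members) rd("IF") else NULL,
      nucleus_centroid = as.numeric(rd("nucleus_centroid")),
      height_map = if ("height_map" %in% members) rd("height_map") else NULL,
      zero_level = if ("zero_level" %in% members) as.integer(rd("zero_level")) else NULL,
      pixel_size_xy = as.numeric(attrs$pixel_size_xy %||% DEFAULT_PIXEL_SIZE),
      z_step = as.numeric(attrs$z_step %||% DEFAULT_Z_STEP)
    )
    key <- paste(mol, gn, cond, sep = "|")
    out[[key]] <- c(out[[key]], list(rec))
  }
  imap(out, function(recs, key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    acquisition_series(recs, gene = parts[2], molecule = parts[1], condition = parts[3])
  }) |> unname()
}

#' Read a table of manual MTOC annotations
#'
#' Delimited text with columns `image_id`, `x`, `y` (pixel coordinates).
#'
#' @param path file path.
#' @param sep field separator.
#' @return A tibble with one row per annotated image.
#' @export
read_mtoc_annotations <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("image_id", "x", "y")
  if (!all(need %in% names(df)))
    abort("MTOC annotation table needs columns image_id, x, y",
          class = "fishspat_schema_error")
  as_tibble(df[, need])
}
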