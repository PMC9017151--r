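# Orchestration: build descriptor repositories from raw stacks, run the
# statistics suite over a repository, run the muscle analyses. These are
# the programmatic equivalents of the command-line entry points (see
# inst/cli/fishspat).

#' Build an HDF5 descriptor repository from raw image stacks
#'
#' For each image: segments the cell (tubulin) and nucleus (DAPI), computes
#' the zero level, detects spots (mRNA) or the summed intensity projection
#' (protein), attaches the annotated MTOC and writes the record to the
#' repository. Images without an MTOC annotation, or whose segmentation
#' fails, are skipped with a log message; the run is idempotent.
#'
#' @param images data frame with columns `id`, `gene`, `molecule`,
#'   `timepoint_h`, `tubulin`, `dapi`, `signal` (TIFF paths).
#' @param mtoc_table data frame with `image_id`, `x`, `y` (see
#'   [read_mtoc_annotations()]).
#' @param h5_path output repository path.
#' @param seg_params a [segmentation_params()].
#' @param spot_params a [spot_detection_params()].
#' @param condition condition label for the repository hierarchy.
#' @return Tibble log with one row per input image (`id`, `status`,
#'   `message`), invisibly; the repository is written to `h5_path`.
#' @export
run_build_descriptors <- function(images, mtoc_table, h5_path,
                                  seg_params = segmentation_params(),
                                  spot_params = spot_detection_params(),
                                  condition = "micropattern") {
  log <- list()
  by_series <- list()
  for (i in seq_len(nrow(images))) {
    row <- images[i, ]
    res <- tryCatch({
      mt <- mtoc_table[mtoc_table$image_id == row$id, ]
      if (!nrow(mt)) stop("no MTOC annotation")
      tub <- load_tiff_stack(row$tubulin, "tubulin")
      dap <- load_tiff_stack(row$dapi, "nucleus")
      sig <- load_tiff_stack(row$signal, "signal")
      cellm <- detect_cell_mask(tub, seg_params)
      nucm <- detect_nucleus_mask(dap, seg_params)
      nucm <- binary_mask(unclass(nucm) & unclass(cellm), "nucleus")
      zl <- compute_zero_level(tub)
      if (row$molecule == "mRNA") {
        sp <- detect_spots(sig, spot_params, zero_level = NULL)
        keep <- .inside_mask(cellm, sp[, 1], sp[, 2])
        rec <- cell_record(row$id, "mRNA", row$gene, row$timepoint_h, cellm, nucm,
                           mtoc = c(mt$x[1], mt$y[1]), spots = sp[keep, , drop = FALSE],
                           zero_level = zl)
      } else {
        rec <- cell_record(row$id, "protein", row$gene, row$timepoint_h, cellm, nucm,
                           mtoc = c(mt$x[1], mt$y[1]),
                           intensity = sum_intensity_projection(sig),
                           zero_level = zl)
      }
      key <- paste(row$gene, row$molecule, sep = "|")
      by_series[[key]] <- c(by_series[[key]], list(rec))
      "ok"
    }, error = function(e) conditionMessage(e))
    if (res != "ok") message(sprintf("image %s skipped: %s", row$id, res))
    log[[i]] <- tibble(id = row$id, status = if (res == "ok") "ok" else "skipped",
                       message = if (res == "ok") "" else res)
  }
  series <- imap(by_series, function(recs, key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    acquisition_series(recs, gene = parts[1], molecule = parts[2],
                       condition = condition)
  }) |> unname()
  write_repository(series, h5_path)
  invisible(bind_rows(log))
}

STAT_NAMES <- c("periph", "noise", "spread", "mpi", "clustering", "deviation")

#' Run the statistics suite over acquisition series
#'
#' Computes the selected statistics for every series and returns one tidy
#' table per statistic. With a fixed seed the output is fully reproducible.
#'
#' @param series_list list of [acquisition_series()] (e.g. from
#'   [read_repository()]).
#' @param which subset of `"periph"`, `"noise"`, `"spread"`, `"mpi"`,
#'   `"clustering"`, `"deviation"`.
#' @param seed integer seed used for every stochastic estimator.
#' @param n_permutations CSR permutations for the clustering statistics.
#' @param n_boot bootstrap resamples for the MPI.
#' @param out_dir optional directory; tables are written there as TSV.
#' @return Named list of tibbles (one per statistic) plus a `report` tibble
#'   recording parameters and seeds.
#' @export
run_stats <- function(series_list, which = STAT_NAMES, seed = 1,
                      n_permutations = 100, n_boot = 100, out_dir = NULL) {
  bad <- setdiff(which, STAT_NAMES)
  if (length(bad))
    abort(sprintf("unknown statistic(s): %s", paste(bad, collapse = ", ")),
          class = "fishspat_usage_error")
  out <- list()
  meta <- function(s) tibble(gene = s$gene, molecule = s$molecule,
                             condition = s$condition)
  prep <- map(series_list, function(s) {
    dmaps <- map(s$records, function(r) {
      cyto <- cytoplasm_mask(r$cell_mask, r$nucleus_mask)
      peripheral_distance_map(cyto, r$nucleus_mask, r$nucleus_centroid,
                              height_map = r$height_map,
                              pixel_size_xy = r$pixel_size_xy, z_step = r$z_step)
    })
    list(series = s, dmaps = dmaps)
  })
  if ("periph" %in% which) {
    out$periph <- bind_rows(map(prep, function(p) {
      bind_cols(meta(p$series), peripheral_fraction_profile(p$series, p$dmaps))
    }))
  }
  if ("noise" %in% which) {
    out$noise <- bind_rows(map(prep, function(p) {
      sm <- bind_rows(map(p$series$records, signal_summary))
      if (all(is.na(sm$volume_um3))) sm$volume_um3 <- sm$area_px # 2D fallback
      nm <- tryCatch(volume_corrected_noise(sm), error = function(e) NA_real_)
      bind_cols(meta(p$series), tibble(nm = nm, n_cells = nrow(sm)))
    }))
  }
  if ("spread" %in% which) {
    out$spread <- bind_rows(map(prep, function(p) {
      s <- p$series
      rows <- map(seq_along(s$records), function(i) {
        r <- s$records[[i]]
        cen <- tryCatch(centrality(r, p$dmaps[[i]]), error = function(e) NA_real_)
        ent <- if (r$molecule == "mRNA" && nrow(r$spots) >= 6) {
          tryCatch(spread_entropy(r$spots[, 1:2]), error = function(e) NA_real_)
        } else NA_real_
        tibble(id = r$id, timepoint_h = r$timepoint_h,
               centrality = cen, entropy = ent)
      })
      df <- bind_rows(rows)
      if (any(!is.na(df$entropy)))
        df$entropy_norm <- df$entropy / max(df$entropy, na.rm = TRUE)
      bind_cols(meta(s)[rep(1, nrow(df)), ], df)
    }))
  }
  if ("mpi" %in% which) {
    out$mpi <- bind_rows(map(prep, function(p) {
      m <- mpi(p$series, dmaps = p$dmaps, n_boot = n_boot, seed = seed)
      bind_cols(meta(p$series), tidy(m))
    }))
  }
  if ("clustering" %in% which) {
    out$clustering <- bind_rows(map(prep, function(p) {
      s <- p$series
      rows <- map(seq_along(s$records), function(i) {
        r <- s$records[[i]]
        cyto <- cytoplasm_mask(r$cell_mask, r$nucleus_mask)
        res <- if (r$molecule == "mRNA") {
          win <- win_mask(cyto)
          sp <- r$spots[.inside_mask(cyto, r$spots[, 1], r$spots[, 2]), , drop = FALSE]
          if (nrow(sp) < 2) return(NULL)
          ripley_clustering(points = sp, window = win,
                            n_permutations = n_permutations, seed = seed + i)
        } else {
          ripley_clustering(intensity = r$intensity, window = cyto,
                            n_permutations = n_permutations, seed = seed + i)
        }
        bind_cols(tibble(id = r$id, timepoint_h = r$timepoint_h), glance(res))
      })
      df <- bind_rows(rows)
      bind_cols(meta(s)[rep(1, nrow(df)), ], df)
    }))
  }
  if ("deviation" %in% which) {
    out$deviation <- bind_rows(map(prep, function(p) {
      vecs <- map(seq_along(p$series$records),
                  ~ peripheral_density_vector(p$series$records[[.x]], p$dmaps[[.x]]))
      n <- length(vecs)
      if (n < 3) return(NULL)
      dev <- pooled_deviation_profile(vecs, pool_sizes = seq_len(min(n - 1, 40)),
                                      seed = seed)
      bind_cols(meta(p$series)[rep(1, nrow(dev)), ], dev)
    }))
  }
  out$report <- tibble(statistic = names(out), seed = seed,
                       n_permutations = n_permutations, n_boot = n_boot)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.table(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  out
}

#' Run the muscle analysis suite
#'
#' Pools the Z-line spacing over fibers, computes the median Z-line
#' distance profile, and the internuclear local density at each requested
#' band count.
#'
#' @param fibers list of [fiber_record()] objects.
#' @param n_segments band counts for the vertical quantization.
#' @param Z optional fixed Z-line spacing.
#' @param min_slice_spots slice inclusion threshold for the distance
#'   profile.
#' @param out_dir optional directory for TSV output.
#' @return Named list: `spacing`, `profile` (tibble), `density` (tibble
#'   with an `n_segments` column).
#' @export
run_muscle <- function(fibers, n_segments = c(20, 80), Z = NULL,
                       min_slice_spots = 25, out_dir = NULL) {
  for (f in fibers) {
    if (is.null(f$zline_masks) || !length(f$zline_masks))
      abort(sprintf("fiber %s has no Z-line masks", f$id),
            class = "fishspat_capability_error")
  }
  Z <- Z %||% zline_spacing(unlist(map(fibers, "zline_masks"), recursive = FALSE))
  prof <- zline_profile(fibers, Z = Z, min_slice_spots = min_slice_spots)
  dens <- bind_rows(map(n_segments, function(n) {
    bind_rows(map(fibers, function(f) {
      segs <- vertical_quantization(f, n)
      mutate(muscle_local_density(f, segs), id = f$id, n_segments = n)
    }))
  }))
  out <- list(spacing = Z, profile = prof, density = dens)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(prof, file.path(out_dir, "zline_profile.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(dens, file.path(out_dir, "muscle_density.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
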