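#' Run the full pipeline on a synthetic cohort
#'
#' Chains all stages under one configuration: simulate the cohort of fields
#' ([simulate_imaging_cohort()]), render both autofluorescence channels and
#' the reporter images per field, fit the decays ([fit_image()]), segment
#' the macrophages and classify TNFα status, aggregate per-cell endpoints
#' and the OMI index, fit the cohort models, and write every artifact plus
#' a manifest (parameters, seeds and an MD5 checksum per file) to the
#' output directory. Re-running with the same configuration reproduces
#' byte-identical CSV outputs.
#'
#' @param config Configuration list, see [default_config()] /
#'   [read_run_config()].
#' @param out_dir Output directory (created if needed). `NULL` skips all
#'   file output and returns results in memory only.
#' @param keep_images Write per-field TIFF artifacts (cubes, maps, labels)?
#'   Default `TRUE` when `out_dir` is set; the cell-record and stats CSVs
#'   are always written.
#' @param quiet Suppress per-stage progress messages.
#' @return List with `cells` (cohort table incl. OMI), `truth` (injected
#'   ground truth), `stats` (named list of `omi_glm` fits), `manifest`.
#' @export
run_all <- function(config = default_config(), out_dir = NULL,
                    keep_images = !is.null(out_dir), quiet = FALSE) {
  cfg <- merge_config(default_config(), config)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf(paste0("[%s] ", fmt),
                                format(Sys.time(), "%H:%M:%S"), ...))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  files <- character()

  ta <- time_axis(cfg$simulate$n_bins, window = cfg$simulate$window_ns)
  irf <- make_irf(cfg$irf$fwhm_ps, ta, cfg$irf$peak_bin)

  say("simulate: %d days x %d larvae x %d cells, %dx%d fields",
      cfg$simulate$n_days, cfg$simulate$larvae_per_day,
      cfg$simulate$cells_per_larva, cfg$simulate$shape[1],
      cfg$simulate$shape[2])
  sim <- simulate_imaging_cohort(
    n_days = cfg$simulate$n_days,
    larvae_per_day = cfg$simulate$larvae_per_day,
    cells_per_larva = cfg$simulate$cells_per_larva,
    shape = cfg$simulate$shape,
    radius_range = cfg$simulate$radius_range,
    tnfa_prop = cfg$simulate$tnfa_prop,
    effect = cfg$simulate$effect,
    day_shift_sd = cfg$simulate$day_shift_sd,
    larva_sd = cfg$simulate$larva_sd,
    budget = cfg$simulate$budget,
    background_offset = cfg$simulate$background_offset,
    treatment = cfg$simulate$treatment,
    seed = cfg$seed
  )

  cell_tables <- list()
  for (k in seq_along(sim$fields)) {
    sp <- sim$fields[[k]]
    scene <- make_scene(sp)
    say("field %d/%d (larva %s): render + fit", k, length(sim$fields),
        sp$larva_id)
    cube_n <- render_decay_cube(scene, "nadph", irf, ta,
                                wrap = cfg$fit$wrap)
    cube_f <- render_decay_cube(scene, "fad", irf, ta,
                                seed = scene$meta$seed + 1L,
                                wrap = cfg$fit$wrap)
    rep_imgs <- render_reporter_images(scene,
                                       noise_sd =
                                         cfg$simulate$reporter_noise_sd)

    maps_n <- fit_image(cube_n, irf, threshold = cfg$fit$threshold,
                        binning = cfg$fit$binning,
                        objective = cfg$fit$objective, wrap = cfg$fit$wrap)
    maps_f <- fit_image(cube_f, irf, threshold = cfg$fit$threshold,
                        binning = cfg$fit$binning,
                        objective = cfg$fit$objective, wrap = cfg$fit$wrap)

    lab <- segment_macrophages(rep_imgs$mcherry,
                               threshold = cfg$segment$threshold,
                               min_area = cfg$segment$min_area)
    if (isTRUE(cfg$segment$exclude_bacteria)) {
      lab <- exclude_bacteria(lab, rep_imgs$mcherry,
                              cfg$segment$bacteria_threshold)
    }
    ann <- classify_tnfa(lab, rep_imgs$gfp, cfg$segment$gfp_threshold)

    redox <- redox_ratio_map(maps_n$intensity, maps_f$intensity,
                             validity = maps_n$valid & maps_f$valid)
    cells <- per_cell_endpoints(
      maps_n, maps_f, redox, lab, annotations = ann,
      metadata = scene$meta,
      min_valid_pixels = cfg$endpoints$min_valid_pixels
    )
    cell_tables[[k]] <- cells

    if (!is.null(out_dir) && keep_images) {
      stem <- file.path(out_dir, sprintf("field_%02d", k))
      files <- c(
        files,
        write_decay_cube(cube_n, paste0(stem, "_nadph.tif")),
        write_decay_cube(cube_f, paste0(stem, "_fad.tif")),
        write_parameter_maps(maps_n, paste0(stem, "_nadph_maps.tif")),
        write_parameter_maps(maps_f, paste0(stem, "_fad_maps.tif")),
        write_label_image(lab, paste0(stem, "_labels.tif"))
      )
    }
  }

  cohort <- dplyr::bind_rows(cell_tables)
  if (nrow(cohort) == 0) {
    stop("endpoints stage produced no cells", call. = FALSE)
  }
  cohort <- omi_index(cohort, by = cfg$endpoints$omi_by)

  say("stats: %d cells from %d larvae", nrow(cohort),
      length(unique(cohort$larva_id)))
  stats_cfg <- cfg$stats
  for (v in stats_cfg$treatment) {
    if (!v %in% names(cohort)) {
      stop(sprintf("stats stage: treatment column '%s' missing from the %s",
                   v, "cell table"), call. = FALSE)
    }
  }
  fits <- list()
  for (oc in stats_cfg$outcome) {
    fits[[oc]] <- fit_glm(
      cohort, outcome = oc, treatment = stats_cfg$treatment,
      block = stats_cfg$block, cluster = stats_cfg$cluster,
      log_transform = stats_cfg$log_transform,
      interaction = stats_cfg$interaction
    )
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    files <- c(
      files,
      write_cell_records(cohort, file.path(out_dir, "cell_records.csv")),
      write_cell_records(sim$truth, file.path(out_dir, "ground_truth.csv"))
    )
    files <- c(files, write_irf(irf, file.path(out_dir, "irf.csv")))
    for (oc in names(fits)) {
      files <- c(files, write_stats_result(fits[[oc]], out_dir, stem = oc))
    }
    sidecars <- vapply(files, sidecar_path, character(1))
    files <- unique(c(files, sidecars[file.exists(sidecars)]))
    manifest <- list(
      package_version = as.character(utils::packageVersion("omiflim")),
      seed = cfg$seed,
      config = cfg,
      files = lapply(sort(files), function(f) {
        list(path = basename(f),
             md5 = unname(tools::md5sum(f)))
      })
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(cells = cohort, truth = sim$truth, stats = fits,
                 manifest = manifest))
}
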