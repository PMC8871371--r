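#' Write / read a decay cube as multi-page TIFF plus JSON sidecar
#'
#' Cubes are stored as 16-bit grayscale multi-page TIFF, one page per time
#' bin in time order, with a JSON sidecar (same path, `.json` extension)
#' holding the time axis, channel, seeds and cohort identifiers. The
#' round-trip is lossless for integer counts up to 65535.
#'
#' @param cube A `decay_cube`.
#' @param path Output TIFF path (`.tif`/`.tiff`); the sidecar goes next to
#'   it.
#' @return `write_decay_cube()` returns `path` invisibly;
#'   `read_decay_cube()` returns the `decay_cube`.
#' @export
write_decay_cube <- function(cube, path) {
  stopifnot(inherits(cube, "decay_cube"))
  counts <- round(cube$counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (max(counts) > 65535) {
    stop("counts exceed the 16-bit TIFF range", call. = FALSE)
  }
  n_bins <- dim(counts)[3]
  pages <- lapply(seq_len(n_bins), function(k) counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  sidecar <- list(
    kind = "decay_cube",
    channel = cube$channel,
    shape = dim(counts)[1:2],
    time_axis = list(n_bins = cube$time_axis$n_bins,
                     bin_width_ns = cube$time_axis$bin_width,
                     window_ns = cube$time_axis$window),
    meta = cube$meta
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_decay_cube
#' @export
read_decay_cube <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) {
    stop(sprintf("missing sidecar '%s'", sc_path), call. = FALSE)
  }
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (field in c("channel", "time_axis")) {
    if (is.null(sc[[field]])) {
      stop(sprintf("sidecar schema error: missing field '%s'", field),
           call. = FALSE)
    }
  }
  for (field in c("n_bins", "bin_width_ns")) {
    if (is.null(sc$time_axis[[field]])) {
      stop(sprintf("sidecar schema error: missing field 'time_axis.%s'",
                   field), call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != sc$time_axis$n_bins) {
    stop(sprintf(
      "page-count mismatch: TIFF has %d pages but sidecar declares %d bins",
      length(pages), sc$time_axis$n_bins), call. = FALSE)
  }
  counts <- vapply(pages, function(p) round(p * 65535), pages[[1]])
  if (any(counts < 0)) {
    stop("negative counts in decay cube", call. = FALSE)
  }
  ta <- time_axis(n_bins = sc$time_axis$n_bins,
                  bin_width = sc$time_axis$bin_width_ns)
  structure(
    list(counts = counts, time_axis = ta, channel = sc$channel,
         meta = as.list(sc$meta)),
    class = "decay_cube"
  )
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Write / read an IRF kernel as two-column CSV
#'
#' Columns `bin` (1-based index) and `counts` (kernel weight); the time
#' axis and construction parameters travel in a JSON sidecar.
#'
#' @param irf An `irf_kernel`.
#' @param path Output CSV path.
#' @export
write_irf <- function(irf, path) {
  stopifnot(inherits(irf, "irf_kernel"))
  readr::write_csv(tibble::tibble(bin = seq_along(irf$values),
                                  counts = irf$values), path)
  jsonlite::write_json(
    list(kind = "irf", fwhm_ps = irf$fwhm_ps, peak_bin = irf$peak_bin,
         time_axis = list(n_bins = irf$time_axis$n_bins,
                          bin_width_ns = irf$time_axis$bin_width)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_irf
#' @export
read_irf <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("bin", "counts") %in% names(tab)))
  sc_path <- sidecar_path(path)
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    ta <- time_axis(sc$time_axis$n_bins, bin_width = sc$time_axis$bin_width_ns)
    fwhm <- sc$fwhm_ps
    peak <- sc$peak_bin
  } else {
    ta <- time_axis(n_bins = nrow(tab))
    peak <- which.max(tab$counts)
    fwhm <- NA_real_
  }
  values <- tab$counts / sum(tab$counts)
  irf <- structure(
    list(values = values, fwhm_ps = fwhm, peak_bin = as.integer(peak),
         time_axis = ta),
    class = "irf_kernel"
  )
  if (is.na(fwhm)) irf$fwhm_ps <- irf_fwhm(irf)
  irf
}

#' Write / read fitted parameter maps
#'
#' Maps are stored as 32-bit float multi-page TIFF in the documented page
#' order tau1, tau2, alpha1, tau_mean, intensity, chi2, validity. Because
#' float TIFF pages hold values in `[0, 1]`, each page is stored divided by
#' a per-page scale recorded in the JSON sidecar (round trip is exact to
#' single-float precision). Invalid pixels are stored as 0 and restored to
#' `NA` from the validity page.
#'
#' @param maps A `parameter_maps` object.
#' @param path Output TIFF path.
#' @export
write_parameter_maps <- function(maps, path) {
  stopifnot(inherits(maps, "parameter_maps"))
  page_names <- c("tau1", "tau2", "alpha1", "tau_mean", "intensity", "chi2")
  scales <- vapply(page_names, function(nm) {
    mx <- suppressWarnings(max(maps[[nm]], na.rm = TRUE))
    if (!is.finite(mx) || mx <= 0) 1 else mx
  }, numeric(1))
  pages <- lapply(page_names, function(nm) {
    m <- maps[[nm]]
    m[is.na(m)] <- 0
    m / scales[[nm]]
  })
  pages <- c(pages, list(maps$valid * 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(kind = "parameter_maps", channel = maps$channel,
         page_order = c(page_names, "valid"),
         page_scales = as.list(scales),
         settings = maps$settings[c("threshold", "binning", "objective",
                                    "wrap", "irf_fwhm_ps", "irf_peak_bin")],
         meta = maps$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_parameter_maps
#' @export
read_parameter_maps <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) {
    stop(sprintf("missing sidecar '%s'", sc_path), call. = FALSE)
  }
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  page_names <- sc$page_order
  if (length(pages) != length(page_names)) {
    stop("page-count mismatch with declared page order", call. = FALSE)
  }
  maps <- list()
  valid <- pages[[length(pages)]] > 0.5
  for (i in seq_along(page_names)) {
    nm <- page_names[i]
    if (nm == "valid") next
    m <- pages[[i]] * sc$page_scales[[nm]]
    m[!valid] <- NA_real_
    maps[[nm]] <- m
  }
  maps$valid <- valid
  structure(
    c(maps, list(channel = sc$channel, settings = as.list(sc$settings),
                 meta = as.list(sc$meta))),
    class = "parameter_maps"
  )
}

#' Write / read a label image as 16-bit TIFF
#'
#' @param label_image Integer matrix of cell labels.
#' @param path Output TIFF path.
#' @export
write_label_image <- function(label_image, path) {
  if (max(label_image) > 65535) {
    stop("too many labels for a 16-bit TIFF", call. = FALSE)
  }
  tiff::writeTIFF(matrix(as.integer(label_image),
                         nrow(label_image)) / 65535,
                  path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(
    list(kind = "label_image",
         threshold = attr(label_image, "threshold"),
         min_area = attr(label_image, "min_area"),
         connectivity = attr(label_image, "connectivity"),
         source = attr(label_image, "source")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  m <- tiff::readTIFF(path)
  lab <- matrix(as.integer(round(m * 65535)), nrow(m))
  sc_path <- sidecar_path(path)
  if (file.exists(sc_path)) {
    sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    return(new_label_image(lab, sc$threshold %||% NA_real_,
                           sc$min_area %||% NA_integer_,
                           sc$source %||% "file"))
  }
  new_label_image(lab, NA_real_, NA_integer_, "file")
}

#' Write a cohort table of cell records
#'
#' The contract between the imaging and statistics halves of the pipeline:
#' one row per cell, columns in documented order (identifiers, TNFα
#' status, coverage, then endpoints).
#'
#' @param cohort_table Tibble of cell records.
#' @param path Output CSV path.
#' @export
write_cell_records <- function(cohort_table, path) {
  lead <- intersect(c("cell_id", "larva_id", "day_id", "treatment",
                      "tnfa_status", "n_valid_pixels", "area"),
                    names(cohort_table))
  out <- cohort_table[, c(lead, setdiff(names(cohort_table), lead)),
                      drop = FALSE]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_cell_records
#' @export
read_cell_records <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a fitted endpoint model to CSV + JSON
#'
#' Writes `<stem>_coefficients.csv`, `<stem>_means.csv`,
#' `<stem>_contrasts.csv` and `<stem>_settings.json` into `dir`.
#'
#' @param x An `omi_glm`.
#' @param dir Output directory.
#' @param stem File-name stem (default the outcome name).
#' @return Character vector of the written paths, invisibly.
#' @export
write_stats_result <- function(x, dir, stem = x$spec$outcome) {
  stopifnot(inherits(x, "omi_glm"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    coefficients = file.path(dir, paste0(stem, "_coefficients.csv")),
    means = file.path(dir, paste0(stem, "_means.csv")),
    contrasts = file.path(dir, paste0(stem, "_contrasts.csv")),
    settings = file.path(dir, paste0(stem, "_settings.json"))
  )
  readr::write_csv(tidy(x), paths[["coefficients"]])
  readr::write_csv(x$means, paths[["means"]])
  readr::write_csv(x$contrasts, paths[["contrasts"]])
  jsonlite::write_json(
    c(x$spec, list(n_cells = x$n_cells, n_larvae = x$n_larvae,
                   n_days = x$n_days, df = x$df,
                   vcov_flavor = "CR1 (t with G-1 df)")),
    paths[["settings"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
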