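#' Per-pixel optical redox ratio map
#'
#' The optical redox ratio used here is
#' `ORR = I_NAD(P)H / (I_NAD(P)H + I_FAD)`, which is bounded in `[0, 1]`
#' and increases with a more reduced intracellular environment. Intensities
#' are the fitted decay-component photon counts (background offset
#' removed). Pixels where both intensities are zero, or that are invalid in
#' the supplied mask, are marked invalid.
#'
#' @param nadph_intensity,fad_intensity Nonnegative matrices of the same
#'   shape.
#' @param validity Optional logical matrix; pixels `FALSE` here are invalid
#'   regardless of intensity (typically the intersection of the two
#'   channels' fit-validity masks).
#' @return A `redox_map`: list with `orr` (matrix, `NA` where invalid) and
#'   logical `valid`.
#' @export
redox_ratio_map <- function(nadph_intensity, fad_intensity,
                            validity = NULL) {
  if (!all(dim(nadph_intensity) == dim(fad_intensity))) {
    stop("channel intensity images must have the same shape", call. = FALSE)
  }
  if (any(nadph_intensity < 0, na.rm = TRUE) ||
      any(fad_intensity < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  tot <- nadph_intensity + fad_intensity
  valid <- !is.na(tot) & tot > 0
  if (!is.null(validity)) {
    stopifnot(all(dim(validity) == dim(valid)))
    valid <- valid & validity
  }
  orr <- matrix(NA_real_, nrow(tot), ncol(tot))
  orr[valid] <- nadph_intensity[valid] / tot[valid]
  structure(list(orr = orr, valid = valid), class = "redox_map")
}

#' Average optical endpoints over each cell
#'
#' For every labelled cell, takes the arithmetic mean of each per-pixel
#' endpoint over the pixels that are valid in the relevant map(s):
#' lifetime endpoints over that channel's fit-validity mask, the redox
#' ratio over the redox validity mask. Cells with no valid pixel in any
#' required map are dropped with a warning. Cohort identifiers and TNFα
#' annotations are propagated onto each record.
#'
#' @param nadph_maps,fad_maps `parameter_maps` for the two channels
#'   ([fit_image()]); `fad_maps` may be `NULL` when FAD was not acquired.
#' @param redox `redox_map` ([redox_ratio_map()]) or `NULL`.
#' @param label_image A `label_image`.
#' @param annotations Optional tibble from [classify_tnfa()]; joined by
#'   `cell_id`.
#' @param metadata Named list with `larva_id`, `day_id`, `treatment`
#'   (defaults taken from `nadph_maps$meta` when present).
#' @param min_valid_pixels Cells with fewer valid pixels than this are
#'   flagged (`low_coverage = TRUE`) but retained; default 5.
#' @return Tibble of cell records: identifiers, `tnfa_status`,
#'   `n_valid_pixels`, `area`, per-cell means `orr`, `nadph_tm`,
#'   `nadph_tau1`, `nadph_tau2`, `nadph_alpha1` (and the `fad_*`
#'   equivalents when FAD maps are given), and `low_coverage`.
#' @export
per_cell_endpoints <- function(nadph_maps, fad_maps = NULL, redox = NULL,
                               label_image, annotations = NULL,
                               metadata = NULL, min_valid_pixels = 5L) {
  stopifnot(inherits(nadph_maps, "parameter_maps"))
  if (!all(dim(nadph_maps$valid) == dim(label_image))) {
    stop("parameter maps and label image must have the same shape",
         call. = FALSE)
  }
  if (!is.null(fad_maps) &&
      !all(dim(fad_maps$valid) == dim(label_image))) {
    stop("FAD maps and label image must have the same shape", call. = FALSE)
  }
  if (is.null(metadata)) metadata <- nadph_maps$meta
  meta <- list(
    larva_id = metadata$larva_id %||% NA_character_,
    day_id = metadata$day_id %||% NA_character_,
    treatment = metadata$treatment %||% NA_character_
  )

  n <- max(label_image)
  if (n == 0L) stop("label image contains no cells", call. = FALSE)
  lab <- as.vector(label_image)

  cell_mean <- function(map, valid) {
    ok <- lab > 0L & as.vector(valid) & !is.na(as.vector(map))
    means <- rep(NA_real_, n)
    if (any(ok)) {
      agg <- tapply(as.vector(map)[ok], lab[ok], mean)
      means[as.integer(names(agg))] <- agg
    }
    means
  }
  count_valid <- function(valid) {
    ok <- lab > 0L & as.vector(valid)
    tabulate(lab[ok], nbins = n)
  }

  rec <- tibble::tibble(
    cell_id = seq_len(n),
    larva_id = meta$larva_id, day_id = meta$day_id,
    treatment = meta$treatment,
    area = as.integer(tabulate(lab[lab > 0L], nbins = n)),
    n_valid_pixels = as.integer(count_valid(nadph_maps$valid)),
    nadph_tm = cell_mean(nadph_maps$tau_mean, nadph_maps$valid),
    nadph_tau1 = cell_mean(nadph_maps$tau1, nadph_maps$valid),
    nadph_tau2 = cell_mean(nadph_maps$tau2, nadph_maps$valid),
    nadph_alpha1 = cell_mean(nadph_maps$alpha1, nadph_maps$valid)
  )
  if (!is.null(fad_maps)) {
    rec$fad_tm <- cell_mean(fad_maps$tau_mean, fad_maps$valid)
    rec$fad_tau1 <- cell_mean(fad_maps$tau1, fad_maps$valid)
    rec$fad_tau2 <- cell_mean(fad_maps$tau2, fad_maps$valid)
    rec$fad_alpha1 <- cell_mean(fad_maps$alpha1, fad_maps$valid)
  }
  if (!is.null(redox)) {
    stopifnot(inherits(redox, "redox_map"))
    rec$orr <- cell_mean(redox$orr, redox$valid)
  }

  if (!is.null(annotations)) {
    rec <- dplyr::left_join(
      rec,
      dplyr::select(annotations, "cell_id", "tnfa_status",
                    "gfp_positive_pixels"),
      by = "cell_id"
    )
  } else {
    rec$tnfa_status <- NA_character_
  }

  dropped <- rec$n_valid_pixels == 0L
  if (any(dropped)) {
    warning(sprintf("dropping %d cell(s) with no valid fitted pixels",
                    sum(dropped)), call. = FALSE)
    rec <- rec[!dropped, , drop = FALSE]
  }
  rec$low_coverage <- rec$n_valid_pixels < min_valid_pixels
  rec
}

#' OMI index with cohort-mean normalisation
#'
#' The optical metabolic imaging (OMI) index of cell i is the linear
#' combination of its mean-centred endpoints with coefficients (1, 1, -1):
#' `omi_i = ORR_i/<ORR> + tmN_i/<tmN> - tmF_i/<tmF>`, where `<.>` are
#' arithmetic means of the per-cell endpoints over the normalisation
#' group. By construction the mean OMI over each normalisation group is
#' exactly 1.
#'
#' @param cohort_table Tibble of cell records with columns `orr`,
#'   `nadph_tm`, `fad_tm`.
#' @param by Optional column name(s) defining normalisation groups (e.g.
#'   `"day_id"`); default `NULL` pools all cells.
#' @return The table with an `omi` column added; the group means are
#'   attached as attribute `"omi_norm"` and the grouping recorded as
#'   attribute `"omi_by"`.
#' @export
omi_index <- function(cohort_table, by = NULL) {
  needed <- c("orr", "nadph_tm", "fad_tm")
  missing <- setdiff(needed, names(cohort_table))
  if (length(missing) > 0) {
    stop(sprintf("cohort table lacks endpoint column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(cohort_table) == 0) stop("cohort table is empty", call. = FALSE)
  grouped <- if (is.null(by)) {
    dplyr::mutate(cohort_table, .omi_grp = "all")
  } else {
    dplyr::mutate(cohort_table,
                  .omi_grp = do.call(paste, c(cohort_table[by], sep = "|")))
  }
  norm <- grouped |>
    dplyr::group_by(.data$.omi_grp) |>
    dplyr::summarise(
      mean_orr = mean(.data$orr, na.rm = TRUE),
      mean_nadph_tm = mean(.data$nadph_tm, na.rm = TRUE),
      mean_fad_tm = mean(.data$fad_tm, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(norm$mean_orr <= 0 | norm$mean_nadph_tm <= 0 |
          norm$mean_fad_tm <= 0, na.rm = TRUE)) {
    stop("cohort means must be positive to normalise the OMI index",
         call. = FALSE)
  }
  out <- grouped |>
    dplyr::left_join(norm, by = ".omi_grp") |>
    dplyr::mutate(
      omi = .data$orr / .data$mean_orr +
        .data$nadph_tm / .data$mean_nadph_tm -
        .data$fad_tm / .data$mean_fad_tm
    ) |>
    dplyr::select(-".omi_grp", -"mean_orr", -"mean_nadph_tm",
                  -"mean_fad_tm")
  attr(out, "omi_norm") <- norm
  attr(out, "omi_by") <- by
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
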