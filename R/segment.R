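#' Segment macrophages from the mCherry marker channel
#'
#' Reproducible version of the interactive segmentation used for in vivo
#' macrophage FLIM: the marker image is rescaled to `[0, 1]` by its
#' brightest pixel, thresholded (default 0.15), holes inside objects are
#' filled, 8-connected components are labelled, and components below a
#' minimum area are dropped. Labels are relabelled to consecutive integers
#' in raster order. Because of the rescale-by-max step the result is
#' invariant to multiplying the image by any positive constant.
#'
#' @param mcherry Nonnegative numeric matrix (marker intensity).
#' @param threshold Foreground threshold on the rescaled image; pixels
#'   `>= threshold` are foreground. Default 0.15.
#' @param min_area Minimum object area in pixels (default 25).
#' @param mask_override Optional user-supplied integer label matrix that
#'   takes precedence over the computed segmentation (the counterpart of
#'   manual mask editing); returned relabelled with provenance noted.
#' @return A `label_image`: integer matrix (0 = background) with attributes
#'   `threshold`, `min_area`, `connectivity`, `source`.
#' @export
segment_macrophages <- function(mcherry, threshold = 0.15, min_area = 25L,
                                mask_override = NULL) {
  if (!is.matrix(mcherry) || !is.numeric(mcherry)) {
    stop("`mcherry` must be a numeric matrix", call. = FALSE)
  }
  if (any(mcherry < 0)) stop("intensities must be nonnegative", call. = FALSE)
  if (!is.null(mask_override)) {
    stopifnot(all(dim(mask_override) == dim(mcherry)))
    lab <- relabel_consecutive(mask_override)
    return(new_label_image(lab, threshold, min_area, source = "override"))
  }
  mx <- max(mcherry)
  if (mx == 0) stop("no signal: the marker image is all zero", call. = FALSE)
  fg <- (mcherry / mx) >= threshold
  fg <- fill_holes(fg)
  lab <- label_components8(fg)
  lab <- drop_small_labels(lab, min_area)
  new_label_image(lab, threshold, min_area, source = "computed")
}

new_label_image <- function(lab, threshold, min_area, source) {
  structure(
    lab,
    threshold = threshold, min_area = as.integer(min_area),
    connectivity = 8L, source = source,
    class = c("label_image", "matrix", "array")
  )
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf(
    "<label_image> %d x %d, %d cells (threshold %g, min area %d, 8-connected)\n",
    nrow(x), ncol(x), max(x), attr(x, "threshold"), attr(x, "min_area")
  ))
  invisible(x)
}

# 8-connected labelling: 4-connected pass (EBImage) followed by union-find
# merging of diagonally adjacent labels.
label_components8 <- function(fg) {
  lab <- matrix(as.integer(EBImage::bwlabel(fg * 1)), nrow(fg))
  nlab <- max(lab)
  if (nlab <= 1L) return(relabel_consecutive(lab))
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left diagonal
  pick <- function(a, b) {
    k <- a > 0L & b > 0L & a != b
    cbind(a[k], b[k])
  }
  pairs <- unique(rbind(pick(a1, b1), pick(a2, b2)))
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  relabel_consecutive(lab)
}

# Fill background holes: 4-connected background components not touching the
# image border become foreground.
fill_holes <- function(fg) {
  filled <- EBImage::fillHull(fg * 1)
  matrix(filled > 0, nrow(fg))
}

drop_small_labels <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  lab[!(lab %in% keep)] <- 0L
  relabel_consecutive(lab)
}

# Relabel to consecutive 1..K in order of first raster appearance.
relabel_consecutive <- function(lab) {
  lab <- matrix(as.integer(lab), nrow(lab))
  ids <- unique(lab[lab > 0L])
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

#' Remove bacteria-mask pixels from a segmentation
#'
#' In the infected-wound model the pathogen also carries mCherry; its
#' pixels are removed from every cell so bacterial photons never enter the
#' per-cell averages. Pixels where the bacteria image reaches
#' `bacteria_threshold` are cleared, emptied cells are dropped, and labels
#' are made consecutive again. The default threshold is 0.6 x the bacteria
#' image maximum (bacteria are the brightest marker objects).
#'
#' @param label_image A [segment_macrophages()] result.
#' @param bacteria_image Numeric matrix, same shape.
#' @param bacteria_threshold Absolute threshold; pixels `>=` it are removed.
#'   Default `0.6 * max(bacteria_image)`.
#' @return A `label_image` with bacteria pixels excised.
#' @export
exclude_bacteria <- function(label_image, bacteria_image,
                             bacteria_threshold = NULL) {
  if (!all(dim(label_image) == dim(bacteria_image))) {
    stop("label and bacteria images must have the same shape", call. = FALSE)
  }
  if (is.null(bacteria_threshold)) {
    bacteria_threshold <- 0.6 * max(bacteria_image)
  }
  lab <- matrix(as.integer(label_image), nrow(label_image))
  lab[bacteria_image >= bacteria_threshold] <- 0L
  lab <- relabel_consecutive(lab)
  new_label_image(lab, attr(label_image, "threshold"),
                  attr(label_image, "min_area"),
                  source = paste0(attr(label_image, "source"),
                                  "+bacteria_excluded"))
}

#' Classify cells by TNFα reporter signal
#'
#' A cell is TNFα positive if any pixel inside its label exceeds the GFP
#' threshold — the imaging counterpart of scoring a cell positive when any
#' reporter signal is detected within it. The default threshold is a robust
#' background rule: median + 3 x MAD of the GFP intensity over background
#' (unlabelled) pixels.
#'
#' @param label_image A `label_image`.
#' @param gfp Numeric matrix, same shape.
#' @param gfp_threshold Absolute threshold; pixels strictly above it count
#'   as reporter signal. Default `median + 3 * mad` over background pixels.
#' @return Tibble with one row per cell: `cell_id`, `area`,
#'   `gfp_positive_pixels`, `tnfa_status` (`"positive"`/`"negative"`), and
#'   the threshold used.
#' @export
classify_tnfa <- function(label_image, gfp, gfp_threshold = NULL) {
  if (!all(dim(label_image) == dim(gfp))) {
    stop("label and GFP images must have the same shape", call. = FALSE)
  }
  if (is.null(gfp_threshold)) {
    bg <- gfp[label_image == 0L]
    bg_mad <- stats::mad(bg)
    gfp_threshold <- if (bg_mad > 0) {
      stats::median(bg) + 3 * bg_mad
    } else {
      # degenerate background (e.g. detector-clipped zeros): anything above
      # the whole background range counts as reporter signal
      max(bg)
    }
  }
  n <- max(label_image)
  if (n == 0L) {
    return(tibble::tibble(cell_id = integer(), area = integer(),
                          gfp_positive_pixels = integer(),
                          tnfa_status = character(),
                          gfp_threshold = numeric()))
  }
  lab <- as.vector(label_image)
  hot <- as.vector(gfp) > gfp_threshold
  area <- tabulate(lab[lab > 0L], nbins = n)
  npos <- tabulate(lab[lab > 0L & hot], nbins = n)
  tibble::tibble(
    cell_id = seq_len(n),
    area = as.integer(area),
    gfp_positive_pixels = as.integer(npos),
    tnfa_status = ifelse(npos > 0L, "positive", "negative"),
    gfp_threshold = gfp_threshold
  )
}

#' Proportional TNFα reporter area
#'
#' Larva-level quantification of reporter expression: the fraction of
#' macrophage (marker-positive) area that is also reporter-positive,
#' `|GFP+ and mCherry+| / |mCherry+|`, with absolute thresholds on both
#' channels.
#'
#' @param gfp,mcherry Numeric matrices of the same shape.
#' @param gfp_threshold,mcherry_threshold Absolute thresholds (>= 0);
#'   pixels `>=` the threshold count as positive.
#' @return A proportion in `[0, 1]`.
#' @examples
#' m <- matrix(0, 10, 10); m[1:10, 1:10] <- 1
#' g <- matrix(0, 10, 10); g[1:5, 1:5] <- 1
#' tnfa_proportional_area(g, m, 0.5, 0.5) # 0.25
#' @export
tnfa_proportional_area <- function(gfp, mcherry, gfp_threshold,
                                   mcherry_threshold) {
  if (!all(dim(gfp) == dim(mcherry))) {
    stop("GFP and mCherry images must have the same shape", call. = FALSE)
  }
  if (gfp_threshold < 0 || mcherry_threshold < 0) {
    stop("thresholds must be >= 0", call. = FALSE)
  }
  mpos <- mcherry >= mcherry_threshold
  if (!any(mpos)) {
    stop("no macrophage area: no pixels reach the mCherry threshold",
         call. = FALSE)
  }
  sum(mpos & (gfp >= gfp_threshold)) / sum(mpos)
}
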