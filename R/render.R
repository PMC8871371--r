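#' Render a TCSPC decay cube for one channel
#'
#' Computes, for every pixel, the expected photon-count histogram under the
#' two-component decay model convolved with the IRF ([model_decay()]): cell
#' pixels receive their cell's true decay scaled to the per-pixel photon
#' budget plus the background offset; background pixels receive offset-only
#' counts. With `poisson = TRUE` (default) each bin is an independent
#' Poisson draw with that expectation, emulating photon-counting shot
#' noise; with `poisson = FALSE` the noiseless expectations are returned.
#'
#' @param scene A [make_scene()] result.
#' @param channel `"nadph"` or `"fad"`.
#' @param irf IRF kernel, see [make_irf()].
#' @param time_axis Time axis; defaults to the standard 256-bin axis.
#' @param seed RNG seed for the Poisson draw (defaults to the scene seed).
#' @param poisson Draw Poisson noise? Default `TRUE`.
#' @param wrap Add the one-period wrapped decay tail (must match the
#'   fitter's setting). Default `FALSE`.
#' @return A `decay_cube`: list with `counts` (rows x cols x n_bins array),
#'   `time_axis`, `channel` and `meta` (seed, cohort ids, IRF summary).
#' @export
render_decay_cube <- function(scene, channel = c("nadph", "fad"),
                              irf = make_irf(time_axis = time_axis),
                              time_axis = omiflim::time_axis(),
                              seed = NULL, poisson = TRUE, wrap = FALSE) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  channel <- match.arg(channel)
  assert_time_axis(time_axis)
  cols_needed <- paste0(channel, c("_tau1", "_tau2", "_alpha1", "_budget"))
  if (!all(cols_needed %in% names(scene$cells))) {
    stop(sprintf("scene lacks decay parameters for channel '%s'", channel),
         call. = FALSE)
  }
  if (is.null(seed)) seed <- scene$meta$seed
  nr <- nrow(scene$label)
  nc <- ncol(scene$label)
  n_bins <- time_axis$n_bins
  offs <- scene$background_offset

  # one expected curve per cell; pixels of a cell share its parameters
  expected <- matrix(offs, nr * nc, n_bins)
  cells <- scene$cells
  lab_vec <- as.vector(scene$label)
  for (i in seq_len(nrow(cells))) {
    curve <- model_decay(
      list(
        amplitude = cells[[paste0(channel, "_budget")]][i],
        alpha1 = cells[[paste0(channel, "_alpha1")]][i],
        tau1 = cells[[paste0(channel, "_tau1")]][i],
        tau2 = cells[[paste0(channel, "_tau2")]][i],
        offset = offs
      ),
      time_axis, irf, wrap = wrap
    )
    expected[lab_vec == i, ] <- matrix(curve, sum(lab_vec == i), n_bins,
                                       byrow = TRUE)
  }

  counts <- if (poisson) {
    withr::with_seed(seed, {
      matrix(stats::rpois(length(expected), expected), nrow(expected))
    })
  } else {
    expected
  }
  dim(counts) <- c(nr, nc, n_bins)

  structure(
    list(
      counts = counts,
      time_axis = time_axis,
      channel = channel,
      meta = c(scene$meta, list(
        render_seed = as.integer(seed), poisson = poisson, wrap = wrap,
        irf_fwhm_ps = irf$fwhm_ps, irf_peak_bin = irf$peak_bin,
        background_offset = offs
      ))
    ),
    class = "decay_cube"
  )
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<decay_cube> %s: %d x %d pixels x %d bins, %.2e photons total\n",
    x$channel, d[1], d[2], d[3], sum(x$counts)
  ))
  invisible(x)
}

#' Render reporter-channel intensity images
#'
#' Produces the mCherry macrophage-marker image (bright inside every cell)
#' and the GFP TNFα-reporter image (bright only inside TNFα+ cells), with
#' optional additive Gaussian noise clipped at zero. Intensities are in
#' arbitrary units with cell interiors at 1.
#'
#' @param scene A [make_scene()] result.
#' @param noise_sd SD of additive Gaussian noise (default 0.01; use 0 for a
#'   noiseless render whose mCherry support equals the cell masks exactly).
#' @param seed RNG seed (defaults to the scene seed).
#' @return List with matrices `mcherry` and `gfp`.
#' @export
render_reporter_images <- function(scene, noise_sd = 0.01, seed = NULL) {
  stopifnot(inherits(scene, "ground_truth_scene"))
  if (is.null(seed)) seed <- scene$meta$seed
  mch <- (scene$label > 0L) * 1
  pos_ids <- scene$cells$cell_id[scene$cells$tnfa_status == "positive"]
  gfp <- (matrix(scene$label %in% pos_ids, nrow(scene$label))) * 1
  if (noise_sd > 0) {
    imgs <- withr::with_seed(seed, list(
      mcherry = mch + stats::rnorm(length(mch), 0, noise_sd),
      gfp = gfp + stats::rnorm(length(gfp), 0, noise_sd)
    ))
    mch <- pmax(matrix(imgs$mcherry, nrow(mch)), 0)
    gfp <- pmax(matrix(imgs$gfp, nrow(gfp)), 0)
  }
  list(mcherry = mch, gfp = gfp)
}
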