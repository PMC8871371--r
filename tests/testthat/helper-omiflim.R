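# Shared fixtures: small, fast synthetic inputs built in code.

default_axis <- time_axis()
default_irf <- make_irf(260, default_axis)

# short axis for fits where 256 bins are not the point
short_axis <- time_axis(n_bins = 64L, window = 12.5)
delta_irf_short <- make_irf(0, short_axis, peak_bin = 3L)

true_params <- list(amplitude = 5000, alpha1 = 0.7, tau1 = 0.4,
                    tau2 = 2.5, offset = 0)

# a small field with well-separated disks
small_scene_spec <- function(n_cells = 6L, shape = c(48L, 48L),
                             seed = 42L, ...) {
  scene_spec(shape = shape, n_cells = n_cells, radius_range = c(3, 4),
             seed = seed, ...)
}

jaccard <- function(a, b) {
  sum(a & b) / sum(a | b)
}

# deterministic cell-record table for endpoint/stats tests
toy_cohort <- function(n_cells = 60, n_larvae = 6, seed = 7) {
  withr::with_seed(seed, {
    larva <- rep(sprintf("L%d", seq_len(n_larvae)), each = n_cells / n_larvae)
    tibble::tibble(
      cell_id = seq_len(n_cells),
      larva_id = larva,
      day_id = rep(c("D1", "D2"), length.out = n_cells),
      treatment = rep(c("control", "treated"), each = n_cells / 2),
      tnfa_status = sample(c("negative", "positive"), n_cells, TRUE),
      orr = runif(n_cells, 0.3, 0.7),
      nadph_tm = runif(n_cells, 0.8, 1.4),
      fad_tm = runif(n_cells, 0.6, 1.0)
    )
  })
}
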