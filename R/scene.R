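#' Default per-group decay-parameter distributions
#'
#' Ground-truth endpoint distributions for the two macrophage activation
#' groups emulated by the synthetic generator: TNFα− (M2-like, baseline) and
#' TNFα+ (M1-like). The TNFα+ group is shifted in the directions reported
#' for activated macrophages: lower optical redox ratio (via a reduced
#' NAD(P)H photon budget), lower NAD(P)H tau1 and tau2, and higher NAD(P)H
#' alpha1; FAD lifetimes are left unchanged. Default shift magnitude is 15%.
#'
#' Baseline values are literature-typical for the free/bound two-component
#' interpretation: NAD(P)H tau1 = 0.45 ns, tau2 = 2.6 ns, alpha1 = 0.72;
#' FAD tau1 = 0.40 ns, tau2 = 2.0 ns, alpha1 = 0.70; 5000 expected decay
#' photons per pixel per channel.
#'
#' @param effect Fractional shift applied to the TNFα+ group (default 0.15).
#' @return Named list with elements `neg` and `pos`; each holds per-channel
#'   (`nadph`, `fad`) means and SDs for `tau1`, `tau2`, `alpha1` (cell-to-
#'   cell variation) and the per-pixel photon `budget`.
#' @export
default_group_params <- function(effect = 0.15) {
  base_ch <- function(tau1, tau2, alpha1, budget) {
    list(
      tau1_mean = tau1, tau1_sd = 0.02,
      tau2_mean = tau2, tau2_sd = 0.08,
      alpha1_mean = alpha1, alpha1_sd = 0.02,
      budget_mean = budget, budget_sd = 0.05 * budget
    )
  }
  neg <- list(
    nadph = base_ch(0.45, 2.6, 0.72, 5000),
    fad = base_ch(0.40, 2.0, 0.70, 5000)
  )
  pos <- neg
  pos$nadph$tau1_mean <- neg$nadph$tau1_mean * (1 - effect)
  pos$nadph$tau2_mean <- neg$nadph$tau2_mean * (1 - effect)
  pos$nadph$alpha1_mean <- min(neg$nadph$alpha1_mean * (1 + effect), 0.98)
  # photon budget chosen so the true optical redox ratio drops by `effect`
  orr_neg <- neg$nadph$budget_mean /
    (neg$nadph$budget_mean + neg$fad$budget_mean)
  orr_pos <- orr_neg * (1 - effect)
  pos$nadph$budget_mean <- orr_pos / (1 - orr_pos) * neg$fad$budget_mean
  pos$nadph$budget_sd <- 0.05 * pos$nadph$budget_mean
  list(neg = neg, pos = pos)
}

#' Specify a synthetic field of view
#'
#' Describes one imaged field: its pixel grid, the macrophages in it
#' (non-overlapping disks by default), the activation group of each cell,
#' the per-group ground-truth decay-parameter distributions for both
#' autofluorescence channels, and the cohort identifiers carried through to
#' the per-cell table.
#'
#' @param shape Field size, `c(rows, cols)` (default 256 x 256).
#' @param n_cells Number of cells to place.
#' @param radius_range Cell radius range in pixels, `c(min, max)`.
#' @param allow_overlap If `FALSE` (default) cells must not overlap.
#' @param tnfa_prop Proportion of TNFα+ cells; `round(tnfa_prop * n_cells)`
#'   cells are positive. Ignored when `tnfa_status` is given.
#' @param tnfa_status Optional explicit logical/character vector of length
#'   `n_cells` (`TRUE`/`"positive"` = TNFα+).
#' @param groups Per-group parameter distributions, see
#'   [default_group_params()].
#' @param background_offset Background light level, counts per time bin.
#' @param larva_id,day_id,treatment Cohort identifiers (strings).
#' @param seed Integer RNG seed; recorded in all output metadata.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(256L, 256L), n_cells = 10L,
                       radius_range = c(5, 9), allow_overlap = FALSE,
                       tnfa_prop = 0.3, tnfa_status = NULL,
                       groups = default_group_params(),
                       background_offset = 0.1,
                       larva_id = "L1", day_id = "D1",
                       treatment = "control", seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 8L))
  n_cells <- as.integer(n_cells)
  stopifnot(n_cells >= 1L, length(radius_range) == 2L,
            radius_range[1] > 0, radius_range[2] >= radius_range[1])
  if (background_offset < 0) {
    stop("`background_offset` must be >= 0", call. = FALSE)
  }
  for (g in groups) {
    for (ch in g) {
      if (ch$budget_mean <= 0) {
        stop("photon budgets must be positive", call. = FALSE)
      }
      bounds <- fit_bounds()
      if (ch$tau1_mean < bounds$lower[["tau1"]] ||
          ch$tau1_mean > bounds$upper[["tau1"]] ||
          ch$tau2_mean < bounds$lower[["tau2"]] ||
          ch$tau2_mean > bounds$upper[["tau2"]]) {
        stop("group lifetime means must lie inside the fitter bounds",
             call. = FALSE)
      }
    }
  }
  if (!is.null(tnfa_status)) {
    if (length(tnfa_status) != n_cells) {
      stop("`tnfa_status` must have one entry per cell", call. = FALSE)
    }
    tnfa_status <- if (is.logical(tnfa_status)) {
      tnfa_status
    } else {
      tnfa_status %in% c("positive", "pos", "+")
    }
  }
  structure(
    list(
      shape = shape, n_cells = n_cells, radius_range = radius_range,
      allow_overlap = allow_overlap, tnfa_prop = tnfa_prop,
      tnfa_status = tnfa_status, groups = groups,
      background_offset = background_offset,
      larva_id = larva_id, day_id = day_id, treatment = treatment,
      seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

#' Realise a ground-truth scene from a specification
#'
#' Places cells in the field, assigns each an activation group, and draws
#' its true decay parameters for both channels from the group
#' distributions, truncated to the fitter's default bounds. Reproducible:
#' the same spec (including its seed) always yields an identical scene.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `ground_truth_scene`: list with `label`
#'   (integer matrix of cell ids, 0 = background), `cells` (tibble of
#'   per-cell truth: centre, radius, TNFα status, per-channel `tau1`,
#'   `tau2`, `alpha1`, `budget`, and derived true `orr` and mean
#'   lifetimes), per-channel true intensity maps, and metadata.
#' @export
make_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, make_scene_impl(spec))
}

make_scene_impl <- function(spec) {
  nr <- spec$shape[1]
  nc <- spec$shape[2]
  n <- spec$n_cells

  radii <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
  if (max(radii) * 2 + 2 > min(nr, nc)) {
    stop(sprintf(
      "cannot place cells of radius up to %.1f in a %d x %d field",
      max(radii), nr, nc
    ), call. = FALSE)
  }
  rows <- numeric(n)
  cols <- numeric(n)
  max_tries <- 2000L * n
  tries <- 0L
  placed <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop(sprintf(
        paste0("could not place %d non-overlapping cells (radius %.1f-%.1f)",
               " in a %d x %d field after %d attempts"),
        n, spec$radius_range[1], spec$radius_range[2], nr, nc, max_tries
      ), call. = FALSE)
    }
    i <- placed + 1L
    r <- radii[i]
    cand_r <- stats::runif(1, r + 1, nr - r)
    cand_c <- stats::runif(1, r + 1, nc - r)
    if (!spec$allow_overlap && placed > 0L) {
      d2 <- (rows[seq_len(placed)] - cand_r)^2 +
        (cols[seq_len(placed)] - cand_c)^2
      if (any(d2 < (radii[seq_len(placed)] + r + 1)^2)) next
    }
    rows[i] <- cand_r
    cols[i] <- cand_c
    placed <- i
  }

  label <- matrix(0L, nr, nc)
  px_r <- matrix(seq_len(nr), nr, nc)
  px_c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(n)) {
    inside <- (px_r - rows[i])^2 + (px_c - cols[i])^2 <= radii[i]^2
    label[inside] <- i
  }

  if (!is.null(spec$tnfa_status)) {
    positive <- spec$tnfa_status
  } else {
    n_pos <- round(spec$tnfa_prop * n)
    positive <- rep(FALSE, n)
    if (n_pos > 0) positive[sample.int(n, n_pos)] <- TRUE
  }

  draw_channel <- function(g, n) {
    b <- fit_bounds()
    tibble::tibble(
      tau1 = pmin(pmax(stats::rnorm(n, g$tau1_mean, g$tau1_sd),
                       b$lower[["tau1"]]), b$upper[["tau1"]]),
      tau2 = pmin(pmax(stats::rnorm(n, g$tau2_mean, g$tau2_sd),
                       b$lower[["tau2"]]), b$upper[["tau2"]]),
      alpha1 = pmin(pmax(stats::rnorm(n, g$alpha1_mean, g$alpha1_sd), 0), 1),
      budget = pmax(stats::rnorm(n, g$budget_mean, g$budget_sd), 1)
    )
  }
  grp <- ifelse(positive, "pos", "neg")
  cells <- tibble::tibble(
    cell_id = seq_len(n), row = rows, col = cols, radius = radii,
    tnfa_status = ifelse(positive, "positive", "negative")
  )
  for (ch in c("nadph", "fad")) {
    draws_neg <- draw_channel(spec$groups$neg[[ch]], n)
    draws_pos <- draw_channel(spec$groups$pos[[ch]], n)
    draws <- draws_neg
    draws[positive, ] <- draws_pos[positive, ]
    names(draws) <- paste0(ch, "_", names(draws))
    cells <- dplyr::bind_cols(cells, draws)
  }
  cells <- dplyr::mutate(
    cells,
    nadph_tm = mean_lifetime(.data$nadph_tau1, .data$nadph_tau2,
                             .data$nadph_alpha1),
    fad_tm = mean_lifetime(.data$fad_tau1, .data$fad_tau2,
                           .data$fad_alpha1),
    orr = .data$nadph_budget / (.data$nadph_budget + .data$fad_budget)
  )

  intensity <- function(ch) {
    m <- matrix(0, nr, nc)
    idx <- label > 0L
    m[idx] <- cells[[paste0(ch, "_budget")]][label[idx]]
    m
  }

  structure(
    list(
      label = label,
      cells = cells,
      nadph_intensity = intensity("nadph"),
      fad_intensity = intensity("fad"),
      background_offset = spec$background_offset,
      meta = list(
        larva_id = spec$larva_id, day_id = spec$day_id,
        treatment = spec$treatment, seed = spec$seed,
        shape = spec$shape
      ),
      spec = spec
    ),
    class = "ground_truth_scene"
  )
}

#' @export
print.ground_truth_scene <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_scene> %d x %d field, %d cells (%d TNFa+), larva %s day %s [%s]\n",
    nrow(x$label), ncol(x$label), nrow(x$cells),
    sum(x$cells$tnfa_status == "positive"),
    x$meta$larva_id, x$meta$day_id, x$meta$treatment
  ))
  invisible(x)
}
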