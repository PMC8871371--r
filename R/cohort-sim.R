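#' Describe a simulated cohort
#'
#' A cohort has the nesting the statistical model assumes: cells within
#' larvae within experiment days, with treatments applied at the larva
#' level and TNFα activation varying cell-to-cell. Endpoint variation is
#' generated on the log scale (endpoints are positive and effects in this
#' field are naturally fold changes): for cell k in larva j on day d,
#' `log y = log(baseline) + log(treatment multiplier) + day shift +
#' larva deviation + cell noise`, with day shifts fixed per day, larva
#' deviations shared by all cells of a larva (inducing within-larva
#' correlation with intraclass correlation
#' `larva_sd^2 / (larva_sd^2 + cell_sd^2)`), and independent cell noise.
#' `scale = "linear"` applies the same decomposition additively to the raw
#' endpoint instead.
#'
#' @param treatments Character vector of treatment labels; the first is the
#'   reference level.
#' @param n_days Number of experiment days (biological repeats).
#' @param larvae_per_day Larvae per treatment per day.
#' @param cells_per_larva Cells measured per larva.
#' @param baseline Named numeric vector of endpoint means for the reference
#'   treatment (all positive).
#' @param effects Named list: one named numeric vector of multiplicative
#'   effects per non-reference treatment (values > 0; endpoints missing
#'   from a vector default to multiplier 1). `NULL` applies the default
#'   15% reduction of `orr` and `nadph_tm` to every non-reference
#'   treatment; use `list()` for a null cohort.
#' @param day_shift_sd SD of the per-day additive block shift (log scale
#'   when `scale = "log"`).
#' @param larva_sd SD of the shared per-larva deviation.
#' @param cell_sd SD of the per-cell noise.
#' @param tnfa_prop Proportion of TNFα+ cells per larva (recorded per cell;
#'   no effect is attached to it in table mode).
#' @param scale `"log"` (default) or `"linear"`.
#' @param seed Integer master seed.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(treatments = c("control", "treated"),
                          n_days = 3L, larvae_per_day = 5L,
                          cells_per_larva = 20L,
                          baseline = c(orr = 0.5, nadph_tm = 1.05,
                                       fad_tm = 0.85),
                          effects = NULL,
                          day_shift_sd = 0.05, larva_sd = 0.05,
                          cell_sd = 0.10, tnfa_prop = 0.3,
                          scale = c("log", "linear"), seed = 1L) {
  scale <- match.arg(scale)
  if (is.null(effects)) {
    effects <- stats::setNames(
      rep(list(c(orr = 0.85, nadph_tm = 0.85)), length(treatments) - 1L),
      treatments[-1]
    )
  }
  stopifnot(length(treatments) >= 1L, !anyDuplicated(treatments),
            n_days >= 1L, larvae_per_day >= 1L, cells_per_larva >= 1L)
  if (any(baseline <= 0) && scale == "log") {
    stop("`baseline` endpoints must be positive on the log scale",
         call. = FALSE)
  }
  for (tr in names(effects)) {
    if (!tr %in% treatments[-1]) {
      stop(sprintf("effect for unknown treatment '%s'", tr), call. = FALSE)
    }
    if (any(effects[[tr]] <= 0)) {
      stop("effect multipliers must be positive", call. = FALSE)
    }
  }
  structure(
    list(
      treatments = treatments, n_days = as.integer(n_days),
      larvae_per_day = as.integer(larvae_per_day),
      cells_per_larva = as.integer(cells_per_larva),
      baseline = baseline, effects = effects,
      day_shift_sd = day_shift_sd, larva_sd = larva_sd, cell_sd = cell_sd,
      tnfa_prop = tnfa_prop, scale = scale, seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
}

#' Simulate a cohort table of per-cell endpoints
#'
#' Draws the full nested cohort described by a [cohort_design()] and
#' returns the ground-truth per-cell endpoint table, one row per cell,
#' carrying `treatment`, `day_id`, `larva_id`, `tnfa_status` and every
#' endpoint named in the design baseline. The injected per-larva deviation
#' and per-day shift are recorded alongside so recovery is checkable.
#'
#' @param design A [cohort_design()].
#' @return A tibble with
#'   `n_days * length(treatments) * larvae_per_day * cells_per_larva` rows.
#' @examples
#' tbl <- simulate_cohort(cohort_design(n_days = 2, larvae_per_day = 2,
#'                                      cells_per_larva = 5))
#' nrow(tbl) # 2 treatments x 2 days x 2 larvae x 5 cells = 40
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  withr::with_seed(design$seed, simulate_cohort_impl(design))
}

simulate_cohort_impl <- function(design) {
  ep_names <- names(design$baseline)
  day_shift <- stats::rnorm(design$n_days, 0, design$day_shift_sd)

  grid <- tidyr::expand_grid(
    treatment = design$treatments,
    day = seq_len(design$n_days),
    larva = seq_len(design$larvae_per_day)
  )
  rows <- purrr::pmap(grid, function(treatment, day, larva) {
    nc <- design$cells_per_larva
    larva_dev <- stats::rnorm(1, 0, design$larva_sd)
    mult <- rep(1, length(ep_names))
    names(mult) <- ep_names
    if (treatment %in% names(design$effects)) {
      eff <- design$effects[[treatment]]
      mult[names(eff)] <- eff
    }
    ep <- sapply(ep_names, function(nm) {
      noise <- stats::rnorm(nc, 0, design$cell_sd)
      if (design$scale == "log") {
        exp(log(design$baseline[[nm]]) + log(mult[[nm]]) +
              day_shift[day] + larva_dev + noise)
      } else {
        design$baseline[[nm]] * mult[[nm]] + day_shift[day] +
          larva_dev + noise
      }
    })
    ep <- matrix(ep, nrow = nc,
                 dimnames = list(NULL, ep_names))
    n_pos <- round(design$tnfa_prop * nc)
    status <- rep("negative", nc)
    if (n_pos > 0) status[sample.int(nc, n_pos)] <- "positive"
    tibble::tibble(
      treatment = treatment,
      day_id = sprintf("D%d", day),
      larva_id = sprintf("%s_D%d_L%d", treatment, day, larva),
      cell_id = seq_len(nc),
      tnfa_status = status,
      tibble::as_tibble(ep),
      true_day_shift = day_shift[day],
      true_larva_dev = larva_dev
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "design") <- design
  out
}

#' Simulate an imaging cohort of synthetic fields
#'
#' Builds one field of view per larva as a [scene_spec()], with TNFα+ and
#' TNFα− cells mixed within each larva and the per-larva/per-day endpoint
#' variation of [cohort_design()] applied multiplicatively to the group
#' lifetime means and photon budgets. Used to drive the full imaging
#' pipeline (render, fit, segment, aggregate) end to end; the returned
#' truth table holds every injected per-cell endpoint.
#'
#' @param n_days,larvae_per_day Number of days and larvae per day.
#' @param cells_per_larva Cells per field.
#' @param shape Field size in pixels.
#' @param radius_range Cell radius range in pixels.
#' @param tnfa_prop Proportion of TNFα+ cells per field.
#' @param effect Fractional TNFα+ endpoint shift, see
#'   [default_group_params()].
#' @param day_shift_sd,larva_sd Log-scale SDs of the day block shift and
#'   the shared larva deviation, applied to lifetimes and budgets.
#' @param budget Per-pixel photon budget for both channels at baseline.
#' @param background_offset Background counts per bin.
#' @param treatment Treatment label recorded for every field.
#' @param seed Master seed; each field gets a recorded child seed.
#' @return List with `fields` (list of `scene_spec`s) and `truth` (tibble
#'   of per-cell injected endpoints across all fields).
#' @export
simulate_imaging_cohort <- function(n_days = 2L, larvae_per_day = 3L,
                                    cells_per_larva = 8L,
                                    shape = c(64L, 64L),
                                    radius_range = c(3, 4.5),
                                    tnfa_prop = 0.5, effect = 0.15,
                                    day_shift_sd = 0.02, larva_sd = 0.02,
                                    budget = 5000,
                                    background_offset = 0.1,
                                    treatment = "wound", seed = 1L) {
  seed <- as.integer(seed)
  withr::with_seed(seed, {
    day_shift <- stats::rnorm(n_days, 0, day_shift_sd)
    field_seeds <- sample.int(.Machine$integer.max - 1L,
                              n_days * larvae_per_day)
    fields <- list()
    k <- 0L
    for (d in seq_len(n_days)) {
      for (l in seq_len(larvae_per_day)) {
        k <- k + 1L
        m <- exp(day_shift[d] + stats::rnorm(1, 0, larva_sd))
        groups <- default_group_params(effect)
        for (g in names(groups)) {
          for (ch in names(groups[[g]])) {
            p <- groups[[g]][[ch]]
            p$budget_mean <- budget / 5000 * p$budget_mean * m
            p$budget_sd <- 0.05 * p$budget_mean
            p$tau1_mean <- p$tau1_mean * m
            p$tau2_mean <- p$tau2_mean * m
            groups[[g]][[ch]] <- p
          }
        }
        fields[[k]] <- scene_spec(
          shape = shape, n_cells = cells_per_larva,
          radius_range = radius_range, tnfa_prop = tnfa_prop,
          groups = groups, background_offset = background_offset,
          larva_id = sprintf("D%d_L%d", d, l), day_id = sprintf("D%d", d),
          treatment = treatment, seed = field_seeds[k]
        )
      }
    }
    truth <- purrr::map_dfr(fields, function(sp) {
      sc <- make_scene(sp)
      dplyr::mutate(sc$cells,
                    larva_id = sp$larva_id, day_id = sp$day_id,
                    treatment = sp$treatment, .before = 1)
    })
    list(fields = fields, truth = truth)
  })
}
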