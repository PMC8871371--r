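#' Fit a general linear model to per-cell endpoints
#'
#' Ordinary least squares on a per-cell optical endpoint, with treatment
#' indicators and the experiment day as a fixed blocking factor, exactly
#' the cell-level analysis used for optical metabolic imaging cohorts:
#' every data point is one macrophage, and uncertainty is computed with
#' cluster-robust (sandwich) standard errors clustered by larva, because
#' cells from one larva are correlated. Inference uses a t reference
#' distribution with (number of clusters - 1) degrees of freedom.
#'
#' With `log_transform = TRUE` the outcome is modelled on the natural-log
#' scale and estimated means and contrasts are back-transformed, so group
#' comparisons are reported as fold changes (ratios) rather than
#' differences. Estimated group means average the day blocks with equal
#' weight. No multiplicity adjustment is applied.
#'
#' @param cohort_table Tibble of cell records (one row per cell).
#' @param outcome Name of the endpoint column to model.
#' @param treatment Name(s) of the treatment factor column(s); with two
#'   factors and `interaction = TRUE` their interaction is included.
#' @param block Name of the day blocking column (`NULL` for none).
#' @param cluster Name of the larva cluster column (`NULL` falls back to
#'   classical OLS standard errors).
#' @param log_transform Model `log(outcome)`? Default `FALSE`.
#' @param interaction Include the interaction between the first two
#'   treatment factors? Default `TRUE` when two factors are given.
#' @return An object of class `omi_glm` with the underlying `lm` fit, the
#'   cluster-robust covariance, the estimated group means with 95% CI
#'   (back-transformed under log), all pairwise group contrasts with 95%
#'   CI and p-values, and the model specification. Use [tidy()],
#'   [glance()], [autoplot()].
#' @export
fit_glm <- function(cohort_table, outcome, treatment, block = "day_id",
                    cluster = "larva_id", log_transform = FALSE,
                    interaction = length(treatment) > 1) {
  tbl <- as.data.frame(cohort_table)
  for (v in c(outcome, treatment, block, cluster)) {
    if (!is.null(v) && !all(v %in% names(tbl))) {
      stop(sprintf("column '%s' not found in the cohort table",
                   paste(setdiff(v, names(tbl)), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (interaction && length(treatment) < 2) {
    stop("an interaction needs at least two treatment factors",
         call. = FALSE)
  }
  tbl <- tbl[stats::complete.cases(tbl[, c(outcome, treatment, block,
                                           cluster), drop = FALSE]), ,
             drop = FALSE]
  y <- tbl[[outcome]]
  if (log_transform) {
    if (any(y <= 0)) {
      stop("log transform requested but the outcome has nonpositive values",
           call. = FALSE)
    }
    tbl$.y <- log(y)
  } else {
    tbl$.y <- y
  }
  for (v in c(treatment, block)) tbl[[v]] <- factor(tbl[[v]])
  n_days <- if (is.null(block)) NA_integer_
            else length(unique(tbl[[block]]))

  # single-level factors carry no information; keep them out of the design
  # (a single group with no blocks reduces to the intercept-only model)
  informative <- treatment[vapply(treatment,
                                  function(v) nlevels(tbl[[v]]) > 1,
                                  logical(1))]
  rhs_terms <- character()
  if (length(informative) >= 2 && interaction) {
    rhs_terms <- paste0(informative[1], " * ", informative[2])
  } else if (length(informative) > 0) {
    rhs_terms <- paste(informative, collapse = " + ")
  }
  if (!is.null(block) && nlevels(tbl[[block]]) > 1) {
    rhs_terms <- c(rhs_terms, block)
  } else {
    block <- NULL
  }
  rhs <- if (length(rhs_terms) == 0) "1" else paste(rhs_terms,
                                                    collapse = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  fit <- stats::lm(fml, data = tbl)

  if (any(is.na(stats::coef(fit)))) {
    stop(sprintf("rank-deficient design: aliased term(s) %s",
                 paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                       collapse = ", ")), call. = FALSE)
  }

  if (!is.null(cluster)) {
    cl <- tbl[[cluster]]
    vc <- cluster_robust_cov(fit, cl)
    df <- length(unique(cl)) - 1L
    n_larvae <- length(unique(cl))
  } else {
    vc <- stats::vcov(fit)
    df <- stats::df.residual(fit)
    n_larvae <- NA_integer_
  }

  grid <- estimate_grid(fit, tbl, treatment, block)
  means <- estimated_means(fit, vc, df, grid, treatment, log_transform)
  contrasts <- group_contrasts(fit, vc, df, grid, treatment, log_transform)

  structure(
    list(
      fit = fit, vcov = vc, df = df,
      means = means, contrasts = contrasts,
      spec = list(outcome = outcome, treatment = treatment, block = block,
                  cluster = cluster, log_transform = log_transform,
                  interaction = interaction),
      n_cells = nrow(tbl), n_larvae = n_larvae, n_days = n_days,
      data = tibble::as_tibble(tbl)
    ),
    class = "omi_glm"
  )
}

# Balanced prediction grid: every treatment-group level crossed with every
# block level (blocks get equal weight in the estimated means).
estimate_grid <- function(fit, tbl, treatment, block) {
  lvls <- lapply(tbl[, treatment, drop = FALSE], levels)
  grid <- expand.grid(lvls, stringsAsFactors = FALSE)
  grid$.group <- do.call(paste, c(grid[treatment], sep = ":"))
  if (!is.null(block)) {
    blk <- levels(tbl[[block]])
    grid <- merge(grid, stats::setNames(data.frame(blk), block))
  }
  grid
}

# L %*% beta with rows averaging over blocks within each group.
group_lmat <- function(fit, grid, treatment) {
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                            data = grid)
  groups <- sort(unique(grid$.group))
  L <- t(vapply(groups, function(g) {
    colMeans(mm[grid$.group == g, , drop = FALSE])
  }, numeric(ncol(mm))))
  rownames(L) <- groups
  L
}

estimated_means <- function(fit, vc, df, grid, treatment, log_transform) {
  L <- group_lmat(fit, grid, treatment)
  est <- unname(drop(L %*% stats::coef(fit)))
  # clamp round-off negatives from low-rank sandwiches (very few clusters)
  se <- unname(sqrt(pmax(diag(L %*% vc %*% t(L)), 0)))
  tcrit <- stats::qt(0.975, df)
  out <- tibble::tibble(
    group = rownames(L),
    estimate = est, se = se,
    conf_low = est - tcrit * se, conf_high = est + tcrit * se,
    df = df
  )
  if (log_transform) {
    out <- dplyr::mutate(out,
                         estimate = exp(.data$estimate),
                         conf_low = exp(.data$conf_low),
                         conf_high = exp(.data$conf_high))
  }
  out
}

group_contrasts <- function(fit, vc, df, grid, treatment, log_transform) {
  L <- group_lmat(fit, grid, treatment)
  groups <- rownames(L)
  if (length(groups) < 2) {
    return(tibble::tibble(contrast = character(), estimate = numeric(),
                          se = numeric(), conf_low = numeric(),
                          conf_high = numeric(), statistic = numeric(),
                          p_value = numeric(), df = numeric()))
  }
  pairs <- utils::combn(seq_along(groups), 2)
  tcrit <- stats::qt(0.975, df)
  rows <- apply(pairs, 2, function(ij) {
    l <- L[ij[2], ] - L[ij[1], ]
    est <- sum(l * stats::coef(fit))
    se <- sqrt(max(drop(t(l) %*% vc %*% l), 0))
    tstat <- est / se
    tibble::tibble(
      contrast = paste(groups[ij[2]], "vs", groups[ij[1]]),
      estimate = est, se = se,
      conf_low = est - tcrit * se, conf_high = est + tcrit * se,
      statistic = tstat,
      p_value = 2 * stats::pt(-abs(tstat), df),
      df = df
    )
  })
  out <- dplyr::bind_rows(rows)
  if (log_transform) {
    out <- dplyr::mutate(out,
                         ratio = exp(.data$estimate),
                         ratio_low = exp(.data$conf_low),
                         ratio_high = exp(.data$conf_high))
  }
  out
}

#' Cluster-robust covariance for an OLS fit
#'
#' CR1 sandwich covariance: cluster-summed score outer products with the
#' small-sample scaling `G/(G-1) * (n-1)/(n-k)` and, downstream, a t
#' reference with G - 1 degrees of freedom. With every observation its own
#' cluster this reduces to the heteroskedasticity-robust HC1 covariance.
#'
#' @param fit An `lm` fit.
#' @param cluster_ids Vector of cluster memberships, one per observation
#'   used in the fit.
#' @return The robust covariance matrix of the coefficients.
#' @export
cluster_robust_cov <- function(fit, cluster_ids) {
  stopifnot(inherits(fit, "lm"))
  if (length(cluster_ids) != stats::nobs(fit)) {
    stop("`cluster_ids` must have one entry per fitted observation",
         call. = FALSE)
  }
  g <- length(unique(cluster_ids))
  if (g < 2) {
    stop("cluster-robust covariance needs at least two clusters",
         call. = FALSE)
  }
  sandwich::vcovCL(fit, cluster = cluster_ids, type = "HC1",
                   cadjust = TRUE)
}

#' Residual diagnostics for an endpoint model
#'
#' Emits plot-ready residual tables: residual versus fitted values and the
#' normal quantile-quantile pairs, plus a coarse heteroskedasticity flag
#' raised when the residual SD doubles between fitted-value quartiles (the
#' situation in which a log transform of the endpoint is warranted).
#'
#' @param x An `omi_glm` ([fit_glm()]).
#' @return List with tibbles `residuals` (`fitted`, `residual`, quartile)
#'   and `qq` (`theoretical`, `sample`), the per-quartile residual SDs and
#'   logical `heteroskedastic`.
#' @export
glm_diagnostics <- function(x) {
  stopifnot(inherits(x, "omi_glm"))
  res <- stats::residuals(x$fit)
  fitted <- stats::fitted(x$fit)
  # round away QR noise so equal design rows share a bin
  fitted <- signif(fitted, 8)
  brk <- unique(stats::quantile(fitted, probs = seq(0, 1, 0.25)))
  q <- if (length(brk) < 2) {
    rep(1L, length(fitted)) # degenerate fitted values: one bin
  } else {
    cut(fitted, brk, include.lowest = TRUE, labels = FALSE)
  }
  sds <- tapply(res, q, stats::sd)
  sds <- sds[!is.na(sds) & sds > 0]
  het <- length(sds) > 1 && max(sds) / min(sds) >= 2
  qq <- stats::qqnorm(res, plot.it = FALSE)
  list(
    residuals = tibble::tibble(fitted = fitted, residual = res,
                               quartile = as.integer(q)),
    qq = tibble::tibble(theoretical = qq$x, sample = qq$y),
    quartile_sd = sds,
    heteroskedastic = het
  )
}

#' @export
print.omi_glm <- function(x, ...) {
  cat(sprintf(
    "<omi_glm> %s ~ %s%s, %d cells / %s larvae / %s days%s\n",
    x$spec$outcome, paste(x$spec$treatment, collapse = " * "),
    if (!is.null(x$spec$block)) paste0(" + ", x$spec$block) else "",
    x$n_cells, x$n_larvae, x$n_days,
    if (x$spec$log_transform) " (log scale)" else ""
  ))
  cat("Estimated means (95% CI):\n")
  print(as.data.frame(x$means), digits = 4)
  cat("Contrasts:\n")
  print(as.data.frame(x$contrasts), digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of an endpoint model
#'
#' @param x An `omi_glm`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, cluster-robust `std.error`,
#'   `statistic`, `p.value`, and the 95% confidence bounds at the
#'   cluster-adjusted degrees of freedom.
#' @export
tidy.omi_glm <- function(x, ...) {
  est <- stats::coef(x$fit)
  se <- sqrt(pmax(diag(x$vcov), 0))
  stat <- est / se
  tcrit <- stats::qt(0.975, x$df)
  tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * stats::pt(-abs(stat), x$df)),
    conf.low = unname(est - tcrit * se),
    conf.high = unname(est + tcrit * se)
  )
}

#' Model-level summary of an endpoint model
#'
#' @param x An `omi_glm`.
#' @param ... Unused.
#' @return One-row tibble: sample sizes (`n_cells`, `n_larvae`, `n_days`),
#'   `r.squared`, `sigma`, `df` (cluster-adjusted), `log_transform`.
#' @export
glance.omi_glm <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    n_cells = x$n_cells, n_larvae = x$n_larvae, n_days = x$n_days,
    r.squared = s$r.squared, sigma = s$sigma, df = x$df,
    log_transform = x$spec$log_transform
  )
}
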