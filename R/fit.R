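#' Default parameter bounds for two-component decay fits
#'
#' Box constraints used by [fit_pixel()] and [fit_image()]. The lifetime
#' boxes (`tau1` in 0.05-1 ns, `tau2` in 1-6 ns) do not overlap, so the
#' short/long ordering `tau1 < tau2` holds by construction. The component
#' fraction is confined to `[0, 1]` and the background offset is
#' nonnegative.
#'
#' @return List with named numeric vectors `lower` and `upper` over
#'   `amplitude`, `alpha1`, `tau1`, `tau2`, `offset`.
#' @export
fit_bounds <- function() {
  list(
    lower = c(amplitude = 0, alpha1 = 0, tau1 = 0.05, tau2 = 1.0,
              offset = 0),
    upper = c(amplitude = Inf, alpha1 = 1, tau1 = 1.0, tau2 = 6.0,
              offset = Inf)
  )
}

#' Default initial values for a channel
#'
#' Literature-typical free/bound starting lifetimes: NAD(P)H
#' `tau1 = 0.4`, `tau2 = 2.5` ns; FAD `tau1 = 0.4`, `tau2 = 2.0` ns; both
#' start at `alpha1 = 0.7`. Amplitude and offset initials are derived from
#' the decay itself at fit time.
#'
#' @param channel `"nadph"` or `"fad"`.
#' @return Named numeric vector `c(tau1, tau2, alpha1)`.
#' @export
fit_init <- function(channel = c("nadph", "fad")) {
  channel <- match.arg(channel)
  if (channel == "nadph") {
    c(tau1 = 0.4, tau2 = 2.5, alpha1 = 0.7)
  } else {
    c(tau1 = 0.4, tau2 = 2.0, alpha1 = 0.7)
  }
}

#' Fit one pixel's decay histogram
#'
#' Recovers the two-component decay parameters from a measured photon-count
#' histogram by bounded nonlinear least squares against [model_decay()]
#' (the IRF is convolved into the model rather than the data being
#' deconvolved — the standard TCSPC formulation). The default objective is
#' Neyman-weighted least squares with per-bin weights `1/max(count, 1)`;
#' `objective = "poisson"` minimises the Poisson deviance instead.
#'
#' The optimiser never throws on failure to converge: the best parameters
#' found are returned with `converged = FALSE` and such pixels can be
#' masked out downstream.
#'
#' @param decay Integer/numeric vector of counts, length `n_bins`.
#' @param irf IRF kernel used in the forward model.
#' @param time_axis Time axis matching the decay.
#' @param init Named vector of starting values (`tau1`, `tau2`, `alpha1`),
#'   e.g. [fit_init()]. Amplitude starts at the background-corrected total
#'   count; offset at the mean of the pre-IRF-peak bins.
#' @param bounds Box constraints, see [fit_bounds()].
#' @param objective `"neyman"` (weighted least squares, default) or
#'   `"poisson"` (maximum likelihood).
#' @param wrap Include the one-period wrapped tail in the model.
#' @param min_photons Decays with fewer total photons are rejected with an
#'   error (`fit_image()` masks them instead). Default 1.
#' @return A `pixel_fit`: list with `params` (named vector `amplitude`,
#'   `alpha1`, `tau1`, `tau2`, `offset`), `tau_mean` (from
#'   [mean_lifetime()]), `reduced_chi2`, `n_photons`, `converged`,
#'   `objective`.
#' @export
fit_pixel <- function(decay, irf, time_axis = omiflim::time_axis(),
                      init = fit_init("nadph"), bounds = fit_bounds(),
                      objective = c("neyman", "poisson"), wrap = FALSE,
                      min_photons = 1) {
  objective <- match.arg(objective)
  assert_time_axis(time_axis)
  if (length(decay) != time_axis$n_bins) {
    stop(sprintf("decay has %d bins but the time axis declares %d",
                 length(decay), time_axis$n_bins), call. = FALSE)
  }
  n_photons <- sum(decay)
  if (n_photons < max(min_photons, 1)) {
    stop("decay is below the photon threshold (all-background pixel?)",
         call. = FALSE)
  }

  n <- time_axis$n_bins
  # offset initial: mean of the bins before the IRF rise; when the IRF
  # peaks too early to leave pre-peak bins, fall back to the smallest count
  offset0 <- if (irf$peak_bin >= 6L) {
    mean(decay[seq_len(min(10L, irf$peak_bin - 5L))])
  } else {
    min(decay)
  }
  amp0 <- max(n_photons - offset0 * n, 1)
  p0 <- c(amplitude = amp0, alpha1 = unname(init[["alpha1"]]),
          tau1 = unname(init[["tau1"]]), tau2 = unname(init[["tau2"]]),
          offset = offset0)
  p0 <- pmin(pmax(p0, bounds$lower), bounds$upper)

  w <- 1 / pmax(decay, 1)
  sw <- sqrt(w)

  # convolution with the IRF via a cached FFT: zero-padded linear conv for
  # the single-pulse model, circular for the periodic (wrapped) model
  tt <- time_axis$centers
  if (wrap) {
    f_irf <- stats::fft(irf$values)
    conv_fast <- function(v) {
      Re(stats::fft(f_irf * stats::fft(v), inverse = TRUE)) / n
    }
  } else {
    pad <- 2^ceiling(log2(2 * n))
    f_irf <- stats::fft(c(irf$values, rep(0, pad - n)))
    conv_fast <- function(v) {
      Re(stats::fft(f_irf * stats::fft(c(v, rep(0, pad - n))),
                    inverse = TRUE))[seq_len(n)] / pad
    }
  }
  shape_parts <- function(p) {
    e1 <- exp(-tt / p[[3]])
    e2 <- exp(-tt / p[[4]])
    if (wrap) {
      tw <- tt + time_axis$window
      e1 <- e1 + exp(-tw / p[[3]])
      e2 <- e2 + exp(-tw / p[[4]])
    }
    list(e1 = e1, e2 = e2)
  }
  model_fn <- function(p) {
    sp <- shape_parts(p)
    u <- conv_fast(p[[2]] * sp$e1 + (1 - p[[2]]) * sp$e2)
    u[u < 0] <- 0
    s <- sum(u)
    if (s <= 0) return(rep(p[[5]], n))
    p[[1]] * u / s + p[[5]]
  }
  # analytic Jacobian of the weighted residuals
  jac_fn <- function(p) {
    sp <- shape_parts(p)
    u <- conv_fast(p[[2]] * sp$e1 + (1 - p[[2]]) * sp$e2)
    s <- sum(u)
    if (s <= 0) s <- .Machine$double.eps
    d_shape <- list(
      alpha1 = sp$e1 - sp$e2,
      tau1 = p[[2]] * tt / p[[3]]^2 * exp(-tt / p[[3]]),
      tau2 = (1 - p[[2]]) * tt / p[[4]]^2 * exp(-tt / p[[4]])
    )
    if (wrap) {
      tw <- tt + time_axis$window
      d_shape$tau1 <- d_shape$tau1 + p[[2]] * tw / p[[3]]^2 * exp(-tw / p[[3]])
      d_shape$tau2 <- d_shape$tau2 +
        (1 - p[[2]]) * tw / p[[4]]^2 * exp(-tw / p[[4]])
    }
    J <- matrix(0, n, 5)
    J[, 1] <- u / s
    J[, 5] <- 1
    for (k in 1:3) {
      du <- conv_fast(d_shape[[k]])
      ds <- sum(du)
      J[, k + 1] <- p[[1]] * (du * s - u * ds) / s^2
    }
    J * sw
  }

  if (objective == "neyman") {
    run_lm <- function(start) {
      minpack.lm::nls.lm(
        par = start,
        lower = bounds$lower, upper = bounds$upper,
        fn = function(p) (model_fn(p) - decay) * sw,
        jac = jac_fn,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-8, ptol = 1e-8, maxfev = 1000, maxiter = 200
        )
      )
    }
    fit <- run_lm(p0)
    # polish restarts: resetting the trust region lets LM keep descending
    # shallow tau/alpha valleys where a single run stops prematurely;
    # cheap because each restart begins at the current solution
    for (r in seq_len(8L)) {
      fit2 <- run_lm(fit$par)
      improved <- fit$deviance - fit2$deviance
      if (fit2$deviance <= fit$deviance) fit <- fit2
      if (improved <= 1e-9 * max(fit$deviance, 1e-12)) break
    }
    pars <- fit$par
    converged <- fit$info %in% c(1, 2, 3)
  } else {
    dev_fn <- function(p) {
      mu <- pmax(model_fn(p), 1e-10)
      2 * sum(mu - decay + ifelse(decay > 0, decay * log(decay / mu), 0))
    }
    upper <- bounds$upper
    upper[!is.finite(upper)] <- 1e9
    opt <- stats::optim(p0, dev_fn, method = "L-BFGS-B",
                        lower = bounds$lower, upper = upper,
                        control = list(maxit = 400))
    pars <- opt$par
    converged <- opt$convergence == 0
  }

  pars <- pmin(pmax(unlist(pars), bounds$lower), bounds$upper)
  yhat <- model_fn(pars)
  chi2 <- sum(w * (decay - yhat)^2) / max(n - length(pars), 1)

  structure(
    list(
      params = pars,
      tau_mean = mean_lifetime(pars[["tau1"]], pars[["tau2"]],
                               pars[["alpha1"]]),
      reduced_chi2 = chi2,
      n_photons = n_photons,
      converged = converged,
      objective = objective
    ),
    class = "pixel_fit"
  )
}

#' @export
print.pixel_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<pixel_fit> tau1 %.3f ns, tau2 %.3f ns, alpha1 %.3f,",
           " tau_m %.3f ns, chi2 %.2f (%s, %s)\n"),
    x$params[["tau1"]], x$params[["tau2"]], x$params[["alpha1"]],
    x$tau_mean, x$reduced_chi2, x$objective,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Fit every pixel of a decay cube
#'
#' Applies [fit_pixel()] across a field of view. Pixels whose total photon
#' count (after optional binning) falls below `threshold` are excluded from
#' fitting and left unset in the validity mask — the counterpart of the
#' per-image background threshold chosen during interactive analysis.
#' Optional `binning = k` pools photons over non-overlapping k x k blocks
#' before fitting and reports each block's parameters on every pixel of the
#' block, trading spatial resolution for photon statistics.
#'
#' @param cube A `decay_cube` (see [render_decay_cube()] /
#'   [read_decay_cube()]).
#' @param irf IRF kernel.
#' @param threshold Minimum total photons per (binned) pixel; default 500.
#' @param binning Block edge k (1 = no binning).
#' @param init,bounds,objective,wrap Passed to [fit_pixel()]; `init`
#'   defaults to [fit_init()] for the cube's channel.
#' @return A `parameter_maps` object: matrices `tau1`, `tau2`, `alpha1`,
#'   `tau_mean`, `intensity` (fitted decay photons per original pixel),
#'   `chi2`, logical `valid`, plus the fit settings. Non-convergent pixels
#'   are marked invalid.
#' @export
fit_image <- function(cube, irf, threshold = 500, binning = 1L,
                      init = NULL, bounds = fit_bounds(),
                      objective = "neyman", wrap = FALSE) {
  stopifnot(inherits(cube, "decay_cube"))
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  binning <- as.integer(binning)
  d <- dim(cube$counts)
  nr <- d[1]; nc <- d[2]; n_bins <- d[3]
  if (binning < 1L || binning > min(nr, nc)) {
    stop("`binning` must be between 1 and the image size", call. = FALSE)
  }
  if (is.null(init)) init <- fit_init(cube$channel)

  maps <- list(
    tau1 = matrix(NA_real_, nr, nc), tau2 = matrix(NA_real_, nr, nc),
    alpha1 = matrix(NA_real_, nr, nc), tau_mean = matrix(NA_real_, nr, nc),
    intensity = matrix(NA_real_, nr, nc), chi2 = matrix(NA_real_, nr, nc),
    valid = matrix(FALSE, nr, nc)
  )

  # block index per pixel (binning = 1 makes every pixel its own block)
  bi <- (seq_len(nr) - 1L) %/% binning
  bj <- (seq_len(nc) - 1L) %/% binning
  block_of <- outer(bi, bj, function(a, b) a + b * (max(bi) + 1L)) + 1L
  blocks <- sort(unique(as.vector(block_of)))

  cnt <- matrix(cube$counts, nr * nc, n_bins)
  for (b in blocks) {
    idx <- which(block_of == b)
    decay <- if (length(idx) == 1L) cnt[idx, ] else colSums(cnt[idx, ,
                                                                drop = FALSE])
    if (sum(decay) < threshold) next
    res <- tryCatch(
      fit_pixel(decay, irf, cube$time_axis, init = init, bounds = bounds,
                objective = objective, wrap = wrap),
      error = function(e) NULL
    )
    if (is.null(res) || !res$converged) next
    maps$tau1[idx] <- res$params[["tau1"]]
    maps$tau2[idx] <- res$params[["tau2"]]
    maps$alpha1[idx] <- res$params[["alpha1"]]
    maps$tau_mean[idx] <- res$tau_mean
    maps$intensity[idx] <- res$params[["amplitude"]] / length(idx)
    maps$chi2[idx] <- res$reduced_chi2
    maps$valid[idx] <- TRUE
  }

  structure(
    c(maps, list(
      channel = cube$channel,
      settings = list(
        threshold = threshold, binning = binning, objective = objective,
        wrap = wrap, init = init, bounds = bounds,
        irf_fwhm_ps = irf$fwhm_ps, irf_peak_bin = irf$peak_bin
      ),
      meta = cube$meta
    )),
    class = "parameter_maps"
  )
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf(
    "<parameter_maps> %s: %d x %d pixels, %d valid (threshold %g, binning %d)\n",
    x$channel, nrow(x$valid), ncol(x$valid), sum(x$valid),
    x$settings$threshold, x$settings$binning
  ))
  invisible(x)
}
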