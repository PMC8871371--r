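test_that("noiseless high-count decays recover parameters within 1%", {
  truth <- list(amplitude = 1e6, alpha1 = 0.7, tau1 = 0.4, tau2 = 2.5,
                offset = 0)
  irf <- make_irf(0, default_axis, peak_bin = 1)
  y <- model_decay(truth, default_axis, irf)
  f <- fit_pixel(round(y), irf, default_axis)
  expect_true(f$converged)
  for (p in c("tau1", "tau2", "alpha1")) {
    expect_lt(abs(f$params[[p]] - truth[[p]]) / truth[[p]], 0.01)
  }
  # with the realistic IRF convolved in, recovery must still hold
  y2 <- model_decay(truth, default_axis, default_irf)
  f2 <- fit_pixel(round(y2), default_irf, default_axis)
  for (p in c("tau1", "tau2", "alpha1")) {
    expect_lt(abs(f2$params[[p]] - truth[[p]]) / truth[[p]], 0.01)
  }
})

test_that("a single-exponential decay yields the right mean lifetime", {
  # component split is unidentifiable; tau_m is the identifiable quantity
  y <- model_decay(list(amplitude = 1e6, alpha1 = 1, tau1 = 1.0,
                        tau2 = 2.5, offset = 0), default_axis, default_irf)
  f <- fit_pixel(round(y), default_irf, default_axis)
  expect_lt(abs(f$tau_mean - 1.0), 0.01)
})

test_that("stored tau_mean equals mean_lifetime of the stored parameters", {
  set.seed(3)
  y <- model_decay(true_params, default_axis, default_irf)
  for (i in 1:5) {
    f <- fit_pixel(rpois(256, y), default_irf, default_axis)
    expect_identical(f$tau_mean,
                     mean_lifetime(f$params[["tau1"]], f$params[["tau2"]],
                                   f$params[["alpha1"]]))
  }
})

test_that("Poisson-noise recovery at 5000 photons: median tau_m error < 10%", {
  tm_true <- mean_lifetime(true_params$tau1, true_params$tau2,
                           true_params$alpha1)
  y <- model_decay(true_params, default_axis, default_irf)
  set.seed(101)
  errs <- replicate(60, {
    f <- fit_pixel(rpois(256, y), default_irf, default_axis)
    abs(f$tau_mean - tm_true) / tm_true
  })
  expect_lt(median(errs), 0.10)
})

test_that("fitting with the rendering IRF recovers tau1 within 5%", {
  y <- model_decay(list(amplitude = 2e5, alpha1 = 0.7, tau1 = 0.4,
                        tau2 = 2.5, offset = 0.1), default_axis,
                   default_irf)
  f <- fit_pixel(round(y), default_irf, default_axis)
  expect_lt(abs(f$params[["tau1"]] - 0.4) / 0.4, 0.05)
})

test_that("the optimiser beats a brute-force grid on toy cubes", {
  # profile the amplitude analytically at each grid node, offset fixed at 0
  irf <- make_irf(0, short_axis, peak_bin = 1)
  grid <- expand.grid(tau1 = seq(0.2, 0.8, 0.1),
                      tau2 = seq(1.5, 3.5, 0.25),
                      alpha1 = seq(0.1, 0.9, 0.1))
  tt <- short_axis$centers
  shapes <- apply(grid, 1, function(g) {
    s <- g[["alpha1"]] * exp(-tt / g[["tau1"]]) +
      (1 - g[["alpha1"]]) * exp(-tt / g[["tau2"]])
    s / sum(s)
  })
  set.seed(77)
  truth <- list(amplitude = 3000, alpha1 = 0.6, tau1 = 0.5, tau2 = 2.2,
                offset = 0)
  y_exp <- model_decay(truth, short_axis, irf)
  for (i in 1:8) {
    d <- rpois(short_axis$n_bins, y_exp)
    w <- 1 / pmax(d, 1)
    f <- fit_pixel(d, irf, short_axis)
    obj_fit <- sum(w * (d - model_decay(as.list(f$params), short_axis,
                                        irf))^2)
    # weighted-LS profile of the amplitude for every grid shape
    obj_grid <- apply(shapes, 2, function(s) {
      a <- sum(w * s * d) / sum(w * s^2)
      sum(w * (d - a * s)^2)
    })
    expect_lte(obj_fit, min(obj_grid) * (1 + 1e-8))
  }
})

test_that("tau_m bias shrinks monotonically with the photon budget", {
  tm_true <- mean_lifetime(true_params$tau1, true_params$tau2,
                           true_params$alpha1)
  set.seed(5)
  bias <- sapply(c(1e3, 1e4, 1e6), function(budget) {
    p <- true_params
    p$amplitude <- budget
    y <- model_decay(p, default_axis, default_irf)
    tms <- replicate(25, fit_pixel(rpois(256, y), default_irf,
                                   default_axis)$tau_mean)
    abs(mean(tms) - tm_true)
  })
  expect_true(all(diff(bias) < 0))
})

test_that("fit_pixel validates its inputs", {
  expect_error(fit_pixel(rep(1, 100), default_irf, default_axis), "bins")
  expect_error(fit_pixel(rep(0, 256), default_irf, default_axis),
               "threshold")
})

test_that("fit_image masks background below the photon threshold", {
  g <- default_group_params()
  sc <- make_scene(scene_spec(shape = c(24, 24), n_cells = 2,
                              radius_range = c(4, 5), groups = g,
                              background_offset = 0.1, seed = 12))
  cube <- render_decay_cube(sc, "nadph", default_irf, default_axis,
                            seed = 3)
  # threshold above offset-only totals (0.1 * 256 ~ 26) but below budgets
  maps <- fit_image(cube, default_irf, threshold = 500)
  expect_identical(maps$valid, sc$label > 0)
  expect_true(all(is.na(maps$tau_mean[!maps$valid])))
  expect_true(all(!is.na(maps$tau_mean[maps$valid])))
  expect_true(all(maps$alpha1[maps$valid] >= 0 &
                    maps$alpha1[maps$valid] <= 1))
  # tau_m identity holds bit-for-bit on every valid pixel
  v <- maps$valid
  expect_identical(maps$tau_mean[v],
                   mean_lifetime(maps$tau1[v], maps$tau2[v],
                                 maps$alpha1[v]))

  # threshold zero keeps every pixel (offset-only pixels fit as flat curves)
  maps0 <- fit_image(cube, default_irf, threshold = 0)
  expect_true(all(maps0$valid))
})

test_that("spatial binning pools photons and reduces estimator spread", {
  g <- default_group_params()
  for (nm in c("tau1_sd", "tau2_sd", "alpha1_sd", "budget_sd")) {
    g$neg$nadph[[nm]] <- 0
  }
  g$neg$nadph$budget_mean <- 600 # low per-pixel budget
  sc <- make_scene(scene_spec(shape = c(30, 30), n_cells = 1,
                              radius_range = c(14, 14), tnfa_prop = 0,
                              groups = g, background_offset = 0, seed = 6))
  cube <- render_decay_cube(sc, "nadph", default_irf, default_axis,
                            seed = 9)
  maps1 <- fit_image(cube, default_irf, threshold = 100, binning = 1)
  maps3 <- fit_image(cube, default_irf, threshold = 100, binning = 3)
  inside <- sc$label == 1 & maps1$valid & maps3$valid
  sd1 <- stats::sd(maps1$tau_mean[inside])
  # one estimate per block: deduplicate before taking the spread
  sd3 <- stats::sd(unique(round(maps3$tau_mean[inside], 12)))
  expect_lt(sd3, sd1 / 2)
  expect_error(fit_image(cube, default_irf, binning = 64), "binning")
})

test_that("the Poisson-deviance objective agrees with weighted LS at high counts", {
  y <- model_decay(list(amplitude = 1e5, alpha1 = 0.7, tau1 = 0.4,
                        tau2 = 2.5, offset = 0.5), default_axis,
                   default_irf)
  set.seed(15)
  d <- rpois(256, y)
  f_ls <- fit_pixel(d, default_irf, default_axis, objective = "neyman")
  f_ml <- fit_pixel(d, default_irf, default_axis, objective = "poisson")
  expect_lt(abs(f_ls$tau_mean - f_ml$tau_mean) / f_ml$tau_mean, 0.02)
})
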