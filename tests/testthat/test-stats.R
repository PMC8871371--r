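test_that("a single group with no blocks or clusters reduces to the t-interval", {
  set.seed(11)
  tbl <- tibble::tibble(y = rnorm(30, 5, 2), grp = "only")
  fit <- fit_glm(tbl, "y", "grp", block = NULL, cluster = NULL)
  tt <- stats::t.test(tbl$y)
  expect_equal(fit$means$estimate, mean(tbl$y))
  expect_equal(fit$means$conf_low, tt$conf.int[1])
  expect_equal(fit$means$conf_high, tt$conf.int[2])
})

test_that("balanced day blocks leave the treatment contrast unchanged", {
  set.seed(12)
  base <- tibble::tibble(
    treatment = rep(c("a", "b"), each = 40),
    day_id = rep(rep(c("D1", "D2"), each = 20), 2),
    larva_id = paste0("L", rep(1:16, each = 5)),
    y = rnorm(80, 10) + rep(c(0, 1.5), each = 40)
  )
  shifted <- base
  shifted$y <- base$y + ifelse(base$day_id == "D2", 7, 0)
  f0 <- fit_glm(base, "y", "treatment", block = NULL, cluster = "larva_id")
  f1 <- fit_glm(shifted, "y", "treatment", block = "day_id",
                cluster = "larva_id")
  c0 <- f0$contrasts$estimate
  c1 <- f1$contrasts$estimate
  expect_equal(c1, c0, tolerance = 1e-10)
})

test_that("singleton clusters reproduce the HC1 covariance", {
  set.seed(13)
  tbl <- tibble::tibble(
    treatment = rep(c("a", "b"), each = 25),
    y = rnorm(50, 3, 1.4)
  )
  fit <- stats::lm(y ~ treatment, data = tbl)
  vc <- cluster_robust_cov(fit, seq_len(50))
  expect_equal(vc, sandwich::vcovHC(fit, type = "HC1"), tolerance = 1e-10)
  expect_error(cluster_robust_cov(fit, rep(1, 50)), "two clusters")
  expect_error(cluster_robust_cov(fit, 1:10), "per fitted observation")
})

test_that("robust SEs exceed classical SEs under strong clustering", {
  # ICC 0.5 via equal larva and cell SDs
  set.seed(29)
  wins <- replicate(60, {
    d <- cohort_design(effects = list(), day_shift_sd = 0,
                       larva_sd = 0.1, cell_sd = 0.1, n_days = 1,
                       larvae_per_day = 10, cells_per_larva = 30,
                       seed = sample.int(1e6, 1))
    tbl <- simulate_cohort(d)
    fit <- stats::lm(log(orr) ~ treatment, data = tbl)
    se_cl <- sqrt(diag(cluster_robust_cov(fit, tbl$larva_id)))[2]
    se_ols <- sqrt(diag(stats::vcov(fit)))[2]
    se_cl > se_ols
  })
  expect_gte(mean(wins), 0.95)
})

test_that("robust SEs track classical SEs without clustering", {
  set.seed(17)
  ratios <- replicate(30, {
    tbl <- tibble::tibble(
      treatment = rep(c("a", "b"), each = 500),
      larva_id = rep(sprintf("L%d", 1:50), each = 20),
      y = rnorm(1000)
    )
    fit <- stats::lm(y ~ treatment, data = tbl)
    se_cl <- sqrt(diag(cluster_robust_cov(fit, tbl$larva_id)))[2]
    se_ols <- sqrt(diag(stats::vcov(fit)))[2]
    se_cl / se_ols
  })
  expect_lt(abs(median(ratios) - 1), 0.15)
})

test_that("log-scale fits report fold changes whose CIs cover the truth", {
  # 0.85 injected ratio, 8 larvae/group x 30 cells; moderate replicate count
  set.seed(31)
  covered <- replicate(120, {
    d <- cohort_design(
      effects = list(treated = c(orr = 0.85)),
      n_days = 2, larvae_per_day = 4, cells_per_larva = 30,
      day_shift_sd = 0.03, larva_sd = 0.05, cell_sd = 0.10,
      seed = sample.int(1e6, 1)
    )
    tbl <- simulate_cohort(d)
    fit <- fit_glm(tbl, "orr", "treatment", log_transform = TRUE)
    ct <- fit$contrasts
    ct$ratio_low <= 0.85 && 0.85 <= ct$ratio_high
  })
  expect_gte(mean(covered), 0.90)
})

test_that("rank-deficient designs and nonpositive log outcomes error", {
  tbl <- toy_cohort()
  tbl$dup <- tbl$treatment
  expect_error(fit_glm(tbl, "orr", c("treatment", "dup")), "aliased")
  tbl$bad <- tbl$orr - 1
  expect_error(fit_glm(tbl, "bad", "treatment", log_transform = TRUE),
               "nonpositive")
  expect_error(fit_glm(tbl, "nope", "treatment"), "not found")
})

test_that("interaction models estimate means for factor combinations", {
  set.seed(19)
  tbl <- tidyr::expand_grid(
    time = c("24h", "72h"), treatment = c("tt", "burn"),
    rep = 1:30
  )
  tbl$larva_id <- paste0(tbl$time, tbl$treatment, rep(1:6, length.out = 120))
  tbl$day_id <- "D1"
  tbl$y <- rnorm(120, 10) +
    ifelse(tbl$treatment == "burn" & tbl$time == "24h", -2, 0)
  fit <- fit_glm(tbl, "y", c("treatment", "time"), block = NULL,
                 interaction = TRUE)
  expect_equal(nrow(fit$means), 4)
  expect_equal(nrow(fit$contrasts), 6)
  # the interaction cell mean is recovered
  m <- fit$means$estimate[fit$means$group == "burn:24h"]
  expect_equal(m, mean(tbl$y[tbl$treatment == "burn" & tbl$time == "24h"]),
               tolerance = 1e-10)
})

test_that("estimated means agree with emmeans under the same covariance", {
  skip_if_not_installed("emmeans")
  tbl <- toy_cohort(n_cells = 120, n_larvae = 12)
  fit <- fit_glm(tbl, "nadph_tm", "treatment", block = "day_id",
                 cluster = "larva_id")
  em <- emmeans::emmeans(fit$fit, "treatment", vcov. = fit$vcov)
  es <- as.data.frame(em)
  expect_equal(fit$means$estimate, es$emmean, tolerance = 1e-10)
  expect_equal(fit$means$se, es$SE, tolerance = 1e-10)
})

test_that("residual diagnostics flag engineered heteroskedasticity only", {
  set.seed(23)
  n <- 400
  tbl <- tibble::tibble(
    treatment = rep(c("a", "b"), each = n / 2),
    larva_id = rep(sprintf("L%d", 1:20), each = n / 20),
    mu = ifelse(treatment == "a", 2, 8)
  )
  tbl$y_ok <- rnorm(n, tbl$mu, 1)
  tbl$y_het <- rnorm(n, tbl$mu, 0.2 * tbl$mu^2)
  f_ok <- fit_glm(tbl, "y_ok", "treatment", block = NULL)
  f_het <- fit_glm(tbl, "y_het", "treatment", block = NULL)
  expect_false(glm_diagnostics(f_ok)$heteroskedastic)
  expect_true(glm_diagnostics(f_het)$heteroskedastic)
  # OLS identity: residuals sum to zero
  expect_lt(abs(sum(glm_diagnostics(f_ok)$residuals$residual)),
            1e-8 * sum(abs(tbl$y_ok)))
})

test_that("tidy and glance summarise the fit with robust uncertainty", {
  tbl <- toy_cohort()
  fit <- fit_glm(tbl, "orr", "treatment")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value")
                  %in% names(td)))
  expect_equal(td$std.error, sqrt(diag(fit$vcov)), ignore_attr = TRUE)
  gl <- glance(fit)
  expect_equal(gl$n_cells, nrow(tbl))
  expect_equal(gl$n_larvae, 6)
  expect_equal(gl$df, 5)
  # CIs contain their point estimates; p-values in (0, 1]
  expect_true(all(fit$means$conf_low <= fit$means$estimate &
                    fit$means$estimate <= fit$means$conf_high))
  expect_true(all(fit$contrasts$p_value > 0 & fit$contrasts$p_value <= 1))
})
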