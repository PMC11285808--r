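test_that("with one virus and no vial variance the fit reduces to a two-group comparison", {
  cfg0 <- small_config(sigma_vial = 0, beta = c(vA = -8, vB = 0),
                       transmission = c(vA = 0.5, vB = 0))
  x <- generate_experiment(cfg0, seed = 17)
  inf <- infection_indicators(x)
  dat <- dplyr::left_join(x$recipients, inf, by = "fly_id")
  ols_diff <- mean(dat$lifespan_days[dat$vA == 1]) -
    mean(dat$lifespan_days[dat$vA == 0])
  fit <- suppressWarnings(fit_lifespan_A(x, quick_cfg(seed = 2, total = 2500,
                                                      burn = 500, rec = 600)))
  d <- fit$chain$draws[, "vA"]
  expect_lt(abs(mean(d) - ols_diff), 3 * sd(d))
})

test_that("estimates are invariant to virus column order", {
  x <- generate_experiment(small_config(), seed = 19)
  x_rev <- experiment_table(x$recipients, x$detections, x$donors,
                            rev(x$virus_panel), x$meta)
  cfg <- quick_cfg(seed = 3, total = 2500, burn = 500, rec = 600)
  fa <- suppressWarnings(fit_lifespan_A(x, cfg))
  fb <- suppressWarnings(fit_lifespan_A(x_rev, cfg))
  for (v in c("vA", "vB")) {
    da <- fa$chain$draws[, v]
    db <- fb$chain$draws[, v]
    se <- sqrt(sd(da)^2 / effective_sample_size(da) +
                 sd(db)^2 / effective_sample_size(db))
    expect_lt(abs(mean(da) - mean(db)), 4 * se)
  }
})

test_that("censoring options agree exactly when nothing is censored", {
  cfg0 <- small_config(mu0 = 30, sigma_e = 5) # virtually nobody reaches day 72
  x <- generate_experiment(cfg0, seed = 23)
  x$recipients$censored <- FALSE
  cfg <- quick_cfg(seed = 4)
  a <- suppressWarnings(fit_lifespan_A(x, cfg, censored = "at_limit"))
  b <- suppressWarnings(fit_lifespan_A(x, cfg, censored = "exclude"))
  expect_identical(a$chain$draws, b$chain$draws)
})

test_that("viruses with no infected flies are dropped with a warning", {
  cfg0 <- small_config(transmission = c(vA = 0.5, vB = 0))
  x <- generate_experiment(cfg0, seed = 29)
  expect_warning(fit <- fit_lifespan_A(x, quick_cfg(seed = 5)), "vB")
  expect_equal(fit$dropped, "vB")
  expect_false("vB" %in% fit$summary$parameter)
  expect_error(percent_reduction(fit, "vB"), "dropped|unknown")
})

test_that("a fully uninfected table is inestimable for both models", {
  cfg0 <- small_config(transmission = c(vA = 0, vB = 0))
  x <- generate_experiment(cfg0, seed = 31)
  expect_error(fit_lifespan_A(x, quick_cfg()), "no infected")
  expect_error(fit_lifespan_B(x, quick_cfg()), "inestimable|no infected")
})

test_that("the infection-count model recovers an additive per-infection effect", {
  cfg0 <- small_config(beta = c(vA = -7, vB = -7),
                       transmission = c(vA = 0.4, vB = 0.4),
                       n_vials = c(Dmel = 10, Dimm = 10, DobsGroup = 0,
                                   LabControl = 2))
  x <- generate_experiment(cfg0, seed = 37)
  fit <- suppressWarnings(
    fit_lifespan_B(x, quick_cfg(seed = 6, total = 2500, burn = 500, rec = 600)))
  s <- fit$summary[fit$summary$parameter == "n_infections", ]
  expect_true(s$hpd_low <= -7 && -7 <= s$hpd_high)
  expect_lt(s$mean, 0)
})

test_that("percent reduction transforms draws rather than point estimates", {
  x <- generate_experiment(small_config(), seed = 41)
  cfg <- quick_cfg(seed = 7)
  fit <- suppressWarnings(fit_lifespan_A(x, cfg))
  pr <- percent_reduction(fit, "vA")
  manual <- 100 * (-fit$chain$draws[, "vA"] / fit$chain$draws[, "(Intercept)"])
  expect_equal(pr$mean, mean(manual))
  expect_equal(unname(c(pr$hpd_low, pr$hpd_high)),
               unname(hpd_interval(manual, 0.95)))
  # truth: -8 days on a 40-day baseline = 20% reduction
  expect_true(pr$hpd_low <= 20 && 20 <= pr$hpd_high)

  alt <- suppressWarnings(fit_lifespan_A(x, cfg, baseline = "uninfected_mean"))
  expect_false(identical(alt$pct_reduction$mean, fit$pct_reduction$mean))
})

test_that("a single-vial experiment fits with a warning", {
  cfg0 <- small_config(n_vials = c(Dmel = 1, Dimm = 0, DobsGroup = 0,
                                   LabControl = 0),
                       recipients_per_vial = 60)
  x <- generate_experiment(cfg0, seed = 43)
  expect_warning(fit_lifespan_A(x, quick_cfg(seed = 8, total = 800, burn = 200,
                                             rec = 150)),
                 "single|vial")
})

test_that("tidy and glance expose the fit in broom style", {
  x <- generate_experiment(small_config(), seed = 47)
  fit <- suppressWarnings(fit_lifespan_A(x, quick_cfg(seed = 9)))
  td <- tidy(fit)
  expect_true(all(c("parameter", "mean", "hpd_low", "hpd_high", "ess",
                    "pmcmc") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, nrow(x$recipients))
  expect_s3_class(autoplot(fit), "ggplot")
})
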