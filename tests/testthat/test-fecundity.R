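test_that("zero-part estimability follows the mixed zero/nonzero rule", {
  r <- tibble::tibble(
    fly_id = paste0("f", 1:6), vial_id = "v1",
    lifespan_days = 40, censored = FALSE,
    offspring_early = c(0L, 3L, 5L, 0L, 2L, 4L),
    offspring_total = c(0L, 9L, 12L, 0L, 6L, 10L),
    excluded_early = FALSE
  )
  d <- tibble::tibble(
    fly_id = rep(paste0("f", 1:6), each = 3),
    virus = rep(c("mixed", "fertile", "ghost"), 6),
    exposed = TRUE,
    detected = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE,  TRUE, FALSE, FALSE,
                 TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  don <- tibble::tibble(vial_id = "v1", species_group = "Dmel",
                        pool_size = 10L,
                        virus = c("mixed", "fertile", "ghost"),
                        assay_positive = TRUE)
  x <- experiment_table(r, d, don)
  ze <- detect_zero_estimable(x)
  # "mixed" infects both a zero-offspring and a fertile fly; "fertile" only
  # fertile flies; "ghost" infects nobody
  expect_true("mixed" %in% ze$estimable)
  expect_equal(ze$excluded$reason[ze$excluded$virus == "fertile"],
               "no_zero_offspring")
  expect_equal(ze$excluded$reason[ze$excluded$virus == "ghost"], "no_infected")
})

test_that("the hurdle fit estimates effects and transforms them to percent scale", {
  x <- generate_experiment(small_config(), seed = 53)
  cfg <- quick_cfg(seed = 11, total = 2000, burn = 500, rec = 500)
  fit <- suppressWarnings(fit_fecundity(x, cfg))
  # vA truth: -0.5 on the log scale = 39.3% reduction
  pr <- percent_offspring_reduction(fit, "vA")
  expect_true(pr$hpd_low <= 100 * (1 - exp(-0.5)) &&
                100 * (1 - exp(-0.5)) <= pr$hpd_high)
  manual <- 100 * (1 - exp(fit$chain$draws[, "count_vA"]))
  expect_equal(pr$mean, mean(manual))
  # predicted zero probabilities are proper probabilities
  expect_true(all(fit$p_zero$mean >= 0 & fit$p_zero$mean <= 1))
  expect_error(percent_offspring_reduction(fit, "nope"), "count part")
})

test_that("the early window drops exactly the flagged flies", {
  x <- generate_experiment(small_config(), seed = 59)
  n_flagged <- sum(x$recipients$excluded_early)
  expect_gt(n_flagged, 0)
  cfg <- quick_cfg(seed = 12, total = 1200, burn = 300, rec = 300)
  fit <- suppressWarnings(fit_fecundity(x, cfg, window = "early"))
  expect_equal(fit$n, nrow(x$recipients) - n_flagged)
})

test_that("lifetime and early fits differ only through response and filter", {
  x <- generate_experiment(small_config(), seed = 61)
  x$recipients$excluded_early <- FALSE
  x$recipients$offspring_early <- x$recipients$offspring_total
  lt <- flyvir:::fecundity_frame(x, "lifetime")
  ea <- flyvir:::fecundity_frame(x, "early")
  expect_equal(lt$y, ea$y)
  expect_equal(dim(lt), dim(ea))
})

test_that("degenerate count vectors are rejected with a named part", {
  x <- generate_experiment(small_config(), seed = 67)
  x$recipients$offspring_total <- 0L
  x$recipients$offspring_early <- 0L
  expect_error(fit_fecundity(x, quick_cfg()), "count part")
  y <- generate_experiment(small_config(), seed = 67)
  y$recipients$offspring_total <- y$recipients$offspring_total + 1L
  expect_error(fit_fecundity(y, quick_cfg()), "zero part")
})

test_that("the posterior-predictive zero check behaves at both extremes", {
  x <- generate_experiment(small_config(), seed = 71)
  cfg <- quick_cfg(seed = 13, total = 2000, burn = 500, rec = 500)
  fit <- suppressWarnings(fit_fecundity(x, cfg))
  ppc <- posterior_predictive_zeros(fit, n_draws = 150, seed = 2)
  # data generated from the same family: the check should pass
  expect_true(ppc$inside)
  expect_length(ppc$simulated, 150)

  # post-hoc doubling of the zeros pushes the observation above the band
  broken <- fit
  zeros <- broken$design$y == 0
  broken$design$y[which(!zeros)[seq_len(sum(zeros))]] <- 0L
  ppc2 <- posterior_predictive_zeros(broken, n_draws = 150, seed = 2)
  expect_false(ppc2$inside)
  expect_gt(ppc2$observed, ppc2$band[2])

  expect_error(posterior_predictive_zeros(fit, n_draws = 0), "n_draws")
  expect_warning(posterior_predictive_zeros(fit, n_draws = 50 - 1, seed = 3),
                 "noisy|50")
  expect_s3_class(autoplot(ppc), "ggplot")
})

test_that("early-late offspring correlation matches closed-form cases", {
  x <- tiny_experiment()
  # identical early and late vectors give r = 1
  x$recipients$offspring_total <- 2L * x$recipients$offspring_early
  expect_equal(early_late_correlation(x)$r, 1, tolerance = 1e-12)

  set.seed(73)
  n <- 596
  rho <- 0.32
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  early <- as.integer(pmax(round(20 + 5 * z1), 0))
  late <- as.integer(pmax(round(60 + 15 * z2), 0))
  r <- tibble::tibble(
    fly_id = paste0("f", 1:n), vial_id = "v1", lifespan_days = 40,
    censored = FALSE, offspring_early = early,
    offspring_total = early + late, excluded_early = FALSE
  )
  don <- tibble::tibble(vial_id = "v1", species_group = "Dmel",
                        pool_size = 10L, virus = "vA", assay_positive = TRUE)
  xx <- experiment_table(r, tibble::tibble(fly_id = character(),
                                           virus = character(),
                                           exposed = logical(),
                                           detected = logical()),
                         don, virus_panel = "vA")
  est <- early_late_correlation(xx)
  se <- (1 - rho^2) / sqrt(n)
  expect_lt(abs(est$r - rho), 3 * se)
  expect_equal(est$df, n - 2)
})
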