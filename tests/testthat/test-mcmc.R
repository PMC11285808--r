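# brute-force HPD oracle over contiguous windows of the sorted draws
hpd_oracle <- function(draws, mass) {
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1)) {
    if (s[i + m - 1] - s[i] < best[2] - best[1]) best <- c(s[i], s[i + m - 1])
  }
  best
}

test_that("HPD intervals match the window-enumeration oracle", {
  expect_equal(unname(hpd_interval(rep(3.5, 10), 0.95)), c(3.5, 3.5))
  expect_equal(unname(hpd_interval(1:100, 0.95)), c(1, 95))
  expect_equal(unname(hpd_interval(c(rep(0, 97), rep(10, 3)), 0.95)), c(0, 0))
  set.seed(51)
  for (i in 1:20) {
    d <- rgamma(200, shape = 2) # skewed
    expect_equal(unname(hpd_interval(d, 0.9)), hpd_oracle(d, 0.9))
  }
  expect_error(hpd_interval(1, 0.95), "2 draws")
})

test_that("effective sample size tracks chain autocorrelation", {
  set.seed(61)
  iid <- rnorm(10000)
  expect_lt(abs(effective_sample_size(iid) - 10000) / 10000, 0.1)

  # AR(1), phi = 0.5: asymptotic ESS ratio (1-phi)/(1+phi) = 1/3
  n <- 20000
  phi <- 0.5
  ar <- as.numeric(stats::arima.sim(list(ar = phi), n))
  expect_lt(abs(effective_sample_size(ar) - n / 3) / (n / 3), 0.2)

  expect_equal(effective_sample_size(rep(2, 100)), 100)
})

test_that("pMCMC follows the two-sided tail rule with its floor", {
  expect_equal(pmcmc(c(-1, -2, 1, 2)), 1)
  expect_equal(pmcmc(c(rep(1, 250), rep(-1, 9750))), 0.05)
  expect_equal(pmcmc(rep(-3, 10000)), 2 / 10000)
})

test_that("the Gibbs sampler matches the closed-form conjugate posterior", {
  set.seed(71)
  n <- 50
  sigma2 <- 4
  y <- rnorm(n, 2, sqrt(sigma2))
  pv <- 100 # informative enough prior that the closed form is non-trivial
  cfg <- run_config(seed = 71, chain_total = 20000, burn_in = 2000,
                    chain_recorded = 6000, priors = prior_spec(beta_var = pv))
  ch <- gibbs_lmm(cbind(mu = rep(1, n)), y, cfg = cfg,
                  priors = prior_spec(beta_var = pv), fix_s2e = sigma2)
  post_var <- 1 / (n / sigma2 + 1 / pv)
  post_mean <- post_var * sum(y) / sigma2
  d <- ch$draws[, "mu"]
  mc_se <- sd(d) / sqrt(effective_sample_size(d))
  expect_lt(abs(mean(d) - post_mean), 3 * mc_se)
  expect_lt(abs(var(d) - post_var) / post_var, 0.15)
})

test_that("chains are exactly reproducible and abort on bad designs", {
  set.seed(81)
  n <- 60
  X <- cbind(int = rep(1, n), x = rnorm(n))
  y <- drop(X %*% c(1, 2)) + rnorm(n)
  cfg <- quick_cfg(seed = 4, total = 600, burn = 100, rec = 100)
  a <- gibbs_lmm(X, y, cfg = cfg)
  b <- gibbs_lmm(X, y, cfg = cfg)
  expect_identical(a$draws, b$draws)

  X2 <- cbind(X, dup = X[, "x"])
  expect_error(gibbs_lmm(X2, y, cfg = cfg), "collinear.*dup")
})

test_that("a flat design with constant response runs without crashing", {
  n <- 40
  cfg <- quick_cfg(seed = 6, total = 600, burn = 100, rec = 100)
  ch <- suppressWarnings(
    gibbs_lmm(cbind(int = rep(1, n)), rep(5, n), cfg = cfg))
  # residual variance collapses toward its prior range
  expect_lt(median(ch$draws[, "sigma2_resid"]), 0.5)
})

test_that("posterior means agree with an independent ML mixed-model fit", {
  skip_if_not_installed("lme4")
  set.seed(91)
  for (i in 1:5) {
    n_vial <- 10
    n <- 30 * n_vial
    vial <- rep(seq_len(n_vial), each = 30)
    x1 <- rnorm(n)
    y <- 5 + 1.5 * x1 + rnorm(n_vial, 0, 2)[vial] + rnorm(n, 0, 3)
    cfg <- quick_cfg(seed = 100 + i, total = 2500, burn = 500, rec = 800)
    ch <- gibbs_lmm(cbind(int = rep(1, n), x1 = x1), y,
                    random = list(vial = factor(vial)), cfg = cfg)
    ml <- lme4::lmer(y ~ x1 + (1 | vial), REML = FALSE)
    for (par in c("int", "x1")) {
      d <- ch$draws[, par]
      ml_est <- lme4::fixef(ml)[[if (par == "int") "(Intercept)" else "x1"]]
      expect_lt(abs(mean(d) - ml_est), 3 * sd(d))
    }
  }
})

test_that("the zero-truncated Poisson sampler has the right mean", {
  set.seed(101)
  draws <- flyvir:::rztpois(20000, 2)
  expect_true(all(draws >= 1))
  target <- 2 / (1 - exp(-2)) # 2.313
  expect_lt(abs(mean(draws) - target), 3 * sd(draws) / sqrt(20000))
})

test_that("the hurdle sampler concentrates the zero part when no zeros exist", {
  set.seed(111)
  n <- 300
  y <- flyvir:::rztpois(n, 40)
  cfg <- quick_cfg(seed = 7, total = 1500, burn = 400, rec = 300)
  ch <- hurdle_poisson_mcmc(y, cbind(int = rep(1, n)), cbind(int = rep(1, n)),
                            cfg = cfg)
  p_zero <- plogis(ch$draws[, "zero_int"])
  expect_lt(mean(p_zero), 0.05)
  expect_error(
    hurdle_poisson_mcmc(rep(0L, 20), cbind(int = rep(1, 20)),
                        cbind(int = rep(1, 20)), cfg = cfg),
    "count-part")
})

test_that("the hurdle sampler recovers a known count-part effect", {
  set.seed(121)
  n <- 600
  vial <- rep(1:30, each = 20)
  infected <- runif(n) < 0.3
  lz <- -1 + rnorm(n, 0, 0.5)
  lc <- log(50) - 0.6 * infected + rnorm(n, 0, 0.5)
  y <- ifelse(runif(n) < plogis(lz), 0L, flyvir:::rztpois(n, exp(lc)))
  cfg <- quick_cfg(seed = 8, total = 2000, burn = 500, rec = 500)
  ch <- hurdle_poisson_mcmc(y, cbind(int = rep(1, n), virus = as.numeric(infected)),
                            cbind(int = rep(1, n)), grouping = factor(vial),
                            cfg = cfg)
  h <- hpd_interval(ch$draws[, "count_virus"], 0.95)
  expect_lt(h[["lower"]], -0.6 + 0.25)
  expect_gt(h[["upper"]], -0.6 - 0.25)
  expect_true(h[["lower"]] <= -0.6 && -0.6 <= h[["upper"]])
})

test_that("chain summaries carry ESS and flag weakly mixing parameters", {
  set.seed(131)
  n <- 80
  y <- rnorm(n)
  cfg <- quick_cfg(seed = 9, total = 800, burn = 200, rec = 150)
  ch <- gibbs_lmm(cbind(int = rep(1, n)), y, cfg = cfg)
  s <- summarize_chain(ch, ess_floor = 1e6)
  expect_true(all(s$low_ess))
  expect_true(all(s$ess <= 150 * 1.1))
})
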