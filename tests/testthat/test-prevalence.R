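# independent grid-search oracle for the pooled-likelihood maximiser,
# two-stage so the effective resolution is 1e-5
grid_mle <- function(pools) {
  ll <- function(ps) vapply(ps, function(p) pooled_loglik(p, pools), numeric(1))
  coarse <- seq(0, 1, 1e-3)
  p0 <- coarse[which.max(ll(coarse))]
  fine <- seq(max(0, p0 - 2e-3), min(1, p0 + 2e-3), 1e-5)
  fine[which.max(ll(fine))]
}

test_that("pooled log-likelihood matches direct arithmetic", {
  one_pos <- data.frame(size = 10, positive = TRUE)
  expect_identical(pooled_loglik(0, one_pos), -Inf)
  expect_equal(pooled_loglik(1, data.frame(size = c(3, 7), positive = TRUE)), 0)
  expect_equal(pooled_loglik(0.1, one_pos), log(1 - 0.9^10))
  mixed <- data.frame(size = c(5, 8), positive = c(TRUE, FALSE))
  expect_equal(pooled_loglik(0.2, mixed),
               log(1 - 0.8^5) + 8 * log(0.8))
  expect_error(pooled_loglik(1.5, one_pos), "0, 1")
})

test_that("unit pools reduce the MLE to the binomial proportion", {
  for (N in c(1, 5, 12)) {
    for (k in 0:N) {
      pools <- data.frame(size = rep(1, N),
                          positive = rep(c(TRUE, FALSE), c(k, N - k)))
      expect_lt(abs(estimate_prevalence(pools)$p_hat - k / N), 1e-6)
    }
  }
})

test_that("the pooled MLE matches the grid-search oracle", {
  pools <- data.frame(size = rep(10, 10), positive = c(TRUE, rep(FALSE, 9)))
  est <- estimate_prevalence(pools)
  expect_lt(abs(est$p_hat - grid_mle(pools)), 2e-5)

  set.seed(21)
  for (i in 1:10) {
    n_pool <- sample(3:15, 1)
    pools <- data.frame(size = sample(1:20, n_pool, replace = TRUE),
                        positive = sample(c(TRUE, FALSE), n_pool,
                                          replace = TRUE, prob = c(0.4, 0.6)))
    if (all(pools$positive) || !any(pools$positive)) next
    expect_lt(abs(estimate_prevalence(pools)$p_hat - grid_mle(pools)), 2e-5)
  }
})

test_that("boundary layouts give boundary estimates with one-sided intervals", {
  neg <- data.frame(size = rep(4, 6), positive = FALSE)
  e <- estimate_prevalence(neg)
  expect_equal(e$p_hat, 0)
  expect_equal(e$lower, 0)
  # closed form: upper solves -sum(n) * log(1-p) = 2
  expect_equal(e$upper, 1 - exp(-2 / 24), tolerance = 1e-6)

  pos <- data.frame(size = rep(4, 6), positive = TRUE)
  e2 <- estimate_prevalence(pos)
  expect_equal(e2$p_hat, 1)
  expect_equal(e2$upper, 1)
  expect_gt(e2$lower, 0)
})

test_that("flipping a negative pool positive never decreases the MLE", {
  set.seed(31)
  for (i in 1:20) {
    n_pool <- sample(4:12, 1)
    pools <- data.frame(size = sample(1:15, n_pool, replace = TRUE),
                        positive = runif(n_pool) < 0.4)
    if (!any(!pools$positive)) next
    flipped <- pools
    flipped$positive[which(!flipped$positive)[1]] <- TRUE
    expect_gte(estimate_prevalence(flipped)$p_hat + 1e-9,
               estimate_prevalence(pools)$p_hat)
  }
})

test_that("support intervals contain the MLE and tighten under replication", {
  pools <- data.frame(size = c(5, 5, 8, 10), positive = c(TRUE, FALSE, TRUE, FALSE))
  widths <- vapply(c(1, 4, 16), function(k) {
    rep_pools <- pools[rep(seq_len(nrow(pools)), k), ]
    e <- estimate_prevalence(rep_pools)
    expect_lte(e$lower, e$p_hat)
    expect_gte(e$upper, e$p_hat)
    e$upper - e$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("transmission rates reproduce the binomial support interval", {
  e <- estimate_transmission(213, 606)
  expect_equal(e$rate, 213 / 606, tolerance = 1e-6)

  z <- estimate_transmission(0, 50)
  expect_equal(z$rate, 0)
  expect_equal(z$lower, 0)

  # 5/20 against a fine grid on the binomial log-likelihood
  g <- seq(1e-5, 1 - 1e-5, 1e-5)
  llb <- 5 * log(g) + 15 * log(1 - g)
  inside <- range(g[llb >= max(llb) - 2])
  e5 <- estimate_transmission(5, 20)
  expect_equal(e5$lower, inside[1], tolerance = 1e-3)
  expect_equal(e5$upper, inside[2], tolerance = 1e-3)
})

test_that("per-virus and per-group estimates cover the experiment tables", {
  x <- generate_experiment(small_config(), seed = 13)
  pg <- prevalence_by_group(x$donors)
  expect_equal(nrow(pg), 3 * 2) # 3 groups with vials x 2 viruses
  expect_true(all(pg$lower <= pg$p_hat & pg$p_hat <= pg$upper))
  tr <- transmission_by_virus(x)
  expect_equal(tr$rate, tr$n_infected / tr$n_exposed, tolerance = 1e-6)
})

test_that("the exact r x 2 test reproduces known p-values", {
  # transmitted/not per donor group: 3/4, 4/7, 4/16
  p <- fisher_exact_rxc(rbind(c(3, 1), c(4, 3), c(4, 12)))
  expect_equal(p, 0.116, tolerance = 5e-3)
  expect_equal(fisher_exact_rxc(rbind(c(1, 1), c(1, 1))), 1)
  # all 4 tables with margins (3,3)/(3,3): only the two extremes qualify
  expect_equal(fisher_exact_rxc(rbind(c(3, 0), c(0, 3))), 0.1, tolerance = 1e-10)
  expect_error(fisher_exact_rxc(rbind(c(1.5, 1), c(1, 1))), "integer")
  expect_error(fisher_exact_rxc(rbind(c(0, 0), c(1, 1))), "margins")
})

test_that("the exact test agrees with the reference implementation on random tables", {
  set.seed(41)
  for (i in 1:60) {
    tab <- matrix(sample(0:6, 6, replace = TRUE), nrow = 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_rxc(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
})
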