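#' Which viruses support a zero-part (sterility) estimate?
#'
#' The logit of the probability of zero offspring is estimable for a virus
#' only if, among its infected flies in the analysis window, at least one
#' produced zero offspring and at least one produced some. Viruses with no
#' infected flies are excluded with their own reason code.
#'
#' @param x A `flyvir_experiment`.
#' @param window `"lifetime"` or `"early"` (the early window drops flies
#'   flagged `excluded_early`).
#' @return List with `estimable` (character vector) and `excluded` (tibble
#'   of virus + reason: `no_infected`, `no_zero_offspring`,
#'   `no_nonzero_offspring`).
#' @export
detect_zero_estimable <- function(x, window = c("lifetime", "early")) {
  window <- match.arg(window)
  dat <- fecundity_frame(x, window)
  status <- purrr::map(x$virus_panel, function(v) {
    yy <- dat$y[dat[[v]] == 1]
    reason <- if (length(yy) == 0) {
      "no_infected"
    } else if (!any(yy == 0)) {
      "no_zero_offspring"
    } else if (!any(yy > 0)) {
      "no_nonzero_offspring"
    } else {
      NA_character_
    }
    tibble::tibble(virus = v, reason = reason)
  }) |> purrr::list_rbind()
  list(estimable = status$virus[is.na(status$reason)],
       excluded = dplyr::filter(status, !is.na(.data$reason)))
}

fecundity_frame <- function(x, window) {
  inf <- infection_indicators(x)
  dat <- dplyr::left_join(x$recipients, inf, by = "fly_id")
  if (window == "early") {
    dat <- dplyr::filter(dat, !.data$excluded_early)
    dat$y <- dat$offspring_early
  } else {
    dat$y <- dat$offspring_total
  }
  dat
}

#' Hurdle-Poisson model of offspring production
#'
#' Fits the lifetime (or early-window) adult offspring count of each
#' recipient female with a two-part hurdle model: a logit-scale probability
#' of producing zero offspring and a zero-truncated Poisson for positive
#' counts. Each part carries its own baseline (no shared overall intercept,
#' so the zero-part levels are directly interpretable), per-virus infection
#' effects — on the count part for every virus with infected flies, on the
#' zero part only for viruses where sterility is estimable — and its own
#' exposure-vial random effect and latent residual variance, with the
#' between-part covariance fixed at zero.
#'
#' @param x A `flyvir_experiment`.
#' @param cfg A [run_config()].
#' @param window `"lifetime"` uses `offspring_total`; `"early"` uses
#'   `offspring_early` and drops flies that died before the early window
#'   closed.
#' @return A `flyvir_fecundity` fit: summaries, per-virus percent reductions
#'   in offspring (count part), per-virus predicted probability of zero
#'   offspring, exclusions, chain, and the design kept for
#'   posterior-predictive checks.
#' @seealso [percent_offspring_reduction()], [posterior_predictive_zeros()]
#' @export
fit_fecundity <- function(x, cfg = run_config(),
                          window = c("lifetime", "early")) {
  stopifnot(inherits(x, "flyvir_experiment"))
  window <- match.arg(window)
  dat <- fecundity_frame(x, window)
  if (all(dat$y == 0)) abort("fit_fecundity: all counts are zero; the count part is inestimable")
  if (!any(dat$y == 0)) abort("fit_fecundity: no zero counts; the zero part is inestimable")

  n_inf <- colSums(dat[, x$virus_panel, drop = FALSE])
  count_viruses <- x$virus_panel[n_inf > 0]
  dropped <- x$virus_panel[n_inf == 0]
  if (length(dropped)) {
    warn(sprintf("dropping virus(es) with no infected fly: %s",
                 paste(dropped, collapse = ", ")))
  }
  ze <- detect_zero_estimable(x, window)
  zero_viruses <- ze$estimable

  X_count <- cbind(`(Baseline)` = 1,
                   as.matrix(dat[, count_viruses, drop = FALSE]))
  X_zero <- cbind(`(Baseline)` = 1,
                  as.matrix(dat[, zero_viruses, drop = FALSE]))
  chain <- hurdle_poisson_mcmc(dat$y, X_count, X_zero,
                               grouping = factor(dat$vial_id),
                               priors = cfg$priors, cfg = cfg,
                               stage = paste0("fit-fecundity-", window))

  main <- !startsWith(colnames(chain$draws), "u_")
  summ_chain <- chain
  summ_chain$draws <- chain$draws[, main, drop = FALSE]
  pct <- purrr::map(count_viruses, function(v) {
    summarize_draws(100 * (1 - exp(chain$draws[, paste0("count_", v)])), v, cfg)
  }) |> purrr::list_rbind()
  g0 <- chain$draws[, "zero_(Baseline)"]
  p_zero <- purrr::map(c("(uninfected)", zero_viruses), function(v) {
    d <- if (v == "(uninfected)") plogis(g0) else {
      plogis(g0 + chain$draws[, paste0("zero_", v)])
    }
    summarize_draws(d, v, cfg)
  }) |> purrr::list_rbind()

  structure(list(
    chain = chain,
    summary = summarize_chain(summ_chain, cfg$hpd_mass, cfg$ess_floor),
    pct_reduction = pct, p_zero = p_zero,
    count_viruses = count_viruses, zero_viruses = zero_viruses,
    excluded = ze$excluded, dropped = dropped, window = window,
    design = list(X_count = X_count, X_zero = X_zero,
                  vial = factor(dat$vial_id), y = dat$y),
    n = nrow(dat), cfg = cfg
  ), class = c("flyvir_fecundity", "flyvir_fit"))
}

#' Percent reduction in offspring production for a virus
#'
#' Per-draw transform `100 * (1 - exp(b_v))` of the count-part (log-scale)
#' effect, summarized as mean and HPD.
#'
#' @param fit A `flyvir_fecundity`.
#' @param virus Virus fitted in the count part.
#' @return One-row posterior-summary tibble.
#' @examples
#' 100 * (1 - exp(-0.616)) # a -0.616 log-rate effect is a 46% reduction
#' @export
percent_offspring_reduction <- function(fit, virus) {
  stopifnot(inherits(fit, "flyvir_fecundity"))
  if (!virus %in% fit$count_viruses) {
    abort(sprintf("virus '%s' is not in the count part", virus))
  }
  fit$pct_reduction[fit$pct_reduction$parameter == virus, ]
}

#' Posterior-predictive check of the number of zero counts
#'
#' For each of `n_draws` recorded posterior draws, simulates a complete
#' offspring vector from the hurdle model at the observed covariates (fixed
#' effects, that draw's vial effects, fresh latent residuals) and counts the
#' zeros; the observed zero count is compared with the central 95% band of
#' the simulated counts.
#'
#' @param fit A `flyvir_fecundity`.
#' @param n_draws Number of posterior draws to simulate from (>= 50
#'   recommended).
#' @param seed Integer seed.
#' @return A `flyvir_ppc` list: `observed`, `simulated`, `band`, `inside`.
#' @export
posterior_predictive_zeros <- function(fit, n_draws = 200, seed = 1L) {
  stopifnot(inherits(fit, "flyvir_fecundity"))
  if (n_draws < 1) abort("posterior_predictive_zeros: n_draws must be >= 1")
  if (n_draws < 50) warn("fewer than 50 draws gives a noisy band")
  ch <- fit$chain$draws
  des <- fit$design
  idx_u_c <- paste0("u_count:", levels(des$vial))
  idx_u_z <- paste0("u_zero:", levels(des$vial))
  vial_i <- as.integer(des$vial)
  n <- length(des$y)
  with_stage_seed(seed, "ppc-zeros", {
    take <- sample(nrow(ch), n_draws, replace = n_draws > nrow(ch))
    sims <- vapply(take, function(i) {
      bc <- ch[i, paste0("count_", colnames(des$X_count))]
      bz <- ch[i, paste0("zero_", colnames(des$X_zero))]
      mu_c <- drop(des$X_count %*% bc) + ch[i, idx_u_c][vial_i]
      mu_z <- drop(des$X_zero %*% bz) + ch[i, idx_u_z][vial_i]
      lc <- rnorm(n, mu_c, sqrt(ch[i, "sigma2_resid_count"]))
      lz <- rnorm(n, mu_z, sqrt(ch[i, "sigma2_resid_zero"]))
      is_zero <- runif(n) < plogis(lz)
      y_sim <- integer(n)
      y_sim[!is_zero] <- rztpois(sum(!is_zero), pmin(exp(lc[!is_zero]), 1e6))
      sum(y_sim == 0)
    }, numeric(1))
    band <- unname(quantile(sims, c(0.025, 0.975)))
    observed <- sum(des$y == 0)
    structure(list(observed = observed, simulated = sims, band = band,
                   inside = observed >= band[1] & observed <= band[2]),
              class = "flyvir_ppc")
  })
}

#' @export
print.flyvir_ppc <- function(x, ...) {
  cat(sprintf("<flyvir_ppc> observed zeros: %d; simulated 95%% band: [%.1f, %.1f] — %s\n",
              x$observed, x$band[1], x$band[2],
              if (x$inside) "consistent" else "OUTSIDE the band"))
  invisible(x)
}

#' Correlation between early and late offspring production
#'
#' Pearson correlation between the early-window count and the remainder
#' (`offspring_total - offspring_early`), with the Fisher-z confidence
#' interval and the t test on n - 2 degrees of freedom.
#'
#' @param x A `flyvir_experiment`.
#' @return One-row tibble: `r`, `conf_low`, `conf_high`, `t`, `df`,
#'   `p_value`, `n`.
#' @export
early_late_correlation <- function(x) {
  stopifnot(inherits(x, "flyvir_experiment"))
  dat <- dplyr::filter(x$recipients, !.data$excluded_early)
  if (nrow(dat) < 3) abort("need at least 3 flies with both windows observed")
  late <- dat$offspring_total - dat$offspring_early
  if (sd(dat$offspring_early) == 0 || sd(late) == 0) {
    abort("zero variance in an offspring margin")
  }
  ct <- cor.test(dat$offspring_early, late)
  tibble::tibble(r = unname(ct$estimate), conf_low = ct$conf.int[1],
                 conf_high = ct$conf.int[2], t = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 n = nrow(dat))
}
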