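#' Per-virus fixed-effects lifespan model
#'
#' Fits lifespan (days) with an intercept (the predicted uninfected
#' baseline), one indicator per virus for detection at death, and an
#' exposure-vial random intercept, by blocked Gibbs sampling. Viruses with
#' no infected fly are inestimable and dropped with a warning. Censored
#' flies (alive at the follow-up limit) are by default analysed at the limit,
#' as a Gaussian lifespan model must; `censored = "exclude"` drops them.
#'
#' @param x A `flyvir_experiment`.
#' @param cfg A [run_config()].
#' @param censored `"at_limit"` (default) or `"exclude"`.
#' @param baseline Denominator of percent-reduction summaries: the model
#'   intercept (default) or the observed uninfected mean.
#' @return A `flyvir_lifespan_a` fit: posterior summaries per parameter,
#'   percent-reduction summaries per virus, the chain, and the dropped
#'   viruses.
#' @seealso [fit_lifespan_B()], [percent_reduction()]
#' @export
fit_lifespan_A <- function(x, cfg = run_config(),
                           censored = c("at_limit", "exclude"),
                           baseline = c("intercept", "uninfected_mean")) {
  stopifnot(inherits(x, "flyvir_experiment"))
  censored <- match.arg(censored)
  baseline <- match.arg(baseline)
  dat <- lifespan_frame(x, censored)
  viruses <- x$virus_panel
  n_inf <- colSums(dat[, viruses, drop = FALSE])
  if (sum(n_inf) == 0) abort("fit_lifespan_A: no infected flies in the table")
  dropped <- viruses[n_inf == 0]
  kept <- viruses[n_inf > 0]
  if (length(dropped)) {
    warn(sprintf("dropping virus(es) with no infected fly: %s",
                 paste(dropped, collapse = ", ")))
  }
  if (dplyr::n_distinct(dat$vial_id) < 2) {
    warn("single exposure vial: vial variance is informed only by its prior")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(dat[, kept, drop = FALSE]))
  chain <- gibbs_lmm(X, dat$lifespan_days,
                     random = list(vial = factor(dat$vial_id)),
                     priors = cfg$priors, cfg = cfg, stage = "fit-lifespan-A")
  base_draws <- if (baseline == "intercept") {
    chain$draws[, "(Intercept)"]
  } else {
    rep(mean(dat$lifespan_days[rowSums(dat[, kept, drop = FALSE]) == 0]),
        nrow(chain$draws))
  }
  pct <- purrr::map(kept, function(v) {
    summarize_draws(100 * (-chain$draws[, v] / base_draws), v, cfg)
  }) |> purrr::list_rbind()
  structure(list(
    chain = chain,
    summary = summarize_chain(chain, cfg$hpd_mass, cfg$ess_floor),
    pct_reduction = pct,
    viruses = kept, dropped = dropped, baseline = baseline,
    n = nrow(dat), cfg = cfg
  ), class = c("flyvir_lifespan_a", "flyvir_fit"))
}

#' Infection-count lifespan model
#'
#' Fits lifespan on the number of viral infections as a continuous predictor
#' (zero = uninfected), with a per-virus random intercept applied only to
#' infected flies — a fly infected with k viruses receives the sum of its k
#' virus deviations, all sharing a single variance — plus the exposure-vial
#' random effect. This asks whether infections have an additive effect on
#' lifespan and whether virus identity adds variance beyond the common
#' per-infection slope.
#'
#' @inheritParams fit_lifespan_A
#' @return A `flyvir_lifespan_b` fit with summaries for the per-infection
#'   slope (`n_infections`, in days) and the virus-identity variance.
#' @export
fit_lifespan_B <- function(x, cfg = run_config(),
                           censored = c("at_limit", "exclude")) {
  stopifnot(inherits(x, "flyvir_experiment"))
  censored <- match.arg(censored)
  dat <- lifespan_frame(x, censored)
  viruses <- x$virus_panel
  Zv <- as.matrix(dat[, viruses, drop = FALSE])
  infected_any <- viruses[colSums(Zv) > 0]
  if (length(infected_any) == 0) {
    abort("fit_lifespan_B: no infected flies, the infected level is inestimable")
  }
  Zv <- Zv[, infected_any, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, n_infections = dat$n_infections)
  chain <- gibbs_lmm(X, dat$lifespan_days,
                     random = list(virus = Zv, vial = factor(dat$vial_id)),
                     priors = cfg$priors, cfg = cfg, stage = "fit-lifespan-B")
  structure(list(
    chain = chain,
    summary = summarize_chain(chain, cfg$hpd_mass, cfg$ess_floor),
    viruses = infected_any, n = nrow(dat), cfg = cfg
  ), class = c("flyvir_lifespan_b", "flyvir_fit"))
}

lifespan_frame <- function(x, censored) {
  inf <- infection_indicators(x)
  dat <- dplyr::left_join(x$recipients, inf, by = "fly_id")
  if (censored == "exclude") dat <- dplyr::filter(dat, !.data$censored)
  dat
}

summarize_draws <- function(d, label, cfg) {
  h <- hpd_interval(d, cfg$hpd_mass)
  tibble::tibble(parameter = label, mean = mean(d),
                 hpd_low = h[["lower"]], hpd_high = h[["upper"]],
                 ess = effective_sample_size(d), pmcmc = pmcmc(d))
}

#' Percent lifespan reduction attributable to a virus
#'
#' Transforms each posterior draw as `100 * (-beta_v / baseline)` so the
#' interval propagates uncertainty in both the effect and the baseline, then
#' summarizes (mean, HPD, ESS, pMCMC of the transformed draws).
#'
#' @param fit A `flyvir_lifespan_a`.
#' @param virus Virus name present in the fit.
#' @return One-row posterior-summary tibble.
#' @export
percent_reduction <- function(fit, virus) {
  stopifnot(inherits(fit, "flyvir_lifespan_a"))
  if (!virus %in% fit$viruses) {
    abort(sprintf("virus '%s' was not fitted (dropped or unknown)", virus))
  }
  fit$pct_reduction[fit$pct_reduction$parameter == virus, ]
}

#' @export
print.flyvir_fit <- function(x, ...) {
  cat(sprintf("<%s> n = %d\n", class(x)[1], x$n))
  print(x$summary, n = Inf)
  invisible(x)
}
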