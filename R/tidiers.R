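#' Tidy posterior summaries of a fitted model
#'
#' @param x A `flyvir_fit` (lifespan or fecundity fit).
#' @param ... Unused.
#' @return The posterior-summary tibble (`parameter`, `mean`, `hpd_low`,
#'   `hpd_high`, `ess`, `pmcmc`, `low_ess`).
#' @export
tidy.flyvir_fit <- function(x, ...) x$summary

#' @rdname tidy.flyvir_fit
#' @export
tidy.flyvir_chain <- function(x, ...) summarize_chain(x)

#' One-row fit overview
#'
#' @param x A `flyvir_fit`.
#' @param ... Unused.
#' @return Tibble with the sample size, parameter count, recorded draws,
#'   minimum ESS and number of low-ESS flags.
#' @export
glance.flyvir_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_parameters = nrow(x$summary),
    n_draws = nrow(x$chain$draws),
    min_ess = min(x$summary$ess),
    n_low_ess = sum(x$summary$low_ess)
  )
}

#' Forest plot of posterior effect summaries
#'
#' @param object A `flyvir_fit`.
#' @param variances Include variance components?
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.flyvir_fit <- function(object, variances = FALSE, ...) {
  s <- object$summary
  if (!variances) s <- dplyr::filter(s, !startsWith(.data$parameter, "sigma2_"))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$mean, y = .data$parameter)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hpd_low,
                                         xmax = .data$hpd_high),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "posterior mean (95% HPD)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a simulated power surface
#'
#' @param object A `flyvir_power_curve` from [power_curve()].
#' @param ... Unused.
#' @return A ggplot of power against group size, one line per effect size.
#' @export
autoplot.flyvir_power_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_infected, y = .data$power,
                               colour = factor(.data$pct_reduction),
                               group = .data$pct_reduction)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$power - .data$mc_se, 0),
                                          ymax = pmin(.data$power + .data$mc_se, 1))) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "flies per group", y = "power",
                  colour = "% lifespan\nreduction") +
    ggplot2::theme_minimal()
}

#' Plot a posterior-predictive zero check
#'
#' @param object A `flyvir_ppc`.
#' @param ... Unused.
#' @return A ggplot: simulated zero counts with the observed count marked.
#' @export
autoplot.flyvir_ppc <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(zeros = object$simulated),
                  ggplot2::aes(x = .data$zeros)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::geom_vline(xintercept = object$band, linetype = 2) +
    ggplot2::labs(x = "simulated number of zero-offspring females",
                  y = "posterior draws") +
    ggplot2::theme_minimal()
}
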