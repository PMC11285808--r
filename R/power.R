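#' Simulated power to detect a percent lifespan reduction
#'
#' For each replicate, lifespans of an infected and an uninfected group are
#' simulated from the per-virus fixed-effects generative model (Gaussian
#' lifespans, a shared vial deviation for co-housed flies, one virus at
#' effect `-pct_reduction/100 * mu` days) and a detection rule is applied.
#' The default rule is the Welch two-sample test at level `alpha`; the
#' `"model"` rule fits the full Bayesian mixed model and rejects when the
#' virus effect's pMCMC falls below `alpha` (much slower; for
#' spot-calibration).
#'
#' @param n_infected,n_uninfected Group sizes.
#' @param pct_reduction Percent lifespan reduction (0 <= pct < 100).
#' @param mu Uninfected mean lifespan (days).
#' @param sigma_vial SD of the shared vial deviation (days); flies are
#'   allocated to vials of `vial_size` spanning both groups.
#' @param sigma_e Residual lifespan SD (days).
#' @param alpha Test level.
#' @param reps Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @param rule `"welch"` or `"model"`.
#' @param vial_size Flies per simulated vial.
#' @param cfg Run configuration for the `"model"` rule.
#' @return One-row tibble: `n_infected`, `n_uninfected`, `pct_reduction`,
#'   `power`, `mc_se`, `reps`, `rule`.
#' @export
simulate_power <- function(n_infected, n_uninfected, pct_reduction, mu,
                           sigma_vial, sigma_e, alpha = 0.05, reps = 400,
                           seed = 1L, rule = c("welch", "model"),
                           vial_size = 20,
                           cfg = run_config(chain_total = 3000,
                                            chain_recorded = 500)) {
  rule <- match.arg(rule)
  stopifnot(n_infected >= 1, n_uninfected >= 1,
            pct_reduction >= 0, pct_reduction < 100, reps >= 100)
  effect <- pct_reduction / 100 * mu
  n <- n_infected + n_uninfected
  stage <- sprintf("power-%d-%d-%g-%s", n_infected, n_uninfected,
                   pct_reduction, rule)
  rejections <- with_stage_seed(seed, stage, {
    vapply(seq_len(reps), function(r) {
      vial <- sample(rep(seq_len(ceiling(n / vial_size)), length.out = n))
      u <- rnorm(max(vial), 0, sigma_vial)
      infected <- rep(c(TRUE, FALSE), c(n_infected, n_uninfected))
      y <- mu - effect * infected + u[vial] + rnorm(n, 0, sigma_e)
      if (rule == "welch") {
        t.test(y[infected], y[!infected])$p.value < alpha
      } else {
        X <- cbind(`(Intercept)` = 1, virus = as.numeric(infected))
        cfg$seed <- derive_seed(seed, paste0(stage, "-rep", r))
        ch <- gibbs_lmm(X, y, random = list(vial = factor(vial)),
                        priors = cfg$priors, cfg = cfg, stage = "power-fit")
        pmcmc(ch$draws[, "virus"]) < alpha
      }
    }, logical(1))
  })
  p <- mean(rejections)
  tibble::tibble(n_infected = n_infected, n_uninfected = n_uninfected,
                 pct_reduction = pct_reduction, power = p,
                 mc_se = sqrt(p * (1 - p) / reps), reps = reps, rule = rule)
}

#' Power over a grid of group sizes and effect sizes
#'
#' @param n_grid Integer vector of per-group sizes (both groups equal).
#' @param pct_grid Percent reductions.
#' @param ... Passed to [simulate_power()] (`mu`, `sigma_vial`, `sigma_e`,
#'   `reps`, `seed`, ...).
#' @return A `flyvir_power_curve` tibble (one row per grid cell).
#' @export
power_curve <- function(n_grid, pct_grid, ...) {
  out <- tidyr::expand_grid(n = n_grid, pct = pct_grid) |>
    purrr::pmap(function(n, pct) {
      simulate_power(n_infected = n, n_uninfected = n,
                     pct_reduction = pct, ...)
    }) |>
    purrr::list_rbind()
  class(out) <- c("flyvir_power_curve", class(out))
  out
}

#' Closed-form two-sample normal power
#'
#' Large-sample power of a two-sided level-`alpha` z test for a difference
#' `delta = pct/100 * mu` between two groups of size n with common SD
#' `sqrt(sigma_e^2 + sigma_vial^2)`. Used as the analytic mode of
#' [required_n()] and as an independent reference for the simulation.
#'
#' @param n Per-group size.
#' @param pct_reduction Percent reduction.
#' @param mu,sigma_vial,sigma_e,alpha As in [simulate_power()].
#' @return Power in `[0, 1]`.
#' @export
analytic_power <- function(n, pct_reduction, mu, sigma_vial, sigma_e,
                           alpha = 0.05) {
  delta <- pct_reduction / 100 * mu
  sigma <- sqrt(sigma_e^2 + sigma_vial^2)
  se <- sigma * sqrt(2 / n)
  z <- qnorm(1 - alpha / 2)
  pnorm(delta / se - z) + pnorm(-delta / se - z)
}

#' Smallest per-group size reaching a target power
#'
#' Bisection over n, monotone in expectation. The `"analytic"` mode inverts
#' the closed-form normal power; the `"simulation"` mode calls
#' [simulate_power()] at each probe (with `reps >= 1000` near the boundary
#' to smooth the Monte-Carlo noise).
#'
#' @param target_power Target in (0, 1).
#' @param pct_reduction Percent reduction; 0 is unreachable by definition.
#' @param mu,sigma_vial,sigma_e,alpha As in [simulate_power()].
#' @param reps,seed Simulation-mode settings.
#' @param mode `"analytic"` or `"simulation"`.
#' @param n_ceiling Largest group size considered.
#' @return The smallest integer n with power >= `target_power`.
#' @examples
#' required_n(0.8, pct_reduction = 1, mu = 34, sigma_vial = 0, sigma_e = 18)
#' @export
required_n <- function(target_power, pct_reduction, mu, sigma_vial, sigma_e,
                       alpha = 0.05, reps = 1000, seed = 1L,
                       mode = c("analytic", "simulation"),
                       n_ceiling = 1e6) {
  mode <- match.arg(mode)
  if (target_power <= 0 || target_power >= 1) {
    abort("required_n: target_power must be in (0, 1)")
  }
  if (pct_reduction <= 0) {
    abort("required_n: unreachable target, power never exceeds alpha at zero effect")
  }
  pow <- function(n) {
    if (mode == "analytic") {
      analytic_power(n, pct_reduction, mu, sigma_vial, sigma_e, alpha)
    } else {
      simulate_power(n, n, pct_reduction, mu, sigma_vial, sigma_e, alpha,
                     reps = reps, seed = seed)$power
    }
  }
  if (pow(n_ceiling) < target_power) {
    abort(sprintf("required_n: target unreachable below n = %g (power %.3f)",
                  n_ceiling, pow(n_ceiling)))
  }
  lo <- 2; hi <- n_ceiling
  if (pow(lo) >= target_power) return(as.integer(lo))
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pow(mid) >= target_power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
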