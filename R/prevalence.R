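#' Log-likelihood of an individual prevalence under pooled Bernoulli testing
#'
#' Donor flies are assayed in pools: a pool of size `n` tests positive iff at
#' least one member is infected, which happens with probability
#' `1 - (1 - p)^n` at individual prevalence `p`. The log-likelihood over
#' independent pools is `sum(log(1 - (1 - p)^n_i))` for positive pools plus
#' `sum(n_i * log(1 - p))` for negative pools; impossible configurations
#' return `-Inf`.
#'
#' @param p Individual prevalence in `[0, 1]`.
#' @param pools Data frame with columns `size` (pool sizes, >= 1) and
#'   `positive` (logical assay results).
#' @return The log-likelihood (scalar).
#' @examples
#' pooled_loglik(0.1, data.frame(size = 10, positive = TRUE))
#' log(1 - 0.9^10)
#' @export
pooled_loglik <- function(p, pools) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    abort("p must be a single number in [0, 1]")
  }
  stopifnot(all(pools$size >= 1))
  n_pos <- pools$size[pools$positive]
  n_neg <- pools$size[!pools$positive]
  ll_pos <- if (length(n_pos)) {
    if (p == 0) -Inf else sum(log1p(-(1 - p)^n_pos))
  } else 0
  ll_neg <- if (length(n_neg)) {
    if (p == 1) -Inf else sum(n_neg * log1p(-p))
  } else 0
  ll_pos + ll_neg
}

# drop (in log-likelihood units) defining the support interval; 2 gives
# ~95.4% asymptotic coverage by the chi-square(1) likelihood-ratio argument
support_drop_default <- 2

bisect_bound <- function(f, lo, hi, tol = 1e-10) {
  # f(lo) and f(hi) must bracket a sign change; endpoint order is free
  flo <- f(lo)
  for (i in 1:200) {
    if (abs(hi - lo) < tol) break
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Maximum-likelihood prevalence from pooled assays
#'
#' Maximises the pooled-Bernoulli likelihood over the individual prevalence
#' `p` (bounded golden-section search, tolerance 1e-8) and reports a support
#' interval: the set of `p` whose log-likelihood is within `drop` units of
#' the maximum, located by bisection on each side. All-negative pools give
#' the boundary estimate 0 (with lower bound 0); all-positive pools give 1
#' (with upper bound 1).
#'
#' @param pools Data frame with columns `size` and `positive`; one row per
#'   pool. Unit pools (`size = 1`) recover the ordinary binomial MLE `k/N`.
#' @param drop Log-likelihood drop defining the interval (default 2; use
#'   `drop = 4` for the reading "drop of 2 in 2 log L").
#' @return One-row tibble: `p_hat`, `lower`, `upper`, `n_pools`, `n_flies`.
#' @examples
#' pools <- data.frame(size = rep(10, 10), positive = c(TRUE, rep(FALSE, 9)))
#' estimate_prevalence(pools)
#' @export
estimate_prevalence <- function(pools, drop = support_drop_default) {
  pools <- tibble::as_tibble(pools)
  if (nrow(pools) == 0) abort("estimate_prevalence: no pools supplied")
  stopifnot(all(pools$size >= 1), is.logical(pools$positive))
  all_pos <- all(pools$positive)
  all_neg <- !any(pools$positive)
  p_hat <- if (all_neg) {
    0
  } else if (all_pos) {
    1
  } else {
    opt <- optimize(function(p) pooled_loglik(p, pools),
                    interval = c(0, 1), maximum = TRUE, tol = 1e-8)
    opt$maximum
  }
  ll_max <- pooled_loglik(p_hat, pools)
  f <- function(p) ll_max - pooled_loglik(p, pools) - drop
  lower <- if (all_neg || f(0) <= 0) 0 else bisect_bound(f, 0, p_hat)
  upper <- if (all_pos || f(1) <= 0) 1 else bisect_bound(f, 1, p_hat)
  tibble::tibble(p_hat = p_hat, lower = lower, upper = upper,
                 n_pools = nrow(pools), n_flies = sum(pools$size))
}

#' Per-virus, per-group wild prevalence from donor pool assays
#'
#' Applies [estimate_prevalence()] to each (species group, virus) cell of the
#' donor table, i.e. the "global" prevalence of each virus in each wild
#' donor group estimated across that group's pools.
#'
#' @param donors Donor table (`donors` component of a `flyvir_experiment`, or
#'   any data frame with `species_group`, `virus`, `pool_size`,
#'   `assay_positive`).
#' @param drop Log-likelihood drop for the support interval.
#' @return Tibble with one row per group x virus.
#' @export
prevalence_by_group <- function(donors, drop = support_drop_default) {
  donors <- tibble::as_tibble(donors)
  donors |>
    dplyr::rename(size = "pool_size", positive = "assay_positive") |>
    dplyr::group_by(.data$species_group, .data$virus) |>
    dplyr::group_modify(~ estimate_prevalence(.x, drop = drop)) |>
    dplyr::ungroup()
}

#' Transmission rate with support interval
#'
#' The transmission rate of a virus is the number of recipient flies that
#' tested positive as a proportion of the number exposed to a positive donor
#' pool. The support interval comes from the same pooled-Bernoulli machinery
#' with every "pool" of size one (the binomial special case).
#'
#' @param n_infected,n_exposed Counts with `0 <= n_infected <= n_exposed`.
#' @param drop Log-likelihood drop for the support interval.
#' @return One-row tibble: `n_infected`, `n_exposed`, `rate`, `lower`,
#'   `upper`.
#' @examples
#' estimate_transmission(213, 606)
#' @export
estimate_transmission <- function(n_infected, n_exposed,
                                  drop = support_drop_default) {
  if (n_exposed < 1) abort("estimate_transmission: n_exposed must be >= 1")
  if (n_infected < 0 || n_infected > n_exposed) {
    abort("estimate_transmission: need 0 <= n_infected <= n_exposed")
  }
  pools <- tibble::tibble(size = rep(1L, n_exposed),
                          positive = rep(c(TRUE, FALSE),
                                         c(n_infected, n_exposed - n_infected)))
  est <- estimate_prevalence(pools, drop = drop)
  tibble::tibble(n_infected = n_infected, n_exposed = n_exposed,
                 rate = est$p_hat, lower = est$lower, upper = est$upper)
}

#' Per-virus transmission rates for an experiment
#'
#' @param x A `flyvir_experiment`.
#' @param by_group Also split by donor species group?
#' @param drop Log-likelihood drop for the support interval.
#' @return Tibble with one row per virus (x group).
#' @export
transmission_by_virus <- function(x, by_group = FALSE,
                                  drop = support_drop_default) {
  stopifnot(inherits(x, "flyvir_experiment"))
  d <- x$detections |>
    dplyr::filter(.data$exposed) |>
    dplyr::left_join(x$recipients[, c("fly_id", "vial_id")], by = "fly_id") |>
    dplyr::left_join(dplyr::distinct(x$donors[, c("vial_id", "species_group")]),
                     by = "vial_id")
  keys <- if (by_group) c("virus", "species_group") else "virus"
  d |>
    dplyr::summarise(n_infected = sum(.data$detected),
                     n_exposed = dplyr::n(), .by = dplyr::all_of(keys)) |>
    dplyr::rowwise() |>
    dplyr::mutate(estimate_transmission(.data$n_infected, .data$n_exposed,
                                        drop = drop)[, c("rate", "lower", "upper")]) |>
    dplyr::ungroup()
}

#' Exact Fisher-Freeman-Halton test for an r x 2 table
#'
#' Enumerates every table with the observed margins and sums the
#' (multivariate hypergeometric) probabilities of tables no more probable
#' than the observed one — the probability-mass ordering used by mainstream
#' implementations of the exact test. Intended for small tables such as
#' viruses transmitted / not transmitted per donor species group.
#'
#' @param x Matrix of non-negative integer counts with 2 columns and at
#'   least 2 rows; all row and column margins must be positive.
#' @return The two-sided p-value.
#' @examples
#' # transmitted / not transmitted viruses per donor group
#' fisher_exact_rxc(rbind(c(3, 1), c(4, 3), c(4, 12)))
#' @export
fisher_exact_rxc <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2 || nrow(x) < 2) abort("need an r x 2 table with r >= 2")
  if (any(x < 0) || any(x != floor(x))) abort("counts must be non-negative integers")
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) abort("all margins must be positive")
  n <- sum(x)
  # log-probability of a table given by its first-column counts a
  log_denom <- lchoose(n, cs[1])
  logp <- function(a) sum(lchoose(rs, a)) - log_denom
  logp_obs <- logp(x[, 1])
  # enumerate all first columns with the fixed margins
  total <- 0
  recurse <- function(i, remaining, acc) {
    if (i == length(rs)) {
      if (remaining <= rs[i]) {
        lp <- logp(c(acc, remaining))
        if (lp <= logp_obs + 1e-12) total <<- total + exp(lp)
      }
      return(invisible())
    }
    for (a in 0:min(rs[i], remaining)) {
      recurse(i + 1, remaining - a, c(acc, a))
    }
  }
  recurse(1, cs[1], integer(0))
  min(total, 1)
}
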