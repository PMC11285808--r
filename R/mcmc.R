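#' Prior specification for the MCMC engine
#'
#' Fixed effects get independent zero-mean normal priors with a large
#' variance; every variance component gets an inverse-gamma prior in the
#' (V, nu) parameterization (shape `nu/2`, rate `nu * V / 2`), weakly
#' informative at the defaults.
#'
#' @param beta_var Prior variance of each fixed effect.
#' @param V,nu Variance-component prior parameters; both must be positive.
#' @return A `flyvir_priors` list.
#' @export
prior_spec <- function(beta_var = 1e10, V = 1, nu = 0.002) {
  stopifnot(beta_var > 0, V > 0, nu > 0)
  structure(list(beta_var = beta_var, V = V, nu = nu),
            class = "flyvir_priors")
}

#' Run configuration for model fitting
#'
#' Controls chain length, burn-in, the number of recorded draws, the
#' credible mass and significance level, priors, and the follow-up limit.
#' Thinning is `floor((chain_total - burn_in) / chain_recorded)`. The
#' defaults are a desk-scale profile; a full-scale analysis in the spirit of
#' the original would use `chain_total = 1e6`, `chain_recorded = 1e4`.
#'
#' @param seed Global integer seed; stages derive their own streams from it.
#' @param chain_total Total MCMC iterations.
#' @param burn_in Iterations discarded; default 10% of `chain_total`.
#' @param chain_recorded Number of recorded (thinned) draws.
#' @param alpha Significance level for flags and power rules.
#' @param hpd_mass Credible mass of reported HPD intervals.
#' @param priors A [prior_spec()].
#' @param followup_days Follow-up limit in days.
#' @param ess_floor Summaries flag parameters whose effective sample size
#'   falls below this floor.
#' @return A `flyvir_run_config` list.
#' @export
run_config <- function(seed = 1L, chain_total = 20000, burn_in = NULL,
                       chain_recorded = 2000, alpha = 0.05, hpd_mass = 0.95,
                       priors = prior_spec(), followup_days = 72,
                       ess_floor = 200) {
  burn_in <- burn_in %||% floor(chain_total / 10)
  if (chain_recorded > chain_total - burn_in) {
    abort("run_config: chain_recorded must be <= chain_total - burn_in")
  }
  if (hpd_mass <= 0 || hpd_mass >= 1) abort("run_config: hpd_mass must be in (0, 1)")
  structure(list(seed = as.integer(seed), chain_total = chain_total,
                 burn_in = burn_in, chain_recorded = chain_recorded,
                 alpha = alpha, hpd_mass = hpd_mass, priors = priors,
                 followup_days = followup_days, ess_floor = ess_floor),
            class = "flyvir_run_config")
}

#' Highest posterior density interval
#'
#' The shortest contiguous window of the sorted draws containing
#' `ceiling(mass * n)` draws; ties in width are broken toward the smallest
#' lower endpoint.
#'
#' @param draws Numeric vector of posterior draws (>= 2).
#' @param mass Credible mass in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(1:100, 0.95)
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (length(draws) < 2) abort("hpd_interval: need at least 2 draws")
  if (mass <= 0 || mass >= 1) abort("hpd_interval: mass must be in (0, 1)")
  s <- sort(draws)
  n <- length(s)
  m <- min(ceiling(mass * n), n)
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- which.min(widths) # first minimum = smallest lower endpoint
  c(lower = s[i], upper = s[i + m - 1])
}

#' Effective sample size of an MCMC chain
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at the
#' first non-positive `rho_k` (initial positive sequence estimator). A
#' zero-variance chain is defined to have ESS = n.
#'
#' @param draws Numeric vector of at least 10 draws.
#' @return Effective sample size (may slightly exceed n for anticorrelated
#'   chains).
#' @export
effective_sample_size <- function(draws) {
  n <- length(draws)
  if (n < 10) abort("effective_sample_size: need at least 10 draws")
  if (var(draws) == 0) return(as.numeric(n))
  rho <- as.numeric(acf(draws, lag.max = min(n - 1, 2000),
                        plot = FALSE, demean = TRUE)$acf)[-1]
  cut <- which(rho <= 0)
  if (length(cut)) rho <- rho[seq_len(cut[1] - 1)]
  n / (1 + 2 * sum(rho))
}

#' MCMC two-sided tail probability relative to zero
#'
#' `2 * min(P(draw > 0), P(draw < 0))`, floored at `2/n` (it can never be
#' exactly zero from a finite chain) and capped at 1.
#'
#' @param draws Numeric vector of at least 2 draws.
#' @return A probability in `(0, 1]`.
#' @export
pmcmc <- function(draws) {
  n <- length(draws)
  if (n < 2) abort("pmcmc: need at least 2 draws")
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  min(max(p, 2 / n), 1)
}

#' Summarize a chain into posterior summaries
#'
#' @param chain A `flyvir_chain`.
#' @param hpd_mass Credible mass.
#' @param ess_floor Parameters with ESS below this are flagged.
#' @return Tibble: `parameter`, `mean`, `hpd_low`, `hpd_high`, `ess`,
#'   `pmcmc`, `low_ess`.
#' @export
summarize_chain <- function(chain, hpd_mass = 0.95, ess_floor = 200) {
  stopifnot(inherits(chain, "flyvir_chain"))
  purrr::map(colnames(chain$draws), function(par) {
    d <- chain$draws[, par]
    h <- hpd_interval(d, hpd_mass)
    tibble::tibble(parameter = par, mean = mean(d),
                   hpd_low = h[["lower"]], hpd_high = h[["upper"]],
                   ess = effective_sample_size(d), pmcmc = pmcmc(d))
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(low_ess = .data$ess < ess_floor)
}

#' @export
print.flyvir_chain <- function(x, ...) {
  cat(sprintf("<flyvir_chain> %d recorded draws x %d parameters (burn-in %d, thin %d)\n",
              nrow(x$draws), ncol(x$draws), x$burn_in, x$thin))
  invisible(x)
}

new_chain <- function(draws, burn_in, thin, seed, acceptance = NULL) {
  if (any(!is.finite(draws))) {
    bad <- which(!is.finite(draws), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite draw for '%s' at recorded iteration %d",
                  colnames(draws)[bad[2]], bad[1]))
  }
  structure(list(draws = draws, burn_in = burn_in, thin = thin, seed = seed,
                 acceptance = acceptance),
            class = "flyvir_chain")
}

# ---- internal Gaussian-LMM machinery -------------------------------------

# normalize a random-effects spec: factors become index blocks (diagonal
# crossproduct), matrices stay dense
prep_random <- function(random, n) {
  purrr::imap(random, function(z, nm) {
    if (is.factor(z) || is.character(z)) {
      f <- droplevels(as.factor(z))
      stopifnot(length(f) == n)
      list(name = nm, type = "factor", idx = as.integer(f),
           levels = levels(f), q = nlevels(f),
           counts = tabulate(as.integer(f), nlevels(f)))
    } else {
      z <- as.matrix(z)
      stopifnot(nrow(z) == n)
      list(name = nm, type = "matrix", Z = z, ZtZ = crossprod(z),
           levels = colnames(z) %||% paste0("u", seq_len(ncol(z))),
           q = ncol(z))
    }
  })
}

block_contrib <- function(block, u) {
  if (block$type == "factor") u[block$idx] else drop(block$Z %*% u)
}

draw_mvn_post <- function(Q, b_vec) {
  # draw from N(Q^{-1} b_vec, Q^{-1})
  R <- chol(Q)
  mu <- backsolve(R, forwardsolve(t(R), b_vec))
  drop(mu + backsolve(R, rnorm(ncol(Q))))
}

draw_var <- function(ss, q, priors) {
  1 / rgamma(1, shape = (priors$nu + q) / 2,
             rate = (priors$nu * priors$V + ss) / 2)
}

# one conjugate sweep of beta, each random block + its variance, and the
# residual variance, for response y with current state `st`
lmm_sweep <- function(y, X, XtX, blocks, st, priors) {
  n <- length(y)
  p <- ncol(X)
  contribs <- purrr::map2(blocks, st$u, block_contrib)
  total_u <- if (length(blocks)) Reduce(`+`, contribs) else 0

  Q <- XtX / st$s2e + diag(1 / priors$beta_var, p)
  st$b <- draw_mvn_post(Q, crossprod(X, y - total_u) / st$s2e)
  fit_fixed <- drop(X %*% st$b)

  for (j in seq_along(blocks)) {
    blk <- blocks[[j]]
    others <- total_u - contribs[[j]]
    r <- y - fit_fixed - others
    if (blk$type == "factor") {
      prec <- blk$counts / st$s2e + 1 / st$s2u[j]
      m <- as.vector(rowsum(r, blk$idx)) / st$s2e / prec
      st$u[[j]] <- rnorm(blk$q, m, sqrt(1 / prec))
    } else {
      Qj <- blk$ZtZ / st$s2e + diag(1 / st$s2u[j], blk$q)
      st$u[[j]] <- draw_mvn_post(Qj, crossprod(blk$Z, r) / st$s2e)
    }
    st$s2u[j] <- draw_var(sum(st$u[[j]]^2), blk$q, priors)
    contribs[[j]] <- block_contrib(blk, st$u[[j]])
    total_u <- others + contribs[[j]]
  }
  e <- y - fit_fixed - total_u
  st$s2e <- draw_var(sum(e^2), n, priors)
  st$fit <- fit_fixed + total_u
  st
}

check_design <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    abort(sprintf("rank-deficient design: collinear column(s) %s",
                  paste(colnames(X)[-keep], collapse = ", ")))
  }
  invisible(X)
}

#' Blocked Gibbs sampler for a Gaussian linear mixed model
#'
#' Samples `y = X b + sum_j Z_j u_j + e` with `u_j ~ N(0, s2_j I)` and
#' `e ~ N(0, s2_e I)` by blocked Gibbs: the fixed effects and each
#' random-effect block from their conjugate multivariate-normal full
#' conditionals, and every variance component from its conjugate
#' inverse-gamma full conditional.
#'
#' @param X Fixed-effect design matrix with column names; must be full rank.
#' @param y Numeric response.
#' @param random Named list of random-effect structures: a factor (one
#'   deviation per level, e.g. exposure vial) or an n x q indicator matrix
#'   (rows may load on several levels, e.g. the per-virus deviations of a
#'   multiply infected fly). Each block has a single shared variance.
#' @param priors A [prior_spec()].
#' @param cfg A [run_config()]; chain geometry and seed.
#' @param stage Stage label used to derive this fit's seed.
#' @param fix_s2e Optionally fix the residual variance at a known value
#'   (used by calibration tests against closed-form conjugate posteriors).
#' @param record_random Record the random-effect draws as extra columns?
#' @return A `flyvir_chain` with one column per fixed effect, one
#'   `sigma2_<block>` column per block, and `sigma2_resid`.
#' @export
gibbs_lmm <- function(X, y, random = list(), priors = prior_spec(),
                      cfg = run_config(), stage = "gibbs-lmm",
                      fix_s2e = NULL, record_random = FALSE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n)
  check_design(X)
  if (n <= ncol(X)) warn("gibbs_lmm: fewer observations than parameters")
  blocks <- prep_random(random, n)
  XtX <- crossprod(X)

  thin <- floor((cfg$chain_total - cfg$burn_in) / cfg$chain_recorded)
  n_iter <- cfg$burn_in + thin * cfg$chain_recorded

  par_names <- c(colnames(X),
                 if (length(blocks)) paste0("sigma2_", names(blocks)),
                 "sigma2_resid")
  extra <- if (record_random && length(blocks)) {
    unlist(purrr::map(blocks, ~ paste0("u_", .x$name, ":", .x$levels)))
  } else character()

  with_stage_seed(cfg$seed, stage, {
    st <- list(b = rep(0, ncol(X)),
               u = purrr::map(blocks, ~ rep(0, .x$q)),
               s2u = rep(max(var(y), 1e-6), length(blocks)),
               s2e = fix_s2e %||% max(var(y), 1e-6))
    draws <- matrix(NA_real_, cfg$chain_recorded,
                    length(par_names) + length(extra),
                    dimnames = list(NULL, c(par_names, extra)))
    rec <- 0L
    for (it in seq_len(n_iter)) {
      st <- lmm_sweep(y, X, XtX, blocks, st, priors)
      if (!is.null(fix_s2e)) st$s2e <- fix_s2e
      if (!all(is.finite(st$b)) || !all(is.finite(st$s2u)) ||
          !is.finite(st$s2e)) {
        abort(sprintf("gibbs_lmm: non-finite state at iteration %d", it))
      }
      if (it > cfg$burn_in && (it - cfg$burn_in) %% thin == 0) {
        rec <- rec + 1L
        draws[rec, ] <- c(st$b, st$s2u, st$s2e,
                          if (length(extra)) unlist(st$u))
      }
    }
    new_chain(draws[seq_len(rec), , drop = FALSE], cfg$burn_in, thin,
              derive_seed(cfg$seed, stage))
  })
}

# ---- hurdle-Poisson machinery --------------------------------------------

log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

# log density of the zero-truncated Poisson at log-rate l
ztpois_loglik <- function(y, l) {
  lambda <- exp(l)
  y * l - lambda - log(-expm1(-lambda))
}

#' Metropolis-within-Gibbs sampler for a hurdle-Poisson mixed model
#'
#' Two latent linear predictors per observation: the logit of the
#' probability of a zero count (the hurdle) and the log rate of a
#' zero-truncated Poisson for positive counts. Each trait has its own fixed
#' effects, its own grouping-level random effect and its own latent residual
#' variance; the between-trait covariance is fixed at zero. Latent values
#' are updated by adaptive random-walk Metropolis (targeting 44% acceptance,
#' adaptation frozen after burn-in); everything Gaussian is updated by its
#' conjugate full conditional.
#'
#' @param counts Non-negative integer response.
#' @param X_count,X_zero Design matrices for the count (log) and zero
#'   (logit) parts.
#' @param grouping Optional factor (e.g. exposure vial) giving each trait a
#'   random intercept with its own variance.
#' @param priors A [prior_spec()].
#' @param cfg A [run_config()].
#' @param stage Stage label for seed derivation.
#' @return A `flyvir_chain` with columns `count_*`, `zero_*`, the variance
#'   components, and the per-level random effects (`u_count:*`, `u_zero:*`)
#'   needed for posterior-predictive simulation. Acceptance rates are kept
#'   in the `acceptance` element.
#' @export
hurdle_poisson_mcmc <- function(counts, X_count, X_zero, grouping = NULL,
                                priors = prior_spec(), cfg = run_config(),
                                stage = "hurdle") {
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers")
  }
  n <- length(counts)
  if (all(counts == 0)) {
    abort(paste("all counts are zero: the zero-truncated Poisson part is",
                "inestimable; remove the count-part terms"))
  }
  X_count <- as.matrix(X_count); X_zero <- as.matrix(X_zero)
  if (nrow(X_count) != n || nrow(X_zero) != n) {
    abort("design matrices must have one row per observation")
  }
  if (is.null(colnames(X_count))) colnames(X_count) <- paste0("c", seq_len(ncol(X_count)))
  if (is.null(colnames(X_zero))) colnames(X_zero) <- paste0("z", seq_len(ncol(X_zero)))
  check_design(X_count); check_design(X_zero)
  z <- as.numeric(counts == 0)
  pos <- counts > 0

  has_group <- !is.null(grouping)
  blocks_c <- if (has_group) prep_random(list(vial = grouping), n) else list()
  blocks_z <- blocks_c
  XtX_c <- crossprod(X_count); XtX_z <- crossprod(X_zero)

  thin <- floor((cfg$chain_total - cfg$burn_in) / cfg$chain_recorded)
  n_iter <- cfg$burn_in + thin * cfg$chain_recorded

  par_names <- c(paste0("count_", colnames(X_count)),
                 paste0("zero_", colnames(X_zero)),
                 if (has_group) c("sigma2_vial_count", "sigma2_vial_zero"),
                 "sigma2_resid_count", "sigma2_resid_zero")
  u_names <- if (has_group) {
    c(paste0("u_count:", blocks_c[[1]]$levels),
      paste0("u_zero:", blocks_z[[1]]$levels))
  } else character()

  with_stage_seed(cfg$seed, stage, {
    st_c <- list(b = rep(0, ncol(X_count)),
                 u = purrr::map(blocks_c, ~ rep(0, .x$q)),
                 s2u = rep(0.5, length(blocks_c)), s2e = 0.5)
    st_z <- list(b = rep(0, ncol(X_zero)),
                 u = purrr::map(blocks_z, ~ rep(0, .x$q)),
                 s2u = rep(0.5, length(blocks_z)), s2e = 0.5)
    lc <- ifelse(pos, log(counts + 0.5), log(mean(counts[pos]) + 0.5))
    lz <- rep(qlogis(min(max(mean(z), 0.02), 0.98)), n)
    sc_c <- 0.8; sc_z <- 1.5
    acc_hist <- c(count = 0, zero = 0)

    draws <- matrix(NA_real_, cfg$chain_recorded,
                    length(par_names) + length(u_names),
                    dimnames = list(NULL, c(par_names, u_names)))
    rec <- 0L
    for (it in seq_len(n_iter)) {
      mu_c <- drop(X_count %*% st_c$b) +
        (if (has_group) block_contrib(blocks_c[[1]], st_c$u[[1]]) else 0)
      mu_z <- drop(X_zero %*% st_z$b) +
        (if (has_group) block_contrib(blocks_z[[1]], st_z$u[[1]]) else 0)

      # count latents: MH where the ZTP likelihood applies, Gibbs elsewhere
      prop <- lc + sc_c * rnorm(n)
      prop <- pmin(prop, 30) # rate overflow guard
      log_acc <- ztpois_loglik(counts, prop) - ztpois_loglik(counts, lc) +
        ((prop - mu_c)^2 - (lc - mu_c)^2) / (-2 * st_c$s2e)
      take <- pos & (log(runif(n)) < log_acc)
      lc[take] <- prop[take]
      lc[!pos] <- rnorm(sum(!pos), mu_c[!pos], sqrt(st_c$s2e))
      acc_c <- if (any(pos)) mean(take[pos]) else 0.44

      # zero latents: MH everywhere (Bernoulli likelihood)
      propz <- lz + sc_z * rnorm(n)
      log_accz <- (z * propz - log1pexp(propz)) - (z * lz - log1pexp(lz)) +
        ((propz - mu_z)^2 - (lz - mu_z)^2) / (-2 * st_z$s2e)
      takez <- log(runif(n)) < log_accz
      lz[takez] <- propz[takez]
      acc_z <- mean(takez)

      if (it <= cfg$burn_in) {
        g <- min(0.1, 1 / sqrt(it))
        sc_c <- sc_c * exp(g * (acc_c - 0.44))
        sc_z <- sc_z * exp(g * (acc_z - 0.44))
      }
      acc_hist <- acc_hist + c(acc_c, acc_z)

      st_c <- lmm_sweep(lc, X_count, XtX_c, blocks_c, st_c, priors)
      st_z <- lmm_sweep(lz, X_zero, XtX_z, blocks_z, st_z, priors)

      if (!all(is.finite(c(st_c$b, st_z$b, st_c$s2e, st_z$s2e)))) {
        abort(sprintf("hurdle_poisson_mcmc: non-finite state at iteration %d", it))
      }
      if (it > cfg$burn_in && (it - cfg$burn_in) %% thin == 0) {
        rec <- rec + 1L
        draws[rec, ] <- c(st_c$b, st_z$b,
                          if (has_group) c(st_c$s2u, st_z$s2u),
                          st_c$s2e, st_z$s2e,
                          if (has_group) c(st_c$u[[1]], st_z$u[[1]]))
      }
    }
    new_chain(draws[seq_len(rec), , drop = FALSE], cfg$burn_in, thin,
              derive_seed(cfg$seed, stage),
              acceptance = acc_hist / n_iter)
  })
}
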