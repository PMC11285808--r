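#' Configuration for the synthetic experiment generator
#'
#' Describes a natural virus-exposure experiment: wild donor flies are
#' co-housed with laboratory recipient females in vials for a transmission
#' window, each vial's donors are assayed as a pool, and each recipient is
#' followed until death, with per-virus detection at death, daily lifespan
#' and offspring counts.
#'
#' @param viruses Character vector of transmissible virus names.
#' @param n_vials Named integer vector of vials per donor species group
#'   (`Dmel`, `Dimm`, `DobsGroup`, `LabControl`).
#' @param recipients_per_vial Recipient females co-housed per vial.
#' @param pool_size_range Integer range of wild flies per donor pool.
#' @param carriage Named list (one element per species group) of named
#'   per-fly carriage probabilities: the probability a single wild donor of
#'   that group carries each virus.
#' @param transmission Named vector of per-virus transmission probabilities
#'   given exposure (the probability an exposed recipient becomes infected).
#' @param mu0 Baseline (uninfected) mean lifespan in days.
#' @param sigma_vial SD of the shared vial deviation in lifespan (days).
#' @param sigma_e Residual lifespan SD (days).
#' @param beta Named vector of per-virus lifespan effects in days
#'   (negative = harmful); viruses absent from the vector get 0.
#' @param fec List of fecundity parameters: `b0` baseline log rate of the
#'   zero-truncated Poisson count part, `b` named per-virus log-rate effects,
#'   `g0` baseline logit of the probability of zero offspring, `g` named
#'   per-virus logit effects, `sigma_resid_count`/`sigma_resid_zero` latent
#'   residual SDs, `sigma_vial_count`/`sigma_vial_zero` vial-effect SDs.
#' @param early_fraction Expected share of lifetime offspring laid in the
#'   early window (early counts are binomially thinned from totals).
#' @param sensitivity Probability a true infection tests positive at death.
#' @param followup_days Follow-up limit; flies alive at the limit are
#'   recorded at the limit with `censored = TRUE`.
#' @return A `flyvir_generator_config` list.
#' @seealso [paper_like_config()], [generate_experiment()]
#' @export
generator_config <- function(
    viruses,
    n_vials = c(Dmel = 11, Dimm = 11, DobsGroup = 14, LabControl = 7),
    recipients_per_vial = 20,
    pool_size_range = c(8L, 20L),
    carriage = list(),
    transmission = setNames(rep(0.1, length(viruses)), viruses),
    mu0 = 38, sigma_vial = 3, sigma_e = 18,
    beta = setNames(rep(0, length(viruses)), viruses),
    fec = list(b0 = log(100), b = setNames(rep(0, length(viruses)), viruses),
               g0 = qlogis(0.1), g = setNames(rep(0, length(viruses)), viruses),
               sigma_resid_count = 0.5, sigma_resid_zero = 0.5,
               sigma_vial_count = 0.1, sigma_vial_zero = 0.1),
    early_fraction = 0.4,
    sensitivity = 1.0,
    followup_days = 72) {
  fill <- function(v) {
    out <- setNames(rep(0, length(viruses)), viruses)
    out[names(v)[names(v) %in% viruses]] <- v[names(v) %in% viruses]
    out
  }
  transmission <- fill(transmission)
  beta <- fill(beta)
  fec$b <- fill(fec$b %||% numeric())
  fec$g <- fill(fec$g %||% numeric())
  carriage <- lapply(setNames(names(n_vials), names(n_vials)), function(g) {
    fill(carriage[[g]] %||% numeric())
  })
  cfg <- structure(list(
    viruses = viruses, n_vials = n_vials,
    recipients_per_vial = recipients_per_vial,
    pool_size_range = as.integer(pool_size_range),
    carriage = carriage, transmission = transmission,
    mu0 = mu0, sigma_vial = sigma_vial, sigma_e = sigma_e, beta = beta,
    fec = fec, early_fraction = early_fraction, sensitivity = sensitivity,
    followup_days = followup_days
  ), class = "flyvir_generator_config")
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  probs <- c(unlist(cfg$carriage), cfg$transmission, cfg$sensitivity,
             cfg$early_fraction, plogis(cfg$fec$g0))
  if (any(probs < 0 | probs > 1)) abort("generator config: probability outside [0, 1]")
  sds <- c(cfg$sigma_vial, cfg$sigma_e, cfg$fec$sigma_resid_count,
           cfg$fec$sigma_resid_zero, cfg$fec$sigma_vial_count,
           cfg$fec$sigma_vial_zero)
  if (any(sds < 0)) abort("generator config: negative standard deviation")
  if (cfg$recipients_per_vial < 1) abort("generator config: recipients_per_vial must be >= 1")
  if (any(!nzchar(cfg$viruses)) || anyDuplicated(cfg$viruses)) {
    abort("generator config: virus names must be non-empty and unique")
  }
  if (diff(cfg$pool_size_range) < 0 || cfg$pool_size_range[1] < 1) {
    abort("generator config: invalid pool size range")
  }
  invisible(cfg)
}

#' Study-calibrated generator configuration
#'
#' A frozen configuration emulating the scale and reported outcomes of the
#' natural-exposure experiment: 43 exposure vials (three wild donor groups
#' plus laboratory controls) of 20 recipient females each; nine
#' transmissible viruses; lifespan effects of -23, -17, -30, -11 and -37
#' percent of the uninfected baseline for galbut virus, DmelNV, DimmNV,
#' Muthill virus and Prestney Burn virus; count-part offspring effects of
#' -46, -39 and -24 percent for DmelNV, DimmNV and Muthill virus; and a
#' positive zero-offspring (sterility) effect for Muthill virus. Carriage
#' and transmission probabilities are calibrated so that, in expectation,
#' about 606 recipients are exposed to at least one virus and about 35
#' percent of them are infected at death, mostly singly.
#'
#' @return A `flyvir_generator_config`.
#' @seealso [expected_infection_summary()] for the closed-form expectations
#'   implied by a configuration.
#' @export
paper_like_config <- function() {
  viruses <- c("galbut", "DmelNV", "DimmNV", "Muthill", "PrestneyBurn",
               "DimmSV", "Grom", "Larkfield", "Corseley")
  mu0 <- 38
  pct_lifespan <- c(galbut = 23, DmelNV = 17, DimmNV = 30, Muthill = 11,
                    PrestneyBurn = 37)
  pct_offspring <- c(DmelNV = 46, DimmNV = 39, Muthill = 24)
  generator_config(
    viruses = viruses,
    carriage = list(
      Dmel = c(galbut = 1.0, DmelNV = 0.30, DimmNV = 0.09, Muthill = 0.10),
      Dimm = c(DimmNV = 0.40, DimmSV = 0.30, Muthill = 0.20,
               PrestneyBurn = 0.30),
      DobsGroup = c(Grom = 0.0175, Larkfield = 0.0125, Corseley = 0.0075,
                    Muthill = 0.005, DimmNV = 0.005),
      LabControl = c(DimmNV = 0.008, Muthill = 0.004)
    ),
    transmission = c(galbut = 0.08, DmelNV = 0.10, DimmNV = 0.18,
                     Muthill = 0.17, PrestneyBurn = 0.16, DimmSV = 0.06,
                     Grom = 0.22, Larkfield = 0.16, Corseley = 0.08),
    mu0 = mu0, sigma_vial = 3, sigma_e = 18,
    beta = -pct_lifespan / 100 * mu0,
    fec = list(
      b0 = log(102) - 0.5^2 / 2,
      b = log(1 - pct_offspring / 100),
      g0 = qlogis(0.10),
      g = c(Muthill = 1.0),
      sigma_resid_count = 0.5, sigma_resid_zero = 0.5,
      sigma_vial_count = 0.1, sigma_vial_zero = 0.1
    )
  )
}

#' Closed-form infection expectations under a generator configuration
#'
#' For each species group the probability that a donor pool assays positive
#' for virus v is `1 - (1 - carriage)^pool_size`, averaged over the uniform
#' pool-size range. Exposure events are independent across viruses, and
#' infection given exposure is Bernoulli with the per-virus transmission
#' probability, so the per-fly number of infections is Poisson-binomial.
#' Used to calibrate configurations against reported infection counts.
#'
#' @param cfg A `flyvir_generator_config`.
#' @return A list with `n_recipients`, expected number `exposed` (to at least
#'   one virus), expected `infected` (at least one infection), expected
#'   counts with exactly 1, 2 and 3+ infections (`singles`, `doubles`,
#'   `triples_plus`), and the per-group detail table.
#' @export
expected_infection_summary <- function(cfg) {
  sizes <- seq(cfg$pool_size_range[1], cfg$pool_size_range[2])
  pool_pos <- function(c) mean(1 - (1 - c)^sizes)
  pb <- function(q, kmax = 3) {
    # Poisson-binomial pmf by polynomial convolution
    pmf <- 1
    for (qi in q) pmf <- c(pmf * (1 - qi), 0) + c(0, pmf * qi)
    k <- seq_along(pmf) - 1
    c(pmf[k < kmax], sum(pmf[k >= kmax]))
  }
  rows <- purrr::map(names(cfg$n_vials), function(g) {
    n_flies <- cfg$n_vials[[g]] * cfg$recipients_per_vial
    e <- vapply(cfg$carriage[[g]], pool_pos, numeric(1))
    q <- e * cfg$transmission
    p_exposed <- 1 - prod(1 - e)
    pk <- pb(q)
    tibble::tibble(
      group = g, n_flies = n_flies, p_exposed = p_exposed,
      exposed = n_flies * p_exposed,
      singles = n_flies * pk[2], doubles = n_flies * pk[3],
      triples_plus = n_flies * pk[4],
      infected = n_flies * (1 - pk[1])
    )
  }) |> purrr::list_rbind()
  list(
    n_recipients = sum(rows$n_flies),
    exposed = sum(rows$exposed),
    infected = sum(rows$infected),
    singles = sum(rows$singles),
    doubles = sum(rows$doubles),
    triples_plus = sum(rows$triples_plus),
    by_group = rows
  )
}

#' Write / read a generator configuration as YAML
#'
#' Named probability and effect vectors are stored as YAML maps at full
#' precision, so a configuration round-trips exactly through its file form.
#'
#' @param cfg A `flyvir_generator_config`.
#' @param path YAML file path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns the configuration.
#' @export
write_generator_config <- function(cfg, path) {
  validate_generator_config(cfg)
  as_map <- function(v) as.list(v)
  out <- list(
    viruses = cfg$viruses,
    n_vials = as_map(cfg$n_vials),
    recipients_per_vial = cfg$recipients_per_vial,
    pool_size_range = cfg$pool_size_range,
    carriage = lapply(cfg$carriage, as_map),
    transmission = as_map(cfg$transmission),
    mu0 = cfg$mu0, sigma_vial = cfg$sigma_vial, sigma_e = cfg$sigma_e,
    beta = as_map(cfg$beta),
    fec = list(b0 = cfg$fec$b0, b = as_map(cfg$fec$b), g0 = cfg$fec$g0,
               g = as_map(cfg$fec$g),
               sigma_resid_count = cfg$fec$sigma_resid_count,
               sigma_resid_zero = cfg$fec$sigma_resid_zero,
               sigma_vial_count = cfg$fec$sigma_vial_count,
               sigma_vial_zero = cfg$fec$sigma_vial_zero),
    early_fraction = cfg$early_fraction, sensitivity = cfg$sensitivity,
    followup_days = cfg$followup_days
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  vec <- function(x) unlist(x)
  generator_config(
    viruses = unlist(raw$viruses),
    n_vials = vec(raw$n_vials),
    recipients_per_vial = raw$recipients_per_vial,
    pool_size_range = unlist(raw$pool_size_range),
    carriage = lapply(raw$carriage, vec),
    transmission = vec(raw$transmission),
    mu0 = raw$mu0, sigma_vial = raw$sigma_vial, sigma_e = raw$sigma_e,
    beta = vec(raw$beta),
    fec = list(b0 = raw$fec$b0, b = vec(raw$fec$b), g0 = raw$fec$g0,
               g = vec(raw$fec$g),
               sigma_resid_count = raw$fec$sigma_resid_count,
               sigma_resid_zero = raw$fec$sigma_resid_zero,
               sigma_vial_count = raw$fec$sigma_vial_count,
               sigma_vial_zero = raw$fec$sigma_vial_zero),
    early_fraction = raw$early_fraction, sensitivity = raw$sensitivity,
    followup_days = raw$followup_days
  )
}

#' Zero-truncated Poisson sampler
#'
#' Draws from a Poisson distribution conditioned on being positive (mean
#' `lambda / (1 - exp(-lambda))`), by inverting the Poisson CDF restricted
#' to its positive support. Used by the offspring generator and the
#' posterior-predictive checks.
#'
#' @param n Number of draws.
#' @param lambda Positive rate parameter (scalar or length-n vector).
#' @return Integer-valued vector of positive counts.
#' @examples
#' mean(rztpois(1000, 2)) # about 2.313
#' @export
rztpois <- function(n, lambda) {
  stopifnot(all(lambda > 0))
  p0 <- dpois(0, lambda)
  u <- runif(n, p0, 1)
  # guard against u == 1 from rounding at tiny lambda
  pmax(1L, qpois(pmin(u, 1 - 1e-16), lambda))
}

#' Generate a synthetic exposure experiment
#'
#' Simulates the full experiment under the configured generative model:
#' donor pools drawn per carriage probabilities (a pool assays positive iff
#' at least one member carries the virus); each recipient exposed to its
#' pool's positive viruses; per-virus Bernoulli transmission; Gaussian
#' lifespans with vial random effects, observed as whole days and censored
#' at the follow-up limit; hurdle-Poisson offspring (a logit-scale zero
#' process and a zero-truncated Poisson count process, each with its own
#' vial effect and latent residual); and detection at death degraded by the
#' configured sensitivity. Deterministic given `(cfg, seed)`.
#'
#' @param cfg A `flyvir_generator_config`.
#' @param seed Integer seed.
#' @return A validated `flyvir_experiment`.
#' @examples
#' x <- generate_experiment(paper_like_config(), seed = 1)
#' x
#' @export
generate_experiment <- function(cfg, seed) {
  validate_generator_config(cfg)
  with_stage_seed(seed, "generate", generate_experiment_impl(cfg, seed))
}

generate_experiment_impl <- function(cfg, seed) {
  groups <- names(cfg$n_vials)
  vials <- purrr::map(groups, function(g) {
    tibble::tibble(
      species_group = g,
      vial_id = sprintf("%s_v%02d", g, seq_len(cfg$n_vials[[g]])),
      pool_size = sample(seq(cfg$pool_size_range[1], cfg$pool_size_range[2]),
                         cfg$n_vials[[g]], replace = TRUE)
    )
  }) |> purrr::list_rbind()

  donors <- vials |>
    tidyr::expand_grid(virus = cfg$viruses) |>
    dplyr::mutate(
      carriage = purrr::map2_dbl(.data$species_group, .data$virus,
                                 ~ cfg$carriage[[.x]][[.y]]),
      carriers = rbinom(dplyr::n(), .data$pool_size, .data$carriage),
      assay_positive = .data$carriers > 0
    ) |>
    dplyr::select("vial_id", "species_group", "pool_size", "virus",
                  "assay_positive")

  recipients <- vials |>
    dplyr::reframe(fly_n = seq_len(cfg$recipients_per_vial),
                   .by = "vial_id") |>
    dplyr::mutate(fly_id = sprintf("%s_f%02d", .data$vial_id, .data$fly_n))

  # exposure = the vial's positive assays; infection ~ Bernoulli(pi_v)
  detections <- recipients |>
    dplyr::select("fly_id", "vial_id") |>
    dplyr::inner_join(
      donors |> dplyr::filter(.data$assay_positive) |>
        dplyr::select("vial_id", "virus"),
      by = "vial_id", relationship = "many-to-many"
    ) |>
    dplyr::mutate(
      exposed = TRUE,
      infected = runif(dplyr::n()) < unname(cfg$transmission[.data$virus]),
      detected = .data$infected & (runif(dplyr::n()) < cfg$sensitivity)
    )

  inf_by_fly <- detections |>
    dplyr::summarise(
      beta_sum = sum(cfg$beta[.data$virus][.data$infected]),
      b_sum = sum(cfg$fec$b[.data$virus][.data$infected]),
      g_sum = sum(cfg$fec$g[.data$virus][.data$infected]),
      .by = "fly_id"
    )

  n_vial <- nrow(vials)
  u_life <- setNames(rnorm(n_vial, 0, cfg$sigma_vial), vials$vial_id)
  u_count <- setNames(rnorm(n_vial, 0, cfg$fec$sigma_vial_count), vials$vial_id)
  u_zero <- setNames(rnorm(n_vial, 0, cfg$fec$sigma_vial_zero), vials$vial_id)

  r <- recipients |>
    dplyr::left_join(inf_by_fly, by = "fly_id") |>
    dplyr::mutate(dplyr::across(c("beta_sum", "b_sum", "g_sum"),
                                ~ tidyr::replace_na(.x, 0)))
  n <- nrow(r)
  life <- cfg$mu0 + r$beta_sum + unname(u_life[r$vial_id]) +
    rnorm(n, 0, cfg$sigma_e)
  censored <- life > cfg$followup_days
  lifespan_days <- ifelse(censored, cfg$followup_days,
                          pmin(ceiling(pmax(life, 1)), cfg$followup_days))

  l_zero <- cfg$fec$g0 + r$g_sum + unname(u_zero[r$vial_id]) +
    rnorm(n, 0, cfg$fec$sigma_resid_zero)
  l_count <- cfg$fec$b0 + r$b_sum + unname(u_count[r$vial_id]) +
    rnorm(n, 0, cfg$fec$sigma_resid_count)
  is_zero <- runif(n) < plogis(l_zero)
  offspring_total <- integer(n)
  offspring_total[!is_zero] <- rztpois(sum(!is_zero), exp(l_count[!is_zero]))
  offspring_early <- rbinom(n, offspring_total, cfg$early_fraction)

  recipients_out <- tibble::tibble(
    fly_id = r$fly_id, vial_id = r$vial_id,
    lifespan_days = as.numeric(lifespan_days), censored = censored,
    offspring_early = as.integer(offspring_early),
    offspring_total = as.integer(offspring_total),
    excluded_early = lifespan_days < 13
  )

  meta <- list(seed = seed, generator_hash = rlang::hash(unclass(cfg)),
               followup_days = cfg$followup_days,
               created = format(Sys.time(), tz = "UTC"))
  experiment_table(
    recipients_out,
    detections |> dplyr::select("fly_id", "virus", "exposed", "detected"),
    donors, virus_panel = cfg$viruses, meta = meta
  )
}

#' Recipients exposed to at least one virus
#'
#' @param x A `flyvir_experiment`.
#' @return Tibble of recipients whose exposure panel is non-empty.
#' @export
exposed_recipients <- function(x) {
  stopifnot(inherits(x, "flyvir_experiment"))
  ids <- x$detections |> dplyr::filter(.data$exposed) |> dplyr::pull("fly_id")
  dplyr::filter(x$recipients, .data$fly_id %in% ids)
}
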