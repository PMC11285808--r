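# shared fixtures, all built in code

# a three-fly experiment small enough to reason about by hand
tiny_experiment <- function() {
  recipients <- tibble::tibble(
    fly_id = c("f1", "f2", "f3"),
    vial_id = c("v1", "v1", "v2"),
    lifespan_days = c(30, 45, 60),
    censored = FALSE,
    offspring_early = c(10L, 0L, 20L),
    offspring_total = c(30L, 0L, 55L),
    excluded_early = FALSE
  )
  detections <- tibble::tibble(
    fly_id = c("f1", "f1", "f2", "f3"),
    virus = c("galbut", "DmelNV", "galbut", "DmelNV"),
    exposed = TRUE,
    detected = c(TRUE, FALSE, FALSE, TRUE)
  )
  donors <- tibble::tibble(
    vial_id = rep(c("v1", "v2"), each = 2),
    species_group = rep(c("Dmel", "Dimm"), each = 2),
    pool_size = 10L,
    virus = rep(c("galbut", "DmelNV"), 2),
    assay_positive = c(TRUE, TRUE, FALSE, TRUE)
  )
  experiment_table(recipients, detections, donors,
                   virus_panel = c("galbut", "DmelNV"))
}

# a small but model-fittable synthetic experiment; override any argument
small_config <- function(...) {
  args <- list(
    viruses = c("vA", "vB"),
    n_vials = c(Dmel = 6, Dimm = 6, DobsGroup = 0, LabControl = 2),
    recipients_per_vial = 15,
    carriage = list(Dmel = c(vA = 0.5, vB = 0.2),
                    Dimm = c(vA = 0.2, vB = 0.5)),
    transmission = c(vA = 0.4, vB = 0.3),
    mu0 = 40, sigma_vial = 2, sigma_e = 10,
    beta = c(vA = -8, vB = -3),
    fec = list(b0 = log(40), b = c(vA = -0.5, vB = 0),
               g0 = qlogis(0.15), g = c(vA = 0.8),
               sigma_resid_count = 0.4, sigma_resid_zero = 0.4,
               sigma_vial_count = 0.1, sigma_vial_zero = 0.1)
  )
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(generator_config, args)
}

quick_cfg <- function(seed = 1, total = 1500, burn = 300, rec = 400, ...) {
  run_config(seed = seed, chain_total = total, burn_in = burn,
             chain_recorded = rec, ...)
}

expect_identical_experiment <- function(a, b) {
  expect_equal(a$recipients, b$recipients)
  expect_equal(a$detections, b$detections)
  expect_equal(a$donors, b$donors)
  expect_identical(sort(a$virus_panel), sort(b$virus_panel))
}
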