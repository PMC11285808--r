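#' Serialize a chain to CSV with a JSON sidecar
#'
#' @param chain A `flyvir_chain`.
#' @param path Output CSV path; the sidecar takes the same path with a
#'   `.json` extension.
#' @return The paths written, invisibly.
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "flyvir_chain"))
  readr::write_csv(tibble::as_tibble(chain$draws), path)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(seed = chain$seed, burn_in = chain$burn_in, thin = chain$thin,
         acceptance = as.list(chain$acceptance)),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(path, sidecar))
}

#' Default pipeline configuration
#'
#' @param seed Global seed.
#' @param profile `"smoke"` (short chains, minutes end-to-end) or `"full"`
#'   (study-scale chains: one million iterations, ten thousand recorded).
#' @param input Optional named list of paths (`recipients`, `detections`,
#'   `donors`) to analyse user data instead of simulating.
#' @param power Optional list with `n_grid`, `pct_grid`, `reps` to add a
#'   simulated power grid to the run.
#' @return A nested list understood by [run_pipeline()]; the same structure
#'   can be written as a YAML file and passed by path.
#' @export
pipeline_config <- function(seed = 1L, profile = c("smoke", "full"),
                            input = NULL, power = NULL) {
  profile <- match.arg(profile)
  chains <- if (profile == "smoke") {
    list(total = 4000, recorded = 720)
  } else {
    list(total = 1e6, recorded = 1e4)
  }
  list(seed = seed, profile = profile, chains = chains, input = input,
       power = power)
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) an experiment, estimate wild prevalence and
#' transmission, fit both lifespan models and the lifetime and early-window
#' fecundity models, run the posterior-predictive zero check, optionally a
#' power grid, and write one summary report. Stages communicate through CSV
#' files plus JSON sidecars under `out_dir`; any stage error aborts naming
#' the stage, with earlier outputs retained. Deterministic given the seed.
#'
#' @param config A list from [pipeline_config()], or the path of a YAML file
#'   with the same structure.
#' @param out_dir Output directory.
#' @return A `flyvir_run_report`: output paths, config snapshot, collected
#'   warnings, and the per-virus effect summary table.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  config <- modifyList(pipeline_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  warnings <- character()
  note <- function(stage) function(w) {
    warnings <<- c(warnings, sprintf("[%s] %s", stage, conditionMessage(w)))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, expr) {
    message(sprintf("[flyvir] stage: %s", name))
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      }),
      warning = note(name)
    )
  }
  cfg <- run_config(seed = config$seed,
                    chain_total = config$chains$total,
                    chain_recorded = config$chains$recorded)

  x <- if (is.null(config$input)) {
    stage("simulate", {
      xx <- generate_experiment(paper_like_config(), seed = config$seed)
      paths$experiment <- write_experiment(xx, file.path(out_dir, "experiment"))
      xx
    })
  } else {
    stage("load", read_experiment(config$input$recipients,
                                  config$input$detections,
                                  config$input$donors))
  }

  prev <- stage("prevalence", {
    p <- prevalence_by_group(x$donors)
    paths$prevalence <- file.path(out_dir, "prevalence.csv")
    readr::write_csv(p, paths$prevalence)
    p
  })

  trans <- stage("transmission", {
    tr <- transmission_by_virus(x)
    paths$transmission <- file.path(out_dir, "transmission.csv")
    readr::write_csv(tr, paths$transmission)
    tr
  })

  fit_a <- stage("fit-lifespan-A", {
    f <- fit_lifespan_A(x, cfg)
    paths$lifespan_A <- file.path(out_dir, "lifespan_A_summary.csv")
    readr::write_csv(dplyr::bind_rows(
      f$summary,
      dplyr::mutate(f$pct_reduction,
                    parameter = paste0("pct_reduction:", .data$parameter),
                    low_ess = NA)), paths$lifespan_A)
    write_chain(f$chain, file.path(out_dir, "lifespan_A_chain.csv"))
    f
  })

  fit_b <- stage("fit-lifespan-B", {
    f <- fit_lifespan_B(x, cfg)
    paths$lifespan_B <- file.path(out_dir, "lifespan_B_summary.csv")
    readr::write_csv(f$summary, paths$lifespan_B)
    write_chain(f$chain, file.path(out_dir, "lifespan_B_chain.csv"))
    f
  })

  fit_fec <- stage("fit-fecundity-lifetime", {
    f <- fit_fecundity(x, cfg, window = "lifetime")
    paths$fecundity <- file.path(out_dir, "fecundity_lifetime_summary.csv")
    readr::write_csv(dplyr::bind_rows(
      f$summary,
      dplyr::mutate(f$pct_reduction,
                    parameter = paste0("pct_reduction:", .data$parameter),
                    low_ess = NA),
      dplyr::mutate(f$p_zero, parameter = paste0("p_zero:", .data$parameter),
                    low_ess = NA)), paths$fecundity)
    write_chain(f$chain, file.path(out_dir, "fecundity_lifetime_chain.csv"))
    f
  })

  fit_early <- stage("fit-fecundity-early", {
    f <- fit_fecundity(x, cfg, window = "early")
    paths$fecundity_early <- file.path(out_dir, "fecundity_early_summary.csv")
    readr::write_csv(f$summary, paths$fecundity_early)
    f
  })

  ppc <- stage("ppc-zeros", {
    p <- posterior_predictive_zeros(fit_fec, n_draws = 200, seed = config$seed)
    paths$ppc <- file.path(out_dir, "ppc_zeros.csv")
    readr::write_csv(tibble::tibble(observed = p$observed,
                                    band_low = p$band[1],
                                    band_high = p$band[2],
                                    inside = p$inside), paths$ppc)
    p
  })

  if (!is.null(config$power)) {
    stage("power", {
      pc <- power_curve(config$power$n_grid, config$power$pct_grid,
                        mu = 34, sigma_vial = 3, sigma_e = 18,
                        reps = config$power$reps %||% 400,
                        seed = config$seed)
      paths$power <- file.path(out_dir, "power.csv")
      readr::write_csv(pc, paths$power)
    })
  }

  report <- stage("report", {
    rate <- dplyr::select(trans, "virus", transmission_rate = "rate")
    life <- dplyr::select(fit_a$pct_reduction, virus = "parameter",
                          lifespan_pct_reduction = "mean",
                          lifespan_pmcmc = "pmcmc")
    fec <- dplyr::select(fit_fec$pct_reduction, virus = "parameter",
                         offspring_pct_reduction = "mean",
                         offspring_pmcmc = "pmcmc")
    pz <- dplyr::select(fit_fec$p_zero, virus = "parameter",
                        p_zero_offspring = "mean")
    out <- rate |>
      dplyr::left_join(life, by = "virus") |>
      dplyr::left_join(fec, by = "virus") |>
      dplyr::left_join(pz, by = "virus")
    paths$report <- file.path(out_dir, "report.csv")
    readr::write_csv(out, paths$report)
    jsonlite::write_json(
      list(seed = config$seed, profile = config$profile,
           config_hash = rlang::hash(config), warnings = warnings,
           n_recipients = nrow(x$recipients),
           ppc_inside = ppc$inside),
      file.path(out_dir, "run_meta.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    out
  })

  structure(list(paths = paths, config = config, warnings = warnings,
                 summary = report,
                 fits = list(lifespan_A = fit_a, lifespan_B = fit_b,
                             fecundity = fit_fec, fecundity_early = fit_early),
                 prevalence = prev, transmission = trans, ppc = ppc),
            class = "flyvir_run_report")
}

#' @export
print.flyvir_run_report <- function(x, ...) {
  cat("<flyvir_run_report>\n")
  cat(sprintf("  profile: %s, seed: %s\n", x$config$profile, x$config$seed))
  cat(sprintf("  warnings: %d\n", length(x$warnings)))
  cat("  per-virus summary:\n")
  print(x$summary, n = Inf)
  invisible(x)
}
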