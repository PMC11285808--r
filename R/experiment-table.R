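#' Construct a validated experiment table
#'
#' The central container of the package: one natural-exposure experiment,
#' held as three tidy tables. `recipients` has one row per exposed laboratory
#' female, `detections` one row per (fly, virus) pair in that fly's exposure
#' panel (the viruses its donor pool tested positive for), and `donors` one
#' row per (vial, virus) pooled assay of the wild donor flies.
#'
#' @param recipients Tibble with columns `fly_id`, `vial_id`, `lifespan_days`,
#'   `censored`, `offspring_early`, `offspring_total`, `excluded_early`.
#' @param detections Tibble with columns `fly_id`, `virus`, `exposed`,
#'   `detected` (long format; one row per exposed virus per fly).
#' @param donors Tibble with columns `vial_id`, `species_group`, `pool_size`,
#'   `virus`, `assay_positive`.
#' @param virus_panel Character vector of virus names covering every assayed
#'   virus; defaults to the union of viruses in `detections` and `donors`.
#' @param meta Named list of run provenance (seed, generator config hash,
#'   follow-up limit in days as `followup_days`, timestamps).
#' @return An object of class `flyvir_experiment`.
#' @seealso [read_experiment()], [write_experiment()], [generate_experiment()]
#' @export
experiment_table <- function(recipients, detections, donors,
                             virus_panel = NULL, meta = list()) {
  recipients <- tibble::as_tibble(recipients)
  detections <- tibble::as_tibble(detections)
  donors <- tibble::as_tibble(donors)
  if (is.null(virus_panel)) {
    virus_panel <- sort(unique(c(detections$virus, donors$virus)))
  }
  meta$followup_days <- meta$followup_days %||% 72
  x <- structure(
    list(recipients = recipients, detections = detections, donors = donors,
         virus_panel = as.character(virus_panel), meta = meta),
    class = "flyvir_experiment"
  )
  validate_experiment(x)
}

#' @export
print.flyvir_experiment <- function(x, ...) {
  inf <- infection_indicators(x)
  n_inf <- sum(rowSums(inf[, x$virus_panel, drop = FALSE]) > 0)
  cat("<flyvir_experiment>\n")
  cat(sprintf("  recipients: %d (infected at death: %d)\n",
              nrow(x$recipients), n_inf))
  cat(sprintf("  donor pools: %d vials, %d species groups\n",
              dplyr::n_distinct(x$donors$vial_id),
              dplyr::n_distinct(x$donors$species_group)))
  cat(sprintf("  virus panel: %s\n", paste(x$virus_panel, collapse = ", ")))
  invisible(x)
}

recipient_cols <- c("fly_id", "vial_id", "lifespan_days", "censored",
                    "offspring_early", "offspring_total", "excluded_early")
detection_cols <- c("fly_id", "virus", "exposed", "detected")
donor_cols <- c("vial_id", "species_group", "pool_size", "virus",
                "assay_positive")
species_groups <- c("Dmel", "Dimm", "DobsGroup", "LabControl")

fail_row <- function(table, i, field, msg) {
  abort(sprintf("%s: row %d, field '%s': %s", table, i, field, msg))
}

#' Validate an experiment table
#'
#' Checks every structural invariant: schema completeness, unique fly ids,
#' detections restricted to the exposure panel, offspring ordering, lifespans
#' within the follow-up limit, recipient vials matching donor pools, and the
#' virus panel covering all assayed viruses. Returns its argument invisibly
#' so it can sit in a pipe.
#'
#' @param x A `flyvir_experiment`.
#' @return `x`, invisibly, or an error naming the offending row and field.
#' @export
validate_experiment <- function(x) {
  stopifnot(inherits(x, "flyvir_experiment"))
  r <- x$recipients; d <- x$detections; p <- x$donors

  for (col in recipient_cols) {
    if (!col %in% names(r)) abort(sprintf("recipients: missing column '%s'", col))
  }
  for (col in detection_cols) {
    if (!col %in% names(d)) abort(sprintf("detections: missing column '%s'", col))
  }
  for (col in donor_cols) {
    if (!col %in% names(p)) abort(sprintf("donors: missing column '%s'", col))
  }

  if (anyDuplicated(r$fly_id)) {
    i <- which(duplicated(r$fly_id))[1]
    fail_row("recipients", i, "fly_id", sprintf("duplicate id '%s'", r$fly_id[i]))
  }
  bad <- which(!is.finite(r$lifespan_days) | r$lifespan_days <= 0)
  if (length(bad)) fail_row("recipients", bad[1], "lifespan_days",
                            "must be a positive number")
  limit <- x$meta$followup_days
  bad <- which(r$lifespan_days > limit)
  if (length(bad)) fail_row("recipients", bad[1], "lifespan_days",
                            sprintf("exceeds follow-up limit of %s days", limit))
  bad <- which(r$offspring_early < 0 | r$offspring_total < 0 |
                 r$offspring_early != floor(r$offspring_early) |
                 r$offspring_total != floor(r$offspring_total))
  if (length(bad)) fail_row("recipients", bad[1], "offspring_early",
                            "offspring counts must be non-negative integers")
  bad <- which(r$offspring_early > r$offspring_total)
  if (length(bad)) fail_row("recipients", bad[1], "offspring_early",
                            "early offspring count exceeds total")
  bad <- which(!r$vial_id %in% p$vial_id)
  if (length(bad)) fail_row("recipients", bad[1], "vial_id",
                            sprintf("vial '%s' has no donor pool record",
                                    r$vial_id[bad[1]]))

  bad <- which(!d$fly_id %in% r$fly_id)
  if (length(bad)) fail_row("detections", bad[1], "fly_id",
                            sprintf("unknown fly '%s'", d$fly_id[bad[1]]))
  bad <- which(!d$virus %in% x$virus_panel)
  if (length(bad)) fail_row("detections", bad[1], "virus",
                            sprintf("virus '%s' not in the panel", d$virus[bad[1]]))
  bad <- which(d$detected & !d$exposed)
  if (length(bad)) fail_row("detections", bad[1], "detected",
                            sprintf("fly '%s' detected positive for '%s' without exposure",
                                    d$fly_id[bad[1]], d$virus[bad[1]]))
  dup <- duplicated(d[, c("fly_id", "virus")])
  if (any(dup)) {
    i <- which(dup)[1]
    fail_row("detections", i, "virus",
             sprintf("duplicate record for fly '%s', virus '%s'",
                     d$fly_id[i], d$virus[i]))
  }

  bad <- which(p$pool_size < 1 | p$pool_size != floor(p$pool_size))
  if (length(bad)) fail_row("donors", bad[1], "pool_size",
                            "must be a positive integer")
  bad <- which(!p$species_group %in% species_groups)
  if (length(bad)) fail_row("donors", bad[1], "species_group",
                            sprintf("'%s' is not one of %s", p$species_group[bad[1]],
                                    paste(species_groups, collapse = ", ")))
  bad <- which(!p$virus %in% x$virus_panel)
  if (length(bad)) fail_row("donors", bad[1], "virus",
                            sprintf("virus '%s' not in the panel", p$virus[bad[1]]))

  if (anyDuplicated(x$virus_panel)) abort("virus_panel: duplicated virus name")
  if (any(!nzchar(x$virus_panel))) abort("virus_panel: empty virus name")
  invisible(x)
}

#' Wide per-fly infection indicators
#'
#' Spreads the long detection table into one row per recipient with a 0/1
#' column per panel virus (1 = virus detected at death) plus the infection
#' count used by the additive lifespan model.
#'
#' @param x A `flyvir_experiment`.
#' @return Tibble with `fly_id`, one integer column per virus, and
#'   `n_infections`.
#' @export
infection_indicators <- function(x) {
  stopifnot(inherits(x, "flyvir_experiment"))
  wide <- x$detections |>
    dplyr::filter(.data$exposed) |>
    dplyr::mutate(value = as.integer(.data$detected)) |>
    tidyr::pivot_wider(id_cols = "fly_id", names_from = "virus",
                       values_from = "value", values_fill = 0L)
  out <- dplyr::left_join(x$recipients["fly_id"], wide, by = "fly_id")
  for (v in x$virus_panel) {
    if (!v %in% names(out)) out[[v]] <- 0L
    out[[v]][is.na(out[[v]])] <- 0L
  }
  out <- out[, c("fly_id", x$virus_panel)]
  out$n_infections <- rowSums(out[, x$virus_panel, drop = FALSE])
  out
}

#' Read an experiment from its CSV files
#'
#' Reads the three-table CSV layout written by [write_experiment()] (or
#' prepared by hand from real data) and validates every invariant.
#'
#' @param recipient_path Path to `recipients.csv`.
#' @param detection_path Path to `detections.csv`.
#' @param donor_path Path to `donors.csv`.
#' @param meta_path Optional path to the JSON provenance sidecar; when absent
#'   a minimal meta record is created.
#' @return A validated `flyvir_experiment`.
#' @export
read_experiment <- function(recipient_path, detection_path, donor_path,
                            meta_path = NULL) {
  for (f in c(recipient_path, detection_path, donor_path)) {
    if (!file.exists(f)) abort(sprintf("file not found: %s", f))
  }
  spec_r <- readr::cols(
    fly_id = readr::col_character(), vial_id = readr::col_character(),
    lifespan_days = readr::col_double(), censored = readr::col_logical(),
    offspring_early = readr::col_integer(),
    offspring_total = readr::col_integer(),
    excluded_early = readr::col_logical()
  )
  spec_d <- readr::cols(
    fly_id = readr::col_character(), virus = readr::col_character(),
    exposed = readr::col_logical(), detected = readr::col_logical()
  )
  spec_p <- readr::cols(
    vial_id = readr::col_character(), species_group = readr::col_character(),
    pool_size = readr::col_integer(), virus = readr::col_character(),
    assay_positive = readr::col_logical()
  )
  recipients <- readr::read_csv(recipient_path, col_types = spec_r)
  detections <- readr::read_csv(detection_path, col_types = spec_d)
  donors <- readr::read_csv(donor_path, col_types = spec_p)
  meta <- if (!is.null(meta_path) && file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  experiment_table(recipients, detections, donors, meta = meta)
}

#' Write an experiment to CSV files
#'
#' Writes `recipients.csv`, `detections.csv`, `donors.csv` and a
#' `run_meta.json` provenance sidecar into `out_dir`. Re-reading reproduces
#' the table exactly for integer, logical and string fields and to full
#' double precision for reals.
#'
#' @param x A validated `flyvir_experiment`.
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of the files written, invisibly.
#' @export
write_experiment <- function(x, out_dir) {
  validate_experiment(x)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory '%s'", out_dir))
  }
  paths <- c(
    recipients = file.path(out_dir, "recipients.csv"),
    detections = file.path(out_dir, "detections.csv"),
    donors = file.path(out_dir, "donors.csv"),
    meta = file.path(out_dir, "run_meta.json")
  )
  readr::write_csv(x$recipients, paths[["recipients"]])
  readr::write_csv(x$detections, paths[["detections"]])
  readr::write_csv(x$donors, paths[["donors"]])
  meta <- x$meta
  meta$virus_panel <- x$virus_panel
  jsonlite::write_json(meta, paths[["meta"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Override infection statuses (re-analysis support)
#'
#' Applies post-hoc infection-status overrides, e.g. reclassifying as
#' infected flies that tested negative at death but whose infection was
#' established by other evidence. The original table is untouched and the
#' provenance record notes the override.
#'
#' @param x A `flyvir_experiment`.
#' @param overrides Tibble with columns `fly_id`, `virus`, `detected` (the new
#'   status).
#' @return A new validated `flyvir_experiment`.
#' @export
apply_reclassification <- function(x, overrides) {
  stopifnot(inherits(x, "flyvir_experiment"))
  overrides <- tibble::as_tibble(overrides)
  if (nrow(overrides) == 0) return(x)
  stopifnot(all(c("fly_id", "virus", "detected") %in% names(overrides)))
  d <- x$detections
  for (i in seq_len(nrow(overrides))) {
    hit <- which(d$fly_id == overrides$fly_id[i] &
                   d$virus == overrides$virus[i] & d$exposed)
    if (length(hit) != 1) {
      abort(sprintf(
        "reclassification %d: fly '%s' has no exposure record for virus '%s'",
        i, overrides$fly_id[i], overrides$virus[i]))
    }
    d$detected[hit] <- overrides$detected[i]
  }
  meta <- x$meta
  meta$reclassified <- c(meta$reclassified,
                         sprintf("%s:%s->%s", overrides$fly_id,
                                 overrides$virus, overrides$detected))
  experiment_table(x$recipients, d, x$donors, x$virus_panel, meta)
}
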