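# Orchestration: full experiment runs binding region generation, the time
# chains, the fleet simulation and the summaries, with provenance-stamped
# CSV output. These functions are the package's command surface; the
# Rscript wrapper in inst/cli only parses flags and calls them.

# Write a data frame as CSV with a provenance header (config hash, seed,
# package version). The fixed dialect (comma, '.', UTF-8, header row) and
# the deterministic upstream seeds make reruns byte-identical.
write_output_csv <- function(df, file, config, seed) {
  hash <- fnv1a32(paste(utils::capture.output(utils::str(unclass(config))),
                        collapse = "\n"))
  con <- file(file, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# provenance: config_hash=%s seed=%d helistroke=%s",
                     hash, as.integer(seed),
                     as.character(utils::packageVersion("helistroke"))), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE)
  invisible(file)
}

log_info <- function(fmt, ...) {
  if (isTRUE(getOption("helistroke.verbose", TRUE)))
    message(sprintf(paste0("[helistroke] ", fmt), ...))
}

#' Run the onset-to-treatment summary experiment
#'
#' Full pipeline: generate the synthetic region, sample addresses, evaluate
#' all four transport configurations over the configured periods, and
#' summarize onset-to-IVT / onset-to-EVT per configuration for addresses in
#' PSC catchments. Deterministic for a fixed seed.
#'
#' @param config an `experiment_config` (default [default_config()]).
#' @param seed master seed; defaults to `config$master_seed`.
#' @param out_dir optional directory; when given, `table1.csv` is written
#'   there with a provenance header.
#' @return the summary tibble (see [table1_summary()]).
#' @export
run_table1 <- function(config = default_config(), seed = config$master_seed,
                       out_dir = NULL) {
  validate_config(config)
  models <- config_models(config)
  rg <- config_region(config, seed)
  log_info("region: %d municipalities, %d facilities; %d addresses",
           nrow(rg$region$municipalities), nrow(rg$region$facilities),
           nrow(rg$addresses))
  tab <- table1_summary(rg$region, rg$addresses, models$ground, models$air,
                        models$delays,
                        periods = unlist(config$stats$periods))
  log_info("table1: %d summary rows", nrow(tab))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_output_csv(tab, file.path(out_dir, "table1.csv"), config, seed)
  }
  tab
}

#' Run the fleet-capacity simulation sweep
#'
#' Generates the region, assigns demand, and sweeps the discrete-event
#' simulation over the three catchment zones and 1 vs 2 helicopters per
#' base with paired replicate streams.
#'
#' @inheritParams run_table1
#' @return tidy replicate tibble (see [scenario_sweep()]).
#' @export
run_des_sweep <- function(config = default_config(),
                          seed = config$master_seed, out_dir = NULL) {
  validate_config(config)
  models <- config_models(config)
  rg <- config_region(config, seed)
  log_info("des sweep: %d reps x 6 cells, horizon %d days",
           config$des$n_reps, config$des$horizon_days)
  sweep <- scenario_sweep(rg$region, models$fleet, models$policy,
                          n_reps = config$des$n_reps,
                          horizon_days = config$des$horizon_days,
                          other_acute_per_day = config$des$other_acute_per_day,
                          lvo_share = config$des$lvo_share,
                          ground = models$ground, air = models$air,
                          delays = models$delays, seed = seed)
  log_info("des sweep: %d result rows", nrow(sweep))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_output_csv(sweep, file.path(out_dir, "des_sweep.csv"), config, seed)
  }
  sweep
}

#' Run the dispatch-pattern correlation analysis
#'
#' Simulates a year of helicopter missions, aggregates flight counts per
#' municipality, and reports the Spearman correlation of counts against
#' (i) ground time to the nearest SHS, (ii) total helicopter time to the
#' SHS (dispatch + base-to-scene + scene-to-SHS), and (iii) the
#' ground-minus-helicopter time difference.
#'
#' @inheritParams run_table1
#' @return list with `correlations` (tibble: measure, rho) and `counts`
#'   (per-municipality tibble).
#' @export
run_dispatch_pattern <- function(config = default_config(),
                                 seed = config$master_seed, out_dir = NULL) {
  validate_config(config)
  models <- config_models(config)
  rg <- config_region(config, seed)
  region <- rg$region
  if (nrow(region$municipalities) < 3)
    stop("undefined correlation: need at least 3 municipalities",
         call. = FALSE)
  missions <- generate_missions(region, "LARGE", horizon_days = 365,
                                other_acute_per_day =
                                  config$des$other_acute_per_day,
                                lvo_share = config$des$lvo_share,
                                ground = models$ground, air = models$air,
                                seed = derive_seed(seed, "dispatch"))
  log_info("dispatch pattern: %d missions over 365 days", nrow(missions))
  shs_tt <- municipality_shs_times(region, models$ground, models$air)
  bases <- region$facilities[region$facilities$role == "HELI_BASE", ]
  pts <- cbind(region$municipalities$seed_x, region$municipalities$seed_y)
  t_base <- apply(travel_time(pts, cbind(bases$x, bases$y), models$air),
                  1, min)
  counts <- tibble::tibble(
    municipality_id = region$municipalities$id,
    flights = tabulate(missions$municipality_id,
                       nbins = nrow(region$municipalities)),
    ground_to_shs = shs_tt$ground_to_shs,
    heli_total = models$delays$heli_dispatch + t_base + shs_tt$air_to_shs
  )
  counts$time_diff <- counts$ground_to_shs - counts$heli_total
  cors <- tibble::tibble(
    measure = c("ground_to_shs", "heli_total", "ground_minus_heli"),
    rho = c(spearman_rho(counts$ground_to_shs, counts$flights),
            spearman_rho(counts$heli_total, counts$flights),
            spearman_rho(counts$time_diff, counts$flights))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_output_csv(cors, file.path(out_dir, "dispatch_correlations.csv"),
                     config, seed)
    write_output_csv(counts, file.path(out_dir, "dispatch_counts.csv"),
                     config, seed)
  }
  list(correlations = cors, counts = counts)
}

#' Run the time-saved raster export
#'
#' @inheritParams run_table1
#' @param resolution grid cell size, km.
#' @param comparison two configuration names (first minus second).
#' @param outcome `"onset_to_groin"` or `"onset_to_needle"`.
#' @return the grid tibble (see [time_saved_grid()]).
#' @export
run_time_saved_grid <- function(config = default_config(),
                                seed = config$master_seed, out_dir = NULL,
                                resolution = 10,
                                comparison = c("BYPASS_HELI",
                                               "DRIP_SHIP_GROUND"),
                                outcome = "onset_to_groin") {
  validate_config(config)
  models <- config_models(config)
  rg <- config_region(config, seed)
  grid <- time_saved_grid(rg$region, models$ground, models$air,
                          models$delays, resolution = resolution,
                          comparison = comparison, outcome = outcome)
  log_info("time-saved grid: %d cells at %.0f km", nrow(grid), resolution)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_output_csv(grid, file.path(out_dir, "time_saved_grid.csv"),
                     config, seed)
    write_ascii_grid(grid, file.path(out_dir, "time_saved_grid.asc"))
  }
  grid
}
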