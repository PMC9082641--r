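#' Default experiment configuration
#'
#' The full parameter set of an experiment as a nested list with sections
#' `region`, `travel`, `delays`, `des`, `stats`, `output` plus a
#' `master_seed`. Every downstream run function takes such a configuration;
#' [read_experiment_config()] overlays a YAML file onto these defaults and
#' rejects unknown keys.
#'
#' @return a nested list of class `experiment_config`.
#' @export
default_config <- function() {
  structure(list(
    master_seed = 1L,
    region = list(
      total_area_km2 = 43000,
      n_municipalities = 98L,
      n_psc = 7L,
      n_csc_fulltime = 3L,
      n_hybrid_psc = 1L,
      n_heli_bases = 4L,
      population_total = 5.8e6,
      rural_density_max = 300,
      urban_density_min = 1500,
      n_addresses_per_municipality = 10L,
      base_rate = 0.004,
      distance_gradient = 0.5
    ),
    travel = list(
      cruise_speed_kmh = 240,
      base_speed_kmh = 80,
      detour_factor = 1.3,
      period_multipliers = list(MORNING_PEAK = 1.0, MIDDAY = 1.0,
                                AFTERNOON_PEAK = 1.1, NIGHT = 1.0)
    ),
    delays = list(
      onset_to_call = 30, ambulance_dispatch = 1, ambulance_response = 8,
      on_scene = 20, heli_dispatch = 5, heli_loading = 11,
      min_call_to_air = 28, door_to_needle = 27, door_to_groin_bypass = 68,
      door_to_groin_dripship = 41, door_in_door_out = 60
    ),
    des = list(
      queue_threshold = 15, reject_threshold = 60, availability = 0.90,
      service_mode = "FIXED_AVERAGE", fixed_mission_minutes = 165,
      handover_minutes = 15, helicopters_per_base = 1L,
      other_acute_per_day = 7, lvo_share = 0.12,
      n_reps = 1000L, horizon_days = 28L
    ),
    stats = list(
      periods = c("MORNING_PEAK", "MIDDAY", "AFTERNOON_PEAK", "NIGHT")
    ),
    output = list(dir = "results", format = "csv")
  ), class = "experiment_config")
}

# Recursive overlay of user values onto defaults, erroring on keys the
# defaults do not know (catches typos in config files early).
overlay_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration section ", full, " must be a mapping",
             call. = FALSE)
      defaults[[key]] <- overlay_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Read an experiment configuration from YAML
#'
#' Values in the file overlay the defaults of [default_config()]; keys not
#' present in the defaults are rejected with an error naming the offending
#' key. A configuration written with [write_experiment_config()] reads back
#' unchanged.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.list(user))
      stop("configuration file must be a YAML mapping", call. = FALSE)
    cfg <- structure(overlay_config(unclass(cfg), user),
                     class = "experiment_config")
  }
  validate_config(cfg)
  cfg
}

#' @rdname read_experiment_config
#' @param config an `experiment_config` to serialize.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  # constructors perform the real validation; build them once to fail fast
  do.call(region_spec, c(cfg$region[c("total_area_km2", "n_municipalities",
                                      "n_psc", "n_csc_fulltime",
                                      "n_hybrid_psc", "n_heli_bases",
                                      "population_total", "rural_density_max",
                                      "urban_density_min")],
                         list(seed = cfg$master_seed)))
  config_models(cfg)
  stopifnot(cfg$region$n_addresses_per_municipality >= 1,
            cfg$des$n_reps >= 1, cfg$des$horizon_days > 0)
  ok_periods <- vapply(cfg$stats$periods, function(p)
    p %in% transport_periods(), TRUE)
  if (!all(ok_periods))
    stop("unknown period in stats.periods", call. = FALSE)
  invisible(cfg)
}

# Build model objects from a configuration.
config_models <- function(cfg) {
  list(
    ground = ground_model(cfg$travel$base_speed_kmh, cfg$travel$detour_factor,
                          unlist(cfg$travel$period_multipliers)),
    air = air_model(cfg$travel$cruise_speed_kmh),
    delays = do.call(delay_table, cfg$delays),
    fleet = fleet_config(cfg$des$helicopters_per_base, cfg$des$availability,
                         cfg$des$service_mode, cfg$des$fixed_mission_minutes,
                         cfg$des$handover_minutes),
    policy = queue_policy(cfg$des$queue_threshold, cfg$des$reject_threshold)
  )
}

# Build the region (with demand) and the address sample from a config.
config_region <- function(cfg, seed = cfg$master_seed) {
  spec <- region_spec(cfg$region$total_area_km2, cfg$region$n_municipalities,
                      cfg$region$n_psc, cfg$region$n_csc_fulltime,
                      cfg$region$n_hybrid_psc, cfg$region$n_heli_bases,
                      cfg$region$population_total,
                      cfg$region$rural_density_max,
                      cfg$region$urban_density_min, seed = seed)
  region <- generate_region(spec)
  region <- assign_demand(region, cfg$region$base_rate,
                          cfg$region$distance_gradient)
  addresses <- sample_addresses(region,
                                cfg$region$n_addresses_per_municipality,
                                seed = seed)
  list(region = region, addresses = addresses)
}
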