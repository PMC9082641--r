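#' Helicopter fleet configuration
#'
#' @param helicopters_per_base units stationed at each base (the study
#'   compares 1 vs 2).
#' @param availability fraction of time a unit can actually be dispatched
#'   (weather, maintenance); realized as an independent per-mission,
#'   per-unit Bernoulli refusal.
#' @param service_mode `"FIXED_AVERAGE"` uses `fixed_mission_minutes` for
#'   every mission (the registry's 165-min average base-to-base trip);
#'   `"COMPUTED"` composes dispatch + flight to scene + loading + flight to
#'   the SHS + handover + return flight.
#' @param fixed_mission_minutes minutes, used in `FIXED_AVERAGE` mode.
#' @param handover_minutes hospital handover, used in `COMPUTED` mode.
#' @return an object of class `fleet_config`.
#' @export
fleet_config <- function(helicopters_per_base = 1,
                         availability = 0.90,
                         service_mode = c("FIXED_AVERAGE", "COMPUTED"),
                         fixed_mission_minutes = 165,
                         handover_minutes = 15) {
  service_mode <- match.arg(service_mode)
  stopifnot(helicopters_per_base >= 1, availability > 0, availability <= 1,
            fixed_mission_minutes > 0, handover_minutes >= 0)
  structure(list(helicopters_per_base = as.integer(helicopters_per_base),
                 availability = availability,
                 service_mode = service_mode,
                 fixed_mission_minutes = fixed_mission_minutes,
                 handover_minutes = handover_minutes),
            class = "fleet_config")
}

#' Queue and rejection policy
#'
#' A waiting request is counted as "queued" once its wait exceeds
#' `queue_threshold` and leaves the system for ground transport
#' ("rejected") once its wait exceeds `reject_threshold`. Rejected requests
#' were necessarily queued first: the two classifications overlap.
#'
#' @param queue_threshold minutes (default 15).
#' @param reject_threshold minutes (default 60); may be `Inf`.
#' @return an object of class `queue_policy`.
#' @export
queue_policy <- function(queue_threshold = 15, reject_threshold = 60) {
  stopifnot(queue_threshold >= 0, reject_threshold > queue_threshold)
  structure(list(queue_threshold = queue_threshold,
                 reject_threshold = reject_threshold),
            class = "queue_policy")
}

#' Helicopter catchment zones
#'
#' Ground-time cutoffs to the nearest SHS defining helicopter demand: only
#' addresses at least this far (in ground minutes) generate helicopter
#' requests. The LARGE helicopter zone corresponds to the smallest ground
#' cutoff (28 min), MIDDLE to 38 and SMALL to 48.
#'
#' @return named numeric vector of cutoffs in minutes.
#' @export
catchment_zones <- function() {
  c(LARGE = 28, MIDDLE = 38, SMALL = 48)
}

# Ground minutes from each municipality (generator point) to its nearest
# SHS, used for zone eligibility and the dispatch-pattern analysis.
municipality_shs_times <- function(region, ground = ground_model(),
                                   air = air_model(), period = "MIDDAY") {
  m <- region$municipalities
  shs <- facilities_with_role(region, "SHS", period)
  if (nrow(shs) == 0)
    stop("configuration error: region has no SHS facilities", call. = FALSE)
  pts <- cbind(m$seed_x, m$seed_y)
  tg <- travel_time(pts, cbind(shs$x, shs$y), ground, period)
  ta <- travel_time(pts, cbind(shs$x, shs$y), air)
  i_g <- max.col(-tg, ties.method = "first")
  i_a <- max.col(-ta, ties.method = "first")
  tibble::tibble(
    municipality_id = m$id,
    ground_to_shs = tg[cbind(seq_len(nrow(m)), i_g)],
    air_to_shs = ta[cbind(seq_len(nrow(m)), i_a)],
    shs_fid_air = shs$fid[i_a],
    shs_x = shs$x[i_a], shs_y = shs$y[i_a]
  )
}

#' Generate a stochastic stream of helicopter mission requests
#'
#' A time-sorted superposition of per-municipality homogeneous Poisson
#' streams of stroke codes (annual rates scaled to per-day, thinned to the
#' helicopter-eligible share) restricted to municipalities outside the
#' zone's ground cutoff, plus a region-wide stream of other acute missions
#' (trauma, PCI) with origins proportional to population. Each request's
#' destination is the nearest SHS by air.
#'
#' @param region a `stroke_region` with demand assigned ([assign_demand()]).
#' @param zone `"LARGE"`, `"MIDDLE"` or `"SMALL"` (see [catchment_zones()]).
#' @param horizon_days simulated horizon.
#' @param other_acute_per_day region-wide other-acute missions per day.
#' @param lvo_share fraction of stroke codes eligible for helicopter
#'   transport (suspected LVO); the demand-magnitude knob.
#' @param ground,air travel models used for zone eligibility/destinations.
#' @param seed integer seed.
#' @return tibble of missions sorted by `arrival_min`, with origin
#'   coordinates, municipality, `kind` and destination SHS.
#' @export
generate_missions <- function(region, zone = "LARGE", horizon_days = 365,
                              other_acute_per_day = 7, lvo_share = 0.12,
                              ground = ground_model(), air = air_model(),
                              seed = 1L) {
  zone <- match.arg(zone, names(catchment_zones()))
  stopifnot(horizon_days > 0)
  m <- region$municipalities
  if (all(is.na(m$annual_stroke_codes)))
    stop("region has no demand; call assign_demand() first", call. = FALSE)
  shs_tt <- municipality_shs_times(region, ground, air)
  cutoff <- catchment_zones()[[zone]]
  eligible <- shs_tt$ground_to_shs >= cutoff
  horizon_min <- horizon_days * 1440

  empty <- tibble::tibble(mission_id = integer(0), arrival_min = numeric(0),
                          x = numeric(0), y = numeric(0),
                          municipality_id = integer(0), kind = character(0),
                          dest_fid = integer(0), dest_x = numeric(0),
                          dest_y = numeric(0))
  if (!any(eligible)) {
    warning("no municipalities outside the ", zone,
            " zone ground cutoff; empty mission stream", call. = FALSE)
    return(empty)
  }

  rate_stroke <- m$annual_stroke_codes * lvo_share / 365  # per day
  rate_stroke[!eligible | is.na(rate_stroke)] <- 0

  with_seed(derive_seed(seed, "missions"), {
    n_stroke <- stats::rpois(1, sum(rate_stroke) * horizon_days)
    n_other <- stats::rpois(1, other_acute_per_day * horizon_days)
    mk <- function(n, probs, kind) {
      if (n == 0 || sum(probs) == 0) return(NULL)
      mid <- sample.int(nrow(m), n, replace = TRUE, prob = probs)
      tibble::tibble(arrival_min = stats::runif(n, 0, horizon_min),
                     x = m$seed_x[mid], y = m$seed_y[mid],
                     municipality_id = m$id[mid], kind = kind)
    }
    res <- dplyr::bind_rows(
      mk(n_stroke, rate_stroke, "STROKE_CODE"),
      mk(n_other, m$population, "OTHER_ACUTE"))
    if (is.null(res) || nrow(res) == 0) return(empty)
    res <- res[order(res$arrival_min), ]
    j <- match(res$municipality_id, shs_tt$municipality_id)
    res$dest_fid <- shs_tt$shs_fid_air[j]
    res$dest_x <- shs_tt$shs_x[j]
    res$dest_y <- shs_tt$shs_y[j]
    res$mission_id <- seq_len(nrow(res))
    res[, c("mission_id", "arrival_min", "x", "y", "municipality_id",
            "kind", "dest_fid", "dest_x", "dest_y")]
  })
}

#' Total duration of one helicopter mission
#'
#' In `FIXED_AVERAGE` mode every mission occupies its helicopter for the
#' configured average trip time. In `COMPUTED` mode the duration is
#' dispatch + flight to the scene + loading + flight to the SHS + handover
#' + return flight to base.
#'
#' @param req one mission (row of [generate_missions()] output, or any list
#'   with `x`, `y`, `dest_x`, `dest_y`).
#' @param base the serving base facility (list with `x`, `y`).
#' @param fleet a [fleet_config()].
#' @param delays a [delay_table()].
#' @param air an [air_model()].
#' @return minutes.
#' @export
mission_duration <- function(req, base, fleet = fleet_config(),
                             delays = delay_table(), air = air_model()) {
  if (fleet$service_mode == "FIXED_AVERAGE") return(fleet$fixed_mission_minutes)
  o <- c(req$x, req$y); d <- c(req$dest_x, req$dest_y); b <- c(base$x, base$y)
  delays$heli_dispatch + air_time(b, o, air) + delays$heli_loading +
    air_time(o, d, air) + fleet$handover_minutes + air_time(d, b, air)
}

#' Simulate the helicopter fleet serving a mission stream
#'
#' Event-driven execution. Each arriving request seizes the nearest base
#' (by air distance) with an idle, in-service helicopter, ties going to the
#' lowest base id; if none is available it waits in a FIFO queue. A wait
#' exceeding the queue threshold marks the request "queued"; a wait
#' exceeding the rejection threshold removes it ("rejected", diverted to
#' ground transport). Availability is an independent per-mission, per-unit
#' Bernoulli: a refused unit never serves that request, which keeps waiting
#' for any other unit. All randomness is pre-drawn from the seed, so output
#' is bit-identical across runs.
#'
#' @param missions tibble from [generate_missions()] (time-sorted); an
#'   optional `duration` column overrides the service-time model per
#'   mission.
#' @param region a `stroke_region` supplying the base facilities.
#' @param fleet a [fleet_config()].
#' @param policy a [queue_policy()].
#' @param seed integer seed for the availability draws.
#' @param horizon_minutes denominator for utilization; defaults to the last
#'   mission completion time.
#' @param delays,air passed to [mission_duration()] in `COMPUTED` mode.
#' @param .refusal internal: a pre-drawn uniform matrix (missions x unit
#'   slots) overriding the availability stream, used by [scenario_sweep()]
#'   to pair scenarios.
#' @return an object of class `des_result`: counters (`n_requests`,
#'   `n_served`, `n_queued`, `n_rejected`), the wait-time vector and
#'   summary, and per-base utilization.
#' @export
simulate_fleet <- function(missions, region, fleet = fleet_config(),
                           policy = queue_policy(), seed = 1L,
                           horizon_minutes = NULL, delays = delay_table(),
                           air = air_model(), .refusal = NULL) {
  bases <- region$facilities[region$facilities$role == "HELI_BASE", ]
  bases <- bases[order(bases$fid), ]
  nb <- nrow(bases)
  if (nb == 0 || fleet$helicopters_per_base < 1)
    stop("configuration error: no helicopter bases", call. = FALSE)
  hpb <- fleet$helicopters_per_base
  nu <- nb * hpb
  n <- nrow(missions)

  # unit u = (base b, slot s); refusal uniforms are laid out on a fixed
  # max-2-slot grid keyed by base so that the 1- and 2-helicopter scenarios
  # share draws for common units under a common seed.
  slot_grid <- max(2L, hpb)
  unit_base <- rep(seq_len(nb), each = hpb)
  unit_col <- (unit_base - 1L) * slot_grid + rep(seq_len(hpb), times = nb)

  res_empty <- function() {
    structure(list(n_requests = 0L, n_served = 0L, n_queued = 0L,
                   n_rejected = 0L, waits = numeric(0),
                   wait_summary = c(mean = NA_real_, median = NA_real_,
                                    q1 = NA_real_, q3 = NA_real_,
                                    p_wait_gt_queue = NA_real_),
                   utilization = tibble::tibble(base_id = bases$id,
                                                utilization = 0),
                   served = logical(0)),
              class = "des_result")
  }
  if (n == 0) return(res_empty())

  if (is.null(.refusal)) {
    .refusal <- with_seed(derive_seed(seed, "availability"),
                          matrix(stats::runif(n * nb * slot_grid),
                                 nrow = n))
  }
  ok <- .refusal[, unit_col, drop = FALSE] <= fleet$availability

  arr <- missions$arrival_min
  dist_mb <- cross_dist(cbind(missions$x, missions$y),
                        cbind(bases$x, bases$y))          # n x nb
  # candidate unit order per mission: by base distance then slot
  unit_rank <- t(apply(dist_mb, 1, function(dr)
    order(rep(dr, each = hpb), rep(seq_len(hpb), times = nb))))
  if (nu == 1) unit_rank <- matrix(unit_rank, ncol = 1)

  has_dur <- "duration" %in% names(missions)
  fixed_mode <- fleet$service_mode == "FIXED_AVERAGE"
  if (!fixed_mode) {
    leg_scene_dest <- air_time(cbind(missions$x, missions$y),
                               cbind(missions$dest_x, missions$dest_y), air)
    dist_db <- cross_dist(cbind(missions$dest_x, missions$dest_y),
                          cbind(bases$x, bases$y))
  }
  dur_of <- function(i, u) {
    if (has_dur) return(missions$duration[i])
    if (fixed_mode) return(fleet$fixed_mission_minutes)
    b <- unit_base[u]
    delays$heli_dispatch + dist_mb[i, b] / air$cruise_speed_kmh * 60 +
      delays$heli_loading + leg_scene_dest[i] + fleet$handover_minutes +
      dist_db[i, b] / air$cruise_speed_kmh * 60
  }

  free_at <- rep(-Inf, nu)
  busy <- rep(0, nu)
  start <- rep(NA_real_, n)
  rejected <- rep(FALSE, n)
  queue <- integer(0)
  rt <- policy$reject_threshold

  try_dispatch <- function(i, t_now) {
    for (u in unit_rank[i, ]) {
      if (free_at[u] <= t_now && ok[i, u]) {
        d <- dur_of(i, u)
        free_at[u] <<- t_now + d
        busy[u] <<- busy[u] + d
        start[i] <<- t_now
        return(TRUE)
      }
    }
    FALSE
  }

  drain_queue <- function(t_now) {
    repeat {
      if (length(queue) == 0) break
      assigned_any <- FALSE
      drop <- logical(length(queue))
      for (qi in seq_along(queue)) {
        i <- queue[qi]
        if (t_now - arr[i] > rt) {
          rejected[i] <<- TRUE
          drop[qi] <- TRUE
          next
        }
        if (try_dispatch(i, t_now)) {
          drop[qi] <- TRUE
          assigned_any <- TRUE
        }
      }
      queue <<- queue[!drop]
      if (!assigned_any) break
    }
  }

  i_next <- 1L
  t_cur <- 0
  repeat {
    t_arr <- if (i_next <= n) arr[i_next] else Inf
    busy_units <- free_at > t_cur
    t_free <- if (length(queue) > 0 && any(busy_units))
      min(free_at[busy_units]) else Inf
    if (is.infinite(t_arr) && is.infinite(t_free)) {
      # nothing can progress: remaining queued requests are never served
      rejected[queue] <- TRUE
      queue <- integer(0)
      break
    }
    if (t_free <= t_arr) {
      t_cur <- t_free
      drain_queue(t_cur)
    } else {
      t_cur <- t_arr
      i <- i_next
      i_next <- i_next + 1L
      # any currently idle unit has already refused everything in the queue,
      # so a fresh arrival may try them without violating FIFO fairness
      if (!try_dispatch(i, t_cur)) queue <- c(queue, i)
    }
  }

  waits <- ifelse(rejected, rt, start - arr)
  waits[is.infinite(waits)] <- NA_real_
  served <- !rejected
  n_queued <- sum(waits > policy$queue_threshold, na.rm = TRUE)
  horizon <- if (!is.null(horizon_minutes)) horizon_minutes
             else max(c(free_at[is.finite(free_at)], arr), na.rm = TRUE)
  util <- vapply(seq_len(nb), function(b)
    sum(busy[unit_base == b]) / (hpb * horizon), 0)
  q <- stats::quantile(waits, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  structure(list(
    n_requests = n,
    n_served = sum(served),
    n_queued = as.integer(n_queued),
    n_rejected = sum(rejected),
    waits = waits,
    wait_summary = c(mean = mean(waits, na.rm = TRUE), median = q[2],
                     q1 = q[1], q3 = q[3],
                     p_wait_gt_queue = mean(waits > policy$queue_threshold,
                                            na.rm = TRUE)),
    utilization = tibble::tibble(base_id = bases$id, utilization = util),
    served = served
  ), class = "des_result")
}

#' @export
print.des_result <- function(x, ...) {
  cat(sprintf("<des_result> %d requests: %d served, %d queued (>threshold), %d rejected\n",
              x$n_requests, x$n_served, x$n_queued, x$n_rejected))
  cat(sprintf("  mean wait %.1f min; mean utilization %.2f\n",
              x$wait_summary[["mean"]], mean(x$utilization$utilization)))
  invisible(x)
}

#' Sweep the fleet simulation over catchment zones and fleet sizes
#'
#' Runs replicate simulations over the 3 x 2 grid of catchment zone
#' (LARGE/MIDDLE/SMALL) and helicopters per base (1 or 2). Within a
#' replicate, all six cells share one mission stream (generated at the
#' LARGE cutoff and thinned to the smaller zones) and one availability
#' stream keyed by mission identity, so comparisons are paired: the same
#' patients and the same weather are replayed under each policy.
#'
#' @param region a `stroke_region` with demand assigned.
#' @param fleet a [fleet_config()] template (its `helicopters_per_base` is
#'   overridden by the sweep).
#' @param policy a [queue_policy()].
#' @param n_reps replicates per cell.
#' @param horizon_days horizon of each replicate.
#' @param other_acute_per_day,lvo_share demand parameters, see
#'   [generate_missions()].
#' @param ground,air,delays models.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return tidy tibble: one row per zone x helicopters-per-base x replicate
#'   with counts and queued/rejected fractions.
#' @export
scenario_sweep <- function(region, fleet = fleet_config(),
                           policy = queue_policy(), n_reps = 1000,
                           horizon_days = 28, other_acute_per_day = 7,
                           lvo_share = 0.12, ground = ground_model(),
                           air = air_model(), delays = delay_table(),
                           seed = 1L) {
  stopifnot(n_reps >= 1)
  shs_tt <- municipality_shs_times(region, ground, air)
  zones <- names(catchment_zones())
  rows <- vector("list", n_reps * length(zones) * 2L)
  k <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, paste0("rep", r))
    missions <- generate_missions(region, "LARGE", horizon_days,
                                  other_acute_per_day, lvo_share,
                                  ground, air, seed = rep_seed)
    nb <- sum(region$facilities$role == "HELI_BASE")
    refusal <- with_seed(derive_seed(rep_seed, "availability"),
                         matrix(stats::runif(max(1, nrow(missions)) * nb * 2),
                                nrow = max(1, nrow(missions))))
    mun_g <- shs_tt$ground_to_shs[match(missions$municipality_id,
                                        shs_tt$municipality_id)]
    for (zone in zones) {
      cutoff <- catchment_zones()[[zone]]
      keep <- missions$kind == "OTHER_ACUTE" | mun_g >= cutoff
      mz <- missions[keep, , drop = FALSE]
      rz <- refusal[keep, , drop = FALSE]
      for (hpb in c(1L, 2L)) {
        fl <- fleet
        fl$helicopters_per_base <- hpb
        res <- simulate_fleet(mz, region, fl, policy, seed = rep_seed,
                              horizon_minutes = horizon_days * 1440,
                              delays = delays, air = air, .refusal = rz)
        k <- k + 1L
        rows[[k]] <- tibble::tibble(
          zone = zone, helicopters_per_base = hpb, replicate = r,
          n_requests = res$n_requests, n_served = res$n_served,
          n_queued = res$n_queued, n_rejected = res$n_rejected,
          frac_queued = ifelse(res$n_requests > 0,
                               res$n_queued / res$n_requests, 0),
          frac_rejected = ifelse(res$n_requests > 0,
                                 res$n_rejected / res$n_requests, 0),
          mean_wait = res$wait_summary[["mean"]])
      }
    }
  }
  dplyr::bind_rows(rows)
}
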