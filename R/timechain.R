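#' Fixed prehospital and in-hospital delay components
#'
#' The central parameter set of the model, in minutes. Defaults are the
#' registry-derived medians for the Danish system: 30 min from symptom onset
#' to the emergency call, 1 min ambulance dispatch, 8 min ambulance
#' response, 20 min on scene, 5 min helicopter dispatch (time to airborne),
#' 11 min to load the patient into the helicopter, 27 min door-to-needle,
#' 68 min door-to-groin under bypass, 41 min door-to-groin after a
#' drip-and-ship transfer, and 60 min door-in-door-out at the PSC.
#'
#' `min_call_to_air` is the earliest time after the emergency call at which
#' air transport from the scene can start: the ambulance must have responded
#' and prepared the patient, so by default it is
#' `ambulance_response + on_scene` (28 min). Note the deliberate asymmetry,
#' reproducing the source arithmetic: the ground chain adds
#' `ambulance_dispatch + ambulance_response` (1 + 8) while the air floor
#' uses `8 + 20` only.
#'
#' @param onset_to_call,ambulance_dispatch,ambulance_response,on_scene
#'   prehospital components, minutes.
#' @param heli_dispatch,heli_loading helicopter components, minutes.
#' @param min_call_to_air floor on call-to-air-transport initiation; `NULL`
#'   derives it as `ambulance_response + on_scene`.
#' @param door_to_needle,door_to_groin_bypass,door_to_groin_dripship,
#'   door_in_door_out in-hospital components, minutes.
#' @return an object of class `delay_table` (a named list, minutes).
#' @export
#' @examples
#' delay_table()$min_call_to_air  # 28
delay_table <- function(onset_to_call = 30,
                        ambulance_dispatch = 1,
                        ambulance_response = 8,
                        on_scene = 20,
                        heli_dispatch = 5,
                        heli_loading = 11,
                        min_call_to_air = NULL,
                        door_to_needle = 27,
                        door_to_groin_bypass = 68,
                        door_to_groin_dripship = 41,
                        door_in_door_out = 60) {
  if (is.null(min_call_to_air))
    min_call_to_air <- ambulance_response + on_scene
  d <- list(onset_to_call = onset_to_call,
            ambulance_dispatch = ambulance_dispatch,
            ambulance_response = ambulance_response,
            on_scene = on_scene,
            heli_dispatch = heli_dispatch,
            heli_loading = heli_loading,
            min_call_to_air = min_call_to_air,
            door_to_needle = door_to_needle,
            door_to_groin_bypass = door_to_groin_bypass,
            door_to_groin_dripship = door_to_groin_dripship,
            door_in_door_out = door_in_door_out)
  if (any(unlist(d) < 0))
    stop("delay components must be >= 0", call. = FALSE)
  if (door_to_groin_bypass <= door_to_needle)
    stop("door_to_groin_bypass must exceed door_to_needle", call. = FALSE)
  structure(d, class = "delay_table")
}

#' The four transport configurations
#' @return character vector of configuration names.
#' @export
transport_configs <- function() {
  c("DRIP_SHIP_GROUND", "DRIP_SHIP_HELI_TRANSFER", "BYPASS_GROUND",
    "BYPASS_HELI")
}

# Build a time_breakdown object from a component table. Each component is
# flagged by whether it contributes to the onset-to-needle and/or
# onset-to-groin totals; the totals are the flagged sums, exactly.
new_breakdown <- function(components, configuration, needle_site, groin_site) {
  onset_to_needle <- sum(components$minutes[components$in_needle])
  onset_to_groin <- if (any(components$in_groin))
    sum(components$minutes[components$in_groin]) else NA_real_
  structure(list(components = components,
                 configuration = configuration,
                 onset_to_needle = onset_to_needle,
                 onset_to_groin = onset_to_groin,
                 needle_site = needle_site,
                 groin_site = groin_site),
            class = "time_breakdown")
}

comp_row <- function(component, minutes, in_needle = TRUE, in_groin = TRUE) {
  tibble::tibble(component = component, minutes = minutes,
                 in_needle = in_needle, in_groin = in_groin)
}

#' @export
print.time_breakdown <- function(x, ...) {
  cat(sprintf("<time_breakdown> %s\n", x$configuration))
  print(as.data.frame(x$components), row.names = FALSE)
  cat(sprintf("  onset-to-needle %.1f min at %s; onset-to-groin %s min at %s\n",
              x$onset_to_needle, x$needle_site,
              ifelse(is.na(x$onset_to_groin), "NA",
                     sprintf("%.1f", x$onset_to_groin)), x$groin_site))
  invisible(x)
}

#' Ground transport chain to the nearest stroke centre
#'
#' Composes onset-to-call + ambulance dispatch + ambulance response + time
#' on scene + ground transport to the nearest facility of the target role +
#' the in-hospital delay. With `target_role = "CSC"` this is the bypass
#' ground strategy and the breakdown carries both totals (needle via
#' door-to-needle, groin via the bypass door-to-groin); with `"PSC"` only
#' the needle total is defined (the drip-and-ship chain adds the transfer).
#'
#' @param p address point `c(x, y)` km.
#' @param target_role `"PSC"` or `"CSC"`.
#' @param region a `stroke_region`.
#' @param ground a [ground_model()].
#' @param delays a [delay_table()].
#' @param period one of [transport_periods()].
#' @return a `time_breakdown`.
#' @export
ground_chain <- function(p, target_role = c("PSC", "CSC"), region,
                         ground = ground_model(), delays = delay_table(),
                         period = "MIDDAY") {
  target_role <- match.arg(target_role)
  nf <- nearest_facility(p, target_role, region, ground, period)
  comps <- dplyr::bind_rows(
    comp_row("onset_to_call", delays$onset_to_call),
    comp_row("ambulance_dispatch", delays$ambulance_dispatch),
    comp_row("ambulance_response", delays$ambulance_response),
    comp_row("on_scene", delays$on_scene),
    comp_row(paste0("ground_transport_to_", target_role), nf$minutes),
    comp_row("door_to_needle", delays$door_to_needle, TRUE, FALSE),
    if (target_role == "CSC")
      comp_row("door_to_groin_bypass", delays$door_to_groin_bypass, FALSE, TRUE)
  )
  if (target_role == "PSC") comps$in_groin <- FALSE
  new_breakdown(comps,
                configuration = if (target_role == "CSC") "BYPASS_GROUND"
                                else "DRIP_SHIP_GROUND",
                needle_site = target_role,
                groin_site = if (target_role == "CSC") "CSC" else NA_character_)
}

#' Helicopter pickup at the scene
#'
#' The ambulance and helicopter are dispatched simultaneously. The
#' helicopter reaches the scene `heli_dispatch + flight` minutes after the
#' call; the patient is ready no earlier than `min_call_to_air` minutes
#' after the call (ambulance response plus on-scene preparation); loading
#' then takes `heli_loading` minutes:
#' `scene_departure = max(heli_arrival, min_call_to_air) + heli_loading`.
#'
#' @param p scene point `c(x, y)` km.
#' @param base the helicopter base facility (one-row tibble or list with
#'   `x`, `y`).
#' @param delays a [delay_table()].
#' @param air an [air_model()].
#' @return list with `heli_arrival`, `patient_ready`, `scene_departure`
#'   (minutes after the call) and the component table.
#' @export
heli_pickup <- function(p, base, delays = delay_table(), air = air_model()) {
  flight <- air_time(p, c(base$x, base$y), air)
  heli_arrival <- delays$heli_dispatch + flight
  patient_ready <- delays$min_call_to_air
  hold <- max(0, patient_ready - heli_arrival)
  departure <- max(heli_arrival, patient_ready) + delays$heli_loading
  comps <- dplyr::bind_rows(
    comp_row("heli_dispatch", delays$heli_dispatch),
    comp_row("flight_to_scene", flight),
    comp_row("scene_hold", hold),
    comp_row("heli_loading", delays$heli_loading)
  )
  list(heli_arrival = heli_arrival, patient_ready = patient_ready,
       scene_departure = departure, components = comps)
}

#' Bypass-by-helicopter chain
#'
#' Direct helicopter transport from the scene to the nearest CSC (by air),
#' picking up from the nearest helicopter base, with the simultaneous
#'-dispatch pickup rule of [heli_pickup()].
#'
#' @inheritParams ground_chain
#' @param air an [air_model()].
#' @return a `time_breakdown`.
#' @export
bypass_heli_chain <- function(p, region, ground = ground_model(),
                              air = air_model(), delays = delay_table(),
                              period = "MIDDAY") {
  base <- nearest_facility(p, "HELI_BASE", region, air, period)$facility
  csc <- nearest_facility(p, "CSC", region, air, period)
  pk <- heli_pickup(p, base, delays, air)
  comps <- dplyr::bind_rows(
    comp_row("onset_to_call", delays$onset_to_call),
    pk$components,
    comp_row("flight_to_CSC", csc$minutes),
    comp_row("door_to_needle", delays$door_to_needle, TRUE, FALSE),
    comp_row("door_to_groin_bypass", delays$door_to_groin_bypass, FALSE, TRUE)
  )
  new_breakdown(comps, "BYPASS_HELI", needle_site = "CSC", groin_site = "CSC")
}

#' Drip-and-ship chain with ground or helicopter transfer
#'
#' Thrombolysis at the nearest PSC (ground chain), then interhospital
#' transfer to a CSC for thrombectomy after the door-in-door-out interval.
#' In `GROUND` mode the transfer is driven to the CSC nearest the PSC by
#' ground; in `HELI` mode the transfer time is helicopter dispatch + flight
#' from the base nearest the PSC to the PSC + flight from the PSC to the
#' CSC nearest by air.
#'
#' @inheritParams bypass_heli_chain
#' @param transfer_mode `"GROUND"` or `"HELI"`.
#' @return a `time_breakdown`.
#' @export
dripship_chain <- function(p, region, ground = ground_model(),
                           air = air_model(), delays = delay_table(),
                           period = "MIDDAY",
                           transfer_mode = c("GROUND", "HELI")) {
  transfer_mode <- match.arg(transfer_mode)
  psc <- nearest_facility(p, "PSC", region, ground, period)
  psc_xy <- c(psc$facility$x, psc$facility$y)
  if (transfer_mode == "GROUND") {
    csc <- nearest_facility(psc_xy, "CSC", region, ground, period)
    transfer <- dplyr::bind_rows(
      comp_row("ground_transfer_PSC_to_CSC", csc$minutes, FALSE, TRUE))
  } else {
    base <- nearest_facility(psc_xy, "HELI_BASE", region, air, period)$facility
    csc <- nearest_facility(psc_xy, "CSC", region, air, period)
    transfer <- dplyr::bind_rows(
      comp_row("heli_dispatch", delays$heli_dispatch, FALSE, TRUE),
      comp_row("flight_base_to_PSC", air_time(psc_xy, c(base$x, base$y), air),
               FALSE, TRUE),
      comp_row("flight_PSC_to_CSC", csc$minutes, FALSE, TRUE))
  }
  comps <- dplyr::bind_rows(
    comp_row("onset_to_call", delays$onset_to_call),
    comp_row("ambulance_dispatch", delays$ambulance_dispatch),
    comp_row("ambulance_response", delays$ambulance_response),
    comp_row("on_scene", delays$on_scene),
    comp_row("ground_transport_to_PSC", psc$minutes),
    comp_row("door_to_needle", delays$door_to_needle, TRUE, FALSE),
    comp_row("door_in_door_out", delays$door_in_door_out, FALSE, TRUE),
    transfer,
    comp_row("door_to_groin_dripship", delays$door_to_groin_dripship,
             FALSE, TRUE)
  )
  new_breakdown(comps,
                configuration = if (transfer_mode == "GROUND")
                  "DRIP_SHIP_GROUND" else "DRIP_SHIP_HELI_TRANSFER",
                needle_site = "PSC", groin_site = "CSC")
}

#' Is helicopter dispatch worthwhile for an address?
#'
#' Air transport from the scene cannot start earlier than
#' `min_call_to_air` minutes after the call, so when ground transport would
#' reach the nearest EVT-capable centre (SHS) in less than the cutoff, only
#' ground transport is used. At the boundary (ground time exactly equal to
#' the cutoff) the helicopter is allowed.
#'
#' @inheritParams bypass_heli_chain
#' @param cutoff minutes; `NULL` uses `delays$min_call_to_air` (28).
#' @return logical.
#' @export
helicopter_viable <- function(p, region, ground = ground_model(),
                              delays = delay_table(), period = "MIDDAY",
                              cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- delays$min_call_to_air
  g <- nearest_facility(p, "SHS", region, ground, period)$minutes
  !(g < cutoff)
}

#' AHA-style bypass rule
#'
#' A patient is routed directly to the CSC when ground transport to the CSC
#' is less than `threshold` minutes longer than to the PSC (strict
#' inequality: a difference of exactly `threshold` keeps the PSC routing).
#'
#' @inheritParams ground_chain
#' @param threshold minutes (default 15).
#' @return logical.
#' @export
aha_bypass_rule <- function(p, region, ground = ground_model(),
                            period = "MIDDAY", threshold = 15) {
  g_csc <- nearest_facility(p, "CSC", region, ground, period)$minutes
  g_psc <- nearest_facility(p, "PSC", region, ground, period)$minutes
  (g_csc - g_psc) < threshold
}

#' Evaluate all transport configurations for a set of addresses
#'
#' Vectorized evaluation of the four transport chains over addresses and
#' periods, using the same composition rules as the single-address chain
#' functions. Used by the Table-1 summary, the time-saved rasters and the
#' dispatch-pattern analysis.
#'
#' @param addresses tibble from [sample_addresses()] (columns `address_id`,
#'   `municipality_id`, `x`, `y`).
#' @param region a `stroke_region`.
#' @param ground a [ground_model()].
#' @param air an [air_model()].
#' @param delays a [delay_table()].
#' @param periods character subset of [transport_periods()].
#' @return a long tibble: one row per address x period x configuration with
#'   `onset_to_needle`, `onset_to_groin`, `needle_site`, `groin_site`,
#'   `ground_to_psc`, `ground_to_csc`, and `nearest_is_psc` (whether the
#'   nearest stroke facility by ground is a PSC in that period).
#' @export
evaluate_transport <- function(addresses, region, ground = ground_model(),
                               air = air_model(), delays = delay_table(),
                               periods = transport_periods()) {
  pxy <- cbind(addresses$x, addresses$y)
  prefix_g <- delays$onset_to_call + delays$ambulance_dispatch +
    delays$ambulance_response + delays$on_scene
  out <- lapply(periods, function(period) {
    pscs <- facilities_with_role(region, "PSC", period)
    cscs <- facilities_with_role(region, "CSC", period)
    bases <- facilities_with_role(region, "HELI_BASE", period)
    if (nrow(pscs) == 0 || nrow(cscs) == 0 || nrow(bases) == 0)
      stop("lookup error: region must have PSC, CSC and base facilities",
           call. = FALSE)
    tt_psc <- travel_time(pxy, cbind(pscs$x, pscs$y), ground, period)
    tt_csc <- travel_time(pxy, cbind(cscs$x, cscs$y), ground, period)
    i_psc <- max.col(-tt_psc, ties.method = "first")
    i_csc <- max.col(-tt_csc, ties.method = "first")
    g_psc <- tt_psc[cbind(seq_len(nrow(pxy)), i_psc)]
    g_csc <- tt_csc[cbind(seq_len(nrow(pxy)), i_csc)]

    # nearest stroke facility overall (tie to lowest fid via fid ordering)
    un <- facilities_with_role(region, c("PSC", "CSC"), period)
    tt_un <- travel_time(pxy, cbind(un$x, un$y), ground, period)
    i_un <- max.col(-tt_un, ties.method = "first")
    near_role <- un$role[i_un]
    working <- is_working_hours(period)
    nearest_is_psc <- near_role == "PSC" |
      (!working & near_role == "HYBRID_PSC")

    # air legs
    at_base <- travel_time(pxy, cbind(bases$x, bases$y), air)
    i_base <- max.col(-at_base, ties.method = "first")
    a_base <- at_base[cbind(seq_len(nrow(pxy)), i_base)]
    at_csc <- travel_time(pxy, cbind(cscs$x, cscs$y), air)
    i_acsc <- max.col(-at_csc, ties.method = "first")
    a_csc <- at_csc[cbind(seq_len(nrow(pxy)), i_acsc)]

    # per-PSC transfer legs (small lookup tables)
    psc_xy <- cbind(pscs$x, pscs$y)
    tg <- travel_time(psc_xy, cbind(cscs$x, cscs$y), ground, period)
    transfer_ground <- apply(tg, 1, min)
    ta_csc <- travel_time(psc_xy, cbind(cscs$x, cscs$y), air)
    ta_base <- travel_time(psc_xy, cbind(bases$x, bases$y), air)
    transfer_heli <- delays$heli_dispatch + apply(ta_base, 1, min) +
      apply(ta_csc, 1, min)

    arrival_psc <- prefix_g + g_psc
    needle_ds <- arrival_psc + delays$door_to_needle
    groin_stub <- arrival_psc + delays$door_in_door_out +
      delays$door_to_groin_dripship

    heli_arrival <- delays$heli_dispatch + a_base
    departure <- pmax(heli_arrival, delays$min_call_to_air) +
      delays$heli_loading
    needle_bh <- delays$onset_to_call + departure + a_csc +
      delays$door_to_needle

    base_tbl <- tibble::tibble(
      address_id = addresses$address_id,
      municipality_id = addresses$municipality_id,
      period = period,
      ground_to_psc = g_psc,
      ground_to_csc = g_csc,
      nearest_is_psc = nearest_is_psc
    )
    dplyr::bind_rows(
      dplyr::mutate(base_tbl, configuration = "DRIP_SHIP_GROUND",
                    onset_to_needle = needle_ds,
                    onset_to_groin = groin_stub + transfer_ground[i_psc],
                    needle_site = "PSC", groin_site = "CSC"),
      dplyr::mutate(base_tbl, configuration = "DRIP_SHIP_HELI_TRANSFER",
                    onset_to_needle = needle_ds,
                    onset_to_groin = groin_stub + transfer_heli[i_psc],
                    needle_site = "PSC", groin_site = "CSC"),
      dplyr::mutate(base_tbl, configuration = "BYPASS_GROUND",
                    onset_to_needle = prefix_g + g_csc + delays$door_to_needle,
                    onset_to_groin = prefix_g + g_csc +
                      delays$door_to_groin_bypass,
                    needle_site = "CSC", groin_site = "CSC"),
      dplyr::mutate(base_tbl, configuration = "BYPASS_HELI",
                    onset_to_needle = needle_bh,
                    onset_to_groin = needle_bh - delays$door_to_needle +
                      delays$door_to_groin_bypass,
                    needle_site = "CSC", groin_site = "CSC")
    )
  })
  dplyr::bind_rows(out)
}
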