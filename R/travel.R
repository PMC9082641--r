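#' Helicopter travel-time model
#'
#' A single cruise speed applied to the straight-line distance; the default
#' 240 km/h is an effective speed that already includes take-off and landing.
#'
#' @param cruise_speed_kmh effective cruise speed, km/h.
#' @return an object of class `air_model`.
#' @export
air_model <- function(cruise_speed_kmh = 240) {
  stopifnot(cruise_speed_kmh > 0)
  structure(list(cruise_speed_kmh = cruise_speed_kmh), class = "air_model")
}

#' Ground travel-time model
#'
#' A stand-in for routed road travel times: straight-line distance inflated
#' by a detour factor (road distance over straight-line distance) at a base
#' ambulance speed, with multiplicative time-of-day effects. The defaults
#' (80 km/h, detour 1.3, a 10% afternoon-peak penalty) put the synthetic
#' national medians near the observed scene-to-PSC (~26 min) and
#' scene-to-CSC (~50 min) times.
#'
#' @param base_speed_kmh free-flow ambulance speed, km/h.
#' @param detour_factor road distance / straight-line distance, >= 1.
#' @param period_multipliers named multipliers (>= 1) for the four sampled
#'   periods of day.
#' @return an object of class `ground_model`.
#' @export
ground_model <- function(base_speed_kmh = 80,
                         detour_factor = 1.3,
                         period_multipliers = c(MORNING_PEAK = 1.0,
                                                MIDDAY = 1.0,
                                                AFTERNOON_PEAK = 1.1,
                                                NIGHT = 1.0)) {
  stopifnot(base_speed_kmh > 0, detour_factor >= 1)
  pm <- period_multipliers[transport_periods()]
  if (anyNA(pm))
    stop("period_multipliers must name all four periods", call. = FALSE)
  if (any(pm < 1))
    stop("period multipliers must be >= 1", call. = FALSE)
  structure(list(base_speed_kmh = base_speed_kmh,
                 detour_factor = detour_factor,
                 period_multipliers = pm),
            class = "ground_model")
}

#' The four sampled periods of day
#'
#' Travel times are sampled at morning peak, midday, afternoon peak and
#' night. Morning peak and midday fall within hospital working hours, when
#' the hybrid PSC operates as a CSC.
#'
#' @return character vector of the four period names.
#' @export
transport_periods <- function() {
  c("MORNING_PEAK", "MIDDAY", "AFTERNOON_PEAK", "NIGHT")
}

#' @rdname transport_periods
#' @param period one of the four period names.
#' @return `is_working_hours`: logical.
#' @export
is_working_hours <- function(period) {
  period <- match.arg(period, transport_periods())
  period %in% c("MORNING_PEAK", "MIDDAY")
}

#' Helicopter flight time between points
#'
#' `euclidean_distance / cruise_speed * 60` minutes; symmetric in its
#' arguments. Vectorized over rows when matrices are supplied.
#'
#' @param a,b points `c(x, y)` in km, or n x 2 matrices.
#' @param model an [air_model()].
#' @return minutes (numeric).
#' @export
air_time <- function(a, b, model = air_model()) {
  euclid(a, b) / model$cruise_speed_kmh * 60
}

#' Ground travel time between points
#'
#' `euclidean_distance * detour_factor / base_speed * 60 * period_multiplier`
#' minutes; symmetric and monotone in distance.
#'
#' @param a,b points `c(x, y)` in km, or n x 2 matrices.
#' @param model a [ground_model()].
#' @param period one of [transport_periods()].
#' @return minutes (numeric).
#' @export
ground_time <- function(a, b, model = ground_model(), period = "MIDDAY") {
  period <- match.arg(period, transport_periods())
  euclid(a, b) * model$detour_factor / model$base_speed_kmh * 60 *
    model$period_multipliers[[period]]
}

# Facilities filling a requested role set under a period's working-hours
# rule. The hybrid PSC counts as a CSC during working hours and as a PSC
# otherwise. "SHS" denotes the EVT-capable sites (CSC + hybrid), which are
# helicopter destinations around the clock.
facilities_with_role <- function(region, roles, period = "MIDDAY") {
  fac <- region$facilities
  working <- is_working_hours(period)
  eff <- lapply(roles, function(r) {
    switch(r,
      CSC = fac[fac$role == "CSC" | (working & fac$role == "HYBRID_PSC"), ],
      PSC = fac[fac$role == "PSC" | (!working & fac$role == "HYBRID_PSC"), ],
      SHS = fac[fac$role %in% c("CSC", "HYBRID_PSC"), ],
      HELI_BASE = fac[fac$role == "HELI_BASE", ],
      stop("unknown facility role: ", r, call. = FALSE))
  })
  out <- dplyr::distinct(dplyr::bind_rows(eff))
  out[order(out$fid), ]
}

#' Nearest facility by travel time
#'
#' Finds the facility of a requested role minimizing travel time from a
#' point under the supplied model and period; ties are broken in favour of
#' the lowest facility id. The hybrid PSC participates in CSC lookups only
#' during working-hours periods.
#'
#' @param p a point `c(x, y)` km.
#' @param roles one or more of `"PSC"`, `"CSC"`, `"SHS"`, `"HELI_BASE"`.
#' @param region a `stroke_region`.
#' @param model an [air_model()] or [ground_model()].
#' @param period one of [transport_periods()].
#' @return a list with `facility` (one-row tibble) and `minutes`.
#' @export
nearest_facility <- function(p, roles, region, model = ground_model(),
                             period = "MIDDAY") {
  fac <- facilities_with_role(region, roles, period)
  if (nrow(fac) == 0)
    stop("lookup error: no facility with role ",
         paste(roles, collapse = "/"),
         if (!is_working_hours(period)) " open in this period", call. = FALSE)
  tt <- travel_time(matrix(p, ncol = 2), cbind(fac$x, fac$y), model, period)
  i <- order(tt[1, ], fac$fid)[1]
  list(facility = fac[i, ], minutes = tt[1, i])
}

# Travel time matrix (origins x destinations) under either model.
travel_time <- function(origins, destinations, model, period = "MIDDAY") {
  d <- cross_dist(origins, destinations)
  if (inherits(model, "air_model")) {
    d / model$cruise_speed_kmh * 60
  } else {
    period <- match.arg(period, transport_periods())
    d * model$detour_factor / model$base_speed_kmh * 60 *
      model$period_multipliers[[period]]
  }
}

#' Origin-by-destination travel-time table
#'
#' Computes a full origin x destination travel-time matrix and optionally
#' writes it as CSV (origins as rows).
#'
#' @param origins,destinations data frames with `x`, `y` columns and an
#'   identifier column (`address_id` or `id`), or n x 2 matrices.
#' @param model an [air_model()] or [ground_model()].
#' @param period one of [transport_periods()].
#' @param file optional path; when given, the table is written as CSV.
#' @return the travel-time matrix in minutes, invisibly when writing.
#' @export
travel_matrix <- function(origins, destinations, model = ground_model(),
                          period = "MIDDAY", file = NULL) {
  oxy <- if (is.data.frame(origins)) cbind(origins$x, origins$y) else origins
  dxy <- if (is.data.frame(destinations)) cbind(destinations$x, destinations$y)
         else destinations
  tt <- travel_time(oxy, dxy, model, period)
  rn <- if (is.data.frame(origins) && !is.null(origins$address_id))
    origins$address_id else if (is.data.frame(origins) && !is.null(origins$id))
    origins$id else seq_len(nrow(tt))
  cn <- if (is.data.frame(destinations) && !is.null(destinations$id))
    destinations$id else seq_len(ncol(tt))
  dimnames(tt) <- list(rn, cn)
  if (!is.null(file)) {
    utils::write.csv(as.data.frame(tt), file, row.names = TRUE)
    return(invisible(tt))
  }
  tt
}
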