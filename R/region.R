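#' Specification for a synthetic intermediate-density region
#'
#' Defaults mirror the Danish setting the package models: 43,000 km2, 98
#' municipalities, 5.8 million inhabitants, seven primary stroke centres
#' (PSC), three full-time comprehensive stroke centres (CSC), one PSC that
#' functions as a CSC during working hours, and four helicopter bases.
#'
#' The density thresholds encode the Eurostat "intermediate density"
#' definition: a region where less than 50% of the population lives at rural
#' densities (below `rural_density_max`) and less than 50% lives at urban
#' densities (above `urban_density_min`).
#'
#' @param total_area_km2 land area of the rectangular country outline.
#' @param n_municipalities number of Voronoi municipalities tiling the area.
#' @param n_psc,n_csc_fulltime,n_hybrid_psc,n_heli_bases facility counts; the
#'   hybrid PSC is counted separately from `n_psc`.
#' @param population_total total population, persons.
#' @param rural_density_max rural density ceiling, persons/km2.
#' @param urban_density_min urban density floor, persons/km2.
#' @param seed integer seed for all stochastic draws in region generation.
#' @return an object of class `region_spec` (a validated list).
#' @export
#' @examples
#' region_spec(seed = 1)
region_spec <- function(total_area_km2 = 43000,
                        n_municipalities = 98,
                        n_psc = 7,
                        n_csc_fulltime = 3,
                        n_hybrid_psc = 1,
                        n_heli_bases = 4,
                        population_total = 5.8e6,
                        rural_density_max = 300,
                        urban_density_min = 1500,
                        seed = 1L) {
  spec <- list(total_area_km2 = total_area_km2,
               n_municipalities = as.integer(n_municipalities),
               n_psc = as.integer(n_psc),
               n_csc_fulltime = as.integer(n_csc_fulltime),
               n_hybrid_psc = as.integer(n_hybrid_psc),
               n_heli_bases = as.integer(n_heli_bases),
               population_total = population_total,
               rural_density_max = rural_density_max,
               urban_density_min = urban_density_min,
               seed = as.integer(seed))
  counts <- unlist(spec[c("n_municipalities", "n_psc", "n_csc_fulltime",
                          "n_hybrid_psc", "n_heli_bases")])
  if (spec$n_municipalities < 1)
    stop("configuration error: n_municipalities must be >= 1", call. = FALSE)
  if (any(counts < 0))
    stop("configuration error: facility counts must be >= 0", call. = FALSE)
  if (total_area_km2 <= 0)
    stop("configuration error: total_area_km2 must be > 0", call. = FALSE)
  if (population_total < 0)
    stop("configuration error: population_total must be >= 0", call. = FALSE)
  if (rural_density_max >= urban_density_min)
    stop("configuration error: rural_density_max must be < urban_density_min",
         call. = FALSE)
  n_stroke <- spec$n_psc + spec$n_csc_fulltime + spec$n_hybrid_psc
  if (n_stroke > spec$n_municipalities)
    stop("configuration error: more stroke facilities than municipalities",
         call. = FALSE)
  if (spec$n_heli_bases > spec$n_municipalities)
    stop("configuration error: more helicopter bases than municipalities",
         call. = FALSE)
  structure(spec, class = "region_spec")
}

# Shares of population placed at town (>= rural ceiling) vs rural density.
# 0.60 in towns leaves the rural share at 0.40 and the urban share near 0.02,
# both strictly below the 0.5 caps of the intermediate-density definition.
.TOWN_POP_SHARE <- 0.60
.URBAN_POP_CAP <- 0.08

#' Generate a synthetic region
#'
#' Municipality territories are a Voronoi partition of seeded generator
#' points clipped to a rectangular country outline (aspect ratio 1.4).
#' About 30% of generators are clustered around a handful of "city" centres,
#' producing small cells there; population is then assigned by density class
#' (one urban core, a set of town cells covering enough area to absorb 60%
#' of the population at 450--1,100 persons/km2, the rest rural) so that the
#' intermediate-density constraint holds: less than half the population at
#' rural density and less than half at urban density. CSCs and PSCs are
#' placed in the highest-population municipalities subject to a minimum
#' mutual separation; helicopter bases are spread by greedy max-min
#' dispersion. Islands are not generated: the territory is contiguous.
#'
#' @param spec a [region_spec()].
#' @return an object of class `stroke_region`: a list with tibbles
#'   `municipalities` and `facilities`, the municipality `polygons`, the
#'   bounding box `bbox` (xmin, xmax, ymin, ymax, km) and the `spec`.
#' @export
#' @examples
#' r <- generate_region(region_spec(seed = 1))
#' r
generate_region <- function(spec) {
  if (!inherits(spec, "region_spec")) spec <- do.call(region_spec, spec)
  n <- spec$n_municipalities
  with_seed(derive_seed(spec$seed, "region"), {
    aspect <- 1.4
    w <- sqrt(spec$total_area_km2 * aspect)
    h <- sqrt(spec$total_area_km2 / aspect)
    bbox <- c(0, w, 0, h)

    pts <- .draw_generators(n, bbox)
    polys <- voronoi_partition(pts, bbox)
    areas <- vapply(polys, polygon_area, 0)
    cents <- t(vapply(polys, polygon_centroid, numeric(2)))

    pop <- .assign_population(areas, spec)

    muni <- tibble::tibble(
      id = seq_len(n),
      seed_x = pts[, 1], seed_y = pts[, 2],
      centroid_x = cents[, 1], centroid_y = cents[, 2],
      area_km2 = areas,
      population = pop,
      density = pop / areas,
      annual_stroke_codes = NA_real_,
      dist_csc_km = NA_real_
    )

    fac <- .place_facilities(muni, spec, bbox)

    shs <- fac[fac$role %in% c("CSC", "HYBRID_PSC"), , drop = FALSE]
    if (nrow(shs) > 0) {
      dm <- cross_dist(pts, cbind(shs$x, shs$y))
      muni$dist_csc_km <- apply(dm, 1, min)
    }

    structure(list(spec = spec, municipalities = muni, facilities = fac,
                   polygons = polys, bbox = bbox),
              class = "stroke_region")
  })
}

# Generator points: a mixture of uniform draws and draws clustered around
# city centres, with a minimum mutual separation scaled to the country
# (~0.5 km at the Danish default).
.draw_generators <- function(n, bbox) {
  w <- bbox[2] - bbox[1]; h <- bbox[4] - bbox[3]
  sep2 <- (0.0025 * sqrt(w * h))^2
  if (n == 1) return(matrix(c(bbox[1] + w / 2, bbox[3] + h / 2), 1, 2))
  n_city <- max(1L, round(n / 20))
  cities <- cbind(stats::runif(n_city, bbox[1] + 0.15 * w, bbox[2] - 0.15 * w),
                  stats::runif(n_city, bbox[3] + 0.15 * h, bbox[4] - 0.15 * h))
  n_clust <- round(0.30 * n)
  sd_clust <- 0.03 * sqrt(w * h)
  pts <- matrix(NA_real_, n, 2)
  k <- 0L
  tries <- 0L
  while (k < n && tries < 50000L) {
    tries <- tries + 1L
    if (k < n_clust) {
      ci <- sample.int(n_city, 1)
      p <- cities[ci, ] + stats::rnorm(2, sd = sd_clust)
    } else {
      p <- c(stats::runif(1, bbox[1], bbox[2]), stats::runif(1, bbox[3], bbox[4]))
    }
    if (p[1] <= bbox[1] || p[1] >= bbox[2] || p[2] <= bbox[3] || p[2] >= bbox[4])
      next
    if (k > 0) {
      d2 <- (pts[seq_len(k), 1] - p[1])^2 + (pts[seq_len(k), 2] - p[2])^2
      if (min(d2) < sep2) next
    }
    k <- k + 1L
    pts[k, ] <- p
  }
  if (k < n) stop("could not place distinct municipality generators")
  pts
}

# Population by density class. Cells sorted by area ascending: the smallest
# becomes the urban core, the next-smallest become towns until their joint
# area can hold the town population share at mid-range density, the rest are
# rural. Within-class draws are rescaled to the class total and clamped back
# into the class density band (redistributing the residual), so the realized
# densities respect the class boundaries for every seed.
.assign_population <- function(areas, spec) {
  n <- length(areas)
  p_total <- spec$population_total
  if (p_total == 0) return(rep(0, n))
  if (n < 12) {
    wts <- areas * stats::rlnorm(n, 0, 0.5)
    return(.round_preserving_sum(p_total * wts / sum(wts)))
  }
  r_max <- spec$rural_density_max
  u_min <- spec$urban_density_min
  ord <- order(areas)
  pop <- numeric(n)

  # urban core
  iu <- ord[1]
  d_u <- stats::runif(1, u_min * 1.15, u_min * 1.75)
  pop_u <- min(d_u * areas[iu], .URBAN_POP_CAP * p_total)
  if (pop_u / areas[iu] <= u_min) pop_u <- 0  # cell too large for urban density
  pop[iu] <- pop_u

  # towns: enough area to hold the remaining town share at ~775 persons/km2
  town_target <- .TOWN_POP_SHARE * p_total - pop_u
  d_lo <- r_max * 1.5; d_hi <- u_min * 0.75   # 450--1125 at the defaults
  d_mid <- (d_lo + d_hi) / 2
  cum <- cumsum(areas[ord[-1]])
  n_town <- max(2L, which(cum >= town_target / d_mid)[1])
  if (is.na(n_town)) n_town <- n - 1L
  it <- ord[1L + seq_len(n_town)]
  d_t <- stats::runif(n_town, d_lo, d_hi)
  pop[it] <- .rescale_clamped(d_t * areas[it], town_target,
                              areas[it], r_max * 1.07, u_min * 0.97)

  # rural remainder
  ir <- setdiff(seq_len(n), c(iu, it))
  rural_target <- p_total - pop_u - town_target
  u_r <- stats::runif(length(ir), 0.5, 1.5)
  pop[ir] <- .rescale_clamped(areas[ir] * u_r, rural_target,
                              areas[ir], 0, r_max * 0.93)

  .round_preserving_sum(pop)
}

# Scale `raw` weights to sum to `target` while keeping each value's density
# (value / area) inside [d_lo, d_hi]: clamp offenders and push the residual
# onto the unclamped entries, iterating to convergence.
.rescale_clamped <- function(raw, target, areas, d_lo, d_hi) {
  if (length(raw) == 0 || target <= 0) return(rep(0, length(raw)))
  v <- raw * target / sum(raw)
  for (iter in 1:50) {
    lo <- d_lo * areas; hi <- d_hi * areas
    clamped <- pmin(pmax(v, lo), hi)
    resid <- target - sum(clamped)
    if (abs(resid) < 1e-6) return(clamped)
    free <- if (resid > 0) clamped < hi - 1e-9 else clamped > lo + 1e-9
    if (!any(free)) return(clamped)  # band cannot absorb the target exactly
    v <- clamped
    v[free] <- v[free] + resid * areas[free] / sum(areas[free])
  }
  v
}

# Round to integers preserving the exact sum (largest-remainder method).
.round_preserving_sum <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x) - sum(fl))
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  fl
}

# Facility placement. Stroke centres go to the highest-population
# municipalities subject to a minimum mutual separation (CSCs first, then
# the hybrid, then PSCs); helicopter bases are spread by greedy max-min
# dispersion starting from the municipality farthest from any CSC.
.place_facilities <- function(muni, spec, bbox) {
  pts <- cbind(muni$seed_x, muni$seed_y)
  scale_km <- sqrt((bbox[2] - bbox[1]) * (bbox[4] - bbox[3]))
  rank_pop <- order(muni$population, decreasing = TRUE)

  pick_separated <- function(ranked, k, taken_xy, minsep) {
    chosen <- integer(0)
    while (length(chosen) < k && minsep > 0.1) {
      chosen <- integer(0)
      for (i in ranked) {
        cand <- pts[i, ]
        all_xy <- rbind(taken_xy, pts[chosen, , drop = FALSE])
        ok <- nrow(all_xy) == 0 ||
          min(sqrt((all_xy[, 1] - cand[1])^2 + (all_xy[, 2] - cand[2])^2)) >= minsep
        if (ok) chosen <- c(chosen, i)
        if (length(chosen) == k) break
      }
      if (length(chosen) < k) minsep <- minsep * 0.7
    }
    if (length(chosen) < k)
      chosen <- c(chosen, setdiff(ranked, chosen)[seq_len(k - length(chosen))])
    chosen
  }

  taken <- matrix(numeric(0), 0, 2)
  i_csc <- pick_separated(rank_pop, spec$n_csc_fulltime, taken, 0.25 * scale_km)
  taken <- rbind(taken, pts[i_csc, , drop = FALSE])
  remaining <- setdiff(rank_pop, i_csc)
  i_hyb <- pick_separated(remaining, spec$n_hybrid_psc, taken, 0.25 * scale_km)
  taken <- rbind(taken, pts[i_hyb, , drop = FALSE])
  remaining <- setdiff(remaining, i_hyb)
  i_psc <- pick_separated(remaining, spec$n_psc, taken, 0.15 * scale_km)

  stroke_xy <- pts[c(i_csc, i_hyb), , drop = FALSE]
  i_base <- integer(0)
  if (spec$n_heli_bases > 0) {
    cand <- seq_len(nrow(muni))
    first <- if (nrow(stroke_xy) > 0) {
      dmin <- apply(cross_dist(pts, stroke_xy), 1, min)
      which.max(dmin)
    } else which.max(muni$population)
    i_base <- first
    while (length(i_base) < spec$n_heli_bases) {
      dmin <- apply(cross_dist(pts, pts[i_base, , drop = FALSE]), 1, min)
      dmin[i_base] <- -Inf
      i_base <- c(i_base, which.max(dmin))
    }
  }

  mk <- function(idx, role, tag) {
    if (length(idx) == 0) return(NULL)
    tibble::tibble(id = paste0(tag, seq_along(idx)), role = role,
                   x = pts[idx, 1], y = pts[idx, 2], municipality_id = idx)
  }
  fac <- dplyr::bind_rows(mk(i_csc, "CSC", "CSC"),
                          mk(i_hyb, "HYBRID_PSC", "HYB"),
                          mk(i_psc, "PSC", "PSC"),
                          mk(i_base, "HELI_BASE", "BASE"))
  fac$fid <- seq_len(nrow(fac))
  fac
}

#' @export
print.stroke_region <- function(x, ...) {
  m <- x$municipalities
  cat(sprintf("<stroke_region> %d municipalities, %.0f km2, population %s\n",
              nrow(m), sum(m$area_km2),
              format(sum(m$population), big.mark = ",")))
  tb <- table(x$facilities$role)
  cat("  facilities:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  frac <- density_class_shares(x)
  cat(sprintf("  population shares: rural %.2f, intermediate %.2f, urban %.2f\n",
              frac["rural"], frac["intermediate"], frac["urban"]))
  invisible(x)
}

#' Population shares by density class
#'
#' Fraction of the population living in municipalities below the rural
#' density ceiling, between the two thresholds, and above the urban floor.
#' A region is "intermediate density" when both the rural and the urban
#' share are below 0.5.
#'
#' @param region a `stroke_region`.
#' @return named numeric vector `c(rural, intermediate, urban)`.
#' @export
density_class_shares <- function(region) {
  m <- region$municipalities
  spec <- region$spec
  p <- sum(m$population)
  if (p == 0) return(c(rural = NA_real_, intermediate = NA_real_, urban = NA_real_))
  rural <- sum(m$population[m$density < spec$rural_density_max]) / p
  urban <- sum(m$population[m$density > spec$urban_density_min]) / p
  c(rural = rural, intermediate = 1 - rural - urban, urban = urban)
}

#' Sample address points uniformly within each municipality
#'
#' Emulates drawing random valid addresses: a fixed number of points per
#' municipality, uniform over the municipality's territory.
#'
#' @param region a `stroke_region`.
#' @param n_per_municipality points per municipality (default 10).
#' @param seed integer seed.
#' @return a tibble with columns `address_id`, `municipality_id`, `x`, `y`.
#' @export
sample_addresses <- function(region, n_per_municipality = 10, seed = 1L) {
  stopifnot(n_per_municipality >= 1)
  n_per_municipality <- as.integer(n_per_municipality)
  with_seed(derive_seed(seed, "addresses"), {
    out <- lapply(seq_along(region$polygons), function(i) {
      xy <- sample_in_polygon(region$polygons[[i]], n_per_municipality)
      tibble::tibble(municipality_id = i, x = xy[, 1], y = xy[, 2])
    })
    res <- dplyr::bind_rows(out)
    res$address_id <- seq_len(nrow(res))
    res[, c("address_id", "municipality_id", "x", "y")]
  })
}

#' Municipality membership of points
#'
#' Voronoi territories are convex cells of their generator points, so a
#' point belongs to the municipality with the nearest generator.
#'
#' @param region a `stroke_region`.
#' @param pts an n x 2 matrix (or data frame with `x`, `y`) of points, km.
#' @return integer vector of municipality ids.
#' @export
municipality_of <- function(region, pts) {
  if (is.data.frame(pts)) pts <- cbind(pts$x, pts$y)
  pts <- matrix(pts, ncol = 2)
  m <- region$municipalities
  dm <- cross_dist(pts, cbind(m$seed_x, m$seed_y))
  max.col(-dm, ties.method = "first")
}

#' Assign annual stroke-code demand to municipalities
#'
#' Per-capita demand increases linearly with distance to the nearest
#' EVT-capable centre, reflecting the higher stroke incidence observed far
#' from the comprehensive centres:
#' `codes = round(population * base_rate * (1 + gradient * d / max(d)))`.
#'
#' @param region a `stroke_region`.
#' @param base_rate stroke codes per person per year at the CSC doorstep.
#' @param distance_gradient relative excess at the maximum distance; with
#'   `distance_gradient = 1` the most remote municipality has twice the
#'   per-capita rate of one adjacent to a CSC.
#' @param seed reserved; the assignment is a deterministic formula.
#' @return the region with `annual_stroke_codes` filled in.
#' @export
assign_demand <- function(region, base_rate = 0.004, distance_gradient = 0.5,
                          seed = NULL) {
  if (base_rate < 0)
    stop("parameter error: base_rate must be >= 0", call. = FALSE)
  m <- region$municipalities
  d <- m$dist_csc_km
  if (all(is.na(d)) || max(d, na.rm = TRUE) == 0) {
    dnorm <- rep(0, nrow(m))
  } else {
    dnorm <- d / max(d, na.rm = TRUE)
  }
  fac <- 1 + distance_gradient * dnorm
  if (any(fac < 0))
    stop("parameter error: negative demand rate (distance_gradient too low)",
         call. = FALSE)
  region$municipalities$annual_stroke_codes <- round(m$population * base_rate * fac)
  region
}
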