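# GeoJSON serialization of regions. Coordinates are planar kilometres (the
# synthetic projection), recorded in the collection's `crs_note` member so
# round-trips are unambiguous.

#' Serialize a region to GeoJSON
#'
#' Writes a FeatureCollection with one Polygon feature per municipality
#' (population, area, demand and distance-to-CSC as properties) and one
#' Point feature per facility (role as property). The generating spec and
#' bounding box travel along as foreign members so [region_from_geojson()]
#' can reconstruct the full object.
#'
#' @param region a `stroke_region`.
#' @param file optional path; when given the GeoJSON is written there.
#' @return the GeoJSON string (invisibly when writing to file).
#' @export
region_to_geojson <- function(region, file = NULL) {
  m <- region$municipalities
  close_ring <- function(poly) {
    ring <- rbind(poly, poly[1, ])
    lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
  }
  muni_feats <- lapply(seq_len(nrow(m)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(close_ring(region$polygons[[i]]))),
         properties = list(feature = "municipality", id = m$id[i],
                           seed_x = m$seed_x[i], seed_y = m$seed_y[i],
                           population = m$population[i],
                           area_km2 = m$area_km2[i],
                           annual_stroke_codes = m$annual_stroke_codes[i],
                           dist_csc_km = m$dist_csc_km[i]))
  })
  f <- region$facilities
  fac_feats <- lapply(seq_len(nrow(f)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(f$x[i], f$y[i])),
         properties = list(feature = "facility", id = f$id[i],
                           fid = f$fid[i], role = f$role[i],
                           municipality_id = f$municipality_id[i]))
  })
  gj <- list(type = "FeatureCollection",
             crs_note = "planar synthetic projection, coordinates in km",
             bbox = region$bbox,
             region_spec = unclass(region$spec),
             features = c(muni_feats, fac_feats))
  txt <- jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA, null = "null",
                          na = "null")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Reconstruct a region from GeoJSON
#'
#' @param file path to a GeoJSON file written by [region_to_geojson()], or
#'   a GeoJSON string.
#' @return a `stroke_region`.
#' @export
region_from_geojson <- function(file) {
  txt <- if (file.exists(file)) paste(readLines(file, warn = FALSE),
                                      collapse = "\n") else file
  gj <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  stopifnot(identical(gj$type, "FeatureCollection"))
  is_muni <- vapply(gj$features,
                    function(ft) ft$properties$feature == "municipality",
                    TRUE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  munis <- gj$features[is_muni]
  polys <- lapply(munis, function(ft) {
    ring <- ft$geometry$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, unlist))
    xy[-nrow(xy), , drop = FALSE]  # drop closing vertex
  })
  m <- dplyr::bind_rows(lapply(munis, function(ft) {
    p <- ft$properties
    tibble::tibble(id = as.integer(p$id), seed_x = p$seed_x, seed_y = p$seed_y,
                   area_km2 = p$area_km2, population = p$population,
                   annual_stroke_codes = num_or_na(p$annual_stroke_codes),
                   dist_csc_km = num_or_na(p$dist_csc_km))
  }))
  cents <- t(vapply(polys, polygon_centroid, numeric(2)))
  m$centroid_x <- cents[, 1]
  m$centroid_y <- cents[, 2]
  m$density <- m$population / m$area_km2
  fac <- dplyr::bind_rows(lapply(gj$features[!is_muni], function(ft) {
    p <- ft$properties
    tibble::tibble(id = p$id, role = p$role,
                   x = ft$geometry$coordinates[[1]],
                   y = ft$geometry$coordinates[[2]],
                   municipality_id = as.integer(p$municipality_id),
                   fid = as.integer(p$fid))
  }))
  fac <- fac[order(fac$fid), ]
  spec <- do.call(region_spec, gj$region_spec)
  structure(list(spec = spec,
                 municipalities = m[, c("id", "seed_x", "seed_y",
                                        "centroid_x", "centroid_y",
                                        "area_km2", "population", "density",
                                        "annual_stroke_codes", "dist_csc_km")],
                 facilities = fac, polygons = polys,
                 bbox = unlist(gj$bbox)),
            class = "stroke_region")
}
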