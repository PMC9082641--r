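# Shared fixtures and independent oracles for the test suite.

options(helistroke.verbose = FALSE)

# Ground model in which minutes equal straight-line kilometres (60 km/h, no
# detour, flat periods): makes hand traces exact.
unit_ground <- function() {
  ground_model(base_speed_kmh = 60, detour_factor = 1,
               period_multipliers = c(MORNING_PEAK = 1, MIDDAY = 1,
                                      AFTERNOON_PEAK = 1, NIGHT = 1))
}

# Hand-built single-municipality region: one rectangular territory with
# facilities at stated coordinates. `fac` is a data.frame with columns
# role, x, y (ids assigned per role in row order).
manual_region <- function(fac, width = 600, height = 400) {
  poly <- matrix(c(0, 0, width, 0, width, height, 0, height),
                 ncol = 2, byrow = TRUE)
  tags <- c(CSC = "CSC", HYBRID_PSC = "HYB", PSC = "PSC", HELI_BASE = "BASE")
  fac <- as.data.frame(fac)
  fac$id <- NA_character_
  for (r in unique(fac$role)) {
    idx <- which(fac$role == r)
    fac$id[idx] <- paste0(tags[[r]], seq_along(idx))
  }
  facilities <- tibble::tibble(id = fac$id, role = fac$role,
                               x = fac$x, y = fac$y,
                               municipality_id = 1L,
                               fid = seq_len(nrow(fac)))
  shs <- facilities[facilities$role %in% c("CSC", "HYBRID_PSC"), ]
  cent <- polygon_centroid_for_tests(poly)
  dist_csc <- if (nrow(shs) > 0)
    min(sqrt((shs$x - cent[1])^2 + (shs$y - cent[2])^2)) else NA_real_
  muni <- tibble::tibble(id = 1L, seed_x = cent[1], seed_y = cent[2],
                         centroid_x = cent[1], centroid_y = cent[2],
                         area_km2 = width * height, population = 1000,
                         density = 1000 / (width * height),
                         annual_stroke_codes = NA_real_,
                         dist_csc_km = dist_csc)
  structure(list(spec = region_spec(total_area_km2 = width * height,
                                    n_municipalities = 1, n_psc = 0,
                                    n_csc_fulltime = 0, n_hybrid_psc = 0,
                                    n_heli_bases = 0, seed = 1),
                 municipalities = muni, facilities = facilities,
                 polygons = list(poly), bbox = c(0, width, 0, height)),
            class = "stroke_region")
}

polygon_centroid_for_tests <- function(poly) colMeans(poly)

euclid_for_tests <- function(a, b) sqrt(sum((a - b)^2))

validate_config_for_tests <- function(cfg) helistroke:::validate_config(cfg)

# A small default-structured region reused across tests (generated once).
default_test_region <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- assign_demand(generate_region(region_spec(seed = 1)))
    cache
  }
})

# --- independent oracles -------------------------------------------------

# Type-7 quantile by explicit order-statistic interpolation.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Spearman's rho as Pearson correlation of mid-ranks, with ranks and the
# Pearson formula written out directly.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) {
      sum(v < vi) + (sum(v == vi) + 1) / 2
    }, 0)
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (valid when the |differences| are distinct and non-zero).
oracle_wilcoxon_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  mean_v <- n * (n + 1) / 4
  p <- mean(abs(v_all - mean_v) >= abs(v_obs - mean_v) - 1e-12)
  list(statistic = v_obs, p_value = min(1, p))
}

# Erlang-C stationary mean wait for an M/M/c queue.
erlang_c_wq <- function(lambda, mu, c) {
  a <- lambda / mu
  stopifnot(a < c)
  terms <- vapply(0:(c - 1), function(k) a^k / factorial(k), 0)
  pc <- a^c / factorial(c) * c / (c - a)
  prob_wait <- pc / (sum(terms) + pc)
  prob_wait / (c * mu - lambda)
}
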