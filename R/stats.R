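#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics (the common
#' type-7 rule).
#'
#' @param values non-empty numeric vector (minutes).
#' @return named numeric vector `c(median, q1, q3)`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3))  # 2, 1.5, 2.5
median_iqr <- function(values) {
  if (length(values) == 0 || all(is.na(values)))
    stop("median_iqr: empty input", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, na.rm = TRUE,
                       names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided paired test on `a - b` after dropping zero differences: the
#' exact null distribution for n <= 25 without ties in the absolute
#' differences, otherwise the normal approximation with tie correction
#' (no continuity correction).
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @return list with `statistic` (V, sum of positive-difference ranks) and
#'   `p_value`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  stopifnot(length(paired_a) == length(paired_b))
  d <- paired_a - paired_b
  d <- d[d != 0]
  if (length(d) == 0)
    stop("degenerate input: all paired differences are zero", call. = FALSE)
  if (length(d) < 5)
    stop("need at least 5 non-zero paired differences", call. = FALSE)
  ties <- any(duplicated(abs(d)))
  exact <- length(d) <= 25 && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("undefined correlation: zero variance in ranks", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Number needed to fly
#'
#' Patients that must be flown for one additional good outcome: the floor
#' of the reciprocal absolute risk difference between two strategies'
#' probabilities of an excellent outcome. Symmetric in its arguments.
#'
#' @param p_baseline,p_new outcome probabilities in `[0, 1]`.
#' @return integer count.
#' @export
#' @examples
#' number_needed_to_fly(0.29, 0.32)  # 33
number_needed_to_fly <- function(p_baseline, p_new) {
  stopifnot(p_baseline >= 0, p_baseline <= 1, p_new >= 0, p_new <= 1)
  if (p_new == p_baseline)
    stop("infinite number needed to fly: equal probabilities", call. = FALSE)
  # guard the floor against binary representation error in the difference
  # (e.g. 0.31 - 0.29 slightly above 1/50)
  as.integer(floor(round(1 / abs(p_new - p_baseline), 9)))
}

#' Default excellent-outcome probabilities per strategy
#'
#' Conditional-outcome model values: drip-and-ship by ground 0.29, bypass
#' by ground 0.31, bypass by helicopter 0.32.
#'
#' @return named numeric vector.
#' @export
outcome_probabilities <- function() {
  c(DRIP_SHIP_GROUND = 0.29, BYPASS_GROUND = 0.31, BYPASS_HELI = 0.32)
}

#' Onset-to-treatment summary table for PSC-catchment patients
#'
#' Evaluates the four transport chains for every address and sampled
#' period, restricts to addresses whose nearest stroke facility (by ground,
#' under that period's working-hours rule) is a PSC — the population for
#' whom the drip-and-ship versus bypass choice exists — and summarizes
#' onset-to-IVT and onset-to-EVT as median (q1, q3) per configuration.
#'
#' @param region a `stroke_region`.
#' @param addresses tibble from [sample_addresses()].
#' @param ground,air,delays models.
#' @param periods periods to pool over (default all four).
#' @return a tibble with one row per configuration x outcome
#'   (`onset_to_IVT`, `onset_to_EVT`) and columns `median`, `q1`, `q3`,
#'   `n`; of class `summary_table`.
#' @export
table1_summary <- function(region, addresses, ground = ground_model(),
                           air = air_model(), delays = delay_table(),
                           periods = transport_periods()) {
  stopifnot(nrow(addresses) > 0)
  ev <- evaluate_transport(addresses, region, ground, air, delays, periods)
  ev <- ev[ev$nearest_is_psc, ]
  if (nrow(ev) == 0)
    stop("no addresses fall in a PSC catchment", call. = FALSE)
  summarize_one <- function(df, what) {
    v <- if (what == "onset_to_IVT") df$onset_to_needle else df$onset_to_groin
    mi <- median_iqr(v)
    tibble::tibble(outcome = what, median = mi[["median"]], q1 = mi[["q1"]],
                   q3 = mi[["q3"]], n = length(v))
  }
  out <- dplyr::bind_rows(lapply(split(ev, ev$configuration), function(df) {
    dplyr::bind_rows(summarize_one(df, "onset_to_IVT"),
                     summarize_one(df, "onset_to_EVT")) |>
      dplyr::mutate(configuration = df$configuration[1], .before = 1)
  }))
  rownames(out) <- NULL
  class(out) <- c("summary_table", class(out))
  out
}

#' Raster of time differences between two transport configurations
#'
#' Evaluates two configurations on a regular grid of cell centres across
#' the region and returns their difference in the chosen outcome time.
#' Positive values mean the first configuration is slower.
#'
#' @param region a `stroke_region`.
#' @param ground,air,delays models.
#' @param resolution cell size, km.
#' @param comparison character vector of two configuration names (see
#'   [transport_configs()]).
#' @param period single period.
#' @param outcome `"onset_to_groin"` (default) or `"onset_to_needle"`.
#' @return tibble `x`, `y`, `minutes_diff` (one row per grid cell).
#' @export
time_saved_grid <- function(region, ground = ground_model(),
                            air = air_model(), delays = delay_table(),
                            resolution = 10,
                            comparison = c("BYPASS_HELI", "DRIP_SHIP_GROUND"),
                            period = "MIDDAY",
                            outcome = c("onset_to_groin", "onset_to_needle")) {
  stopifnot(resolution > 0, length(comparison) == 2,
            all(comparison %in% transport_configs()))
  outcome <- match.arg(outcome)
  bb <- region$bbox
  xs <- seq(bb[1] + resolution / 2, bb[2], by = resolution)
  ys <- seq(bb[3] + resolution / 2, bb[4], by = resolution)
  grid <- expand.grid(x = xs, y = ys)
  pts <- tibble::tibble(address_id = seq_len(nrow(grid)),
                        municipality_id = municipality_of(region, grid),
                        x = grid$x, y = grid$y)
  ev <- evaluate_transport(pts, region, ground, air, delays, period)
  v <- ev[[outcome]]
  a <- v[ev$configuration == comparison[1]]
  b <- v[ev$configuration == comparison[2]]
  tibble::tibble(x = pts$x, y = pts$y, minutes_diff = a - b)
}

#' Export a time-difference raster as an ESRI-ASCII-style text grid
#'
#' @param grid output of [time_saved_grid()].
#' @param file path to write.
#' @return the file path, invisibly.
#' @export
write_ascii_grid <- function(grid, file) {
  xs <- sort(unique(grid$x)); ys <- sort(unique(grid$y))
  cell <- if (length(xs) > 1) xs[2] - xs[1] else 1
  m <- matrix(NA_real_, nrow = length(ys), ncol = length(xs))
  m[cbind(match(grid$y, ys), match(grid$x, xs))] <- grid$minutes_diff
  hdr <- c(sprintf("ncols %d", length(xs)),
           sprintf("nrows %d", length(ys)),
           sprintf("xllcorner %.6f", min(xs) - cell / 2),
           sprintf("yllcorner %.6f", min(ys) - cell / 2),
           sprintf("cellsize %.6f", cell),
           "NODATA_value -9999")
  m[is.na(m)] <- -9999
  lines <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1,
                 function(r) paste(format(r, trim = TRUE), collapse = " "))
  writeLines(c(hdr, lines), file)
  invisible(file)
}
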