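test_that("median_iqr follows the interpolated quartile rule", {
  expect_equal(median_iqr(c(1, 2, 3)),
               c(median = 2, q1 = 1.5, q3 = 2.5))
  expect_equal(median_iqr(c(5, 5, 5, 5)), c(median = 5, q1 = 5, q3 = 5))
  expect_error(median_iqr(numeric(0)), "empty")
  set.seed(61)
  v <- rlnorm(1000, 4, 0.4)
  got <- median_iqr(v)
  expect_equal(unname(got), c(oracle_quantile7(v, 0.5),
                              oracle_quantile7(v, 0.25),
                              oracle_quantile7(v, 0.75)))
})

test_that("median_iqr matches the sort-based oracle on 150 random inputs", {
  set.seed(62)
  for (i in 1:150) {
    n <- sample(2:40, 1)
    v <- round(rnorm(n, 100, 30), sample(0:2, 1))  # ties likely
    got <- median_iqr(v)
    expect_equal(unname(got["median"]), oracle_quantile7(v, 0.5))
    expect_equal(unname(got["q1"]), oracle_quantile7(v, 0.25))
    expect_equal(unname(got["q3"]), oracle_quantile7(v, 0.75))
    expect_lte(got[["q1"]], got[["median"]])
    expect_lte(got[["median"]], got[["q3"]])
  }
})

test_that("spearman_rho is exact on monotone inputs and matches the oracle", {
  expect_equal(spearman_rho(1:10, exp(1:10)), 1)
  expect_equal(spearman_rho(1:10, -(1:10)^3), -1)
  x <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
  y <- c(2, 1, 3, 3, 5, 4, 6, 6, 7, 9)
  expect_equal(spearman_rho(x, y), oracle_spearman(x, y))
  set.seed(63)
  for (i in 1:120) {
    n <- sample(3:25, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- x + sample(-3:3, n, replace = TRUE)
    if (var(rank(x)) == 0 || var(rank(y)) == 0) {
      expect_error(spearman_rho(x, y), "undefined correlation")
    } else {
      expect_equal(spearman_rho(x, y), oracle_spearman(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("signed-rank test matches exhaustive sign-flip enumeration", {
  expect_error(wilcoxon_signed_rank(1:10, 1:10), "degenerate")
  # strong uniform separation is significant
  a <- seq(40, 78, by = 2); b <- seq(10, 29, by = 1)
  expect_lt(wilcoxon_signed_rank(a, b)$p_value, 0.05)
  # n = 6 worked pairs (distinct absolute differences, so the exact
  # distribution applies): exact p equals the 2^6 enumeration
  a6 <- c(10, 14, 9, 20, 30, 12)
  b6 <- c(8, 15, 5, 12, 21, 11.5)
  got <- wilcoxon_signed_rank(a6, b6)
  want <- oracle_wilcoxon_exact(a6 - b6)
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$p_value, want$p_value)
  # randomized small inputs with distinct absolute differences
  set.seed(64)
  for (i in 1:110) {
    n <- sample(6:11, 1)
    d <- sample(c(-1, 1), n, replace = TRUE) * sample(seq_len(50), n) / 4
    got <- wilcoxon_signed_rank(d, rep(0, n))
    want <- oracle_wilcoxon_exact(d)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("number needed to fly floors the reciprocal risk difference", {
  expect_equal(number_needed_to_fly(0.29, 0.32), 33L)
  expect_equal(number_needed_to_fly(0.5, 0.75), 4L)
  expect_equal(number_needed_to_fly(0.29, 0.31), 50L)
  expect_error(number_needed_to_fly(0.3, 0.3), "infinite")
  set.seed(65)
  for (i in 1:50) {
    p <- runif(2)
    if (p[1] != p[2])
      expect_equal(number_needed_to_fly(p[1], p[2]),
                   number_needed_to_fly(p[2], p[1]))
  }
})

test_that("outcome probability defaults give the headline NNF values", {
  p <- outcome_probabilities()
  expect_equal(number_needed_to_fly(p[["DRIP_SHIP_GROUND"]],
                                    p[["BYPASS_HELI"]]), 33L)
  expect_equal(number_needed_to_fly(p[["DRIP_SHIP_GROUND"]],
                                    p[["BYPASS_GROUND"]]), 50L)
})

test_that("summary table reduces to the address totals for a single address", {
  r <- default_test_region()
  ad <- sample_addresses(r, 1, seed = 2)
  one <- ad[which.max(ad$x), ]  # far east: surely in some catchment
  ev <- evaluate_transport(one, r, periods = "MIDDAY")
  if (ev$nearest_is_psc[1]) {
    tab <- table1_summary(r, one, periods = "MIDDAY")
    for (cf in transport_configs()) {
      row <- tab[tab$configuration == cf & tab$outcome == "onset_to_EVT", ]
      expect_equal(row$median,
                   ev$onset_to_groin[ev$configuration == cf])
      expect_equal(row$q1, row$median)
    }
  }
  # degenerate co-located region: ground IVT floor of 86 min
  fac <- data.frame(role = c("PSC", "CSC", "HELI_BASE"),
                    x = 300, y = 200)
  r0 <- manual_region(fac)
  a0 <- tibble::tibble(address_id = 1L, municipality_id = 1L, x = 300, y = 200)
  t0 <- table1_summary(r0, a0, unit_ground(), periods = "MIDDAY")
  ivt_ground <- t0[t0$configuration == "DRIP_SHIP_GROUND" &
                   t0$outcome == "onset_to_IVT", ]
  expect_equal(ivt_ground$median, 86)
})

test_that("bypass EVT-IVT gap of 41 min propagates to the summary medians", {
  r <- default_test_region()
  ad <- sample_addresses(r, 2, seed = 8)
  tab <- table1_summary(r, ad)
  for (cf in c("BYPASS_GROUND", "BYPASS_HELI")) {
    ivt <- tab[tab$configuration == cf & tab$outcome == "onset_to_IVT", ]
    evt <- tab[tab$configuration == cf & tab$outcome == "onset_to_EVT", ]
    expect_equal(evt$median - ivt$median, 41)
    expect_equal(evt$q1 - ivt$q1, 41)
  }
})

test_that("time-saved raster is zero on self-comparison and -33 at a CSC", {
  fac <- data.frame(role = c("PSC", "CSC", "HELI_BASE"),
                    x = c(25, 25, 25), y = c(25, 25, 25))
  r0 <- manual_region(fac, width = 50, height = 50)
  self <- time_saved_grid(r0, unit_ground(), resolution = 50,
                          comparison = c("BYPASS_GROUND", "BYPASS_GROUND"))
  expect_equal(self$minutes_diff, 0)
  # single 50-km cell centred on the co-located facilities:
  # bypass-ground minus drip-and-ship = -(60 + 41 - 68) = -33
  at_csc <- time_saved_grid(r0, unit_ground(), resolution = 50,
                            comparison = c("BYPASS_GROUND",
                                           "DRIP_SHIP_GROUND"))
  expect_equal(nrow(at_csc), 1)
  expect_equal(at_csc$x, 25)
  expect_equal(at_csc$minutes_diff, -33)
})

test_that("helicopter advantage grows with distance past the viability range", {
  # CSC, PSC and base at the origin end of a long strip: along the ray the
  # bypass-helicopter advantage over bypass-ground increases monotonically
  fac <- data.frame(role = c("CSC", "PSC", "HELI_BASE"),
                    x = c(0, 0, 0), y = c(100, 100, 100))
  r <- manual_region(fac, width = 600, height = 200)
  xs <- seq(100, 550, by = 50)
  delta <- vapply(xs, function(x) {
    p <- c(x, 100)
    bypass_heli_chain(p, r, unit_ground())$onset_to_groin -
      ground_chain(p, "CSC", r, unit_ground())$onset_to_groin
  }, 0)
  expect_true(all(diff(delta) < 0))
  grd <- vapply(xs, function(x)
    ground_time(c(x, 100), c(0, 100), unit_ground()), 0)
  expect_true(all(grd >= 28))  # all sampled points are helicopter-viable
})

test_that("ascii grid export round-trips the raster values", {
  r <- default_test_region()
  g <- time_saved_grid(r, resolution = 60)
  f <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^ncols", lines)), 1)
  body <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  expect_equal(sort(as.numeric(body[body != -9999])),
               sort(g$minutes_diff), tolerance = 1e-6)
})
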