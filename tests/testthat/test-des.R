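# Minimal mission tibble builder for engine-level tests.
mk_missions <- function(arrival, x = 0, y = 0, dest_x = 0, dest_y = 0,
                        duration = NULL) {
  n <- length(arrival)
  m <- tibble::tibble(mission_id = seq_len(n), arrival_min = arrival,
                      x = rep_len(x, n), y = rep_len(y, n),
                      municipality_id = 1L, kind = "STROKE_CODE",
                      dest_fid = 1L, dest_x = rep_len(dest_x, n),
                      dest_y = rep_len(dest_y, n))
  if (!is.null(duration)) m$duration <- rep_len(duration, n)
  m
}

one_base_region <- function(nb = 1) {
  fac <- data.frame(role = c("CSC", rep("HELI_BASE", nb)),
                    x = c(0, seq(0, by = 50, length.out = nb)), y = 0)
  manual_region(fac)
}

test_that("mission generation matches its Poisson intensity", {
  r <- default_test_region()
  # zone cutoffs nest the eligible municipality sets
  tt <- helistroke:::municipality_shs_times(r)
  zl <- which(tt$ground_to_shs >= catchment_zones()[["LARGE"]])
  zm <- which(tt$ground_to_shs >= catchment_zones()[["MIDDLE"]])
  zs <- which(tt$ground_to_shs >= catchment_zones()[["SMALL"]])
  expect_true(all(zs %in% zm), all(zm %in% zl))
  expect_gt(length(zl), length(zs))

  # zero rates give an empty stream
  r0 <- r
  r0$municipalities$annual_stroke_codes <- 0
  expect_equal(nrow(generate_missions(r0, "LARGE", horizon_days = 2,
                                      other_acute_per_day = 0, seed = 1)), 0)

  # observed counts within 3 sigma of the Poisson expectation (100 seeds)
  horizon <- 2
  rate_day <- sum(r$municipalities$annual_stroke_codes[zl]) * 0.12 / 365 + 7
  lambda <- rate_day * horizon * 100
  n_tot <- sum(vapply(1:100, function(s)
    nrow(generate_missions(r, "LARGE", horizon, other_acute_per_day = 7,
                           lvo_share = 0.12, seed = s)), 0L))
  expect_lt(abs(n_tot - lambda), 3 * sqrt(lambda))

  # only eligible municipalities produce stroke codes; arrivals are sorted
  mi <- generate_missions(r, "SMALL", horizon_days = 30, seed = 3)
  expect_true(all(mi$municipality_id[mi$kind == "STROKE_CODE"] %in% zs))
  expect_true(!is.unsorted(mi$arrival_min))

  # no eligible municipalities: empty stream with a warning
  rr <- r
  expect_warning(
    out <- generate_missions(rr, "SMALL", 2, seed = 1,
                             ground = ground_model(base_speed_kmh = 2000)),
    "empty mission stream")
  expect_equal(nrow(out), 0)
})

test_that("mission duration composes the flight legs or uses the fixed average", {
  expect_equal(mission_duration(list(x = 0, y = 0, dest_x = 999, dest_y = 0),
                                list(x = 5, y = 5),
                                fleet_config(service_mode = "FIXED_AVERAGE")),
               165)
  fl0 <- fleet_config(service_mode = "COMPUTED", handover_minutes = 0)
  expect_equal(mission_duration(list(x = 0, y = 0, dest_x = 0, dest_y = 0),
                                list(x = 0, y = 0), fl0), 16)
  # origin 40 km from base, SHS 80 km from origin, base 100 km from SHS:
  # 5 + 10 + 11 + 20 + 15 + 25 = 86
  fl <- fleet_config(service_mode = "COMPUTED", handover_minutes = 15)
  req <- list(x = 40, y = 0, dest_x = 65, dest_y = sqrt(5775))
  base <- list(x = 0, y = 0)
  expect_equal(euclid_for_tests(c(req$dest_x, req$dest_y), c(req$x, req$y)), 80)
  expect_equal(euclid_for_tests(c(req$dest_x, req$dest_y), c(0, 0)), 100)
  expect_equal(mission_duration(req, base, fl), 86)
})

test_that("simulator handles trivial streams and the two-mission hand trace", {
  r1 <- one_base_region(1)
  # zero missions
  res0 <- simulate_fleet(mk_missions(numeric(0)), r1)
  expect_equal(c(res0$n_requests, res0$n_served, res0$n_queued,
                 res0$n_rejected), c(0L, 0L, 0L, 0L))
  # one mission, idle fleet, full availability
  res1 <- simulate_fleet(mk_missions(10), r1, fleet_config(availability = 1))
  expect_equal(res1$n_served, 1L)
  expect_equal(res1$n_queued, 0L)
  expect_equal(res1$waits, 0)
  # two simultaneous missions, one helicopter, 165-min service:
  # the second passes 15 min (queued) then 60 min (rejected)
  res2 <- simulate_fleet(mk_missions(c(0, 0)), r1,
                         fleet_config(availability = 1),
                         queue_policy(15, 60))
  expect_equal(res2$n_served, 1L)
  expect_equal(res2$n_queued, 1L)
  expect_equal(res2$n_rejected, 1L)
  expect_equal(res2$n_served + res2$n_rejected, res2$n_requests)
})

test_that("counter conservation holds on stochastic replicates", {
  r <- default_test_region()
  for (s in 1:5) {
    mi <- generate_missions(r, "LARGE", horizon_days = 20, seed = s)
    res <- simulate_fleet(mi, r, fleet_config(), queue_policy(), seed = s)
    expect_equal(res$n_served + res$n_rejected, res$n_requests)
    expect_gte(res$n_queued, res$n_rejected)  # rejected were queued first
    expect_true(all(res$utilization$utilization >= 0 &
                    res$utilization$utilization <= 1))
  }
})

test_that("utilization matches the offered load when nothing is lost", {
  # single base, 2 units, availability 1, no rejection: rho = lambda*E[S]/c
  r1 <- one_base_region(1)
  set.seed(55)
  lambda <- 1 / 60; mean_s <- 50; c_units <- 2
  arr <- cumsum(rexp(4000, lambda))
  mi <- mk_missions(arr, duration = NULL)
  mi$duration <- rexp(4000, 1 / mean_s)
  res <- simulate_fleet(mi, r1, fleet_config(c_units, availability = 1),
                        queue_policy(15, Inf), seed = 1,
                        horizon_minutes = max(arr))
  rho <- lambda * mean_s / c_units
  expect_equal(res$utilization$utilization, rho, tolerance = 0.05)
  expect_equal(res$n_rejected, 0L)
})

test_that("simulation output is bit-identical for a fixed seed", {
  r <- default_test_region()
  mi <- generate_missions(r, "LARGE", horizon_days = 30, seed = 7)
  mi2 <- generate_missions(r, "LARGE", horizon_days = 30, seed = 7)
  expect_identical(mi, mi2)
  a <- simulate_fleet(mi, r, fleet_config(), queue_policy(), seed = 7)
  b <- simulate_fleet(mi, r, fleet_config(), queue_policy(), seed = 7)
  expect_identical(a, b)
})

test_that("scenario sweep has the right shape and paired monotonicity", {
  r <- default_test_region()
  sw <- scenario_sweep(r, n_reps = 6, horizon_days = 10, seed = 11)
  expect_equal(nrow(sw), 6 * 6)  # 3 zones x 2 fleet sizes x 6 reps
  expect_setequal(unique(sw$zone), c("LARGE", "MIDDLE", "SMALL"))
  wide <- merge(sw[sw$helicopters_per_base == 1, ],
                sw[sw$helicopters_per_base == 2, ],
                by = c("zone", "replicate"), suffixes = c("_1", "_2"))
  # doubling the fleet never increases rejected or queued counts
  expect_true(all(wide$n_rejected_2 <= wide$n_rejected_1))
  expect_true(all(wide$n_queued_2 <= wide$n_queued_1))
  # demand grows with the helicopter zone: LARGE serves at least as many
  # requests, and rejected counts are non-decreasing from SMALL to LARGE
  z <- merge(sw[sw$zone == "SMALL", ], sw[sw$zone == "LARGE", ],
             by = c("helicopters_per_base", "replicate"),
             suffixes = c("_s", "_l"))
  expect_true(all(z$n_requests_l >= z$n_requests_s))
  expect_true(all(z$n_rejected_l >= z$n_rejected_s))
  # single replicate gives the single 6-cell grid
  expect_equal(nrow(scenario_sweep(r, n_reps = 1, horizon_days = 5,
                                   seed = 2)), 6)
})

test_that("an all-refusing draw stream still terminates via rejection", {
  r1 <- one_base_region(1)
  res <- simulate_fleet(mk_missions(c(0, 1)), r1,
                        fleet_config(availability = 1e-9),
                        queue_policy(15, 60), seed = 3)
  expect_equal(res$n_rejected, 2L)
  expect_equal(res$n_served + res$n_rejected, res$n_requests)
})
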