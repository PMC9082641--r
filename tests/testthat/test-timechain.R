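test_that("delay table defaults compose the 28-min air-transport floor", {
  d <- delay_table()
  expect_equal(d$min_call_to_air, 28)
  expect_equal(d$min_call_to_air, d$ambulance_response + d$on_scene)
  expect_error(delay_table(onset_to_call = -1), "must be >= 0")
  expect_error(delay_table(door_to_groin_bypass = 20), "must exceed")
})

# Line geometry used for hand traces: patient at x = 0 on the midline.
line_region <- function(psc_km = NULL, csc_km = NULL, base_km = NULL) {
  fac <- rbind(
    if (!is.null(csc_km)) data.frame(role = "CSC", x = csc_km, y = 200),
    if (!is.null(psc_km)) data.frame(role = "PSC", x = psc_km, y = 200),
    if (!is.null(base_km)) data.frame(role = "HELI_BASE", x = base_km, y = 200)
  )
  manual_region(fac, width = 600, height = 400)
}
P <- c(0, 200)

test_that("ground chain reproduces the drip-and-ship worked example", {
  # scene-to-PSC ground time 26 min: onset-to-needle 30+1+8+20+26+27 = 112
  r <- line_region(psc_km = 26, csc_km = 50)
  bd <- ground_chain(P, "PSC", r, unit_ground())
  expect_equal(bd$onset_to_needle, 112)
  expect_equal(bd$needle_site, "PSC")
  # co-located patient: 86 min floor
  r0 <- line_region(psc_km = 0, csc_km = 0)
  expect_equal(ground_chain(P, "PSC", r0, unit_ground())$onset_to_needle, 86)
  # bypass by ground with 50 min to CSC: groin 30+1+8+20+50+68 = 177
  bg <- ground_chain(P, "CSC", r, unit_ground())
  expect_equal(bg$onset_to_groin, 177)
  expect_equal(bg$onset_to_needle, 136)
})

test_that("helicopter pickup departs at max(arrival, readiness) plus loading", {
  d <- delay_table()
  base40 <- list(x = 40, y = 200)   # 10 min flight at 240 km/h
  pk <- heli_pickup(P, base40, d)
  expect_equal(pk$heli_arrival, 15)
  expect_equal(pk$scene_departure, 39)  # 28 + 11
  base240 <- list(x = 240, y = 200)     # 60 min flight: helicopter is limiting
  pk2 <- heli_pickup(P, base240, d)
  expect_equal(pk2$heli_arrival, 65)
  expect_equal(pk2$scene_departure, 76)
  # degenerate delays: departure reduces to the dispatch time
  d0 <- delay_table(min_call_to_air = 0, heli_loading = 0)
  pk3 <- heli_pickup(P, list(x = 0, y = 200), d0)
  expect_equal(pk3$scene_departure, d0$heli_dispatch)
})

test_that("bypass helicopter chain composes pickup, flight and door delays", {
  r <- line_region(csc_km = 80, base_km = 40)
  bd <- bypass_heli_chain(P, r)
  # 30 + (28 + 11) + 20 + 27 = 116 needle; groin swaps 27 for 68
  expect_equal(bd$onset_to_needle, 116)
  expect_equal(bd$onset_to_groin, 157)
  expect_equal(bd$onset_to_groin - bd$onset_to_needle, 41)
})

test_that("drip-and-ship chain adds DIDO, transfer and dripship groin delay", {
  # needle chain 85 + 27; groin = 85 + 60 + 48 + 41 = 234
  r <- line_region(psc_km = 26, csc_km = 74)
  bd <- dripship_chain(P, r, unit_ground(), transfer_mode = "GROUND")
  expect_equal(bd$onset_to_needle, 112)
  expect_equal(bd$onset_to_groin, 234)
  # PSC co-located with CSC: groin = needle + 74
  r0 <- line_region(psc_km = 30, csc_km = 30)
  b0 <- dripship_chain(P, r0, unit_ground(), transfer_mode = "GROUND")
  expect_equal(b0$onset_to_groin, b0$onset_to_needle + 74)
  # helicopter transfer: 5 + air(base->PSC 20 km) + air(PSC->CSC 60 km)
  rh <- line_region(psc_km = 0, csc_km = 60, base_km = -20)
  bh <- dripship_chain(P, rh, unit_ground(), transfer_mode = "HELI")
  transfer <- sum(bh$components$minutes[bh$components$component %in%
    c("heli_dispatch", "flight_base_to_PSC", "flight_PSC_to_CSC")])
  expect_equal(transfer, 25)  # 5 + 5 + 15
  expect_equal(bh$onset_to_groin, bh$onset_to_needle - 27 + 60 + transfer + 41)
})

test_that("helicopter viability uses a strict-below-cutoff exclusion", {
  expect_false(helicopter_viable(P, line_region(csc_km = 10), unit_ground()))
  expect_true(helicopter_viable(P, line_region(csc_km = 120), unit_ground()))
  # boundary: ground time exactly 28 -> helicopter allowed
  expect_true(helicopter_viable(P, line_region(csc_km = 28), unit_ground()))
  expect_false(helicopter_viable(P, line_region(csc_km = 27.99), unit_ground()))
})

test_that("AHA bypass rule compares CSC and PSC ground times strictly", {
  mk <- function(csc) line_region(psc_km = 10, csc_km = csc)
  expect_true(aha_bypass_rule(P, mk(5), unit_ground()))      # CSC nearer
  expect_false(aha_bypass_rule(P, mk(25), unit_ground()))    # diff exactly 15
  expect_true(aha_bypass_rule(P, mk(24.9), unit_ground()))   # diff 14.9
})

test_that("every breakdown total equals the sum of its components", {
  r <- default_test_region()
  set.seed(41)
  pts <- cbind(runif(25, r$bbox[1], r$bbox[2]),
               runif(25, r$bbox[3], r$bbox[4]))
  for (i in seq_len(nrow(pts))) {
    for (bd in list(ground_chain(pts[i, ], "CSC", r),
                    bypass_heli_chain(pts[i, ], r),
                    dripship_chain(pts[i, ], r, transfer_mode = "GROUND"),
                    dripship_chain(pts[i, ], r, transfer_mode = "HELI"))) {
      cmp <- bd$components
      expect_equal(bd$onset_to_needle, sum(cmp$minutes[cmp$in_needle]),
                   tolerance = 1e-9)
      expect_equal(bd$onset_to_groin, sum(cmp$minutes[cmp$in_groin]),
                   tolerance = 1e-9)
    }
  }
})

test_that("vectorized evaluation agrees with the single-address chains", {
  r <- default_test_region()
  ad <- sample_addresses(r, 1, seed = 9)[1:12, ]
  for (period in c("MIDDAY", "NIGHT")) {
    ev <- evaluate_transport(ad, r, periods = period)
    for (i in seq_len(nrow(ad))) {
      p <- c(ad$x[i], ad$y[i])
      byconf <- function(conf) ev[ev$address_id == ad$address_id[i] &
                                  ev$configuration == conf, ]
      expect_equal(byconf("BYPASS_GROUND")$onset_to_groin,
                   ground_chain(p, "CSC", r, period = period)$onset_to_groin)
      expect_equal(byconf("BYPASS_HELI")$onset_to_needle,
                   bypass_heli_chain(p, r, period = period)$onset_to_needle)
      expect_equal(byconf("DRIP_SHIP_GROUND")$onset_to_groin,
                   dripship_chain(p, r, period = period,
                                  transfer_mode = "GROUND")$onset_to_groin)
      expect_equal(byconf("DRIP_SHIP_HELI_TRANSFER")$onset_to_groin,
                   dripship_chain(p, r, period = period,
                                  transfer_mode = "HELI")$onset_to_groin)
    }
  }
})

test_that("bypass needle time never increases with cruise speed", {
  r <- default_test_region()
  p <- c(50, 50)
  speeds <- c(180, 240, 300, 360)
  needles <- vapply(speeds, function(s)
    bypass_heli_chain(p, r, air = air_model(s))$onset_to_needle, 0)
  expect_true(all(diff(needles) <= 1e-12))
})

test_that("off-hours closure of the hybrid centre lengthens some CSC trips", {
  r <- default_test_region()
  ad <- sample_addresses(r, 3, seed = 4)
  ev_day <- evaluate_transport(ad, r, periods = "MIDDAY")
  ev_night <- evaluate_transport(ad, r, periods = "NIGHT")
  d_day <- ev_day$ground_to_csc[ev_day$configuration == "BYPASS_GROUND"]
  d_night <- ev_night$ground_to_csc[ev_night$configuration == "BYPASS_GROUND"]
  expect_true(all(d_night >= d_day - 1e-9))
  expect_gt(sum(d_night > d_day + 1e-9), 0)
})
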