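# helper to build a constant-rate series with optional gaps cut out
make_series <- function(hours, o2 = 1.0, co2 = 0.9, cage = "c1",
                        start = as.POSIXct("2023-06-01 00:00:00", tz = "UTC")) {
  times <- seq(start, by = 300, length.out = hours * 12)
  data.frame(timestamp = times, cage_id = cage,
             o2_ml_min = o2, co2_ml_min = co2,
             water_g = seq(250, by = -0.01, length.out = length(times)),
             food_g = seq(400, by = -0.005, length.out = length(times)),
             stringsAsFactors = FALSE)
}

cut_gap <- function(s, from_h, minutes) {
  gs <- s$timestamp[1] + from_h * 3600
  s[!(s$timestamp > gs & s$timestamp < gs + minutes * 60), , drop = FALSE]
}

test_that("gap filling obeys the duration rules and never alters observations", {
  s <- make_series(30)
  # 45-min gap after 10 h of constant 1.0 ml/min -> filled at 1.0
  g1 <- cut_gap(s, 10, 45)
  f1 <- fill_gaps(g1)
  filled <- f1$series[f1$series$filled, ]
  expect_equal(nrow(filled), 8)  # 45 min at 5-min cadence, endpoints observed
  expect_true(all(filled$o2_ml_min == 1.0))
  expect_equal(f1$gaps$action, "filled_short")
  # observed records untouched, counts restored to nominal cadence
  expect_identical(f1$series[!f1$series$filled, "o2_ml_min"], g1$o2_ml_min)
  expect_equal(nrow(f1$series), nrow(s))
  # 20-min gap -> nothing inserted
  g2 <- cut_gap(s, 10, 20)
  f2 <- fill_gaps(g2)
  expect_equal(sum(f2$series$filled), 0)
  expect_equal(f2$gaps$action, "left_missing")
})

test_that("long gaps use the previous 24 h of observed records only", {
  # 0.97 ml/min for 24 h, then a step to 1.5 just before a 120-min gap
  s <- make_series(40, o2 = 0.97)
  s$o2_ml_min[s$timestamp >= s$timestamp[1] + 26 * 3600] <- 1.5
  g <- cut_gap(s, 26, 120)
  f <- fill_gaps(g)
  filled <- f$series[f$series$filled, ]
  look <- g$o2_ml_min[g$timestamp > g$timestamp[1] + 2 * 3600 &
                        g$timestamp <= g$timestamp[1] + 26 * 3600]
  expect_equal(unique(filled$o2_ml_min), mean(look), tolerance = 1e-12)
  expect_equal(f$gaps$action, "filled_long")
  # filled records never feed later fills: a second gap after the first
  g2 <- cut_gap(cut_gap(s, 26, 120), 30, 45)
  expect_no_error(fill_gaps(g2))
})

test_that("gap at the series start with no usable lookback is left unfilled", {
  s <- make_series(10)
  g <- rbind(s[1, ], s[-(1:12), ])          # single leading record, 55-min gap
  g$o2_ml_min[1] <- NA                      # and its rate is unusable
  expect_warning(f <- fill_gaps(g), "no lookback")
  expect_equal(sum(f$series$filled), 0)
  expect_true("unfillable" %in% f$gaps$action)
})

test_that("water leakage correction and unrealistic-day replacement", {
  expect_equal(correct_water_intake(11.6), 10.44)
  expect_equal(correct_water_intake(0), 0)
  expect_equal(correct_water_intake(5, 0), 5)
  expect_error(correct_water_intake(5, 1), "leakage_fraction")
  daily <- data.frame(date = as.Date("2023-06-01") + 0:3, cage_id = "c1",
                      water_ml = c(2.4, 2.5, 25.0, 2.3),
                      food_g = c(3.5, 3.4, 30, 3.6), flags = "")
  out <- replace_unrealistic(daily)
  expect_equal(out$water_ml[3], mean(c(2.4, 2.5, 2.3)))
  expect_equal(out$food_g[3], mean(c(3.5, 3.4, 3.6)))
  expect_match(out$flags[3], "replaced_outlier")
  # below-threshold data pass through unchanged
  clean <- daily; clean$water_ml[3] <- 2.6; clean$food_g[3] <- 3.3
  expect_equal(replace_unrealistic(clean), clean)
  allbad <- daily; allbad$water_ml <- 25
  expect_error(replace_unrealistic(allbad), "no replacement basis")
})

test_that("window totals integrate rates and are additive across windows", {
  s <- make_series(96, o2 = 0.95, co2 = 0.95 * 0.87)
  daily <- data.frame(date = as.Date("2023-06-01") + 0:3, cage_id = "c1",
                      water_ml = 2.42, food_g = 3.48, flags = "")
  end <- s$timestamp[1] + 96 * 3600
  tot <- window_totals(s, daily, end, 96)
  expect_equal(tot$o2_ml, 0.95 * 60 * 96, tolerance = 1e-9)
  expect_equal(tot$co2_mol, 0.95 * 0.87 * 60 * 96 / 22400, tolerance = 1e-9)
  expect_equal(tot$water_ml, 4 * 2.42, tolerance = 1e-12)
  expect_equal(tot$food_kg, 4 * 3.48 / 1000, tolerance = 1e-12)
  # additivity: (0,48] + (48,96] = (0,96]
  t1 <- window_totals(s, daily, s$timestamp[1] + 48 * 3600, 48)
  t2 <- window_totals(s, daily, end, 48)
  expect_equal(t1$o2_ml + t2$o2_ml, tot$o2_ml, tolerance = 1e-9)
  expect_equal(t1$water_ml + t2$water_ml, tot$water_ml, tolerance = 1e-12)
  # zero-length window gives zero totals
  t0 <- window_totals(s, daily, end, 0)
  expect_equal(c(t0$o2_ml, t0$co2_mol, t0$food_kg, t0$water_ml), rep(0, 4))
  # uncovered window errors with the missing span counted
  expect_error(window_totals(s[1:100, ], daily, end, 96), "not covered")
})

test_that("the QC chain is idempotent", {
  daily <- data.frame(date = as.Date("2023-06-01") + 0:3, cage_id = "c1",
                      water_ml = c(2.4, 2.5, 25.0, 2.3),
                      food_g = c(3.5, 3.4, 3.3, 3.6), flags = "")
  once <- replace_unrealistic(daily)
  once$water_ml <- correct_water_intake(once$water_ml)
  twice <- replace_unrealistic(once)
  expect_equal(twice$water_ml, once$water_ml)
  expect_equal(twice$food_g, once$food_g)
})
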