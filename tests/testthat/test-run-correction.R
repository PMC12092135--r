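test_that("two-point correction solves the standards exactly", {
  # pre-calibrated instrument: raw means equal known values
  waters <- run_waters()
  run <- simulate_analysis_run(waters, sigma_d18O = 0, sigma_cap_permeg = 0,
                               seed = 3)
  cm <- fit_correction(run, standard_defs(waters))
  expect_equal(cm$stretching, rep(1, 3), tolerance = 1e-9)
  expect_equal(cm$offset, rep(0, 3), tolerance = 1e-9)
  # textbook two-point solve for d18O
  s <- (-1.60 - (-26.78)) / (-1.00 - (-26.00))
  expect_equal(s, 1.0072)
  expect_equal(-1.60 - s * (-1.00), -0.5928)
  # correction is exact on the standards (by construction, to 1e-12)
  run2 <- simulate_analysis_run(waters, stretching = c(d17O = 1.013, d18O = 1.02, d2H = 1.1),
                                offset = c(d17O = 0.2, d18O = 0.3, d2H = 2),
                                sigma_d18O = 0.05, sigma_cap_permeg = 10, seed = 4)
  cm2 <- fit_correction(run2, standard_defs(waters))
  corr <- apply_correction(run2, cm2)
  for (nm in c("USGS50", "USGS47")) {
    known <- standard_defs(waters)
    expect_equal(mean(corr$d18O[corr$water_id == nm]),
                 known$known_d18O[known$name == nm], tolerance = 1e-12)
    expect_equal(mean(corr$d17O[corr$water_id == nm]),
                 known$known_d17O[known$name == nm], tolerance = 1e-12)
  }
  expect_error(fit_correction(run[run$water_id != "USGS47", ],
                              standard_defs(waters)), "missing")
})

test_that("a known stretch/offset is recovered from a synthetic run", {
  waters <- run_waters()
  run <- simulate_analysis_run(waters,
                               stretching = c(d17O = 1.02, d18O = 1.02, d2H = 1.02),
                               offset = c(d17O = 0.3, d18O = 0.3, d2H = 0.3),
                               sigma_d18O = 0, sigma_cap_permeg = 0, seed = 5)
  cm <- fit_correction(run, standard_defs(waters))
  expect_equal(cm$stretching, rep(1.02, 3), tolerance = 1e-10)
  expect_equal(cm$offset, rep(0.3, 3), tolerance = 1e-10)
  # with injection noise, recovery to ~1e-3
  runN <- simulate_analysis_run(waters,
                                stretching = c(d17O = 1.02, d18O = 1.02, d2H = 1.02),
                                offset = c(d17O = 0.3, d18O = 0.3, d2H = 0.3),
                                sigma_d18O = 0.05, seed = 6)
  cmN <- fit_correction(runN, standard_defs(waters))
  expect_equal(cmN$stretching[cmN$isotope == "d18O"], 1.02, tolerance = 5e-3)
  expect_equal(cmN$offset[cmN$isotope == "d18O"], 0.3, tolerance = 0.1)
})

test_that("water summaries drop displaced injections and report moments", {
  waters <- run_waters()
  run <- simulate_analysis_run(waters, sigma_d18O = 0, sigma_cap_permeg = 0,
                               seed = 7)
  cm <- fit_correction(run, standard_defs(waters))
  # identical injections: mean is the value, SD 0, none removed
  s <- summarize_water(run, "ctrl1", cm)
  expect_equal(s$mean_d18O, -2, tolerance = 1e-9)
  expect_equal(s$sd_d18O, 0)
  expect_equal(s$n_d18O, sum(run$water_id == "ctrl1"))
  # 7 injections with one displaced by +10 SD: that one is removed
  inj <- data.frame(run_id = "r", water_id = "w", water_role = "sample",
                    replicate_id = 1,
                    raw_d17O = c(rnorm(6, -1, 0.02), -1),
                    raw_d18O = c(rnorm(6, -2, 0.05), -2 + 10 * 0.05),
                    raw_d2H = -6)
  s2 <- summarize_water(inj, "w", cm)
  expect_equal(s2$n_d18O, 6)
  expect_lt(abs(s2$mean_d18O - mean(apply_correction(inj, cm)$d18O[1:6])), 1e-9)
  expect_error(summarize_water(run[1:2, ], run$water_id[1], cm), "at least 3")
})

test_that("outlier flagging is single-pass and capped at 20%", {
  x <- c(rnorm(8, 0, 0.01), 5)
  keep <- flag_outliers(x)
  expect_false(keep[9])
  expect_true(all(keep[1:8]))
  # never removes more than 20%: with 5 values, at most 1
  y <- c(0, 0, 0.001, 10, 10)
  expect_gte(sum(flag_outliers(y)), 4)
  expect_true(all(flag_outliers(rep(1, 6))))
})

test_that("the control-water gate rejects only beyond 2 failing controls", {
  waters <- run_waters()
  run <- simulate_analysis_run(waters, sigma_d18O = 0.01,
                               sigma_cap_permeg = 2, seed = 8)
  cm <- fit_correction(run, standard_defs(waters))
  ctl <- control_defs(waters)
  qc0 <- qc_run(run, ctl, cm)
  expect_true(qc0$accepted)
  expect_equal(qc0$n_failing, 0)
  # displace controls one by one by a failing d18O offset
  fail_run <- function(k) {
    r <- run
    for (nm in ctl$name[seq_len(k)])
      r$raw_d18O[r$water_id == nm] <- r$raw_d18O[r$water_id == nm] + 0.5
    qc_run(r, ctl, cm)
  }
  expect_true(fail_run(2)$accepted)     # exactly 2 failing: still accepted
  expect_false(fail_run(3)$accepted)    # 3 failing: rejected
  # monotone: worsening a control of a rejected run never re-accepts it
  r3 <- run
  for (nm in ctl$name[1:3])
    r3$raw_d18O[r3$water_id == nm] <- r3$raw_d18O[r3$water_id == nm] + 0.5
  r4 <- r3
  r4$raw_d18O[r4$water_id == ctl$name[1]] <- r4$raw_d18O[r4$water_id == ctl$name[1]] + 2
  expect_false(qc_run(r4, ctl, cm)$accepted)
})

test_that("grand means are unweighted, permutation-invariant and recompute the excess", {
  reps <- data.frame(mean_d17O = d17O_from_cap(c(-2.0, -2.2, -2.4), 20),
                     mean_d18O = c(-2.0, -2.2, -2.4))
  # d18O spread of 0.4 permil exceeds the 0.3 repeatability: flagged, but the
  # unweighted mean is still returned
  expect_warning(g <- grand_mean(reps), "repeatability")
  expect_equal(g$d18O, -2.2)
  expect_equal(g$n_replicates, 3)
  expect_equal(g$cap17O, cap_delta17(mean(reps$mean_d17O), -2.2),
               tolerance = 1e-9)
  expect_false(g$consistent)
  g2 <- suppressWarnings(grand_mean(reps[c(3, 1, 2), ]))
  expect_equal(g2$d18O, g$d18O)
  # replicates within the repeatability bounds pass the consistency check
  tight <- data.frame(mean_d17O = d17O_from_cap(c(-2.0, -2.1, -2.2), c(18, 20, 22)),
                      mean_d18O = c(-2.0, -2.1, -2.2))
  expect_true(grand_mean(tight)$consistent)
  # single replicate is itself
  expect_equal(grand_mean(reps[1, ])$d18O, -2.0)
  # replicate spread beyond the distillation repeatability warns
  bad <- data.frame(mean_d17O = c(-1.0, -1.5), mean_d18O = c(-2.0, -2.8))
  expect_warning(gb <- grand_mean(bad), "repeatability")
  expect_false(gb$consistent)
  expect_error(grand_mean(reps[0, ]), "no accepted")
})

test_that("drinking-water-grade precision survives the full correction path", {
  # a sample at the drinking-water composition measured with realistic noise
  waters <- run_waters(data.frame(water_id = "dw", water_role = "sample",
                                  d18O = -4, d17O = d17O_from_cap(-4, 20)))
  run <- simulate_analysis_run(waters,
                               stretching = c(d17O = 1.01, d18O = 1.015, d2H = 1.05),
                               offset = c(d17O = 0.1, d18O = 0.15, d2H = 1),
                               sigma_d18O = 0.01, sigma_cap_permeg = 4,
                               n_injections = c(8, 11), seed = 11)
  cm <- fit_correction(run, standard_defs(waters))
  s <- summarize_water(run, "dw", cm)
  expect_equal(s$mean_d18O, -4.0, tolerance = 0.02)
  expect_equal(s$mean_cap17O, 20, tolerance = 6)
})
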