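test_that("calibration fits an exact six-step line perfectly", {
  lv <- data.frame(conc_mM = seq(0, 1, by = 0.2),
                   area = 1000 * seq(0, 1, by = 0.2))
  cal <- fit_calibration(lv, "1b")
  expect_equal(cal$slope, 1000)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$n_levels, 6)
  # round trip conc -> area -> conc
  conc <- c(0, 0.13, 0.5, 0.99)
  expect_equal(conc_from_area(cal, area_from_conc(cal, conc)), conc,
               tolerance = 1e-9)
})

test_that("calibration recovers a known slope from noisy levels", {
  set.seed(21)
  true_slope <- 2500; true_int <- 15
  lv <- data.frame(conc_mM = rep(seq(0, 1, by = 0.2), each = 3))
  lv$area <- true_slope * lv$conc_mM + true_int + rnorm(nrow(lv), sd = 20)
  cal <- fit_calibration(lv, "3b")
  se <- summary(lm(area ~ conc_mM, lv))$coefficients["conc_mM", "Std. Error"]
  expect_lt(abs(cal$slope - true_slope), 3 * se)
  expect_gt(cal$r_squared, 0.99)
})

test_that("degenerate or out-of-range calibrations are flagged", {
  expect_error(fit_calibration(data.frame(conc_mM = 0.5, area = 100)),
               "two distinct")
  expect_error(fit_calibration(data.frame(conc_mM = c(0.5, 0.5),
                                          area = c(100, 110))),
               "two distinct")
  expect_warning(fit_calibration(data.frame(conc_mM = c(0, 2),
                                            area = c(0, 2000))),
                 "range")
  expect_error(conc_from_area(list(slope = 1), 5))
  # negative back-calculated concentrations clip to zero
  cal <- fit_calibration(data.frame(conc_mM = seq(0, 1, 0.2),
                                    area = 50 + 1000 * seq(0, 1, 0.2)))
  expect_equal(conc_from_area(cal, 10), 0)
})

test_that("peaks are assigned to the nearest expected analyte within tolerance", {
  pt <- peak_table(rt_min = c(4.7, 6.0, 4.05), area = c(500, 30, 200))
  out <- assign_peaks(pt, expected = c(`1b` = 4.7, `4b` = 4.0), tol = 0.2)
  expect_equal(out$analyte, c("1b", NA, "4b"))

  # closest peak wins when two candidates compete for one analyte
  pt2 <- peak_table(rt_min = c(4.65, 4.78), area = c(10, 900))
  out2 <- assign_peaks(pt2, expected = c(`1b` = 4.7), tol = 0.2)
  expect_equal(out2$analyte, c("1b", NA))
})

test_that("co-eluting expected analytes raise an ambiguity error", {
  pt <- peak_table(rt_min = 8.2, area = 100)
  expect_error(assign_peaks(pt, expected = c(`3a` = 8.2, `3d` = 8.2)),
               "ambiguous")
  # the shipped panel contains the collision, so per-reaction subsets work
  rt <- retention_times(c("1b", "4b", "3d", "2b"))
  expect_silent(assign_peaks(pt, expected = rt))
})

test_that("conversion percent is exact, scale-invariant and guarded", {
  expect_equal(conversion_percent(4.6, 0.4), 92)
  expect_equal(conversion_percent(0, 1), 0)
  expect_equal(conversion_percent(3, 3), 50)
  expect_equal(conversion_percent(7 * 2.75, 7 * 2.25),
               conversion_percent(2.75, 2.25))
  expect_error(conversion_percent(0, 0), "undefined")
  expect_error(conversion_percent(-1, 1), "non-negative")
})

test_that("dilution correction restores reactor concentrations", {
  expect_equal(correct_dilution(0.25), 5)
  expect_equal(correct_dilution(3.2, 1, 1), 3.2)
  expect_error(correct_dilution(1, 0.5, 10), ">= 1")
  expect_error(correct_dilution(-1), "non-negative")
})

test_that("plateau detection finds equilibrium times and values", {
  # constant series: plateau from the first sample
  tc <- data.frame(time_h = c(0, 1, 2, 4), conversion = rep(55, 4))
  pl <- detect_plateau(tc)
  expect_true(pl$reached)
  expect_equal(pl$time_reached, 0)
  expect_equal(pl$plateau_conversion, 55)

  # saturating series plateaus where changes fall below 2%
  tc2 <- data.frame(time_h = c(0.25, 0.5, 1, 2, 4, 6),
                    conversion = c(20, 40, 54.5, 55.0, 55.3, 55.1))
  pl2 <- detect_plateau(tc2)
  expect_true(pl2$reached)
  expect_equal(pl2$time_reached, 1)
  expect_equal(pl2$plateau_conversion, mean(c(54.5, 55, 55.3, 55.1)))

  # strictly growing, never-saturating series
  tc3 <- data.frame(time_h = 1:6, conversion = c(10, 20, 30, 40, 50, 60))
  pl3 <- detect_plateau(tc3)
  expect_false(pl3$reached)
  expect_equal(pl3$plateau_conversion, 60)

  expect_error(detect_plateau(data.frame(time_h = c(1, 2),
                                         conversion = c(1, 1))),
               "3 time points")
})

test_that("fast synthetic kinetics plateau within an hour at the solver yield", {
  sys <- transglycosylation_system(0.125, 0.071, 5, 5, 2)
  tc <- simulate_time_course(sys, kinetic_params(kf1 = 12, kf2 = 12))
  pl <- detect_plateau(tc, product_id = "N2", substrate_id = "B2")
  expect_true(pl$reached)
  expect_lte(pl$time_reached, 1)
  conv_eq <- 100 * yield_from_state(
    solve_transglycosylation_equilibrium(sys), 5)
  expect_equal(pl$plateau_conversion, conv_eq, tolerance = 0.01)

  # slow kinetics reach the same endpoint later
  tcs <- simulate_time_course(sys, kinetic_params(kf1 = 1.5, kf2 = 1.5))
  pls <- detect_plateau(tcs, product_id = "N2", substrate_id = "B2")
  expect_gt(pls$time_reached, 1)
})

test_that("time-course and peak-table CSVs round-trip", {
  tc <- time_course(c(0, 1, 0, 1), c("3d", "3d", "2b", "2b"),
                    c(0, 2.7, 5, 2.3))
  p1 <- tempfile(fileext = ".csv")
  write_time_course(tc, p1)
  back <- read_time_course(p1)
  expect_equal(back$conc_mM, tc$conc_mM)

  pt <- peak_table(rt_min = c(8.2, 7.0), area = c(120, 340), time_h = 1)
  p2 <- tempfile(fileext = ".csv")
  write_peak_table(pt, p2)
  expect_equal(read_peak_table(p2)$area, pt$area)
})
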