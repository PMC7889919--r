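test_that("ICNIRP local limits reproduce the guideline formula", {
  expect_equal(round(icnirp_local_limit(26), 2), 30.90)
  expect_equal(round(icnirp_local_limit(60), 2), 26.65)
  expect_equal(icnirp_local_limit(26, "occupational") / icnirp_local_limit(26), 5)
  expect_equal(icnirp_local_limit(123, "occupational") / icnirp_local_limit(123), 5)
  f <- seq(6, 300, by = 2)
  expect_true(all(diff(icnirp_local_limit(f)) < 0))
  expect_error(icnirp_local_limit(5), "6-300")
  expect_error(icnirp_local_limit(301), "6-300")
})

test_that("exposure scenarios resolve ICNIRP power densities", {
  sc <- exposure_scenario(26e9, "icnirp_general")
  expect_equal(sc$ipd, icnirp_local_limit(26))
  sc2 <- exposure_scenario(60e9, "icnirp_occupational")
  expect_equal(sc2$ipd, icnirp_local_limit(60, "occupational"))
  expect_error(exposure_scenario(26e9, "nonsense"))
  expect_error(exposure_scenario(26e9, 10, "cheese"))
})

test_that("relative change is the percent difference from the young reference", {
  expect_equal(relative_change(54, 59), 100 * 5 / 54)
  expect_equal(round(relative_change(54, 59), 2), 9.26)
  expect_equal(relative_change(7, 7), 0)
  expect_equal(relative_change(10, 5), -50)
  expect_error(relative_change(0, 5), "zero")
})

test_that("a scenario with no age-dependent factors is constant over age", {
  sc <- exposure_scenario(26e9, 10, factors = character(0))
  sw <- sweep_age(c(5, 35, 70), sc, default_age_tables(), thermal = TRUE)
  for (q in c("tc", "apd", "peak_sar", "peak_delta_T")) {
    expect_equal(diff(range(sw[[q]])), 0, tolerance = 1e-12)
  }
})

test_that("sweeping the adult age reproduces the standalone adult results", {
  sc <- exposure_scenario(26e9, 10,
                          factors = c("thickness", "permittivity", "blood_flow"))
  sw <- sweep_age(35, sc, default_age_tables(), thermal = TRUE)
  st <- build_adult_stack(26e9, age = 35)
  em <- em_result(st, plane_wave(26e9, 10))
  expect_equal(sw$tc, em$tc, tolerance = 1e-10)
  expect_equal(sw$peak_sar, em$peak_sar, tolerance = 1e-8)
  expect_equal(sw$frac_ED, unname(em$fractions["ED"]), tolerance = 1e-10)
  expect_equal(sw$peak_delta_T, temperature_rise(st)$peak$value,
               tolerance = 1e-8)
})

test_that("a single-factor table variation matches the combined scenario", {
  # when only the thickness table actually varies, toggling permittivity and
  # blood flow too must not change anything
  tabs <- make_age_tables(list(
    skin_thickness_mm = data.frame(age = c(5, 35, 70), mean = c(1.0, 1.396, 1.1)),
    tbw = data.frame(age = c(5, 35, 70), mean = c(0.6, 0.6, 0.6)),
    body_weight_kg = data.frame(age = c(5, 35, 70), mean = c(20, 74, 72))))
  ages <- c(5, 35, 70)
  sw_thick <- sweep_age(ages, exposure_scenario(26e9, 10, "thickness"),
                        tabs, thermal = FALSE)
  sw_all <- sweep_age(ages,
                      exposure_scenario(26e9, 10,
                                        c("thickness", "permittivity")),
                      tabs, thermal = FALSE)
  expect_equal(sw_all$tc, sw_thick$tc, tolerance = 1e-12)
  expect_equal(sw_all$peak_sar, sw_thick$peak_sar, tolerance = 1e-12)
})

test_that("age trends on the synthetic fixture match the reported directions", {
  tabs <- default_age_tables()
  for (f in c(26e9, 60e9)) {
    sc <- exposure_scenario(f, 10,
                            c("thickness", "permittivity", "blood_flow"))
    sw <- sweep_age(c(5, 70), sc, tabs, thermal = TRUE)
    expect_gt(sw$tc[2], sw$tc[1])                    # TC rises with age
    expect_gt(sw$apd[2], sw$apd[1])                  # APD follows TC
    expect_lt(sw$peak_sar[2], sw$peak_sar[1])        # peak SAR falls
    expect_gt(sw$peak_delta_T[2], sw$peak_delta_T[1])  # heating rises
    for (q in c("tc", "apd", "peak_sar", "peak_delta_T")) {
      expect_lt(abs(relative_change(sw[[q]][1], sw[[q]][2])), 20)
    }
  }
})

test_that("permittivity-only aging drives TC monotonically upward", {
  sc <- exposure_scenario(26e9, 10, "permittivity")
  sw <- sweep_age(c(5, 20, 35, 50, 70), sc, default_age_tables(),
                  thermal = FALSE)
  expect_true(all(diff(sw$tc) > 0))
})

test_that("Monte Carlo: zero spread collapses to the deterministic result", {
  tabs0 <- make_age_tables(list(
    skin_thickness_mm = data.frame(age = c(5, 70), mean = c(1.396, 1.396),
                                   sd = c(0, 0)),
    tbw = data.frame(age = c(5, 70), mean = c(0.6, 0.6), sd = c(0, 0)),
    body_weight_kg = data.frame(age = c(5, 70), mean = c(74, 74), sd = c(0, 0))))
  sc <- exposure_scenario(26e9, 10)
  set.seed(5)
  mc <- monte_carlo_uncertainty(sc, 35, tabs0, n_trials = 64)
  expect_equal(mc["lo", ], mc["hi", ], tolerance = 1e-12)  # width zero
  st <- build_adult_stack(26e9, age = 35)
  em <- em_result(st, plane_wave(26e9, 10), dz = 20e-6)
  expect_equal(unname(mc["mean", "tc"]), em$tc, tolerance = 1e-12)
  expect_equal(unname(mc["mean", "peak_sar"]), em$peak_sar, tolerance = 1e-12)
})

test_that("Monte Carlo recovers the mean of a linear map of one Gaussian input", {
  tab <- age_table("tbw", data.frame(age = c(5, 70), mean = c(0.6, 0.6),
                                     sd = c(0.02, 0.02)))
  draw_fn <- function(n) data.frame(tbw = sample_individual(tab, 35, n))
  output_fn <- function(d) list(y = 3 + 5 * d$tbw)
  set.seed(21)
  res <- agederm:::.mc_propagate(draw_fn, output_fn, 1e4)
  se <- 5 * 0.02 / sqrt(1e4)
  expect_lt(abs(res["mean", "y"] - (3 + 5 * 0.6)), 3 * se)
  # interval covers ~95%: endpoints near mu +/- 1.96 sd
  expect_equal(unname(res["hi", "y"] - res["lo", "y"]), 2 * 1.96 * 5 * 0.02,
               tolerance = 0.05)
})

test_that("Monte Carlo summaries are reproducible under a fixed seed", {
  sc <- exposure_scenario(26e9, 10)
  set.seed(77)
  a <- monte_carlo_uncertainty(sc, 30, n_trials = 40)
  set.seed(77)
  b <- monte_carlo_uncertainty(sc, 30, n_trials = 40)
  expect_identical(a, b)
})

test_that("shrinking the input spread shrinks the output interval", {
  mk <- function(s) make_age_tables(list(
    skin_thickness_mm = data.frame(age = c(5, 70), mean = c(1.396, 1.396),
                                   sd = c(0.1, 0.1) * s),
    tbw = data.frame(age = c(5, 70), mean = c(0.6, 0.6), sd = c(0.03, 0.03) * s),
    body_weight_kg = data.frame(age = c(5, 70), mean = c(74, 74),
                                sd = c(7, 7) * s)))
  sc <- exposure_scenario(26e9, 10)
  set.seed(13)
  wide <- monte_carlo_uncertainty(sc, 35, mk(1), n_trials = 300)
  set.seed(13)
  narrow <- monte_carlo_uncertainty(sc, 35, mk(0.25), n_trials = 300)
  expect_lt(narrow["hi", "tc"] - narrow["lo", "tc"],
            wide["hi", "tc"] - wide["lo", "tc"])
})

test_that("reports emit consistent percentage tables and survive empty extras", {
  dir <- withr::local_tempdir()
  sc <- exposure_scenario(26e9, 10, c("permittivity"))
  sw <- sweep_age(c(5, 35, 70), sc, default_age_tables(), thermal = FALSE)
  files <- make_report(sw, uncertainty = NULL, dir = dir, prefix = "t")
  pct <- utils::read.csv(file.path(dir, "t_layer_power_pct.csv"))
  expect_true(all(abs(pct$total - 100) < 0.01))
  # round-trip: re-parsed fractions equal the in-memory sweep values
  expect_equal(pct$ED / 100, sw$frac_ED, tolerance = 1e-10)
  rc <- utils::read.csv(file.path(dir, "t_relative_change.csv"))
  expect_equal(rc$change_pct[rc$quantity == "tc"],
               relative_change(sw$tc[1], sw$tc[3]), tolerance = 1e-10)
})
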