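test_that("noiseless two-regime series recovers the CAC exactly", {
  s <- synth_cac_series(cac = 2.1e-4, noise_level = 0)
  res <- fit_cac(s)
  expect_equal(res$cac, 2.1e-4, tolerance = 1e-9)
  expect_equal(res$post_slope, 1, tolerance = 1e-9)
  expect_equal(res$pre_level, 1, tolerance = 1e-9)  # log10(10 kcps)
  expect_equal(res$rss, 0, tolerance = 1e-18)
})

test_that("CAC estimation tolerates 5% multiplicative noise (simulation)", {
  errs <- vapply(1:20, function(seed) {
    s <- synth_cac_series(cac = 2.1e-4, n = 12, noise_level = 0.05, seed = seed)
    abs(log10(fit_cac(s)$cac / 2.1e-4))
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("fit_cac is exactly scale-equivariant", {
  s <- synth_cac_series(cac = 2.1e-4, noise_level = 0.05, seed = 7)
  base <- fit_cac(s)
  for (cs in c(0.1, 3, 100)) {
    scaled <- concentration_series(s$concentration * cs, s$response)
    expect_equal(fit_cac(scaled)$cac, base$cac * cs, tolerance = 1e-12)
  }
})

test_that("degenerate CAC inputs raise classed errors", {
  flat <- synth_cac_series(post_slope = 0, noise_level = 0)
  expect_error(fit_cac(flat), class = "mesosaxs_no_aggregation_error")
  narrow <- concentration_series(10^seq(-4, -3.5, length.out = 6), 1:6)
  expect_error(fit_cac(narrow), class = "mesosaxs_validation_error")
})

test_that("calibration fit and inversion", {
  std <- synth_assay_data("calibration", params = list(slope = 2))
  cal <- fit_calibration(std)
  expect_equal(cal$slope, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  inv <- quantify_concentration(cal, 1.0)
  expect_equal(inv$concentration, 0.5, tolerance = 1e-12)
  expect_false(inv$extrapolated)
  expect_true(quantify_concentration(cal, 2 * max(std$response))$extrapolated)
  expect_error(fit_calibration(data.frame(concentration = rep(1, 4),
                                          response = 1:4)),
               class = "mesosaxs_input_error")
})

test_that("encapsulation efficiency arithmetic and guards", {
  expect_equal(encapsulation_efficiency(0.5, 0.5)$ee_percent, 100)
  expect_equal(encapsulation_efficiency(0.31, 0.50)$ee_percent, 62)
  expect_equal(encapsulation_efficiency(0, 0.5)$ee_percent, 0)
  # unit invariance
  expect_equal(encapsulation_efficiency(310, 500)$ee_percent, 62)
  # replicates propagate SD
  res <- encapsulation_efficiency(c(0.30, 0.31, 0.32), 0.50)
  expect_equal(res$ee_percent, 62)
  expect_equal(res$sd, 100 * sd(c(0.30, 0.31, 0.32)) / 0.5)
  expect_error(encapsulation_efficiency(0.8, 0.5),
               class = "mesosaxs_inconsistency_error")
})

test_that("cumulative release corrects for withdraw-and-replace sampling", {
  # closure: one timepoint holding the full load
  one <- cumulative_release(data.frame(time = 1, concentration = 10),
                            volumes = list(medium = 30, aliquot = 1),
                            total_loaded = 300)
  expect_equal(one$fraction_percent, 100)
  # correction visible: equal concentrations still accumulate by C*V_aliquot
  two <- cumulative_release(data.frame(time = c(1, 2), concentration = c(4, 4)),
                            volumes = list(medium = 45, aliquot = 1),
                            total_loaded = 300)
  expect_equal(two$released_mass[2] - two$released_mass[1], 4 * 1)
  # first-order generator round-trip, < 1% error at every point
  dat <- synth_assay_data("release", params = list(k = 0.1))
  rc <- cumulative_release(dat$samples, dat$volumes, dat$total_loaded)
  expect_lt(max(abs(rc$fraction_percent - dat$true_fraction)), 1)
  expect_true(all(diff(rc$fraction_percent) >= 0))
  # mass-balance guard
  expect_error(cumulative_release(data.frame(time = 1, concentration = 20),
                                  volumes = list(medium = 30, aliquot = 1),
                                  total_loaded = 300),
               class = "mesosaxs_mass_balance_error")
})
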