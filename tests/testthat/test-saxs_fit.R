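make_curve <- function(preset = "unloaded", level = 0, seed = 1, n = 400) {
  synth_saxs_curve(saxs_preset(preset), qgrid = list(n = n),
                   noise = noise_spec(level = level, seed = seed))
}

test_that("detect_peaks finds generated Lorentzians and nothing else", {
  # single peak over a Porod tail, noiseless
  m <- composite_model(level1 = gp_level(1, 20, 4),
                       cylinder = gp_cylinder(0.01, 0.898, 5.93, 4),
                       peaks = list(lorentzian_peak(0.016, 0.0938, 1.140)),
                       background = 1e-4)
  cv <- synth_saxs_curve(m, noise = noise_spec(level = 0))
  pk <- detect_peaks(cv)
  expect_equal(nrow(pk), 1L)
  grid_step <- max(diff(cv$q))
  expect_lt(abs(pk$q_position - 1.140), grid_step)

  # three peaks at hexagonal ratios arrive sorted and all found
  m3 <- composite_model(level1 = gp_level(1, 20, 4),
                        cylinder = gp_cylinder(0.01, 0.898, 5.93, 4),
                        peaks = list(lorentzian_peak(0.02, 0.03, 0.60),
                                     lorentzian_peak(0.012, 0.03, 0.60 * sqrt(3)),
                                     lorentzian_peak(0.010, 0.03, 1.20)),
                        background = 1e-4)
  cv3 <- synth_saxs_curve(m3, noise = noise_spec(level = 0))
  pk3 <- detect_peaks(cv3)
  expect_equal(nrow(pk3), 3L)
  expect_true(!is.unsorted(pk3$q_position))
  expect_equal(pk3$q_position, c(0.60, 0.60 * sqrt(3), 1.20), tolerance = 0.02)

  # flat background only: empty candidate list
  flat <- scattering_curve(seq(0.1, 1.7, length.out = 200),
                           rep(0.3, 200))
  expect_equal(nrow(detect_peaks(flat)), 0L)
})

test_that("initialize_model seeds sensible starting values", {
  cv <- make_curve()
  init <- initialize_model(cv)
  expect_lt(abs(init$level1$Rg - 20) / 20, 0.3)
  expect_equal(init$level1$d, 4)
  expect_equal(length(init$peaks), 2L)

  # empty candidate list disables peaks
  no_peaks <- initialize_model(cv, candidates = detect_peaks(cv)[0, ])
  expect_length(no_peaks$peaks, 0L)

  # near-constant curve: background absorbs the level, Guinier warning fires
  q <- seq(0.1, 1.7, length.out = 100)
  const <- scattering_curve(q, rep(2, 100))
  expect_warning(init_c <- initialize_model(const, detect_peaks(const)),
                 class = "mesosaxs_initialization_warning")
  expect_equal(init_c$background, 2, tolerance = 0.05)
})

test_that("noiseless fit recovers the generator to tight tolerances", {
  cv <- make_curve("unloaded", level = 0)
  fit <- fit_composite(cv, initialize_model(cv), opts = list(seed = 1))
  expect_true(fit$provenance$converged)
  truth <- saxs_preset("unloaded")
  dm <- derived_metrics(fit$model)
  expect_lt(abs(dm$Rg - 20) / 20, 0.01)
  q_true <- vapply(truth$peaks, `[[`, numeric(1), "q_max")
  q_fit <- sort(dm$peaks$q_max)
  expect_lt(max(abs(q_fit - q_true) / q_true), 0.001)
  expect_lt(abs(dm$Rc - 1.27) / 1.27, 0.02)
  # structural identity holds for the fitted model regardless of fit quality
  expect_identical(dm$Dsphere / dm$Rg, 2 * sqrt(5 / 3))
})

test_that("fits are deterministic given a seed and monotone across starts", {
  cv <- make_curve("LEF", level = 0.01, seed = 3)
  f1 <- fit_composite(cv, initialize_model(cv),
                      opts = list(multistart = 3, seed = 11))
  f2 <- fit_composite(cv, initialize_model(cv),
                      opts = list(multistart = 3, seed = 11))
  expect_identical(model_to_config(f1$model), model_to_config(f2$model))
  expect_identical(f1$provenance$objective, f2$provenance$objective)
  # best-so-far objective trace never increases
  expect_true(all(diff(f1$provenance$objective_trace) <= 0))
})

test_that("pure-background curves collapse structure scales with a warning", {
  q <- 10^seq(log10(0.074), log10(1.7), length.out = 120)
  set.seed(99)
  cv <- scattering_curve(q, rnorm(120, mean = 1, sd = 0.01),
                         uncertainty = rep(0.01, 120))
  init <- suppressWarnings(initialize_model(cv, detect_peaks(cv)[0, ]))
  fit <- fit_composite(cv, init, opts = list(multistart = 2, seed = 1))
  expect_true(any(grepl("collapsed|bound", fit$provenance$warnings)) ||
                fit$model$background > 0.9)
})

test_that("fit_composite validates its inputs", {
  cv <- make_curve(n = 40)
  init <- initialize_model(make_curve())
  short <- scattering_curve(cv$q[1:12], cv$intensity[1:12])
  expect_error(fit_composite(short, init),
               class = "mesosaxs_validation_error")
  expect_error(fit_composite(cv, composite_model(background = 1)),
               class = "mesosaxs_configuration_error")
})
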