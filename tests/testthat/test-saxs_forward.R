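test_that("one-level Guinier-Porod matches hand-derived values", {
  lv <- gp_level(G = 1, Rg = 20, d = 4)
  expect_equal(lv$q1, sqrt(6) / 20)                       # 0.12247
  expect_equal(eval_gp1(lv, lv$q1), exp(-2), tolerance = 1e-12)
  expect_equal(lv$D, exp(-2) * 36 / 20^4, tolerance = 1e-12)
  expect_equal(lv$D * lv$q1^(-4), exp(-2), tolerance = 1e-12)
  # Guinier limit
  expect_equal(eval_gp1(lv, 1e-6), 1, tolerance = 1e-9)
  expect_error(gp_level(-1, 20), class = "mesosaxs_parameter_error")
  expect_error(gp_level(1, 20, d = 5), class = "mesosaxs_parameter_error")
})

test_that("cylinder term reproduces derived crossovers and scales", {
  cy <- gp_cylinder(G1 = 1, Rg1 = 0.898, Rg2 = 5.93, d = 4)
  expect_equal(cy$q2, ((2 / 3) * 5.93^2 - 0.898^2)^(-0.5))
  expect_equal(cy$q2, 0.2102, tolerance = 1e-3)
  expect_equal(cy$G2, (1 / cy$q2) * exp(0.5))
  expect_equal(cy$G2, 7.844, tolerance = 1e-3)
  expect_equal(cy$q1, sqrt(3) / 0.898)
  expect_equal(cy$q1, 1.929, tolerance = 1e-3)
  # branch agreement at q2 to 1e-9 relative
  guinier <- cy$G2 * exp(-cy$q2^2 * cy$Rg2^2 / 3)
  rod <- (cy$G1 / cy$q2) * exp(-cy$q2^2 * cy$Rg1^2 / 2)
  expect_lt(rel_err(guinier, rod), 1e-9)
  expect_error(gp_cylinder(1, 5, 5.5), class = "mesosaxs_parameter_error")
})

test_that("Lorentzian peaks: maximum, symmetry, unit area", {
  pk <- lorentzian_peak(k = 1, sigma = 0.0938, q_max = 1.140)
  expect_equal(eval_peaks(list(pk), 1.140), 1 / (pi * 0.0938))
  dlt <- c(0.01, 0.05, 0.2)
  expect_equal(eval_peaks(list(pk), 1.140 + dlt),
               eval_peaks(list(pk), 1.140 - dlt))
  # truncated Cauchy mass over +/- m*sigma is (2/pi)*atan(m); +/-50 sigma
  # captures 98.73%, so the within-1%-of-k check integrates +/-200 sigma
  area50 <- stats::integrate(function(x) eval_peaks(list(pk), x),
                             1.140 - 50 * 0.0938, 1.140 + 50 * 0.0938,
                             rel.tol = 1e-10)$value
  expect_equal(area50, (2 / pi) * atan(50), tolerance = 1e-6)
  area200 <- stats::integrate(function(x) eval_peaks(list(pk), x),
                              1.140 - 200 * 0.0938, 1.140 + 200 * 0.0938,
                              rel.tol = 1e-10)$value
  expect_equal(area200, 1, tolerance = 0.01)
  expect_length(eval_peaks(list(), 1:5), 5L)
})

test_that("composite is the sum of its parts and degenerates correctly", {
  q <- 10^seq(log10(0.074), log10(1.7), length.out = 100)
  m <- saxs_preset("unloaded")
  total <- eval_composite(m, q)
  parts <- eval_gp1(m$level1, q) + eval_cylinder_gp(m$cylinder, q) +
    eval_peaks(m$peaks, q) + m$background
  expect_equal(total, parts, tolerance = 1e-14)  # summation order only
  bg_only <- composite_model(background = 0.5)
  expect_equal(eval_composite(bg_only, q), rep(0.5, 100))
  expect_error(composite_model(), class = "mesosaxs_configuration_error")
  # far past every crossover the composite is background + both Porod tails
  qt <- 10 * max(m$level1$q1, m$cylinder$q1)
  tails <- m$background + m$level1$D * qt^-4 + m$cylinder$D * qt^-4
  expect_equal(eval_composite(m, qt), tails, tolerance = 1e-3)
})

test_that("piecewise evaluations agree with the brute-force oracle", {
  set.seed(601)
  for (i in 1:100) {
    p <- random_gp1_params()
    q <- 10^seq(runif(1, -2, -1.3), runif(1, 0, 0.5), length.out = 60)
    got <- eval_gp1(gp_level(p$G, p$Rg, p$d), q)
    want <- oracle_gp1(p$G, p$Rg, p$d, q)
    expect_lt(max(rel_err(got, want)), 1e-10)

    cp <- random_cylinder_params()
    got2 <- eval_cylinder_gp(gp_cylinder(cp$G1, cp$Rg1, cp$Rg2, cp$d), q)
    want2 <- oracle_cylinder(cp$G1, cp$Rg1, cp$Rg2, cp$d, q)
    expect_lt(max(rel_err(got2, want2)), 1e-10)
  }
})

test_that("value and slope are continuous at every crossover", {
  set.seed(602)
  for (i in 1:40) {
    p <- random_gp1_params()
    lv <- gp_level(p$G, p$Rg, p$d)
    f <- function(x) eval_gp1(lv, x)
    check_crossover(f, lv$q1)

    cp <- random_cylinder_params()
    cy <- gp_cylinder(cp$G1, cp$Rg1, cp$Rg2, cp$d)
    g <- function(x) eval_cylinder_gp(cy, x)
    check_crossover(g, cy$q2)
    check_crossover(g, cy$q1)
  }
})

test_that("length rescaling moves crossovers reciprocally, values invariant", {
  set.seed(603)
  for (c_scale in c(0.5, 2, 7)) {
    p <- random_gp1_params()
    lv1 <- gp_level(p$G, p$Rg, p$d)
    lv2 <- gp_level(p$G, p$Rg * c_scale, p$d)
    expect_equal(lv2$q1, lv1$q1 / c_scale)
    q <- 10^seq(-2, 0.3, length.out = 30)
    expect_equal(eval_gp1(lv2, q / c_scale), eval_gp1(lv1, q),
                 tolerance = 1e-12)
    cp <- random_cylinder_params()
    cy1 <- gp_cylinder(cp$G1, cp$Rg1, cp$Rg2, cp$d)
    cy2 <- gp_cylinder(cp$G1, cp$Rg1 * c_scale, cp$Rg2 * c_scale, cp$d)
    expect_equal(cy2$q2, cy1$q2 / c_scale)
    expect_equal(cy2$q1, cy1$q1 / c_scale)
  }
})

test_that("derived metrics implement the documented closed forms", {
  m <- composite_model(
    level1 = gp_level(1, 20, 4),
    cylinder = gp_cylinder(0.01, 0.898, 5.93, 4),
    peaks = list(lorentzian_peak(1, 0.0938, 1.140)))
  dm <- derived_metrics(m)
  expect_identical(dm$Dsphere / dm$Rg, 2 * sqrt(5 / 3))
  expect_equal(dm$Rc, sqrt(2) * 0.898)
  expect_equal(dm$Rc, 1.270, tolerance = 1e-3)
  expect_equal(dm$L, 20.3, tolerance = 1e-3)
  expect_equal(dm$peaks$l_c, 2 * pi / 0.0938)
  expect_equal(dm$peaks$l_c, 67, tolerance = 5e-3)
  expect_equal(dm$peaks$a_hex, 4 * pi / (sqrt(3) * 1.140))
  expect_equal(dm$peaks$a_hex, 6.364, tolerance = 1e-3)
  expect_equal(dm$peaks$d_spacing, 2 * pi / 1.140)
})

test_that("Dsphere/Rg identity reproduces all three printed pairs", {
  pairs <- list(c(20.0, 51.6), c(26.6, 68.6), c(30.3, 78.2))
  for (p in pairs) {
    dm <- derived_metrics(composite_model(level1 = gp_level(1, p[1], 4),
                                          background = 0))
    # agreement within one unit of the last printed digit
    expect_lt(abs(dm$Dsphere - p[2]), 0.1)
  }
})

test_that("model config round-trips through the flat key-value format", {
  m <- saxs_preset("LEF")
  path <- withr::local_tempfile(fileext = ".cfg")
  write_model_config(m, path)
  back <- read_model_config(path)
  expect_equal(model_to_config(back), model_to_config(m), tolerance = 1e-14)
})
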