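# Synthetic-data generators. All are pure functions of (parameters, seed);
# the caller's RNG state is saved and restored.

with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Noise specification for synthetic scattering curves
#'
#' @param model `"gaussian_multiplicative"` (SD = level * I) or
#'   `"poisson_like"` (SD = level * sqrt(I * max(I)), i.e. SD grows with
#'   sqrt(I) and equals `level * max(I)` at the maximum — counting-statistics
#'   realism).
#' @param level relative noise level, >= 0.
#' @param seed RNG seed.
#' @export
noise_spec <- function(model = c("gaussian_multiplicative", "poisson_like"),
                       level = 0.01, seed = 1) {
  model <- match.arg(model)
  if (!is.finite(level) || level < 0) {
    abort("noise level must be >= 0", "mesosaxs_parameter_error")
  }
  list(model = model, level = level, seed = seed)
}

#' Names of the shipped composite-model presets
#' @return character vector.
#' @export
preset_names <- function() c("unloaded", "LEF", "LEF_G")

#' Load a shipped composite-model preset
#'
#' Presets encode the three fitted systems of the drug-loading study:
#' `unloaded`, `LEF` (leflunomide-loaded) and `LEF_G` (leflunomide impurity
#' G-loaded) fluorinated-amphiphile dispersions. The plain-text config files under
#' `inst/extdata/presets/` store the published derived metrics (Rg, Rc, L,
#' lattice constants, correlation lengths) plus the package's documented scale
#' choices; the loader back-computes the model shape parameters
#' (`Rg1 = Rc/sqrt(2)`, `Rg2 = sqrt((L^2+6*Rc^2)/12)`, peak positions from the
#' hexagonal (100) relation, sigma from `l_c`) so that [derived_metrics()] of
#' the returned model reproduces the printed values by construction.
#'
#' @param name one of [preset_names()].
#' @return a [composite_model()] with attributes `targets` (the printed
#'   values) and `primary_peak` (index of the main lattice peak after q
#'   sorting).
#' @export
saxs_preset <- function(name = preset_names()) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".cfg"),
                      package = "mesosaxs", mustWork = TRUE)
  cfg <- read_flat_config(path)
  Rg1 <- cfg$Rc / sqrt(2)
  Rg2 <- sqrt((cfg$L^2 + 6 * cfg$Rc^2) / 12)
  level1 <- gp_level(cfg$G, cfg$Rg, cfg$d)
  cylinder <- gp_cylinder(cfg$G1, Rg1, Rg2, cfg$d)

  continuum <- function(q) {
    eval_gp1(level1, q) + eval_cylinder_gp(cylinder, q) + cfg$background
  }
  make_peak <- function(a, lc, contrast) {
    q <- 4 * pi / (sqrt(3) * a)
    sigma <- 2 * pi / lc
    lorentzian_peak(k = contrast * continuum(q) * pi * sigma,
                    sigma = sigma, q_max = q)
  }
  peaks <- list(make_peak(cfg$a1, cfg$lc1, cfg$contrast1))
  if (!is.null(cfg$a2)) {
    peaks <- c(peaks, list(make_peak(cfg$a2, cfg$lc2, cfg$contrast2)))
  }
  model <- composite_model(level1, cylinder, peaks, cfg$background)
  qm <- vapply(model$peaks, `[[`, numeric(1), "q_max")
  attr(model, "primary_peak") <- which.min(abs(qm - 4 * pi / (sqrt(3) * cfg$a1)))
  attr(model, "targets") <- list(Rg = cfg$Rg, Rc = cfg$Rc, L = cfg$L,
                                 a1 = cfg$a1, lc1 = cfg$lc1,
                                 a2 = cfg$a2, lc2 = cfg$lc2)
  attr(model, "preset") <- name
  model
}

#' Generate a synthetic scattering curve from a composite model
#'
#' Evaluates the model on a linear or logarithmic q grid (defaulting to the
#' Kratky-camera range 0.074-1.70 nm^-1 used for the encapsulation samples)
#' and adds seeded noise. The uncertainty column holds the nominal noise SD
#' (floored at 1e-12 of the maximum intensity).
#'
#' @param model a [composite_model()].
#' @param qgrid list: `q_min` (default 0.074), `q_max` (default 1.70), `n`
#'   (default 400, >= 32), `spacing` (`"log"` or `"linear"`, default log).
#' @param noise a [noise_spec()].
#' @return a [scattering_curve()] (marked background-subtracted, since noise
#'   can take near-zero intensities slightly negative).
#' @export
synth_saxs_curve <- function(model, qgrid = list(), noise = noise_spec()) {
  stopifnot(inherits(model, "composite_model"))
  q_min <- qgrid$q_min %||% 0.074
  q_max <- qgrid$q_max %||% 1.70
  n <- qgrid$n %||% 400L
  spacing <- qgrid$spacing %||% "log"
  if (!is.finite(q_min) || q_min <= 0 || q_max <= q_min) {
    abort("need 0 < q_min < q_max", "mesosaxs_parameter_error")
  }
  if (n < 32L) abort("need n >= 32", "mesosaxs_parameter_error")
  q <- switch(spacing,
              log = exp(seq(log(q_min), log(q_max), length.out = n)),
              linear = seq(q_min, q_max, length.out = n),
              abort("spacing must be 'log' or 'linear'", "mesosaxs_parameter_error"))
  I0 <- eval_composite(model, q)
  eps <- 1e-12 * max(I0)
  sd_nom <- switch(noise$model,
                   gaussian_multiplicative = noise$level * I0,
                   poisson_like = noise$level * sqrt(I0 * max(I0)))
  I <- if (noise$level > 0) {
    with_seed(noise$seed, I0 + stats::rnorm(n) * sd_nom)
  } else {
    I0
  }
  scattering_curve(q, I, uncertainty = pmax(sd_nom, eps),
                   meta = list(source_unit = "nm^-1",
                               background_subtracted = TRUE,
                               label = attr(model, "preset") %||% "synthetic"))
}

#' Generate a two-regime CAC dilution series
#'
#' Log-spaced concentrations around the breakpoint; response is a plateau
#' below the CAC and `plateau * (c/cac)^post_slope` above, with seeded
#' multiplicative Gaussian noise.
#'
#' @param cac breakpoint concentration (M); default 2.1e-4, the headline
#'   fluorinated-amphiphile value.
#' @param span_decades numeric length-2: decades below/above the CAC covered
#'   by the series (default `c(-1.25, 1.25)`).
#' @param n number of concentrations (default 12).
#' @param plateau pre-CAC response level in kcps (default 10).
#' @param post_slope log-log slope above the CAC (default 1, scattering
#'   proportional to aggregate concentration); 0 produces the degenerate flat
#'   series used to exercise the no-aggregation error path.
#' @param noise_level relative multiplicative noise SD (default 0.05).
#' @param seed RNG seed.
#' @return a [concentration_series()].
#' @export
synth_cac_series <- function(cac = 2.1e-4, span_decades = c(-1.25, 1.25),
                             n = 12L, plateau = 10, post_slope = 1,
                             noise_level = 0.05, seed = 1) {
  if (!is.finite(cac) || cac <= 0) {
    abort("cac must be > 0", "mesosaxs_parameter_error")
  }
  if (span_decades[1L] >= 0 || span_decades[2L] <= 0) {
    abort("cac must lie inside the concentration range",
          "mesosaxs_parameter_error")
  }
  conc <- cac * 10^seq(span_decades[1L], span_decades[2L], length.out = n)
  resp <- ifelse(conc <= cac, plateau, plateau * (conc / cac)^post_slope)
  if (noise_level > 0) {
    resp <- with_seed(seed, resp * exp(stats::rnorm(n, sd = noise_level)))
  }
  concentration_series(conc, resp)
}

#' Generate a periodic lattice image
#'
#' Stripes: a single cosine grating of the given period. Hexagonal: the sum
#' of three plane waves at 60 degrees, each with wavelength equal to the row
#' spacing, giving a hexagonal dot lattice whose first-order spectral ring
#' sits at 1/spacing. Gaussian pixel noise is seeded.
#'
#' @param spacing row spacing in nm; must exceed `2 * pixel_size` (Nyquist).
#' @param pixel_size nm per pixel.
#' @param size image side in pixels (default 512).
#' @param pattern `"stripes"` or `"hexagonal"`.
#' @param rotation_deg lattice rotation (default 0).
#' @param noise_level SD of additive Gaussian pixel noise relative to the
#'   unit pattern amplitude (default 0.05).
#' @param seed RNG seed.
#' @return a [calibrated_image()].
#' @export
synth_lattice_image <- function(spacing, pixel_size, size = 512L,
                                pattern = c("stripes", "hexagonal"),
                                rotation_deg = 0, noise_level = 0.05,
                                seed = 1) {
  pattern <- match.arg(pattern)
  if (!is.finite(spacing) || spacing <= 2 * pixel_size) {
    abort("spacing must exceed 2*pixel_size (Nyquist)", "mesosaxs_sampling_error")
  }
  ax <- (seq_len(size) - 1) * pixel_size
  x <- matrix(ax, size, size, byrow = TRUE)
  y <- matrix(ax, size, size)
  th0 <- rotation_deg * pi / 180
  wave <- function(theta) {
    cos(2 * pi * (x * cos(theta) + y * sin(theta)) / spacing)
  }
  img <- if (pattern == "stripes") {
    wave(th0)
  } else {
    wave(th0) + wave(th0 + pi / 3) + wave(th0 + 2 * pi / 3)
  }
  if (noise_level > 0) {
    img <- with_seed(seed, img + stats::rnorm(length(img), sd = noise_level))
  }
  calibrated_image(img, pixel_size)
}

#' Generate synthetic assay tables
#'
#' `kind = "calibration"`: standards on a line
#' `response = slope * concentration + intercept` with homoscedastic Gaussian
#' noise. `kind = "release"`: a first-order release profile
#' `fraction = 100 * (1 - exp(-k t))` sampled through the withdraw-and-replace
#' dialysis bookkeeping that [cumulative_release()] inverts.
#'
#' @param kind `"calibration"` or `"release"`.
#' @param params list. Calibration: `slope` (2), `intercept` (0),
#'   `concentrations` (6 levels 0.05-1), `noise_sd` (0). Release: `k` (0.1
#'   per h), `total_loaded` (300, e.g. micrograms), `times` (h), `medium` (45
#'   mL), `aliquot` (1 mL), `noise_level` (0, relative).
#' @param seed RNG seed.
#' @return calibration: a data.frame of standards. Release: a list with
#'   `samples` (time, concentration), `volumes`, `total_loaded`, and
#'   `true_fraction` (the noiseless generating fractions, for round-trip
#'   checks).
#' @export
synth_assay_data <- function(kind = c("calibration", "release"),
                             params = list(), seed = 1) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) abort(
                     sprintf("unknown assay kind '%s'", kind[1]),
                     "mesosaxs_parameter_error"))
  if (kind == "calibration") {
    slope <- params$slope %||% 2
    intercept <- params$intercept %||% 0
    conc <- params$concentrations %||% c(0.05, 0.1, 0.2, 0.4, 0.7, 1.0)
    noise_sd <- params$noise_sd %||% 0
    resp <- slope * conc + intercept
    if (noise_sd > 0) {
      resp <- with_seed(seed, resp + stats::rnorm(length(conc), sd = noise_sd))
    }
    return(data.frame(concentration = conc, response = resp))
  }
  k <- params$k %||% 0.1
  total <- params$total_loaded %||% 300
  times <- params$times %||% c(0.5, 1, 2, 4, 8, 24, 48)
  vm <- params$medium %||% 45
  va <- params$aliquot %||% 1
  noise_level <- params$noise_level %||% 0
  frac <- 1 - exp(-k * times)
  released <- total * frac
  conc <- numeric(length(times))
  withdrawn <- 0
  for (i in seq_along(times)) {
    conc[i] <- (released[i] - withdrawn) / vm
    withdrawn <- withdrawn + conc[i] * va
  }
  if (noise_level > 0) {
    conc <- with_seed(seed, conc * exp(stats::rnorm(length(conc), sd = noise_level)))
  }
  list(samples = data.frame(time = times, concentration = conc),
       volumes = list(medium = vm, aliquot = va),
       total_loaded = total,
       true_fraction = 100 * frac)
}
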