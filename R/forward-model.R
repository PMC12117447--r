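#' One-level Guinier-Porod term
#'
#' The empirical Guinier-Porod form describes the overall particle scattering:
#' a Guinier branch \eqn{G \exp(-q^2 R_g^2/3)} for \eqn{q \le q_1} and a Porod
#' power-law branch \eqn{D q^{-d}} for \eqn{q > q_1}. Requiring the two
#' branches and their slopes to be continuous fixes the crossover at
#' \eqn{q_1 = (1/R_g)\sqrt{3d/2}} and the Porod scale at
#' \eqn{D = G e^{-d/2} (3d/2)^{d/2} R_g^{-d}}.
#'
#' @param G Guinier scale (> 0, intensity units).
#' @param Rg radius of gyration in nm (> 0).
#' @param d Porod exponent, in (1, 4]; 4 indicates a sharp smooth interface.
#' @return object of class `gp_level` carrying the derived `q1` and `D`.
#' @export
gp_level <- function(G, Rg, d = 4) {
  if (!is.finite(G) || G <= 0) abort("G must be > 0", "mesosaxs_parameter_error")
  if (!is.finite(Rg) || Rg <= 0) abort("Rg must be > 0", "mesosaxs_parameter_error")
  if (!is.finite(d) || d <= 1 || d > 4) {
    abort("Porod exponent d must be in (1, 4]", "mesosaxs_parameter_error")
  }
  q1 <- sqrt(3 * d / 2) / Rg
  D <- G * exp(-d / 2) * (3 * d / 2)^(d / 2) / Rg^d
  structure(list(G = G, Rg = Rg, d = d, q1 = q1, D = D), class = "gp_level")
}

#' Evaluate the one-level Guinier-Porod term
#'
#' @param level a [gp_level()].
#' @param q positive q grid (nm^-1).
#' @return intensities.
#' @export
eval_gp1 <- function(level, q) {
  stopifnot(inherits(level, "gp_level"))
  if (any(q <= 0)) abort("q must be > 0", "mesosaxs_parameter_error")
  out <- numeric(length(q))
  lo <- q <= level$q1
  out[lo] <- level$G * exp(-q[lo]^2 * level$Rg^2 / 3)
  out[!lo] <- level$D * q[!lo]^(-level$d)
  out
}

#' Two-level Guinier-Porod term for cylindrical substructure
#'
#' Models scattering from the curved cylinder-like water channels inside
#' hexosomes with three branches: an overall Guinier regime
#' (\eqn{G_2 \exp(-q^2 R_{g2}^2/3)} for \eqn{q \le q_2}), a rod regime
#' (\eqn{(G_1/q) \exp(-q^2 R_{g1}^2/2)} for \eqn{q_2 \le q \le q_1}) and a
#' Porod regime (\eqn{D q^{-d}} for \eqn{q \ge q_1}). The crossovers and
#' dependent scales are all fixed by continuity:
#' \itemize{
#'   \item \eqn{q_2 = [(2/3) R_{g2}^2 - R_{g1}^2]^{-1/2}};
#'   \item \eqn{G_2 = (G_1/q_2) e^{1/2}} (value continuity at `q2`; the
#'     exponent reduces to exactly 1/2 given the `q2` relation);
#'   \item \eqn{q_1 = \sqrt{d-1}/R_{g1}} and
#'     \eqn{D = G_1 q_1^{d-1} e^{-(d-1)/2}} (value + slope continuity of the
#'     rod and Porod branches).
#' }
#'
#' @param G1 rod-regime scale (> 0).
#' @param Rg1 cross-section radius of gyration (nm); cylinder radius is
#'   \eqn{R_c = \sqrt{2} R_{g1}}.
#' @param Rg2 overall radius of gyration (nm); must satisfy
#'   \eqn{(2/3) R_{g2}^2 > R_{g1}^2} for `q2` to be real.
#' @param d Porod exponent in (1, 4].
#' @return object of class `gp_cylinder` carrying derived `q1`, `q2`, `G2`, `D`.
#' @export
gp_cylinder <- function(G1, Rg1, Rg2, d = 4) {
  if (!is.finite(G1) || G1 <= 0) abort("G1 must be > 0", "mesosaxs_parameter_error")
  if (!is.finite(Rg1) || Rg1 <= 0) abort("Rg1 must be > 0", "mesosaxs_parameter_error")
  if (!is.finite(Rg2) || Rg2 <= Rg1) {
    abort("Rg2 must exceed Rg1", "mesosaxs_parameter_error")
  }
  if (!is.finite(d) || d <= 1 || d > 4) {
    abort("Porod exponent d must be in (1, 4]", "mesosaxs_parameter_error")
  }
  rad <- (2 / 3) * Rg2^2 - Rg1^2
  if (rad <= 0) {
    abort("q2 not real: (2/3)*Rg2^2 - Rg1^2 <= 0", "mesosaxs_parameter_error")
  }
  q2 <- rad^(-0.5)
  G2 <- (G1 / q2) * exp(0.5)
  q1 <- sqrt(d - 1) / Rg1
  D <- G1 * q1^(d - 1) * exp(-(d - 1) / 2)
  if (q2 >= q1) {
    abort("invalid geometry: q2 >= q1 (Rg1 too large relative to Rg2)",
          "mesosaxs_parameter_error")
  }
  structure(list(G1 = G1, G2 = G2, Rg1 = Rg1, Rg2 = Rg2, d = d,
                 q1 = q1, q2 = q2, D = D),
            class = "gp_cylinder")
}

#' Evaluate the cylinder two-level Guinier-Porod term
#'
#' @param cyl a [gp_cylinder()].
#' @param q positive q grid (nm^-1).
#' @return intensities.
#' @export
eval_cylinder_gp <- function(cyl, q) {
  stopifnot(inherits(cyl, "gp_cylinder"))
  if (any(q <= 0)) abort("q must be > 0", "mesosaxs_parameter_error")
  out <- numeric(length(q))
  lo <- q <= cyl$q2
  hi <- q >= cyl$q1
  mid <- !lo & !hi
  out[lo] <- cyl$G2 * exp(-q[lo]^2 * cyl$Rg2^2 / 3)
  out[mid] <- (cyl$G1 / q[mid]) * exp(-q[mid]^2 * cyl$Rg1^2 / 2)
  out[hi] <- cyl$D * q[hi]^(-cyl$d)
  out
}

#' Lorentzian lattice peak
#'
#' A Bragg peak from the periodic internal lattice, modelled as a Cauchy
#' profile \eqn{k \sigma / (\pi(\sigma^2 + (q - q_{max})^2))}, normalised so
#' that `k` is the integrated peak area. `sigma` is the half-width at
#' half-maximum; the lattice correlation length is \eqn{l_c = 2\pi/\sigma}.
#'
#' @param k integrated peak weight (> 0).
#' @param sigma HWHM in nm^-1 (> 0).
#' @param q_max peak position in nm^-1 (> 0).
#' @export
lorentzian_peak <- function(k, sigma, q_max) {
  if (!is.finite(k) || k <= 0) abort("k must be > 0", "mesosaxs_parameter_error")
  if (!is.finite(sigma) || sigma <= 0) {
    abort("sigma must be > 0", "mesosaxs_parameter_error")
  }
  if (!is.finite(q_max) || q_max <= 0) {
    abort("q_max must be > 0", "mesosaxs_parameter_error")
  }
  structure(list(k = k, sigma = sigma, q_max = q_max), class = "lorentzian_peak")
}

#' Evaluate a sum of Lorentzian peaks
#'
#' @param peaks list of [lorentzian_peak()] objects (may be empty).
#' @param q numeric q grid.
#' @return intensities (zero for an empty peak list).
#' @export
eval_peaks <- function(peaks, q) {
  out <- numeric(length(q))
  for (p in peaks) {
    stopifnot(inherits(p, "lorentzian_peak"))
    out <- out + p$k * p$sigma / (pi * (p$sigma^2 + (q - p$q_max)^2))
  }
  out
}

#' Composite scattering model
#'
#' Sum of up to four contributions: overall-particle Guinier-Porod term
#' (`level1`), cylinder-substructure term (`cylinder`), Lorentzian lattice
#' peaks (`peaks`), and a flat background. Components may be disabled by
#' passing `NULL` (or an empty peak list); at least one contribution must be
#' present (a positive background counts).
#'
#' @param level1 a [gp_level()] or `NULL`.
#' @param cylinder a [gp_cylinder()] or `NULL`.
#' @param peaks list of [lorentzian_peak()]; stored sorted by `q_max`.
#' @param background constant background intensity, >= 0.
#' @return object of class `composite_model`.
#' @export
composite_model <- function(level1 = NULL, cylinder = NULL, peaks = list(),
                            background = 0) {
  if (!is.null(level1)) stopifnot(inherits(level1, "gp_level"))
  if (!is.null(cylinder)) stopifnot(inherits(cylinder, "gp_cylinder"))
  if (!is.finite(background) || background < 0) {
    abort("background must be >= 0", "mesosaxs_parameter_error")
  }
  if (length(peaks)) {
    stopifnot(all(vapply(peaks, inherits, logical(1), "lorentzian_peak")))
    peaks <- peaks[order(vapply(peaks, `[[`, numeric(1), "q_max"))]
  }
  if (is.null(level1) && is.null(cylinder) && !length(peaks) && background == 0) {
    abort("all model components disabled", "mesosaxs_configuration_error")
  }
  structure(list(level1 = level1, cylinder = cylinder, peaks = peaks,
                 background = background),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat("<composite_model>\n")
  if (!is.null(x$level1)) {
    cat(sprintf("  level1:   G=%.4g Rg=%.4g nm d=%.3g\n",
                x$level1$G, x$level1$Rg, x$level1$d))
  }
  if (!is.null(x$cylinder)) {
    cat(sprintf("  cylinder: G1=%.4g Rg1=%.4g Rg2=%.4g nm d=%.3g\n",
                x$cylinder$G1, x$cylinder$Rg1, x$cylinder$Rg2, x$cylinder$d))
  }
  for (p in x$peaks) {
    cat(sprintf("  peak:     k=%.4g sigma=%.4g q_max=%.4g nm^-1\n",
                p$k, p$sigma, p$q_max))
  }
  cat(sprintf("  background: %.4g\n", x$background))
  invisible(x)
}

#' Evaluate the composite model
#'
#' Elementwise sum of the enabled contributions plus background.
#'
#' @param model a [composite_model()].
#' @param q positive q grid (nm^-1).
#' @return intensities.
#' @export
eval_composite <- function(model, q) {
  stopifnot(inherits(model, "composite_model"))
  if (is.null(model$level1) && is.null(model$cylinder) &&
      !length(model$peaks) && model$background == 0) {
    abort("all model components disabled", "mesosaxs_configuration_error")
  }
  out <- rep(model$background, length(q))
  if (!is.null(model$level1)) out <- out + eval_gp1(model$level1, q)
  if (!is.null(model$cylinder)) out <- out + eval_cylinder_gp(model$cylinder, q)
  if (length(model$peaks)) out <- out + eval_peaks(model$peaks, q)
  out
}

#' Structural metrics derived from a fitted composite model
#'
#' Computes the standard derived quantities of the Guinier-Porod analysis of
#' hexosome-type particles:
#' \itemize{
#'   \item \eqn{D_{sphere} = 2\sqrt{5/3}\,R_g}, the scatter-equivalent sphere
#'     diameter, from `level1`;
#'   \item \eqn{R_c = \sqrt{2} R_{g1}}, the cylinder cross-section radius, and
#'     \eqn{L = \sqrt{12 R_{g2}^2 - 6 R_c^2}}, the cylinder length, from the
#'     cylinder term;
#'   \item per peak: Bragg spacing \eqn{d = 2\pi/q_{max}}, correlation length
#'     \eqn{l_c = 2\pi/\sigma}, and hexagonal lattice constant
#'     \eqn{a_{hex} = 4\pi/(\sqrt{3}\,q_{max})}. The `a_hex` column assumes
#'     the peak is the hexagonal (100) reflection; use the phase-indexing
#'     functions for other indices or other phases.
#' }
#' Every scalar is tagged with the formula used (the `formulas` element).
#'
#' @param model a [composite_model()].
#' @return a `structural_report` list with elements `Rg`, `Dsphere`, `Rc`, `L`
#'   (present only when the relevant component is enabled), a `peaks`
#'   data.frame, and `formulas`.
#' @export
derived_metrics <- function(model) {
  stopifnot(inherits(model, "composite_model"))
  rep_ <- list(formulas = list())
  if (!is.null(model$level1)) {
    rep_$Rg <- model$level1$Rg
    rep_$Dsphere <- 2 * sqrt(5 / 3) * model$level1$Rg
    rep_$formulas$Dsphere <- "2*sqrt(5/3)*Rg"
  }
  if (!is.null(model$cylinder)) {
    Rc <- sqrt(2) * model$cylinder$Rg1
    rad <- 12 * model$cylinder$Rg2^2 - 6 * Rc^2
    if (rad <= 0) {
      abort(sprintf(
        "cylinder length undefined: 12*Rg2^2 (= %.4g) <= 6*Rc^2 (= %.4g)",
        12 * model$cylinder$Rg2^2, 6 * Rc^2), "mesosaxs_geometry_error")
    }
    rep_$Rc <- Rc
    rep_$L <- sqrt(rad)
    rep_$formulas$Rc <- "sqrt(2)*Rg1"
    rep_$formulas$L <- "sqrt(12*Rg2^2 - 6*Rc^2)"
  }
  if (length(model$peaks)) {
    qm <- vapply(model$peaks, `[[`, numeric(1), "q_max")
    sg <- vapply(model$peaks, `[[`, numeric(1), "sigma")
    rep_$peaks <- data.frame(
      q_max = qm,
      d_spacing = 2 * pi / qm,
      a_hex = 4 * pi / (sqrt(3) * qm),
      l_c = 2 * pi / sg
    )
    rep_$formulas$d_spacing <- "2*pi/q_max"
    rep_$formulas$a_hex <- "4*pi/(sqrt(3)*q_max) [assumes (100)]"
    rep_$formulas$l_c <- "2*pi/sigma"
  } else {
    rep_$peaks <- data.frame(q_max = numeric(0), d_spacing = numeric(0),
                             a_hex = numeric(0), l_c = numeric(0))
  }
  class(rep_) <- "structural_report"
  rep_
}

#' @export
print.structural_report <- function(x, ...) {
  cat("<structural_report>\n")
  for (nm in c("Rg", "Dsphere", "Rc", "L")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %-8s %.4g nm\n", nm, x[[nm]]))
  }
  if (nrow(x$peaks)) {
    cat("  peaks:\n")
    print(format(x$peaks, digits = 4), row.names = FALSE)
  }
  invisible(x)
}
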