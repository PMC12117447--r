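# Independent brute-force evaluation of the piecewise Guinier-Porod terms.
# Crossovers are located by numeric root-finding on log-slope conditions, and
# dependent scales by direct continuity ratios -- no reuse of the package's
# closed forms.

oracle_gp1 <- function(G, Rg, d, q) {
  guinier <- function(x) G * exp(-x^2 * Rg^2 / 3)
  # log-slope of Guinier branch equals -d at the crossover
  f <- function(x) -2 * x^2 * Rg^2 / 3 + d
  q1 <- stats::uniroot(f, c(1e-8 / Rg, 1e3 / Rg), tol = 1e-15)$root
  D <- guinier(q1) * q1^d
  ifelse(q <= q1, guinier(q), D * q^(-d))
}

oracle_cylinder <- function(G1, Rg1, Rg2, d, q) {
  rod <- function(x) (G1 / x) * exp(-x^2 * Rg1^2 / 2)
  # rod log-slope (-1 - x^2 Rg1^2) equals -d at the high-q crossover
  f1 <- function(x) -1 - x^2 * Rg1^2 + d
  q1 <- stats::uniroot(f1, c(1e-8 / Rg1, 1e3 / Rg1), tol = 1e-15)$root
  D <- rod(q1) * q1^d
  q2 <- ((2 / 3) * Rg2^2 - Rg1^2)^(-0.5)          # definitional
  G2 <- rod(q2) / exp(-q2^2 * Rg2^2 / 3)          # value continuity at q2
  ifelse(q <= q2, G2 * exp(-q^2 * Rg2^2 / 3),
         ifelse(q <= q1, rod(q), D * q^(-d)))
}

# Random valid parameter draws (assumes RNG already seeded by the caller).
random_gp1_params <- function() {
  list(G = 10^stats::runif(1, -1, 1),
       Rg = stats::runif(1, 5, 50),
       d = stats::runif(1, 1.6, 4))
}

random_cylinder_params <- function() {
  Rg1 <- stats::runif(1, 0.5, 2)
  list(G1 = 10^stats::runif(1, -3, 0),
       Rg1 = Rg1,
       Rg2 = Rg1 * stats::runif(1, 3, 10),
       d = stats::runif(1, 1.6, 4))
}

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), .Machine$double.xmin)

# numeric one-sided derivative, for crossover slope checks
one_sided_slope <- function(f, x, h, side = +1) {
  (f(x + side * h) - f(x + side * 2 * h)) / (-side * h)
}

# value continuity to 1e-9 relative, one-sided slopes to 1e-3 relative
# (finite-difference limited)
check_crossover <- function(f, x) {
  hv <- 1e-9 * x
  v <- f(x)
  testthat::expect_lt(abs(f(x - hv) - f(x + hv)) / abs(v), 1e-8)
  hs <- 1e-6 * x
  sl <- one_sided_slope(f, x, hs, side = -1)
  sr <- one_sided_slope(f, x, hs, side = +1)
  testthat::expect_lt(abs(sl - sr) / max(abs(sl), abs(sr)), 1e-3)
}
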