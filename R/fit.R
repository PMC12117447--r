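#' Detect Bragg-peak candidates on a scattering curve
#'
#' Works on a background-detrended signal: the curve is lightly smoothed with a
#' running mean, a local baseline is estimated with a wide running median, and
#' local maxima of the difference are screened by topographic prominence.
#' Deterministic for fixed options.
#'
#' @param curve a [scattering_curve()] with at least 32 points.
#' @param opts list; `min_prominence_rel` (fraction of the maximum detrended
#'   amplitude, default 0.05), `smooth` (running-mean window, odd, default 5),
#'   `baseline_window` (running-median window, odd, default ~n/8).
#' @return data.frame of candidates (class `peak_candidates`) with columns
#'   `q_position`, `prominence`, `width`, sorted by q. May have zero rows.
#' @export
detect_peaks <- function(curve, opts = list()) {
  stopifnot(inherits(curve, "scattering_curve"))
  n <- length(curve$q)
  if (n < 32L) abort("need >= 32 points", "mesosaxs_validation_error")
  min_prom <- opts$min_prominence_rel %||% 0.05
  sw <- opts$smooth %||% 5L
  bw <- opts$baseline_window %||% max(7L, 2L * (n %/% 16L) + 1L)
  if (sw %% 2L == 0L) sw <- sw + 1L
  if (bw %% 2L == 0L) bw <- bw + 1L

  y <- running_mean(curve$intensity, sw)
  base <- stats::runmed(y, bw, endrule = "median")
  det <- y - base
  top <- max(det)
  empty <- data.frame(q_position = numeric(0), prominence = numeric(0),
                      width = numeric(0))
  class(empty) <- c("peak_candidates", "data.frame")
  if (top <= 0) return(empty)

  is_max <- which(diff(sign(diff(det))) < 0) + 1L
  if (!length(is_max)) return(empty)
  cand <- lapply(is_max, function(i) {
    prom <- peak_prominence(det, i)
    if (prom < min_prom * top) return(NULL)
    half <- det[i] - prom / 2
    li <- i; while (li > 1L && det[li] > half) li <- li - 1L
    ri <- i; while (ri < n && det[ri] > half) ri <- ri + 1L
    width <- max(curve$q[ri] - curve$q[li], curve$q[min(i + 1L, n)] - curve$q[max(i - 1L, 1L)])
    data.frame(q_position = curve$q[i], prominence = prom, width = width)
  })
  cand <- do.call(rbind, cand[!vapply(cand, is.null, logical(1))])
  if (is.null(cand)) return(empty)
  cand <- cand[order(cand$q_position), , drop = FALSE]
  rownames(cand) <- NULL
  class(cand) <- c("peak_candidates", "data.frame")
  cand
}

running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  y <- as.numeric(y)
  bad <- is.na(y)
  y[bad] <- x[bad]
  y
}

peak_prominence <- function(x, i) {
  n <- length(x)
  left_min <- x[i]
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (x[j] > x[i]) break
    left_min <- min(left_min, x[j])
  }
  right_min <- x[i]
  j <- i
  while (j < n) {
    j <- j + 1L
    if (x[j] > x[i]) break
    right_min <- min(right_min, x[j])
  }
  x[i] - max(left_min, right_min)
}

#' Build a starting composite model from a curve
#'
#' Heuristics: `Rg` from an iteratively restricted Guinier fit (slope of
#' \eqn{\ln I} vs \eqn{q^2} over points with \eqn{q R_g \lesssim 1.3});
#' `d` starts at 4; the cylinder term is seeded with `Rg2 = Rg/3`,
#' `Rg1 = 1` nm and a rod-scale `G1` matched to the mid-q data; peak
#' parameters come from the candidates (sigma from the width estimate, area
#' `k = prominence * pi * sigma`); background from the 5th percentile of the
#' highest-q decade. A low-q fit with non-negative slope triggers an
#' initialization warning and seeds `Rg = 2*pi/q_min`.
#'
#' @param curve a [scattering_curve()].
#' @param candidates optional data.frame from [detect_peaks()]; `NULL` runs
#'   detection with defaults. An empty frame disables the peak component.
#' @return a [composite_model()].
#' @export
initialize_model <- function(curve, candidates = NULL) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (is.null(candidates)) candidates <- detect_peaks(curve)
  q <- curve$q
  I <- curve$intensity
  n <- length(q)

  hi <- q >= max(q) / 10
  if (sum(hi) < 5L) hi <- q >= stats::quantile(q, 0.8)
  bg <- max(stats::quantile(I[hi], 0.05), 1e-12 * max(I))

  pos <- I > 0
  sel <- pos & (q <= min(q) * 10)
  if (sum(sel) < 5L) sel <- pos & (seq_len(n) <= max(8L, n %/% 4L))
  Rg <- NA_real_
  G <- max(I)
  for (iter in 1:3) {
    if (sum(sel) < 4L) break
    fit <- stats::lm(log(I[sel]) ~ I(q[sel]^2))
    slope <- stats::coef(fit)[[2L]]
    if (!is.finite(slope) || slope >= 0) break
    Rg <- sqrt(-3 * slope)
    G <- exp(stats::coef(fit)[[1L]])
    sel <- pos & (q <= 1.3 / Rg)
  }
  if (!is.finite(Rg)) {
    warn("low-q Guinier fit has non-negative slope; seeding Rg from 2*pi/q_min",
         "mesosaxs_initialization_warning")
    Rg <- 2 * pi / min(q)
    G <- max(max(I) - bg, 1e-10 * max(I))
  }

  Rg2 <- max(Rg / 3, 1.6)
  Rg1 <- min(1, 0.6 * Rg2)
  d <- 4
  q_rod1 <- sqrt(d - 1) / Rg1
  q_rod2 <- ((2 / 3) * Rg2^2 - Rg1^2)^(-0.5)
  q_mid <- sqrt(q_rod1 * q_rod2)
  i_mid <- which.min(abs(q - min(q_mid, max(q))))
  I_mid <- max(I[i_mid] - bg, 1e-10 * max(I))
  G1 <- I_mid * q[i_mid] * exp(q[i_mid]^2 * Rg1^2 / 2)

  peaks <- list()
  if (nrow(candidates)) {
    dq <- stats::median(diff(q))
    for (i in seq_len(nrow(candidates))) {
      sigma <- max(candidates$width[i] / 2, dq)
      peaks[[i]] <- lorentzian_peak(k = candidates$prominence[i] * pi * sigma,
                                    sigma = sigma,
                                    q_max = candidates$q_position[i])
    }
  }
  composite_model(level1 = gp_level(G, Rg, d),
                  cylinder = gp_cylinder(G1, Rg1, Rg2, d),
                  peaks = peaks,
                  background = bg)
}

# --- parameter packing -------------------------------------------------------
# Scales and radii are log-parameterised for positivity; Rg2 is represented as
# sqrt(1.5*Rg1^2 + exp(u)) so the q2-real constraint (2/3*Rg2^2 > Rg1^2) holds
# by construction; peak positions stay on the natural scale with box bounds.

pack_model <- function(model, fix_d) {
  th <- c(); lo <- c(); up <- c(); nm <- c()
  add <- function(v, l, u, name) {
    th <<- c(th, v); lo <<- c(lo, l); up <<- c(up, u); nm <<- c(nm, name)
  }
  add(log(model$level1$G), -Inf, Inf, "logG")
  add(log(model$level1$Rg), -Inf, Inf, "logRg")
  add(log(model$cylinder$G1), -Inf, Inf, "logG1")
  add(log(model$cylinder$Rg1), -Inf, Inf, "logRg1")
  u0 <- (2 / 3) * model$cylinder$Rg2^2 - model$cylinder$Rg1^2
  add(log(1.5 * max(u0, 1e-8)), -Inf, Inf, "uRg2")
  add(log(max(model$background, 1e-14)), -Inf, Inf, "logBg")
  if (!fix_d) add(model$level1$d, 1.5, 4, "d")
  for (i in seq_along(model$peaks)) {
    p <- model$peaks[[i]]
    add(log(p$k), -Inf, Inf, paste0("logk", i))
    add(log(p$sigma), -Inf, Inf, paste0("logsigma", i))
    add(p$q_max, NA, NA, paste0("qmax", i))  # bounds filled by caller
  }
  names(th) <- nm
  list(theta = th, lower = lo, upper = up, names = nm,
       n_peaks = length(model$peaks))
}

unpack_model <- function(theta, n_peaks, fix_d, d_fixed) {
  d <- if (fix_d) d_fixed else theta[["d"]]
  Rg1 <- exp(theta[["logRg1"]])
  Rg2 <- sqrt(1.5 * (Rg1^2 + exp(theta[["uRg2"]]) / 1.5))
  peaks <- list()
  off <- if (fix_d) 6L else 7L
  for (i in seq_len(n_peaks)) {
    j <- off + 3L * (i - 1L)
    peaks[[i]] <- lorentzian_peak(exp(theta[[j + 1L]]), exp(theta[[j + 2L]]),
                                  theta[[j + 3L]])
  }
  composite_model(
    level1 = gp_level(exp(theta[["logG"]]), exp(theta[["logRg"]]), d),
    cylinder = gp_cylinder(exp(theta[["logG1"]]), Rg1, Rg2, d),
    peaks = peaks,
    background = exp(theta[["logBg"]])
  )
}

#' Fit the composite model to a scattering curve
#'
#' Weighted least squares with `stats::nlminb` (quasi-Newton with box
#' bounds) on a transformed parameter vector: scales and radii on the log
#' scale, the cylinder `Rg2` reparameterised so the branch-continuity
#' constraints hold by construction, peak positions box-bounded to the
#' observed q range. Weights are `1/uncertainty^2` when the curve carries
#' uncertainties, else Poisson-like `1/max(I, eps)^2` with
#' `eps = 1e-12 * max(I)`. Several jittered restarts guard against the
#' multimodality of the composite; the best objective wins and the whole
#' procedure is a pure function of `(curve, init, opts)`.
#'
#' @param curve a [scattering_curve()].
#' @param init a [composite_model()] starting point, e.g. from
#'   [initialize_model()]. Must contain `level1` and `cylinder`.
#' @param opts list: `fix_d` (default `TRUE`, pins the Porod exponent at
#'   `d_value`), `d_value` (default 4), `max_peaks` (default 3), `multistart`
#'   (default 8), `seed` (default 1), `maxit` (default 400).
#' @return a `fit_result` list: `model`, `uncertainties` (per-parameter SEs on
#'   the natural scale), `gof` (`chisq_dof`, `residuals`, weighted),
#'   `provenance` (init record, iteration count, convergence flag, seed,
#'   objective trace, warnings).
#' @export
fit_composite <- function(curve, init, opts = list()) {
  stopifnot(inherits(curve, "scattering_curve"), inherits(init, "composite_model"))
  if (is.null(init$level1) || is.null(init$cylinder)) {
    abort("init must enable level1 and cylinder components",
          "mesosaxs_configuration_error")
  }
  fix_d <- opts$fix_d %||% TRUE
  d_value <- opts$d_value %||% init$level1$d
  max_peaks <- opts$max_peaks %||% 3L
  multistart <- opts$multistart %||% 8L
  seed <- opts$seed %||% 1L
  maxit <- opts$maxit %||% 400L

  if (length(init$peaks) > max_peaks) {
    ks <- vapply(init$peaks, `[[`, numeric(1), "k")
    keep <- order(ks, decreasing = TRUE)[seq_len(max_peaks)]
    init$peaks <- init$peaks[sort(keep)]
    init <- composite_model(init$level1, init$cylinder, init$peaks,
                            init$background)
  }

  q <- curve$q
  I <- curve$intensity
  eps <- 1e-12 * max(abs(I))
  # 1/sigma^2 weights when real uncertainties exist; an uncertainty column
  # that is only the generator's epsilon floor (noiseless synthetic data)
  # carries no information and falls through to Poisson-like 1/I^2 weights.
  use_unc <- !is.null(curve$uncertainty) &&
    stats::median(curve$uncertainty) > 1e-9 * max(abs(I))
  w <- if (use_unc) 1 / curve$uncertainty^2 else 1 / pmax(abs(I), eps)^2
  w <- w / mean(w)  # objective scaling only; does not move the optimum
  sw <- sqrt(w)

  packed <- pack_model(init, fix_d)
  n_free <- length(packed$theta)
  if (length(q) <= n_free) {
    abort("fewer points than free parameters", "mesosaxs_validation_error")
  }
  qb <- grep("^qmax", packed$names)
  packed$lower[qb] <- min(q)
  packed$upper[qb] <- max(q)

  resid_fn <- function(theta) {
    names(theta) <- packed$names
    m <- tryCatch(unpack_model(theta, packed$n_peaks, fix_d, d_value),
                  error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, length(q)))
    (eval_composite(m, q) - I) * sw
  }
  obj <- function(theta) {
    r <- resid_fn(theta)
    if (any(!is.finite(r))) return(1e30)
    sum(r^2)
  }

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(as.integer(seed))

  best <- NULL
  trace <- numeric(0)
  n_iter_total <- 0L
  for (s in seq_len(max(1L, multistart))) {
    th0 <- packed$theta
    if (s > 1L) {
      jit <- stats::rnorm(length(th0), sd = 0.25)
      jit[qb] <- stats::rnorm(length(qb), sd = 0.1) *
        exp(th0[grep("^logsigma", packed$names)])
      th0 <- th0 + jit
      th0[qb] <- pmin(pmax(packed$theta[qb] + jit[qb], packed$lower[qb]),
                      packed$upper[qb])
      if (!fix_d) th0[packed$names == "d"] <- packed$theta[packed$names == "d"]
    }
    res <- tryCatch(
      stats::nlminb(th0, obj, lower = packed$lower, upper = packed$upper,
                    control = list(iter.max = maxit, eval.max = 4L * maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$objective)) next
    n_iter_total <- n_iter_total + res$iterations
    if (is.null(best) || res$objective < best$objective) best <- res
    trace <- c(trace, if (is.null(best)) NA_real_ else best$objective)
  }
  if (is.null(best)) {
    abort("fit did not converge in any start", "mesosaxs_fit_error")
  }

  theta <- best$par
  names(theta) <- packed$names
  model <- unpack_model(theta, packed$n_peaks, fix_d, d_value)
  r <- resid_fn(theta)
  dof <- length(q) - n_free
  chisq_dof <- sum(r^2) / dof

  warnings <- character(0)
  scale_pars <- grep("^log(G|G1|k)", packed$names)
  if (any(exp(theta[scale_pars]) < 1e-10 * max(abs(I)))) {
    warnings <- c(warnings, "structure scale collapsed toward zero bound")
  }
  at_bound <- which(is.finite(packed$lower) & (theta - packed$lower < 1e-8) |
                    is.finite(packed$upper) & (packed$upper - theta < 1e-8))
  if (length(at_bound)) {
    warnings <- c(warnings, paste("parameter at bound:",
                                  paste(packed$names[at_bound], collapse = ", ")))
  }

  se <- fit_standard_errors(resid_fn, theta, chisq_dof, packed, fix_d, d_value)

  structure(list(
    model = model,
    uncertainties = se,
    gof = list(chisq_dof = chisq_dof, residuals = r, weighted = TRUE),
    provenance = list(
      init = model_to_config(init),
      iterations = n_iter_total,
      converged = best$convergence == 0,
      seed = seed,
      multistart = multistart,
      fix_d = fix_d,
      d_value = if (fix_d) d_value else NA_real_,
      objective = best$objective,
      objective_trace = trace,
      warnings = warnings
    )
  ), class = "fit_result")
}

# Gauss-Newton standard errors: numeric Jacobian of weighted residuals on the
# transformed scale, delta-method back to natural parameters.
fit_standard_errors <- function(resid_fn, theta, chisq_dof, packed,
                                fix_d, d_value) {
  p <- length(theta)
  r0 <- resid_fn(theta)
  J <- matrix(NA_real_, length(r0), p)
  h <- pmax(1e-6, abs(theta) * 1e-6)
  for (j in seq_len(p)) {
    tp <- theta; tp[j] <- tp[j] + h[j]
    tm <- theta; tm[j] <- tm[j] - h[j]
    J[, j] <- (resid_fn(tp) - resid_fn(tm)) / (2 * h[j])
  }
  cov <- tryCatch(chisq_dof * solve(crossprod(J)), error = function(e) NULL)
  cfg <- model_to_config(unpack_model(theta, packed$n_peaks, fix_d, d_value))
  if (is.null(cov)) {
    return(stats::setNames(rep(NA_real_, length(cfg)), names(cfg)))
  }
  # numeric gradient of each natural parameter wrt theta
  se <- vapply(seq_along(cfg), function(i) {
    g <- vapply(seq_len(p), function(j) {
      tp <- theta; tp[j] <- tp[j] + h[j]
      tm <- theta; tm[j] <- tm[j] - h[j]
      cp <- model_to_config(unpack_model(tp, packed$n_peaks, fix_d, d_value))[[i]]
      cm <- model_to_config(unpack_model(tm, packed$n_peaks, fix_d, d_value))[[i]]
      (cp - cm) / (2 * h[j])
    }, numeric(1))
    v <- drop(t(g) %*% cov %*% g)
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }, numeric(1))
  stats::setNames(se, names(cfg))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> chisq/dof = %.4g, converged = %s, seed = %s\n",
              x$gof$chisq_dof, x$provenance$converged, x$provenance$seed))
  print(x$model)
  invisible(x)
}
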