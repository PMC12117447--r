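#' Bragg d-spacing from a peak position
#'
#' @param q peak position(s) in nm^-1, > 0.
#' @return d = 2*pi/q in nm.
#' @examples
#' bragg_spacing(1.140)  # 5.511 nm
#' @export
bragg_spacing <- function(q) {
  if (any(!is.finite(q)) || any(q <= 0)) {
    abort("q must be finite and > 0", "mesosaxs_domain_error")
  }
  2 * pi / q
}

# Allowed-reflection tables for the lyotropic phases handled here. `m` is the
# reflection modulus (sqrt(h^2+hk+k^2) for 2D hexagonal, sqrt(h^2+k^2+l^2) for
# cubic, l for lamellar); relative peak-position ratios are m/m[1].
RATIO_TABLES <- list(
  hexagonal_HII = list(m = c(1, sqrt(3), 2),
                       labels = c("100", "110", "200")),
  cubic_Pn3m = list(m = sqrt(c(2, 3, 4, 6, 8, 9)),
                    labels = c("110", "111", "200", "211", "220", "221")),
  cubic_Im3m = list(m = sqrt(c(2, 4, 6, 8, 10, 12)),
                    labels = c("110", "200", "211", "220", "310", "222")),
  cubic_Ia3d = list(m = sqrt(c(6, 8, 14, 16)),
                    labels = c("211", "220", "321", "400")),
  lamellar = list(m = c(1, 2, 3),
                  labels = c("001", "002", "003"))
)

#' Allowed-reflection ratio table
#'
#' @param phase phase name, or `NULL` for the full table.
#' @return list with reflection moduli `m`, Miller-index `labels`, and
#'   relative `ratios` (m normalised to the first allowed reflection).
#' @export
ratio_table <- function(phase = NULL) {
  if (is.null(phase)) {
    return(lapply(stats::setNames(names(RATIO_TABLES), names(RATIO_TABLES)),
                  ratio_table))
  }
  if (!phase %in% names(RATIO_TABLES)) {
    abort(sprintf("unknown phase '%s'", phase), "mesosaxs_parameter_error")
  }
  tab <- RATIO_TABLES[[phase]]
  tab$ratios <- tab$m / tab$m[1L]
  tab
}

#' Index observed peaks against candidate mesophases
#'
#' For each candidate phase the first observed peak is anchored to the phase's
#' first allowed reflection; the remaining reflections are predicted and
#' matched greedily (monotone, gaps allowed on both sides) within a relative
#' tolerance. Assignments are ranked by number of matched peaks (descending)
#' then RMS relative deviation (ascending). A single observed peak is returned
#' `unassigned` unless exactly one phase is requested.
#'
#' @param q_obs sorted observed peak positions (nm^-1).
#' @param phases character vector of phases to try (default: all known).
#' @param tol_rel relative matching tolerance (default 0.02).
#' @return list of `phase_assignment` objects, best first. Each has fields
#'   `phase`, `matched` (data.frame: `q_obs`, `index`, `q_expected`,
#'   `rel_dev`, `d_spacing`), `a` (lattice constant, nm), `score` (RMS
#'   relative deviation), `n_matched`, and `note`.
#' @export
index_peaks <- function(q_obs, phases = names(RATIO_TABLES), tol_rel = 0.02) {
  if (!length(q_obs)) abort("empty peak list", "mesosaxs_input_error")
  if (any(!is.finite(q_obs)) || any(q_obs <= 0)) {
    abort("peak positions must be finite and > 0", "mesosaxs_input_error")
  }
  if (is.unsorted(q_obs, strictly = TRUE)) {
    abort("q_obs must be sorted increasing", "mesosaxs_input_error")
  }
  phases <- match.arg(phases, names(RATIO_TABLES), several.ok = TRUE)

  if (length(q_obs) == 1L && length(phases) > 1L) {
    ua <- unassigned_assignment(q_obs,
      "single peak cannot discriminate between candidate phases")
    return(list(ua))
  }

  out <- lapply(phases, function(ph) match_phase(q_obs, ph, tol_rel))
  ord <- order(-vapply(out, `[[`, numeric(1), "n_matched"),
               vapply(out, `[[`, numeric(1), "n_missing"),
               vapply(out, `[[`, numeric(1), "score"))
  out <- out[ord]
  if (out[[1L]]$n_matched < 2L && length(phases) > 1L) {
    out <- c(list(unassigned_assignment(q_obs,
      "no phase matched at least two reflections")), out)
  }
  out
}

# The first observed peak is anchored, in turn, to each allowed reflection
# (so a series missing its leading reflections still indexes); the hypothesis
# with most matches, then lowest score, then lowest anchor index wins. With a
# single observed peak only the first-reflection anchor is considered.
match_phase <- function(q_obs, phase, tol_rel) {
  n_anchor <- if (length(q_obs) >= 2L) length(ratio_table(phase)$m) else 1L
  best <- NULL
  for (anchor in seq_len(n_anchor)) {
    cand <- match_phase_anchor(q_obs, phase, tol_rel, anchor)
    better <- is.null(best) ||
      cand$n_matched > best$n_matched ||
      (cand$n_matched == best$n_matched && cand$n_missing < best$n_missing) ||
      (cand$n_matched == best$n_matched && cand$n_missing == best$n_missing &&
         cand$score < best$score)
    if (better) best <- cand
  }
  best
}

match_phase_anchor <- function(q_obs, phase, tol_rel, anchor) {
  tab <- ratio_table(phase)
  scale <- q_obs[1L] / tab$ratios[anchor]
  expected <- scale * tab$ratios
  used <- rep(FALSE, length(expected))
  rows <- list()
  last_k <- 0L
  for (qo in q_obs) {
    dev <- abs(qo - expected) / expected
    dev[used] <- Inf
    if (last_k > 0L) dev[seq_len(last_k)] <- Inf
    k <- which.min(dev)
    if (dev[k] <= tol_rel) {
      used[k] <- TRUE
      last_k <- k
      rows[[length(rows) + 1L]] <- data.frame(
        q_obs = qo, index = tab$labels[k], q_expected = expected[k],
        rel_dev = (qo - expected[k]) / expected[k],
        d_spacing = 2 * pi / qo)
    }
  }
  matched <- if (length(rows)) do.call(rbind, rows) else
    data.frame(q_obs = numeric(0), index = character(0),
               q_expected = numeric(0), rel_dev = numeric(0),
               d_spacing = numeric(0))
  score <- if (nrow(matched)) sqrt(mean(matched$rel_dev^2)) else Inf
  # parsimony: allowed reflections predicted inside the observed q span but
  # not matched count against the assignment (breaks subset degeneracies,
  # e.g. hexagonal 1:sqrt(3):2 versus Pn3m sqrt(2):sqrt(6):sqrt(8))
  interior <- expected >= min(q_obs) * (1 - tol_rel) &
              expected <= max(q_obs) * (1 + tol_rel)
  n_missing <- sum(interior & !used)
  asg <- structure(list(phase = phase, matched = matched,
                        a = NA_real_, score = score,
                        n_matched = nrow(matched), n_missing = n_missing,
                        note = NULL),
                   class = "phase_assignment")
  if (nrow(matched)) asg$a <- lattice_constant(asg)
  asg
}

unassigned_assignment <- function(q_obs, note) {
  structure(list(phase = "unassigned",
                 matched = data.frame(q_obs = q_obs, index = NA_character_,
                                      q_expected = NA_real_, rel_dev = NA_real_,
                                      d_spacing = 2 * pi / q_obs),
                 a = NA_real_, score = Inf, n_matched = 0L,
                 n_missing = NA_integer_, note = note),
            class = "phase_assignment")
}

#' Lattice constant from a phase assignment
#'
#' Hexagonal: \eqn{a = 4\pi m/(\sqrt{3} q)} per matched reflection (for the
#' (100) reflection this is the familiar \eqn{4\pi/(\sqrt{3} q_{100})});
#' cubic: \eqn{a = 2\pi\sqrt{h^2+k^2+l^2}/q}; lamellar: \eqn{a = d_{001}}.
#' `method = "anchor"` (default) uses the first matched reflection only, which
#' keeps single-strong-peak cases deterministic; `"regression"` least-squares
#' the lattice constant over all matched reflections.
#'
#' @param assignment a `phase_assignment` with at least one matched peak.
#' @param method `"anchor"` or `"regression"`.
#' @return lattice constant in nm.
#' @export
lattice_constant <- function(assignment, method = c("anchor", "regression")) {
  method <- match.arg(method)
  stopifnot(inherits(assignment, "phase_assignment"))
  if (assignment$phase == "unassigned") {
    abort("cannot compute lattice constant for unassigned phase",
          "mesosaxs_state_error")
  }
  if (!nrow(assignment$matched)) {
    abort("assignment has no matched peaks", "mesosaxs_state_error")
  }
  tab <- ratio_table(assignment$phase)
  m <- tab$m[match(assignment$matched$index, tab$labels)]
  q <- assignment$matched$q_obs
  per_peak_a <- switch(substr(assignment$phase, 1, 5),
    hexag = 4 * pi * m / (sqrt(3) * q),
    cubic = 2 * pi * m / q,
    lamel = 2 * pi * m / q)
  if (method == "anchor") {
    per_peak_a[1L]
  } else {
    # least-squares q = c*m => c = sum(m q)/sum(m^2); a = conversion/c
    cstar <- sum(m * q) / sum(m^2)
    switch(substr(assignment$phase, 1, 5),
           hexag = 4 * pi / (sqrt(3) * cstar),
           cubic = 2 * pi / cstar,
           lamel = 2 * pi / cstar)
  }
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat(sprintf("<phase_assignment> %s: %d matched, score %.3g, a = %.4g nm\n",
              x$phase, x$n_matched, x$score, x$a))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (nrow(x$matched)) print(format(x$matched, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Locate mesophase transitions across a temperature series
#'
#' Assigns each temperature's peak set independently with [index_peaks()] and
#' reports a transition at the first temperature whose phase differs from the
#' previous assignable one. Points with no peaks (or no confident assignment)
#' are marked `unassigned` and skipped in the comparison.
#'
#' @param series list of `list(temperature = , q_obs = )`, sorted by
#'   temperature, length >= 2.
#' @param phases,tol_rel passed to [index_peaks()].
#' @return list with `assignments` (data.frame: temperature, phase, a, score)
#'   and `transitions` (data.frame: temperature, from, to; zero rows if none).
#' @export
detect_transition <- function(series, phases = names(RATIO_TABLES),
                              tol_rel = 0.02) {
  if (length(series) < 2L) {
    abort("need at least 2 temperatures", "mesosaxs_input_error")
  }
  temps <- vapply(series, `[[`, numeric(1), "temperature")
  if (is.unsorted(temps)) {
    abort("series must be sorted by temperature", "mesosaxs_input_error")
  }
  rows <- lapply(series, function(pt) {
    if (!length(pt$q_obs)) {
      return(data.frame(temperature = pt$temperature, phase = "unassigned",
                        a = NA_real_, score = NA_real_))
    }
    best <- index_peaks(sort(pt$q_obs), phases = phases, tol_rel = tol_rel)[[1L]]
    data.frame(temperature = pt$temperature, phase = best$phase,
               a = best$a, score = if (is.finite(best$score)) best$score else NA_real_)
  })
  assignments <- do.call(rbind, rows)
  known <- assignments[assignments$phase != "unassigned", , drop = FALSE]
  transitions <- data.frame(temperature = numeric(0), from = character(0),
                            to = character(0))
  if (nrow(known) >= 2L) {
    chg <- which(known$phase[-1L] != known$phase[-nrow(known)])
    if (length(chg)) {
      transitions <- data.frame(temperature = known$temperature[chg + 1L],
                                from = known$phase[chg],
                                to = known$phase[chg + 1L])
    }
  }
  list(assignments = assignments, transitions = transitions)
}
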