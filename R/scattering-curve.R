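#' Scattering curve container
#'
#' A validated one-dimensional small-angle scattering curve: strictly
#' increasing positive q (canonically in nm^-1), intensities in arbitrary
#' units, and an optional per-point standard deviation.
#'
#' @param q numeric vector of scattering-vector magnitudes (nm^-1), strictly
#'   increasing and positive.
#' @param intensity numeric vector, same length as `q`. Negative values are
#'   only accepted when `meta$background_subtracted` is `TRUE`.
#' @param uncertainty optional numeric vector of positive standard deviations,
#'   same length as `q`.
#' @param meta list of metadata; recognised fields: `source_unit`
#'   (`"nm^-1"` or `"A^-1"`), `temperature_C`, `label`, `instrument`,
#'   `background_subtracted` (logical, default `FALSE`), `n_dropped`
#'   (rows discarded on load).
#' @return an object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, uncertainty = NULL, meta = list()) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  meta$source_unit <- meta$source_unit %||% "nm^-1"
  meta$background_subtracted <- isTRUE(meta$background_subtracted)
  if (length(q) != length(intensity)) {
    abort("q and intensity must have the same length", "mesosaxs_validation_error")
  }
  if (length(q) == 0L) {
    abort("empty curve", "mesosaxs_validation_error")
  }
  if (any(!is.finite(q)) || any(q <= 0)) {
    abort("q must be finite and > 0", "mesosaxs_validation_error")
  }
  if (any(diff(q) <= 0)) {
    abort("q must be strictly increasing (duplicate abscissae?)",
          "mesosaxs_duplicate_abscissa_error")
  }
  if (any(!is.finite(intensity))) {
    abort("intensity must be finite", "mesosaxs_validation_error")
  }
  if (!meta$background_subtracted && any(intensity < 0)) {
    abort("negative intensity on data not marked background-subtracted",
          "mesosaxs_validation_error")
  }
  if (!is.null(uncertainty)) {
    uncertainty <- as.numeric(uncertainty)
    if (length(uncertainty) != length(q) || any(!is.finite(uncertainty)) ||
        any(uncertainty <= 0)) {
      abort("uncertainty must be positive, finite and match q in length",
            "mesosaxs_validation_error")
    }
  }
  structure(list(q = q, intensity = intensity, uncertainty = uncertainty,
                 meta = meta),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q in [%.4g, %.4g] nm^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$uncertainty)) "" else ", with uncertainties"))
  if (!is.null(x$meta$label)) cat("  label:", x$meta$label, "\n")
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$q)

#' Read a scattering curve from delimited text
#'
#' Accepts 2- or 3-column delimited text (comma, tab or whitespace; sniffed),
#' with `#` comment lines and an optional header row. Column 3, when present,
#' is read as the per-point standard deviation. Rows containing non-finite
#' values are dropped and counted in `meta$n_dropped`. The q axis is converted
#' to the canonical nm^-1.
#'
#' Unit resolution: `unit_hint` wins; otherwise a header mentioning angstroms
#' (e.g. `q(A^-1)`) is used; otherwise max(q) < 0.5 is taken to indicate A^-1
#' (typical SAXS ranges in A^-1 end well below 0.5). The decision is recorded
#' in `meta$source_unit` and messaged.
#'
#' @param path file path.
#' @param unit_hint optional unit tag (see [convert_q_units()]).
#' @return a [scattering_curve()].
#' @export
read_curve <- function(path, unit_hint = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta <- parse_curve_header_meta(lines)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort("no data rows found", "mesosaxs_malformed_input_error")
  }
  sep <- if (any(grepl(",", lines))) "," else ""
  header_unit <- NULL
  first <- strsplit(trimws(lines[[1L]]), if (sep == ",") "," else "[ \t]+")[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  if (has_header) {
    header_unit <- sniff_unit_from_header(lines[[1L]])
    lines <- lines[-1L]
  }
  df <- utils::read.table(text = lines, sep = sep, header = FALSE,
                          comment.char = "#", fill = TRUE,
                          colClasses = "numeric")
  if (ncol(df) < 2L) {
    abort("need at least two numeric columns (q, intensity)",
          "mesosaxs_malformed_input_error")
  }
  keep <- is.finite(df[[1L]]) & is.finite(df[[2L]])
  if (ncol(df) >= 3L) keep <- keep & is.finite(df[[3L]])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 8L) {
    abort(sprintf("only %d valid points (need >= 8)", nrow(df)),
          "mesosaxs_malformed_input_error")
  }
  ord <- order(df[[1L]])
  df <- df[ord, , drop = FALSE]
  if (any(diff(df[[1L]]) <= 0)) {
    abort("duplicate q values after sorting", "mesosaxs_duplicate_abscissa_error")
  }

  unit <- if (!is.null(unit_hint)) {
    normalize_q_unit(unit_hint)
  } else if (!is.null(meta$source_unit)) {
    normalize_q_unit(meta$source_unit)
  } else if (!is.null(header_unit)) {
    header_unit
  } else if (max(df[[1L]]) < 0.5) {
    message("read_curve: max(q) < 0.5 with no unit hint; assuming A^-1")
    "A^-1"
  } else {
    "nm^-1"
  }
  meta$source_unit <- unit
  meta$n_dropped <- n_dropped
  scattering_curve(q = convert_q_units(df[[1L]], unit, "nm^-1"),
                   intensity = df[[2L]],
                   uncertainty = if (ncol(df) >= 3L) df[[3L]] else NULL,
                   meta = meta)
}

parse_curve_header_meta <- function(lines) {
  meta <- list()
  kv <- regmatches(lines, regexec("^#\\s*([A-Za-z_]+):\\s*(.*)$", lines))
  for (m in kv) {
    if (length(m) == 3L) {
      key <- m[[2L]]; val <- trimws(m[[3L]])
      meta[[switch(key,
                   unit = "source_unit",
                   temperature_C = "temperature_C",
                   label = "label",
                   instrument = "instrument",
                   background_subtracted = "background_subtracted",
                   key)]] <-
        switch(key,
               temperature_C = as.numeric(val),
               background_subtracted = identical(tolower(val), "true"),
               val)
    }
  }
  meta
}

sniff_unit_from_header <- function(header) {
  h <- tolower(header)
  if (grepl("a\\^?-1|1/a|ang|å", h) && !grepl("nm", h)) return("A^-1")
  if (grepl("nm", h)) return("nm^-1")
  NULL
}

#' Write a scattering curve to delimited text
#'
#' Emits a `#`-commented header recording units and metadata followed by 2 or 3
#' whitespace-separated numeric columns at full double precision, so that
#' `read_curve(write_curve(x))` round-trips bit-exactly. Output is a pure
#' function of the curve.
#'
#' @param curve a [scattering_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  if (!inherits(curve, "scattering_curve")) {
    abort("not a scattering_curve", "mesosaxs_validation_error")
  }
  hdr <- c("# mesosaxs scattering curve",
           "# unit: nm^-1",
           sprintf("# columns: q intensity%s",
                   if (is.null(curve$uncertainty)) "" else " uncertainty"))
  for (key in c("label", "instrument")) {
    if (!is.null(curve$meta[[key]])) {
      hdr <- c(hdr, sprintf("# %s: %s", key, curve$meta[[key]]))
    }
  }
  if (!is.null(curve$meta$temperature_C)) {
    hdr <- c(hdr, sprintf("# temperature_C: %.17g", curve$meta$temperature_C))
  }
  if (isTRUE(curve$meta$background_subtracted)) {
    hdr <- c(hdr, "# background_subtracted: true")
  }
  cols <- list(curve$q, curve$intensity)
  if (!is.null(curve$uncertainty)) cols <- c(cols, list(curve$uncertainty))
  rows <- do.call(paste, c(lapply(cols, function(v) sprintf("%.17g", v))))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(sprintf("cannot write '%s': %s", path, conditionMessage(ok)),
          "mesosaxs_io_error")
  }
  invisible(path)
}

#' Concentration/response series for CAC analysis
#'
#' @param concentration molar concentrations, > 0, at least 4 distinct values.
#' @param response scattered-light count rate (kcps) or detector response,
#'   >= 0, same length.
#' @param replicate optional replicate index.
#' @return a `data.frame` with class `concentration_series`.
#' @export
concentration_series <- function(concentration, response, replicate = NULL) {
  concentration <- as.numeric(concentration)
  response <- as.numeric(response)
  if (length(concentration) != length(response)) {
    abort("concentration and response lengths differ", "mesosaxs_validation_error")
  }
  if (any(!is.finite(concentration)) || any(concentration <= 0)) {
    abort("concentrations must be finite and > 0", "mesosaxs_validation_error")
  }
  if (any(!is.finite(response)) || any(response < 0)) {
    abort("responses must be finite and >= 0", "mesosaxs_validation_error")
  }
  if (length(unique(concentration)) < 4L) {
    abort("need at least 4 distinct concentrations", "mesosaxs_validation_error")
  }
  df <- data.frame(concentration = concentration, response = response)
  if (!is.null(replicate)) df$replicate <- replicate
  class(df) <- c("concentration_series", "data.frame")
  df
}

#' Read a concentration series from CSV
#'
#' Expects columns `concentration_M` and `response_kcps` (or the first two
#' numeric columns), plus an optional `replicate` column.
#'
#' @param path CSV file path.
#' @return a [concentration_series()].
#' @export
read_concentration_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  conc_col <- intersect(c("concentration_M", "concentration"), names(df))[1]
  resp_col <- intersect(c("response_kcps", "response"), names(df))[1]
  if (is.na(conc_col) || is.na(resp_col)) {
    conc_col <- names(df)[1L]
    resp_col <- names(df)[2L]
  }
  concentration_series(df[[conc_col]], df[[resp_col]],
                       replicate = df[["replicate"]])
}
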