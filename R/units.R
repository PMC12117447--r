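#' Convert scattering-vector magnitudes between reciprocal units
#'
#' The package works internally in nm^-1; instrument exports frequently use
#' A^-1 (angstrom). The conversion is an exact factor of 10.
#'
#' @param values numeric vector of q magnitudes.
#' @param from_unit,to_unit unit tags; any of `"nm^-1"`, `"A^-1"` (aliases
#'   `"1/nm"`, `"1/A"`, `"angstrom^-1"`, `"Å^-1"` are accepted).
#' @return numeric vector in `to_unit`.
#' @examples
#' convert_q_units(0.1140, "A^-1", "nm^-1")  # 1.140
#' @export
convert_q_units <- function(values, from_unit, to_unit) {
  from <- normalize_q_unit(from_unit)
  to <- normalize_q_unit(to_unit)
  if (from == to) return(values)
  if (from == "A^-1" && to == "nm^-1") return(values * 10)
  values / 10
}

normalize_q_unit <- function(unit) {
  if (length(unit) != 1L || !is.character(unit)) {
    abort("unit tag must be a single string", "mesosaxs_unit_error")
  }
  u <- tolower(gsub("\\s", "", unit))
  if (u %in% c("a^-1", "1/a", "a-1", "ang^-1", "angstrom^-1",
               "å^-1", "å-1", "1/å", "inva")) {
    return("A^-1")
  }
  if (u %in% c("nm^-1", "1/nm", "nm-1", "invnm")) {
    return("nm^-1")
  }
  abort(sprintf("unknown q unit tag: '%s'", unit), "mesosaxs_unit_error")
}
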