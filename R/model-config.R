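# Flat key-value serialization of composite models.
# Documented keys: g1.G, g1.Rg, g1.d, cyl.G1, cyl.Rg1, cyl.Rg2, cyl.d,
# peak1.k, peak1.sigma, peak1.qmax, ..., background.

#' Serialize a composite model to a flat named vector
#'
#' @param model a [composite_model()].
#' @return named numeric vector.
#' @export
model_to_config <- function(model) {
  stopifnot(inherits(model, "composite_model"))
  out <- c()
  if (!is.null(model$level1)) {
    out <- c(out, g1.G = model$level1$G, g1.Rg = model$level1$Rg,
             g1.d = model$level1$d)
  }
  if (!is.null(model$cylinder)) {
    out <- c(out, cyl.G1 = model$cylinder$G1, cyl.Rg1 = model$cylinder$Rg1,
             cyl.Rg2 = model$cylinder$Rg2, cyl.d = model$cylinder$d)
  }
  for (i in seq_along(model$peaks)) {
    p <- model$peaks[[i]]
    v <- c(p$k, p$sigma, p$q_max)
    names(v) <- paste0("peak", i, c(".k", ".sigma", ".qmax"))
    out <- c(out, v)
  }
  c(out, background = model$background)
}

#' Rebuild a composite model from a flat named vector
#'
#' @param config named numeric vector as produced by [model_to_config()].
#' @return a [composite_model()].
#' @export
config_to_model <- function(config) {
  nm <- names(config)
  level1 <- if ("g1.G" %in% nm) {
    gp_level(config[["g1.G"]], config[["g1.Rg"]],
             if ("g1.d" %in% nm) config[["g1.d"]] else 4)
  }
  cylinder <- if ("cyl.G1" %in% nm) {
    gp_cylinder(config[["cyl.G1"]], config[["cyl.Rg1"]], config[["cyl.Rg2"]],
                if ("cyl.d" %in% nm) config[["cyl.d"]] else 4)
  }
  peaks <- list()
  i <- 1L
  while (paste0("peak", i, ".k") %in% nm) {
    peaks[[i]] <- lorentzian_peak(config[[paste0("peak", i, ".k")]],
                                  config[[paste0("peak", i, ".sigma")]],
                                  config[[paste0("peak", i, ".qmax")]])
    i <- i + 1L
  }
  composite_model(level1 = level1, cylinder = cylinder, peaks = peaks,
                  background = if ("background" %in% nm) config[["background"]] else 0)
}

#' Write a model config file (`key = value` lines)
#'
#' @param model a [composite_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  cfg <- model_to_config(model)
  writeLines(c("# mesosaxs model config",
               sprintf("%s = %.17g", names(cfg), cfg)), path)
  invisible(path)
}

#' Read a model config file
#'
#' @param path path to a `key = value` file (`#` comments allowed).
#' @return a [composite_model()].
#' @export
read_model_config <- function(path) {
  cfg <- read_flat_config(path)
  cfg <- cfg[vapply(cfg, is.numeric, logical(1))]
  config_to_model(unlist(cfg))
}

read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(parts, function(p) trimws(p[[1L]]), character(1))
  vals <- vapply(parts, function(p) trimws(paste(p[-1L], collapse = "=")),
                 character(1))
  num <- suppressWarnings(as.numeric(vals))
  out <- as.list(ifelse(is.na(num), vals, num))
  out <- stats::setNames(lapply(seq_along(keys), function(i) {
    if (is.na(num[[i]])) vals[[i]] else num[[i]]
  }), keys)
  out
}
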