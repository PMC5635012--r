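#' Read model parameters from a configuration file
#'
#' Configuration files are YAML with up to four sections: `physical`
#' (fields of [trapping_params()]), `dimensionless` (fields of
#' [dimensionless_params()] plus optional `k_off_scale`, `D_P_scale`),
#' `geometry` (`L`, `T`), and `simulation` (free-form, returned as-is).
#' If a `dimensionless` section is present it takes precedence and is
#' realized via [from_dimensionless()]; `physical` and `geometry` entries
#' then act as overrides of the realized parameters.
#'
#' @param path Path to the YAML configuration file.
#' @param overrides Named list applied last (e.g. from command-line flags).
#' @return A list with `params` (a [trapping_params()] object) and
#'   `simulation` (list of simulation settings, possibly empty).
#' @export
read_config <- function(path, overrides = list()) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package", call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("malformed configuration file", call. = FALSE)
  # YAML 1.1 parses the bare keys N and T as booleans; undo that
  fix_keys <- function(x) {
    if (is.list(x))
      names(x) <- sub("^FALSE$", "N", sub("^TRUE$", "T", names(x)))
    x
  }
  cfg <- lapply(cfg, fix_keys)
  phys <- c(cfg$physical, cfg$geometry)
  if (!is.null(cfg$dimensionless)) {
    dl <- cfg$dimensionless
    scales <- list(k_off_scale = dl$k_off_scale %||% 1,
                   D_P_scale = dl$D_P_scale %||% 1)
    dl$k_off_scale <- NULL
    dl$D_P_scale <- NULL
    dp <- do.call(dimensionless_params, dl)
    p <- from_dimensionless(dp, k_off_scale = scales$k_off_scale,
                            D_P_scale = scales$D_P_scale)
    fields <- unclass(p)
    for (nm in names(phys)) fields[[nm]] <- phys[[nm]]
  } else {
    fields <- phys
  }
  for (nm in names(overrides)) fields[[nm]] <- overrides[[nm]]
  fields <- fields[names(fields) %in% names(formals(trapping_params))]
  list(params = do.call(trapping_params, fields),
       simulation = cfg$simulation %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
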