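#' Serialize analysis inputs to a YAML config
#'
#' Writes the inputs from which a scenario specification is rebuilt:
#' scenario id, epoch anchoring, prior bounds, clock, and sampling design
#' (ISO-8601 dates).  Constraints are not stored; they are re-derived by
#' [build_scenario()], which guarantees file and object never disagree.
#'
#' @param spec a [build_scenario()] spec.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
scenario_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  d <- spec$design
  y <- list(
    scenario_id = spec$scenario_id,
    anchor = spec$anchor,
    ne_bounds = spec$ne_bounds,
    clock = list(generations_per_year = spec$clock$gpy,
                 reference_date = format(spec$clock$reference_date)),
    design = list(dates = format(d$dates), sizes = as.integer(d$sizes),
                  n_loci = d$n_loci,
                  spray_dates = if (is.null(d$spray_dates)) NULL
                  else format(d$spray_dates),
                  rainfall = if (is.null(d$rainfall)) NULL
                  else list(months = format(d$rainfall$months),
                            mm = d$rainfall$mm)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Rebuild a scenario specification from a YAML config
#'
#' @param path YAML file written by [scenario_to_yaml()] (or hand-written
#'   to the same schema).
#' @return A `scenario_spec`.
#' @export
scenario_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  needed <- c("scenario_id", "anchor", "ne_bounds", "clock", "design")
  missing <- setdiff(needed, names(y))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "))
  d <- y$design
  rainfall <- if (!is.null(d$rainfall))
    rainfall_series(d$rainfall$months, d$rainfall$mm)
  design <- sampling_design(d$dates, d$sizes, d$n_loci,
                            spray_dates = d$spray_dates,
                            rainfall = rainfall)
  clock <- generation_clock(y$clock$generations_per_year,
                            y$clock$reference_date)
  build_scenario(y$scenario_id, design, clock,
                 ne_bounds = as.numeric(y$ne_bounds), anchor = y$anchor)
}

#' Read and validate a run configuration
#'
#' A run configuration gathers the knobs of a full analysis.  Recognized
#' keys: `genepop` (path), `dates`, `scenarios` (integer vector),
#' `n_per_scenario`, `retention_fraction`, `generations_per_year`, `seed`,
#' `anchor`, `out_dir`.  Unknown keys are rejected, and values are
#' validated before any computation.
#'
#' @param path YAML file.
#' @return Named list of validated settings (class `run_config`) with
#'   defaults filled in.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("genepop", "dates", "scenarios", "n_per_scenario",
             "retention_fraction", "generations_per_year", "seed",
             "anchor", "out_dir")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(scenarios = 1:6, n_per_scenario = 10000,
                   retention_fraction = 0.01, generations_per_year = 18,
                   seed = 1, anchor = "sampling", out_dir = ".")
  cfg <- utils::modifyList(defaults, y)
  stopifnot(all(cfg$scenarios %in% 1:6), cfg$n_per_scenario >= 100,
            cfg$retention_fraction > 0, cfg$retention_fraction <= 1,
            cfg$generations_per_year > 0,
            cfg$anchor %in% c("sampling", "spray"))
  structure(cfg, class = "run_config")
}

#' Machine-readable provenance for a run
#'
#' @param config a [read_run_config()] result (or any list of settings).
#' @param seed the master seed actually used.
#' @return List with a stable rolling hash of the configuration, the seed,
#'   and package/R versions.
#' @export
run_provenance <- function(config, seed) {
  txt <- paste(deparse(config[order(names(config))]), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  list(config_hash = sprintf("%08x", h), seed = seed,
       package_version = as.character(utils::packageVersion("irsabc")),
       r_version = R.version.string)
}
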