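# Structured-text (YAML) configuration files for models and scenarios,
# used by the command-line interface and for archiving run setups.

#' Write a model configuration file
#'
#' Serializes the sex label and the full parameter set of a model to
#' YAML; [read_model_config()] rebuilds an identical model.
#'
#' @param model A [build_model()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "neck_model"))
  yaml::write_yaml(list(sex = model$sex, parameters = model$params), path)
  invisible(path)
}

#' Read a model configuration file
#'
#' @param path YAML file written by [write_model_config()] (or hand
#'   written: `sex` plus any subset of [model_parameter_names()] under
#'   `parameters`).
#' @return A [build_model()] result.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$sex)) stop("model config needs a 'sex' field", call. = FALSE)
  pars <- cfg$parameters
  if (!is.null(pars$head_com)) pars$head_com <- as.numeric(pars$head_com)
  build_model(cfg$sex, overrides = if (is.null(pars)) list() else pars)
}

#' Read a scenario configuration file
#'
#' YAML fields: `toggles` (`cco`/`pde`/`apf` logicals), `pulse`
#' (`delta_v`, `duration`, `shape`, `dt`) or `t1_csv` (path to a channel
#' CSV with T1-x/z/ry), and optional `settle_ms`, `term_ms`, `dt`,
#' `out_dt`, `gravity`.
#'
#' @param path YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$toggles))
    args$toggles <- lapply(cfg$toggles, isTRUE)[c("cco", "pde", "apf")]
  if (!is.null(cfg$t1_csv)) {
    args$t1 <- read_channels(cfg$t1_csv)
  } else if (!is.null(cfg$pulse)) {
    p <- cfg$pulse
    args$pulse <- pulse_spec(
      delta_v = if (is.null(p$delta_v)) 5.8 else p$delta_v,
      duration = if (is.null(p$duration)) 100 else p$duration,
      shape = if (is.null(p$shape)) "haversine" else p$shape,
      dt = if (is.null(p$dt)) 0.5 else p$dt)
  }
  for (nm in c("settle_ms", "term_ms", "dt", "out_dt", "gravity",
               "drift_threshold"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  do.call(scenario_config, args)
}

#' Write an optimization/calibration specification file
#' @param spec An [optimization_spec()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_optimization_config <- function(spec, path) {
  stopifnot(inherits(spec, "optimization_spec"))
  yaml::write_yaml(list(
    bounds = lapply(spec$bounds, as.numeric),
    initial = as.list(spec$initial),
    seed = spec$seed, budget = spec$budget, pop_size = spec$pop_size,
    f = spec$f, cr = spec$cr, strategy = spec$strategy,
    polish_frac = spec$polish_frac), path)
  invisible(path)
}

#' Read an optimization/calibration specification file
#' @param path YAML file with any subset of [optimization_spec()] fields.
#' @return An [optimization_spec()].
#' @export
read_optimization_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$bounds)) args$bounds <- lapply(cfg$bounds, as.numeric)
  if (!is.null(cfg$initial)) args$initial <- unlist(cfg$initial)
  for (nm in c("seed", "budget", "pop_size", "f", "cr", "strategy",
               "polish_frac"))
    if (!is.null(cfg[[nm]])) args[[nm]] <- cfg[[nm]]
  do.call(optimization_spec, args)
}
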