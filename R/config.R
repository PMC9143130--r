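#' Run configuration
#'
#' Aggregates every tunable stage parameter with its conventional
#' default: simulation temperature 310 K, umbrella force constant 2500
#' kJ/mol/A^2 (stored in kJ and converted at use), WHAM density tolerance
#' 1e-3, grid-scan steps 0.05 A (hydrogen transfer) and 0.1 A (heavy
#' atoms), H-bond criteria 3.0 A / 135 deg, and switching bounds
#' 14.5-16 A.  Serializes losslessly to YAML.
#'
#' @param ... overrides of the defaults (unknown keys are an error).
#' @return named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    temperature = 310,
    force_constant_kj = 2500,
    wham_tolerance = 1e-3,
    wham_max_iter = 50000L,
    grid_step_hydrogen = 0.05,
    grid_step_heavy = 0.1,
    hbond_distance_cut = 3.0,
    hbond_angle_cut = 135.0,
    switch_r_on = 14.5,
    switch_r_off = 16.0,
    equil_time = 5,
    prod_time = 20,
    dt = 0.01,
    friction = 5,
    stride = 1L,
    seed = 0L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname default_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
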