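# Flat, validated run configuration. Keys are dotted module.parameter
# names; unknown keys are rejected and the object round-trips through
# YAML unchanged.

.vaa_config_defaults <- function() {
  list(
    preprocess.border_threshold = 20 / 255,
    preprocess.target_mean = 128,
    preprocess.target_sd = 40,
    preprocess.median_size = 3L,
    preprocess.clip_limit = 2,
    preprocess.tile_size = 8L,
    preprocess.denoise = TRUE,
    preprocess.normalize = TRUE,
    preprocess.enhance = TRUE,
    disc.score_floor = 2.5,
    disc.vessel_weight = 0.5,
    disc.n_theta = 360L,
    disc.rho_step = 0.5,
    disc.edge_sigma = 2,
    disc.edge_floor = 0.02,
    disc.center_mode = "circle",
    vessel.high_threshold = 0.30,
    vessel.low_threshold = 0.12,
    vessel.min_component_px = NA_real_, # NA: scaled with image area
    vessel.ring_radius_pd = 0.75,
    vaa.point_c_rule = "symmetric", # or "vertical"
    vaa.radius_3pd = 3,
    vaa.n_scan = 256L,
    stats.vif_ceiling = 10,
    stats.n_trend_groups = 4L,
    stats.paired_test = "auto-wilcoxon", # or "auto-mannwhitney", "t", "wilcoxon"
    strict_mode = FALSE,
    seed = 1L
  )
}

#' Pipeline configuration
#'
#' All tunable parameters of the measurement and statistics pipeline as a
#' flat named list with dotted keys (`preprocess.*`, `disc.*`,
#' `vessel.*`, `vaa.*`, `stats.*`). Unknown keys are rejected.
#'
#' @param ... Overrides, e.g. `vaa.point_c_rule = "vertical"`.
#' @return A named list of class `vaa_config`.
#' @examples
#' cfg <- vaa_config(disc.center_mode = "bbox")
#' cfg$disc.center_mode
#' @export
vaa_config <- function(...) {
  defaults <- .vaa_config_defaults()
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop_vaangle(paste0("unknown config keys: ", paste(unknown, collapse = ", ")),
                 "invalid_params")
  }
  defaults[names(over)] <- over
  structure(defaults, class = "vaa_config")
}

#' Read / write a configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns a validated [vaa_config()];
#'   `write_config()` returns the path invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(vaa_config, vals)
}

#' @rdname read_config
#' @param config A [vaa_config()] object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vaa_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.vaa_config <- function(x, ...) {
  cat("<vaa_config>\n")
  for (k in names(x)) cat(sprintf("  %s: %s\n", k, format(x[[k]])))
  invisible(x)
}
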