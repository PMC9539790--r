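# Flat key-value configuration shared by all pipeline stages.

#' Default analysis configuration
#'
#' Returns the flat list of tunable parameters used across the pipeline,
#' with the defaults of the reference setup: 127 nm camera pixels, G factor
#' 0.93, a 10 nm super-resolution render grid, the (6, 40] nm localization
#' precision keep-window, a 1 nm duplicate-merge radius, the 6 / 30 nm mean
#' Voronoi-neighbour-distance class band edges, and a density threshold
#' factor alpha = 2 for cluster segmentation.
#'
#' @param ... name = value overrides of any listed field.
#' @return a named list of class `corrfret_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    g_factor = 0.93,
    camera_pixel_nm = 127,
    render_pixel_nm = 10,
    saturation_level = 65535L,
    intensity_threshold = NA_real_,   # NA = 3 x robust border sigma
    merge_radius_nm = 1.0,
    uncertainty_min_nm = 6,
    uncertainty_max_nm = 40,
    photon_min = 100,
    class_edges_nm = c(6, 30),
    density_factor = 2,
    min_cluster_locs = 10L,
    max_cluster_locs = Inf,
    min_cluster_area_nm2 = 0,
    max_cluster_area_nm2 = Inf,
    gof_p_threshold = 1e-3,
    seed = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown configuration field(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "corrfret_config")
}

#' @rdname default_config
#' @param cfg a configuration list.
#' @export
validate_config <- function(cfg) {
  stop_if_not_scalar_pos(cfg$g_factor, "g_factor")
  stop_if_not_scalar_pos(cfg$camera_pixel_nm, "camera_pixel_nm")
  stop_if_not_scalar_pos(cfg$render_pixel_nm, "render_pixel_nm")
  if (cfg$uncertainty_min_nm >= cfg$uncertainty_max_nm)
    stop("uncertainty_min_nm must be < uncertainty_max_nm")
  if (length(cfg$class_edges_nm) != 2L ||
      cfg$class_edges_nm[1L] >= cfg$class_edges_nm[2L])
    stop("class_edges_nm must be two increasing positive values")
  stop_if_not_scalar_pos(cfg$density_factor, "density_factor")
  invisible(cfg)
}

#' Read / write a configuration file (YAML key-value)
#'
#' @param path file path.
#' @return `read_config`: a validated configuration list; `write_config`:
#'   `path`, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' @rdname read_config
#' @param cfg a configuration list from [default_config()].
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1L))]
  x <- lapply(x, function(v) if (is.numeric(v) && any(is.infinite(v))) NULL else v)
  x <- x[!vapply(x, is.null, logical(1L))]
  yaml::write_yaml(x, path)
  invisible(path)
}
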