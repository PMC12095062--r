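## Run configuration and provenance: YAML configs validated against the
## package defaults (unknown keys rejected), JSON manifests echoing every
## effective parameter and seed.

#' Default run configuration
#'
#' One section per pipeline stage; every stochastic stage has an explicit
#' seed.  Lengths are nm internally; pixel calibrations carry their unit in
#' the key name.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    afm = list(
      preset = "wt-afm",
      n_filaments = 25L,            # per rendered scene; pipelines use more
      image_size_px = c(2048L, 2048L),
      pixel_size_nm = 4,
      tube_height_nm = 6,
      tip_radius_nm = 5,
      noise_sd_nm = 0,
      estimator = "kulpa",
      mask_source = "truth",
      min_length_nm = 200,
      s = 1,
      seed = 1L
    ),
    guv = list(
      image_size_px = c(512L, 512L),
      pixel_size_um = 0.2,
      hough_radius_range_um = c(5, 20),
      hough_radius_step_um = 0.5,
      blur_sigma = 3,
      min_area_fraction_pct = 1,
      angular_width_um = 3,
      angular_every = 10L,
      noise_sd = 0,
      seed = 1L
    ),
    traj = list(
      n_layers = 100L,
      tiles_per_layer = 3L,
      nt_per_tile = 300L,
      bend_P_nm = 2000,
      n_frames = 100L,
      save_every_steps = 5e5,
      total_steps = 1e9,
      final_fraction = 0.1,
      middle_fraction = 0.8,
      seed = 1L
    )
  )
}

merge_validate <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1L) "s" else "",
                 paste0(path, unknown, collapse = ", ")), call. = FALSE)
  for (k in names(user))
    defaults[[k]] <- merge_validate(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML file and merges it over [default_config()]; keys not
#' present in the defaults are rejected with a schema error naming them.
#'
#' @param path YAML file; `NULL` returns the defaults.
#' @return object of class `run_config`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  structure(merge_validate(default_config(), user), class = "run_config")
}

#' Write a JSON run manifest
#'
#' Echoes every effective parameter and seed of a run, plus optional result
#' fields, for provenance.
#'
#' @param config a `run_config` (or any named list of parameters).
#' @param path output JSON file.
#' @param extra optional named list appended under `"results"`.
#' @return invisibly, `path`.
#' @export
write_manifest <- function(config, path, extra = NULL) {
  payload <- list(package = "nanotrace",
                  version = as.character(utils::packageVersion("nanotrace")),
                  config = unclass(config))
  if (!is.null(extra)) payload$results <- extra
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
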