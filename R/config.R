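#' Default run configuration
#'
#' Flat key-value configuration describing a complete run: swimmer
#' morphology and beat, background flow, wall repulsion and numerical
#' parameters. The defaults reproduce the virtual promastigote scenario
#' (body 11 x 3.5 um, flagellum 13 um, A = 1.8 um, lambda = 13 um,
#' f = 28 Hz, gamma_d = 1 1/s).
#'
#' @return named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    body_major_axis = 11, body_minor_axis = 3.5, flagellum_length = 13,
    flagellum_radius = 0.25, beat_amplitude = 1.8, beat_wavelength = 13,
    beat_frequency = 28, beat_direction = "puller", body_scale = 1,
    gamma_d = 1, geometry = "bulk_shear", mu = 8.9e-4,
    wall_present = FALSE, repulsion_enabled = FALSE, repulsion_g = 1250,
    repulsion_l = 0.2, dt_per_beat = 100, n_phases = 20, n_theta = 36,
    refinement = 1, seed = 1
  ), class = "run_config")
}

#' Load and validate a run configuration from JSON
#'
#' Unknown keys are rejected with the offending name; missing keys take
#' their defaults, so an empty file yields the full virtual-promastigote
#' configuration.
#'
#' @param path JSON file path.
#' @return a validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  given <- if (nchar(trimws(txt)) == 0) list()
           else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  validate_config(given)
}

#' Validate a partial configuration against the defaults
#' @param given named list of overrides.
#' @return a `run_config` with defaults filled in.
#' @export
validate_config <- function(given) {
  cfg <- default_run_config()
  unknown <- setdiff(names(given), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(given)) cfg[[k]] <- given[[k]]
  # type/constraint validation through the constructors
  as_swimmer_config(cfg)
  as_flow_model(cfg)
  stopifnot(cfg$dt_per_beat > 0, cfg$n_phases >= 2, cfg$n_theta >= 4,
            cfg$refinement %in% 0:2)
  cfg
}

#' Write a run configuration as JSON
#' @param cfg a `run_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Swimmer part of a run configuration
#' @param cfg a `run_config`.
#' @return a [swimmer_config()].
#' @export
as_swimmer_config <- function(cfg) {
  swimmer_config(cfg$body_major_axis, cfg$body_minor_axis,
                 cfg$flagellum_length, cfg$flagellum_radius,
                 cfg$beat_amplitude, cfg$beat_wavelength,
                 cfg$beat_frequency, cfg$beat_direction, cfg$body_scale)
}

#' Flow part of a run configuration
#' @param cfg a `run_config`.
#' @return a [flow_model()].
#' @export
as_flow_model <- function(cfg) {
  rep <- if (isTRUE(cfg$repulsion_enabled))
    wall_repulsion(cfg$repulsion_g, cfg$repulsion_l) else NULL
  flow_model(cfg$gamma_d, cfg$geometry, cfg$mu, cfg$wall_present, rep)
}

#' Canonical study configurations
#'
#' * `promastigote`: the default virtual promastigote.
#' * `pusher`: identical morphology with the beat direction reversed.
#' * `passive_spheroid`: no beat (A = 0), body aspect ratio `r`.
#' * `small_body_0.2`: promastigote with the body lengthscale reduced by
#'   80 percent.
#'
#' @param name fixture name.
#' @param r aspect ratio for the passive spheroid.
#' @return a `run_config`.
#' @export
make_fixture <- function(name = c("promastigote", "pusher",
                                  "passive_spheroid", "small_body_0.2"),
                         r = 3) {
  name <- match.arg(name)
  cfg <- default_run_config()
  if (name == "pusher") {
    cfg$beat_direction <- "pusher"
  } else if (name == "passive_spheroid") {
    cfg$beat_amplitude <- 0
    cfg$body_minor_axis <- 3.5
    cfg$body_major_axis <- 3.5 * r
  } else if (name == "small_body_0.2") {
    cfg$body_scale <- 0.2
  }
  cfg
}

#' Write a run manifest for exact re-runs
#'
#' Records the configuration, its MD5 digest, the seed, and code/runtime
#' versions alongside an output set.
#'
#' @param cfg a `run_config`.
#' @param path manifest output path (JSON).
#' @param extra optional named list of extra fields.
#' @return the path, invisibly.
#' @export
write_manifest <- function(cfg, path, extra = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  man <- c(list(
    package = "promaswim",
    version = as.character(utils::packageVersion("promaswim")),
    r_version = as.character(getRversion()),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    config = unclass(cfg)
  ), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
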