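#' Write a trajectory to plain-text files
#'
#' Writes the snapshot table as CSV (long format: `time`, `species`,
#' `level`, `patch`, `density`, `trait_mean`), the extinction-event log as
#' JSON, and a run manifest (scenario, seed, sizes, solver settings, a hash
#' of the configuration, and the package version) as JSON.
#'
#' @param trajectory An `ee_trajectory`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; defaults to `scenarioid_seed`.
#' @return Invisibly, the paths written.
#' @export
write_trajectory <- function(trajectory, dir, stem = NULL) {
  cfg <- trajectory$config
  if (is.null(stem)) {
    sc <- cfg$scenario
    stem <- sprintf("%s_%s_%s_%s_seed%d", sc$dispersal, sc$variance,
                    sc$trophic, sc$competition, cfg$seed)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    states = file.path(dir, paste0(stem, "_states.csv")),
    events = file.path(dir, paste0(stem, "_events.json")),
    manifest = file.path(dir, paste0(stem, "_manifest.json"))
  )
  utils::write.csv(trajectory$states, paths$states, row.names = FALSE)
  jsonlite::write_json(trajectory$events, paths$events, digits = NA)
  manifest <- list(
    scenario = unclass(cfg$scenario), seed = cfg$seed,
    S_R = cfg$S_R, S_C = cfg$S_C, L = cfg$L,
    times = cfg$times, solver = cfg$solver,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("ecoevoclim"))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a trajectory states table written by [write_trajectory()]
#'
#' Restores the snapshot tibble only (the metrics layer needs no more than
#' this plus a climate profile).
#'
#' @param path Path to a `*_states.csv` file.
#' @return A tibble in the long snapshot format.
#' @export
read_trajectory_states <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a replicate configuration to YAML
#'
#' Serialises everything needed to re-create a configuration, including the
#' drawn per-species parameters, so a run can be reproduced without
#' re-drawing. Matrices are stored row-wise.
#'
#' @param config An `ee_config`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  ser <- list(
    scenario = unclass(config$scenario), seed = config$seed,
    S_R = config$S_R, S_C = config$S_C, L = config$L,
    climate = unclass(config$climate),
    species = as.list(config$species),
    b_w = config$b_w, a_w = config$a_w, eta = config$eta,
    a_matrix = as.vector(t(config$a_matrix)),
    web = if (is.null(config$web)) NULL else
      list(W = as.vector(t(config$web$W)), omega = as.vector(t(config$web$omega))),
    defaults = config$defaults, solver = config$solver, times = config$times
  )
  yaml::write_yaml(ser, path, precision = 17)
  invisible(path)
}

#' Read a replicate configuration from YAML
#'
#' @param path Path written by [write_config()].
#' @return An `ee_config` identical to the one serialised.
#' @export
read_config <- function(path) {
  ser <- yaml::read_yaml(path)
  web <- if (!is.null(ser$web)) {
    list(W = matrix(ser$web$W, ser$S_C, ser$S_R, byrow = TRUE),
         omega = matrix(ser$web$omega, ser$S_C, ser$S_R, byrow = TRUE))
  } else NULL
  structure(
    list(
      scenario = structure(ser$scenario, class = "ee_scenario"),
      seed = as.integer(ser$seed),
      S_R = as.integer(ser$S_R), S_C = as.integer(ser$S_C),
      L = as.integer(ser$L),
      climate = structure(ser$climate, class = "ee_climate"),
      species = tibble::as_tibble(ser$species),
      b_w = ser$b_w, a_w = ser$a_w, eta = ser$eta,
      a_matrix = matrix(ser$a_matrix, ser$S_R, ser$S_R, byrow = TRUE),
      web = web, defaults = ser$defaults, solver = ser$solver,
      times = ser$times
    ),
    class = "ee_config"
  )
}
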