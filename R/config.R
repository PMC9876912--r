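#' Default run configuration
#'
#' The complete set of tunables for a simulation + evaluation run, with
#' the benchmark's study conditions as defaults: the 12-well landscape,
#' the default two-body phantom, SNR 1, uniform orientations, 40-bin
#' occupancy maps.
#'
#' @return nested named list (landscape / phantom / imaging / evaluation).
#' @export
default_run_config <- function() {
  w <- default_wells()
  list(
    landscape = list(
      wells = lapply(seq_len(nrow(w)), function(i) as.list(w[i, ])),
      kT = 1.0,
      domain = list(cc1 = c(0, 1), cc2 = c(0, 1)),
      grid_resolution = 128L),
    phantom = list(
      box_size = 64L,
      voxel_size = 3.0,
      max_angle1 = 10.0,
      max_angle2 = 10.0),
    imaging = list(
      # named n_particles (not plain "n"): a bare "n" YAML key parses as
      # boolean under YAML 1.1
      n_particles = 1000L,
      snr = 1.0,
      seed = 1L,
      orientation_mode = "uniform",
      ctf = FALSE),
    evaluation = list(
      bins = 40L,
      floor_count = 1L,
      sd_convention = "population"))
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k != "wells") {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "."))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys fall back to
#' [default_run_config()].
#'
#' @param path YAML file path (`NULL` returns the defaults).
#' @return validated nested config list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  cfg
}

#' Write a run configuration as YAML
#'
#' @param config nested config list.
#' @param path output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build the energy landscape described by a run config
#'
#' @param config a [read_run_config()] list.
#' @return an [energy_landscape()].
#' @export
config_landscape <- function(config = default_run_config()) {
  lc <- config$landscape
  wells <- do.call(rbind, lapply(lc$wells, function(w)
    data.frame(id = as.integer(w$id), cc1 = w$cc1, cc2 = w$cc2,
               depth = w$depth, width = w$width)))
  energy_landscape(
    wells = wells, kT = lc$kT,
    domain = rbind(c(lc$domain$cc1[1], lc$domain$cc2[1]),
                   c(lc$domain$cc1[2], lc$domain$cc2[2])))
}

#' Build the phantom described by a run config
#'
#' @param config a [read_run_config()] list.
#' @return a [two_body_phantom()].
#' @export
config_phantom <- function(config = default_run_config()) {
  pc <- config$phantom
  ph <- build_default_phantom(pc$box_size, pc$voxel_size)
  ph$max_angle1 <- pc$max_angle1
  ph$max_angle2 <- pc$max_angle2
  ph
}
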