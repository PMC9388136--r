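# Scenario presets for the network experiments: thin boxes at a fixed
# microtubule density of 0.8 filaments/um^2 of X-Y area, cross-linker counts
# as complexes per filament, durations at the full experimental scale.
preset_table <- function() {
  list(
    fig5b_kif11 = list(box_xy = 60, ratios = c(kif11 = 16), duration = 5000),
    fig5d_hset = list(box_xy = 40, ratios = c(hset = 32), duration = 5000),
    fig6a_mixed = list(box_xy = 60, ratios = c(kif11 = 2), duration = 8000,
                       mixed = TRUE),
    fig6c_sweep = list(box_xy = 20, ratios = c(kif11 = 2), duration = 8000,
                       variant = TRUE),
    fig6d_variant = list(box_xy = 20, ratios = c(kif11 = 2), duration = 8000,
                         variant = TRUE),
    si4_symmetric_minus = list(box_xy = 40,
                               ratios = c(symmetric_minus = 32),
                               duration = 5000),
    si6_variant = list(box_xy = 20, ratios = c(kif11 = 2), duration = 8000,
                       variant = TRUE),
    no_motor_control = list(box_xy = 20, ratios = numeric(0),
                            duration = 8000)
  )
}

#' Scenario presets
#' @return Character vector of preset names accepted by [build_scenario()].
#' @export
scenario_presets <- function() names(preset_table())

#' Build a network scenario
#'
#' Produces a fully resolved configuration and the corresponding initial
#' system state. The linear `scale` factor multiplies the lateral box
#' dimensions (Z stays 0.2 um), the run duration and the default speed
#' analysis window `delta_t`, while preserving all intensive quantities:
#' microtubule density (0.8/um^2) and cross-linkers per filament. Filament
#' count is `round(density * X * Y)`; the tubulin pool is
#' `mean_steady_length * n_filaments` so the steady-state mean length is
#' scale-independent. All cross-linkers start unbound, uniformly placed.
#'
#' Presets: `fig5b_kif11` (60 x 60 um, 16 KIF11/MT), `fig5d_hset`
#' (40 x 40 um, 32 HSET/MT), `fig6a_mixed` (60 x 60 um, 2 KIF11/MT plus
#' `hset_per_kif11` HSET per KIF11), `fig6c_sweep` / `fig6d_variant` /
#' `si6_variant` (20 x 20 um, 2 KIF11/MT plus `variant` at `variant_ratio`
#' per MT), `si4_symmetric_minus` (40 x 40 um, 32 symmetric minus motors/MT),
#' `no_motor_control` (20 x 20 um, no cross-linkers).
#'
#' @param name Preset name (see [scenario_presets()]).
#' @param scale Linear reduction factor in (0, 1]; 1 is the full
#'   experimental scale.
#' @param seed Integer seed controlling placement and dynamics.
#' @param hset_per_kif11 Mixing ratio for `fig6a_mixed` (2 or 16 in the
#'   reference experiments).
#' @param variant Cross-linker catalog name for the variant presets.
#' @param variant_ratio Variant complexes per filament.
#' @param overrides Named list merged into the resolved config before the
#'   state is built; sublists `physics` and `growth` merge into those
#'   blocks, `linker_specs` (named list of [linker_spec()]) replaces catalog
#'   entries, other entries replace top-level config fields (e.g.
#'   `duration_s`, `linker_ratios`).
#' @return List with the resolved `config` and the initial `state`.
#' @export
build_scenario <- function(name, scale = 1, seed = 1L, hset_per_kif11 = 2,
                           variant = "hset", variant_ratio = 4,
                           overrides = list()) {
  tab <- preset_table()
  if (!name %in% names(tab)) {
    stop("unknown preset '", name, "'; presets: ",
         paste(names(tab), collapse = ", "))
  }
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  p <- tab[[name]]
  ratios <- p$ratios
  if (isTRUE(p$mixed)) {
    ratios <- c(ratios, hset = unname(ratios["kif11"]) * hset_per_kif11)
  }
  if (isTRUE(p$variant)) {
    ratios <- c(ratios, structure(variant_ratio, names = variant))
  }
  config <- list(
    schema_version = 1L,
    name = name,
    scale = scale,
    seed = as.integer(seed),
    box_um = c(p$box_xy * scale, p$box_xy * scale, 0.2),
    mt_density_per_um2 = 0.8,
    linker_ratios = as.list(ratios),
    duration_s = p$duration * scale,
    delta_t_s = 640 * scale,
    frame_interval_s = 640 * scale / 8,
    mean_steady_length_um = 2.5,
    # argument-level physics: derived drags (gamma_*) are computed when the
    # state is built, so overriding e.g. eta propagates consistently
    physics = local({
      ph <- unclass(physics_params())
      ph$gamma_vertex <- NULL
      ph$gamma_linker <- NULL
      ph
    }),
    growth = list(alpha0 = 0.05, speed_sd_factor = 0.25,
                  speed_clip = c(0, 2), nucleation_rate = 0.1,
                  growth_until = 600, initial_length = 0.1),
    linker_specs = list()
  )
  if (length(overrides)) {
    for (key in names(overrides)) {
      if (key %in% c("physics", "growth")) {
        config[[key]] <- utils::modifyList(config[[key]], overrides[[key]])
      } else {
        config[[key]] <- overrides[[key]]
      }
    }
  }
  config$n_filaments <- round(config$mt_density_per_um2 *
                                config$box_um[1] * config$box_um[2])
  if (config$n_filaments < 8) {
    stop("scale ", scale, " yields ", config$n_filaments,
         " filaments (< 8); increase scale")
  }
  config$linker_counts <- lapply(config$linker_ratios,
                                 function(r) round(r * config$n_filaments))
  config$omega_um <- config$mean_steady_length_um * config$n_filaments
  list(config = config, state = scenario_state(config))
}

#' Initial system state from a resolved scenario config
#'
#' Deterministic given the config (including its seed): rebuilding from a
#' [write_scenario_config()] echo reproduces the run exactly.
#'
#' @param config Resolved config, as produced by [build_scenario()] or read
#'   back by [read_scenario_config()].
#' @return An `mt_system`.
#' @export
scenario_state <- function(config) {
  set.seed(config$seed)
  box <- simulation_box(config$box_um[1], config$box_um[2], config$box_um[3])
  physics <- do.call(physics_params,
                     config$physics[intersect(names(config$physics),
                                              names(formals(physics_params)))])
  growth <- do.call(growth_config,
                    c(config$growth, list(omega = config$omega_um)))
  types <- lapply(names(config$linker_counts), function(nm) {
    if (!is.null(config$linker_specs[[nm]])) config$linker_specs[[nm]]
    else linker_catalog(nm)
  })
  st <- new_system(box, physics, growth, seeds = config$n_filaments,
                   linker_types = types, seed = config$seed)
  for (nm in names(config$linker_counts)) {
    n <- config$linker_counts[[nm]]
    if (n > 0) st <- add_linkers(st, nm, n)
  }
  st
}

#' Run a scenario
#'
#' @param scenario List `(config, state)` from [build_scenario()].
#' @param t_end Simulated end time (s); defaults to the config duration.
#' @param frame_interval Frame capture interval (s); defaults to the config
#'   value.
#' @return List `(state, trajectory, config)`.
#' @export
run_scenario <- function(scenario, t_end = NULL,
                         frame_interval = NULL) {
  cfg <- scenario$config
  if (is.null(t_end)) t_end <- cfg$duration_s
  if (is.null(frame_interval)) frame_interval <- cfg$frame_interval_s
  res <- run_until(scenario$state, t_end, frame_interval)
  res$trajectory$meta$config <- cfg
  list(state = res$state, trajectory = res$trajectory, config = cfg)
}

#' Summarise a trajectory (speed and cluster time courses)
#'
#' Thin wrapper over [timeseries_summary()] using the scenario's default
#' analysis window.
#'
#' @param traj An `mt_trajectory`.
#' @param delta_t Window (s); defaults to the config's `delta_t_s` when the
#'   trajectory carries its config.
#' @return A data.frame.
#' @export
analyze_trajectory <- function(traj, delta_t = NULL) {
  if (is.null(delta_t)) delta_t <- traj$meta$config$delta_t_s
  if (is.null(delta_t)) stop("delta_t not given and not stored in trajectory")
  timeseries_summary(traj, delta_t)
}

#' Write / read a resolved scenario configuration (YAML)
#'
#' The echoed config is self-contained: [scenario_state()] on the read-back
#' config reproduces the initial state exactly. Physical quantities carry
#' their units in the key names (`_um`, `_s`, `_per_um2`). `linker_specs`
#' overrides are serialized with their full parameter sets.
#'
#' @param config Resolved config list.
#' @param path File path.
#' @return `path` (write) or the config list (read), invisibly for write.
#' @export
write_scenario_config <- function(config, path) {
  cfg <- config
  cfg$linker_specs <- lapply(cfg$linker_specs, function(s) {
    s <- unclass(s)
    s$unit_a <- unclass(s$unit_a)
    s$unit_b <- unclass(s$unit_b)
    s
  })
  yaml::write_yaml(cfg, path, precision = 17) # full double precision
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version) || cfg$schema_version != 1L) {
    stop("config schema version ", cfg$schema_version,
         " not supported (expected 1)")
  }
  cfg$box_um <- as.numeric(cfg$box_um)
  cfg$growth$speed_clip <- as.numeric(cfg$growth$speed_clip)
  cfg$linker_specs <- lapply(cfg$linker_specs, function(s) {
    s$unit_a <- do.call(unit_spec, s$unit_a)
    s$unit_b <- do.call(unit_spec, s$unit_b)
    do.call(linker_spec, s[c("name", "unit_a", "unit_b", "k_spring",
                             "rest_length")])
  })
  cfg
}

#' Write / read a trajectory container
#'
#' Versioned single-file container (RDS) holding `/meta` (resolved config,
#' seed, format version, linker type names) and the frame list (time,
#' unwrapped filament vertices with minus-end-first polarity, per-frame
#' linker anchor table, conservation bookkeeping). `read_trajectory()`
#' reproduces the object exactly and fails loudly on version mismatch or a
#' truncated file.
#'
#' @param traj An `mt_trajectory`.
#' @param path File path.
#' @return `path` invisibly (write); the `mt_trajectory` (read).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "mt_trajectory"))
  saveRDS(list(format = "mtnetsim_trajectory", version = 1L,
               meta = traj$meta, frames = traj$frames), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  x <- tryCatch(readRDS(path),
                error = function(e) stop("unreadable trajectory file: ",
                                         conditionMessage(e)))
  if (!is.list(x) || !identical(x$format, "mtnetsim_trajectory")) {
    stop("not a trajectory container")
  }
  if (!identical(as.integer(x$version), 1L)) {
    stop("trajectory format version ", x$version,
         " not supported (expected 1)")
  }
  structure(list(meta = x$meta, frames = x$frames), class = "mt_trajectory")
}

#' Frame index at a given time
#'
#' @param traj An `mt_trajectory`.
#' @param time Time stamp (s).
#' @param tol Matching tolerance (s).
#' @return Integer frame index.
#' @export
frame_index_at_time <- function(traj, time, tol = 1e-6) {
  times <- vapply(traj$frames, `[[`, 0, "time")
  i <- which(abs(times - time) <= tol)
  if (length(i) == 0) stop("no frame at time ", time)
  i[1]
}
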