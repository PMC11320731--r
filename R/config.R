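#' Run configuration
#'
#' Bundles every tunable of a mapping run: thermostat settings for the
#' sampler, nonbonded model parameters, wall stiffness, and the distance
#' cutoffs used by the analyses. All stochastic operations take their
#' randomness from `seed`, so a `(config, inputs)` pair replays exactly.
#'
#' @param temperature K (default 310, body temperature)
#' @param friction Langevin friction, ps^-1
#' @param seed integer RNG seed
#' @param n_steps integration steps
#' @param dt integration time step, ps
#' @param save_interval save a frame every this many steps
#' @param n_probes probe copies per run
#' @param min_separation minimum initial heavy-atom separation, Angstrom
#' @param cutoff nonbonded cutoff, Angstrom
#' @param dielectric relative dielectric constant
#' @param switching smooth the nonbonded potential to zero at the cutoff
#' @param switch_start switching onset, Angstrom
#' @param k_wall wall force constant, kcal mol^-1 A^-2
#' @param occupancy_cutoff pocket-occupancy distance, Angstrom
#' @param residue_cutoff residue-energy shell, Angstrom
#' @param hbond_dist,hbond_angle hydrogen-bond cutoffs (Angstrom, degrees)
#' @param contact_cutoff contact-frequency distance, Angstrom
#' @param density_spacing density-grid cell side, Angstrom
#' @param isovalue density threshold
#' @param probe_radius solvent probe radius for SASA/volume, Angstrom
#' @param energy_abort abort the sampler if |total energy| exceeds this
#' @return a `run_config` (named list)
#' @export
run_config <- function(temperature = 310, friction = 1.0, seed = 1L,
                       n_steps = 20000L, dt = 0.002, save_interval = 100L,
                       n_probes = 10L, min_separation = 2.5,
                       cutoff = 12.0, dielectric = 1.0,
                       switching = TRUE, switch_start = 10.0,
                       k_wall = 10.0,
                       occupancy_cutoff = 4.0, residue_cutoff = 5.0,
                       hbond_dist = 3.5, hbond_angle = 90,
                       contact_cutoff = 4.0, density_spacing = 1.0,
                       isovalue = 0.5, probe_radius = 1.4,
                       energy_abort = 1e6) {
  cfg <- list(
    temperature = temperature, friction = friction, seed = as.integer(seed),
    n_steps = as.integer(n_steps), dt = dt,
    save_interval = as.integer(save_interval),
    n_probes = as.integer(n_probes), min_separation = min_separation,
    cutoff = cutoff, dielectric = dielectric,
    switching = isTRUE(switching) || identical(switching, "on"),
    switch_start = switch_start, k_wall = k_wall,
    occupancy_cutoff = occupancy_cutoff, residue_cutoff = residue_cutoff,
    hbond_dist = hbond_dist, hbond_angle = hbond_angle,
    contact_cutoff = contact_cutoff, density_spacing = density_spacing,
    isovalue = isovalue, probe_radius = probe_radius,
    energy_abort = energy_abort
  )
  if (cfg$temperature <= 0) abort("temperature must be > 0")
  if (cfg$friction <= 0) abort("friction must be > 0")
  if (cfg$dt <= 0 || cfg$n_steps < 1) abort("invalid integration settings")
  structure(cfg, class = "run_config")
}

#' Read a configuration file
#'
#' Plain `key = value` text; `#` starts a comment. Vector values (e.g.
#' `region_base`) are comma-separated. A confinement region may be
#' embedded with the `region_*` keys understood by [read_region()]; it
#' is attached as `$region`. Unknown keys raise an error so typos do not
#' silently fall back to defaults.
#'
#' @param path config file
#' @return a `run_config` (with `$region` if the file defines one)
#' @export
read_run_config <- function(path) {
  kv <- parse_kv_lines(readLines(path, warn = FALSE))
  keys <- names(kv)
  region_keys <- keys[startsWith(keys, "region_")]
  known <- names(formals(run_config))
  extra <- setdiff(keys, c(known, "dt_integration", region_keys,
                           "probe_template"))
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  parse_val <- function(v) {
    if (v %in% c("on", "off", "true", "false")) {
      return(v %in% c("on", "true"))
    }
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }
  main <- setdiff(keys, c(region_keys, "probe_template"))
  args <- setNames(lapply(kv[main], parse_val), main)
  names(args)[names(args) == "dt_integration"] <- "dt"
  cfg <- do.call(run_config, args)
  if (length(region_keys) > 0) {
    tmp <- tempfile(fileext = ".cfg")
    on.exit(unlink(tmp))
    writeLines(sprintf("%s = %s", region_keys, unlist(kv[region_keys])), tmp)
    cfg$region <- read_region(tmp)
  }
  if ("probe_template" %in% keys) cfg$probe_template <- kv[["probe_template"]]
  cfg
}

#' @export
format.run_config <- function(x, ...) {
  flat <- x[vapply(x, is.atomic, logical(1))]
  paste(sprintf("%s = %s", names(flat),
                vapply(flat, function(v) paste(format(v), collapse = ","),
                       character(1))),
        collapse = "\n")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(format(x), "\n")
  invisible(x)
}
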