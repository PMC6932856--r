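## canonical defaults for every run parameter
config_defaults <- function() {
  list(
    lv_preset = "healthy",      # ventricle preset: healthy | dilated
    mv_preset = "healthy",      # valve preset: healthy | P3like | P2like
    severity = 0,               # coaptation-defect severity in [0, 1]
    nx = 48L, ny = 48L, nz = 72L,  # grid cells
    lv_n_theta = 48L, lv_n_s = 24L,  # LV surface resolution
    mv_n_theta = 24L, mv_n_s = 8L,   # leaflet surface resolution
    aortic_radius = 0.85,       # cm
    cfl_max = 0.5,
    dt_max = 1.5e-3,            # s
    n_cycles = 2L,
    nu = 0.04,                  # kinematic viscosity, cm^2/s
    kappa = 0.04,               # marker diffusivity, cm^2/s (Schmidt 1)
    period = 1.0,               # heartbeat period, s
    phi_closed_tol = 0.02,      # rad; "closed" threshold for the AV logic
    valve_rate_max = 40,        # rad/s cap on leaflet angular rates
    upwind_blend = 0,           # local Lax-Friedrichs blend (0 = central)
    poisson_rtol = 1e-4,        # masked-projection relative residual
    poisson_maxit = 300L,       # masked-projection iteration cap
    mark_cycle = 1L,            # cycle whose end-systole releases the marker
    end_time = -1,              # s; > 0 truncates the run early
    metric_every = 1L,          # steps between metric-series samples
    output_dir = NULL,          # optional run directory
    snapshot_every = 0L,        # steps between VTK snapshots (0 = off)
    seed = 1L)                  # reserved; the pipeline is deterministic
}

#' Validate and complete a run configuration
#'
#' Applies documented defaults, rejects unknown keys, and checks types and
#' ranges. The result round-trips losslessly through YAML.
#'
#' @param config named list (possibly partial) of run parameters.
#' @return completed configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (inherits(config, "run_config")) return(config)
  defaults <- config_defaults()
  if (length(config)) {
    if (is.null(names(config)) || any(names(config) == ""))
      stop("config error: all entries must be named")
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
      stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  chk_num <- function(field, lo = -Inf, hi = Inf) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < lo || v > hi)
      stop(sprintf("config error: field '%s' must be a number in [%g, %g]",
                   field, lo, hi))
  }
  if (!cfg$lv_preset %in% c("healthy", "dilated"))
    stop("config error: field 'lv_preset' must be healthy or dilated")
  if (!cfg$mv_preset %in% c("healthy", "P3like", "P2like"))
    stop("config error: field 'mv_preset' must be healthy, P3like or P2like")
  chk_num("severity", 0, 1)
  for (f in c("nx", "ny", "nz")) chk_num(f, 8, 1024)
  chk_num("cfl_max", 1e-3, 1)
  chk_num("dt_max", 1e-8, 0.1)
  chk_num("n_cycles", 0, 100)
  chk_num("nu", 1e-8, 10)
  chk_num("kappa", 0, 10)
  chk_num("period", 1e-3, 100)
  chk_num("aortic_radius", 0.1, 5)
  for (f in c("nx", "ny", "nz", "n_cycles", "lv_n_theta", "lv_n_s",
              "mv_n_theta", "mv_n_s", "mark_cycle", "snapshot_every",
              "metric_every", "seed"))
    cfg[[f]] <- as.integer(cfg[[f]])
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file; an empty file yields all defaults.
#' @return a validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  run_config(raw)
}

#' Write a run configuration to YAML
#' @param cfg a [run_config()].
#' @param path output file.
#' @export
save_config <- function(cfg, path) {
  cfg <- run_config(cfg)
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
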