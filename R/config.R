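# Configuration, validated YAML loading, and atomic output writing.

#' Default run configuration
#'
#' Nested configuration covering every stage. Blocks: `cell` (region,
#' integration step, constant overrides), `tissue` (surface-to-volume
#' ratio, capacitance, baseline resistivity, activation threshold, step),
#' `myofilament` (constant overrides, default sarcomere length, template
#' sampling), `circulation` (integration step, ensemble size, failing
#' preset, parameter overrides, sarcomere-length/volume coupling),
#' `sweep` (conditions, cycle length, cycle counts, calibration
#' tolerance), `fixtures` (sinus-protocol constants), `output`, and the
#' global `seed`.
#'
#' The study conditions are the defaults: sinus pacing at a 600 ms cycle
#' length, 3 s of electrical simulation, 32 mechanical cycles, conditions
#' 30-70 cm/s, Purkinje-terminal onset 20 ms at 200 cm/s path speed, and
#' the failing (10% stiffened) vasculature.
#'
#' @return nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 101,
    cell = list(region = "epi", dt = 0.02, overrides = list()),
    tissue = list(rho = 162, S = 2000, Cm = 2, threshold = 0, dt = 0.02),
    myofilament = list(overrides = list(), sl_default = 2.0,
                       template_dt = 0.1),
    circulation = list(dt = 0.1, ensemble_size = 64, failing = TRUE,
                       overrides = list(), lv = list(), rv = list(),
                       init_pressures = list(sa = 120, sv = 9, pa = 14,
                                             pv = 11),
                       sl_coupling = TRUE, sl_ref = 2.15,
                       v_ref_sl_lv = 95, v_ref_sl_rv = 95, out_stride = 10),
    sweep = list(conditions = c(30, 40, 50, 60, 70), cl = 600,
                 n_cycles = 32, electrical_duration = 3000,
                 calibration_tol = 0.01),
    fixtures = list(protocol = list(n_sites = 12, onset = 20,
                                    purkinje_speed = 200, stim_delay = 5)),
    output = list(dir = "cardiomech-out", log_level = "info")
  ), class = "run_config")
}

# Recursive merge of `user` into `base`, rejecting keys absent from the
# skeleton. Blocks named `overrides`/`lv`/`rv` are free-form (validated by
# their consumers).
merge_config <- function(base, user, path = character()) {
  free <- c("overrides", "lv", "rv")
  for (k in names(user)) {
    here <- paste(c(path, k), collapse = ".")
    if (!k %in% names(base))
      stop("unknown configuration key: ", here)
    if (is.list(base[[k]]) && !k %in% free) {
      if (!is.list(user[[k]]))
        stop("configuration key ", here, " must be a block")
      base[[k]] <- merge_config(base[[k]], user[[k]], c(path, k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, fills defaults for everything unspecified, and
#' rejects unknown keys with the offending path. An empty file yields the
#' full default configuration.
#'
#' @param path YAML file.
#' @return validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("configuration must be a YAML mapping")
  cfg <- merge_config(unclass(default_config()), user)
  structure(cfg, class = "run_config")
}

# Atomic CSV write: write to a temporary sibling then rename, so partial
# failures never leave a half-written file.
write_atomic_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

write_atomic_json <- function(x, path, ...) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, ...)
  file.rename(tmp, path)
  invisible(path)
}

#' Write sweep outputs with a reproducibility manifest
#'
#' Writes the result as CSV and JSON (atomically), echoes the effective
#' configuration, and writes a manifest with the configuration hash and
#' package version, from which the run can be reconstructed.
#'
#' @param result a `sweep_result` (or any data.frame).
#' @param dir output directory (created if needed).
#' @param config the configuration used.
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(result, dir, config = default_config()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  paths <- c(csv = file.path(dir, "sweep_result.csv"),
             json = file.path(dir, "sweep_result.json"),
             config = file.path(dir, "config_echo.yaml"),
             manifest = file.path(dir, "manifest.json"))
  write_atomic_csv(as.data.frame(result), paths[["csv"]])
  write_atomic_json(as.data.frame(result), paths[["json"]], dataframe = "rows")
  cfg_tmp <- paste0(paths[["config"]], ".tmp", Sys.getpid())
  yaml::write_yaml(unclass(config), cfg_tmp)
  file.rename(cfg_tmp, paths[["config"]])
  manifest <- list(
    package = "cardiomech",
    version = as.character(utils::packageVersion("cardiomech")),
    config_hash = unname(tools::md5sum(paths[["config"]])),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = as.list(basename(paths[c("csv", "json", "config")]))
  )
  write_atomic_json(manifest, paths[["manifest"]])
  invisible(paths)
}
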