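# Configuration, seed derivation and result serialisation. A run_config fully
# determines a run: two runs from equal configs produce identical outputs.

MOD31 <- 2147483647  # 2^31 - 1; all derived seeds stay below R's integer cap

#' Derive deterministic per-component child seeds
#'
#' Hashes each label (polynomial byte hash mod 2^31 - 1) and combines it with
#' the master seed, giving stable, collision-avoiding seeds for the network,
#' frequency, initial-condition, schedule and placement draws of one run.
#'
#' @param master_seed Integer master seed, or `NULL` (returns `NULL`:
#'   unseeded downstream draws).
#' @param labels Character vector of distinct component labels.
#' @return Named integer vector of child seeds (scalar for one label), or
#'   `NULL`.
#' @examples
#' derive_seeds(42, c("network", "frequencies"))
#' @export
derive_seeds <- function(master_seed, labels) {
  if (anyDuplicated(labels))
    abort("labels must be distinct", "invalid_parameter")
  if (is.null(master_seed)) return(NULL)
  check_scalar(master_seed, "master_seed")
  h <- vapply(labels, function(lb) {
    x <- 17
    for (b in utf8ToInt(lb)) x <- (x * 31 + b) %% MOD31
    x
  }, numeric(1))
  out <- as.integer(((as.numeric(master_seed) %% MOD31) * 7919 + h) %% MOD31)
  names(out) <- labels
  if (length(out) == 1L) out <- unname(out)
  out
}

config_schema <- list(
  model = NULL, n = NULL, reps = NULL, seed = NULL,
  network = c("type", "p", "k_half", "q", "path", "format"),
  frequencies = c("mean", "sd"),
  coupling = c("K", "schedule", "scale", "plateau"),
  control = c("method", "M", "gamma_over_4", "P", "D", "c_s",
              "distance_mode", "control_mode"),
  integrator = c("dt", "t_end", "record_every", "transient_fraction"))

check_keys <- function(keys, known, where) {
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    hint <- vapply(unknown, function(k) {
      near <- agrep(k, known, max.distance = 2, value = TRUE)
      if (length(near)) sprintf(" (did you mean '%s'?)", near[1]) else ""
    }, character(1))
    abort(paste0("unknown ", where, " key(s): ",
                 paste0("'", unknown, "'", hint, collapse = ", ")),
          "config_error")
  }
}

#' Build and validate a run configuration
#'
#' Fills defaults and rejects unknown keys (with a nearest-match suggestion,
#' e.g. `gamma` instead of `gamma_over_4`). The returned object fully
#' determines a run given its `seed`.
#'
#' @param ... Configuration fields: `model` (`"km"`/`"sl"`), `n`, `network`
#'   (list with `type` = `"all_to_all"`/`"newman_watts"`/`"erdos_renyi"` and
#'   parameters), `frequencies` (`mean`, `sd`), `coupling` (`K`, or
#'   `schedule` = `"seizure_km"`/`"seizure_sl"` with `scale`), `control`
#'   (`method`, `M`, `gamma_over_4`, `P`, `D`, `c_s`, `distance_mode`,
#'   `control_mode`), `integrator` (`dt`, `t_end`, `record_every`,
#'   `transient_fraction`), `reps`, `seed`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1L && is.null(names(cfg)) && is.list(cfg[[1]]))
    cfg <- cfg[[1]]
  check_keys(names(cfg), names(config_schema), "config")
  for (sec in names(config_schema)) {
    if (!is.null(config_schema[[sec]]) && !is.null(cfg[[sec]]))
      check_keys(names(cfg[[sec]]), config_schema[[sec]], sec)
  }
  if (is.null(cfg$model)) abort("config needs a model ('km' or 'sl')", "config_error")
  if (!cfg$model %in% c("km", "sl"))
    abort("model must be 'km' or 'sl'", "config_error")
  if (is.null(cfg$n)) abort("config needs n", "config_error")
  defaults <- list(
    network = list(type = "all_to_all"),
    frequencies = list(mean = 1, sd = 0.1),
    coupling = list(K = 0.5),
    control = list(method = "none"),
    integrator = list(dt = 0.01, t_end = 100, record_every = 10,
                      transient_fraction = 0.5),
    reps = 1, seed = NULL)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      for (kk in names(defaults[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
  }
  ndef <- list(newman_watts = list(p = 0.85, k_half = 2),
               erdos_renyi = list(q = 0.1))
  if (!is.null(ndef[[cfg$network$type]]))
    for (kk in names(ndef[[cfg$network$type]]))
      if (is.null(cfg$network[[kk]])) cfg$network[[kk]] <- ndef[[cfg$network$type]][[kk]]
  cdef <- list(hamiltonian = list(M = 20, gamma_over_4 = 4.25, c_s = 1,
                                  distance_mode = "ring",
                                  control_mode = "global-R"),
               pdf = list(M = 20, P = 10, D = 10))
  if (!is.null(cdef[[cfg$control$method]]))
    for (kk in names(cdef[[cfg$control$method]]))
      if (is.null(cfg$control[[kk]])) cfg$control[[kk]] <- cdef[[cfg$control$method]][[kk]]
  structure(cfg, class = "run_config")
}

#' Load / save a run configuration (YAML or JSON)
#'
#' The format follows the file extension (`.yaml`/`.yml` or `.json`).
#' Loading validates and fills defaults, so a save/load round trip is the
#' identity on a validated config.
#'
#' @param path Config file path.
#' @return `load_config` returns a [run_config()]; `save_config` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path), "io_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else abort("config must be .yaml/.yml or .json", "config_error")
  run_config(raw)
}

#' @rdname load_config
#' @param cfg A [run_config()].
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            null = "null")
  invisible(path)
}

#' Execute a run configuration
#'
#' Builds the network, frequencies, schedule and control from a validated
#' config (all child seeds derived from `cfg$seed`) and integrates the model.
#'
#' @param cfg A [run_config()].
#' @param record_phases Keep full trajectories.
#' @return A `sim_trace`.
#' @export
run_from_config <- function(cfg, record_phases = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  n <- cfg$n
  net <- switch(cfg$network$type,
    all_to_all = all_to_all(n),
    newman_watts = newman_watts(n, cfg$network$p, cfg$network$k_half,
                                seed = derive_seeds(cfg$seed, "network")),
    erdos_renyi = erdos_renyi_connected(n, cfg$network$q,
                                        seed = derive_seeds(cfg$seed, "network")),
    file = load_network(cfg$network$path, cfg$network$format %||% "edgelist"),
    abort(paste("unknown network type:", cfg$network$type), "config_error"))
  omega <- sample_frequencies(n, cfg$frequencies$mean, cfg$frequencies$sd,
                              seed = derive_seeds(cfg$seed, "frequencies"))
  sch <- if (!is.null(cfg$coupling$schedule)) {
    s <- switch(cfg$coupling$schedule,
      seizure_km = seizure_schedule_km(cfg$coupling$scale %||% 50,
                                       plateau = cfg$coupling$plateau %||%
                                         c(0.55, 0.65)),
      seizure_sl = seizure_schedule_sl(),
      abort(paste("unknown schedule:", cfg$coupling$schedule), "config_error"))
    s$seed <- derive_seeds(cfg$seed, "schedule")
    s
  } else constant_schedule(cfg$coupling$K, cfg$integrator$t_end)
  lay <- NULL; pdf <- NULL
  if (cfg$control$method == "hamiltonian") {
    lay <- place_electrodes(net, cfg$control$M,
                            seed = derive_seeds(cfg$seed, "placement"),
                            distance_mode = cfg$control$distance_mode,
                            c_s = cfg$control$c_s,
                            gamma_over_4 = cfg$control$gamma_over_4)
  } else if (cfg$control$method == "pdf") {
    pdf <- pdf_config(n, cfg$control$M, P = cfg$control$P, D = cfg$control$D,
                      seed = derive_seeds(cfg$seed, "placement"))
  }
  if (cfg$model == "km") {
    ic <- random_phases(n, seed = derive_seeds(cfg$seed, "initial"))
    integrate_km(ic, omega, net = net, schedule = sch, dt = cfg$integrator$dt,
                 record_every = cfg$integrator$record_every, control = lay,
                 control_mode = cfg$control$control_mode %||% "global-R",
                 pdf = pdf, record_phases = record_phases)
  } else {
    ic <- random_unit_state(n, seed = derive_seeds(cfg$seed, "initial"))
    integrate_sl(ic, omega, net = net, schedule = sch, dt = cfg$integrator$dt,
                 record_every = cfg$integrator$record_every, control = lay,
                 control_mode = cfg$control$control_mode %||% "global-R",
                 record_states = record_phases)
  }
}

#' Write a trace or sweep result to disk
#'
#' Emits CSV data, a JSON metadata summary (configuration echo, seeds,
#' package version, wall time) and a manifest with content hashes; re-running
#' an identical seeded computation reproduces identical data hashes.
#'
#' @param x A `sim_trace` or `sweep_result`.
#' @param out_dir Output directory (created if missing).
#' @param stem File-name stem, default `"result"`.
#' @return Invisible data frame manifest (`file`, `md5`), also written as
#'   `<stem>_manifest.json`.
#' @export
write_results <- function(x, out_dir, stem = "result") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste("cannot create", out_dir), "io_error")
  t0 <- proc.time()[["elapsed"]]
  files <- character(0)
  if (inherits(x, "sim_trace")) {
    data_path <- file.path(out_dir, paste0(stem, "_series.csv"))
    df <- data.frame(time = x$times, R = x$R_series, K = x$K_series)
    if (x$model == "km") df$Psi <- x$Psi_series
    if (x$model == "sl") df$total_signal <- x$total_signal
    utils::write.csv(df, data_path, row.names = FALSE)
    files <- data_path
    if (!is.null(x$phases)) {
      long_path <- file.path(out_dir, paste0(stem, "_phases.csv"))
      long <- data.frame(
        time = rep(x$times, times = ncol(x$phases)),
        node = rep(seq_len(ncol(x$phases)) - 1L, each = nrow(x$phases)),
        phase = as.vector(x$phases))
      utils::write.csv(long, long_path, row.names = FALSE)
      files <- c(files, long_path)
    }
    summary <- list(kind = "sim_trace", model = x$model, dt = x$dt,
                    t_end = x$t_end, mean_R = mean_R(x), meta = x$meta)
  } else if (inherits(x, "sweep_result")) {
    data_path <- file.path(out_dir, paste0(stem, "_cells.csv"))
    grid <- expand.grid(count = x$counts, strength = x$strengths)
    grid$mean_R <- as.vector(x$mean_R)
    grid$sd_R <- as.vector(x$sd_R)
    utils::write.csv(grid, data_path, row.names = FALSE)
    files <- data_path
    summary <- list(kind = "sweep_result", reps = x$reps, meta = x$meta,
                    counts = x$counts, strengths = x$strengths)
  } else abort("unsupported result type", "invalid_parameter")
  summary$package_version <- as.character(utils::packageVersion("desynctrl"))
  summary$wall_time_s <- proc.time()[["elapsed"]] - t0
  meta_path <- file.path(out_dir, paste0(stem, "_meta.json"))
  jsonlite::write_json(summary, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  files <- c(files, meta_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stem, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Reload a sweep result written by [write_results()]
#'
#' @param out_dir,stem Location used when writing.
#' @return A `sweep_result` equal to the original up to metadata.
#' @export
read_sweep_result <- function(out_dir, stem = "result") {
  grid <- utils::read.csv(file.path(out_dir, paste0(stem, "_cells.csv")))
  meta <- jsonlite::read_json(file.path(out_dir, paste0(stem, "_meta.json")),
                              simplifyVector = TRUE)
  counts <- sort(unique(grid$count))
  strengths <- sort(unique(grid$strength))
  m <- matrix(NA_real_, length(counts), length(strengths))
  s <- m
  m[cbind(match(grid$count, counts), match(grid$strength, strengths))] <- grid$mean_R
  s[cbind(match(grid$count, counts), match(grid$strength, strengths))] <- grid$sd_R
  new_sweep_result(counts, strengths, m, s, meta$reps, meta$meta)
}
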