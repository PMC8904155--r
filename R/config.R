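#' @noRd
config_defaults <- function() {
  list(
    cell = list(preset = "A2", source = "reduced", budget = 12,
                swc = NULL, overrides = NULL),
    electrode = list(radius = 100, sigma = 0.1, distance_to_soma = 50),
    solver = list(dt = 0.01, method = "backward_euler",
                  spike_threshold = -20, spike_deadtime = 1.5,
                  settle_ms = 500),
    protocol = list(amplitude_uA = 100, pw_ms = 0.5, ipg_ms = 0,
                    freq_hz = 120, duration_ms = 1000, resolution_uA = 1,
                    amp_min_uA = NULL, amp_max_uA = NULL, step_uA = 5,
                    channel = NULL, value = NULL, level = 0.5,
                    step_nA = -0.02),
    output = list(dir = ".", force = FALSE),
    seed = 1
  )
}

#' Validate and normalize a run configuration
#'
#' Fills defaults, rejects unknown keys (typo guard) with a field-path
#' message, and checks units/signs (amplitudes are magnitudes; polarity is
#' not encoded in the sign).  Normalization is idempotent.
#'
#' @param src A YAML file path, a YAML string, or a nested list.
#' @return Normalized configuration list of class `run_config`.
#' @export
validate_config <- function(src) {
  cfg <- if (is.list(src)) {
    src
  } else if (length(src) == 1 && file.exists(src)) {
    yaml::read_yaml(src)
  } else {
    yaml::yaml.load(paste(src, collapse = "\n"))
  }
  if (is.null(cfg)) cfg <- list()
  class(cfg) <- NULL
  defs <- config_defaults()
  bad <- setdiff(names(cfg), names(defs))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (blk in names(defs)) {
    if (!is.list(defs[[blk]])) next
    extra <- setdiff(names(cfg[[blk]]), names(defs[[blk]]))
    if (length(extra)) {
      stop("unknown config key(s): ",
           paste(paste0(blk, ".", extra), collapse = ", "))
    }
    defs[[blk]][names(cfg[[blk]])] <- cfg[[blk]]
  }
  if (!is.null(cfg$seed)) defs$seed <- cfg$seed
  if (!defs$cell$preset %in% c("A2", "D1")) {
    stop("cell.preset must be A2 or D1")
  }
  if (!defs$cell$source %in% c("reduced", "stylized", "swc")) {
    stop("cell.source must be reduced, stylized or swc")
  }
  if (is.null(defs$electrode$radius) || defs$electrode$radius <= 0) {
    stop("electrode.radius must be a positive number (um)")
  }
  if (defs$electrode$sigma <= 0) stop("electrode.sigma must be positive (S/m)")
  if (defs$protocol$amplitude_uA < 0) {
    stop("protocol.amplitude_uA is a magnitude and must be >= 0 ",
         "(polarity is fixed by the waveform convention)")
  }
  if (defs$protocol$pw_ms <= 0) stop("protocol.pw_ms must be positive")
  if (defs$protocol$ipg_ms < 0) stop("protocol.ipg_ms must be >= 0")
  if (defs$solver$dt <= 0) stop("solver.dt must be positive (ms)")
  class(defs) <- "run_config"
  defs
}

#' @noRd
config_cell <- function(cfg, which = cfg$cell$preset) {
  src <- cfg$cell$source
  ov <- cfg$cell$overrides
  if (src == "reduced") {
    pair <- make_reduced_pair(cfg$cell$budget)
    cell <- if (which == "A2") pair$a2 else pair$d1
    if (!is.null(ov)) {
      cell <- build_preset_cell(which, cell$morphology, overrides = ov)
    }
    cell
  } else if (src == "stylized") {
    m <- attach_axon(generate_stylized_morphology(
      preset_cell_spec(which, seed = cfg$seed)))
    build_preset_cell(which, m, overrides = ov)
  } else {
    if (is.null(cfg$cell$swc)) stop("cell.swc path required for source 'swc'")
    m <- attach_axon(load_swc(cfg$cell$swc))
    build_preset_cell(which, m, overrides = ov)
  }
}

#' @noRd
config_electrode <- function(cfg) {
  electrode_model(radius = cfg$electrode$radius, sigma = cfg$electrode$sigma,
                  distance_to_soma = cfg$electrode$distance_to_soma)
}

#' @noRd
config_settings <- function(cfg) {
  solver_settings(dt = cfg$solver$dt, method = cfg$solver$method,
                  spike_threshold = cfg$solver$spike_threshold,
                  spike_deadtime = cfg$solver$spike_deadtime,
                  settle_ms = cfg$solver$settle_ms)
}

#' @noRd
write_artifact_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s rgcstim %s", hash,
                     as.character(utils::packageVersion("rgcstim"))), con)
  write.csv(df, con, row.names = FALSE)
}

#' Run a named protocol from a configuration
#'
#' Dispatches one of the protocol subcommands (`simulate`, `threshold`,
#' `curve`, `sweep-pw`, `sweep-ipg`, `window`, `swap`, `refractory`, `sag`,
#' `make-fixture`), writing one CSV of the grid/trace outputs and one JSON
#' summary embedding the config hash and package version.  Existing outputs
#' are refused unless `output.force` is set.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param protocol Protocol name.
#' @return Invisibly, the paths written (named list with `csv`, `json`).
#' @export
run_protocol <- function(config, protocol) {
  cfg <- validate_config(config)
  known <- c("simulate", "threshold", "curve", "sweep-pw", "sweep-ipg",
             "window", "swap", "refractory", "sag", "make-fixture")
  if (!protocol %in% known) {
    stop("unknown protocol '", protocol, "'; one of: ",
         paste(known, collapse = ", "))
  }
  # the hash covers the scientific configuration, not the output policy
  hash <- rlang::hash(unclass(cfg)[setdiff(names(cfg), "output")])
  dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(cfg$output$dir, paste0(protocol, "-", cfg$cell$preset))
  csv_path <- paste0(stem, ".csv")
  json_path <- paste0(stem, ".json")
  if (!isTRUE(cfg$output$force) &&
      (file.exists(csv_path) || file.exists(json_path))) {
    stop("output exists (", stem, ".*); set output.force to overwrite")
  }
  el <- config_electrode(cfg)
  st <- config_settings(cfg)
  p <- cfg$protocol
  summary <- list(protocol = protocol, config_hash = hash,
                  version = as.character(utils::packageVersion("rgcstim")),
                  dt = st$dt, seed = cfg$seed)
  df <- NULL

  if (protocol == "simulate") {
    cell <- config_cell(cfg)
    train <- pulse_train(p$amplitude_uA, p$pw_ms, p$ipg_ms, p$freq_hz,
                         p$duration_ms)
    sim <- simulate_cell(cell, train, el, settings = st)
    df <- data.frame(time_ms = sim$time, v_soma_mV = sim$soma_voltage,
                     i_stim_uA = c(NA, sim$stimulus))
    summary$n_spikes <- length(sim$spike_times)
    summary$spike_probability <- spike_probability(sim$spike_times, train)
  } else if (protocol == "threshold") {
    cell <- config_cell(cfg)
    th <- find_threshold(cell, p$pw_ms, p$ipg_ms, p$freq_hz,
                         resolution = p$resolution_uA,
                         duration = p$duration_ms, electrode = el,
                         settings = st)
    df <- th$search_trace
    summary$current_uA <- th$current
    summary$charge_nC <- th$charge
    summary$achieved_probability <- th$achieved_probability
  } else if (protocol %in% c("curve", "window")) {
    cell <- config_cell(cfg)
    rng <- c(p$amp_min_uA, p$amp_max_uA)
    if (length(rng) != 2) stop("protocol.amp_min_uA/amp_max_uA required")
    curve <- rate_vs_amplitude(cell, rng, p$step_uA, p$pw_ms, p$ipg_ms,
                               p$freq_hz, p$duration_ms, el, st)
    df <- as.data.frame(curve)
    if (protocol == "window") {
      w <- saturation_window(curve, p$level)
      summary$window_width_uA <- w$width
      summary$window_interval <- w$interval
    }
  } else if (protocol %in% c("sweep-pw", "sweep-ipg")) {
    pair <- make_reduced_pair(cfg$cell$budget)
    df <- if (protocol == "sweep-pw") {
      strength_duration_sweep(pair$a2, pair$d1, resolution = p$resolution_uA,
                              duration = p$duration_ms, electrode = el,
                              settings = st)
    } else {
      ipg_sweep(pair$a2, pair$d1, resolution = p$resolution_uA,
                duration = p$duration_ms, electrode = el, settings = st)
    }
    df <- as.data.frame(df)
  } else if (protocol == "swap") {
    if (is.null(p$channel) || is.null(p$value)) {
      stop("protocol.channel and protocol.value required for swap")
    }
    cell <- config_cell(cfg)
    res <- channel_swap_experiment(cell, p$channel, p$value, settings = st)
    df <- data.frame(time_ms = res$base$time,
                     v_base_mV = res$base$soma_voltage,
                     v_swapped_mV = res$swapped$soma_voltage)
    summary$delta_width_ms <- res$delta$width
    summary$delta_peak_mV <- res$delta$peak
  } else if (protocol == "refractory") {
    cell <- config_cell(cfg)
    rp <- measure_refractory(cell, pulse_width = p$pw_ms, ipg = p$ipg_ms,
                             electrode = el, settings = st)
    df <- data.frame(refractory_ms = rp)
    summary$refractory_ms <- rp
  } else if (protocol == "sag") {
    cell <- config_cell(cfg)
    sag <- measure_sag(cell, amp = p$step_nA, settings = st)
    df <- data.frame(sag_mV = sag)
    summary$sag_mV <- sag
  } else if (protocol == "make-fixture") {
    m <- generate_stylized_morphology(preset_cell_spec(cfg$cell$preset,
                                                       seed = cfg$seed))
    lines <- write_swc(m)
    writeLines(lines, paste0(stem, ".swc"))
    df <- data.frame(n_points = attr(load_swc(lines), "swc_n_points"))
    summary$swc <- paste0(stem, ".swc")
  }

  write_artifact_csv(df, csv_path, hash)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(list(csv = csv_path, json = json_path))
}
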