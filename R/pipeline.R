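#' Build a pipeline configuration
#'
#' A pipeline configuration bundles the acquisition, gating, detection,
#' kinetics and pore-model parameters for an end-to-end run, either from a
#' YAML file mirroring this structure or from arguments. Units are fixed
#' package-wide: pA, s, mV, M, Angstrom, S/m.
#'
#' @param path Optional YAML file; entries override the defaults below.
#' @param acquisition List of [acquisition_config()] arguments.
#' @param gating List of [gating_model()] arguments.
#' @param voltages Optional voltage ladder, mV; when present the pipeline
#'   simulates one trace per voltage and fits the voltage dependence.
#' @param detection List: `enter_frac`, `exit_frac`, `min_duration`.
#' @param electrolyte List: `c_salt` (M), `valence`, `temperature` (K),
#'   `epsilon_r`, `conductivity` (S/m).
#' @param simulate Generate traces (`TRUE`) or analyse `trace_file`.
#' @param trace_file Existing trace CSV used when `simulate = FALSE`.
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL,
                            acquisition = list(),
                            gating = list(),
                            voltages = NULL,
                            detection = list(),
                            electrolyte = list(),
                            simulate = TRUE,
                            trace_file = NULL,
                            seed = 1L) {
  cfg <- list(
    acquisition = acquisition, gating = gating, voltages = voltages,
    detection = detection, electrolyte = electrolyte,
    simulate = simulate, trace_file = trace_file, seed = seed
  )
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg$detection <- utils::modifyList(
    list(enter_frac = 0.7, exit_frac = 0.9, min_duration = 1e-4),
    cfg$detection %||% list()
  )
  cfg$electrolyte <- utils::modifyList(
    list(c_salt = 2, valence = 1, temperature = 300, epsilon_r = 70,
         conductivity = 20),
    cfg$electrolyte %||% list()
  )
  cfg$acquisition$seed <- cfg$acquisition$seed %||% cfg$seed
  structure(cfg, class = "pipeline_config")
}

#' Run the full simulate-detect-characterize-fit pipeline
#'
#' Orchestrates the package end to end: simulate (or load) traces, detect
#' and idealize events, pool the amplitude histogram, estimate dwell-time
#' constants and rate constants per voltage, fit the exponential voltage
#' dependence when a voltage ladder is configured, and evaluate the Debye
#' length of the electrolyte. Every output is written under `out_dir`
#' (trace CSVs, event TSVs, a rates TSV, and `summary.json`); an identical
#' seed and configuration reproduces `summary.json` byte for byte. A
#' failure in any stage propagates with the stage name attached.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips file
#'   output.
#' @return Invisibly, the summary list: `frac_block_1`, `frac_block_2`,
#'   `k_on`, `k_off`, `k0`, `a`, `debye_length_A`, `n_events`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  acq <- stage("config", do.call(acquisition_config, config$acquisition))
  model <- stage("config", do.call(gating_model, config$gating))

  traces <- stage("simulate", {
    if (!config$simulate) {
      if (is.null(config$trace_file)) abort("`trace_file` required when simulate = FALSE.")
      stats::setNames(list(read_trace(config$trace_file)),
                      as.character(acq$voltage))
    } else if (!is.null(config$voltages)) {
      generate_voltage_series(model, config$voltages, acq)
    } else {
      stats::setNames(list(simulate_trace(model, acq)),
                      as.character(acq$voltage))
    }
  })
  if (!is.null(out_dir) && config$simulate) {
    purrr::iwalk(traces, function(tr, v) {
      write_trace(tr, file.path(out_dir, sprintf("trace_%smV.csv", v)))
    })
  }

  det <- config$detection
  event_tables <- stage("detect", purrr::map(traces, function(tr) {
    detect_events(tr, enter_frac = det$enter_frac, exit_frac = det$exit_frac,
                  min_duration = det$min_duration)
  }))
  if (!is.null(out_dir)) {
    purrr::iwalk(event_tables, function(ev, v) {
      write_events(ev, file.path(out_dir, sprintf("events_%smV.tsv", v)))
    })
  }

  ref <- event_tables[[1]]
  stats_blk <- stage("histogram", {
    if (nrow(ref) > 0) amplitude_histogram(ref, traces[[1]]) else NULL
  })

  conc <- config$gating$concentration %||% model$concentration
  rates <- stage("kinetics", purrr::imap_dfr(event_tables, function(ev, v) {
    durs <- event_durations(ev)
    waits <- event_intervals(ev)
    if (length(durs) == 0 || length(waits) == 0) {
      return(tibble(voltage_mV = as.numeric(v), n_events = nrow(ev),
                    k_on = NA_real_, k_on_lo = NA_real_, k_on_hi = NA_real_,
                    k_off = NA_real_, k_off_lo = NA_real_, k_off_hi = NA_real_))
    }
    kon <- compute_kon(exp_mle(waits), conc)
    koff <- compute_koff(exp_mle(durs))
    tibble(voltage_mV = as.numeric(v), n_events = nrow(ev),
           k_on = kon$rate, k_on_lo = kon$ci_low, k_on_hi = kon$ci_high,
           k_off = koff$rate, k_off_lo = koff$ci_low, k_off_hi = koff$ci_high)
  }))
  if (!is.null(out_dir)) {
    utils::write.table(as.data.frame(rates), file.path(out_dir, "rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  fit <- NULL
  if (sum(is.finite(rates$k_on)) >= 3) {
    fit <- stage("voltage_fit", fit_voltage_dependence(
      tibble(voltage_mV = rates$voltage_mV, k = rates$k_on)
    ))
  }

  el <- config$electrolyte
  debye <- stage("debye", debye_length(el$c_salt, el$valence,
                                       el$temperature, el$epsilon_r))

  summary <- list(
    frac_block_1 = if (!is.null(stats_blk)) stats_blk$frac_block_1 else NA,
    frac_block_2 = if (!is.null(stats_blk)) stats_blk$frac_block_2 else NA,
    k_on = rates$k_on[[1]],
    k_off = rates$k_off[[1]],
    k0 = if (!is.null(fit)) fit$k0 else NA,
    a = if (!is.null(fit)) fit$a else NA,
    debye_length_A = debye,
    n_events = sum(rates$n_events)
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(structure(list(summary = summary, rates = rates, fit = fit,
                           blockade = stats_blk, events = event_tables),
                      class = "pipeline_result"))
}

#' Generate the canonical synthetic test fixtures
#'
#' Writes, under `out_dir`: a noise-free square-wave trace
#' (`square_wave_trace.csv`), a noisy two-substate trace
#' (`noisy_substate_trace.csv`) with its generating truth
#' (`noisy_substate_truth.json`), an event-level voltage-series dataset
#' (`voltage_series.tsv` + `voltage_series_truth.json`), cylinder and
#' annulus pseudo-atom PDB files with their analytic geometry truths, and a
#' `manifest.json` listing each file with its size and MD5. All fixtures
#' are synthetic, generated from the given seed.
#'
#' @param out_dir Writable output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the manifest as a tibble (`file`, `bytes`, `md5`).
#' @export
generate_fixtures <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) abort(sprintf("Cannot create '%s'.", out_dir))
  }

  # 1. Noise-free square wave: 50 events, 10 ms each, depth 0.91 (25% duty
  # cycle so the amplitude mode is unambiguously the open-pore level).
  cfg_sq <- acquisition_config(duration = 2, seed = seed)
  mod_sq <- gating_model(noise_sd = 0, frac_block_1 = 0.91, frac_block_2 = 0.83,
                         substate_switch_rates = c(0, 0))
  ev_sq <- tibble(
    event = 1:50,
    start_s = 0.005 + (0:49) * 0.04,
    duration_s = 0.01,
    censored = FALSE
  )
  ev_sq$substates <- purrr::map2(ev_sq$start_s, ev_sq$duration_s,
                                 ~ tibble(level = 1L, start_s = .x, end_s = .x + .y))
  tr_sq <- render_trace(ev_sq, mod_sq, cfg_sq)
  write_trace(tr_sq, file.path(out_dir, "square_wave_trace.csv"))

  # 2. Noisy two-substate trace with ground truth.
  cfg_ns <- acquisition_config(duration = 5, seed = seed + 1L)
  mod_ns <- gating_model(k_on_0 = 10 / 3e-5, a = 0, concentration = 3e-5,
                         k_off_0 = 50, noise_sd = 2)
  tr_ns <- simulate_trace(mod_ns, cfg_ns)
  write_trace(tr_ns, file.path(out_dir, "noisy_substate_trace.csv"))
  truth <- attr(tr_ns, "true_events")
  jsonlite::write_json(
    list(
      seed = cfg_ns$seed, capture_rate = 10, k_off = 50,
      i_open = mod_ns$i_open, frac_block_1 = mod_ns$frac_block_1,
      frac_block_2 = mod_ns$frac_block_2, noise_sd = mod_ns$noise_sd,
      n_events = nrow(truth),
      events = truth[c("start_s", "duration_s", "censored")]
    ),
    file.path(out_dir, "noisy_substate_truth.json"),
    auto_unbox = TRUE, digits = NA
  )

  # 3. Event-level voltage series (dwells per voltage).
  mod_vs <- gating_model(k_on_0 = 8.35e4, a = 0.02, concentration = 3e-5,
                         k_off_0 = 100)
  volts <- seq(40, 140, by = 20)
  series <- generate_voltage_series(mod_vs, volts,
                                    acquisition_config(seed = seed + 2L),
                                    events_only = TRUE, n_events = 200)
  vs <- purrr::imap_dfr(series, function(ev, v) {
    tibble(voltage_mV = as.numeric(v), event = ev$event,
           wait_s = ev$wait_s, duration_s = ev$duration_s)
  })
  utils::write.table(as.data.frame(vs), file.path(out_dir, "voltage_series.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(k_on_0 = mod_vs$k_on_0, a = mod_vs$a, k_off_0 = mod_vs$k_off_0,
         concentration_M = mod_vs$concentration, voltages_mV = volts,
         events_per_voltage = 200, seed = seed + 2L),
    file.path(out_dir, "voltage_series_truth.json"),
    auto_unbox = TRUE, digits = NA
  )

  # 4. Cylinder and annulus pseudo-atom PDBs (probe 1.4, carbon radius 1.7).
  probe <- 1.4; r_atom <- 1.7
  cyl <- .pseudo_cylinder_atoms(inner_radius = 10, length = 20,
                                r_eff = r_atom + probe)
  write_pseudo_atoms_pdb(cyl, file.path(out_dir, "cylinder_synthetic.pdb"))
  rod <- .pseudo_rod_atoms(radius = 5, length = 20, r_eff = r_atom + probe)
  write_pseudo_atoms_pdb(rbind(cyl, rod),
                         file.path(out_dir, "annulus_synthetic.pdb"))
  jsonlite::write_json(
    list(cylinder = list(inner_radius_A = 10, area_A2 = pi * 100,
                         n_atoms = nrow(cyl)),
         annulus = list(outer_A = 10, inner_A = 5, area_A2 = pi * (100 - 25),
                        n_atoms = nrow(cyl) + nrow(rod)),
         probe_A = probe, atom_radius_A = r_atom),
    file.path(out_dir, "geometry_truth.json"),
    auto_unbox = TRUE, digits = NA
  )

  files <- c("square_wave_trace.csv", "noisy_substate_trace.csv",
             "noisy_substate_truth.json", "voltage_series.tsv",
             "voltage_series_truth.json", "cylinder_synthetic.pdb",
             "annulus_synthetic.pdb", "geometry_truth.json")
  paths <- file.path(out_dir, files)
  manifest <- tibble(
    file = files,
    bytes = file.info(paths)$size,
    md5 = unname(tools::md5sum(paths))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA)
  invisible(manifest)
}

# Hollow cylinder wall: atom centers at inner_radius + r_eff so the dilated
# wall leaves exactly `inner_radius` of open lumen; rings every r_eff/2 in z
# with center spacing below r_eff to keep the wall watertight.
.pseudo_cylinder_atoms <- function(inner_radius, length, r_eff) {
  r_wall <- inner_radius + r_eff
  n_ring <- ceiling(2 * pi * r_wall / (0.6 * r_eff))
  th <- seq(0, 2 * pi, length.out = n_ring + 1)[-(n_ring + 1)]
  zs <- seq(0, length, by = r_eff / 2)
  out <- expand.grid(th = th, z = zs)
  data.frame(x = r_wall * cos(out$th), y = r_wall * sin(out$th), z = out$z)
}

# Solid coaxial rod of effective radius `radius`: stacked axis atoms whose
# dilated radius equals the rod radius (atoms carry radius - probe, but the
# fixture writes carbon atoms, so callers pass matched r_eff).
.pseudo_rod_atoms <- function(radius, length, r_eff) {
  stopifnot(radius >= r_eff)
  # concentric filled disc of atom centers so the union of dilated discs is
  # a solid rod of the requested radius
  radii <- seq(0, radius - r_eff, by = 0.6 * r_eff)
  pts <- purrr::map_dfr(radii, function(rr) {
    if (rr == 0) return(data.frame(th = 0, r = 0))
    n <- ceiling(2 * pi * rr / (0.6 * r_eff))
    data.frame(th = seq(0, 2 * pi, length.out = n + 1)[-(n + 1)], r = rr)
  })
  zs <- seq(0, length, by = r_eff / 2)
  out <- merge(pts, data.frame(z = zs))
  data.frame(x = out$r * cos(out$th), y = out$r * sin(out$th), z = out$z)
}
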