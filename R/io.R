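#' Write a current trace to a two-column CSV with metadata header
#'
#' Columns are `time_s,current_pA`; acquisition and gating metadata are kept
#' as `#`-prefixed header lines so the file round-trips through
#' [read_trace()]. Units are fixed package-wide (s, pA, Hz, mV, M).
#'
#' @param trace An `np_trace` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  cfg <- trace_config(trace)
  model <- trace_truth(trace)
  hdr <- c(
    "# nanoblock trace v1 (units: time_s, current_pA)",
    if (!is.null(cfg)) c(
      sprintf("# sampling_rate_Hz: %.10g", cfg$sampling_rate),
      sprintf("# filter_cutoff_Hz: %.10g", cfg$filter_cutoff),
      sprintf("# voltage_mV: %.10g", cfg$voltage),
      sprintf("# duration_s: %.10g", cfg$duration),
      sprintf("# seed: %d", cfg$seed)
    ),
    if (!is.null(model)) c(
      sprintf("# concentration_M: %.10g", model$concentration),
      sprintf("# side: %s", model$side),
      sprintf("# i_open_pA: %.10g", model$i_open)
    )
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s,current_pA", con)
  writeLines(paste(format(trace$time_s, trim = TRUE, scientific = FALSE),
                   format(trace$current_pA, trim = TRUE, digits = 10),
                   sep = ","), con)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV file with `#` metadata header lines.
#' @return An `np_trace` tibble; acquisition metadata found in the header is
#'   restored as the `config` attribute.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+):\\s*(.+)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  dat <- utils::read.csv(path, comment.char = "#")
  out <- as_tibble(dat)
  class(out) <- c("np_trace", class(out))
  if (!is.null(meta$sampling_rate_Hz)) {
    cfg <- acquisition_config(
      sampling_rate = as.numeric(meta$sampling_rate_Hz),
      filter_cutoff = as.numeric(meta$filter_cutoff_Hz %||%
                                   (as.numeric(meta$sampling_rate_Hz) / 2)),
      voltage = as.numeric(meta$voltage_mV %||% 0),
      duration = as.numeric(meta$duration_s %||%
                              (nrow(out) / as.numeric(meta$sampling_rate_Hz))),
      seed = as.integer(meta$seed %||% 0)
    )
    attr(out, "config") <- cfg
  }
  attr(out, "metadata") <- meta
  out
}

#' Write a trace as raw little-endian float32 with a JSON sidecar
#'
#' The binary file holds the current samples only; the sidecar
#' (`<path without extension>.json`) records `sampling_rate`, `voltage_mV`,
#' `concentration_M`, `side` and `i_open_pA`.
#'
#' @param trace An `np_trace` tibble.
#' @param path Output binary file (e.g. `trace.f32`).
#' @return `path`, invisibly.
#' @export
write_trace_binary <- function(trace, path) {
  con <- file(path, open = "wb")
  writeBin(as.numeric(trace$current_pA), con, size = 4L, endian = "little")
  close(con)
  cfg <- trace_config(trace)
  model <- trace_truth(trace)
  sidecar <- list(
    sampling_rate = if (!is.null(cfg)) cfg$sampling_rate else NULL,
    voltage_mV = if (!is.null(cfg)) cfg$voltage else NULL,
    concentration_M = if (!is.null(model)) model$concentration else NULL,
    side = if (!is.null(model)) model$side else NULL,
    i_open_pA = if (!is.null(model)) model$i_open else NULL
  )
  jsonlite::write_json(sidecar[!vapply(sidecar, is.null, logical(1))],
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read a binary trace written by [write_trace_binary()]
#'
#' @param path Binary file; its JSON sidecar must sit alongside.
#' @return An `np_trace` tibble.
#' @export
read_trace_binary <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  n <- file.info(path)$size / 4L
  con <- file(path, open = "rb")
  x <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  close(con)
  fs <- meta$sampling_rate
  out <- tibble(time_s = (seq_along(x) - 1) / fs, current_pA = x)
  class(out) <- c("np_trace", class(out))
  attr(out, "config") <- acquisition_config(
    sampling_rate = fs, filter_cutoff = fs / 2,
    voltage = meta$voltage_mV %||% 0,
    duration = length(x) / fs, seed = 0L
  )
  attr(out, "metadata") <- meta
  out
}

#' Write an event table (and its substates) to TSV
#'
#' The main table has columns `event`, `start_s`, `end_s`, `duration_s`,
#' `wait_s`, `mean_amplitude_pA`, `n_samples`, `censored`, `n_substates`;
#' substates, when present, go to a companion
#' `<path without extension>_substates.tsv` keyed by event index.
#'
#' @param events An `np_events` tibble.
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  main <- as.data.frame(events[setdiff(names(events), "substates")])
  utils::write.table(main, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if ("substates" %in% names(events)) {
    subs <- dplyr::bind_rows(
      purrr::map2(events[["substates"]], events$event,
                  ~ dplyr::mutate(.x, event = .y))
    )
    utils::write.table(as.data.frame(subs), .substates_path(path),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.substates_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_substates.tsv")
}

#' Read an event table written by [write_events()]
#'
#' @param path Main TSV file; a `_substates.tsv` companion is picked up
#'   automatically.
#' @return An `np_events` tibble.
#' @export
read_events <- function(path) {
  main <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
  sp <- .substates_path(path)
  if (file.exists(sp)) {
    subs <- as_tibble(utils::read.table(sp, header = TRUE, sep = "\t"))
    main$substates <- purrr::map(main$event, function(e) {
      s <- subs[subs$event == e, setdiff(names(subs), "event")]
      as_tibble(s)
    })
  }
  class(main) <- c("np_events", class(main))
  main
}

#' Read atoms from a PDB file for the area-profile calculation
#'
#' Parses ATOM/HETATM records with `bio3d::read.pdb` (first alternate
#' location kept, occupancy ignored) and assigns van der Waals radii by
#' element from a bundled table (H 1.2, C 1.7, N 1.55, O 1.52, S 1.8,
#' P 1.8 Angstrom; unknown elements get `default_radius`).
#'
#' @param path PDB file.
#' @param default_radius Radius for elements missing from the table,
#'   Angstrom.
#' @return Tibble with columns `x`, `y`, `z`, `radius`, `element`.
#' @export
read_pore_pdb <- function(path, default_radius = 1.7) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  elem <- toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                         substr(trimws(at$elety), 1, 1), trimws(at$elesy)))
  vdw <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8)
  radius <- unname(vdw[elem])
  radius[is.na(radius)] <- default_radius
  tibble(x = at$x, y = at$y, z = at$z, radius = radius, element = elem)
}

#' Write pseudo-atoms to a minimal PDB file
#'
#' Emits plain ATOM records (carbon pseudo-atoms) so that programmatically
#' built geometries round-trip through [read_pore_pdb()]. The per-atom
#' radius is not a PDB field; it is re-derived from the element on reading,
#' so build fixtures with carbon-radius atoms or pass explicit radii to
#' [area_profile_from_coords()].
#'
#' @param atoms Data frame with columns `x`, `y`, `z`.
#' @param path Output PDB file.
#' @return `path`, invisibly.
#' @export
write_pseudo_atoms_pdb <- function(atoms, path) {
  n <- nrow(atoms)
  lines <- sprintf(
    "ATOM  %5d  C   PSD A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000L, (seq_len(n) %% 10000L), atoms$x, atoms$y, atoms$z
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a pore geometry to TSV
#' @param geometry A `pore_geometry`.
#' @param path Output TSV with columns `z_A`, `area_A2`.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  utils::write.table(as.data.frame(geometry), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pore geometry TSV written by [write_geometry()]
#' @param path TSV file.
#' @param conductivity Electrolyte conductivity to attach, S/m.
#' @return A `pore_geometry` tibble.
#' @export
read_geometry <- function(path, conductivity = 20) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t")
  pore_geometry(dat$z_A, dat$area_A2, conductivity)
}
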