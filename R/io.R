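#' Write an atomic model as a PDB file
#'
#' Standard fixed-column ATOM/HETATM records (via bio3d) preceded by a
#' CRYST1 record carrying the orthogonal cell. Coordinates keep 3 decimals,
#' occupancy and B factor 2 (PDB column widths).
#'
#' @param model An [atomic_model()].
#' @param path Output file.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  het <- a$resid %in% c("HEM", "CMO")
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords(model))),
                   type = ifelse(het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid, eleno = a$atom,
                   elety = a$name, chain = rep("A", nrow(a)),
                   o = a$occ, b = a$b, elesy = a$element)
  lines <- readLines(path)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   model$cell[1], model$cell[2], model$cell[3], 90, 90, 90)
  writeLines(c(cryst, lines), path)
}

#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) and the CRYST1 cell. Malformed
#' coordinate records raise a parse error naming the line number.
#'
#' @param path PDB file with a CRYST1 record (or `cell` given).
#' @param cell Optional cell override (length-3, Angstrom).
#' @return An [atomic_model()].
#' @export
read_pdb <- function(path, cell = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("parse error: no ATOM/HETATM records in ", path)
  for (ln in which(rec)) {
    l <- lines[ln]
    if (nchar(l) < 54 ||
        anyNA(suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                            substr(l, 39, 46),
                                            substr(l, 47, 54)))))) {
      stop("parse error: malformed coordinate record at line ", ln)
    }
  }
  if (is.null(cell)) {
    cl <- lines[grepl("^CRYST1", lines)]
    if (length(cl) == 0) stop("no CRYST1 record and no cell given in ", path)
    cell <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                         substr(cl[1], 25, 33)))
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  elem <- toupper(trimws(ifelse(is.na(a$elesy) | a$elesy == "",
                                substr(trimws(a$elety), 1, 1), a$elesy)))
  atoms <- data.frame(atom = a$eleno, name = trimws(a$elety),
                      element = elem, resid = trimws(a$resid),
                      resno = a$resno, x = a$x, y = a$y, z = a$z,
                      b = a$b, occ = a$o)
  atomic_model(atoms, cell, wrap = FALSE)
}

#' Default replay configuration
#'
#' The run configuration gathers every knob of the end-to-end synthetic
#' replay: the RNG seed, the structural system, the ground-truth kinetics
#' schedule, the per-frame noise model, the nominal delay series with
#' frames per delay, the sliding-window parameters, the bootstrap size and
#' the titration grid. All randomness flows from `seed`.
#'
#' @param seed Integer RNG seed.
#' @param system Named list of [build_two_state_system()] overrides.
#' @param schedule Named list of [ground_truth_schedule()] overrides.
#' @param noise Named list of [frame_noise()] overrides.
#' @param delays Nominal pump-probe delays in fs. The default is the
#'   150-1300 fs ultrafast series plus a 10 ps point anchoring the
#'   apparent-occupancy plateau.
#' @param n_frames_per_delay Frames simulated per nominal delay.
#' @param n_state_groups Number of delay groups the pooled, sorted actual
#'   (jittered) delays are discretized into when generating frame
#'   intensities; each group diffracts from the structural state at its
#'   mean actual delay, so the simulated physics follows the timing-tool
#'   delay, not the nominal one.
#' @param d_min Resolution cutoff in Angstrom.
#' @param window,step Sliding-window binning parameters (frames).
#' @param bootstrap_b Bootstrap replicates per bin (0 disables).
#' @param trial_fs Titration trial-occupancy grid.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(seed = 1,
                       system = list(),
                       schedule = list(),
                       noise = list(),
                       delays = c(150, 225, 300, 375, 450, 525, 600, 750,
                                  900, 1300, 10000),
                       n_frames_per_delay = 400,
                       n_state_groups = 32,
                       d_min = 1.4,
                       window = 500, step = 250,
                       bootstrap_b = 20,
                       trial_fs = seq(0.05, 0.95, by = 0.05)) {
  structure(list(seed = seed, system = system, schedule = schedule,
                 noise = noise, delays = delays,
                 n_frames_per_delay = n_frames_per_delay,
                 n_state_groups = n_state_groups, d_min = d_min,
                 window = window, step = step, bootstrap_b = bootstrap_b,
                 trial_fs = trial_fs),
            class = "run_config")
}

#' Validate a replay configuration
#'
#' Checks every typed-field invariant; violations are returned as data,
#' not raised.
#'
#' @param config A `run_config`.
#' @return Character vector of violations (empty iff valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  say <- function(msg) v <<- c(v, msg)
  if (!is.numeric(config$seed) || length(config$seed) != 1 ||
      config$seed != round(config$seed)) say("seed must be a single integer")
  sch <- tryCatch(do.call(ground_truth_schedule, config$schedule),
                  error = function(e) conditionMessage(e))
  if (is.character(sch)) say(paste("schedule:", sch))
  nz <- tryCatch(do.call(frame_noise, config$noise),
                 error = function(e) conditionMessage(e))
  if (is.character(nz)) say(paste("noise:", nz))
  if (length(config$delays) < 1 || any(config$delays < 0)) {
    say("delays must be non-negative")
  }
  if (config$n_frames_per_delay < 1) say("n_frames_per_delay must be >= 1")
  if (is.null(config$n_state_groups) || config$n_state_groups < 1) {
    say("n_state_groups must be >= 1")
  }
  if (config$d_min <= 0) say("d_min must be > 0")
  n_total <- config$n_frames_per_delay * length(config$delays)
  if (config$window > n_total) {
    say(paste0("window (", config$window, ") exceeds total frames (",
               n_total, "): bin_by_delay precondition violated"))
  }
  if (config$step < 1 || config$step > config$window) {
    say("step must satisfy 1 <= step <= window")
  }
  if (!(config$bootstrap_b == 0 || config$bootstrap_b >= 2)) {
    say("bootstrap_b must be 0 or >= 2")
  }
  if (length(config$trial_fs) < 3 || any(diff(config$trial_fs) <= 0) ||
      any(config$trial_fs <= 0 | config$trial_fs >= 1)) {
    say("trial_fs must be >= 3 strictly increasing values in (0, 1)")
  }
  v
}

#' Write / read a run configuration as YAML
#'
#' @param config A `run_config`.
#' @param path YAML file path.
#' @return `read_config` returns a `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[names(raw) %in% names(formals(run_config))])
  cfg
}
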