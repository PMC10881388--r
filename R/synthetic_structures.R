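#' Build the synthetic two-state protein-heme crystal system
#'
#' Constructs a ~110-atom toy system in an orthogonal P1 box emulating a
#' carboxy-heme protein: a 25-atom heme core (Fe, 4 pyrrole N, 20 ring C),
#' a bound CO ligand, a proximal histidine mimic (His N-epsilon attached to
#' one helix), and two short backbone alpha-helices (proximal "F" and distal
#' "E"). The excited (photolysed) state shares the atom roster and differs
#' only in coordinates: the iron is displaced out of the heme plane toward
#' the proximal histidine by `delta_fe`, the CO is translocated to a docking
#' site, and the proximal helix segment is displaced away from the heme.
#'
#' @param delta_fe Iron out-of-plane displacement in the excited state
#'   (Angstrom, toward the proximal His). Default 0.28, a conventional
#'   deoxy-like value.
#' @param co_shift Translocation vector of the CO carbon from its bound
#'   position to the docking site (Angstrom, heme frame: x,y in plane,
#'   z toward the distal side).
#' @param helix_shift Displacement of the proximal helix (and His) away
#'   from the heme in the excited state (Angstrom, > 0 moves away).
#' @param cell Orthogonal box lengths (Angstrom).
#' @param b_iso Isotropic B factor given to every atom (Angstrom^2).
#' @return An object of class `two_state_system`: fields `dark`, `excited`
#'   (both [atomic_model()]), `deltas`, and index helpers for the heme core,
#'   CO, and proximal-helix atoms.
#' @export
build_two_state_system <- function(delta_fe = 0.28,
                                   co_shift = c(1.6, -2.0, 0.35),
                                   helix_shift = 0.45,
                                   cell = c(34, 30, 28),
                                   b_iso = 15) {
  stopifnot(all(is.finite(c(delta_fe, co_shift, helix_shift))),
            length(cell) == 3, all(cell > 0), b_iso > 0)
  centre <- cell / 2
  rows <- list()
  add <- function(name, element, resid, resno, pos) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, element = element, resid = resid, resno = resno,
      x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
  }

  # --- heme core in the z = centre[3] plane, Fe at the centre -------------
  add("FE", "FE", "HEM", 200L, centre)
  ring <- function(prefix, element, radius, angles_deg) {
    for (i in seq_along(angles_deg)) {
      a <- angles_deg[i] * pi / 180
      add(paste0(prefix, i), element, "HEM", 200L,
          centre + c(radius * cos(a), radius * sin(a), 0))
    }
  }
  ring("N",  "N", 2.00, c(45, 135, 225, 315))                       # pyrrole N
  ring("CA", "C", 3.05, rep(c(45, 135, 225, 315), each = 2) +
         rep(c(-23, 23), 4))                                        # alpha C
  ring("CB", "C", 4.30, rep(c(45, 135, 225, 315), each = 2) +
         rep(c(-36, 36), 4))                                        # beta C
  ring("CM", "C", 3.45, c(0, 90, 180, 270))                         # meso C

  # --- bound CO on the distal side (+z) -----------------------------------
  add("C", "C", "CMO", 201L, centre + c(0, 0, 1.85))
  add("O", "O", "CMO", 201L, centre + c(0, 0, 2.98))

  # --- proximal His mimic: N-epsilon bonded to the iron (-z side) ---------
  add("NE2", "N", "HIS", 93L, centre + c(0, 0, -2.15))

  # --- two short backbone helices (N, CA, C, O per residue) ---------------
  helix <- function(resnos, axis_origin, z_level) {
    # idealized helix, axis along x: rise 1.5 A and 100 deg per residue;
    # backbone atoms ride the same helical curve at fractional residue
    # offsets, the carbonyl O sticks radially outward
    at <- function(s, radius) {
      th <- s * 100 * pi / 180
      c(axis_origin[1] + s * 1.5,
        axis_origin[2] + radius * cos(th),
        z_level + radius * sin(th))
    }
    for (i in seq_along(resnos)) {
      s <- i - 1
      add("N",  "N", "ALA", resnos[i], at(s - 0.33, 2.0))
      add("CA", "C", "ALA", resnos[i], at(s, 2.0))
      add("C",  "C", "ALA", resnos[i], at(s + 0.33, 2.0))
      add("O",  "O", "ALA", resnos[i], at(s + 0.38, 3.2))
    }
  }
  helix(89:98, c(centre[1] - 6.8, centre[2], 0), centre[3] - 6.4)  # proximal F
  helix(58:67, c(centre[1] - 6.8, centre[2], 0), centre[3] + 6.6)  # distal E

  atoms <- do.call(rbind, rows)
  atoms$atom <- seq_len(nrow(atoms))
  atoms$b <- b_iso
  atoms$occ <- 1
  dark <- atomic_model(atoms, cell, wrap = FALSE)
  if (min_distance(dark) < 0.5) {
    stop("invalid geometry: atoms closer than 0.5 A in the dark state")
  }

  prox_sel <- (atom_select(dark, resid = "ALA") & dark$atoms$resno %in% 89:98) |
    atom_select(dark, name = "NE2", resid = "HIS")
  co_sel <- atom_select(dark, resid = "CMO")
  fe_sel <- atom_select(dark, name = "FE", resid = "HEM")

  xyz <- coords(dark)
  xyz[fe_sel, 3] <- xyz[fe_sel, 3] - delta_fe            # toward proximal His
  xyz[prox_sel, 3] <- xyz[prox_sel, 3] - helix_shift     # helix recoils away
  xyz[co_sel, ] <- sweep(xyz[co_sel, , drop = FALSE], 2, co_shift, "+")
  excited <- set_coords(dark, xyz)
  if (min_distance(excited) < 0.5) {
    stop("invalid geometry: atoms closer than 0.5 A in the excited state")
  }

  structure(list(
    dark = dark, excited = excited,
    deltas = list(delta_fe = delta_fe, co_shift = co_shift,
                  helix_shift = helix_shift),
    sel = list(fe = fe_sel, co = co_sel, proximal = prox_sel,
               core = atom_select(dark, resid = "HEM"))),
    class = "two_state_system")
}

#' @export
print.two_state_system <- function(x, ...) {
  cat(sprintf(
    "<two_state_system> %d atoms; delta_Fe %.2f A, CO shift (%.1f, %.1f, %.1f) A\n",
    nrow(x$dark$atoms), x$deltas$delta_fe, x$deltas$co_shift[1],
    x$deltas$co_shift[2], x$deltas$co_shift[3]))
  invisible(x)
}

#' Bound and docked CO carbon positions of a system
#'
#' @param system A `two_state_system`.
#' @return List with `dark` (bound CO carbon) and `excited` (docking-site
#'   CO carbon) Cartesian positions.
#' @export
co_sites <- function(system) {
  sel <- atom_select(system$dark, name = "C", resid = "CMO")
  list(dark = as.numeric(coords(system$dark)[sel, ]),
       excited = as.numeric(coords(system$excited)[sel, ]))
}

#' Ground-truth kinetics schedule for the photolysis reaction
#'
#' Time constants and amplitudes that the generator imposes on the excited
#' state: the photolysis event itself is complete at t = 0 (the true
#' excited-state fraction is `f_plateau` at all delays); what evolves is the
#' *apparent* CO* occupancy (docking-site localization with time constant
#' `tau_occ`), the iron out-of-plane displacement (instantaneous fraction
#' `w_fast`, slow phase `tau_slow`), and a damped heme-doming oscillation
#' (amplitude `dome_amp`, damping `tau_dome`, period `period`).
#'
#' @param f_plateau True photolysed fraction (default 0.8, the saturation
#'   level seen in high-fluence power titrations).
#' @param tau_occ Apparent-occupancy rise time constant in fs (default 400,
#'   in the 350-450 fs range reported for heme-CO photolysis).
#' @param w_fast Instantaneous fraction of the iron out-of-plane motion.
#' @param tau_slow Slow-phase time constant of the out-of-plane motion and
#'   proximal-helix recoil in fs (default 400).
#' @param dome_amp Doming oscillation amplitude in Angstrom (mode-projected).
#' @param tau_dome Doming damping time constant in fs.
#' @param period Doming oscillation period in fs (default 300, the coherent
#'   low-fluence oscillation period).
#' @param jitter_sd Pump-probe timing jitter SD in fs (default 100).
#' @return Object of class `ground_truth_schedule` (a validated list).
#' @export
ground_truth_schedule <- function(f_plateau = 0.8, tau_occ = 400,
                                  w_fast = 0.4, tau_slow = 400,
                                  dome_amp = 0.06, tau_dome = 400,
                                  period = 300, jitter_sd = 100) {
  s <- list(f_plateau = f_plateau, tau_occ = tau_occ, w_fast = w_fast,
            tau_slow = tau_slow, dome_amp = dome_amp, tau_dome = tau_dome,
            period = period, jitter_sd = jitter_sd)
  if (any(c(s$tau_occ, s$tau_slow, s$tau_dome, s$period) <= 0)) {
    stop("all time constants and the period must be > 0")
  }
  if (s$f_plateau < 0 || s$f_plateau > 1) stop("f_plateau must lie in [0, 1]")
  if (s$w_fast < 0 || s$w_fast > 1) stop("w_fast must lie in [0, 1]")
  if (s$jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(s, class = "ground_truth_schedule")
}

#' Apparent CO* occupancy prescribed by a schedule
#'
#' The generator parameterizes the observable directly: the apparent
#' (peak-ratio) CO* occupancy follows
#' f_app(t) = f_plateau * (1 - exp(-t / tau_occ)),
#' the exponential-rise form in which experimental apparent-occupancy time
#' constants are reported.
#'
#' @param schedule A `ground_truth_schedule`.
#' @param t Delay in fs (vectorized).
#' @return Apparent occupancy in \[0, f_plateau\].
#' @export
apparent_occupancy <- function(schedule, t) {
  schedule$f_plateau * (1 - exp(-pmax(t, 0) / schedule$tau_occ))
}

# Docking-site localized fraction of the photodissociated CO that produces
# the scheduled apparent occupancy under the peak-ratio estimator
# f = rho_CO* / (rho_dark + rho_CO*) with dark CO density (1 - f_plateau):
# solve f_p u / ((1 - f_p) + f_p u) = f_app for u.
localized_fraction <- function(schedule, t) {
  fp <- schedule$f_plateau
  if (fp <= 0) return(rep(0, length(t)))
  fa <- apparent_occupancy(schedule, t)
  pmin(1, pmax(0, (1 - fp) * fa / (fp * (1 - fa))))
}

#' Out-of-plane doming mode vector of the heme core
#'
#' Unit-Euclidean-norm out-of-plane displacement pattern over the 25 core
#' atoms (Fe + 4 N + 20 C): iron and inner ring (pyrrole N, alpha C) move
#' toward the proximal side while the ring periphery (beta and meso C)
#' moves oppositely -- an A2u-like doming deformation. The normalization is
#' a convention; it rescales reported doming amplitudes uniformly.
#'
#' @param model An `atomic_model` containing the heme core (resid "HEM").
#' @return Named numeric vector of per-atom mode weights (unit norm) over
#'   the core atoms, in core-atom order.
#' @export
doming_mode <- function(model) {
  core <- model$atoms[atom_select(model, resid = "HEM"), ]
  w <- numeric(nrow(core))
  w[core$name == "FE"] <- 2
  w[grepl("^N", core$name)] <- 1
  w[grepl("^CA", core$name)] <- 0.4
  w[grepl("^CM", core$name)] <- -0.6
  w[grepl("^CB", core$name)] <- -1
  w <- w / sqrt(sum(w^2))
  names(w) <- core$name
  w
}

#' Interpolate the excited-state model at a pump-probe delay
#'
#' Applies the schedule to the two-state system: the iron out-of-plane
#' displacement follows w_fast + (1 - w_fast) * (1 - exp(-t/tau_slow)), the
#' proximal-helix recoil follows (1 - exp(-t/tau_slow)), a damped cosine
#' dome_amp * exp(-t/tau_dome) * cos(2 pi t / period) displaces the heme
#' core along the doming mode, the CO sits in its docking site from t = 0,
#' and the CO* occupancy equals the docking-site localized fraction (the
#' photodissociated CO is initially delocalized and "narrows" into the
#' site, which is what makes the apparent occupancy rise while the true
#' photolysed fraction stays at f_plateau).
#'
#' @param system A `two_state_system`.
#' @param schedule A `ground_truth_schedule`.
#' @param t Delay in fs (>= 0).
#' @return List with `model` (the excited-state [atomic_model()] at t) and
#'   `true_fraction` (= f_plateau).
#' @export
interpolate_state <- function(system, schedule, t) {
  stopifnot(inherits(system, "two_state_system"),
            inherits(schedule, "ground_truth_schedule"), t >= 0)
  dark <- system$dark
  exc <- system$excited
  g_slow <- 1 - exp(-t / schedule$tau_slow)
  g_oop <- schedule$w_fast + (1 - schedule$w_fast) * g_slow
  dome <- schedule$dome_amp * exp(-t / schedule$tau_dome) *
    cos(2 * pi * t / schedule$period)

  xyz_d <- coords(dark)
  xyz_e <- coords(exc)
  xyz <- xyz_d
  xyz[system$sel$fe, ] <- xyz_d[system$sel$fe, ] +
    g_oop * (xyz_e[system$sel$fe, ] - xyz_d[system$sel$fe, ])
  xyz[system$sel$proximal, ] <- xyz_d[system$sel$proximal, ] +
    g_slow * (xyz_e[system$sel$proximal, , drop = FALSE] -
                xyz_d[system$sel$proximal, , drop = FALSE])
  xyz[system$sel$co, ] <- xyz_e[system$sel$co, , drop = FALSE]
  # doming along the heme normal toward the proximal side (-z in the
  # generator frame), patterned by the unit mode vector
  mode <- doming_mode(dark)
  core_idx <- which(system$sel$core)
  xyz[core_idx, 3] <- xyz[core_idx, 3] - dome * mode

  model <- set_coords(dark, xyz)
  model$atoms$occ[system$sel$co] <- localized_fraction(schedule, t)
  list(model = model, true_fraction = schedule$f_plateau)
}

#' Per-frame noise configuration for serial diffraction simulation
#'
#' @param frac_obs Fraction of reflections observed per frame.
#' @param scale_sdlog SD of the per-frame log-normal scale factor.
#' @param partiality Range (lo, hi) of the uniform per-observation
#'   partiality.
#' @param sigma_rel Relative Gaussian intensity noise (fraction of the true
#'   partial intensity).
#' @param sigma_abs Absolute Gaussian intensity noise (intensity units).
#' @return List of class `frame_noise`.
#' @export
frame_noise <- function(frac_obs = 0.3, scale_sdlog = 0.2,
                        partiality = c(0.3, 1), sigma_rel = 0.1,
                        sigma_abs = 0) {
  stopifnot(frac_obs > 0, frac_obs <= 1, scale_sdlog >= 0,
            length(partiality) == 2, partiality[1] <= partiality[2],
            partiality[1] >= 0, sigma_rel >= 0, sigma_abs >= 0)
  structure(list(frac_obs = frac_obs, scale_sdlog = scale_sdlog,
                 partiality = partiality, sigma_rel = sigma_rel,
                 sigma_abs = sigma_abs), class = "frame_noise")
}

#' Zero-noise frame configuration (every reflection, unit scale/partiality)
#' @return A `frame_noise` with no stochastic degradation.
#' @export
frame_noise_none <- function() {
  frame_noise(frac_obs = 1, scale_sdlog = 0, partiality = c(1, 1),
              sigma_rel = 0, sigma_abs = 0)
}

#' Simulate per-frame serial diffraction snapshots
#'
#' Each frame observes a random subset of reflections with
#' I_obs = s_j * p_jh * F^2 + eps: s_j a log-normal frame scale, p_jh a
#' uniform partiality, eps Gaussian. Each frame carries an actual delay
#' drawn as nominal + N(0, jitter_sd), emulating timing-tool readout.
#'
#' @param amplitudes A `reflection_set` (the mixture amplitudes; phases,
#'   if present, are ignored).
#' @param n_frames Number of frames (>= 1).
#' @param noise A [frame_noise()] configuration.
#' @param nominal_delay Nominal pump-probe delay in fs: a scalar or a
#'   length-`n_frames` vector.
#' @param jitter_sd Timing jitter SD in fs.
#' @param seed Integer seed; the simulation is reproducible under it. NULL
#'   continues the current RNG stream (used internally by the replay
#'   orchestrator, which seeds once).
#' @return Object of class `frame_set`: `hkl`, `cell`, `frames` (data.frame
#'   frame, delay), `obs` (data.frame frame, ridx, i, sigma), `meta`.
#' @export
simulate_frames <- function(amplitudes, n_frames, noise = frame_noise(),
                            nominal_delay = 0, jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(amplitudes, "reflection_set"), n_frames >= 1,
            inherits(noise, "frame_noise"))
  n_refl <- nrow(amplitudes$hkl)
  if (n_refl == 0) stop("empty reflection input")
  if (!is.null(seed)) set.seed(seed)
  nominal <- rep_len(nominal_delay, n_frames)
  delays <- nominal + if (jitter_sd > 0) stats::rnorm(n_frames, 0, jitter_sd)
                      else 0
  i2 <- amplitudes$f^2
  sig_floor <- 1e-8 * max(stats::median(i2), 1)

  ridx_l <- vector("list", n_frames)
  i_l <- vector("list", n_frames)
  sig_l <- vector("list", n_frames)
  for (j in seq_len(n_frames)) {
    if (noise$frac_obs >= 1) {
      ridx <- seq_len(n_refl)
    } else {
      ridx <- which(stats::runif(n_refl) < noise$frac_obs)
      if (length(ridx) == 0) ridx <- sample.int(n_refl, 1)
    }
    s_j <- if (noise$scale_sdlog > 0)
      stats::rlnorm(1, meanlog = -noise$scale_sdlog^2 / 2,
                    sdlog = noise$scale_sdlog) else 1
    p <- if (noise$partiality[1] < noise$partiality[2])
      stats::runif(length(ridx), noise$partiality[1], noise$partiality[2])
    else noise$partiality[1]
    itrue <- s_j * p * i2[ridx]
    sd <- noise$sigma_rel * abs(itrue) + noise$sigma_abs
    iobs <- itrue + if (any(sd > 0)) stats::rnorm(length(ridx), 0, sd) else 0
    ridx_l[[j]] <- ridx
    i_l[[j]] <- iobs
    sig_l[[j]] <- sd + sig_floor
  }
  counts <- lengths(ridx_l)
  obs <- data.frame(frame = rep.int(seq_len(n_frames), counts),
                    ridx = unlist(ridx_l), i = unlist(i_l),
                    sigma = unlist(sig_l))
  structure(list(hkl = amplitudes$hkl, cell = amplitudes$cell,
                 d_min = amplitudes$d_min, d_max = amplitudes$d_max,
                 frames = data.frame(frame = seq_len(n_frames),
                                     delay = delays),
                 obs = obs,
                 meta = list(nominal_delay = nominal_delay,
                             jitter_sd = jitter_sd)),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frames, %d reflections, %d observations\n",
              nrow(x$frames), nrow(x$hkl), nrow(x$obs)))
  invisible(x)
}

#' Concatenate frame sets (re-numbering frames)
#'
#' @param ... `frame_set` objects sharing one reflection list.
#' @return A single `frame_set`.
#' @export
bind_frames <- function(...) {
  fs <- list(...)
  if (length(fs) == 1 && is.list(fs[[1]]) && !inherits(fs[[1]], "frame_set")) {
    fs <- fs[[1]]
  }
  stopifnot(length(fs) >= 1, all(vapply(fs, inherits, logical(1), "frame_set")))
  base <- fs[[1]]
  offset <- 0L
  frames <- list()
  obs <- list()
  for (f in fs) {
    if (!identical(dim(f$hkl), dim(base$hkl))) {
      stop("frame sets index different reflection lists")
    }
    fr <- f$frames
    ob <- f$obs
    fr$frame <- fr$frame + offset
    ob$frame <- ob$frame + offset
    offset <- offset + nrow(f$frames)
    frames[[length(frames) + 1]] <- fr
    obs[[length(obs) + 1]] <- ob
  }
  structure(list(hkl = base$hkl, cell = base$cell, d_min = base$d_min,
                 d_max = base$d_max,
                 frames = do.call(rbind, frames), obs = do.call(rbind, obs),
                 meta = list(nominal_delay = NA, jitter_sd = base$meta$jitter_sd)),
            class = "frame_set")
}

# data.frame constructor skipping rowname bookkeeping (columns must be
# equal-length vectors)
quick_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = c(NA_integer_, -length(cols[[1]])))
}

#' Subset a frame set by frame ids (with replacement allowed)
#'
#' Selected frames are re-instanced with new consecutive ids, so a frame
#' sampled twice contributes twice -- the operation behind bootstrap
#' resampling of serial datasets.
#'
#' @param fs A `frame_set`.
#' @param frame_ids Vector of frame ids (duplicates allowed).
#' @return A `frame_set`.
#' @export
subset_frames <- function(fs, frame_ids) {
  stopifnot(inherits(fs, "frame_set"))
  ord <- seq_len(nrow(fs$obs))
  if (is.unsorted(fs$obs$frame)) ord <- order(fs$obs$frame)
  # contiguous row ranges per frame id (observations are frame-sorted)
  counts_all <- tabulate(fs$obs$frame[ord], nbins = max(fs$frames$frame))
  starts_all <- cumsum(c(1L, counts_all[-length(counts_all)]))
  counts <- counts_all[frame_ids]
  rows <- ord[sequence(counts, from = starts_all[frame_ids])]
  # column-wise subset (row-subsetting a data.frame with duplicated rows
  # triggers make.unique on rownames, which dominates bootstrap runtime)
  obs <- quick_df(list(frame = rep.int(seq_along(frame_ids), counts),
                       ridx = fs$obs$ridx[rows], i = fs$obs$i[rows],
                       sigma = fs$obs$sigma[rows]))
  frames <- quick_df(list(frame = seq_along(frame_ids),
                          delay = fs$frames$delay[
                            match(frame_ids, fs$frames$frame)]))
  structure(list(hkl = fs$hkl, cell = fs$cell, d_min = fs$d_min,
                 d_max = fs$d_max, frames = frames, obs = obs,
                 meta = fs$meta), class = "frame_set")
}
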