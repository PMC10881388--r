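#' Occupancy from difference-density peak heights
#'
#' The peak-ratio estimator: f = rho_CO* / (rho_dark + rho_CO*), with
#' rho_CO* and rho_dark the omit-map peak heights at the docking-site and
#' bound-CO positions respectively. Negative peak heights are clamped to
#' zero before the ratio (noise-induced negative density has no occupancy
#' interpretation). The estimate is invariant to any common positive
#' rescaling of the map.
#'
#' @param map A `density_grid` omit map computed from a model lacking every
#'   CO copy (see [omit_map()]).
#' @param dark_site Cartesian position of the bound (dark-state) CO.
#' @param excited_site Cartesian position of the docking-site CO*.
#' @param search_radius Local-maximum search radius passed to
#'   [peak_height()] (default 0.8 Angstrom).
#' @return Object of class `occupancy_estimate`: fields `f`, `method`
#'   ("peak_ratio"), `rho_co_star`, `rho_dark`.
#' @export
occupancy_peak_ratio <- function(map, dark_site, excited_site,
                                 search_radius = 0.8) {
  stopifnot(inherits(map, "density_grid"))
  rho_star <- max(0, peak_height(map, excited_site, search_radius))
  rho_dark <- max(0, peak_height(map, dark_site, search_radius))
  if (rho_star + rho_dark <= 0) {
    stop("both CO peaks are non-positive: occupancy undefined")
  }
  structure(list(f = rho_star / (rho_dark + rho_star), method = "peak_ratio",
                 rho_co_star = rho_star, rho_dark = rho_dark),
            class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf("<occupancy_estimate> f = %.3f (%s)\n", x$f, x$method))
  invisible(x)
}

#' Occupancy by multicopy titration with zero-crossing
#'
#' For each trial occupancy f, builds the complex two-state mixture Fc,
#' computes the (Fo - Fc) residual map, and records the residual density at
#' the dark-state CO position. A line is fitted through residual-vs-f by
#' unweighted least squares; the occupancy at which it crosses zero (no
#' residual density left at the bound-CO site) is the estimate. Coordinates
#' of both states are held fixed (no refinement inside the titration).
#'
#' @param f_obs Observed amplitudes (`reflection_set`; phases ignored).
#' @param system A `two_state_system` providing dark and excited models.
#' @param trial_fs Strictly increasing trial occupancies in (0, 1), at
#'   least 3 (default seq(0.05, 0.95, 0.05)).
#' @param site "C" evaluates the residual at the dark CO carbon (default);
#'   "CO" averages over the carbon and oxygen positions.
#' @param excited_model Optional `atomic_model` overriding
#'   `system$excited` (e.g. a time-interpolated state).
#' @param scale Wilson-scale Fo onto each mixture Fc (default TRUE).
#' @return An `occupancy_estimate` with method "titration", the titration
#'   `samples` (trial_f, residual) and fitted `line` (intercept, slope).
#' @export
occupancy_titration <- function(f_obs, system,
                                trial_fs = seq(0.05, 0.95, by = 0.05),
                                site = c("C", "CO"), excited_model = NULL,
                                scale = TRUE) {
  stopifnot(inherits(f_obs, "reflection_set"),
            inherits(system, "two_state_system"))
  site <- match.arg(site)
  if (length(trial_fs) < 3 || any(diff(trial_fs) <= 0) ||
      any(trial_fs <= 0 | trial_fs >= 1)) {
    stop("trial_fs must be >= 3 strictly increasing values in (0, 1)")
  }
  excited <- if (is.null(excited_model)) system$excited else excited_model
  d_min <- f_obs$d_min
  fc_dark <- structure_factors(system$dark, d_min, f_obs$d_max)
  fc_exc <- structure_factors(excited, d_min, f_obs$d_max)
  ci <- common_indices(fc_dark, f_obs)
  fc_dark <- subset_reflections(fc_dark, ci$i1)
  fo <- subset_reflections(f_obs, ci$i2)
  fc_exc <- subset_reflections(fc_exc, match_indices(fc_dark, fc_exc))

  co_c <- as.numeric(coords(system$dark)[
    atom_select(system$dark, name = "C", resid = "CMO"), ])
  co_o <- as.numeric(coords(system$dark)[
    atom_select(system$dark, name = "O", resid = "CMO"), ])

  residuals <- vapply(trial_fs, function(f) {
    fc_mix <- mix_states(fc_dark, fc_exc, f)
    fo_s <- if (scale) scale_light_to_dark(fo, fc_mix)$scaled else fo
    rmap <- synthesize_map(difference_coefficients(fo_s, fc_mix),
                           provenance = "difference")
    val <- peak_height(rmap, co_c, search_radius = 0)
    if (site == "CO") val <- (val + peak_height(rmap, co_o, 0)) / 2
    val
  }, numeric(1))

  fit <- titration_root(trial_fs, residuals)
  if (fit$root < -0.1 || fit$root > 1.1) {
    warning("titration zero-crossing at ", signif(fit$root, 3),
            " lies well outside [0, 1]; clipping")
  }
  structure(list(f = min(1, max(0, fit$root)), method = "titration",
                 samples = data.frame(trial_f = trial_fs,
                                      residual = residuals),
                 line = fit$line),
            class = "occupancy_estimate")
}

#' Zero crossing of a titration residual line
#'
#' Fits residual-vs-trial-occupancy by unweighted least squares and returns
#' the root. When enough samples lie near the first crossing, the line is
#' refit locally (within +/- 0.2 of the global root) to suppress the bias
#' a mild curvature of the residual curve puts on the global fit.
#'
#' @param trial_f Trial occupancies (>= 2).
#' @param residual Residual densities at the bound-CO site.
#' @param local_halfwidth Refinement window half-width (default 0.2; 0
#'   disables refinement).
#' @return List with `root` and `line` (intercept, slope of the fit used).
#' @export
titration_root <- function(trial_f, residual, local_halfwidth = 0.2) {
  stopifnot(length(trial_f) == length(residual), length(trial_f) >= 2)
  if (all(abs(residual) < 1e-12 * max(1, max(abs(residual))))) {
    stop("titration residuals are identically zero: occupancy unidentifiable")
  }
  fit_line <- function(tf, rs) {
    beta <- stats::coef(stats::lm(rs ~ tf))
    if (!is.finite(beta[2]) ||
        abs(beta[2]) < 1e-10 * max(abs(residual))) {
      stop("titration line has (near-)zero slope: occupancy unidentifiable")
    }
    list(root = unname(-beta[1] / beta[2]),
         line = c(intercept = unname(beta[1]), slope = unname(beta[2])))
  }
  glob <- fit_line(trial_f, residual)
  if (local_halfwidth > 0) {
    near <- abs(trial_f - glob$root) <= local_halfwidth
    if (sum(near) >= 3) {
      loc <- tryCatch(fit_line(trial_f[near], residual[near]),
                      error = function(e) NULL)
      if (!is.null(loc)) return(loc)
    }
  }
  glob
}

#' Extrapolated structure factors toward the pure excited state
#'
#' Amplitude mode (the experimental situation, phases unknown):
#' F_ext = F_dark + (1/f) (F_light - F_dark) on amplitudes; negative
#' extrapolated values are clamped to zero and counted. Complex mode (the
#' exact algebraic inverse of [mix_states()], available when model phases
#' are at hand) extrapolates the complex structure factors and is the
#' oracle against which the amplitude approximation is quantified.
#'
#' @param f_light,f_dark `reflection_set`s on a common scale and index set.
#' @param f Excited-state fraction in (0, 1].
#' @param mode "amplitude" (default) or "complex" (requires phases on both
#'   sets).
#' @return A `reflection_set`; attribute `n_negative` counts clamped
#'   amplitudes (amplitude mode).
#' @export
extrapolate_structure_factors <- function(f_light, f_dark, f,
                                          mode = c("amplitude", "complex")) {
  mode <- match.arg(mode)
  if (f <= 0 || f > 1) stop("extrapolation requires 0 < f <= 1")
  idx <- match_indices(f_dark, f_light)
  if (mode == "complex") {
    fc <- as_complex(f_dark) + (as_complex(f_light)[idx] - as_complex(f_dark)) / f
    out <- reflection_set(f_dark$hkl, Mod(fc), f_dark$cell,
                          phase = Arg(fc) * 180 / pi,
                          d_min = f_dark$d_min, d_max = f_dark$d_max)
    attr(out, "n_negative") <- 0L
    return(out)
  }
  fe <- f_dark$f + (f_light$f[idx] - f_dark$f) / f
  n_neg <- sum(fe < 0)
  out <- reflection_set(f_dark$hkl, pmax(fe, 0), f_dark$cell,
                        d_min = f_dark$d_min, d_max = f_dark$d_max)
  attr(out, "n_negative") <- n_neg
  out
}

#' Occupancy by extrapolation consistency
#'
#' For each trial f, extrapolates the observed amplitudes toward the pure
#' excited state (amplitude mode), synthesizes the map of
#' (F_ext - Fc_excited-without-CO*) with model phases, and records the
#' residual bound-CO density; at the correct f no bound-CO density should
#' survive extrapolation. The zero crossing of the fitted line is the
#' estimate. Noise in F_light is amplified by 1/f, which is what makes
#' this comparator noisier than the titration.
#'
#' @inheritParams occupancy_titration
#' @param f_dark_obs Dark observed (or calculated) amplitudes on the same
#'   scale as `f_obs`.
#' @return An `occupancy_estimate` with method "extrapolation".
#' @export
occupancy_extrapolation <- function(f_obs, f_dark_obs, system,
                                    trial_fs = seq(0.1, 0.95, by = 0.05),
                                    excited_model = NULL) {
  excited <- if (is.null(excited_model)) system$excited else excited_model
  d_min <- f_obs$d_min
  fc_dark <- structure_factors(system$dark, d_min, f_obs$d_max)
  ci <- common_indices(fc_dark, f_obs)
  fc_dark <- subset_reflections(fc_dark, ci$i1)
  fo <- subset_reflections(f_obs, ci$i2)
  fd <- subset_reflections(f_dark_obs, match_indices(fc_dark, f_dark_obs))
  co_c <- as.numeric(coords(system$dark)[
    atom_select(system$dark, name = "C", resid = "CMO"), ])
  residuals <- vapply(trial_fs, function(f) {
    fe <- extrapolate_structure_factors(fo, fd, f)
    coeffs <- reflection_set(fc_dark$hkl, fe$f, fc_dark$cell,
                             phase = fc_dark$phase,
                             d_min = fc_dark$d_min, d_max = fc_dark$d_max)
    dmap <- synthesize_map(difference_coefficients(coeffs, fc_dark),
                           provenance = "difference")
    peak_height(dmap, co_c, search_radius = 0)
  }, numeric(1))
  fit <- titration_root(trial_fs, residuals)
  structure(list(f = min(1, max(0, fit$root)), method = "extrapolation",
                 samples = data.frame(trial_f = trial_fs,
                                      residual = residuals)),
            class = "occupancy_estimate")
}

#' Omit model for the peak-ratio estimator
#'
#' The two-state mixture model with every CO copy removed, standing in for
#' the paper-style "dark model without CO refined against light data": the
#' non-CO atoms take their ensemble-average (mixture) description, so the
#' omit difference map contains the two CO peaks and little else.
#'
#' @param system A `two_state_system`.
#' @param f Mixture fraction used for the non-CO atoms.
#' @param excited_model Optional interpolated excited state.
#' @return An `atomic_model` holding both states' non-CO atoms at weights
#'   (1-f) and f.
#' @export
mixture_omit_model <- function(system, f, excited_model = NULL) {
  excited <- if (is.null(excited_model)) system$excited else excited_model
  keep <- !system$sel$co
  d <- system$dark$atoms[keep, ]
  e <- excited$atoms[keep, ]
  d$occ <- d$occ * (1 - f)
  e$occ <- e$occ * f
  e$atom <- e$atom + max(d$atom)
  atomic_model(rbind(d, e), system$dark$cell, wrap = FALSE)
}

#' Full mixture model (both states, all atoms)
#'
#' @inheritParams mixture_omit_model
#' @return An `atomic_model` superposing dark (weight 1-f) and excited
#'   (weight f) copies.
#' @export
mixture_model <- function(system, f, excited_model = NULL) {
  excited <- if (is.null(excited_model)) system$excited else excited_model
  d <- system$dark$atoms
  e <- excited$atoms
  d$occ <- d$occ * (1 - f)
  e$occ <- e$occ * f
  e$atom <- e$atom + max(d$atom)
  atomic_model(rbind(d, e), system$dark$cell, wrap = FALSE)
}

#' Benchmark occupancy estimators on simulated mixtures
#'
#' Full factorial simulate-then-estimate sweep over true occupancies and
#' noise levels: for each cell, mixture amplitudes are computed (exactly,
#' or degraded through frame simulation and Monte-Carlo merging when the
#' noise level is positive) and each estimator is applied. Deterministic
#' under the seed.
#'
#' @param system A `two_state_system`.
#' @param true_f Vector of true excited-state fractions in (0, 1).
#' @param noise Vector of relative intensity noise levels (0 = exact
#'   amplitudes; > 0 simulates `n_frames` partial frames at that
#'   `sigma_rel` with default scale/partiality variation and merges them).
#' @param methods Estimators to run (subset of "peak_ratio", "titration",
#'   "extrapolation").
#' @param d_min Resolution (default 1.4 Angstrom).
#' @param n_frames Frames per simulated dataset (default 400).
#' @param trial_fs Trial grid for the titration/extrapolation estimators.
#' @param seed Integer seed.
#' @return data.frame: true_f, noise, method, estimate, error; attribute
#'   "summary" holds per-method bias and RMSE.
#' @export
benchmark_estimators <- function(system, true_f = seq(0.1, 0.9, by = 0.1),
                                 noise = c(0, 0.1),
                                 methods = c("peak_ratio", "titration"),
                                 d_min = 1.4, n_frames = 400,
                                 trial_fs = seq(0.05, 0.95, by = 0.05),
                                 seed = 1) {
  stopifnot(length(true_f) > 0, length(noise) > 0)
  methods <- match.arg(methods, c("peak_ratio", "titration", "extrapolation"),
                       several.ok = TRUE)
  set.seed(seed)
  fc_dark <- structure_factors(system$dark, d_min)
  fc_exc <- structure_factors(system$excited, d_min)
  sites <- co_sites(system)
  rows <- list()
  for (nz in noise) {
    for (f in true_f) {
      f_mix <- mix_states(fc_dark, fc_exc, f)
      if (nz > 0) {
        fs <- simulate_frames(f_mix, n_frames,
                              frame_noise(sigma_rel = nz), seed = NULL)
        f_obs <- merge_frames(fs)
      } else {
        f_obs <- reflection_set(f_mix$hkl, f_mix$f, f_mix$cell,
                                d_min = f_mix$d_min, d_max = f_mix$d_max)
      }
      for (m in methods) {
        est <- switch(m,
          peak_ratio = {
            omit <- omit_map(f_obs, mixture_omit_model(system, f),
                             scale = nz > 0)
            occupancy_peak_ratio(omit, sites$dark, sites$excited)$f
          },
          titration = occupancy_titration(f_obs, system, trial_fs,
                                          scale = nz > 0)$f,
          extrapolation = {
            fd_obs <- reflection_set(fc_dark$hkl, fc_dark$f, fc_dark$cell,
                                     d_min = fc_dark$d_min,
                                     d_max = fc_dark$d_max)
            occupancy_extrapolation(f_obs, fd_obs, system,
                                    trial_fs = trial_fs[trial_fs >= 0.1])$f
          })
        rows[[length(rows) + 1]] <- data.frame(
          true_f = f, noise = nz, method = m, estimate = est,
          error = est - f)
      }
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out, list(out$method, out$noise)),
    function(g) data.frame(method = g$method[1], noise = g$noise[1],
                           bias = mean(g$error),
                           rmse = sqrt(mean(g$error^2)))))
  rownames(agg) <- NULL
  attr(out, "summary") <- agg
  out
}
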