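# peak-ratio occupancy straight from observed amplitudes and a precomputed
# omit-model Fc (used per bootstrap replicate; avoids recomputing Fc)
peak_ratio_from_fobs <- function(f_obs, fc_omit, dark_site, excited_site,
                                 scale = TRUE) {
  ci <- common_indices(fc_omit, f_obs)
  fc <- subset_reflections(fc_omit, ci$i1)
  fo <- subset_reflections(f_obs, ci$i2)
  if (scale) fo <- scale_light_to_dark(fo, fc)$scaled
  m <- synthesize_map(difference_coefficients(fo, fc), provenance = "omit")
  occupancy_peak_ratio(m, dark_site, excited_site)$f
}

#' End-to-end synthetic replay of the pump-probe analysis
#'
#' Runs the whole pipeline on generated data: build the two-state system
#' and schedule, simulate noisy partial frames at each nominal delay with
#' timing jitter, pool and sort the frames, cut sliding-window delay bins,
#' Monte-Carlo merge each bin, estimate the apparent CO* occupancy per bin
#' from omit-map peak ratios (with frame-bootstrap error bars), titrate the
#' final bin for the photolysed fraction, evaluate the structural metric
#' curves, and fit the kinetics (exponential occupancy and iron
#' out-of-plane rises; damped-cosine doming oscillation after detrending).
#' Fully deterministic under `config$seed`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @param verbose Log each stage with input/output sizes (default FALSE).
#' @return Object of class `replay_report`: `bins` (per-bin table),
#'   `metrics` (metric curves), `fits` (kinetics_fit objects), `summary`
#'   (recovered vs scheduled parameters), `config`.
#' @export
replay <- function(config = run_config(), out_dir = NULL, verbose = FALSE) {
  viol <- validate_config(config)
  if (length(viol) > 0) {
    stop("invalid config: ", paste(viol, collapse = "; "))
  }
  log_stage <- function(...) if (verbose) message("[replay] ", sprintf(...))
  set.seed(config$seed)
  system <- do.call(build_two_state_system, config$system)
  schedule <- do.call(ground_truth_schedule, config$schedule)
  noise <- do.call(frame_noise, config$noise)
  sites <- co_sites(system)
  d_min <- config$d_min

  log_stage("dark structure factors at d_min %.2f A", d_min)
  fc_dark <- structure_factors(system$dark, d_min)

  # actual (timing-tool) delays: nominal + Gaussian jitter; the diffracting
  # structure follows the actual delay, discretized into state groups
  n_total <- config$n_frames_per_delay * length(config$delays)
  actual <- rep(config$delays, each = config$n_frames_per_delay) +
    stats::rnorm(n_total, 0, schedule$jitter_sd)
  ord <- order(actual)
  n_grp <- min(config$n_state_groups, n_total)
  grp <- split(ord, ceiling(seq_along(ord) / (n_total / n_grp)))
  fs_list <- vector("list", length(grp))
  for (i in seq_along(grp)) {
    idx <- grp[[i]]
    t_rep <- max(mean(actual[idx]), 0)
    st <- interpolate_state(system, schedule, t_rep)
    fc_exc <- structure_factors(st$model, d_min)
    f_mix <- mix_states(fc_dark, fc_exc, st$true_fraction)
    fs_list[[i]] <- simulate_frames(f_mix, length(idx), noise,
                                    nominal_delay = actual[idx],
                                    jitter_sd = 0)
    log_stage("state group %2d (<t> = %6.0f fs): %d frames", i, t_rep,
              length(idx))
  }
  all_frames <- bind_frames(fs_list)
  bins <- bin_by_delay(all_frames, config$window, config$step)
  log_stage("%d frames pooled into %d bins (W=%d, S=%d)",
            nrow(all_frames$frames), length(bins), config$window, config$step)

  # ground-truth metric curves, sampled finely then bin-averaged over the
  # actual frame delays (so binning smears the curves as it does the data)
  t_hi <- max(all_frames$frames$delay) * 1.05
  t_grid <- seq(0, max(t_hi, 1), length.out = 400)
  truth <- do.call(rbind, lapply(t_grid, function(t) {
    m <- interpolate_state(system, schedule, t)$model
    metric_record(m, system$dark, label = t)
  }))

  bin_rows <- vector("list", length(bins))
  for (k in seq_along(bins)) {
    bin <- bins[[k]]
    t_bin <- attr(bin, "mean_delay")
    merged <- merge_frames(bin)
    st_bin <- interpolate_state(system, schedule, max(t_bin, 0))
    omit_model <- mixture_omit_model(system, schedule$f_plateau,
                                     st_bin$model)
    fc_omit <- structure_factors(omit_model, d_min)
    f_app <- peak_ratio_from_fobs(merged, fc_omit, sites$dark, sites$excited)
    f_app_sd <- NA_real_
    if (config$bootstrap_b >= 2) {
      bs <- bootstrap_metric(bin, function(fsub) {
        peak_ratio_from_fobs(merge_frames(fsub), fc_omit,
                             sites$dark, sites$excited)
      }, b = config$bootstrap_b)
      f_app_sd <- bs$sd
    }
    tt <- pmax(bin$frames$delay, 0)
    bin_rows[[k]] <- data.frame(
      bin = k, mean_delay = t_bin, sd_delay = attr(bin, "sd_delay"),
      n_frames = nrow(bin$frames), n_merged = nrow(merged$hkl),
      f_apparent = f_app, f_apparent_sd = f_app_sd,
      oop_fe = mean(stats::approx(truth$label, truth$oop_fe, xout = tt,
                                  rule = 2)$y),
      fe_his = mean(stats::approx(truth$label, truth$fe_his, xout = tt,
                                  rule = 2)$y),
      doming = mean(stats::approx(truth$label, truth$doming, xout = tt,
                                  rule = 2)$y))
    log_stage("bin %2d: <t> = %6.0f fs (SD %4.0f), f_app = %.3f", k, t_bin,
              attr(bin, "sd_delay"), f_app)
  }
  bins_df <- do.call(rbind, bin_rows)

  # photolysed fraction from multicopy titration of the last (plateau) bin
  last_bin <- bins[[length(bins)]]
  merged_last <- merge_frames(last_bin)
  st_last <- interpolate_state(system, schedule,
                               attr(last_bin, "mean_delay"))
  f_titration <- tryCatch(
    occupancy_titration(merged_last, system, config$trial_fs,
                        excited_model = st_last$model)$f,
    error = function(e) NA_real_)

  # kinetics fits on the per-bin curves
  fit_occ <- fit_exponential_rise(bins_df$mean_delay, bins_df$f_apparent,
                                  sigma_y = if (all(is.finite(bins_df$f_apparent_sd)) &&
                                                all(bins_df$f_apparent_sd > 0))
                                    bins_df$f_apparent_sd else NULL)
  fit_oop <- fit_exponential_rise(bins_df$mean_delay, bins_df$oop_fe)
  # doming: remove the slow rise carried in by the iron/core displacement,
  # then fit the damped oscillation on the residual
  dome_trend <- fit_exponential_rise(bins_df$mean_delay, bins_df$doming)
  dome_resid <- bins_df$doming -
    (dome_trend$par["y0"] + dome_trend$par["a"] *
       (1 - exp(-pmax(bins_df$mean_delay - dome_trend$par["t0"], 0) /
                  dome_trend$par["tau"])))
  fit_dome <- tryCatch(
    fit_damped_cosine(bins_df$mean_delay, dome_resid,
                      period_init = schedule$period),
    error = function(e) NULL)

  summary <- list(
    f_plateau_hat = unname(fit_occ$par["y0"] + fit_occ$par["a"]),
    f_plateau_true = schedule$f_plateau,
    f_titration_last_bin = f_titration,
    tau_occ_hat = unname(fit_occ$par["tau"]),
    tau_occ_true = schedule$tau_occ,
    tau_oop_hat = unname(fit_oop$par["tau"]),
    tau_oop_true = schedule$tau_slow,
    period_doming_hat = if (is.null(fit_dome)) NA_real_
                        else unname(fit_dome$par["period"]),
    period_doming_true = schedule$period,
    n_bins = nrow(bins_df),
    seed = config$seed)

  report <- structure(list(bins = bins_df, metrics = truth,
                           fits = list(occupancy = fit_occ, oop = fit_oop,
                                       doming = fit_dome),
                           summary = summary, config = config),
                      class = "replay_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(bins_df, file.path(out_dir, "bins.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "metric_curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.replay_report <- function(x, ...) {
  s <- x$summary
  cat("<replay_report>\n")
  cat(sprintf("  bins: %d   seed: %d\n", s$n_bins, s$seed))
  cat(sprintf("  f_plateau: %.3f (true %.3f); titration (last bin): %.3f\n",
              s$f_plateau_hat, s$f_plateau_true, s$f_titration_last_bin))
  cat(sprintf("  tau_occ: %.0f fs (true %.0f)   tau_OOP: %.0f fs (true %.0f)\n",
              s$tau_occ_hat, s$tau_occ_true, s$tau_oop_hat, s$tau_oop_true))
  cat(sprintf("  doming period: %.0f fs (true %.0f)\n",
              s$period_doming_hat, s$period_doming_true))
  invisible(x)
}
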