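#' Sliding-window binning of frames by actual delay
#'
#' Sorts frames by their (timing-tool) delay and cuts index windows
#' \[0, W), \[S, S + W), ... while a full window fits, emulating the
#' moving-window scheme used to split large serial datasets into
#' overlapping time points. Consecutive bins overlap by W - S frames; the
#' overlap smears time-dependent effects, which is surfaced as the per-bin
#' delay SD.
#'
#' @param fs A `frame_set`.
#' @param window Window size W in frames (<= number of frames).
#' @param step Step S in frames (1 <= S <= W).
#' @return List of `frame_set` bins, each carrying attributes
#'   `mean_delay` and `sd_delay` (fs); also exposed via
#'   [bin_summary()].
#' @export
bin_by_delay <- function(fs, window, step) {
  stopifnot(inherits(fs, "frame_set"))
  n <- nrow(fs$frames)
  if (window > n) stop("window (", window, ") exceeds frame count (", n, ")")
  if (step < 1 || step > window) stop("step must satisfy 1 <= step <= window")
  ord <- fs$frames$frame[order(fs$frames$delay)]
  starts <- seq(1, n - window + 1, by = step)
  lapply(starts, function(s) {
    ids <- ord[s:(s + window - 1)]
    bin <- subset_frames(fs, ids)
    attr(bin, "mean_delay") <- mean(bin$frames$delay)
    attr(bin, "sd_delay") <- stats::sd(bin$frames$delay)
    bin
  })
}

#' Summary table of a list of delay bins
#'
#' @param bins List returned by [bin_by_delay()].
#' @return data.frame with bin index, n_frames, mean_delay, sd_delay.
#' @export
bin_summary <- function(bins) {
  data.frame(bin = seq_along(bins),
             n_frames = vapply(bins, function(b) nrow(b$frames), numeric(1)),
             mean_delay = vapply(bins, function(b) attr(b, "mean_delay"),
                                 numeric(1)),
             sd_delay = vapply(bins, function(b) attr(b, "sd_delay"),
                               numeric(1)))
}

#' Monte-Carlo merging of partial serial intensities
#'
#' Per reflection, the unweighted mean of I_obs over the frames observing
#' it; F = sqrt(max(mean I, 0)); sigma = SD(I)/sqrt(n) (intensity scale).
#' Reflections observed fewer than `n_min` times are dropped.
#'
#' @param fs A non-empty `frame_set` (typically one delay bin).
#' @param n_min Minimum number of observations per reflection (default 3).
#' @return A `reflection_set` of merged amplitudes (no phases).
#' @export
merge_frames <- function(fs, n_min = 3) {
  stopifnot(inherits(fs, "frame_set"))
  if (nrow(fs$obs) == 0) stop("frame set has no observations")
  g <- fs$obs$ridx
  sums <- rowsum(cbind(1, fs$obs$i, fs$obs$i^2), g)
  ridx <- as.integer(rownames(sums))
  keep <- sums[, 1] >= n_min
  if (!any(keep)) stop("no reflection observed at least n_min = ",
                       n_min, " times")
  n <- sums[keep, 1]
  imean <- sums[keep, 2] / n
  var <- pmax(sums[keep, 3] - n * imean^2, 0) / pmax(n - 1, 1)
  var[n < 2] <- 0
  ridx <- ridx[keep]
  ord <- order(ridx)
  reflection_set(fs$hkl[ridx[ord], , drop = FALSE],
                 sqrt(pmax(imean[ord], 0)), fs$cell,
                 sigma = (sqrt(var) / sqrt(n))[ord],
                 d_min = fs$d_min, d_max = fs$d_max)
}

new_kinetics_fit <- function(model, par, se, rms, flags = character(0)) {
  structure(list(model = model, par = par, se = se, rms = rms, flags = flags),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %s\n", x$model))
  print(round(rbind(estimate = x$par, sd = x$se), 5))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fit an exponential rise to a delay series
#'
#' Weighted least squares of y(t) = y0 + A (1 - exp(-(t - t0)/tau)) for
#' t >= t0 (y = y0 before t0), with a multi-start over a tau grid to avoid
#' local minima. Parameter SDs come from the covariance at the optimum.
#'
#' @param t,y Delay (fs) and response vectors (>= 4 points).
#' @param sigma_y Optional response SDs (weights 1/sigma^2).
#' @param fix_t0 Fix the onset time (default 0); set NULL to fit t0.
#' @param tau_grid Multi-start grid for tau (fs); default spans the data.
#' @return A `kinetics_fit` with parameters y0, a, t0, tau. A flat series
#'   (amplitude indistinguishable from zero) is flagged
#'   "amplitude_zero_tau_unidentifiable".
#' @export
fit_exponential_rise <- function(t, y, sigma_y = NULL, fix_t0 = 0,
                                 tau_grid = NULL) {
  stopifnot(length(t) == length(y), length(t) >= 4)
  span <- diff(range(t))
  if (span <= 0) stop("time span must be positive")
  w <- fit_weights(sigma_y, length(y))
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    # flat input: amplitude is zero and tau carries no information
    return(new_kinetics_fit("exp_rise",
                            c(y0 = mean(y), a = 0,
                              t0 = if (is.null(fix_t0)) min(t) else fix_t0,
                              tau = NA_real_),
                            c(y0 = 0, a = 0, t0 = 0, tau = NA_real_), 0,
                            "amplitude_zero_tau_unidentifiable"))
  }
  if (is.null(tau_grid)) tau_grid <- span * c(0.05, 0.15, 0.4, 1, 3)
  model_fun <- function(t, y0, a, t0, tau) {
    y0 + a * (1 - exp(-pmax(t - t0, 0) / tau))
  }
  best <- NULL
  for (tau0 in tau_grid) {
    fit <- tryCatch({
      if (is.null(fix_t0)) {
        minpack.lm::nlsLM(
          y ~ y0 + a * (1 - exp(-pmax(t - t0, 0) / tau)),
          start = list(y0 = min(y), a = diff(range(y)), t0 = min(t),
                       tau = tau0),
          lower = c(-Inf, -Inf, -Inf, span * 1e-4), weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        t0 <- fix_t0
        minpack.lm::nlsLM(
          y ~ y0 + a * (1 - exp(-pmax(t - t0, 0) / tau)),
          start = list(y0 = min(y), a = diff(range(y)), tau = tau0),
          lower = c(-Inf, -Inf, span * 1e-4), weights = w,
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("exponential-rise fit failed from all starts ",
                          "(tau grid: ", paste(signif(tau_grid, 3),
                                               collapse = ", "), ")")
  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  par <- c(y0 = unname(cf["y0"]), a = unname(cf["a"]),
           t0 = if (is.null(fix_t0)) unname(cf["t0"]) else fix_t0,
           tau = unname(cf["tau"]))
  ses <- c(y0 = unname(se["y0"]), a = unname(se["a"]),
           t0 = if (is.null(fix_t0)) unname(se["t0"]) else 0,
           tau = unname(se["tau"]))
  flags <- character(0)
  spread <- stats::sd(y)
  if (abs(par["a"]) <= 2 * max(ses["a"], 0, na.rm = TRUE) &&
      abs(par["a"]) < 0.05 * max(spread, .Machine$double.eps) ||
      spread < 1e-12 * max(abs(y), 1)) {
    flags <- "amplitude_zero_tau_unidentifiable"
  }
  rms <- sqrt(mean(stats::residuals(best$fit)^2))
  new_kinetics_fit("exp_rise", par, ses, rms, flags)
}

#' Fit an exponentially damped cosine to a delay series
#'
#' y(t) = y0 + A exp(-t/tau_d) cos(2 pi t / T + phi), weighted least
#' squares. The period is initialized from the dominant component of the
#' discrete spectrum of the detrended, uniformly resampled series, with a
#' multi-start around it.
#'
#' @param t,y Delay (fs) and response (>= 6 points spanning at least one
#'   period of the initial estimate).
#' @param sigma_y Optional response SDs.
#' @param period_init Optional period initialization overriding the
#'   spectral estimate.
#' @return A `kinetics_fit` with parameters y0, a, tau_d, period, phi.
#'   Near-zero amplitude is flagged "amplitude_zero".
#' @export
fit_damped_cosine <- function(t, y, sigma_y = NULL, period_init = NULL) {
  stopifnot(length(t) == length(y), length(t) >= 6)
  span <- diff(range(t))
  if (span <= 0) stop("time span must be positive")
  w <- fit_weights(sigma_y, length(y))
  if (is.null(period_init)) period_init <- dominant_period(t, y)
  if (span < period_init) {
    stop("time span (", signif(span, 3), " fs) is below one period of the ",
         "initial estimate (", signif(period_init, 3),
         " fs): period unidentifiable")
  }
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    return(new_kinetics_fit("damped_cosine",
                            c(y0 = mean(y), a = 0, tau_d = NA_real_,
                              period = NA_real_, phi = 0),
                            c(y0 = 0, a = 0, tau_d = NA_real_,
                              period = NA_real_, phi = 0), 0,
                            "amplitude_zero"))
  }
  best <- NULL
  for (p0 in period_init * c(0.7, 1, 1.4)) {
    for (phi0 in c(0.1, 1.6, 3.0, -1.6)) {
      for (td0 in span * c(0.4, 1.5)) {
        fit <- tryCatch(
          minpack.lm::nlsLM(
            y ~ y0 + a * exp(-t / tau_d) * cos(2 * pi * t / period + phi),
            start = list(y0 = mean(y), a = stats::sd(y) * sqrt(2),
                         tau_d = td0, period = p0, phi = phi0),
            lower = c(-Inf, -Inf, span * 1e-3, span * 1e-3, -2 * pi),
            upper = c(Inf, Inf, 1e6 * span, 10 * span, 2 * pi),
            weights = w,
            control = minpack.lm::nls.lm.control(maxiter = 300)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          rss <- sum(w * stats::residuals(fit)^2)
          if (is.null(best) || rss < best$rss) {
            best <- list(fit = fit, rss = rss)
          }
        }
      }
    }
  }
  if (is.null(best)) stop("damped-cosine fit failed from all starts")
  cf <- stats::coef(best$fit)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  par <- c(y0 = unname(cf["y0"]), a = unname(cf["a"]),
           tau_d = unname(cf["tau_d"]), period = unname(cf["period"]),
           phi = unname(cf["phi"]))
  ses <- stats::setNames(unname(se[c("y0", "a", "tau_d", "period", "phi")]),
                         c("y0", "a", "tau_d", "period", "phi"))
  flags <- character(0)
  if (abs(par["a"]) < 1e-8 * max(abs(y), 1) ||
      abs(par["a"]) < 0.02 * max(stats::sd(y), .Machine$double.eps)) {
    flags <- "amplitude_zero"
  }
  rms <- sqrt(mean(stats::residuals(best$fit)^2))
  new_kinetics_fit("damped_cosine", par, ses, rms, flags)
}

fit_weights <- function(sigma_y, n) {
  if (is.null(sigma_y)) return(rep(1, n))
  stopifnot(length(sigma_y) == n, all(sigma_y > 0))
  1 / sigma_y^2
}

# dominant period of an irregularly sampled series: linear-detrend,
# resample on a uniform grid, take the peak of the discrete spectrum
dominant_period <- function(t, y) {
  ord <- order(t)
  t <- t[ord]
  y <- y[ord]
  y <- stats::residuals(stats::lm(y ~ t))
  n <- max(64, 2 * length(t))
  tu <- seq(min(t), max(t), length.out = n)
  yu <- stats::approx(t, y, xout = tu)$y
  sp <- Mod(stats::fft(yu - mean(yu)))[2:(n %/% 2)]
  k <- which.max(sp)  # k cycles over the span
  span <- diff(range(t))
  span / k
}

#' Bootstrap uncertainty of a frame-pipeline metric
#'
#' Draws B same-size resamples of the frames with replacement
#' (sample-and-replace over serial images), applies `pipeline` to each
#' resampled `frame_set`, and returns the SD over replicates. Replicates on
#' which the pipeline fails are dropped and counted; more than 20% failures
#' is an error.
#'
#' @param fs A `frame_set`.
#' @param pipeline Function `frame_set -> numeric scalar`.
#' @param b Number of bootstrap replicates (default 100).
#' @param seed Integer seed (NULL continues the current RNG stream).
#' @return List with `sd`, `replicates` (vector), `n_failed`.
#' @export
bootstrap_metric <- function(fs, pipeline, b = 100, seed = NULL) {
  stopifnot(inherits(fs, "frame_set"), b >= 2, is.function(pipeline))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(fs$frames)
  reps <- rep(NA_real_, b)
  for (r in seq_len(b)) {
    ids <- sample(fs$frames$frame, n, replace = TRUE)
    reps[r] <- tryCatch(as.numeric(pipeline(subset_frames(fs, ids))),
                        error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.2 * b) {
    stop("bootstrap pipeline failed on ", n_failed, " of ", b, " replicates")
  }
  list(sd = stats::sd(reps, na.rm = TRUE), replicates = reps,
       n_failed = n_failed)
}
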