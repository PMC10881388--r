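test_that("the peak-ratio formula and its clamping behave as defined", {
  # build a uniform map and override two positions via a constructed grid
  s <- default_system()
  sites <- co_sites(s)
  fake_map <- function(v_dark, v_star) {
    g <- structure(list(values = array(0, c(20, 20, 20)),
                        cell = s$dark$cell, dim = c(20, 20, 20),
                        provenance = "omit"), class = "density_grid")
    put <- function(g, pos, v) {
      idx <- round(pos / g$cell * g$dim) %% g$dim + 1
      g$values[idx[1], idx[2], idx[3]] <- v
      g
    }
    put(put(g, sites$dark, v_dark), sites$excited, v_star)
  }
  est <- occupancy_peak_ratio(fake_map(70, 30), sites$dark, sites$excited)
  expect_equal(est$f, 0.3, tolerance = 1e-12)
  expect_equal(occupancy_peak_ratio(fake_map(50, 0), sites$dark,
                                    sites$excited)$f, 0)
  # negative CO* density clamps to zero, not a negative occupancy
  expect_equal(occupancy_peak_ratio(fake_map(50, -20), sites$dark,
                                    sites$excited)$f, 0)
  expect_error(occupancy_peak_ratio(fake_map(-1, -1), sites$dark,
                                    sites$excited), "undefined")
})

test_that("peak-ratio occupancy is invariant to common map rescaling", {
  s <- default_system()
  sites <- co_sites(s)
  fd <- structure_factors(s$dark, fast_dmin)
  fe <- structure_factors(s$excited, fast_dmin)
  fm <- mix_states(fd, fe, 0.55)
  map <- omit_map(as_observed(fm), mixture_omit_model(s, 0.55),
                  scale = FALSE)
  est1 <- occupancy_peak_ratio(map, sites$dark, sites$excited)
  map$values <- map$values * 7.3
  map$coeffs$fc <- map$coeffs$fc * 7.3
  est2 <- occupancy_peak_ratio(map, sites$dark, sites$excited)
  expect_equal(est1$f, est2$f, tolerance = 1e-12)
  expect_equal(est2$rho_dark, 7.3 * est1$rho_dark, tolerance = 1e-12)
})

test_that("noise-free synthetic mixtures are recovered by both estimators", {
  s <- default_system()
  sites <- co_sites(s)
  fd <- structure_factors(s$dark, fast_dmin)
  fe <- structure_factors(s$excited, fast_dmin)
  f_true <- 0.6
  fobs <- as_observed(mix_states(fd, fe, f_true))
  pr <- occupancy_peak_ratio(omit_map(fobs, mixture_omit_model(s, f_true),
                                      scale = FALSE),
                             sites$dark, sites$excited)
  expect_lt(abs(pr$f - f_true), 0.05)
  ti <- occupancy_titration(fobs, s, scale = FALSE)
  expect_lt(abs(ti$f - 0.6), 0.02)
  f7 <- as_observed(mix_states(fd, fe, 0.7))
  ti7 <- occupancy_titration(f7, s, scale = FALSE)
  expect_lt(abs(ti7$f - 0.7), 0.02)
})

test_that("titration line logic: root, local refinement, degenerate cases", {
  # two samples (0.2, +0.3), (0.6, -0.1): line crosses zero at f = 0.5
  expect_equal(titration_root(c(0.2, 0.6), c(0.3, -0.1))$root, 0.5,
               tolerance = 1e-12)
  expect_error(titration_root(c(0.2, 0.4, 0.6), c(0, 0, 0)),
               "identically zero")
  expect_error(titration_root(c(0.2, 0.4, 0.6), c(0.5, 0.5, 0.5) + 0),
               "zero slope")
  expect_error(occupancy_titration(
    as_observed(structure_factors(default_system()$dark, 3.5)),
    default_system(), trial_fs = c(0.3, 0.2, 0.5)), "strictly increasing")
})

test_that("scale errors on F_obs do not move the titration root", {
  s <- default_system()
  fd <- structure_factors(s$dark, fast_dmin)
  fe <- structure_factors(s$excited, fast_dmin)
  fobs <- as_observed(mix_states(fd, fe, 0.4))
  base <- occupancy_titration(fobs, s, scale = TRUE)$f
  bumped <- reflection_set(fobs$hkl, fobs$f * 1.37, fobs$cell,
                           d_min = fobs$d_min, d_max = fobs$d_max)
  expect_equal(occupancy_titration(bumped, s, scale = TRUE)$f, base,
               tolerance = 1e-6)
})

test_that("extrapolation identities: f = 1 and exact complex inversion", {
  s <- default_system()
  fd <- structure_factors(s$dark, fast_dmin)
  fe <- structure_factors(s$excited, fast_dmin)
  fm <- mix_states(fd, fe, 0.35)
  ext1 <- extrapolate_structure_factors(fm, fd, 1)
  expect_equal(ext1$f, fm$f, tolerance = 1e-12)
  # complex mode with the exact f inverts the mixing to 1e-8
  extc <- extrapolate_structure_factors(fm, fd, 0.35, mode = "complex")
  expect_equal(extc$f, fe$f, tolerance = 1e-8)
  expect_error(extrapolate_structure_factors(fm, fd, 0), "0 < f")
  # amplitude mode deviates from the pure excited state; the deviation is
  # real (nonzero) and bounded by what the complex oracle proves possible
  exta <- extrapolate_structure_factors(fm, fd, 0.35)
  rms_amp <- sqrt(mean((exta$f - fe$f)^2))
  rms_cpx <- sqrt(mean((extc$f - fe$f)^2))
  expect_gt(rms_amp, 1e-6)
  expect_lt(rms_cpx, 1e-8)
  expect_true(attr(exta, "n_negative") >= 0)
})

test_that("CO* B-factor inflation lowers apparent occupancy at fixed truth", {
  s <- default_system()
  sites <- co_sites(s)
  fd <- structure_factors(s$dark, fast_dmin)
  f_true <- 0.6
  apparent <- vapply(c(15, 40, 80), function(bstar) {
    exc <- s$excited
    exc$atoms$b[s$sel$co] <- bstar
    fm <- mix_states(fd, structure_factors(exc, fast_dmin), f_true)
    map <- omit_map(as_observed(fm),
                    mixture_omit_model(s, f_true, excited_model = exc),
                    scale = FALSE)
    occupancy_peak_ratio(map, sites$dark, sites$excited)$f
  }, numeric(1))
  expect_true(all(diff(apparent) < 0))
})

test_that("the benchmark sweep is deterministic and monotone in true f", {
  s <- default_system()
  tab1 <- benchmark_estimators(s, true_f = c(0.3, 0.5, 0.7), noise = 0.1,
                               d_min = fast_dmin, n_frames = 60, seed = 99)
  tab2 <- benchmark_estimators(s, true_f = c(0.3, 0.5, 0.7), noise = 0.1,
                               d_min = fast_dmin, n_frames = 60, seed = 99)
  expect_identical(tab1, tab2)
  for (m in unique(tab1$method)) {
    est <- tab1$estimate[tab1$method == m]
    expect_true(all(diff(est) >= 0))
  }
})
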