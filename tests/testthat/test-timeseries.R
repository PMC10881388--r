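# a minimal frame set where each frame carries one scalar observation
scalar_frames <- function(values, delays = seq_along(values)) {
  rs <- reflection_set(matrix(c(1L, 0L, 0L), 1), 1, c(10, 10, 10))
  fs <- simulate_frames(rs, length(values), frame_noise_none(),
                        nominal_delay = delays, seed = 1)
  fs$obs$i <- values
  fs
}

test_that("sliding windows cut the documented index bins", {
  fs <- scalar_frames(rnorm(50), delays = sample(1:50))
  bins <- bin_by_delay(fs, window = 20, step = 10)
  expect_length(bins, 4)
  expect_equal(vapply(bins, function(b) nrow(b$frames), numeric(1)),
               rep(20, 4))
  # consecutive bins overlap by W - S frames; step = W gives disjoint bins
  disjoint <- bin_by_delay(fs, window = 10, step = 10)
  expect_length(disjoint, 5)
  all_ids <- unlist(lapply(disjoint, function(b) sort(b$frames$delay)))
  expect_equal(sort(all_ids), sort(fs$frames$delay))
  # bin delay means are non-decreasing
  means <- vapply(bins, function(b) attr(b, "mean_delay"), numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_error(bin_by_delay(fs, window = 100, step = 10), "exceeds")
  expect_error(bin_by_delay(fs, window = 20, step = 30), "step")
})

test_that("per-bin delay SD falls in the tens-of-fs regime at 100 fs jitter", {
  set.seed(31)
  fs <- scalar_frames(rnorm(3500), delays = rnorm(3500, 500, 100))
  bins <- bin_by_delay(fs, window = 2000, step = 500)
  sds <- bin_summary(bins)$sd_delay
  interior <- sds[2:(length(sds) - 1)]
  expect_true(all(interior > 40 & interior < 70))
})

test_that("merging reduces to sqrt(max(I, 0)) and obeys the SD law", {
  rs <- reflection_set(matrix(c(1, 0, 0, 0, 2, 0, 1, 1, 1), 3, byrow = TRUE),
                       c(4, 0.5, 2), c(12, 12, 12))
  one <- simulate_frames(rs, 1, frame_noise_none(), seed = 2)
  one$obs$i <- c(16, -1, 4)   # negative background-subtracted intensity
  m <- merge_frames(one, n_min = 1)
  expect_equal(m$f, c(4, 0, 2), tolerance = 1e-12)
  # duplicated identical frames: same F, sigma shrinks as 1/sqrt(n)
  set.seed(7)
  vals <- rnorm(3, 10, 1)
  f4 <- scalar_frames(rep(vals, 4))
  f16 <- scalar_frames(rep(vals, 16))
  m4 <- merge_frames(subset_frames(f4, 1:12), n_min = 1)
  m16 <- merge_frames(subset_frames(f16, 1:48), n_min = 1)
  expect_equal(m4$f, m16$f, tolerance = 1e-12)
  # sigma = SD/sqrt(n): quadrupling n halves it twice (up to the n-1
  # denominator of the sample SD)
  expect_equal(m4$sigma / m16$sigma, 2, tolerance = 0.05)
})

test_that("merging is permutation-invariant and matches a brute-force merge", {
  s <- default_system()
  fc <- structure_factors(s$dark, 3.0)
  fs <- simulate_frames(fc, 50, frame_noise(), seed = 12)
  m1 <- merge_frames(fs)
  perm <- subset_frames(fs, rev(fs$frames$frame))
  m2 <- merge_frames(perm)
  expect_equal(m1$f, m2$f, tolerance = 1e-12)
  orc <- oracle_merge(fs)
  expect_equal(m1$f, orc$f, tolerance = 1e-12)
})

test_that("merged amplitudes track the truth with high correlation", {
  s <- default_system()
  fc <- structure_factors(s$dark, fast_dmin)
  fs <- simulate_frames(fc, 600, frame_noise(), seed = 8)
  m <- merge_frames(fs)
  idx <- match_indices(m, fc)
  cc <- oracle_cc(m$f, fc$f[idx])
  expect_gt(cc, 0.95)
  expect_equal(cc, stats::cor(m$f, fc$f[idx]), tolerance = 1e-12)
})

test_that("exponential-rise fits recover noiseless parameters exactly", {
  t <- seq(0, 2000, by = 100)
  y <- 0.1 + 0.7 * (1 - exp(-t / 350))
  fit <- fit_exponential_rise(t, y)
  expect_equal(unname(fit$par["tau"]), 350, tolerance = 1e-6)
  expect_equal(unname(fit$par["y0"]), 0.1, tolerance = 1e-6)
  expect_equal(unname(fit$par["a"]), 0.7, tolerance = 1e-6)
  flat <- fit_exponential_rise(t, rep(0.42, length(t)))
  expect_true("amplitude_zero_tau_unidentifiable" %in% flat$flags)
})

test_that("fitters are covariant under joint time translation", {
  t <- seq(0, 1800, by = 120)
  y <- 0.2 + 0.5 * (1 - exp(-t / 420))
  f0 <- fit_exponential_rise(t, y, fix_t0 = 0)
  f1 <- fit_exponential_rise(t + 500, y, fix_t0 = 500)
  expect_equal(unname(f0$par["tau"]), unname(f1$par["tau"]),
               tolerance = 1e-6)
  td <- seq(0, 1500, by = 60)
  yd <- 1 + 0.4 * exp(-td / 500) * cos(2 * pi * td / 300)
  g0 <- fit_damped_cosine(td, yd)
  expect_equal(unname(g0$par["period"]), 300, tolerance = 1e-6)
})

test_that("damped-cosine fits recover the period and flag flat input", {
  t <- seq(0, 1200, by = 40)
  y <- 2 + 0.8 * cos(2 * pi * t / 300)
  fit <- fit_damped_cosine(t, y, period_init = 280)
  expect_equal(unname(fit$par["period"]), 300, tolerance = 1e-6)
  flat <- fit_damped_cosine(t, rep(1.5, length(t)), period_init = 300)
  expect_true("amplitude_zero" %in% flat$flags)
  expect_error(fit_damped_cosine(t[t <= 200], y[t <= 200],
                                 period_init = 300), "unidentifiable")
})

test_that("bootstrap SDs: constant pipelines give zero, means give sigma/sqrt(n)", {
  fs <- scalar_frames(rnorm(200, 5, 2))
  const <- bootstrap_metric(fs, function(x) 1, b = 50, seed = 3)
  expect_equal(const$sd, 0)
  bs <- bootstrap_metric(fs, function(x) mean(x$obs$i), b = 100, seed = 4)
  expect_equal(bs$sd, 2 / sqrt(200), tolerance = 0.2)
})

test_that("bootstrap SD of a merged-amplitude metric shrinks as sqrt(n)", {
  s <- default_system()
  fc <- structure_factors(s$dark, 3.2)
  pipeline <- function(fs) mean(merge_frames(fs, n_min = 1)$f)
  sds <- vapply(c(60, 240), function(n) {
    fs <- simulate_frames(fc, n, frame_noise(), seed = 21)
    bootstrap_metric(fs, pipeline, b = 60, seed = 22)$sd
  }, numeric(1))
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.35)
})

test_that("failing pipelines are dropped and eventually fatal", {
  fs <- scalar_frames(rnorm(40))
  flaky <- function(x) if (stats::runif(1) < 0.5) stop("boom") else 1
  expect_error(bootstrap_metric(fs, flaky, b = 40, seed = 5), "failed")
  rare <- local({
    k <- 0
    function(x) {
      k <<- k + 1
      if (k == 2) stop("boom") else mean(x$obs$i)
    }
  })
  res <- bootstrap_metric(fs, rare, b = 20, seed = 6)
  expect_equal(res$n_failed, 1)
})
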