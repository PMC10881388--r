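test_that("a single atom at the origin scatters Z at zero phase", {
  m <- toy_model(matrix(c(0, 0, 0), 1), b = 1e-9)
  # B -> 0: no damping; atom at origin: all phases 0, F = Z
  fc <- structure_factors(m, d_min = 3, d_max = 10)
  expect_equal(fc$f, rep(6, nrow(fc$hkl)), tolerance = 1e-6)
  expect_equal(sin(fc$phase * pi / 180), rep(0, nrow(fc$hkl)),
               tolerance = 1e-6)
})

test_that("F(000) equals the total electron count", {
  m <- toy_model(matrix(runif(9, 2, 8), 3), b = 25, occ = 0.5)
  fc <- structure_factors(m, d_min = 3, include_f000 = TRUE)
  i000 <- which(rowSums(abs(fc$hkl)) == 0)
  expect_equal(fc$f[i000], 3 * 0.5 * 6, tolerance = 1e-12)
})

test_that("direct summation matches the quadrature Fourier oracle", {
  set.seed(2)
  m <- toy_model(matrix(runif(15, 2.5, 7.5), 5), b = 30)
  fc <- structure_factors(m, d_min = 2.0, d_max = 10)
  pick <- seq(1, nrow(fc$hkl), length.out = 12)
  oracle <- oracle_structure_factors(m, fc$hkl[pick, , drop = FALSE],
                                     n_grid = 48)
  expect_equal(fc$f[pick], Mod(oracle), tolerance = 5e-3)
})

test_that("amplitudes obey Friedel symmetry for any real model", {
  set.seed(3)
  m <- toy_model(matrix(runif(12, 2, 8), 4), b = 18)
  fc <- structure_factors(m, d_min = 2.5, hemisphere = FALSE)
  key <- paste(fc$hkl[, 1], fc$hkl[, 2], fc$hkl[, 3])
  mate <- match(paste(-fc$hkl[, 1], -fc$hkl[, 2], -fc$hkl[, 3]), key)
  expect_equal(fc$f, fc$f[mate], tolerance = 1e-10)
})

test_that("state mixing is the complex convex combination", {
  s <- default_system()
  fd <- structure_factors(s$dark, fast_dmin)
  fe <- structure_factors(s$excited, fast_dmin)
  expect_equal(mix_states(fd, fe, 0)$f, fd$f, tolerance = 1e-12)
  expect_equal(mix_states(fd, fe, 1)$f, fe$f, tolerance = 1e-12)
  # equal amplitudes in antiphase cancel at f = 0.5
  hkl <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  a <- reflection_set(hkl, c(5, 3), c(10, 10, 10), phase = c(0, 90))
  b <- reflection_set(hkl, c(5, 3), c(10, 10, 10), phase = c(180, 270))
  expect_equal(mix_states(a, b, 0.5)$f, c(0, 0), tolerance = 1e-12)
  expect_error(mix_states(a, subset_reflections(b, 1), 0.5), "mismatch")
})

test_that("Wilson scaling recovers identity, pure-scale and B-law factors", {
  s <- default_system()
  fd <- structure_factors(s$dark, fast_dmin)
  same <- scale_light_to_dark(fd, fd)
  expect_equal(same$k, 1, tolerance = 1e-9)
  expect_equal(same$b_rel, 0, tolerance = 1e-7)
  doubled <- reflection_set(fd$hkl, 2 * fd$f, fd$cell, d_min = fd$d_min,
                            d_max = fd$d_max)
  sc <- scale_light_to_dark(doubled, fd)
  expect_equal(sc$k, 0.5, tolerance = 1e-9)
  expect_equal(sc$b_rel, 0, tolerance = 1e-7)
  # synthetic B-law: F_light = F_dark * exp(-5 |s|^2 / 4) => B_rel = -5
  s2 <- 1 / fd$d^2
  damped <- reflection_set(fd$hkl, fd$f * exp(-5 * s2 / 4), fd$cell,
                           d_min = fd$d_min, d_max = fd$d_max)
  sc5 <- scale_light_to_dark(damped, fd)
  expect_equal(sc5$b_rel, -5, tolerance = 1e-6)
  expect_equal(sc5$scaled$f, fd$f, tolerance = 1e-6)
  # idempotence: re-scaling a scaled set is a no-op
  again <- scale_light_to_dark(sc5$scaled, fd)
  expect_equal(again$k, 1, tolerance = 1e-6)
  expect_equal(again$b_rel, 0, tolerance = 1e-5)
})

test_that("map synthesis is linear and peaks on the atom", {
  m <- toy_model(matrix(c(4.1, 5.3, 6.2), 1), b = 15)
  fc <- structure_factors(m, d_min = 1.2)
  map <- synthesize_map(fc)
  peak_idx <- which(map$values == max(map$values), arr.ind = TRUE)[1, ]
  peak_pos <- (peak_idx - 1) / map$dim * map$cell
  expect_lt(sqrt(sum((peak_pos - c(4.1, 5.3, 6.2))^2)),
            sqrt(sum((map$cell / map$dim)^2)))
  # all-zero amplitudes -> all-zero map
  z <- reflection_set(fc$hkl, rep(0, nrow(fc$hkl)), fc$cell,
                      phase = fc$phase, d_min = fc$d_min, d_max = fc$d_max)
  expect_equal(max(abs(synthesize_map(z)$values)), 0)
  # linearity: map(F1 - F2) == map(F1) - map(F2) pointwise (complex
  # coefficient difference re-encoded as amplitude and phase)
  m2 <- toy_model(matrix(c(6.0, 4.0, 5.0), 1), b = 22)
  fc2 <- structure_factors(m2, d_min = 1.2)
  dc <- as_complex(fc) - as_complex(fc2)[match_indices(fc, fc2)]
  dif <- reflection_set(fc$hkl, Mod(dc), fc$cell,
                        phase = Arg(dc) * 180 / pi,
                        d_min = fc$d_min, d_max = fc$d_max)
  lhs <- synthesize_map(dif, dim = c(30, 30, 30))$values
  rhs <- synthesize_map(fc, dim = c(30, 30, 30))$values -
    synthesize_map(fc2, dim = c(30, 30, 30))$values
  expect_equal(lhs, rhs, tolerance = 1e-8)
  # difference map has near-zero mean (F000 excluded)
  expect_lt(abs(mean(lhs)), 1e-10)
})

test_that("Parseval: sum |F|^2 / V matches the map norm on small models", {
  m <- toy_model(matrix(c(3, 4, 5, 6.5, 5.5, 4.5), 2, byrow = TRUE), b = 40)
  fc <- structure_factors(m, d_min = 1.0, d_max = 50, include_f000 = TRUE)
  map <- synthesize_map(fc, dim = c(40, 40, 40))
  lhs <- (sum(fc$f^2) + sum(fc$f[-which(fc$d == Inf)]^2)) / prod(m$cell)
  # hemisphere set: count every non-000 term twice (Friedel mate)
  rhs <- mean(map$values^2) * prod(m$cell)
  expect_equal(lhs, rhs, tolerance = 0.05)
})

test_that("peak heights interpolate exactly on nodes and uniform maps", {
  m <- toy_model(matrix(c(5, 5, 5), 1), b = 20)
  fc <- structure_factors(m, d_min = 1.5)
  map <- synthesize_map(fc)
  node <- c(3, 5, 7)
  pos <- (node - 1) / map$dim * map$cell
  expect_equal(peak_height(map, pos),
               map$values[node[1], node[2], node[3]], tolerance = 1e-12)
  flat <- map
  flat$values[] <- 3.25
  expect_equal(peak_height(flat, c(1.234, 4.56, 7.89)), 3.25,
               tolerance = 1e-12)
  expect_equal(peak_height(flat, c(0.1, 0.1, 9.9), search_radius = 0.8),
               3.25, tolerance = 1e-12)
})

test_that("local-maximum search agrees with 4x oversampled resampling", {
  s <- default_system()
  fd <- structure_factors(s$dark, fast_dmin)
  fe <- structure_factors(s$excited, fast_dmin)
  fm <- mix_states(fd, fe, 0.6)
  dif <- difference_coefficients(as_observed(fm), fd)
  map <- synthesize_map(dif, provenance = "difference")
  fine <- synthesize_map(dif, dim = 4 * map$dim, provenance = "difference")
  site <- co_sites(s)$excited
  v <- peak_height(map, site, search_radius = 0.8)
  v_fine <- peak_height(fine, site, search_radius = 0.8)
  expect_equal(v, v_fine, tolerance = 0.02)
})
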