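test_that("plane fitting handles the symmetric square and rotations", {
  sq <- matrix(c(1, 1, 0, -1, 1, 0, -1, -1, 0, 1, -1, 0), 4, 3, byrow = TRUE)
  pl <- fit_plane(sq)
  expect_equal(abs(pl$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$centroid, c(0, 0, 0), tolerance = 1e-12)
  # equivariance: rotating the points rotates the normal identically
  set.seed(4)
  pts <- cbind(matrix(rnorm(20), 10, 2), rnorm(10, sd = 0.01))
  pl0 <- fit_plane(pts, orient_toward = c(0, 0, 10))
  rot <- rigid_rotate(pts)
  ref_rot <- as.numeric(rigid_rotate(matrix(c(0, 0, 10), 1)))
  pl1 <- fit_plane(rot, orient_toward = ref_rot)
  n_expected <- as.numeric(rigid_rotate(matrix(pl0$normal, 1), shift = c(0, 0, 0)))
  expect_equal(pl1$normal, n_expected, tolerance = 1e-6)
  expect_error(fit_plane(matrix(c(0, 0, 0, 1, 1, 1, 2, 2, 2), 3, byrow = TRUE)),
               "collinear")
})

test_that("noisy coplanar clouds match the eigen-decomposition plane oracle", {
  set.seed(9)
  pts <- cbind(matrix(rnorm(60, sd = 2), 30, 2), rnorm(30, sd = 0.05))
  pl <- fit_plane(pts)
  orc <- oracle_plane(pts)
  expect_equal(abs(sum(pl$normal * orc$normal)), 1, tolerance = 1e-10)
  expect_equal(pl$centroid, orc$centroid, tolerance = 1e-12)
})

test_that("iron out-of-plane distance is signed toward the proximal His", {
  # Fe displaced toward the His (His is 2.1 A below the N plane)
  expect_equal(fe_out_of_plane(mini_heme(fe_z = -0.3)), 0.3,
               tolerance = 1e-12)
  expect_equal(fe_out_of_plane(mini_heme(fe_z = 0.3)), -0.3,
               tolerance = 1e-12)
  expect_equal(fe_out_of_plane(mini_heme(fe_z = 0)), 0, tolerance = 1e-12)
  expect_error(fe_out_of_plane(toy_model(matrix(1:6, 2, 3))), "FE")
})

test_that("ruffled nitrogen rings agree with the TLS-plane oracle", {
  m <- mini_heme(fe_z = 0.2, n_z = c(0.1, -0.1, 0.1, -0.1))
  pl <- oracle_plane(pyrrole_n <- coords(m)[2:5, ])
  n <- pl$normal
  his <- coords(m)[6, ]
  if (sum(n * (his - pl$centroid)) < 0) n <- -n
  expected <- sum((coords(m)[1, ] - pl$centroid) * n)
  expect_equal(fe_out_of_plane(m), expected, tolerance = 1e-10)
})

test_that("doming projection returns the injected amplitude and ignores
           in-plane motion", {
  s <- default_system()
  dark <- s$dark
  expect_equal(doming_coefficient(dark, dark), 0, tolerance = 1e-14)
  mode <- doming_mode(dark)
  core <- which(atom_select(dark, resid = "HEM"))
  # displacement exactly A x mode (along -z = toward the His) -> returns A
  for (a in c(0.05, 0.12)) {
    xyz <- coords(dark)
    xyz[core, 3] <- xyz[core, 3] - a * mode
    expect_equal(doming_coefficient(set_coords(dark, xyz), dark), a,
                 tolerance = 1e-10)
  }
  # linearity in amplitude is implied by the two-point check above;
  # pure in-plane breathing projects to zero
  xyz <- coords(dark)
  ctr <- colMeans(xyz[core, ])
  xyz[core, 1:2] <- ctr[1:2] + 1.05 * sweep(xyz[core, 1:2], 2, ctr[1:2])
  expect_equal(doming_coefficient(set_coords(dark, xyz), dark), 0,
               tolerance = 1e-10)
})

test_that("difference-distance matrices vanish for rigid motion and match
           hand-computed single-atom moves", {
  s <- default_system()
  dark <- s$dark
  expect_equal(max(abs(difference_distance_matrix(dark, dark))), 0)
  moved <- set_coords(dark, rigid_rotate(coords(dark)))
  expect_lt(max(abs(difference_distance_matrix(moved, dark))), 1e-9)
  # move one Calpha by (1, 0, 0): only its row/column change, by the
  # brute-force pairwise difference
  sel <- which(atom_select(dark, name = "CA") & dark$atoms$resid != "HEM")
  xyz <- coords(dark)
  xyz[sel[3], ] <- xyz[sel[3], ] + c(1, 0, 0)
  light <- set_coords(dark, xyz)
  m <- difference_distance_matrix(light, dark)
  orc <- oracle_ddm(coords(light)[sel, ], coords(dark)[sel, ])
  expect_equal(unname(m), orc, tolerance = 1e-12)
  untouched <- m[-3, -3]
  expect_equal(max(abs(untouched)), 0)
  expect_true(isSymmetric(m, check.attributes = FALSE))
  expect_equal(max(abs(diag(m))), 0)
})

test_that("displacement-from-heme is zero at rest and radial for pure
           radial moves", {
  s <- default_system()
  dark <- s$dark
  tab0 <- displacement_from_haem(list(dark), dark, delays = 0)
  expect_equal(max(abs(tab0$delta)), 0)
  # move one backbone atom radially +0.5 A from the (static) heme centre
  ctr <- colMeans(coords(dark)[atom_select(dark, resid = "HEM", element = "N"), ])
  sel <- which(atom_select(dark, name = "N") & dark$atoms$resid == "ALA")
  xyz <- coords(dark)
  u <- (xyz[sel[1], ] - ctr) / sqrt(sum((xyz[sel[1], ] - ctr)^2))
  xyz[sel[1], ] <- xyz[sel[1], ] + 0.5 * u
  tab <- displacement_from_haem(list(set_coords(dark, xyz)), dark)
  hit <- tab[tab$resno == dark$atoms$resno[sel[1]] & tab$atom == "N", ]
  expect_equal(hit$delta[1], 0.5, tolerance = 1e-9)
})

test_that("radius of gyration: two-atom case, homogeneity and brute force", {
  two <- toy_model(matrix(c(4, 5, 5, 6, 5, 5), 2, byrow = TRUE))
  expect_equal(radius_of_gyration(two), 1, tolerance = 1e-12)
  s <- default_system()
  rg <- radius_of_gyration(s$dark)
  scaled <- set_coords(s$dark, coords(s$dark) * 1.7)
  scaled$cell <- s$dark$cell * 1.7
  expect_equal(radius_of_gyration(scaled), 1.7 * rg, tolerance = 1e-9)
  expect_equal(rg, oracle_rg(coords(s$dark)), tolerance = 1e-12)
})

test_that("scalar metrics are invariant under joint rigid-body motion", {
  s <- default_system()
  move <- function(m) set_coords(m, rigid_rotate(coords(m)))
  d2 <- move(s$dark)
  e2 <- move(s$excited)
  expect_equal(fe_out_of_plane(d2), fe_out_of_plane(s$dark),
               tolerance = 1e-9)
  expect_equal(radius_of_gyration(d2), radius_of_gyration(s$dark),
               tolerance = 1e-9)
  expect_equal(doming_coefficient(e2, d2),
               doming_coefficient(s$excited, s$dark), tolerance = 1e-9)
  expect_equal(fe_out_of_plane(e2) - fe_out_of_plane(d2),
               s$deltas$delta_fe, tolerance = 1e-9)
})
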