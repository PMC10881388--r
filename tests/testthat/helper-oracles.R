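# Independent brute-force oracles used to freeze expected values.
# Each deliberately takes a different computational path from the package.

# plain double-loop RMSD over a matched roster
oracle_rmsd <- function(xyz_a, xyz_b) {
  stopifnot(nrow(xyz_a) == nrow(xyz_b))
  acc <- 0
  for (i in seq_len(nrow(xyz_a))) {
    acc <- acc + sum((xyz_a[i, ] - xyz_b[i, ])^2)
  }
  sqrt(acc / nrow(xyz_a))
}

# plane through points via eigen-decomposition of the covariance
# (fit_plane uses svd of the centered coordinates)
oracle_plane <- function(points) {
  ctr <- colMeans(points)
  ev <- eigen(stats::cov(points))
  list(normal = ev$vectors[, 3], centroid = ctr)
}

# radius of gyration via the pairwise-distance identity
# Rg^2 = (1/2N^2) * sum_ij d_ij^2
oracle_rg <- function(xyz) {
  n <- nrow(xyz)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- acc + sum((xyz[i, ] - xyz[j, ])^2)
  }
  sqrt(acc / (2 * n^2))
}

# difference-distance matrix by explicit double loop
oracle_ddm <- function(xyz_l, xyz_d) {
  n <- nrow(xyz_l)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- sqrt(sum((xyz_l[i, ] - xyz_l[j, ])^2)) -
      sqrt(sum((xyz_d[i, ] - xyz_d[j, ])^2))
  }
  m
}

# structure factors by quadrature: evaluate the Gaussian-atom density of
# the model on a fine real-space grid and Fourier-sum it numerically.
# The density of an atom with electron count Z and B factor B is
# Z * (4 pi / B)^(3/2) * exp(-4 pi^2 r^2 / B), whose analytic transform is
# Z * exp(-B s^2 / 4).
oracle_structure_factors <- function(model, hkl, n_grid = 48) {
  cell <- model$cell
  z <- element_electrons()[model$atoms$element]
  xyz <- coords(model)
  gx <- (seq_len(n_grid) - 1) / n_grid * cell[1]
  gy <- (seq_len(n_grid) - 1) / n_grid * cell[2]
  gz <- (seq_len(n_grid) - 1) / n_grid * cell[3]
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  rho <- numeric(nrow(pts))
  for (a in seq_len(nrow(xyz))) {
    b <- model$atoms$b[a]
    # minimum-image displacement in the periodic box
    d2 <- 0
    for (k in 1:3) {
      dk <- pts[, k] - xyz[a, k]
      dk <- dk - round(dk / cell[k]) * cell[k]
      d2 <- d2 + dk^2
    }
    rho <- rho + model$atoms$occ[a] * z[a] * (4 * pi / b)^1.5 *
      exp(-4 * pi^2 * d2 / b)
  }
  dv <- prod(cell) / n_grid^3
  frac <- sweep(pts, 2, cell, "/")
  vapply(seq_len(nrow(hkl)), function(r) {
    phase <- 2 * pi * (frac %*% hkl[r, ])
    sum(rho * exp(1i * phase)) * dv
  }, complex(1))
}

# Pearson correlation by explicit sums (independent of stats::cor)
oracle_cc <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# brute-force merge: per reflection index, plain loop mean
oracle_merge <- function(fs, n_min = 3) {
  out <- numeric(0)
  idx <- integer(0)
  for (r in sort(unique(fs$obs$ridx))) {
    ii <- fs$obs$i[fs$obs$ridx == r]
    if (length(ii) >= n_min) {
      out <- c(out, sqrt(max(mean(ii), 0)))
      idx <- c(idx, r)
    }
  }
  list(ridx = idx, f = out)
}
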