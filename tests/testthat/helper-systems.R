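# Shared fixtures, built in code. Unit tests run the toy crystal at a
# reduced resolution (2.2 A) to stay fast; the acceptance suite uses the
# default 1.4 A study conditions.

fast_dmin <- 2.2

default_system <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_two_state_system()
    cache
  }
})

# small free-standing models -------------------------------------------------

# n arbitrary carbon atoms in a small box
toy_model <- function(xyz, b = 20, occ = 1, cell = c(10, 10, 10),
                      element = "C") {
  n <- nrow(xyz)
  atomic_model(data.frame(
    atom = seq_len(n), name = paste0("C", seq_len(n)),
    element = rep_len(element, n), resid = "LIG", resno = 1L,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = rep_len(b, n), occ = rep_len(occ, n)), cell, wrap = FALSE)
}

# minimal heme-like model: 4 pyrrole N (z = 0 plane), Fe at height fe_z,
# His NE2 below -- enough for the plane/OOP metrics
mini_heme <- function(fe_z = 0, n_z = c(0, 0, 0, 0), cell = c(20, 20, 20)) {
  ctr <- cell / 2
  atoms <- data.frame(
    atom = 1:6,
    name = c("FE", "N1", "N2", "N3", "N4", "NE2"),
    element = c("FE", "N", "N", "N", "N", "N"),
    resid = c(rep("HEM", 5), "HIS"),
    resno = c(rep(200L, 5), 93L),
    x = ctr[1] + c(0, 2, 0, -2, 0, 0),
    y = ctr[2] + c(0, 0, 2, 0, -2, 0),
    z = ctr[3] + c(fe_z, n_z, -2.1),
    b = 15, occ = 1)
  atomic_model(atoms, cell, wrap = FALSE)
}

rigid_rotate <- function(xyz, axis = c(1, 1, 1), angle = 0.7,
                         shift = c(1, -2, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  r <- diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
  sweep(xyz %*% t(r), 2, shift, "+")
}

# exact amplitude copy of a reflection set without phases (an "observed" set)
as_observed <- function(rs) {
  reflection_set(rs$hkl, rs$f, rs$cell, sigma = rs$sigma,
                 d_min = rs$d_min, d_max = rs$d_max)
}
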