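#' Total-least-squares plane through points
#'
#' Fits the plane minimizing orthogonal distances (via the centered
#' cross-product / smallest principal direction), with an optional
#' orientation reference: the normal is flipped so it points toward
#' `orient_toward`.
#'
#' @param points n x 3 matrix, n >= 3, not collinear.
#' @param orient_toward Optional Cartesian point; the returned normal has
#'   positive dot product with (orient_toward - centroid).
#' @return List with `normal` (unit vector) and `centroid`.
#' @export
fit_plane <- function(points, orient_toward = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, nrow(points) >= 3)
  centroid <- colMeans(points)
  x <- sweep(points, 2, centroid)
  sv <- svd(x)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300)) {
    stop("points are collinear: plane is undefined")
  }
  normal <- sv$v[, 3]
  if (!is.null(orient_toward)) {
    if (sum(normal * (orient_toward - centroid)) < 0) normal <- -normal
  }
  list(normal = normal, centroid = centroid)
}

# pyrrole nitrogen coordinates of a model (named N1..N4 in resid HEM)
pyrrole_n <- function(model) {
  sel <- atom_select(model, resid = "HEM", element = "N")
  if (sum(sel) < 3) stop("missing labeled heme pyrrole nitrogen atoms (HEM N*)")
  coords(model)[sel, , drop = FALSE]
}

# proximal histidine N-epsilon position (sign reference for heme normals)
proximal_reference <- function(model) {
  sel <- atom_select(model, name = "NE2", resid = "HIS")
  if (sum(sel) != 1) stop("missing labeled proximal His NE2 atom")
  as.numeric(coords(model)[sel, ])
}

#' Iron out-of-plane displacement (OOP_Fe)
#'
#' Signed distance of the heme iron from the total-least-squares plane of
#' the four pyrrole nitrogens; positive when the iron is displaced toward
#' the proximal histidine.
#'
#' @param model An `atomic_model` with labeled FE, heme N and proximal
#'   His NE2 atoms.
#' @return Signed displacement in Angstrom.
#' @export
fe_out_of_plane <- function(model) {
  fe_sel <- atom_select(model, name = "FE", resid = "HEM")
  if (sum(fe_sel) != 1) stop("missing labeled heme FE atom")
  fe <- as.numeric(coords(model)[fe_sel, ])
  pl <- fit_plane(pyrrole_n(model), orient_toward = proximal_reference(model))
  sum((fe - pl$centroid) * pl$normal)
}

#' Heme doming coefficient
#'
#' Projects the out-of-plane displacement field of the 25 heme core atoms
#' (model minus reference, components along the reference heme normal
#' oriented toward the proximal histidine) onto the unit-norm doming mode
#' vector of [doming_mode()]. Linear in displacement amplitude;
#' pure in-plane motion projects to zero.
#'
#' @param model,reference `atomic_model`s with matched heme core rosters.
#' @return Signed doming amplitude in Angstrom.
#' @export
doming_coefficient <- function(model, reference) {
  assert_same_roster(model, reference)
  sel <- atom_select(reference, resid = "HEM")
  pl <- fit_plane(pyrrole_n(reference),
                  orient_toward = proximal_reference(reference))
  disp <- coords(model)[sel, , drop = FALSE] -
    coords(reference)[sel, , drop = FALSE]
  oop <- as.numeric(disp %*% pl$normal)
  sum(oop * doming_mode(reference))
}

#' Iron to proximal histidine distance
#'
#' @param model An `atomic_model` with labeled FE and His NE2 atoms.
#' @return Distance in Angstrom.
#' @export
fe_his_distance <- function(model) {
  fe_sel <- atom_select(model, name = "FE", resid = "HEM")
  if (sum(fe_sel) != 1) stop("missing labeled heme FE atom")
  sqrt(sum((as.numeric(coords(model)[fe_sel, ]) -
              proximal_reference(model))^2))
}

#' Calpha-Calpha difference-distance matrix (Go plot)
#'
#' M_ij = d_ij(light) - d_ij(dark) over the matched Calpha rosters of two
#' states: symmetric, zero diagonal, invariant under rigid-body motion of
#' either structure.
#'
#' @param light,dark `atomic_model`s with identical rosters.
#' @param name Atom name defining the selection (default "CA"; heme ring
#'   CA* atoms are excluded by requiring an amino-acid residue label).
#' @return Square numeric matrix (Angstrom), dimnames = residue indices.
#' @export
difference_distance_matrix <- function(light, dark, name = "CA") {
  assert_same_roster(light, dark)
  sel <- atom_select(dark, name = name) & dark$atoms$resid != "HEM"
  if (sum(sel) < 2) stop("fewer than two atoms selected for the matrix")
  d_l <- as.matrix(stats::dist(coords(light)[sel, , drop = FALSE]))
  d_d <- as.matrix(stats::dist(coords(dark)[sel, , drop = FALSE]))
  m <- d_l - d_d
  dimnames(m) <- list(dark$atoms$resno[sel], dark$atoms$resno[sel])
  m
}

#' Displacement of main-chain atoms from the heme centre
#'
#' For each backbone N, CA and C atom of each model in a delay series:
#' Delta(t) = |r_atom(t) - c_heme(t)| - |r_atom(dark) - c_heme(dark)|,
#' where c_heme is the centroid of the four pyrrole nitrogens of that same
#' model (default) or of the full heme core.
#'
#' @param models List of `atomic_model`s (the light/time series).
#' @param dark Reference `atomic_model`.
#' @param delays Optional numeric labels (fs), one per model.
#' @param reference "nitrogens" (4 pyrrole N centroid, default) or
#'   "core" (all heme atoms).
#' @return data.frame with columns delay, resno, atom, delta (Angstrom).
#' @export
displacement_from_haem <- function(models, dark, delays = NULL,
                                   reference = c("nitrogens", "core")) {
  reference <- match.arg(reference)
  if (inherits(models, "atomic_model")) models <- list(models)
  if (is.null(delays)) delays <- seq_along(models)
  stopifnot(length(delays) == length(models))
  centre_of <- function(m) {
    if (reference == "nitrogens") colMeans(pyrrole_n(m))
    else colMeans(coords(m)[atom_select(m, resid = "HEM"), , drop = FALSE])
  }
  sel <- atom_select(dark, name = c("N", "CA", "C")) & dark$atoms$resid != "HEM"
  c_dark <- centre_of(dark)
  r_dark <- sqrt(rowSums(sweep(coords(dark)[sel, , drop = FALSE],
                               2, c_dark)^2))
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    assert_same_roster(m, dark)
    c_m <- centre_of(m)
    r_m <- sqrt(rowSums(sweep(coords(m)[sel, , drop = FALSE], 2, c_m)^2))
    out[[i]] <- data.frame(delay = delays[i],
                           resno = dark$atoms$resno[sel],
                           atom = dark$atoms$name[sel],
                           delta = r_m - r_dark)
  }
  do.call(rbind, out)
}

#' Radius of gyration
#'
#' R_g = sqrt(sum w_i |r_i - rbar|^2 / sum w_i) over non-hydrogen atoms;
#' unweighted by default, optionally mass-weighted.
#'
#' @param model An `atomic_model` with >= 2 atoms.
#' @param mass_weighted Use atomic masses as weights (default FALSE).
#' @return R_g in Angstrom.
#' @export
radius_of_gyration <- function(model, mass_weighted = FALSE) {
  stopifnot(inherits(model, "atomic_model"))
  keep <- model$atoms$element != "H"
  xyz <- coords(model)[keep, , drop = FALSE]
  if (nrow(xyz) < 2) stop("radius of gyration needs at least 2 atoms")
  w <- if (mass_weighted) element_masses()[model$atoms$element[keep]]
       else rep(1, nrow(xyz))
  ctr <- colSums(xyz * w) / sum(w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)) / sum(w))
}

#' Metric record of one model against a reference
#'
#' Convenience wrapper evaluating the scalar structural metrics at once.
#'
#' @param model,dark `atomic_model`s with matched rosters.
#' @param label Delay (fs) or fluence label attached to the record.
#' @return One-row data.frame: label, oop_fe, fe_his, doming, rg.
#' @export
metric_record <- function(model, dark, label = NA_real_) {
  data.frame(label = label,
             oop_fe = fe_out_of_plane(model),
             fe_his = fe_his_distance(model),
             doming = doming_coefficient(model, dark),
             rg = radius_of_gyration(model))
}
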