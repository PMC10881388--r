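#' Tabulated electron counts for supported elements
#'
#' Atomic numbers used as scattering weights by the point-atom form factor.
#' Only elements occurring in the synthetic protein-heme system are tabulated.
#'
#' @return Named integer vector of electron counts.
#' @export
element_electrons <- function() {
  c(H = 1L, C = 6L, N = 7L, O = 8L, S = 16L, FE = 26L)
}

# atomic masses (u), used only by the optional mass-weighted radius of gyration
element_masses <- function() {
  c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, FE = 55.845)
}

#' Construct an atomic model
#'
#' An `atomic_model` is a labelled point-atom structure in an orthogonal P1
#' box: one row per atom with element, PDB-style atom name, residue label and
#' index, Cartesian position (Angstrom), isotropic B factor (Angstrom^2) and
#' occupancy. It is the unit on which all geometry metrics and structure
#' factor calculations operate.
#'
#' @param atoms data.frame with columns `atom` (integer id), `name` (atom
#'   name, e.g. "CA", "FE"), `element` (symbol matching
#'   [element_electrons()]), `resid` (residue label), `resno` (residue
#'   index), `x`, `y`, `z` (Angstrom), `b` (Angstrom^2, > 0), `occ` (in
#'   \[0, 1\]).
#' @param cell Numeric length-3 vector of orthogonal box lengths (a, b, c)
#'   in Angstrom.
#' @param wrap Wrap positions into the cell (default TRUE).
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, cell, wrap = TRUE) {
  stopifnot(is.data.frame(atoms), length(cell) == 3, all(cell > 0))
  needed <- c("atom", "name", "element", "resid", "resno",
              "x", "y", "z", "b", "occ")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, needed]
  atoms$element <- toupper(atoms$element)
  unknown <- setdiff(unique(atoms$element), names(element_electrons()))
  if (length(unknown) > 0) {
    stop("no tabulated electron count for element(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom position")
  }
  if (any(atoms$b <= 0)) stop("B factors must be > 0")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must lie in [0, 1]")
  if (wrap) {
    for (i in seq_len(3)) {
      ax <- c("x", "y", "z")[i]
      atoms[[ax]] <- atoms[[ax]] %% cell[i]
    }
  }
  structure(list(atoms = atoms, cell = as.numeric(cell), spacegroup = "P1"),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d atoms, cell %.1f x %.1f x %.1f A (%s)\n",
              nrow(x$atoms), x$cell[1], x$cell[2], x$cell[3], x$spacegroup))
  invisible(x)
}

#' Coordinate matrix of an atomic model
#'
#' @param model An `atomic_model`.
#' @return n x 3 numeric matrix of Cartesian coordinates (Angstrom).
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "atomic_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Select atoms from a model
#'
#' @param model An `atomic_model`.
#' @param name,resid,resno,element Optional filters; each keeps atoms whose
#'   field is in the given set.
#' @return Logical vector over the atom table.
#' @export
atom_select <- function(model, name = NULL, resid = NULL, resno = NULL,
                        element = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  keep <- rep(TRUE, nrow(model$atoms))
  if (!is.null(name))    keep <- keep & model$atoms$name %in% name
  if (!is.null(resid))   keep <- keep & model$atoms$resid %in% resid
  if (!is.null(resno))   keep <- keep & model$atoms$resno %in% resno
  if (!is.null(element)) keep <- keep & model$atoms$element %in% toupper(element)
  keep
}

#' Replace coordinates of a model
#'
#' @param model An `atomic_model`.
#' @param xyz n x 3 matrix of new Cartesian coordinates.
#' @param wrap Wrap into the cell (default FALSE: trajectories stay
#'   continuous; wrapping is applied where scattering code needs it).
#' @return The modified `atomic_model`.
#' @export
set_coords <- function(model, xyz, wrap = FALSE) {
  stopifnot(inherits(model, "atomic_model"),
            nrow(xyz) == nrow(model$atoms), ncol(xyz) == 3)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  if (wrap) {
    for (i in seq_len(3)) {
      ax <- c("x", "y", "z")[i]
      model$atoms[[ax]] <- model$atoms[[ax]] %% model$cell[i]
    }
  }
  model
}

#' Check that two models share an atom roster
#'
#' Identity of ids, names, elements, residue labels and indices; coordinates,
#' B factors and occupancies may differ.
#'
#' @param a,b `atomic_model` objects.
#' @return TRUE invisibly, or an error naming the first mismatch.
#' @export
assert_same_roster <- function(a, b) {
  stopifnot(inherits(a, "atomic_model"), inherits(b, "atomic_model"))
  if (nrow(a$atoms) != nrow(b$atoms)) stop("atom rosters differ in size")
  for (col in c("atom", "name", "element", "resid", "resno")) {
    if (!identical(a$atoms[[col]], b$atoms[[col]])) {
      stop("atom rosters differ in column '", col, "'")
    }
  }
  invisible(TRUE)
}

#' Minimum interatomic distance
#'
#' @param model An `atomic_model` with at least two atoms.
#' @return Smallest pairwise distance in Angstrom (no periodic images; the
#'   synthetic systems are padded well inside their box).
#' @export
min_distance <- function(model) {
  xyz <- coords(model)
  if (nrow(xyz) < 2) return(Inf)
  min(stats::dist(xyz))
}
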