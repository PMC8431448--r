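# Periodic geometry primitives: minimum image, molecule unwrapping,
# mass-weighted centers of mass, least-squares ring planes, axial angles.

# minimum-image displacement(s); d is a vector or an n x 3 matrix
min_image <- function(d, box) {
  if (is.matrix(d)) {
    b <- matrix(box, nrow = nrow(d), ncol = 3, byrow = TRUE)
    d - b * round(d / b)
  } else {
    d - box * round(d / box)
  }
}

# wrap points into [0, box)
wrap_box <- function(x, box) {
  if (is.matrix(x)) {
    b <- matrix(box, nrow = nrow(x), ncol = 3, byrow = TRUE)
    x - b * floor(x / b)
  } else {
    x - box * floor(x / box)
  }
}

# make a set of atom coordinates whole across the periodic boundary by
# minimum-image displacement relative to the first atom
make_whole <- function(xyz, box) {
  ref <- xyz[1, ]
  d <- sweep(xyz, 2, ref)
  sweep(min_image(d, box), 2, ref, `+`)
}

#' Mass-weighted center of mass of a coordinate set
#'
#' Low-level COM on raw coordinates. When `box` is given, the atoms are first
#' made whole across the periodic boundary (minimum image relative to the
#' first atom) and the resulting COM is wrapped back into the primary box.
#'
#' @param xyz Numeric matrix (atoms x 3), Angstrom.
#' @param masses Atomic masses (g/mol); total must be positive.
#' @param box Optional length-3 orthorhombic box.
#' @return Length-3 numeric COM position.
#' @export
center_of_mass <- function(xyz, masses, box = NULL) {
  stopifnot(is.matrix(xyz), length(masses) == nrow(xyz))
  M <- sum(masses)
  if (!is.finite(M) || M <= 0) stop("zero or invalid total mass")
  if (!is.null(box)) xyz <- make_whole(xyz, box)
  com <- colSums(xyz * masses) / M
  if (!is.null(box)) com <- wrap_box(com, box)
  com
}

#' Centers of mass of molecules in a trajectory frame
#'
#' Each molecule is made whole across the periodic boundary before mass
#' weighting; the COM is wrapped into the primary box.
#'
#' @param traj An `md_trajectory`.
#' @param frame Frame index.
#' @param molecules Molecule indices (default all).
#' @return Numeric matrix (length(molecules) x 3) with rownames the molecule
#'   indices.
#' @export
molecule_com <- function(traj, frame, molecules = NULL) {
  top <- traj$topology
  xyz <- traj$coords[[frame]]
  box <- traj$box[frame, ]
  if (is.null(molecules)) molecules <- top$molecules$mol
  a <- top$atoms[top$atoms$mol %in% molecules, , drop = FALSE]
  if (any(!is.finite(a$mass)) || any(a$mass <= 0)) stop("invalid atomic mass")
  first <- a$atom[!duplicated(a$mol)]
  names(first) <- a$mol[!duplicated(a$mol)]
  ref <- xyz[first[as.character(a$mol)], , drop = FALSE]
  d <- min_image(xyz[a$atom, , drop = FALSE] - ref, box)
  wsum <- rowsum(d * a$mass, group = a$mol)   # rows sorted by molecule index
  msum <- rowsum(a$mass, group = a$mol)
  com <- wsum / as.vector(msum) + xyz[first[rownames(wsum)], , drop = FALSE]
  com <- wrap_box(com, box)
  com <- com[match(as.character(molecules), rownames(com)), , drop = FALSE]
  rownames(com) <- molecules
  com
}

#' Least-squares plane normal of a molecule's ring atoms
#'
#' Fits a plane to the molecule's ring-atom positions (made whole across the
#' periodic boundary) and returns the unit normal: the principal axis of
#' smallest variance of the centered coordinates. The sign of the normal is
#' arbitrary; stacking angles treat normals as axes.
#'
#' @param traj An `md_trajectory`.
#' @param frame Frame index.
#' @param molecule Molecule index; its species must flag at least 3 ring
#'   atoms.
#' @return Unit length-3 numeric vector.
#' @export
plane_normal <- function(traj, frame, molecule) {
  idx <- ring_atoms(traj$topology, molecule)
  xyz <- make_whole(traj$coords[[frame]][idx, , drop = FALSE],
                    traj$box[frame, ])
  plane_normal_xyz(xyz)
}

#' @rdname plane_normal
#' @param xyz Ring-atom coordinates (>= 3 x 3), already whole.
#' @export
plane_normal_xyz <- function(xyz) {
  stopifnot(is.matrix(xyz), nrow(xyz) >= 3L)
  cen <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(cen, nu = 0)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    stop("ring atoms are collinear or degenerate; no plane is defined")
  }
  n <- sv$v[, 3]
  n / sqrt(sum(n^2))
}

#' Acute angle between two plane normals
#'
#' Normals are axial (sign-free), so the angle is folded into [0, 90] degrees
#' via `acos(|n1 . n2|)`: antiparallel normals give 0 degrees.
#'
#' @param n1,n2 Length-3 vectors (need not be normalized, but non-zero).
#' @return Angle in degrees in [0, 90].
#' @export
pair_angle <- function(n1, n2) {
  l1 <- sqrt(sum(n1^2)); l2 <- sqrt(sum(n2^2))
  if (l1 < 1e-12 || l2 < 1e-12) stop("zero vector has no direction")
  acos(pmin(1, abs(sum(n1 * n2)) / (l1 * l2))) * 180 / pi
}

# rotation matrix: angle (rad) about unit axis (Rodrigues)
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# uniform random rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# uniform random unit vector
random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
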