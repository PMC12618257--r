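#' Signed dihedral angle over four points
#'
#' Computes the torsion about the p2-p3 axis using the two-plane normal
#' construction with an atan2 form, so the result is numerically stable
#' near 0 and 180 degrees.  The sign follows the biomolecular torsion
#' convention used throughout the package: looking down the p2->p3
#' axis, a clockwise rotation carrying the p2->p1 direction onto the
#' p3->p4 direction is positive.  Under this convention
#' `dihedral((0,1,0),(0,0,0),(1,0,0),(1,0,1))` is -90.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom)
#' @return signed angle in degrees, in (-180, 180]
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  scale <- max(vnorm(b1), vnorm(b2), vnorm(b3))
  if (vnorm(b2) < 1e-9 || vnorm(n1) < 1e-9 * scale^2 ||
      vnorm(n2) < 1e-9 * scale^2) {
    abort("degenerate dihedral: coincident or collinear points", "degenerate_geometry")
  }
  m <- cross3(n1, n2)
  y <- sum(m * b2) / vnorm(b2)
  x <- sum(n1 * n2)
  wrap_angle(-atan2(y, x) * 180 / pi)
}

#' Interior angle at a vertex
#'
#' @param p1,p2,p3 numeric 3-vectors; the angle is measured at `p2`
#' @return angle in degrees, in \[0, 180\]
#' @export
angle3 <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  if (vnorm(u) < 1e-9 || vnorm(v) < 1e-9) {
    abort("degenerate angle: coincident points", "degenerate_geometry")
  }
  atan2(vnorm(cross3(u, v)), sum(u * v)) * 180 / pi
}

#' Center of mass of an atom selection
#'
#' Mass weighting uses average atomic masses over heavy atoms
#' (hydrogens are dropped); geometric weighting is the unweighted mean
#' of all supplied atoms.  Both modes are exposed because published
#' subdomain-center metrics do not always state their weighting.
#'
#' @param atoms data.frame of atom records (as from [select_atoms()])
#' @param weighting `"mass"` or `"geometric"`
#' @param mass_table named numeric vector (defaults to [atomic_masses()])
#' @return numeric 3-vector
#' @export
center_of_mass <- function(atoms, weighting = c("mass", "geometric"),
                           mass_table = atomic_masses()) {
  weighting <- match.arg(weighting)
  if (is.null(atoms) || nrow(atoms) == 0) {
    abort("empty selection: no atoms for center of mass", "empty_selection")
  }
  if (weighting == "mass") {
    atoms <- atoms[atoms$element != "H", , drop = FALSE]
    if (nrow(atoms) == 0) {
      abort("empty selection after dropping hydrogens", "empty_selection")
    }
    unknown <- setdiff(unique(atoms$element), names(mass_table))
    if (length(unknown)) {
      abort(sprintf("element(s) missing from mass table: %s",
                    paste(unknown, collapse = ", ")), "mass_table_error")
    }
    w <- mass_table[atoms$element]
  } else {
    w <- rep(1, nrow(atoms))
  }
  c(sum(w * atoms$x), sum(w * atoms$y), sum(w * atoms$z)) / sum(w)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R (det = +1; reflections disallowed) and
#' translation t minimising the RMSD between `R %*% mobile + t` and
#' `reference`, with point lists paired by row order.
#'
#' @param reference,mobile n x 3 coordinate matrices, n >= 3,
#'   non-collinear
#' @return a `rigid_transform` with elements `rotation` (3 x 3),
#'   `translation` (3-vector) and `rmsd` (Angstrom)
#' @export
superpose <- function(reference, mobile) {
  P <- as_xyz_matrix(reference)
  Q <- as_xyz_matrix(mobile)
  if (nrow(P) != nrow(Q)) {
    abort(sprintf("point lists differ in length (%d vs %d)", nrow(P), nrow(Q)),
          "pairing_error")
  }
  if (nrow(P) < 3) abort("superposition needs at least 3 point pairs",
                         "degenerate_geometry")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_ref <- svd(Pc)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1)) {
    abort("reference points are collinear", "degenerate_geometry")
  }
  H <- t(Qc) %*% Pc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- cp - as.numeric(R %*% cq)
  moved <- Q %*% t(R) + matrix(t_vec, nrow(Q), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - P)^2)))
  rigid_transform(R, t_vec, rmsd = rmsd)
}

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det +1)
#' @param translation numeric 3-vector
#' @param rmsd optional fit residual to carry along
#' @return a `rigid_transform` object
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0), rmsd = NULL) {
  rotation <- as.matrix(rotation)
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    abort("rotation must be orthonormal with determinant +1", "degenerate_geometry")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates or a StructureModel
#'
#' @param transform a `rigid_transform`
#' @param x an n x 3 matrix, a numeric 3-vector, or a `StructureModel`
#' @return object of the same kind with transformed coordinates
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "StructureModel")) {
    xyz <- as.matrix(x$atoms[, c("x", "y", "z")])
    moved <- apply_transform(transform, xyz)
    x$atoms$x <- moved[, 1]; x$atoms$y <- moved[, 2]; x$atoms$z <- moved[, 3]
    return(x)
  }
  v <- is.null(dim(x))
  m <- as_xyz_matrix(x)
  out <- m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (v) as.numeric(out) else out
}

#' Theoretical average molecular mass of a protein sequence
#'
#' Sum of average residue masses plus one water, reported in kDa to
#' match how construct masses are quoted alongside mass-photometry
#' peaks.
#'
#' @param sequence one-letter amino-acid string (or character vector of
#'   single letters)
#' @return mass in kDa
#' @export
sequence_mass <- function(sequence) {
  letters1 <- if (length(sequence) == 1) {
    strsplit(toupper(gsub("[[:space:]]", "", sequence)), "")[[1]]
  } else toupper(sequence)
  if (length(letters1) == 0) abort("empty sequence", "sequence_error")
  tab <- residue_masses()
  m <- tab$mass[match(letters1, tab$letter)]
  if (anyNA(m)) {
    abort(sprintf("unknown residue letter(s): %s",
                  paste(unique(letters1[is.na(m)]), collapse = ", ")),
          "sequence_error")
  }
  (sum(m) + water_mass) / 1000
}

# deterministic random rotation from a seed-controlled RNG stream
random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    n <- vnorm(q)
    if (n > 1e-6) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
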