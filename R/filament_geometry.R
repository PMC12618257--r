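#' Fit the helical axis of a short nucleated filament
#'
#' Nucleated filaments in the bidirectional assembly are only a few
#' subunits long (Arp2 and Arp3 proto-subunits plus the first actins),
#' too short for a full helix regression, so the axis is taken as the
#' first principal direction of the subunit centers of mass (total
#' least squares), anchored at their centroid.  The direction is
#' oriented from the first to the last subunit of `subunit_sequence`,
#' i.e. pointed (Arp) end to barbed end.
#'
#' @param model a `StructureModel`
#' @param map a [subunit_map()]
#' @param subunit_sequence ordered logical names, pointed to barbed
#'   (>= 3 required)
#' @param weighting COM weighting, `"mass"` or `"geometric"`
#' @return an `axis_fit`: `point`, `direction` (unit 3-vector),
#'   `residual` (RMS perpendicular deviation of the COMs, Angstrom),
#'   `subunits_used`, `coms`
#' @export
fit_axis <- function(model, map, subunit_sequence, weighting = "mass") {
  if (length(subunit_sequence) < 3) {
    abort("axis fit needs at least 3 subunits", "degenerate_geometry")
  }
  coms <- t(vapply(subunit_sequence, function(s) {
    atoms <- select_atoms(model, s, map, "protein_heavy")
    if (nrow(atoms) == 0) {
      abort(sprintf("subunit %s selects no atoms", s), "empty_selection")
    }
    center_of_mass(atoms, weighting)
  }, numeric(3)))
  centroid <- colMeans(coms)
  centered <- sweep(coms, 2, centroid)
  sv <- svd(centered)
  dir <- sv$v[, 1]
  span <- coms[nrow(coms), ] - coms[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  proj <- centered %*% dir
  perp <- centered - proj %*% t(dir)
  residual <- sqrt(mean(rowSums(perp^2)))
  structure(list(point = centroid, direction = as.numeric(dir),
                 residual = residual, subunits_used = subunit_sequence,
                 coms = coms, weighting = weighting),
            class = "axis_fit")
}

#' @export
print.axis_fit <- function(x, ...) {
  cat(sprintf("axis_fit over %d subunits: direction (%.3f, %.3f, %.3f), residual %.2f A\n",
              length(x$subunits_used), x$direction[1], x$direction[2],
              x$direction[3], x$residual))
  invisible(x)
}

#' Angle between two oriented filament axes
#'
#' Uses the oriented (pointed-to-barbed) directions, so 180 degrees
#' means perfectly antiparallel bidirectional growth.
#'
#' @param fit_a,fit_b `axis_fit` objects from [fit_axis()]
#' @return angle in degrees, \[0, 180\]
#' @export
interfilament_angle <- function(fit_a, fit_b) {
  u <- fit_a$direction; v <- fit_b$direction
  atan2(vnorm(cross3(u, v)), sum(u * v)) * 180 / pi
}

#' Screw decomposition of the transform between two filament subunits
#'
#' Superposes subunit i onto subunit j (C-alpha atoms matched by
#' author residue number) and expresses the resulting rigid transform
#' as a rotation (twist) about and translation (rise) along its screw
#' axis.  The axis sign is fixed so the rise is non-negative; the
#' twist keeps its handedness (left-handed actin-like helices give
#' negative twist).
#'
#' @param model a `StructureModel`
#' @param map a [subunit_map()]
#' @param subunit_i,subunit_j logical subunit names (i -> j is the
#'   pointed-to-barbed step)
#' @return a `screw_parameters` list: `rise` (Angstrom per subunit),
#'   `twist` (degrees, in (-180, 180\]), `axis` (unit 3-vector),
#'   `rmsd` of the superposition
#' @export
screw_decompose <- function(model, map, subunit_i, subunit_j) {
  ca_i <- select_atoms(model, subunit_i, map, "calpha")
  ca_j <- select_atoms(model, subunit_j, map, "calpha")
  shared <- intersect(paste(ca_i$resno, ca_i$insert),
                      paste(ca_j$resno, ca_j$insert))
  if (length(shared) < 3) {
    abort(sprintf("subunits %s/%s share only %d C-alpha position(s)",
                  subunit_i, subunit_j, length(shared)), "pairing_error")
  }
  xi <- as.matrix(ca_i[match(shared, paste(ca_i$resno, ca_i$insert)),
                       c("x", "y", "z")])
  xj <- as.matrix(ca_j[match(shared, paste(ca_j$resno, ca_j$insert)),
                       c("x", "y", "z")])
  tr <- superpose(xj, xi)  # maps subunit i onto subunit j
  sp <- screw_from_transform(tr$rotation, tr$translation)
  structure(c(sp, list(rmsd = tr$rmsd, n_matched = length(shared))),
            class = "screw_parameters")
}

# rotation angle/axis + rise along axis from (R, t)
screw_from_transform <- function(R, t_vec) {
  cos_t <- (sum(diag(R)) - 1) / 2
  cos_t <- min(1, max(-1, cos_t))
  theta <- acos(cos_t) * 180 / pi
  if (theta < 1e-4) {
    # pure translation
    rise <- vnorm(t_vec)
    axis <- if (rise > 1e-12) t_vec / rise else c(0, 0, 1)
    return(list(rise = rise, twist = 0, axis = axis))
  }
  if (theta > 180 - 1e-5) {
    # axis from the eigenvector of R with eigenvalue +1
    e <- eigen(R)
    k <- which.min(abs(e$values - 1))
    axis <- Re(e$vectors[, k])
    axis <- axis / vnorm(axis)
    twist <- 180
  } else {
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    axis <- axis / (2 * sin(theta * pi / 180))
    twist <- theta
  }
  rise <- sum(t_vec * axis)
  if (rise < 0) {
    axis <- -axis
    rise <- -rise
    if (twist < 180 - 1e-9) twist <- -twist
  }
  list(rise = rise, twist = wrap_angle(twist), axis = axis)
}

#' @export
print.screw_parameters <- function(x, ...) {
  cat(sprintf("screw: rise %.2f A, twist %.2f deg\n", x$rise, x$twist))
  invisible(x)
}

#' Axis fits and pairwise angles for a set of filaments
#'
#' @param model a `StructureModel`
#' @param maps named list of [subunit_map()]s, one per filament
#' @param subunit_sequence ordered subunit names used for every
#'   filament (default the nucleated-filament proto-subunits plus the
#'   first two actins)
#' @param weighting COM weighting
#' @return list with `fits` (per filament), `axes` (data.frame) and
#'   `angles` (data.frame of pairwise interfilament angles)
#' @export
filament_report <- function(model, maps,
                            subunit_sequence = c("Arp3", "Arp2", "Ac1", "Ac2"),
                            weighting = "mass") {
  fits <- lapply(maps, function(m) fit_axis(model, m, subunit_sequence,
                                            weighting))
  axes <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(filament = nm, dir_x = f$direction[1], dir_y = f$direction[2],
               dir_z = f$direction[3], residual = f$residual,
               stringsAsFactors = FALSE)
  }))
  cmb <- if (length(fits) >= 2) utils::combn(names(fits), 2) else NULL
  angles <- if (!is.null(cmb)) {
    data.frame(filament_a = cmb[1, ], filament_b = cmb[2, ],
               angle_deg = apply(cmb, 2, function(p)
                 interfilament_angle(fits[[p[1]]], fits[[p[2]]])),
               stringsAsFactors = FALSE)
  } else {
    data.frame(filament_a = character(), filament_b = character(),
               angle_deg = numeric(), stringsAsFactors = FALSE)
  }
  list(fits = fits, axes = axes, angles = angles)
}
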