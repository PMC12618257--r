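# Build a StructureModel from row-wise atom specs (internal builder
# for all generators; truth records never come from the modules under
# test, only from the closed-form constructions below)
build_model <- function(rows, identifier) {
  atoms <- do.call(rbind, rows)
  atoms$insert <- atoms$insert %||% ""
  new_structure_model(atoms, identifier, "synthetic")
}

atom_row <- function(chain, resno, resid, elety, element, pos, hetero = FALSE) {
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = resid, elety = elety, element = element,
             x = pos[1], y = pos[2], z = pos[3], o = 1, alt = "",
             hetero = hetero, stringsAsFactors = FALSE)
}

# place p4 so that dihedral(p1,p2,p3,p4) == tau under the package
# convention (independent construction: direct coordinates, no call to
# dihedral())
dihedral_points <- function(tau_deg, bond = 3.8) {
  t_rad <- tau_deg * pi / 180
  list(p1 = c(0, bond, 0), p2 = c(0, 0, 0), p3 = c(bond, 0, 0),
       p4 = c(bond, bond * cos(t_rad), -bond * sin(t_rad)))
}

# place three points with interior angle alpha at the vertex
angle_points <- function(alpha_deg, arm = 5) {
  a_rad <- alpha_deg * pi / 180
  list(p1 = c(arm, 0, 0), p2 = c(0, 0, 0),
       p3 = c(arm * cos(a_rad), arm * sin(a_rad), 0))
}

#' Synthetic anchor-cloud fixture for the conformational metrics
#'
#' Emits a minimal multi-chain structure whose resolved anchors
#' realize requested metric values exactly by construction: an ArpC2 /
#' ArpC4 chain pair carrying the clamp-twist anchors, the ArpC4 bend
#' trio, and an Arp3 chain of four single-atom subdomains (residues
#' 1-4, subdomain scheme 1:1 per residue) realizing the flattening
#' dihedral.
#'
#' @param clamp_dihedral target clamp-twist dihedral in degrees,
#'   (-180, 180]
#' @param bend_angle target bend angle in degrees, (0, 180)
#' @param arp3_dihedral target flattening dihedral in degrees
#' @param identifier model identifier
#' @return list with `model`, `map` ([subunit_map()]), `scheme` (the
#'   single-atom [subdomain_scheme()] for Arp3), and `truth` (the
#'   requested values)
#' @export
make_anchor_cloud <- function(clamp_dihedral = -35, bend_angle = 141,
                              arp3_dihedral = -2.5,
                              identifier = "anchor_cloud") {
  for (v in c(clamp_dihedral, arp3_dihedral)) {
    if (!is.finite(v) || v <= -180 || v > 180) {
      abort("target dihedral must lie in (-180, 180]", "parameter_error")
    }
  }
  if (!is.finite(bend_angle) || bend_angle <= 0 || bend_angle >= 180) {
    abort("target bend angle must lie in (0, 180)", "parameter_error")
  }
  cl <- dihedral_points(clamp_dihedral)
  bd <- angle_points(bend_angle)
  off_b <- c(0, 0, 60)   # keep the bend trio away from the clamp set
  a3 <- dihedral_points(arp3_dihedral)
  off_a <- c(0, 0, 120)
  rows <- list(
    # Arp3: four one-atom subdomains; COM order 2,1,3,4 = residues 1..4
    atom_row("A", 1, "GLY", "CA", "C", a3$p1 + off_a),
    atom_row("A", 2, "GLY", "CA", "C", a3$p2 + off_a),
    atom_row("A", 3, "GLY", "CA", "C", a3$p3 + off_a),
    atom_row("A", 4, "GLY", "CA", "C", a3$p4 + off_a),
    # ArpC2 clamp anchors
    atom_row("B", 18, "LYS", "CA", "C", cl$p1),
    atom_row("B", 244, "ILE", "CA", "C", cl$p2),
    # ArpC4 clamp + bend anchors
    atom_row("D", 147, "SER", "CA", "C", cl$p3),
    atom_row("D", 32, "ARG", "CA", "C", cl$p4),
    atom_row("D", 130, "LYS", "CA", "C", bd$p1 + off_b),
    atom_row("D", 141, "GLU", "CA", "C", bd$p2 + off_b),
    atom_row("D", 163, "GLU", "CA", "C", bd$p3 + off_b)
  )
  model <- build_model(rows, identifier)
  map <- subunit_map(c(Arp3 = "A", ArpC2 = "B", ArpC4 = "D"))
  scheme <- subdomain_scheme("Arp3", list(
    "1" = list(residue_range("Arp3", 2, 2)),
    "2" = list(residue_range("Arp3", 1, 1)),
    "3" = list(residue_range("Arp3", 3, 3)),
    "4" = list(residue_range("Arp3", 4, 4))
  ))
  list(model = model, map = map, scheme = scheme,
       truth = list(clamp_dihedral = clamp_dihedral, bend_angle = bend_angle,
                    arp3_dihedral = arp3_dihedral))
}

# rigid, non-coplanar pseudo-subunit (5 heavy atoms): equal-mass cloud
# with its COM exactly at the origin, atoms spread to ~radius
base_subunit_cloud <- function(radius = 12) {
  raw <- rbind(c(3, 0, 0),
               c(-1, 3, 0.5),
               c(-1, -2, -1),
               c(1, -2, 2.5),
               c(-2, 1.5, -2))
  raw <- sweep(raw, 2, colMeans(raw))
  raw * radius / sqrt(mean(rowSums(raw^2)))
}

screw_matrix <- function(twist_deg) {
  t_rad <- twist_deg * pi / 180
  matrix(c(cos(t_rad), -sin(t_rad), 0,
           sin(t_rad), cos(t_rad), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Synthetic ideal filament with known screw parameters
#'
#' Repeats a rigid five-atom pseudo-subunit by the screw transform
#' (twist about and rise along z), labels the copies Ac1..AcN on
#' consecutive chains, then optionally applies a seeded random rigid
#' transform so tests never rely on an axis-aligned frame.
#'
#' With the default `com_radius = 0` the subunit centers of mass lie
#' exactly on the generator axis, so axis and inter-axis angle
#' recovery are exact by construction; a positive `com_radius` puts
#' the COMs on a helix of that radius (the axis-fit residual then
#' reads the radius).
#'
#' @param rise rise per subunit in Angstrom
#' @param twist twist per subunit in degrees, (-180, 180]
#' @param n_subunits number of subunits (>= 2; >= 3 for axis fitting)
#' @param radius atom spread of the subunit cloud in Angstrom
#' @param com_radius distance of each subunit COM from the axis
#' @param orient logical; apply a random rigid transform (seeded via
#'   `seed`)
#' @param seed integer seed for the orientation
#' @param identifier model identifier
#' @param chain_offset first chain id index (to combine filaments in
#'   one model)
#' @return list with `model`, `map`, `subunits` (names in order),
#'   `truth` (`rise`, `twist`, `axis_direction` after orientation,
#'   `radius`)
#' @export
make_filament <- function(rise = 27.5, twist = -166.7, n_subunits = 8,
                          radius = 12, com_radius = 0, orient = FALSE,
                          seed = 1, identifier = "ideal_filament",
                          chain_offset = 0) {
  if (n_subunits < 2) abort("need at least 2 subunits", "parameter_error")
  if (abs(rise) < 1e-9 && abs(twist) < 1e-9) {
    abort("zero rise with zero twist gives coincident subunits",
          "parameter_error")
  }
  base <- sweep(base_subunit_cloud(radius), 2, c(com_radius, 0, 0), "+")
  Rz <- screw_matrix(twist)
  chains <- c(LETTERS, letters)[chain_offset + seq_len(n_subunits)]
  rot <- diag(3); shift <- c(0, 0, 0)
  if (orient) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    rot <- random_rotation()
    shift <- stats::runif(3, -50, 50)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  rows <- list()
  xyz <- base
  for (k in seq_len(n_subunits)) {
    placed <- xyz %*% t(rot) + matrix(shift, nrow(xyz), 3, byrow = TRUE)
    for (r in seq_len(nrow(placed))) {
      rows[[length(rows) + 1]] <- atom_row(chains[k], r, "GLY", "CA", "C",
                                           placed[r, ])
    }
    xyz <- xyz %*% t(Rz) + matrix(c(0, 0, rise), nrow(xyz), 3, byrow = TRUE)
  }
  model <- build_model(rows, identifier)
  subunits <- paste0("Ac", seq_len(n_subunits))
  map <- subunit_map(stats::setNames(chains, subunits))
  axis_dir <- as.numeric(rot %*% c(0, 0, sign(rise)))
  list(model = model, map = map, subunits = subunits,
       truth = list(rise = abs(rise), twist = wrap_angle(twist),
                    axis_direction = axis_dir, radius = radius,
                    com_radius = com_radius))
}

#' Pair of synthetic filaments at a prescribed inter-axis angle
#'
#' Builds two ideal filaments whose oriented axes enclose exactly the
#' requested angle: the first grows along +z, the second along the
#' direction obtained by rotating +z by `angle` about y, offset
#' laterally so the filaments do not overlap.
#'
#' @param angle inter-axis angle in degrees, \[0, 180\]
#' @param rise,twist,n_subunits,radius as in [make_filament()]
#' @param separation lateral offset of the second filament in Angstrom
#' @return list with `model` (both filaments in one file), `map_a`,
#'   `map_b`, `subunits`, and `truth$angle`
#' @export
make_filament_pair <- function(angle = 165, rise = 27.5, twist = -166.7,
                               n_subunits = 4, radius = 12,
                               separation = 80) {
  if (angle < 0 || angle > 180) {
    abort("inter-axis angle must lie in [0, 180]", "parameter_error")
  }
  fa <- make_filament(rise, twist, n_subunits, radius,
                      identifier = "pair_a", chain_offset = 0)
  fb <- make_filament(rise, twist, n_subunits, radius,
                      identifier = "pair_b", chain_offset = n_subunits)
  g <- angle * pi / 180
  rot_y <- matrix(c(cos(g), 0, sin(g), 0, 1, 0, -sin(g), 0, cos(g)),
                  3, 3, byrow = TRUE)
  tb <- rigid_transform(rot_y, c(separation, 0, 0))
  mb <- apply_transform(tb, fb$model)
  model <- build_model(list(fa$model$atoms, mb$atoms), "filament_pair")
  list(model = model, map_a = fa$map, map_b = fb$map,
       subunits = fa$subunits, truth = list(angle = angle, rise = abs(rise),
                                            twist = wrap_angle(twist)))
}

#' Two-sphere fixture with analytic SASA ground truth
#'
#' Two single-atom "chains" at a given separation; the ground truth is
#' computed by the closed-form spherical-cap formula for the expanded
#' (van der Waals + probe) spheres, independently of the quadrature
#' code under test.
#'
#' @param d center separation in Angstrom (>= 0)
#' @param elements two element symbols (radii from the active set)
#' @param params a [sasa_params()] (probe radius and radius set feed
#'   the ground truth)
#' @return list with `model`, `map` (chains A and B as `Ac1`, `Ac2`),
#'   and `truth` (`sasa_a`, `sasa_b`, `sasa_union`, `buried`)
#' @export
make_sphere_fixture <- function(d = 3, elements = c("C", "C"),
                                params = sasa_params()) {
  if (d < 0) abort("separation must be non-negative", "parameter_error")
  radii <- vdw_radii(params$radii_set)
  R1 <- radii[[elements[1]]] + params$probe_radius
  R2 <- radii[[elements[2]]] + params$probe_radius
  rows <- list(
    atom_row("A", 1, "UNK", elements[1], elements[1], c(0, 0, 0)),
    atom_row("B", 1, "UNK", elements[2], elements[2], c(d, 0, 0))
  )
  model <- build_model(rows, "sphere_pair")
  acc <- two_sphere_sasa(R1, R2, d)
  full <- list(a1 = 4 * pi * R1^2, a2 = 4 * pi * R2^2)
  truth <- list(sasa_a = full$a1, sasa_b = full$a2,
                sasa_union = acc$a1 + acc$a2,
                buried = (full$a1 + full$a2 - acc$a1 - acc$a2) / 2)
  list(model = model, map = subunit_map(c(Ac1 = "A", Ac2 = "B")),
       truth = truth)
}

#' Caged-atom fixture: a central atom fully enclosed by a shell
#'
#' @param n_shell number of shell atoms (Fibonacci-distributed)
#' @param shell_distance center-to-shell distance in Angstrom (small
#'   enough that the shell occludes the whole central surface)
#' @return list with `model` and `center_index` (row of the caged atom)
#' @export
make_cage <- function(n_shell = 80, shell_distance = 0.8) {
  pts <- fibonacci_sphere(n_shell) * shell_distance
  rows <- c(list(atom_row("A", 1, "UNK", "C", "C", c(0, 0, 0))),
            lapply(seq_len(n_shell), function(i)
              atom_row("B", i, "UNK", "C", "C", pts[i, ])))
  list(model = build_model(rows, "cage"), center_index = 1L)
}

#' Miniature C2 toy complex with full ground truth
#'
#' A reduced bidirectional assembly: one half holds an anchor cloud
#' (Arp3 four-point subdomains, ArpC2/ArpC4 clamp and bend anchors)
#' and a short nucleated filament tilted so that the C2-related
#' filaments enclose the requested interfilament angle; the second
#' half is the exact C2 image (rotation by 180 degrees about z).  The
#' whole assembly is then placed in a seeded random orientation.
#' Every metric the pipeline reports is recorded as ground truth from
#' the construction parameters alone.
#'
#' @param clamp_dihedral,bend_angle,arp3_dihedral anchor-cloud targets
#'   (degrees)
#' @param interfilament_angle angle between the two oriented filament
#'   axes (degrees)
#' @param rise,twist filament screw parameters
#' @param n_subunits filament length (subunits per side)
#' @param seed integer seed for the global orientation
#' @return list with `model`, `maps` (per copy), `filament_maps` (per
#'   copy), `scheme`, `subunits`, and `truth`
#' @export
make_toy_complex <- function(clamp_dihedral = -35, bend_angle = 141,
                             arp3_dihedral = -2.5,
                             interfilament_angle = 163.5,
                             rise = 27.5, twist = -166.7, n_subunits = 4,
                             seed = 1) {
  half <- make_anchor_cloud(clamp_dihedral, bend_angle, arp3_dihedral)
  beta <- interfilament_angle / 2 * pi / 180
  fil <- make_filament(rise, twist, n_subunits, identifier = "fil",
                       chain_offset = 4)   # chains E..H
  # tilt the filament axis (initially +z) to beta off +z in the xz
  # plane; the C2 rotation about z then maps it to -beta, giving an
  # oriented inter-axis angle of exactly 2*beta
  tilt <- matrix(c(cos(beta), 0, sin(beta), 0, 1, 0,
                   -sin(beta), 0, cos(beta)), 3, 3, byrow = TRUE)
  fil_m <- apply_transform(rigid_transform(tilt, c(90, 0, 0)), fil$model)
  copy1 <- build_model(list(half$model$atoms, fil_m$atoms), "toy")
  c2 <- rigid_transform(diag(c(-1, -1, 1)), c(0, 0, 0))
  copy2_atoms <- apply_transform(c2, copy1)$atoms
  n_ch <- 4 + n_subunits
  lower_ids <- letters[seq_len(n_ch)]
  copy2_atoms$chain <- lower_ids[match(copy2_atoms$chain,
                                       c("A", "B", "D", LETTERS[5:(4 + n_subunits)]))]
  model <- build_model(list(copy1$atoms, copy2_atoms), "toy_complex")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  glob <- rigid_transform(random_rotation(), stats::runif(3, -20, 20))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  model <- apply_transform(glob, model)
  fil_chains1 <- LETTERS[5:(4 + n_subunits)]
  fil_chains2 <- letters[3 + seq_len(n_subunits)]
  subunits <- paste0("Ac", seq_len(n_subunits))
  maps <- list(
    copy1 = subunit_map(c(Arp3 = "A", ArpC2 = "B", ArpC4 = "D",
                          stats::setNames(fil_chains1, subunits)),
                        copy_label = "copy1"),
    copy2 = subunit_map(c(Arp3 = "a", ArpC2 = "b", ArpC4 = "c",
                          stats::setNames(fil_chains2, subunits)),
                        copy_label = "copy2")
  )
  list(model = model, maps = maps, scheme = half$scheme, subunits = subunits,
       truth = list(clamp_dihedral = clamp_dihedral, bend_angle = bend_angle,
                    arp3_dihedral = arp3_dihedral,
                    interfilament_angle = interfilament_angle,
                    rise = abs(rise), twist = wrap_angle(twist),
                    n_subunits = n_subunits, seed = seed))
}
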