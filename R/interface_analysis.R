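#' Parameters for solvent-accessible surface area
#'
#' @param probe_radius probe sphere radius in Angstrom (water, 1.4)
#' @param points_per_atom quadrature points per atom (>= 92); the point
#'   set is a deterministic Fibonacci spiral, so results are
#'   bit-reproducible at fixed parameters
#' @param radii_set name of the van der Waals radius set (see
#'   [vdw_radii()])
#' @param include_hetero include hetero atoms (ions, nucleotides,
#'   ligands) in the calculation; off by default because the package's
#'   interface metrics are defined between protein subunits
#' @return a `sasa_params` object
#' @export
sasa_params <- function(probe_radius = 1.4, points_per_atom = 960,
                        radii_set = "protor", include_hetero = FALSE) {
  if (probe_radius <= 0) abort("probe_radius must be positive", "config_error")
  if (points_per_atom < 92) abort("points_per_atom must be >= 92", "config_error")
  structure(list(probe_radius = probe_radius,
                 points_per_atom = as.integer(points_per_atom),
                 radii_set = radii_set, include_hetero = include_hetero),
            class = "sasa_params")
}

# Deterministic quasi-uniform unit-sphere point set (Fibonacci spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the van der Waals spheres of the supplied
#' atoms by testing a deterministic spiral point set on each expanded
#' sphere against all neighbouring expanded spheres.  Surface points
#' that fall exactly on a neighbour's expanded sphere (coincident
#' atoms) are kept by the lower-indexed atom, so a degenerate union
#' surface is counted once.
#'
#' @param atoms data.frame of atom records; the caller chooses the
#'   selection (the interface functions use heavy protein atoms)
#' @param params a [sasa_params()]
#' @return list with `total` (Angstrom^2) and `per_atom` (numeric
#'   vector, same order as `atoms`)
#' @export
sasa <- function(atoms, params = sasa_params()) {
  if (is.null(atoms) || nrow(atoms) == 0) {
    abort("empty selection: no atoms for SASA", "empty_selection")
  }
  radii <- vdw_radii(params$radii_set)
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown)) {
    abort(sprintf("no van der Waals radius for element(s): %s",
                  paste(unknown, collapse = ", ")), "radii_error")
  }
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- radii[atoms$element] + params$probe_radius
  pts <- fibonacci_sphere(params$points_per_atom)
  tol <- 1e-9
  per_atom <- numeric(n)
  max_reach <- max(R)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + max_reach)^2)
    nb <- nb[nb != i]
    nb <- nb[sqrt(d2[nb]) < R[i] + R[nb]]
    if (length(nb) == 0) {
      per_atom[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, params$points_per_atom)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(p[acc, , drop = FALSE], 2, xyz[j, ])^2)
      dj <- sqrt(dj2)
      occl <- dj < R[j] - tol | (abs(dj - R[j]) <= tol & j < i)
      acc[acc] <- !occl
    }
    per_atom[i] <- 4 * pi * R[i]^2 * sum(acc) / params$points_per_atom
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

side_atoms <- function(model, map, side, params) {
  filt <- if (isTRUE(params$include_hetero)) "heavy" else "protein_heavy"
  select_atoms(model, side, map, atom_filter = filt)
}

check_disjoint <- function(model, map, side_a, side_b) {
  ch_a <- vapply(side_a, function(s) map_chain(map, s, model), "")
  ch_b <- vapply(side_b, function(s) map_chain(map, s, model), "")
  both <- intersect(ch_a, ch_b)
  if (length(both)) {
    abort(sprintf("interface sides overlap on chain(s): %s",
                  paste(both, collapse = ", ")), "disjointness_error")
  }
}

#' Buried surface area between two subunit sets
#'
#' Computes `(SASA(A) + SASA(B) - SASA(A u B)) / 2`: half the solvent-
#' accessible area lost on complex formation, the convention in which
#' single protein-protein interfaces of this size read in the high
#' hundreds of Angstrom^2.  The full (unhalved) loss is attached for
#' transparency.
#'
#' @param model a `StructureModel`
#' @param map a [subunit_map()]
#' @param side_a,side_b disjoint character vectors of logical subunit
#'   names (or lists of [residue_range()]s on disjoint chains)
#' @param params a [sasa_params()]
#' @return numeric buried area in Angstrom^2 with attributes
#'   `full_loss`, `sasa_a`, `sasa_b`, `sasa_ab`, `radii_set`
#' @export
buried_area <- function(model, map, side_a, side_b, params = sasa_params()) {
  if (is.character(side_a) && is.character(side_b)) {
    check_disjoint(model, map, side_a, side_b)
  }
  at_a <- side_atoms(model, map, side_a, params)
  at_b <- side_atoms(model, map, side_b, params)
  if (nrow(at_a) == 0 || nrow(at_b) == 0) {
    abort("one interface side selects no atoms", "empty_selection")
  }
  s_a <- sasa(at_a, params)$total
  s_b <- sasa(at_b, params)$total
  s_ab <- sasa(rbind(at_a, at_b), params)$total
  loss <- s_a + s_b - s_ab
  structure(loss / 2, full_loss = loss, sasa_a = s_a, sasa_b = s_b,
            sasa_ab = s_ab, radii_set = params$radii_set)
}

#' Contact classification rules
#'
#' Distance thresholds for the interface definitions: 5 A heavy-atom
#' interface membership, 4 A charged-group salt bridges (Asp/Glu
#' carboxylate vs Lys/Arg/His nitrogen), 3.5 A donor/acceptor
#' heavy-atom hydrogen bonds (distance-only: the criterion is applied
#' to models built into ~3 A maps where hydrogens are unresolved), and
#' 4.5 A carbon-carbon contacts between apolar residues.
#'
#' @param interface_cutoff,salt_bridge_cutoff,hbond_cutoff,hydrophobic_cutoff
#'   distances in Angstrom
#' @param hydrophobic_residues residue names treated as apolar
#' @return a `contact_rules` object
#' @export
contact_rules <- function(interface_cutoff = 5.0, salt_bridge_cutoff = 4.0,
                          hbond_cutoff = 3.5, hydrophobic_cutoff = 4.5,
                          hydrophobic_residues = c("ALA", "VAL", "LEU", "ILE",
                                                   "MET", "PHE", "TRP", "PRO")) {
  cuts <- c(interface_cutoff, salt_bridge_cutoff, hbond_cutoff,
            hydrophobic_cutoff)
  if (any(cuts <= 0)) abort("all cutoffs must be positive", "config_error")
  structure(list(interface_cutoff = interface_cutoff,
                 salt_bridge_cutoff = salt_bridge_cutoff,
                 hbond_cutoff = hbond_cutoff,
                 hydrophobic_cutoff = hydrophobic_cutoff,
                 hydrophobic_residues = hydrophobic_residues),
            class = "contact_rules")
}

# charged side-chain atoms carrying formal charge
acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
basic_atoms <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))

is_charged <- function(resid, elety, table) {
  mapply(function(r, e) r %in% names(table) && e %in% table[[r]], resid, elety)
}

cross_pairs <- function(at_a, at_b, cutoff) {
  # all heavy-atom pairs across the interface within cutoff
  xa <- as.matrix(at_a[, c("x", "y", "z")])
  xb <- as.matrix(at_b[, c("x", "y", "z")])
  out <- vector("list", nrow(xa))
  for (i in seq_len(nrow(xa))) {
    d2 <- rowSums(sweep(xb, 2, xa[i, ])^2)
    hit <- which(d2 <= cutoff^2)
    if (length(hit)) out[[i]] <- data.frame(ia = i, ib = hit,
                                            dist = sqrt(d2[hit]))
  }
  do.call(rbind, out)
}

#' Interface residues within a distance cutoff
#'
#' A residue belongs to the interface iff any of its heavy atoms lies
#' within `rules$interface_cutoff` (default 5 A) of a heavy atom on
#' the other side; each listed residue is annotated with its minimum
#' cross-side distance.
#'
#' @inheritParams buried_area
#' @param rules a [contact_rules()]
#' @return list with data.frames `a` and `b` (columns `chain`, `resno`,
#'   `insert`, `resid`, `min_dist`)
#' @export
interface_residues <- function(model, map, side_a, side_b,
                               rules = contact_rules(),
                               params = sasa_params()) {
  if (is.character(side_a) && is.character(side_b)) {
    check_disjoint(model, map, side_a, side_b)
  }
  at_a <- side_atoms(model, map, side_a, params)
  at_b <- side_atoms(model, map, side_b, params)
  pr <- cross_pairs(at_a, at_b, rules$interface_cutoff)
  res_list <- function(at, idx, dist) {
    if (length(idx) == 0) {
      return(data.frame(chain = character(), resno = integer(),
                        insert = character(), resid = character(),
                        min_dist = numeric(), stringsAsFactors = FALSE))
    }
    key <- paste(at$chain[idx], at$resno[idx], at$insert[idx])
    agg <- tapply(dist, key, min)
    first <- idx[!duplicated(key)]
    ord_key <- key[!duplicated(key)]
    out <- data.frame(chain = at$chain[first], resno = at$resno[first],
                      insert = at$insert[first], resid = at$resid[first],
                      min_dist = as.numeric(agg[ord_key]),
                      stringsAsFactors = FALSE)
    out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  }
  if (is.null(pr)) pr <- data.frame(ia = integer(), ib = integer(),
                                    dist = numeric())
  list(a = res_list(at_a, pr$ia, pr$dist), b = res_list(at_b, pr$ib, pr$dist))
}

#' Classify cross-interface atomic contacts
#'
#' Every heavy-atom pair within the interface cutoff is labelled by the
#' first matching rule in priority order salt_bridge > hbond >
#' hydrophobic > other.
#'
#' @inheritParams interface_residues
#' @return data.frame of contacts (`chain_a`, `resno_a`, `resid_a`,
#'   `atom_a`, likewise `_b`, `dist`, `class`) with a `counts`
#'   attribute (per-class totals)
#' @export
classify_contacts <- function(model, map, side_a, side_b,
                              rules = contact_rules(),
                              params = sasa_params()) {
  if (is.character(side_a) && is.character(side_b)) {
    check_disjoint(model, map, side_a, side_b)
  }
  at_a <- side_atoms(model, map, side_a, params)
  at_b <- side_atoms(model, map, side_b, params)
  pr <- cross_pairs(at_a, at_b, rules$interface_cutoff)
  if (is.null(pr) || nrow(pr) == 0) {
    out <- data.frame(chain_a = character(), resno_a = integer(),
                      resid_a = character(), atom_a = character(),
                      chain_b = character(), resno_b = integer(),
                      resid_b = character(), atom_b = character(),
                      dist = numeric(), class = character(),
                      stringsAsFactors = FALSE)
    attr(out, "counts") <- c(salt_bridge = 0L, hbond = 0L, hydrophobic = 0L,
                             other = 0L)
    return(out)
  }
  a <- at_a[pr$ia, ]; b <- at_b[pr$ib, ]
  acid_a <- is_charged(a$resid, a$elety, acidic_atoms)
  base_a <- is_charged(a$resid, a$elety, basic_atoms)
  acid_b <- is_charged(b$resid, b$elety, acidic_atoms)
  base_b <- is_charged(b$resid, b$elety, basic_atoms)
  salt <- pr$dist <= rules$salt_bridge_cutoff &
    ((acid_a & base_b) | (base_a & acid_b))
  dono <- c("N", "O", "S")
  hb <- pr$dist <= rules$hbond_cutoff &
    a$element %in% dono & b$element %in% dono
  hyd <- pr$dist <= rules$hydrophobic_cutoff &
    a$element == "C" & b$element == "C" &
    a$resid %in% rules$hydrophobic_residues &
    b$resid %in% rules$hydrophobic_residues
  cls <- ifelse(salt, "salt_bridge",
                ifelse(hb, "hbond", ifelse(hyd, "hydrophobic", "other")))
  out <- data.frame(chain_a = a$chain, resno_a = a$resno, resid_a = a$resid,
                    atom_a = a$elety, chain_b = b$chain, resno_b = b$resno,
                    resid_b = b$resid, atom_b = b$elety, dist = pr$dist,
                    class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$resno_a, out$atom_a, out$chain_b,
                   out$resno_b, out$atom_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- vapply(c("salt_bridge", "hbond", "hydrophobic",
                                  "other"),
                                function(k) sum(cls == k), integer(1))
  out
}

#' Buried-area table over a list of subunit-pair interfaces
#'
#' One row per defined pair: buried area, interface residue counts and
#' contact class counts.  A failing pair (e.g. a disjointness
#' violation) is recorded as a flagged row and the run continues.
#'
#' @param model a `StructureModel`
#' @param map a [subunit_map()]
#' @param pair_list named list; each element is
#'   `list(a = <subunit set>, b = <subunit set>)`
#' @param params a [sasa_params()]
#' @param rules a [contact_rules()]
#' @return data.frame with one row per pair
#' @export
interface_table <- function(model, map, pair_list, params = sasa_params(),
                            rules = contact_rules()) {
  if (length(pair_list) == 0) {
    return(data.frame(pair = character(), buried_area = numeric(),
                      full_sasa_loss = numeric(), n_res_a = integer(),
                      n_res_b = integer(), n_salt_bridge = integer(),
                      n_hbond = integer(), n_hydrophobic = integer(),
                      n_other = integer(), error = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(names(pair_list))) {
    names(pair_list) <- vapply(pair_list, function(p)
      paste(paste(p$a, collapse = "+"), paste(p$b, collapse = "+"),
            sep = "--"), "")
  }
  rows <- lapply(names(pair_list), function(nm) {
    p <- pair_list[[nm]]
    tryCatch({
      ba <- buried_area(model, map, p$a, p$b, params)
      ir <- interface_residues(model, map, p$a, p$b, rules, params)
      cc <- classify_contacts(model, map, p$a, p$b, rules, params)
      ct <- attr(cc, "counts")
      data.frame(pair = nm, buried_area = as.numeric(ba),
                 full_sasa_loss = attr(ba, "full_loss"),
                 n_res_a = nrow(ir$a), n_res_b = nrow(ir$b),
                 n_salt_bridge = ct[["salt_bridge"]], n_hbond = ct[["hbond"]],
                 n_hydrophobic = ct[["hydrophobic"]], n_other = ct[["other"]],
                 error = "", stringsAsFactors = FALSE)
    }, arpgeom_error = function(e) {
      data.frame(pair = nm, buried_area = NA_real_, full_sasa_loss = NA_real_,
                 n_res_a = NA_integer_, n_res_b = NA_integer_,
                 n_salt_bridge = NA_integer_, n_hbond = NA_integer_,
                 n_hydrophobic = NA_integer_, n_other = NA_integer_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Closed-form accessible areas for two spheres (expanded radii R1, R2
# at center distance d): the independent oracle for the quadrature.
two_sphere_sasa <- function(R1, R2, d) {
  full1 <- 4 * pi * R1^2
  full2 <- 4 * pi * R2^2
  if (d >= R1 + R2) return(list(a1 = full1, a2 = full2))
  if (d < 1e-12 && abs(R1 - R2) < 1e-12) {
    # coincident identical spheres: the union surface counts once
    return(list(a1 = full1, a2 = 0))
  }
  if (d + R1 <= R2) return(list(a1 = 0, a2 = full2))
  if (d + R2 <= R1) return(list(a1 = full1, a2 = 0))
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x1
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  list(a1 = full1 - 2 * pi * R1 * h1, a2 = full2 - 2 * pi * R2 * h2)
}
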