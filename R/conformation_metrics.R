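#' Anchor sets for the activation-state metrics
#'
#' Reads the shipped anchor configuration: the ArpC2/ArpC4 clamp-twist
#' dihedral anchors (human numbering, plus the alternate metazoan
#' ArpC2 numbering) and the ArpC4 hinge-helix bend anchors.  Anchors
#' are data, not code; pass a custom file to analyse species with
#' different numbering.
#'
#' @param path optional path to an anchors YAML file; defaults to the
#'   shipped configuration
#' @return nested list: `clamp_twist$<set>` and `arpc4_bend$default`,
#'   each a list of anchors with fields `subunit`, `resno`, `resid`,
#'   `atom`
#' @export
anchor_sets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "config", "anchors.yaml",
                                package = "arpgeom", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' Subdomain residue-range scheme for an actin-fold subunit
#'
#' @param subunit logical subunit name the scheme applies to
#' @param ranges named list `"1".."4"`, each a list of
#'   [residue_range()]s (possibly discontinuous)
#' @return a `subdomain_scheme` object
#' @export
subdomain_scheme <- function(subunit, ranges) {
  if (!setequal(names(ranges), c("1", "2", "3", "4"))) {
    abort("subdomain scheme needs ranges for subdomains 1..4", "config_error")
  }
  structure(list(subunit = subunit, ranges = ranges),
            class = "subdomain_scheme")
}

#' Default subdomain scheme from the shipped configuration
#'
#' The shipped ranges follow the conventional actin-fold subdomain
#' division mapped onto each subunit; they are stored as editable data
#' because published boundaries vary between authors.
#'
#' @param subunit `"Arp3"`, `"Arp2"` or `"actin"`
#' @param path optional alternative YAML file
#' @return a [subdomain_scheme()]
#' @export
default_subdomain_scheme <- function(subunit = "Arp3", path = NULL) {
  path <- path %||% system.file("extdata", "config", "subdomains.yaml",
                                package = "arpgeom", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  key <- if (grepl("^Ac[0-9]+$|^MA[0-9]+$|^actin$", subunit)) "actin" else subunit
  if (is.null(cfg[[key]])) {
    abort(sprintf("no subdomain scheme for '%s' in %s", subunit, path),
          "config_error")
  }
  ranges <- lapply(cfg[[key]], function(sd) {
    lapply(sd, function(se) residue_range(subunit, se[[1]], se[[2]]))
  })
  subdomain_scheme(subunit, ranges)
}

metric_result <- function(name, value, anchors, weighting, model, warnings = character(),
                          extra = list()) {
  structure(c(list(metric = name, value = value, anchors = anchors,
                   weighting = weighting, structure = model$identifier,
                   warnings = warnings), extra),
            class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s [%s]: %.2f deg (%s)\n", x$metric, x$structure, x$value,
              x$weighting %||% "anchor"))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Actin-fold flattening dihedral over subdomain centers of mass
#'
#' The activation state of an actin-fold subunit (Arp2, Arp3, or an
#' actin protomer) is quantified as the signed dihedral over the
#' centers of mass of its four subdomains taken in the order 2, 1, 3,
#' 4.  Near 0 the two lobes are coplanar ("flattened", the
#' filament-like active state); more negative values indicate the
#' twisted inactive state.
#'
#' @param model a `StructureModel`
#' @param map a [subunit_map()]
#' @param subunit subunit to measure (default `"Arp3"`)
#' @param scheme a [subdomain_scheme()]; defaults to the shipped scheme
#'   for `subunit`
#' @param weighting `"mass"` (default) or `"geometric"` centers
#' @return a `metric_result`; `$value` in degrees, `$atom_counts` the
#'   per-subdomain atom counts used
#' @export
arp_flattening_dihedral <- function(model, map, subunit = "Arp3",
                                    scheme = default_subdomain_scheme(subunit),
                                    weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  coms <- list(); counts <- integer(4)
  for (i in 1:4) {
    sd <- as.character(i)
    ranges <- lapply(scheme$ranges[[sd]], function(rr) {
      residue_range(subunit, rr$start, rr$end)
    })
    atoms <- select_atoms(model, ranges, map, atom_filter = "protein_heavy")
    if (nrow(atoms) == 0) {
      abort(sprintf("subdomain %s of %s selects no atoms (ranges: %s)", sd,
                    subunit, paste(vapply(ranges, function(r)
                      sprintf("%d-%d", r$start, r$end), ""), collapse = ",")),
            "empty_selection")
    }
    counts[i] <- nrow(atoms)
    coms[[sd]] <- center_of_mass(atoms, weighting)
  }
  val <- dihedral(coms[["2"]], coms[["1"]], coms[["3"]], coms[["4"]])
  metric_result(paste0(subunit, "_flattening_dihedral"), val,
                anchors = do.call(rbind, coms[c("2", "1", "3", "4")]),
                weighting = weighting, model = model,
                extra = list(atom_counts = counts, subunit = subunit))
}

resolve_anchor_list <- function(model, map, anchors, permissive = FALSE) {
  t(vapply(anchors, function(an) {
    resolve_anchor(model, map, an$subunit, an$resno, an$resid %||% NA,
                   an$atom %||% "CA", permissive = permissive)
  }, numeric(3)))
}

#' Clamp-twist dihedral across the ArpC2/ArpC4 clamp
#'
#' Signed dihedral over four identity-checked C-alpha anchors spanning
#' ArpC2 and ArpC4, reporting the hinge rotation of the clamp that
#' accompanies Arp2/3 activation.
#'
#' @param model a `StructureModel`
#' @param map a [subunit_map()]
#' @param anchor_set `"human"`, `"metazoan_alt"`, or `"custom"` (then
#'   supply `anchors`)
#' @param anchors custom ordered list of 4 anchors (fields `subunit`,
#'   `resno`, `resid`, `atom`)
#' @param permissive downgrade anchor identity mismatches to warnings
#' @return a `metric_result` with `$value` in degrees
#' @export
clamp_twist_dihedral <- function(model, map, anchor_set = "human",
                                 anchors = NULL, permissive = FALSE) {
  if (is.null(anchors)) {
    sets <- anchor_sets()$clamp_twist
    if (!anchor_set %in% names(sets)) {
      abort(sprintf("unknown clamp anchor set '%s'", anchor_set), "config_error")
    }
    anchors <- sets[[anchor_set]]
  }
  if (length(anchors) != 4) abort("clamp-twist needs 4 anchors", "config_error")
  pos <- resolve_anchor_list(model, map, anchors, permissive)
  val <- dihedral(pos[1, ], pos[2, ], pos[3, ], pos[4, ])
  metric_result("clamp_twist_dihedral", val, anchors = pos,
                weighting = "anchor", model = model,
                extra = list(anchor_set = anchor_set))
}

#' ArpC4 hinge-helix bend angle
#'
#' Interior angle at the GLU141 C-alpha between the LYS130 and GLU163
#' C-alpha positions of ArpC4; a straight hinge helix reads near 180
#' degrees and activation-associated bending lowers it.
#'
#' @inheritParams clamp_twist_dihedral
#' @param anchors optional custom list of 3 anchors
#' @return a `metric_result` with `$value` in degrees (0-180)
#' @export
arpc4_bend_angle <- function(model, map, anchors = NULL, permissive = FALSE) {
  anchors <- anchors %||% anchor_sets()$arpc4_bend$default
  if (length(anchors) != 3) abort("bend angle needs 3 anchors", "config_error")
  pos <- resolve_anchor_list(model, map, anchors, permissive)
  val <- angle3(pos[1, ], pos[2, ], pos[3, ])
  metric_result("arpc4_bend_angle", val, anchors = pos,
                weighting = "anchor", model = model)
}

#' Superpose two models over a restricted residue range
#'
#' Pairs C-alpha atoms by author residue number within the range on
#' the mapped subunit of each model (e.g. ArpC4 residues 2-141),
#' superposes on the shared residues, and returns the mobile model
#' transformed into the reference frame.  Residues present in only one
#' model are dropped and counted.
#'
#' @param reference_model,mobile_model `StructureModel`s
#' @param reference_map,mobile_map [subunit_map()]s for each model
#' @param range a [residue_range()] naming the subunit and residue span
#' @return list with `transform` (`rigid_transform`), `rmsd`,
#'   `mobile_transformed` (a `StructureModel`), `n_pairs`, `n_dropped`
#' @export
align_states <- function(reference_model, mobile_model, reference_map,
                         mobile_map, range = residue_range("ArpC4", 2, 141)) {
  ca_ref <- select_atoms(reference_model, range, reference_map, "calpha")
  rr_mob <- residue_range(range$subunit, range$start, range$end)
  ca_mob <- select_atoms(mobile_model, rr_mob, mobile_map, "calpha")
  shared <- intersect(paste(ca_ref$resno, ca_ref$insert),
                      paste(ca_mob$resno, ca_mob$insert))
  if (length(shared) < 3) {
    abort(sprintf("only %d shared C-alpha position(s) in range %d-%d",
                  length(shared), range$start, range$end), "pairing_error")
  }
  ref_xyz <- as.matrix(ca_ref[match(shared, paste(ca_ref$resno, ca_ref$insert)),
                              c("x", "y", "z")])
  mob_xyz <- as.matrix(ca_mob[match(shared, paste(ca_mob$resno, ca_mob$insert)),
                              c("x", "y", "z")])
  tr <- superpose(ref_xyz, mob_xyz)
  n_drop <- (nrow(ca_ref) - length(shared)) + (nrow(ca_mob) - length(shared))
  list(transform = tr, rmsd = tr$rmsd,
       mobile_transformed = apply_transform(tr, mobile_model),
       n_pairs = length(shared), n_dropped = n_drop)
}

#' Activation-state metrics table over a set of structures
#'
#' Computes the requested metrics for every (structure, map) pair and
#' returns one row per structure x metric, with failures recorded as
#' flagged rows rather than aborting the run.  The table is the input
#' for a clamp-twist vs flattening scatter across published states.
#'
#' @param models list of `StructureModel`s
#' @param maps list of [subunit_map()]s, parallel to `models` (or one
#'   map recycled)
#' @param metrics character subset of `c("arp3_flattening",
#'   "arp2_flattening", "clamp_twist", "arpc4_bend")`
#' @param anchor_set clamp anchor set per structure (recycled)
#' @param weighting COM weighting for flattening dihedrals
#' @param scheme optional [subdomain_scheme()] for the flattening
#'   metrics (else the shipped default per subunit)
#' @param scheme_file optional YAML file the default schemes are read
#'   from
#' @param permissive passed to anchor resolution
#' @return data.frame with columns `structure`, `copy`, `metric`,
#'   `value_deg`, `weighting`, `anchor_set`, `error`
#' @export
metrics_table <- function(models, maps,
                          metrics = c("arp3_flattening", "clamp_twist",
                                      "arpc4_bend"),
                          anchor_set = "human",
                          weighting = "mass", scheme = NULL,
                          scheme_file = NULL, permissive = FALSE) {
  if (inherits(models, "StructureModel")) models <- list(models)
  if (inherits(maps, "subunit_map")) maps <- list(maps)
  if (length(maps) == 1) maps <- rep(maps, length(models))
  anchor_set <- rep(anchor_set, length.out = length(models))
  rows <- list()
  for (i in seq_along(models)) {
    for (met in metrics) {
      res <- tryCatch({
        r <- switch(met,
          arp3_flattening = arp_flattening_dihedral(
            models[[i]], maps[[i]], "Arp3",
            scheme = scheme %||% default_subdomain_scheme("Arp3", scheme_file),
            weighting = weighting),
          arp2_flattening = arp_flattening_dihedral(
            models[[i]], maps[[i]], "Arp2",
            scheme = scheme %||% default_subdomain_scheme("Arp2", scheme_file),
            weighting = weighting),
          clamp_twist = clamp_twist_dihedral(models[[i]], maps[[i]],
                                             anchor_set[i], permissive = permissive),
          arpc4_bend = arpc4_bend_angle(models[[i]], maps[[i]],
                                        permissive = permissive),
          abort(sprintf("unknown metric '%s'", met), "config_error"))
        data.frame(structure = models[[i]]$identifier,
                   copy = maps[[i]]$copy_label, metric = met,
                   value_deg = r$value, weighting = r$weighting %||% "anchor",
                   anchor_set = anchor_set[i], error = "",
                   stringsAsFactors = FALSE)
      }, arpgeom_error = function(e) {
        data.frame(structure = models[[i]]$identifier,
                   copy = maps[[i]]$copy_label, metric = met,
                   value_deg = NA_real_, weighting = weighting,
                   anchor_set = anchor_set[i], error = conditionMessage(e),
                   stringsAsFactors = FALSE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
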