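subunit_vocabulary <- c("Arp2", "Arp3", "ArpC1", "ArpC2", "ArpC3", "ArpC4",
                        "ArpC5", "SPIN90", "SPIN90*")

valid_subunit_name <- function(x) {
  x %in% subunit_vocabulary | grepl("^Ac[0-9]+$", x) | grepl("^MA[0-9]+$", x)
}

#' Bind logical subunit names to chain identifiers
#'
#' A subunit map translates the fixed logical vocabulary (Arp2, Arp3,
#' ArpC1-ArpC5, SPIN90, SPIN90*, actin subunits Ac1..AcN, mother
#' filament subunits MA1..MAN) into the chain ids of a particular
#' coordinate file.  For C2 assemblies the two asymmetric copies are
#' separate maps distinguished by `copy_label`.
#'
#' @param mapping named character vector, logical name -> chain id
#' @param copy_label label for the asymmetric copy (e.g. `"copy1"`)
#' @return a `subunit_map` object
#' @export
subunit_map <- function(mapping, copy_label = "copy1") {
  mapping <- unlist(mapping)
  bad <- names(mapping)[!valid_subunit_name(names(mapping))]
  if (length(bad)) {
    abort(sprintf("unknown logical subunit name(s): %s",
                  paste(bad, collapse = ", ")), "mapping_error")
  }
  structure(list(mapping = mapping, copy_label = copy_label),
            class = "subunit_map")
}

#' @export
print.subunit_map <- function(x, ...) {
  cat(sprintf("subunit_map [%s]: %s\n", x$copy_label,
              paste(names(x$mapping), x$mapping, sep = "=", collapse = " ")))
  invisible(x)
}

map_chain <- function(map, subunit, model = NULL) {
  if (!inherits(map, "subunit_map")) {
    abort("map must be a subunit_map", "mapping_error")
  }
  ch <- if (subunit %in% names(map$mapping)) map$mapping[[subunit]] else NA
  if (is.na(ch)) {
    abort(sprintf("subunit '%s' is not in the map [%s]", subunit,
                  map$copy_label), "mapping_error")
  }
  if (!is.null(model) && !ch %in% model$atoms$chain) {
    abort(sprintf("mapped chain '%s' (subunit %s) absent from structure '%s'",
                  ch, subunit, model$identifier), "mapping_error")
  }
  ch
}

#' Load subunit maps from a YAML configuration file
#'
#' The configuration holds one map per asymmetric copy under `copies:`.
#' If `verify_anchors` is true in the file (the shipped templates set
#' it) and a model is supplied, the map is checked against the
#' structure: mapped chains must exist and the clamp/bend anchor
#' residues must carry their expected identities on the mapped ArpC2 /
#' ArpC4 chains.  A template whose chain layout does not match the file
#' is refused rather than silently producing wrong metrics.
#'
#' @param path YAML file (see `system.file("extdata/config/maps",
#'   package = "arpgeom")` for the shipped templates)
#' @param model optional `StructureModel` to verify against
#' @param anchor_set anchor set used for verification (see
#'   [anchor_sets()])
#' @return named list of [subunit_map()] objects, one per copy
#' @export
load_map <- function(path, model = NULL, anchor_set = "human") {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$copies)) abort("map config lacks a 'copies' section", "config_error")
  maps <- lapply(names(cfg$copies), function(lbl) {
    subunit_map(cfg$copies[[lbl]], copy_label = lbl)
  })
  names(maps) <- names(cfg$copies)
  if (!is.null(model)) {
    for (m in maps) {
      for (s in names(m$mapping)) map_chain(m, s, model)
      if (isTRUE(cfg$verify_anchors)) verify_map(model, m, anchor_set)
    }
  }
  maps
}

#' Verify a subunit map against anchor residue identities
#'
#' @param model a `StructureModel`
#' @param map a [subunit_map()]
#' @param anchor_set anchor set name (see [anchor_sets()])
#' @return `TRUE` invisibly; errors with class `mapping_error` on failure
#' @export
verify_map <- function(model, map, anchor_set = "human") {
  anchors <- c(anchor_sets()$clamp_twist[[anchor_set]],
               anchor_sets()$arpc4_bend$default)
  for (an in anchors) {
    if (!an$subunit %in% names(map$mapping)) next
    ok <- tryCatch({
      resolve_anchor(model, map, an$subunit, an$resno, an$resid, an$atom)
      TRUE
    }, arpgeom_error = function(e) e)
    if (!isTRUE(ok)) {
      abort(sprintf(
        "map [%s] failed anchor verification (%s); use infer_subunit_map() to propose chain assignments",
        map$copy_label, conditionMessage(ok)), "mapping_error")
    }
  }
  invisible(TRUE)
}

#' Propose subunit chain assignments from anchor fingerprints
#'
#' Scans every chain of a structure for the identity fingerprints of
#' the metric anchors (e.g. LYS18 + ILE244 for ArpC2; ARG32 + LYS130 +
#' GLU141 + GLU163 + SER147 for ArpC4) and reports which chains are
#' plausible carriers of each anchored subunit.  Intended for verifying
#' the shipped map templates against a freshly downloaded deposition.
#'
#' @param model a `StructureModel`
#' @param anchor_set anchor set name
#' @return data.frame with columns `subunit`, `chain`, `n_matched`,
#'   `n_anchors`
#' @export
infer_subunit_map <- function(model, anchor_set = "human") {
  anchors <- c(anchor_sets()$clamp_twist[[anchor_set]],
               anchor_sets()$arpc4_bend$default)
  by_sub <- split(anchors, vapply(anchors, `[[`, "", "subunit"))
  a <- model$atoms[!model$atoms$hetero, ]
  chains <- unique(a$chain)
  out <- do.call(rbind, lapply(names(by_sub), function(su) {
    ans <- by_sub[[su]]
    n_hit <- vapply(chains, function(ch) {
      sum(vapply(ans, function(an) {
        any(a$chain == ch & a$resno == an$resno & a$resid == an$resid &
              a$elety == an$atom)
      }, logical(1)))
    }, integer(1))
    data.frame(subunit = su, chain = chains, n_matched = n_hit,
               n_anchors = length(ans), stringsAsFactors = FALSE)
  }))
  out <- out[out$n_matched > 0, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$subunit, -out$n_matched, out$chain), , drop = FALSE]
}
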