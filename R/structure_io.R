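#' Read an atomic coordinate file into a StructureModel
#'
#' Parses a PDB or mmCIF file into a `StructureModel`: a flat table of
#' atom records carrying author chain ids and residue numbering,
#' insertion codes, element symbols, occupancies and a hetero flag.
#' Alternate locations are resolved deterministically before the model
#' is returned: for each (chain, residue, insertion code, atom name)
#' the highest-occupancy copy is kept, ties broken by alphabetical
#' altloc id.  Hydrogens and hetero records (ions, nucleotides,
#' ligands, waters) are retained but flagged, and are excluded by
#' default from every downstream metric.
#'
#' @param path path to a coordinate file
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension)
#' @param identifier optional model identifier; defaults to the file
#'   base name
#' @return an object of class `StructureModel` with elements
#'   `identifier`, `atoms` (data.frame with columns `chain`, `resno`,
#'   `insert`, `resid`, `elety`, `element`, `x`, `y`, `z`, `o`, `alt`,
#'   `hetero`), and `source_format`
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           identifier = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("coordinate file not found: %s", path), "parse_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
      pdb = "pdb", ent = "pdb",
      cif = "mmcif", mmcif = "mmcif",
      abort(sprintf("cannot infer format from extension '.%s'", ext),
            "format_error"))
  }
  raw <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    },
    error = function(e) {
      abort(sprintf("failed to parse %s as %s: %s", path, format,
                    conditionMessage(e)), "parse_error")
    }
  )
  at <- raw$atom
  if (is.null(at) || nrow(at) == 0) {
    abort(sprintf("no atom records in %s", path), "parse_error")
  }
  element <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                   guess_element(at$elety), at$elesy)))
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    element = element,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt)),
    hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) {
    abort(sprintf("non-finite coordinates at atom record(s) %s",
                  paste(utils::head(which(bad), 5), collapse = ", ")),
          "parse_error")
  }
  atoms <- resolve_altlocs(atoms)
  new_structure_model(atoms, identifier %||% sub("\\.[^.]*$", "", basename(path)),
                      format)
}

guess_element <- function(elety) {
  # first alphabetic character of the atom name, PDB convention
  e <- sub("^[0-9']*", "", elety)
  substr(e, 1, 1)
}

resolve_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  # highest occupancy wins; ties broken by alphabetical altloc id
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

new_structure_model <- function(atoms, identifier, source_format) {
  rownames(atoms) <- NULL
  structure(list(identifier = identifier, atoms = atoms,
                 source_format = source_format),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("StructureModel '%s' (%s): %d chains, %d residues, %d atoms (%d hetero)\n",
              x$identifier, x$source_format,
              length(unique(a$chain)),
              nrow(unique(a[, c("chain", "resno", "insert")])),
              nrow(a), sum(a$hetero)))
  invisible(x)
}

#' Write a StructureModel to a PDB file
#'
#' @param model a `StructureModel`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(
    file = path,
    type = ifelse(a$hetero, "HETATM", "ATOM"),
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno,
    resid = a$resid,
    eleno = seq_len(nrow(a)),
    elety = a$elety,
    chain = a$chain,
    insert = ifelse(a$insert == "", NA, a$insert),
    o = a$o,
    b = rep(0, nrow(a)),
    elesy = a$element
  )
  invisible(path)
}

#' A residue range on a logical subunit
#'
#' @param subunit logical subunit name (e.g. `"ArpC4"`) or chain id
#' @param start,end first and last author residue number (inclusive)
#' @return a `residue_range` object
#' @export
residue_range <- function(subunit, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    abort("residue_range requires start <= end", "range_error")
  }
  structure(list(subunit = subunit, start = start, end = end),
            class = "residue_range")
}

#' Select atoms from a StructureModel
#'
#' Selects atoms belonging to logical subunits (resolved through a
#' [subunit_map()]) and/or [residue_range()]s, optionally restricted by
#' an atom filter.  Output rows are in deterministic
#' (chain, residue number, insertion code, atom name) order regardless
#' of input order.
#'
#' @param model a `StructureModel`
#' @param subunits character vector of logical subunit names, a single
#'   `residue_range`, or a list of `residue_range`s
#' @param map a [subunit_map()] binding logical names to chain ids
#' @param atom_filter one of `"protein_heavy"` (default: non-hydrogen,
#'   non-hetero), `"all"`, `"heavy"` (non-hydrogen, hetero kept),
#'   `"calpha"` (protein C-alpha), `"protein_only"` (all protein atoms)
#' @return data.frame of atom records (possibly empty)
#' @export
select_atoms <- function(model, subunits, map,
                         atom_filter = c("protein_heavy", "all", "heavy",
                                         "calpha", "protein_only")) {
  atom_filter <- match.arg(atom_filter)
  a <- model$atoms
  if (inherits(subunits, "residue_range")) subunits <- list(subunits)
  keep <- rep(FALSE, nrow(a))
  if (is.character(subunits)) {
    for (s in subunits) {
      keep <- keep | a$chain == map_chain(map, s, model)
    }
  } else if (is.list(subunits)) {
    for (rr in subunits) {
      if (!inherits(rr, "residue_range")) {
        abort("subunits list must contain residue_range objects", "mapping_error")
      }
      ch <- map_chain(map, rr$subunit, model)
      keep <- keep | (a$chain == ch & a$resno >= rr$start & a$resno <= rr$end)
    }
  } else {
    abort("subunits must be character or a list of residue_range", "mapping_error")
  }
  sel <- a[keep, , drop = FALSE]
  sel <- switch(atom_filter,
    all = sel,
    heavy = sel[sel$element != "H", , drop = FALSE],
    calpha = sel[!sel$hetero & sel$elety == "CA" & sel$element == "C", ,
                 drop = FALSE],
    protein_only = sel[!sel$hetero, , drop = FALSE],
    protein_heavy = sel[!sel$hetero & sel$element != "H", , drop = FALSE]
  )
  sel[order(sel$chain, sel$resno, sel$insert, sel$elety), , drop = FALSE]
}

#' Resolve a named anchor atom to its position
#'
#' Anchors are identity-checked: the residue found at the requested
#' author number must carry the expected residue name (e.g. LYS at
#' ArpC2 residue 18).  In permissive mode a mismatch downgrades to a
#' warning, which supports exploratory runs on structures with shifted
#' numbering.
#'
#' @param model a `StructureModel`
#' @param map a [subunit_map()]
#' @param subunit logical subunit name
#' @param resno author residue number
#' @param expected_resid expected 3-letter residue name, or `NA` to
#'   skip the check
#' @param atom atom name (default `"CA"`)
#' @param permissive logical; downgrade identity mismatch to a warning
#' @return numeric position 3-vector with attribute `resid`
#' @export
resolve_anchor <- function(model, map, subunit, resno, expected_resid = NA,
                           atom = "CA", permissive = FALSE) {
  ch <- map_chain(map, subunit, model)
  a <- model$atoms
  hit <- a[a$chain == ch & a$resno == resno & a$elety == atom, , drop = FALSE]
  if (nrow(hit) == 0) {
    abort(sprintf("anchor %s %d %s not found on chain %s (%s)",
                  subunit, resno, atom, ch, model$identifier),
          "anchor_missing")
  }
  hit <- hit[1, ]
  if (!is.na(expected_resid) && hit$resid != expected_resid) {
    msg <- sprintf("anchor identity mismatch: %s %d is %s, expected %s (%s)",
                   subunit, resno, hit$resid, expected_resid, model$identifier)
    if (permissive) warning(msg, call. = FALSE) else abort(msg, "anchor_identity")
  }
  structure(c(hit$x, hit$y, hit$z), resid = hit$resid)
}
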