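.arpgeom_cache <- new.env(parent = emptyenv())

read_table_file <- function(name) {
  path <- system.file("extdata", name, package = "arpgeom", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Average atomic masses (Da) keyed by element symbol
#'
#' Standard average atomic masses for the elements found in protein
#' models and their common ligands (C, N, O, S, P, H, Mg, ...), shipped
#' as a plain-text data file so the table is inspectable and editable.
#'
#' @return named numeric vector, element symbol -> mass in Da
#' @export
atomic_masses <- function() {
  if (is.null(.arpgeom_cache$masses)) {
    tab <- read_table_file("atomic_masses.csv")
    .arpgeom_cache$masses <- stats::setNames(tab$mass, toupper(tab$element))
  }
  .arpgeom_cache$masses
}

#' Average amino-acid residue masses (Da)
#'
#' Masses of the 20 standard residues as incorporated in a chain
#' (i.e. minus one water); a free water (18.01528 Da) is added once per
#' chain by [sequence_mass()].
#'
#' @return data.frame with columns `letter`, `code`, `mass`
#' @export
residue_masses <- function() {
  if (is.null(.arpgeom_cache$resmass)) {
    .arpgeom_cache$resmass <- read_table_file("residue_masses.csv")
  }
  .arpgeom_cache$resmass
}

#' Van der Waals radii used for solvent-accessible surface area
#'
#' A single published united-atom style element radius set ("protor").
#' The set in use is named in every report so results are traceable to
#' the radii that produced them.
#'
#' @param set name of the radius set (currently only `"protor"`)
#' @return named numeric vector, element symbol -> radius in Angstrom
#' @export
vdw_radii <- function(set = "protor") {
  key <- paste0("radii_", set)
  if (is.null(.arpgeom_cache[[key]])) {
    fname <- paste0("vdw_radii_", set, ".csv")
    path <- system.file("extdata", fname, package = "arpgeom")
    if (!nzchar(path)) abort(sprintf("unknown radius set '%s'", set), "radii_error")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    .arpgeom_cache[[key]] <- stats::setNames(tab$radius, toupper(tab$element))
  }
  .arpgeom_cache[[key]]
}

water_mass <- 18.01528
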