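#' @include AllClasses.R
NULL

# Normalise site labels: trim whitespace, map Unicode prime/acute to the
# ASCII apostrophe used in flavonoid numbering (3', 4').
.normalizeSite <- function(site) {
  site <- trimws(site)
  site <- gsub("′", "'", site)
  site <- gsub("´", "'", site)
  site[!nzchar(site)] <- NA_character_
  site
}

#' Construct a SpeciesSet
#'
#' @param molecule_id character vector of molecule identifiers.
#' @param form species form: `"neutral"`, `"radical"`, `"radical_cation"`,
#'   `"anion"` or `"cation"`.
#' @param site O-H site label (free text, e.g. `"3"`, `"4'"`); required for
#'   `radical`/`anion` forms, `NA` otherwise.
#' @param phase `"gas"` or `"water"`.
#' @param enthalpy_hartree species enthalpy in hartree.
#' @param electronic_energy_hartree optional electronic energy in hartree.
#' @param homo_ev,lumo_ev optional frontier-orbital energies in eV.
#' @return a validated [SpeciesSet-class].
#' @export
#' @examples
#' speciesSet(molecule_id = "PhOH", form = c("neutral", "radical"),
#'            site = c(NA, "1"), phase = "gas",
#'            enthalpy_hartree = c(-307.3, -306.7))
speciesSet <- function(molecule_id, form, site = NA_character_, phase,
                       enthalpy_hartree,
                       electronic_energy_hartree = NA_real_,
                       homo_ev = NA_real_, lumo_ev = NA_real_) {
  d <- data.frame(
    molecule_id = as.character(molecule_id),
    form = as.character(form),
    site = .normalizeSite(as.character(site)),
    phase = as.character(phase),
    enthalpy_hartree = as.numeric(enthalpy_hartree),
    electronic_energy_hartree = as.numeric(electronic_energy_hartree),
    homo_ev = as.numeric(homo_ev),
    lumo_ev = as.numeric(lumo_ev),
    stringsAsFactors = FALSE
  )
  new("SpeciesSet", data = d)
}

setMethod("show", "SpeciesSet", function(object) {
  d <- object@data
  cat("SpeciesSet with", nrow(d), "species\n")
  if (nrow(d)) {
    cat("  molecules:", paste(unique(d$molecule_id), collapse = ", "), "\n")
    cat("  phases:   ", paste(unique(d$phase), collapse = ", "), "\n")
    tb <- table(d$form)
    cat("  forms:    ", paste(names(tb), tb, sep = ":", collapse = "  "), "\n")
  }
  invisible(object)
})

#' Subset a SpeciesSet
#'
#' @param x a [SpeciesSet-class].
#' @param molecule,phase,form optional filters.
#' @return a [SpeciesSet-class] with the matching records.
#' @export
subsetSpecies <- function(x, molecule = NULL, phase = NULL, form = NULL) {
  stopifnot(is(x, "SpeciesSet"))
  d <- x@data
  keep <- rep(TRUE, nrow(d))
  if (!is.null(molecule)) keep <- keep & d$molecule_id %in% molecule
  if (!is.null(phase)) keep <- keep & d$phase %in% phase
  if (!is.null(form)) keep <- keep & d$form %in% form
  new("SpeciesSet", data = d[keep, , drop = FALSE])
}

#' Read a species table from CSV
#'
#' The flat on-disk schema has one species per row with columns
#' `molecule_id`, `form`, `site`, `phase`, `enthalpy_hartree`,
#' `electronic_energy_hartree`, `homo_ev`, `lumo_ev`; empty cells mark absent
#' optional values. Site labels are whitespace-trimmed and the Unicode prime
#' is accepted as an apostrophe.
#'
#' @param path path to a CSV file.
#' @return a validated [SpeciesSet-class].
#' @export
readSpeciesTable <- function(path) {
  if (!file.exists(path)) stop("species table not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(.species_columns, names(raw))
  if (length(missing_cols)) {
    stop("species table schema error: missing column(s) ",
         paste(sQuote(missing_cols), collapse = ", "))
  }
  num <- function(col) {
    v <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & nzchar(v) & is.na(out))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at row ", bad[1],
           ": '", v[bad[1]], "'")
    }
    out
  }
  speciesSet(
    molecule_id = trimws(raw$molecule_id),
    form = trimws(raw$form),
    site = raw$site,
    phase = trimws(raw$phase),
    enthalpy_hartree = num("enthalpy_hartree"),
    electronic_energy_hartree = num("electronic_energy_hartree"),
    homo_ev = num("homo_ev"),
    lumo_ev = num("lumo_ev")
  )
}

#' Write a species table to CSV
#'
#' Inverse of [readSpeciesTable()]: numeric fields are written with 17
#' significant digits so that a write/read round trip reproduces the set
#' field-for-field.
#'
#' @param x a [SpeciesSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpeciesTable <- function(x, path) {
  stopifnot(is(x, "SpeciesSet"))
  d <- x@data
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- data.frame(
    molecule_id = d$molecule_id,
    form = d$form,
    site = ifelse(is.na(d$site), "", d$site),
    phase = d$phase,
    enthalpy_hartree = fmt(d$enthalpy_hartree),
    electronic_energy_hartree = fmt(d$electronic_energy_hartree),
    homo_ev = fmt(d$homo_ev),
    lumo_ev = fmt(d$lumo_ev),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Reference enthalpies of H-atom, proton and electron
#'
#' Defaults for the gas phase follow the convention standard in
#' phenolic-antioxidant DFT work: H(H.) = -0.49765 hartree electronic energy
#' plus a 2.5RT thermal enthalpy of 0.00236 hartree; H(H+) = 2.5RT =
#' 0.00236 hartree; H(e-) = 0.00120 hartree. There is no accepted universal
#' aqueous convention, so water-phase values must be supplied explicitly
#' (directly or via [readReferenceConfig()]).
#'
#' @param phase `"gas"` or `"water"`.
#' @param hAtom,proton,electron enthalpies in hartree; required for
#'   `phase = "water"`.
#' @return a [ReferenceEnthalpies-class].
#' @export
#' @examples
#' referenceEnthalpies()  # gas-phase defaults
referenceEnthalpies <- function(phase = c("gas", "water"),
                                hAtom = NULL, proton = NULL, electron = NULL) {
  phase <- match.arg(phase)
  if (phase == "gas") {
    if (is.null(hAtom)) hAtom <- -0.49765 + 0.00236
    if (is.null(proton)) proton <- 0.00236
    if (is.null(electron)) electron <- 0.00120
  } else if (is.null(hAtom) || is.null(proton) || is.null(electron)) {
    stop("no default aqueous reference convention: supply hAtom, proton and ",
         "electron explicitly for phase = 'water'")
  }
  new("ReferenceEnthalpies", hAtom = hAtom, proton = proton,
      electron = electron, phase = phase)
}

setMethod("show", "ReferenceEnthalpies", function(object) {
  cat(sprintf("ReferenceEnthalpies (%s phase)\n", object@phase))
  cat(sprintf("  H(H.)  = %.6f hartree\n", object@hAtom))
  cat(sprintf("  H(H+)  = %.6f hartree\n", object@proton))
  cat(sprintf("  H(e-)  = %.6f hartree\n", object@electron))
  invisible(object)
})

#' Read reference enthalpies and unit overrides from a YAML config
#'
#' Expected layout:
#' \preformatted{
#' references:
#'   gas:   {h_atom: -0.49529, proton: 0.00236, electron: 0.00120}
#'   water: {h_atom: ..., proton: ..., electron: ...}
#' }
#'
#' @param path YAML file path.
#' @return a named list of [ReferenceEnthalpies-class], one per phase present.
#' @export
readReferenceConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  refs <- cfg$references
  if (is.null(refs)) stop("config file has no 'references' section")
  out <- list()
  for (ph in intersect(names(refs), .species_phases)) {
    r <- refs[[ph]]
    out[[ph]] <- referenceEnthalpies(phase = ph, hAtom = r$h_atom,
                                     proton = r$proton, electron = r$electron)
  }
  out
}
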