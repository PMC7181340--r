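#' @include descriptors.R mechanisms.R site_reactivity.R druglikeness.R
NULL

# deterministic CSV writer: numbers pre-formatted, no row names
.writeReportCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

.writeReportJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.fmt2 <- function(x) sprintf("%.2f", roundHalfUp(x, 2))

#' Global-descriptor report
#'
#' Runs [globalDescriptors()] over a set of IP/EA pairs and writes a
#' descriptor-by-method table (rows IE, EA, eta, S, chi, mu, omega; one
#' column per molecule and method, values rounded to two decimals half-up)
#' as CSV plus a full-precision JSON. All arithmetic happens in the
#' computation layer; the report only formats. Output bytes depend only on
#' the inputs.
#'
#' @param pairs data.frame with `molecule_id`, `method`, `ip`, `ea` (eV), as
#'   in [descriptorTable()].
#' @param outDir output directory, created if missing.
#' @return invisibly, the full-precision descriptor table.
#' @export
runDescriptors <- function(pairs, outDir) {
  if (is.null(pairs) || !is.data.frame(pairs) || nrow(pairs) == 0L) {
    stop("usage: runDescriptors() needs a non-empty data.frame of IP/EA pairs")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tab <- descriptorTable(pairs)
  wide <- data.frame(descriptor = c("IE", "EA", "eta", "S", "chi", "mu", "omega"))
  for (i in seq_len(nrow(tab))) {
    col <- paste(tab$molecule_id[i], tab$method[i], sep = ".")
    wide[[col]] <- .fmt2(unlist(
      tab[i, c("ip", "ea", "eta", "softness", "chi", "mu", "omega")]))
  }
  .writeReportCsv(wide, file.path(outDir, "descriptors.csv"))
  .writeReportJson(tab, file.path(outDir, "descriptors.json"))
  invisible(tab)
}

#' Antioxidant-mechanism report
#'
#' Builds the per-site thermochemistry table, the mechanism verdict and the
#' BDE site-ordering string; optionally appends substituent comparisons.
#' Writes `site_thermo.csv` (2-decimal kcal/mol) and `antioxidant.json`.
#'
#' @param species a [SpeciesSet-class] (one molecule, one phase).
#' @param refs matching [ReferenceEnthalpies-class].
#' @param outDir output directory.
#' @param variants optional named list of site/bde data.frames to compare
#'   against the parent via [substituentEffect()].
#' @return invisibly, a list with `site_table`, `verdict`, `ordering`,
#'   `substituents`.
#' @export
runAntioxidant <- function(species, refs, outDir, variants = NULL) {
  if (missing(species) || length(species) == 0L) {
    stop("usage: runAntioxidant() needs a non-empty SpeciesSet")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tab <- siteTable(species, refs)
  incomplete <- names(which(colSums(is.na(tab[c("aip", "pde", "pa", "ete")])) > 0))
  if (length(incomplete)) {
    warning("partial table: missing species leave ",
            paste(incomplete, collapse = ", "), " absent")
  }
  verdict <- preferredMechanism(tab)
  ordering <- siteOrdering(tab, "bde")
  out_tab <- tab
  for (cc in c("bde", "aip", "pde", "pa", "ete")) {
    out_tab[[cc]] <- ifelse(is.na(tab[[cc]]), "", .fmt2(tab[[cc]]))
  }
  .writeReportCsv(out_tab, file.path(outDir, "site_thermo.csv"))
  subst <- NULL
  if (!is.null(variants)) {
    subst <- lapply(variants, substituentEffect, parent = tab)
  }
  .writeReportJson(list(
    molecule = tab$molecule_id[1], phase = tab$phase[1],
    site_ordering_by_bde = ordering,
    preferred_mechanism = verdict@mechanism,
    first_step_kcal_mol = verdict@firstStepParameter,
    excluded = verdict@candidates[verdict@candidates$excluded,
                                  c("mechanism", "reason")],
    substituent_effects = lapply(subst, function(s) {
      list(verdict = s$verdict, not_comparable = s$not_comparable,
           delta = s$delta)
    })
  ), file.path(outDir, "antioxidant.json"))
  invisible(list(site_table = tab, verdict = verdict, ordering = ordering,
                 substituents = subst))
}

#' Druglikeness report
#'
#' Evaluates the Lipinski and Veber rule engines, classifies bioactivity
#' scores and computes the drug score; writes `druglikeness.json` plus a
#' properties CSV. When a SMILES string is given the countable properties
#' (MW, heavy atoms, HBD, HBA, ROTB, TPSA) are computed from the structure
#' and merged with the supplied ones (supplied values win); externally
#' predicted values (logP, logS, druglikeness) cannot be derived from the
#' graph and must be supplied.
#'
#' @param props a [MolecularProperties-class], or `NULL` to derive counts
#'   from `smiles` only.
#' @param outDir output directory.
#' @param smiles optional SMILES string.
#' @param bioactivity optional named numeric of bioactivity scores.
#' @return invisibly, list with `properties`, `lipinski`, `veber`,
#'   `bioactivity_classes`, `drug_score`.
#' @export
runDruglike <- function(props = NULL, outDir, smiles = NULL,
                        bioactivity = NULL) {
  if (is.null(props) && is.null(smiles)) {
    stop("usage: runDruglike() needs properties and/or a SMILES string")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(smiles)) {
    g <- parseStructure(smiles)
    derived <- list(mw = molecularWeight(g), nhba = countHBA(g),
                    nhbd = countHBD(g), nrotb = countRotatable(g),
                    natoms = countHeavyAtoms(g), tpsa = tpsa(g))
    if (is.null(props)) {
      props <- molecularProperties()
    }
    for (nm in names(derived)) {
      if (is.na(slot(props, nm))) {
        slot(props, nm) <- if (is.integer(slot(props, nm))) {
          as.integer(derived[[nm]])
        } else derived[[nm]]
      }
    }
  }
  lip <- lipinskiViolations(props)
  veb <- veberCheck(props)
  ds <- drugScore(props)
  classes <- if (!is.null(bioactivity)) {
    stats::setNames(as.character(bioactivityClass(bioactivity)),
                    names(bioactivity))
  }
  prop_row <- data.frame(
    miLogP = props@milogp, TPSA = props@tpsa, nAtoms = props@natoms,
    MW = props@mw, nHBA = props@nhba, nHBD = props@nhbd,
    nViolations = lip@violations, nROTB = props@nrotb,
    Volume = props@volume, clogP = props@clogp, logS = props@logs,
    druglikeness = props@druglikeness,
    drug_score = as.numeric(sprintf("%.3f", roundHalfUp(ds, 3)))
  )
  .writeReportCsv(prop_row, file.path(outDir, "properties.csv"))
  .writeReportJson(list(
    lipinski = list(violations = lip@violations, rules = lip@rules),
    veber = list(pass = veb@violations == 0L, rules = veb@rules),
    bioactivity_classes = classes,
    toxicity = as.list(props@toxicity),
    drug_score = ds
  ), file.path(outDir, "druglikeness.json"))
  invisible(list(properties = props, lipinski = lip, veber = veb,
                 bioactivity_classes = classes, drug_score = ds))
}

#' Run every report on a fixture bundle
#'
#' Convenience driver mirroring the full published analysis on a bundle
#' shaped like [petunidinFixture()]: descriptors, gas- and water-phase
#' antioxidant tables with the substituted-variant comparison, and the
#' druglikeness layer.
#'
#' @param bundle a fixture bundle (see [petunidinFixture()]).
#' @param outDir output directory.
#' @return invisibly, a list of the three sub-reports.
#' @export
runReportAll <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  desc <- runDescriptors(bundle$ip_ea_pairs, outDir)
  antiox <- runAntioxidant(
    bundle$species_gas, bundle$refs_gas, outDir,
    variants = list(amino = bundle$amino_bde,
                    glucoside = bundle$glucoside_bde))
  druglike <- runDruglike(bundle$properties, outDir,
                          smiles = bundle$smiles,
                          bioactivity = bundle$bioactivity)
  invisible(list(descriptors = desc, antioxidant = antiox,
                 druglike = druglike))
}
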