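#' @include AllClasses.R units.R species.R
NULL

.checkPhase <- function(refs, phase) {
  if (!is(refs, "ReferenceEnthalpies")) {
    stop("'refs' must be a ReferenceEnthalpies object")
  }
  if (!missing(phase) && !is.null(phase) && refs@phase != phase) {
    stop("phase mismatch: species are '", phase, "' but references are '",
         refs@phase, "'")
  }
  invisible(TRUE)
}

# All mechanism arithmetic is done in hartree and converted exactly once at
# the end, so 2-decimal kcal/mol reports are never double-rounded.
.h2k <- function(x) x * unitConstants$hartree_to_kcal

#' Bond dissociation enthalpy (HAT first step)
#'
#' BDE = H(ArO.) + H(H.) - H(ArOH): the enthalpy cost of homolytic O-H
#' cleavage. The lower the BDE, the better the hydrogen-atom donor.
#'
#' @param h_parent enthalpy of the neutral parent ArOH, hartree.
#' @param h_radical enthalpy of the site radical ArO., hartree.
#' @param refs a [ReferenceEnthalpies-class] for the same phase.
#' @param phase phase of the two species; checked against `refs`.
#' @return BDE in kcal/mol.
#' @export
bde <- function(h_parent, h_radical, refs, phase = refs@phase) {
  .checkPhase(refs, phase)
  .h2k(h_radical + refs@hAtom - h_parent)
}

#' Adiabatic ionisation potential (SET / SET-PT first step)
#'
#' AIP = H(ArOH.+) - H(ArOH). As conventionally printed the electron
#' enthalpy is omitted; `include_electron = TRUE` restores the
#' thermodynamically complete convention by adding H(e-).
#'
#' @param h_parent enthalpy of ArOH, hartree.
#' @param h_radical_cation enthalpy of ArOH.+, hartree.
#' @param refs a [ReferenceEnthalpies-class].
#' @param phase phase of the species.
#' @param include_electron add H(e-) to the products (default `FALSE`).
#' @return AIP in kcal/mol.
#' @export
aip <- function(h_parent, h_radical_cation, refs, phase = refs@phase,
                include_electron = FALSE) {
  .checkPhase(refs, phase)
  .h2k(h_radical_cation - h_parent +
         if (include_electron) refs@electron else 0)
}

#' Proton dissociation enthalpy (SET-PT second step)
#'
#' PDE = H(ArO.) + H(H+) - H(ArOH.+).
#'
#' @param h_radical enthalpy of ArO., hartree.
#' @param h_radical_cation enthalpy of ArOH.+, hartree.
#' @param refs a [ReferenceEnthalpies-class].
#' @param phase phase of the species.
#' @return PDE in kcal/mol.
#' @export
pde <- function(h_radical, h_radical_cation, refs, phase = refs@phase) {
  .checkPhase(refs, phase)
  .h2k(h_radical + refs@proton - h_radical_cation)
}

#' Proton affinity of the phenolate pathway (SPLET first step)
#'
#' PA = H(ArO-) + H(H+) - H(ArOH). Negative values are preserved (and later
#' flagged by the mechanism-preference policy as non-physical first-step
#' costs under the chosen reference convention).
#'
#' @param h_parent enthalpy of ArOH, hartree.
#' @param h_anion enthalpy of ArO-, hartree.
#' @param refs a [ReferenceEnthalpies-class].
#' @param phase phase of the species.
#' @return PA in kcal/mol.
#' @export
pa <- function(h_parent, h_anion, refs, phase = refs@phase) {
  .checkPhase(refs, phase)
  .h2k(h_anion + refs@proton - h_parent)
}

#' Electron transfer enthalpy (SPLET second step)
#'
#' ETE = H(ArO.) - H(ArO-).
#'
#' @param h_anion enthalpy of ArO-, hartree.
#' @param h_radical enthalpy of ArO., hartree.
#' @param phase unused beyond documentation; the difference is
#'   reference-free.
#' @return ETE in kcal/mol.
#' @export
ete <- function(h_anion, h_radical, phase = NULL) {
  .h2k(h_radical - h_anion)
}

#' Per-site antioxidant thermochemistry table
#'
#' Assembles BDE/AIP/PDE/PA/ETE for every O-H site of one molecule in one
#' phase from its species records. A neutral record is required; one row is
#' produced per site that has a radical record. AIP is site-independent and
#' repeated on each row; parameters whose species are missing come back
#' `NA`. When a site has the full species complement the thermodynamic-cycle
#' identity AIP + PDE = PA + ETE = BDE + (H(H+) - H(H.)) is asserted to
#' 1e-6 kcal/mol.
#'
#' @param species a [SpeciesSet-class] holding one molecule and one phase
#'   (subset first with [subsetSpecies()] if needed).
#' @param refs a [ReferenceEnthalpies-class] for that phase.
#' @param include_electron passed to [aip()].
#' @return data.frame with columns `molecule_id`, `site`, `phase`, `bde`,
#'   `aip`, `pde`, `pa`, `ete` (kcal/mol), ordered by ascending BDE.
#' @export
siteTable <- function(species, refs, include_electron = FALSE) {
  stopifnot(is(species, "SpeciesSet"))
  d <- speciesData(species)
  if (length(unique(d$molecule_id)) != 1L || length(unique(d$phase)) != 1L) {
    stop("siteTable() expects exactly one molecule in one phase; got ",
         length(unique(d$molecule_id)), " molecule(s) x ",
         length(unique(d$phase)), " phase(s)")
  }
  phase <- d$phase[1]
  .checkPhase(refs, phase)
  h_parent <- d$enthalpy_hartree[d$form == "neutral"]
  if (length(h_parent) != 1L) {
    stop("no neutral record for molecule '", d$molecule_id[1], "' (", phase, ")")
  }
  h_rc <- d$enthalpy_hartree[d$form == "radical_cation"]
  has_rc <- length(h_rc) == 1L
  rad <- d[d$form == "radical", , drop = FALSE]
  if (nrow(rad) == 0L) stop("no radical records: no O-H site to tabulate")
  anio <- d[d$form == "anion", , drop = FALSE]
  mol_aip <- if (has_rc) {
    aip(h_parent, h_rc, refs, phase, include_electron)
  } else NA_real_
  rows <- lapply(seq_len(nrow(rad)), function(i) {
    s <- rad$site[i]
    h_rad <- rad$enthalpy_hartree[i]
    h_an <- anio$enthalpy_hartree[match(s, anio$site)]
    r <- data.frame(
      molecule_id = d$molecule_id[1], site = s, phase = phase,
      bde = bde(h_parent, h_rad, refs, phase),
      aip = mol_aip,
      pde = if (has_rc) pde(h_rad, h_rc, refs, phase) else NA_real_,
      pa = if (!is.na(h_an)) pa(h_parent, h_an, refs, phase) else NA_real_,
      ete = if (!is.na(h_an)) ete(h_an, h_rad) else NA_real_,
      stringsAsFactors = FALSE
    )
    if (!anyNA(r[, c("bde", "aip", "pde", "pa", "ete")])) {
      bridge <- .h2k(refs@proton - refs@hAtom)
      if (abs(r$aip + r$pde - (r$bde + bridge)) > 1e-6 ||
          abs(r$pa + r$ete - (r$bde + bridge)) > 1e-6) {
        warning("thermodynamic cycle closure violated at site '", s,
                "': inconsistent species enthalpies")
      }
    }
    r
  })
  out <- do.call(rbind, rows)
  out[order(out$bde), , drop = FALSE]
}

#' Preferred radical-scavenging mechanism
#'
#' Compares the first-step thermochemical costs of the three pathways —
#' minimum site BDE for HAT, AIP for SET-PT, minimum site PA for SPLET — and
#' picks the cheapest among the candidates not excluded by policy. The
#' default policy excludes candidates whose first-step cost is non-positive
#' (e.g. a negative PA, non-physical as a cost under the gas-phase reference
#' convention). Ties are broken in the fixed order HAT, SPLET, SET-PT.
#'
#' @param table a site-thermochemistry data.frame from [siteTable()] (or any
#'   data.frame with `bde` and optionally `aip`, `pa` columns).
#' @param excludeNonphysical exclude candidates with first-step cost <= 0
#'   (default `TRUE`).
#' @return a [MechanismVerdict-class].
#' @export
#' @examples
#' tab <- data.frame(bde = 78.72, aip = 229.91, pa = -112.68)
#' preferredMechanism(tab)  # HAT; SPLET excluded as non-physical
preferredMechanism <- function(table, excludeNonphysical = TRUE) {
  if (!is.data.frame(table) || nrow(table) == 0L || !"bde" %in% names(table) ||
      all(is.na(table$bde))) {
    stop("mechanism preference needs a non-empty site table with BDE values")
  }
  first_step <- c(
    HAT = min(table$bde, na.rm = TRUE),
    SET_PT = if ("aip" %in% names(table) && any(!is.na(table$aip))) {
      min(table$aip, na.rm = TRUE)
    } else NA_real_,
    SPLET = if ("pa" %in% names(table) && any(!is.na(table$pa))) {
      min(table$pa, na.rm = TRUE)
    } else NA_real_
  )
  cand <- data.frame(mechanism = names(first_step), parameter = first_step,
                     excluded = FALSE, reason = "", stringsAsFactors = FALSE,
                     row.names = NULL)
  cand$excluded[is.na(cand$parameter)] <- TRUE
  cand$reason[is.na(cand$parameter)] <- "parameter unavailable"
  if (excludeNonphysical) {
    bad <- !cand$excluded & cand$parameter <= 0
    cand$excluded[bad] <- TRUE
    cand$reason[bad] <- "non-physical first-step cost (<= 0 kcal/mol)"
  }
  ok <- cand[!cand$excluded, , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop("all mechanism candidates excluded; re-run with an explicit policy ",
         "(excludeNonphysical = FALSE) or supply physical parameters")
  }
  # fixed tie-break order
  pref <- c(HAT = 1L, SPLET = 2L, SET_PT = 3L)
  ok <- ok[order(ok$parameter, pref[ok$mechanism]), , drop = FALSE]
  new("MechanismVerdict", mechanism = ok$mechanism[1],
      firstStepParameter = ok$parameter[1], candidates = cand)
}

setMethod("show", "MechanismVerdict", function(object) {
  cat(sprintf("Preferred mechanism: %s (first step %.2f kcal/mol)\n",
              object@mechanism, object@firstStepParameter))
  exc <- object@candidates[object@candidates$excluded, , drop = FALSE]
  if (nrow(exc)) {
    for (i in seq_len(nrow(exc))) {
      cat(sprintf("  excluded %-7s %s\n", exc$mechanism[i], exc$reason[i]))
    }
  }
  invisible(object)
})

#' Substituent effect on per-site BDEs
#'
#' Compares the site-resolved BDEs of a parent compound with a substituted
#' variant: Delta = BDE(variant) - BDE(parent) on shared sites. Sites absent
#' from one table (e.g. the glycosylated O-H) are reported as not
#' comparable.
#'
#' @param parent,variant site-thermochemistry data.frames with `site` and
#'   `bde` columns.
#' @return list with `delta` (data.frame: site, bde_parent, bde_variant,
#'   delta), `not_comparable` (character sites), and `verdict` — one of
#'   `"all_lower"`, `"all_higher"`, `"mixed"`, `"none"` (identical tables).
#' @export
substituentEffect <- function(parent, variant) {
  for (tb in list(parent, variant)) {
    if (!is.data.frame(tb) || !all(c("site", "bde") %in% names(tb))) {
      stop("both tables need 'site' and 'bde' columns")
    }
  }
  shared <- intersect(parent$site, variant$site)
  if (length(shared) == 0L) {
    stop("site label sets are disjoint: nothing to compare")
  }
  delta <- data.frame(
    site = shared,
    bde_parent = parent$bde[match(shared, parent$site)],
    bde_variant = variant$bde[match(shared, variant$site)],
    stringsAsFactors = FALSE
  )
  delta$delta <- delta$bde_variant - delta$bde_parent
  verdict <- if (all(delta$delta == 0)) "none"
  else if (all(delta$delta < 0)) "all_lower"
  else if (all(delta$delta > 0)) "all_higher"
  else "mixed"
  list(
    delta = delta,
    not_comparable = setdiff(union(parent$site, variant$site), shared),
    verdict = verdict
  )
}

#' Site ordering string
#'
#' Formats the sites of a thermochemistry table ordered by a parameter, e.g.
#' `"3 < 4' < 5 < 7 < 3'"` for ascending BDE.
#'
#' @param table site-thermochemistry data.frame.
#' @param parameter column to order by (default `"bde"`).
#' @return a single character string.
#' @export
siteOrdering <- function(table, parameter = "bde") {
  if (!parameter %in% names(table)) stop("no column '", parameter, "'")
  paste(table$site[order(table[[parameter]])], collapse = " < ")
}
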