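#' @import methods
NULL

.species_forms <- c("neutral", "radical", "radical_cation", "anion", "cation")
.species_phases <- c("gas", "water")
.site_forms <- c("radical", "anion")
.toxicity_keys <- c("mutagenic", "tumorigenic", "irritant", "reproductive")
.toxicity_levels <- c("none", "medium", "high")

.species_columns <- c("molecule_id", "form", "site", "phase",
                      "enthalpy_hartree", "electronic_energy_hartree",
                      "homo_ev", "lumo_ev")

#' SpeciesSet: a table of computed chemical species
#'
#' Canonical container for the output of quantum-chemical runs on a phenolic
#' antioxidant: the neutral parent, per-site O-H radicals (`ArO.`), the
#' radical cation (`ArOH.+`), per-site anions (`ArO-`) and the vertical
#' cation, in gas and/or aqueous phase. One row per species; enthalpies and
#' electronic energies in hartree, frontier-orbital energies in eV.
#'
#' Validity enforces: known `form`/`phase` levels, finite enthalpies, a site
#' label present exactly for the site-resolved forms (`radical`, `anion`),
#' HOMO < LUMO whenever both are given, and uniqueness of the
#' (molecule, form, site, phase) key.
#'
#' @slot data a `data.frame` with columns `molecule_id`, `form`, `site`,
#'   `phase`, `enthalpy_hartree`, `electronic_energy_hartree`, `homo_ev`,
#'   `lumo_ev`.
#' @seealso [speciesSet()], [readSpeciesTable()], [siteTable()]
#' @export
setClass("SpeciesSet", representation(data = "data.frame"))

setValidity("SpeciesSet", function(object) {
  d <- object@data
  msgs <- character()
  missing_cols <- setdiff(.species_columns, names(d))
  if (length(missing_cols)) {
    return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(d)) {
    bad_form <- !d$form %in% .species_forms
    if (any(bad_form)) {
      msgs <- c(msgs, paste0("unknown form(s): ",
                             paste(unique(d$form[bad_form]), collapse = ", ")))
    }
    bad_phase <- !d$phase %in% .species_phases
    if (any(bad_phase)) {
      msgs <- c(msgs, paste0("unknown phase(s): ",
                             paste(unique(d$phase[bad_phase]), collapse = ", ")))
    }
    if (any(!is.finite(d$enthalpy_hartree))) {
      msgs <- c(msgs, "enthalpy_hartree must be finite for every species")
    }
    needs_site <- d$form %in% .site_forms
    has_site <- !is.na(d$site) & nzchar(d$site)
    if (any(needs_site & !has_site)) {
      msgs <- c(msgs, paste0("form '", .site_forms[1], "'/'", .site_forms[2],
                             "' requires a site label (rows ",
                             paste(which(needs_site & !has_site), collapse = ", "), ")"))
    }
    if (any(!needs_site & has_site)) {
      msgs <- c(msgs, paste0("site label only allowed for site-resolved forms (rows ",
                             paste(which(!needs_site & has_site), collapse = ", "), ")"))
    }
    both <- is.finite(d$homo_ev) & is.finite(d$lumo_ev)
    if (any(both & d$homo_ev >= d$lumo_ev)) {
      msgs <- c(msgs, "HOMO must lie below LUMO when both are present")
    }
    key <- paste(d$molecule_id, d$form, ifelse(is.na(d$site), "", d$site), d$phase)
    if (anyDuplicated(key)) {
      msgs <- c(msgs, paste0("duplicate (molecule, form, site, phase) key: ",
                             key[duplicated(key)][1]))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' ReferenceEnthalpies: enthalpies of H-atom, proton and electron
#'
#' Reference species entering the antioxidant thermochemistry: the enthalpy
#' of the hydrogen atom (BDE), of the proton (PDE, PA) and of the electron
#' (optional term of the ionisation step), all in hartree, for one phase.
#'
#' @slot hAtom enthalpy of H-atom, hartree.
#' @slot proton enthalpy of H+, hartree.
#' @slot electron enthalpy of e-, hartree.
#' @slot phase `"gas"` or `"water"`.
#' @seealso [referenceEnthalpies()]
#' @export
setClass("ReferenceEnthalpies",
         representation(hAtom = "numeric", proton = "numeric",
                        electron = "numeric", phase = "character"))

setValidity("ReferenceEnthalpies", function(object) {
  msgs <- character()
  for (s in c("hAtom", "proton", "electron")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) {
      msgs <- c(msgs, paste0("'", s, "' must be a single finite number"))
    }
  }
  if (length(object@phase) != 1L || !object@phase %in% .species_phases) {
    msgs <- c(msgs, "phase must be 'gas' or 'water'")
  }
  if (length(msgs)) msgs else TRUE
})

#' ReactivityDescriptors: the global conceptual-DFT descriptor bundle
#'
#' Ionisation potential, electron affinity and the descriptors derived from
#' them: hardness eta = (IP-EA)/2, softness S = 1/(2 eta), electronegativity
#' chi = (IP+EA)/2, chemical potential mu = -chi and electrophilicity index
#' omega = mu^2/(2 eta), all in eV (softness in 1/eV). Carries the provenance
#' of the IP/EA pair: `"orbital"` (Koopmans, from HOMO/LUMO) or `"energy"`
#' (from total energies of the neutral, cation and anion).
#'
#' The degenerate limit IP = EA (zero hardness) is kept as a flagged result
#' with infinite softness/electrophilicity rather than an error, so batch
#' tables survive degenerate rows.
#'
#' @slot method `"orbital"` or `"energy"`.
#' @slot ip,ea,eta,softness,chi,mu,omega numeric scalars (eV; softness 1/eV).
#' @slot degenerate logical, `TRUE` when IP == EA.
#' @seealso [globalDescriptors()]
#' @export
setClass("ReactivityDescriptors",
         representation(method = "character", ip = "numeric", ea = "numeric",
                        eta = "numeric", softness = "numeric", chi = "numeric",
                        mu = "numeric", omega = "numeric", degenerate = "logical"))

setValidity("ReactivityDescriptors", function(object) {
  msgs <- character()
  if (!object@method %in% c("orbital", "energy")) {
    msgs <- c(msgs, "method must be 'orbital' or 'energy'")
  }
  if (!isTRUE(object@degenerate)) {
    if (abs(object@mu + object@chi) > 1e-9) msgs <- c(msgs, "mu must equal -chi")
    if (object@eta > 0 && abs(object@softness * 2 * object@eta - 1) > 1e-9) {
      msgs <- c(msgs, "softness must equal 1/(2 eta)")
    }
  }
  if (object@ip >= object@ea && object@eta < -1e-12) {
    msgs <- c(msgs, "hardness must be non-negative when IP >= EA")
  }
  if (length(msgs)) msgs else TRUE
})

#' MechanismVerdict: preferred radical-scavenging mechanism
#'
#' Result of comparing the first-step thermochemical cost of the three
#' scavenging pathways: HAT (minimum site BDE), SET-PT (AIP) and SPLET
#' (minimum site PA). Candidates excluded by policy (by default any with a
#' non-physical, non-positive first-step cost) are recorded with reasons.
#'
#' @slot mechanism `"HAT"`, `"SET_PT"` or `"SPLET"`.
#' @slot firstStepParameter the winning first-step cost, kcal/mol.
#' @slot candidates data.frame of all candidates (mechanism, parameter,
#'   excluded, reason).
#' @seealso [preferredMechanism()]
#' @export
setClass("MechanismVerdict",
         representation(mechanism = "character", firstStepParameter = "numeric",
                        candidates = "data.frame"))

setValidity("MechanismVerdict", function(object) {
  if (!object@mechanism %in% c("HAT", "SET_PT", "SPLET")) {
    return("mechanism must be one of HAT, SET_PT, SPLET")
  }
  ok <- object@candidates[!object@candidates$excluded, , drop = FALSE]
  if (nrow(ok) && object@firstStepParameter - min(ok$parameter) > 1e-9) {
    return("chosen mechanism's first-step parameter must be the minimum among non-excluded candidates")
  }
  TRUE
})

#' MolecularGraph: a hydrogen-suppressed molecular graph
#'
#' Heavy-atom graph of a molecule parsed from SMILES, with perceived ring
#' membership and implicit-hydrogen counts. Bond orders are kekulized;
#' aromaticity is carried as a per-atom flag.
#'
#' @slot atoms data.frame with columns `element`, `charge`, `nH` (attached
#'   hydrogens), `degree` (heavy-atom neighbours), `inRing`, `aromatic`.
#' @slot bonds data.frame with columns `a1`, `a2` (atom indices), `order`
#'   (1, 2, 3), `inRing`.
#' @slot smiles the input SMILES string.
#' @seealso [parseStructure()]
#' @export
setClass("MolecularGraph",
         representation(atoms = "data.frame", bonds = "data.frame",
                        smiles = "character"))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  if (nrow(a) == 0L) msgs <- c(msgs, "graph must contain at least one atom")
  if (nrow(b)) {
    if (any(b$a1 < 1 | b$a1 > nrow(a) | b$a2 < 1 | b$a2 > nrow(a))) {
      msgs <- c(msgs, "bond endpoints out of range")
    }
    if (any(!b$order %in% 1:3)) msgs <- c(msgs, "bond orders must be 1, 2 or 3")
  }
  if (nrow(a) && any(a$nH < 0)) msgs <- c(msgs, "negative hydrogen count")
  if (length(msgs)) msgs else TRUE
})

#' MolecularProperties: the druglikeness property vector
#'
#' Properties consumed by the rule engine and drug score: logP estimates
#' (`milogp` for the rule checks; `clogp`, the estimate used inside the drug
#' score, defaults to `milogp` when not given separately), aqueous solubility
#' `logs` (log mol/L), topological polar surface area, molecular weight,
#' donor/acceptor/rotatable/heavy-atom counts, an externally supplied
#' fragment-based druglikeness value, and the four toxicity-risk flags.
#' Counts may be `NA` when a property file is partial; operations that need a
#' missing value raise an error naming it.
#'
#' @slot milogp,clogp,logs,tpsa,mw,volume,druglikeness numeric scalars.
#' @slot nhba,nhbd,nrotb,natoms integer scalars.
#' @slot toxicity named character vector over
#'   mutagenic/tumorigenic/irritant/reproductive with levels none/medium/high.
#' @seealso [molecularProperties()], [drugScore()], [lipinskiViolations()]
#' @export
setClass("MolecularProperties",
         representation(milogp = "numeric", clogp = "numeric", logs = "numeric",
                        tpsa = "numeric", mw = "numeric",
                        nhba = "integer", nhbd = "integer", nrotb = "integer",
                        natoms = "integer", volume = "numeric",
                        druglikeness = "numeric", toxicity = "character"))

setValidity("MolecularProperties", function(object) {
  msgs <- character()
  for (s in c("nhba", "nhbd", "nrotb", "natoms")) {
    v <- slot(object, s)
    if (!is.na(v) && v < 0L) msgs <- c(msgs, paste0("'", s, "' must be non-negative"))
  }
  tox <- object@toxicity
  if (!setequal(names(tox), .toxicity_keys)) {
    msgs <- c(msgs, paste0("toxicity must name exactly: ",
                           paste(.toxicity_keys, collapse = ", ")))
  }
  if (any(!tox %in% .toxicity_levels)) {
    msgs <- c(msgs, paste0("toxicity levels must be in: ",
                           paste(.toxicity_levels, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' RuleReport: per-rule druglikeness check outcome
#'
#' One row per rule with the threshold, the observed value and pass/fail;
#' the violation count equals the number of failed rules by construction.
#'
#' @slot rules data.frame with columns `rule`, `threshold`, `observed`, `pass`.
#' @slot violations integer, number of failed rules.
#' @seealso [lipinskiViolations()], [veberCheck()]
#' @export
setClass("RuleReport",
         representation(rules = "data.frame", violations = "integer"))

setValidity("RuleReport", function(object) {
  if (object@violations != sum(!object@rules$pass)) {
    return("violation count must equal the number of failed rules")
  }
  TRUE
})
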