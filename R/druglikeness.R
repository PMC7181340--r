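#' @include AllClasses.R
NULL

#' Construct a MolecularProperties vector
#'
#' @param milogp logP estimate used by the rule checks.
#' @param logs aqueous solubility, log(mol/L).
#' @param tpsa topological polar surface area, square Angstrom.
#' @param mw molecular weight, Dalton.
#' @param nhba,nhbd,nrotb,natoms acceptor/donor/rotatable/heavy-atom counts.
#' @param clogp logP estimate used inside the drug score; defaults to
#'   `milogp` (the two may come from different predictors).
#' @param volume molecular volume, cubic Angstrom (informational).
#' @param druglikeness externally supplied fragment-based druglikeness.
#' @param toxicity named character over
#'   `mutagenic`/`tumorigenic`/`irritant`/`reproductive`, each one of
#'   `"none"`, `"medium"`, `"high"`.
#' @return a validated [MolecularProperties-class].
#' @export
#' @examples
#' molecularProperties(milogp = -0.73, clogp = 1.980, logs = -2.338,
#'                     tpsa = 121.54, mw = 317.27, nhba = 7, nhbd = 5,
#'                     nrotb = 2, natoms = 23, druglikeness = 1.310)
molecularProperties <- function(milogp = NA_real_, logs = NA_real_,
                                tpsa = NA_real_, mw = NA_real_,
                                nhba = NA_integer_, nhbd = NA_integer_,
                                nrotb = NA_integer_, natoms = NA_integer_,
                                clogp = milogp, volume = NA_real_,
                                druglikeness = NA_real_,
                                toxicity = c(mutagenic = "none",
                                             tumorigenic = "none",
                                             irritant = "none",
                                             reproductive = "none")) {
  new("MolecularProperties",
      milogp = as.numeric(milogp), clogp = as.numeric(clogp),
      logs = as.numeric(logs), tpsa = as.numeric(tpsa), mw = as.numeric(mw),
      nhba = as.integer(nhba), nhbd = as.integer(nhbd),
      nrotb = as.integer(nrotb), natoms = as.integer(natoms),
      volume = as.numeric(volume), druglikeness = as.numeric(druglikeness),
      toxicity = toxicity)
}

setMethod("show", "MolecularProperties", function(object) {
  cat("MolecularProperties\n")
  cat(sprintf("  MW %.2f  miLogP %s  logS %s  TPSA %s\n",
              object@mw, format(object@milogp), format(object@logs),
              format(object@tpsa)))
  cat(sprintf("  HBA %s  HBD %s  ROTB %s  heavy atoms %s\n",
              object@nhba, object@nhbd, object@nrotb, object@natoms))
  risky <- object@toxicity[object@toxicity != "none"]
  cat("  toxicity:", if (length(risky)) {
    paste(names(risky), risky, sep = "=", collapse = ", ")
  } else "no risks flagged", "\n")
  invisible(object)
})

.needProps <- function(props, slots) {
  for (s in slots) {
    if (is.na(slot(props, s))) stop("property '", s, "' is missing but required")
  }
  invisible(TRUE)
}

#' Lipinski rule-of-five check
#'
#' Four rules, boundary-inclusive: MW <= 500 Da, logP <= 5, H-bond donors
#' <= 5, H-bond acceptors (N+O) <= 10. A compound with HBD exactly 5 passes
#' the donor rule.
#'
#' @param props a [MolecularProperties-class] with `mw`, `milogp`, `nhbd`,
#'   `nhba` present.
#' @return a [RuleReport-class].
#' @export
#' @examples
#' p <- molecularProperties(milogp = -0.73, mw = 317.27, nhba = 7, nhbd = 5)
#' lipinskiViolations(p)  # 0 violations
lipinskiViolations <- function(props) {
  stopifnot(is(props, "MolecularProperties"))
  .needProps(props, c("mw", "milogp", "nhbd", "nhba"))
  rules <- data.frame(
    rule = c("MW <= 500", "logP <= 5", "HBD <= 5", "HBA <= 10"),
    threshold = c(500, 5, 5, 10),
    observed = c(props@mw, props@milogp, props@nhbd, props@nhba),
    stringsAsFactors = FALSE
  )
  rules$pass <- rules$observed <= rules$threshold
  new("RuleReport", rules = rules, violations = sum(!rules$pass))
}

#' Veber oral-bioavailability check
#'
#' TPSA strictly below 140 square Angstrom and at most 10 rotatable bonds.
#'
#' @param props a [MolecularProperties-class] with `tpsa` and `nrotb`.
#' @return a [RuleReport-class] with the two rules.
#' @export
veberCheck <- function(props) {
  stopifnot(is(props, "MolecularProperties"))
  .needProps(props, c("tpsa", "nrotb"))
  rules <- data.frame(
    rule = c("TPSA < 140", "ROTB <= 10"),
    threshold = c(140, 10),
    observed = c(props@tpsa, props@nrotb),
    pass = c(props@tpsa < 140, props@nrotb <= 10),
    stringsAsFactors = FALSE
  )
  new("RuleReport", rules = rules, violations = sum(!rules$pass))
}

setMethod("show", "RuleReport", function(object) {
  cat(sprintf("RuleReport: %d violation(s)\n", object@violations))
  r <- object@rules
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-12s observed %8.2f  %s\n", r$rule[i], r$observed[i],
                if (r$pass[i]) "pass" else "FAIL"))
  }
  invisible(object)
})

#' Classify a bioactivity score
#'
#' Positive scores indicate considerable activity against the target, scores
#' in [-0.5, 0] moderate activity, and scores below -0.5 inactivity. The
#' three classes partition the real line; both boundaries belong to
#' `moderate`.
#'
#' @param score numeric vector of bioactivity scores.
#' @return factor with levels `considerable`, `moderate`, `inactive`.
#' @export
#' @examples
#' bioactivityClass(c(0.03, -0.15, -0.51))
bioactivityClass <- function(score) {
  if (!all(is.finite(score))) stop("scores must be finite")
  cls <- ifelse(score > 0, "considerable",
                ifelse(score >= -0.5, "moderate", "inactive"))
  factor(cls, levels = c("considerable", "moderate", "inactive"))
}

#' Sigmoid contribution of one property to the drug score
#'
#' The logistic s = 1 / (1 + exp(a p + b)), evaluated overflow-safely; the
#' midpoint s = 1/2 sits at p = -b/a.
#'
#' @param p property value.
#' @param a,b slope and offset of the property's spline.
#' @return value in (0, 1).
#' @export
#' @examples
#' sigmoidContribution(1.98, 1, -5)  # ~0.9535, the clogP term of petunidin
sigmoidContribution <- function(p, a, b) {
  if (!all(is.finite(c(p, a, b)))) stop("inputs must be finite")
  stats::plogis(-(a * p + b))
}

# (a, b) spline parameters per property term; `corrected` fixes the signs of
# the logS and druglikeness terms so that better solubility and higher
# druglikeness increase the score (the literal published pairs, kept behind
# the compatibility switch, invert those two terms).
.ds_params <- list(
  corrected = list(clogp = c(1, -5), logs = c(-1, -5),
                   mw = c(0.012, -6), druglikeness = c(-1, 0)),
  literal = list(clogp = c(1, -5), logs = c(1, 5),
                 mw = c(0.012, -6), druglikeness = c(1, 0))
)

.tox_multiplier <- c(none = 1.0, medium = 0.8, high = 0.6)

#' Aggregate drug score
#'
#' Multiplicative aggregation of four sigmoid-transformed properties and the
#' four toxicity-risk multipliers:
#' \deqn{DS = \prod_i \left(\tfrac12 + \tfrac12 s_i\right) \prod_j t_j}
#' with s_i the logistic contributions of clogP, logS, MW and druglikeness
#' (parameter pairs (1, -5), (-1, -5), (0.012, -6), (-1, 0)) and t_j = 1.0,
#' 0.8 or 0.6 for no, medium or high risk in each toxicity category. The
#' score lies in (0, 1); higher is more drug-like.
#'
#' @param props a [MolecularProperties-class] with `clogp`, `logs`, `mw`,
#'   `druglikeness` and the toxicity flags present.
#' @param literalParams use the literal published (a, b) pairs instead of
#'   the sign-corrected ones (compatibility switch; inverts the solubility
#'   and druglikeness terms and gives grossly different scores).
#' @return the drug score, a number in (0, 1).
#' @export
#' @examples
#' p <- molecularProperties(clogp = 1.980, logs = -2.338, mw = 317.27,
#'                          druglikeness = 1.310)
#' drugScore(p)  # ~0.802
drugScore <- function(props, literalParams = FALSE) {
  stopifnot(is(props, "MolecularProperties"))
  .needProps(props, c("clogp", "logs", "mw", "druglikeness"))
  pars <- .ds_params[[if (literalParams) "literal" else "corrected"]]
  vals <- c(clogp = props@clogp, logs = props@logs, mw = props@mw,
            druglikeness = props@druglikeness)
  terms <- vapply(names(pars), function(nm) {
    s <- sigmoidContribution(vals[[nm]], pars[[nm]][1], pars[[nm]][2])
    0.5 + 0.5 * s
  }, numeric(1))
  prod(terms) * prod(.tox_multiplier[props@toxicity])
}
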