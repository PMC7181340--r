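#' @include AllClasses.R
NULL

#' Rank O-H sites by one reactivity metric
#'
#' Stable sort of site labels by a chosen per-site metric (BDE, Wiberg bond
#' order, pKa, dissociation energy, atomic charge, ...). Ties keep input
#' order and are flagged via the `"ties"` attribute. For atomic charges the
#' reactive site carries the most negative oxygen charge, so rank those
#' ascending too.
#'
#' @param evidence data.frame with a `site` column and one column per
#'   metric; `NA` marks an absent value.
#' @param metric name of the metric column to rank by.
#' @param direction `"asc"` (default; most labile first for BDE, bond order,
#'   pKa, charge) or `"desc"`.
#' @return character vector of site labels (sites with `NA` metric dropped),
#'   with attribute `ties` (logical) marking whether any tie occurred.
#' @export
#' @examples
#' ev <- data.frame(site = c("3", "5"), bond_order = c(0.6825, 0.7180))
#' rankSites(ev, "bond_order")
rankSites <- function(evidence, metric, direction = c("asc", "desc")) {
  direction <- match.arg(direction)
  if (!"site" %in% names(evidence)) stop("'evidence' needs a 'site' column")
  if (!metric %in% names(evidence)) {
    stop("metric '", metric, "' absent from the evidence table")
  }
  v <- evidence[[metric]]
  keep <- !is.na(v)
  if (!any(keep)) stop("metric '", metric, "' has no values to rank")
  v <- v[keep]
  sites <- as.character(evidence$site[keep])
  ord <- order(if (direction == "asc") v else -v)  # stable radix/shell sort
  out <- sites[ord]
  attr(out, "ties") <- anyDuplicated(v) > 0L
  out
}

#' Concordance of reactivity metrics on the most labile site
#'
#' Each metric nominates its extremal site (the first after ranking); the
#' concordance is the fraction of metrics agreeing with the modal nominee.
#' 1.0 means every line of evidence (BDE, bond order, pKa, atomic charge,
#' ...) points at the same site.
#'
#' @param evidence data.frame as in [rankSites()].
#' @param metrics named character vector mapping metric column names to
#'   ranking directions, e.g. `c(bde = "asc", bond_order = "asc")`.
#' @return list with `concordance` in [0, 1], `nominations` (named character
#'   of each metric's extremal site) and `modal_site`.
#' @export
siteConcordance <- function(evidence, metrics) {
  if (is.null(names(metrics)) || any(!nzchar(names(metrics)))) {
    stop("'metrics' must be a named vector: c(metric = direction, ...)")
  }
  noms <- vapply(names(metrics), function(m) {
    rankSites(evidence, m, metrics[[m]])[1]
  }, character(1))
  tab <- sort(table(noms), decreasing = TRUE)
  list(
    concordance = as.numeric(tab[1]) / length(noms),
    nominations = noms,
    modal_site = names(tab)[1]
  )
}

#' Protonation state of an O-H site at ambient pH
#'
#' pH above the site pKa means the deprotonated form dominates; below, the
#' undissociated form. At pH exactly equal to pKa the site is
#' half-dissociated; by convention the undissociated label is returned with
#' a boundary flag.
#'
#' @param pka site pKa.
#' @param ph ambient pH; [bloodPH] (7.4) is the conventional physiological
#'   value.
#' @return `"deprotonated"` or `"undissociated"`, with logical attribute
#'   `half_dissociated`.
#' @export
#' @examples
#' protonationState(5.99, bloodPH)  # deprotonated in blood
protonationState <- function(pka, ph = bloodPH) {
  if (!all(is.finite(c(pka, ph)))) stop("pKa and pH must be finite")
  state <- if (ph > pka) "deprotonated" else "undissociated"
  attr(state, "half_dissociated") <- ph == pka
  state
}

#' Physiological blood pH
#'
#' Conventional value 7.4, used as the default ambient pH in protonation
#' reports.
#' @export
bloodPH <- 7.4
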