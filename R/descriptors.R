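#' @include AllClasses.R units.R
NULL

#' IP and EA by the Koopmans (orbital) approximation
#'
#' IP = -E(HOMO), EA = -E(LUMO).
#'
#' @param homo,lumo frontier-orbital energies in eV.
#' @return named numeric `c(ip = , ea = )` in eV.
#' @export
#' @examples
#' koopmansIpEa(-8.73, -6.16)  # petunidin, gas phase
koopmansIpEa <- function(homo, lumo) {
  if (!all(is.finite(c(homo, lumo)))) stop("HOMO and LUMO must be finite")
  c(ip = -homo, ea = -lumo)
}

#' IP and EA from total energies of the neutral, cation and anion
#'
#' Vertical energy differences: IP = E(cation) - E(neutral),
#' EA = E(neutral) - E(anion). All three energies must already share a unit
#' (convert hartree inputs with [convertEnergy()] first).
#'
#' @param e_neutral,e_cation,e_anion total energies, common unit (eV for
#'   eV-scale descriptors).
#' @return named numeric `c(ip = , ea = )`.
#' @export
#' @examples
#' energyIpEa(0, 9.97, -4.87)  # petunidin
energyIpEa <- function(e_neutral, e_cation, e_anion) {
  if (!all(is.finite(c(e_neutral, e_cation, e_anion)))) {
    stop("all three energies must be finite")
  }
  c(ip = e_cation - e_neutral, ea = e_neutral - e_anion)
}

#' Global conceptual-DFT reactivity descriptors from an IP/EA pair
#'
#' Hardness eta = (IP - EA)/2, electronegativity chi = (IP + EA)/2, softness
#' S = 1/(2 eta), chemical potential mu = -chi and electrophilicity index
#' omega = mu^2 / (2 eta). Full precision is kept internally; rounding to two
#' decimals happens only at the report boundary.
#'
#' When IP = EA the hardness vanishes and softness/electrophilicity are
#' undefined; the result is returned with `degenerate = TRUE`, infinite
#' S and omega, and a warning — not an error — so batch tables survive
#' degenerate rows.
#'
#' @param ip,ea ionisation potential and electron affinity, eV.
#' @param method provenance of the pair, `"orbital"` or `"energy"`.
#' @return a [ReactivityDescriptors-class].
#' @export
#' @examples
#' globalDescriptors(9.97, 4.87, "energy")  # petunidin, energy method
globalDescriptors <- function(ip, ea, method = c("orbital", "energy")) {
  method <- match.arg(method)
  if (!all(is.finite(c(ip, ea)))) stop("IP and EA must be finite")
  eta <- (ip - ea) / 2
  chi <- (ip + ea) / 2
  mu <- -chi
  degenerate <- eta == 0
  if (degenerate) {
    warning("IP equals EA: hardness is zero, softness and electrophilicity ",
            "are undefined (flagged infinite)")
    softness <- Inf
    omega <- if (chi == 0) NaN else Inf
  } else {
    softness <- 1 / (2 * eta)
    omega <- mu^2 / (2 * eta)
  }
  new("ReactivityDescriptors", method = method, ip = ip, ea = ea, eta = eta,
      softness = softness, chi = chi, mu = mu, omega = omega,
      degenerate = degenerate)
}

setMethod("show", "ReactivityDescriptors", function(object) {
  cat(sprintf("ReactivityDescriptors (%s method%s)\n", object@method,
              if (object@degenerate) ", degenerate IP = EA" else ""))
  v <- c(IP = object@ip, EA = object@ea, eta = object@eta,
         S = object@softness, chi = object@chi, mu = object@mu,
         omega = object@omega)
  for (n in names(v)) {
    cat(sprintf("  %-6s %8s\n", n,
                ifelse(is.finite(v[[n]]), sprintf("%.2f", roundHalfUp(v[[n]])),
                       format(v[[n]]))))
  }
  invisible(object)
})

#' Flatten descriptors to a one-row data.frame
#'
#' @param x a [ReactivityDescriptors-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with method, ip, ea, eta, softness, chi, mu, omega,
#'   degenerate.
#' @export
as.data.frame.ReactivityDescriptors <- function(x, row.names = NULL,
                                                optional = FALSE, ...) {
  data.frame(method = x@method, ip = x@ip, ea = x@ea, eta = x@eta,
             softness = x@softness, chi = x@chi, mu = x@mu, omega = x@omega,
             degenerate = x@degenerate, stringsAsFactors = FALSE)
}

#' Convert a HOMO-LUMO gap to the corresponding photon wavelength
#'
#' lambda = 1239.842 eV nm / gap.
#'
#' @param gap energy gap in eV, strictly positive.
#' @return wavelength in nm.
#' @export
#' @examples
#' gapToWavelength(2.57)  # ~482.4 nm: the visible absorption of petunidin
gapToWavelength <- function(gap) {
  if (!all(is.finite(gap)) || any(gap <= 0)) {
    stop("gap must be a positive, finite energy in eV")
  }
  unitConstants$ev_nm_product / gap
}

#' Descriptor table for several IP/EA pairs
#'
#' Builds the descriptor-by-method report table (one column set per method,
#' one block per molecule), mirroring the usual presentation of global
#' reactivity descriptors.
#'
#' @param pairs data.frame with columns `molecule_id`, `method`, `ip`, `ea`
#'   (eV).
#' @return data.frame with one row per (molecule, method) and the descriptor
#'   columns at full precision.
#' @export
descriptorTable <- function(pairs) {
  req <- c("molecule_id", "method", "ip", "ea")
  if (!all(req %in% names(pairs))) {
    stop("'pairs' needs columns ", paste(sQuote(req), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    d <- globalDescriptors(pairs$ip[i], pairs$ea[i], pairs$method[i])
    cbind(molecule_id = pairs$molecule_id[i], as.data.frame(d))
  })
  do.call(rbind, rows)
}
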