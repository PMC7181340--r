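#' @include AllClasses.R AllGenerics.R
NULL

# standard atomic weights (Dalton)
.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904
)

# SDF V2000 old-style charge codes
.sdf_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                 `5` = -1L, `6` = -2L, `7` = -3L)

# bond is in a ring iff it is not a bridge: endpoints stay connected after
# removing it (molecular graphs here are tiny, BFS per bond is fine)
.ringBonds <- function(n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  adj <- lapply(seq_len(n_atoms), function(i) integer(0))
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  vapply(seq_len(nrow(bonds)), function(k) {
    from <- bonds$a1[k]; to <- bonds$a2[k]
    seen <- rep(FALSE, n_atoms)
    seen[from] <- TRUE
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == k) next
        w <- if (bonds$a1[e] == v) bonds$a2[e] else bonds$a1[e]
        if (!seen[w]) {
          if (w == to) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

#' Parse a SMILES string into a molecular graph
#'
#' Structure perception (ring closure, aromaticity, implicit hydrogens,
#' formal charges) is delegated to OpenBabel through
#' \pkg{ChemmineOB}/\pkg{ChemmineR}; the result is reduced to a
#' hydrogen-suppressed heavy-atom graph with kekulized bond orders,
#' perceived ring membership and attached-hydrogen counts, on which the
#' property counters operate.
#'
#' @param smiles a single SMILES string.
#' @return a validated [MolecularGraph-class].
#' @export
#' @examples
#' g <- parseStructure("Oc1ccccc1")  # phenol
#' countHBD(g)
parseStructure <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles))) {
    stop("'smiles' must be a single non-empty string")
  }
  sdfstr <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF", source = paste0(smiles, "\n"),
      options = data.frame(names = "h", args = "", stringsAsFactors = FALSE)
    ),
    error = function(e) {
      stop("SMILES parse failure for '", smiles, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (!nzchar(sdfstr)) stop("SMILES parse failure for '", smiles, "'")
  sdf <- suppressWarnings(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdfstr)))
  )[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  charge_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charges <- .sdf_charge[as.character(charge_col)]
  charges[is.na(charges)] <- 0L
  all_bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  is_h <- elements == "H"
  heavy_idx <- which(!is_h)
  if (length(heavy_idx) == 0L) stop("no heavy atoms in '", smiles, "'")
  remap <- integer(n); remap[heavy_idx] <- seq_along(heavy_idx)

  nH <- integer(length(heavy_idx))
  keep <- logical(nrow(all_bonds))
  for (k in seq_len(nrow(all_bonds))) {
    a1 <- all_bonds$a1[k]; a2 <- all_bonds$a2[k]
    if (is_h[a1] && is_h[a2]) next
    if (is_h[a2]) {
      nH[remap[a1]] <- nH[remap[a1]] + 1L
    } else if (is_h[a1]) {
      nH[remap[a2]] <- nH[remap[a2]] + 1L
    } else {
      keep[k] <- TRUE
    }
  }
  hb <- all_bonds[keep, , drop = FALSE]
  hb$a1 <- remap[hb$a1]; hb$a2 <- remap[hb$a2]
  rownames(hb) <- NULL

  degree <- integer(length(heavy_idx))
  for (k in seq_len(nrow(hb))) {
    degree[hb$a1[k]] <- degree[hb$a1[k]] + 1L
    degree[hb$a2[k]] <- degree[hb$a2[k]] + 1L
  }
  hb$inRing <- .ringBonds(length(heavy_idx), hb)
  in_ring <- rep(FALSE, length(heavy_idx))
  if (nrow(hb)) {
    in_ring[unique(c(hb$a1[hb$inRing], hb$a2[hb$inRing]))] <- TRUE
  }

  has_double <- rep(FALSE, length(heavy_idx))
  if (nrow(hb)) {
    dd <- hb[hb$order >= 2, , drop = FALSE]
    has_double[unique(c(dd$a1, dd$a2))] <- TRUE
  }
  # kekulized aromaticity: a ring atom is aromatic-like when it carries a
  # double bond itself, or is a ring heteroatom all of whose ring
  # neighbours do (the lone-pair donor of an aromatic sextet, e.g. furan O)
  el <- elements[heavy_idx]
  aromatic <- rep(FALSE, length(heavy_idx))
  for (i in which(in_ring)) {
    if (has_double[i]) { aromatic[i] <- TRUE; next }
    if (el[i] %in% c("O", "N", "S")) {
      nb <- integer(0)
      for (k in which(hb$inRing)) {
        if (hb$a1[k] == i) nb <- c(nb, hb$a2[k])
        if (hb$a2[k] == i) nb <- c(nb, hb$a1[k])
      }
      if (length(nb) && all(has_double[nb])) aromatic[i] <- TRUE
    }
  }

  atoms <- data.frame(
    element = el,
    charge = as.integer(charges[heavy_idx]),
    nH = nH,
    degree = degree,
    inRing = in_ring,
    aromatic = aromatic,
    stringsAsFactors = FALSE
  )
  new("MolecularGraph", atoms = atoms, bonds = hb, smiles = smiles)
}

setMethod("show", "MolecularGraph", function(object) {
  a <- object@atoms
  comp <- table(a$element)
  cat("MolecularGraph:", object@smiles, "\n")
  cat("  heavy atoms:", nrow(a),
      paste0("(", paste(names(comp), comp, sep = "", collapse = " "), ")"),
      " bonds:", nrow(object@bonds), "\n")
  cat("  attached H:", sum(a$nH), "  net charge:", sum(a$charge), "\n")
  invisible(object)
})

#' Heavy-atom count
#' @param x a [MolecularGraph-class].
#' @return integer number of non-hydrogen atoms.
#' @export
countHeavyAtoms <- function(x) {
  stopifnot(is(x, "MolecularGraph"))
  nrow(x@atoms)
}

#' @rdname molecularWeight
#' @export
setMethod("molecularWeight", "MolecularGraph", function(x) {
  a <- x@atoms
  unknown <- setdiff(unique(a$element), names(.atomic_weights))
  if (length(unknown)) {
    stop("no atomic weight for element(s): ", paste(unknown, collapse = ", "))
  }
  sum(.atomic_weights[a$element]) + sum(a$nH) * .atomic_weights[["H"]]
})

#' @rdname countHBD
#' @export
setMethod("countHBD", "MolecularGraph", function(x) {
  a <- x@atoms
  as.integer(sum(a$nH[a$element %in% c("O", "N")]))
})

#' @rdname countHBA
#' @export
setMethod("countHBA", "MolecularGraph", function(x) {
  as.integer(sum(x@atoms$element %in% c("O", "N")))
})

#' @rdname countRotatable
#' @export
setMethod("countRotatable", "MolecularGraph", function(x) {
  a <- x@atoms; b <- x@bonds
  if (nrow(b) == 0L) return(0L)
  cand <- b$order == 1L & !b$inRing &
    a$degree[b$a1] >= 2L & a$degree[b$a2] >= 2L
  # exclude amide C-N: single bond between N and a carbon double-bonded to O
  carbonyl_c <- rep(FALSE, nrow(a))
  dd <- b[b$order == 2L, , drop = FALSE]
  for (k in seq_len(nrow(dd))) {
    i <- dd$a1[k]; j <- dd$a2[k]
    if (a$element[i] == "C" && a$element[j] == "O") carbonyl_c[i] <- TRUE
    if (a$element[j] == "C" && a$element[i] == "O") carbonyl_c[j] <- TRUE
  }
  amide <- (a$element[b$a1] == "N" & carbonyl_c[b$a2]) |
           (a$element[b$a2] == "N" & carbonyl_c[b$a1])
  as.integer(sum(cand & !amide))
})

# Ertl fragment contributions (square Angstrom) for the N/O environments
# needed here; charged aromatic oxygen is mapped onto the aromatic-oxygen
# value, the closest published fragment.
.tpsaO <- function(atom, has_double, in_3ring) {
  if (atom$aromatic) return(13.14)
  if (atom$nH >= 1L) return(20.23)
  if (atom$charge < 0L) return(23.06)
  if (has_double) return(17.07)
  if (in_3ring) return(12.53)
  9.23
}

.tpsaN <- function(atom, has_double, has_triple) {
  if (atom$aromatic) {
    if (atom$charge > 0L) return(if (atom$nH > 0L) 14.14 else 4.10)
    if (atom$nH > 0L) return(15.79)
    if (atom$degree >= 3L) return(4.41)
    return(12.89)
  }
  if (atom$charge > 0L) {
    if (atom$nH == 3L) return(27.64)
    if (atom$nH == 2L) return(if (has_double) 25.59 else 16.61)
    if (atom$nH == 1L) return(if (has_double) 13.97 else 4.44)
    if (has_triple) return(4.36)
    return(if (has_double) 3.01 else 0.00)
  }
  if (atom$nH == 2L) return(26.02)
  if (atom$nH == 1L) return(if (has_double) 23.85 else 12.03)
  if (has_triple) return(23.79)
  if (has_double) return(12.36)
  3.24
}

#' @rdname tpsa
#' @export
setMethod("tpsa", "MolecularGraph", function(x) {
  a <- x@atoms; b <- x@bonds
  if (nrow(a) == 0L) return(0)
  n_double <- integer(nrow(a)); n_triple <- integer(nrow(a))
  ring_sz3 <- rep(FALSE, nrow(a))
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == 2L) {
      n_double[b$a1[k]] <- n_double[b$a1[k]] + 1L
      n_double[b$a2[k]] <- n_double[b$a2[k]] + 1L
    } else if (b$order[k] == 3L) {
      n_triple[b$a1[k]] <- n_triple[b$a1[k]] + 1L
      n_triple[b$a2[k]] <- n_triple[b$a2[k]] + 1L
    }
  }
  # oxygen in a three-membered ring (oxirane): both neighbours bonded
  has_bond <- function(i, j) any((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
  for (i in which(a$element == "O" & a$inRing & a$degree == 2L)) {
    nb <- c(b$a2[b$a1 == i], b$a1[b$a2 == i])
    if (length(nb) == 2L && has_bond(nb[1], nb[2])) ring_sz3[i] <- TRUE
  }
  total <- 0
  for (i in seq_len(nrow(a))) {
    if (!a$element[i] %in% c("N", "O")) next
    atom <- a[i, ]
    total <- total + if (atom$element == "O") {
      .tpsaO(atom, n_double[i] > 0L, ring_sz3[i])
    } else {
      .tpsaN(atom, n_double[i] > 0L, n_triple[i] > 0L)
    }
  }
  total
})
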