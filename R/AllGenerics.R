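#' @include AllClasses.R
NULL

#' Access the underlying species table
#' @param x a [SpeciesSet-class].
#' @return the `data.frame` of species records.
#' @export
setGeneric("speciesData", function(x) standardGeneric("speciesData"))

#' @rdname speciesData
#' @export
setMethod("speciesData", "SpeciesSet", function(x) x@data)

#' Number of records / atoms
#' @param x a SpeciesSet or MolecularGraph.
#' @export
setMethod("length", "SpeciesSet", function(x) nrow(x@data))

#' Atom table of a molecular graph
#' @param x a [MolecularGraph-class].
#' @return data.frame of heavy atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "MolecularGraph", function(x) x@atoms)

#' Bond table of a molecular graph
#' @param x a [MolecularGraph-class].
#' @return data.frame of bonds between heavy atoms.
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname bonds
#' @export
setMethod("bonds", "MolecularGraph", function(x) x@bonds)

#' Molecular weight of a parsed structure
#'
#' Sum of standard atomic weights over heavy atoms and attached hydrogens
#' (C 12.011, H 1.008, O 15.999, ...). The electron mass of charged species
#' is ignored, so formal charge does not alter the weight. Additive over
#' disconnected components.
#'
#' @param x a [MolecularGraph-class].
#' @return molecular weight in Dalton.
#' @export
#' @examples
#' molecularWeight(parseStructure("C"))  # methane, 16.04
setGeneric("molecularWeight", function(x) standardGeneric("molecularWeight"))

#' Count hydrogen-bond donors
#'
#' Number of hydrogens attached to oxygen or nitrogen.
#'
#' @param x a [MolecularGraph-class].
#' @return integer count.
#' @export
setGeneric("countHBD", function(x) standardGeneric("countHBD"))

#' Count hydrogen-bond acceptors
#'
#' Count of nitrogen plus oxygen atoms — the original rule-of-five N+O
#' convention, which includes charged aromatic oxygen (the pyrylium O+ of
#' anthocyanidins counts).
#'
#' @param x a [MolecularGraph-class].
#' @return integer count.
#' @export
setGeneric("countHBA", function(x) standardGeneric("countHBA"))

#' Count rotatable bonds
#'
#' Non-ring single bonds between two non-terminal heavy atoms (both ends
#' with at least two heavy neighbours); amide C-N bonds are excluded. Under
#' this convention a methoxy O-CH3 bond is terminal (not rotatable) while
#' the aryl-O bond of the methoxy group rotates.
#'
#' @param x a [MolecularGraph-class].
#' @return integer count.
#' @export
setGeneric("countRotatable", function(x) standardGeneric("countRotatable"))

#' Topological polar surface area
#'
#' Ertl fragment-contribution TPSA over N and O environments (e.g. hydroxyl
#' 20.23, ether 9.23, aromatic ring O 13.14, carbonyl 17.07 square Angstrom).
#' Charged aromatic oxygen (pyrylium O+) is assigned the aromatic-oxygen
#' fragment value, the closest published environment.
#'
#' @param x a [MolecularGraph-class].
#' @return TPSA in square Angstrom.
#' @export
setGeneric("tpsa", function(x) standardGeneric("tpsa"))
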