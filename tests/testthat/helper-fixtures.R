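# shared builders for the unit tests

petunidin_smiles <- "COc1cc(-c2[o+]c3cc(O)cc(O)c3cc2O)cc(O)c1O"

# same molecule, three different atom orderings
petunidin_renumberings <- c(
  "Oc1cc(O)c2cc(O)c(-c3cc(OC)c(O)c(O)c3)[o+]c2c1",
  "COc1cc(cc(O)c1O)-c1[o+]c2cc(O)cc(O)c2cc1O",
  "c1(O)cc(O)c2c(c1)[o+]c(-c1cc(OC)c(O)c(O)c1)c(O)c2"
)

tiny_species <- function() {
  speciesSet(
    molecule_id = "PhOH",
    form = c("neutral", "radical", "radical_cation", "anion", "radical"),
    site = c(NA, "1", NA, "1", "2"),
    phase = "gas",
    enthalpy_hartree = c(-307.35, -306.72, -307.05, -306.90, -306.70),
    homo_ev = c(-6.2, NA, NA, NA, NA),
    lumo_ev = c(-0.8, NA, NA, NA, NA)
  )
}

random_fixture_spec <- function(molecule_id = "rand", n_sites = 3,
                                phase = "gas",
                                refs = referenceEnthalpies()) {
  sites <- as.character(seq_len(n_sites))
  fixtureSpec(
    molecule_id, phase,
    bde = stats::setNames(runif(n_sites, 60, 110), sites),
    aip = runif(1, 120, 260),
    pa = stats::setNames(runif(n_sites, -120, 60), sites),
    refs = refs,
    neutral_anchor = runif(1, -2000, -100)
  )
}
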