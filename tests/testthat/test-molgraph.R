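test_that("small molecules parse with correct hydrogen and atom counts", {
  w <- parseStructure("O")
  expect_equal(countHeavyAtoms(w), 1)
  expect_equal(atoms(w)$nH, 2L)
  expect_equal(molecularWeight(parseStructure("C")), 16.04, tolerance = 1e-3)
  expect_error(parseStructure("C1CC"), "parse failure")   # unclosed ring
  expect_error(parseStructure(""), "non-empty")
})

test_that("petunidin structure counting matches the published property table", {
  g <- parseStructure(petunidin_smiles)
  expect_equal(countHeavyAtoms(g), 23)
  expect_equal(round(molecularWeight(g), 2), 317.27)
  expect_equal(countHBD(g), 5L)
  expect_equal(countHBA(g), 7L)
  expect_equal(countRotatable(g), 2L)
  expect_equal(tpsa(g), 121.54, tolerance = 2.5 / 121.54)
  expect_equal(sum(atoms(g)$charge), 1L)  # flavylium cation
})

test_that("counts are invariant under atom renumbering of the SMILES", {
  ref <- parseStructure(petunidin_smiles)
  for (s in petunidin_renumberings) {
    g <- parseStructure(s)
    expect_equal(countHeavyAtoms(g), countHeavyAtoms(ref))
    expect_equal(molecularWeight(g), molecularWeight(ref), tolerance = 1e-9)
    expect_equal(countHBD(g), countHBD(ref))
    expect_equal(countHBA(g), countHBA(ref))
    expect_equal(countRotatable(g), countRotatable(ref))
    expect_equal(tpsa(g), tpsa(ref), tolerance = 1e-9)
  }
})

test_that("donor/acceptor counts follow the N+O convention", {
  expect_equal(countHBD(parseStructure("c1ccccc1")), 0L)   # benzene
  expect_equal(countHBA(parseStructure("c1ccccc1")), 0L)
  expect_equal(countHBD(parseStructure("CCO")), 1L)        # ethanol
  expect_equal(countHBA(parseStructure("NCC(=O)O")), 3L)   # glycine: N + 2 O
  g <- parseStructure("NCC(=O)O")
  expect_lte(countHBD(g), countHBA(g) +
               sum(atoms(g)$nH > 0 & atoms(g)$element %in% c("N", "O")))
})

test_that("rotatable-bond rule: terminal atoms and amides excluded", {
  expect_equal(countRotatable(parseStructure("CC")), 0L)      # both terminal
  expect_equal(countRotatable(parseStructure("CCCC")), 1L)    # n-butane
  expect_equal(countRotatable(parseStructure("CCCCC")), 2L)
  expect_equal(countRotatable(parseStructure("CC(=O)NC")), 0L) # N-methylacetamide
  expect_equal(countRotatable(parseStructure("c1ccccc1-c1ccccc1")), 1L) # biphenyl
})

test_that("TPSA fragment sums match the published fragment table", {
  expect_equal(tpsa(parseStructure("c1ccccc1")), 0)
  expect_equal(tpsa(parseStructure("Oc1ccccc1")), 20.23)  # phenol: one OH
  expect_equal(tpsa(parseStructure("COC")), 9.23)         # ether
  expect_equal(tpsa(parseStructure("CC(C)=O")), 17.07)    # ketone
  expect_equal(tpsa(parseStructure("c1ccoc1")), 13.14)    # furan aromatic O
  expect_equal(tpsa(parseStructure("NCC(=O)O")),
               26.02 + 17.07 + 20.23)                     # glycine fragments
})

test_that("molecular weight is additive over disconnected components", {
  both <- parseStructure("CCO.O")
  expect_equal(molecularWeight(both),
               molecularWeight(parseStructure("CCO")) +
                 molecularWeight(parseStructure("O")),
               tolerance = 1e-9)
})
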