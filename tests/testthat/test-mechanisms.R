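refs <- referenceEnthalpies()
k <- unitConstants$hartree_to_kcal

test_that("each mechanism parameter reduces correctly on null reactions", {
  # parent = radical + H atom: zero-cost homolysis
  expect_equal(bde(h_parent = -300 + refs@hAtom, h_radical = -300, refs), 0)
  expect_equal(aip(-300, -300, refs), 0)
  expect_equal(aip(-300, -300, refs, include_electron = TRUE),
               refs@electron * k)
  expect_equal(pde(-300, -300, refs), refs@proton * k)
  expect_equal(pa(-300, -300, refs), refs@proton * k)
  expect_equal(ete(-300, -300), 0)
})

test_that("phase mismatch between species and references is rejected", {
  expect_error(bde(-300, -299, refs, phase = "water"), "phase mismatch")
})

test_that("petunidin fixture reproduces the published mechanism parameters", {
  fx <- petunidinFixture()
  tab <- siteTable(fx$species_gas, fx$refs_gas)
  s3 <- tab[tab$site == "3", ]
  expect_equal(s3$bde, 78.72, tolerance = 1e-9)
  expect_equal(s3$aip, 229.91, tolerance = 1e-9)
  expect_equal(s3$pde, 162.56, tolerance = 1e-9)
  expect_equal(s3$pa, -112.68, tolerance = 1e-9)
  expect_equal(s3$ete, 505.15, tolerance = 1e-9)
  # the two two-step routes share the published cycle sum
  expect_equal(s3$aip + s3$pde, 392.47, tolerance = 1e-9)
  expect_equal(s3$pa + s3$ete, 392.47, tolerance = 1e-9)

  tw <- siteTable(fx$species_water, fx$refs_water)
  expect_equal(tw$bde[tw$site == "3"], 77.02, tolerance = 1e-9)

  expect_equal(siteOrdering(tab), "3 < 4' < 5 < 7 < 3'")
  expect_equal(stats::setNames(tab$bde[match(c("3","5","7","3'","4'"), tab$site)],
                               c("3","5","7","3'","4'")),
               c(`3` = 78.72, `5` = 85.06, `7` = 88.94, `3'` = 90.25,
                 `4'` = 79.84), tolerance = 1e-9)
})

test_that("siteTable demands a neutral record and tolerates partial species", {
  s <- tiny_species()
  tab <- siteTable(s, refs)
  expect_equal(nrow(tab), 2)          # one row per radical site
  expect_true(all(!is.na(tab$bde)))
  expect_true(is.na(tab$pa[tab$site == "2"]))  # no anion at site 2

  no_neutral <- subsetSpecies(s, form = c("radical", "anion"))
  expect_error(siteTable(no_neutral, refs), "no neutral record")

  single <- speciesSet("m", c("neutral", "radical"), c(NA, "1"), "gas",
                       c(-300.5, -299.9))
  expect_equal(nrow(siteTable(single, refs)), 1)
})

test_that("cycle closure holds exactly on seeded random fixtures", {
  set.seed(123)
  for (i in 1:200) {
    spec <- random_fixture_spec(n_sites = sample(1:5, 1))
    tab <- siteTable(makeSpeciesSet(spec), spec$refs)
    bridge <- (spec$refs@proton - spec$refs@hAtom) * k
    expect_equal(tab$aip + tab$pde, tab$bde + bridge, tolerance = 1e-6)
    expect_equal(tab$pa + tab$ete, tab$bde + bridge, tolerance = 1e-6)
  }
})

test_that("parameters are invariant under a uniform enthalpy translation", {
  spec <- random_fixture_spec(n_sites = 3)
  tab1 <- siteTable(makeSpeciesSet(spec), spec$refs)
  shift <- 5.4321
  spec$neutral_anchor <- spec$neutral_anchor + shift
  tab2 <- siteTable(makeSpeciesSet(spec), spec$refs)
  for (col in c("bde", "aip", "pde", "pa", "ete")) {
    expect_equal(tab2[[col]], tab1[[col]], tolerance = 1e-7)
  }
})

test_that("mechanism preference follows the cheapest physical first step", {
  v <- preferredMechanism(data.frame(bde = 78.72, aip = 229.91, pa = -112.68))
  expect_equal(v@mechanism, "HAT")
  expect_true("SPLET" %in% v@candidates$mechanism[v@candidates$excluded])

  expect_equal(preferredMechanism(
    data.frame(bde = 50, aip = 200, pa = 80))@mechanism, "HAT")
  expect_equal(preferredMechanism(
    data.frame(bde = 90, aip = 60, pa = 75))@mechanism, "SET_PT")
  # SPLET wins when proton loss is cheapest and physical
  expect_equal(preferredMechanism(
    data.frame(bde = 90, aip = 140, pa = 30))@mechanism, "SPLET")
  # ties broken HAT first, then SPLET
  expect_equal(preferredMechanism(
    data.frame(bde = 50, aip = 50, pa = 50))@mechanism, "HAT")
  expect_error(preferredMechanism(data.frame(bde = -1, aip = -2, pa = -3)),
               "excluded")
  expect_error(preferredMechanism(data.frame(x = 1)), "BDE")
})

test_that("substituent comparison classifies per-site BDE shifts", {
  fx <- petunidinFixture()
  parent <- siteTable(fx$species_gas, fx$refs_gas)

  amino <- substituentEffect(parent, fx$amino_bde)
  expect_equal(amino$verdict, "all_lower")
  expect_equal(nrow(amino$delta), 5)
  expect_true(all(amino$delta$delta < 0))

  glu <- substituentEffect(parent, fx$glucoside_bde)
  expect_equal(glu$verdict, "all_lower")
  expect_equal(nrow(glu$delta), 4)          # site 3 is glycosylated
  expect_equal(glu$not_comparable, "3")

  same <- substituentEffect(parent, parent)
  expect_equal(same$verdict, "none")
  expect_true(all(same$delta$delta == 0))

  expect_error(
    substituentEffect(parent, data.frame(site = "9", bde = 1)),
    "disjoint")
})
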