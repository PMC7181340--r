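test_that("inverse construction recovers prescribed targets to 1e-9 kcal/mol", {
  set.seed(99)
  for (i in 1:25) {
    spec <- random_fixture_spec(n_sites = sample(1:5, 1))
    tab <- siteTable(makeSpeciesSet(spec), spec$refs)
    expect_equal(stats::setNames(tab$bde, tab$site)[names(spec$bde)],
                 spec$bde, tolerance = 1e-9)
    expect_equal(unique(tab$aip), spec$aip, tolerance = 1e-9)
    expect_equal(stats::setNames(tab$pa, tab$site)[names(spec$pa)],
                 spec$pa, tolerance = 1e-9)
  }
})

test_that("zero targets with zero references collapse onto the neutral anchor", {
  refs0 <- referenceEnthalpies("gas", hAtom = 0, proton = 0, electron = 0)
  spec <- fixtureSpec("flat", bde = c(`1` = 0, `2` = 0), aip = 0,
                      pa = c(`1` = 0, `2` = 0), refs = refs0,
                      neutral_anchor = -500)
  d <- speciesData(makeSpeciesSet(spec))
  expect_true(all(d$enthalpy_hartree == -500))
})

test_that("over-constrained PA/ETE prescriptions are rejected", {
  refs <- referenceEnthalpies()
  bridge <- (refs@proton - refs@hAtom) * unitConstants$hartree_to_kcal
  expect_error(
    fixtureSpec("m", bde = c(`1` = 80), aip = 200,
                pa = c(`1` = 30), ete = c(`1` = 999), refs = refs),
    "over-constrained")
  # consistent pair is accepted; ete alone derives pa
  spec <- fixtureSpec("m", bde = c(`1` = 80), aip = 200,
                      ete = c(`1` = 60), refs = refs)
  expect_equal(unname(spec$pa), 80 + bridge - 60, tolerance = 1e-12)
})

test_that("generated species sets pass SpeciesSet validation", {
  set.seed(17)
  for (i in 1:5) {
    s <- makeSpeciesSet(random_fixture_spec())
    expect_true(validObject(s))
  }
})

test_that("anchoring is cosmetic: descriptor values ignore the anchor", {
  spec1 <- random_fixture_spec()
  spec2 <- spec1
  spec2$neutral_anchor <- -1143.88
  t1 <- siteTable(makeSpeciesSet(spec1), spec1$refs)
  t2 <- siteTable(makeSpeciesSet(spec2), spec2$refs)
  expect_equal(t1$bde, t2$bde, tolerance = 1e-7)
  expect_equal(t1$pa, t2$pa, tolerance = 1e-7)
})

test_that("the petunidin bundle is internally consistent", {
  fx <- petunidinFixture()
  expect_equal(length(fx$species_gas), 12L)    # 1+5+1+5 species
  expect_equal(length(fx$species_water), 12L)
  d <- speciesData(fx$species_gas)
  expect_equal(d$enthalpy_hartree[d$form == "neutral"], -1143.88)
  hl <- d[d$form == "neutral", ]
  expect_equal(hl$lumo_ev - hl$homo_ev, 2.57)  # printed optical gap
  dw <- speciesData(fx$species_water)
  hw <- dw[dw$form == "neutral", ]
  expect_equal(hw$lumo_ev - hw$homo_ev, 2.71)
  expect_equal(nrow(fx$site_evidence), 5)
  expect_setequal(fx$site_evidence$site, c("3", "5", "7", "3'", "4'"))
})

test_that("bundled CSV fixture files mirror the in-code construction", {
  fx <- petunidinFixture()
  for (ph in c("gas", "water")) {
    path <- system.file("extdata",
                        sprintf("petunidin_species_%s.csv", ph),
                        package = "AntioxScreen")
    expect_true(nzchar(path))
    onDisk <- speciesData(readSpeciesTable(path))
    inCode <- speciesData(fx[[paste0("species_", ph)]])
    expect_equal(onDisk, inCode, tolerance = 1e-12)
  }
  ev_path <- system.file("extdata", "petunidin_site_evidence.csv",
                         package = "AntioxScreen")
  ev <- utils::read.csv(ev_path, check.names = FALSE, fileEncoding = "UTF-8",
                        colClasses = c(site = "character"))
  expect_equal(ev, fx$site_evidence, tolerance = 1e-12)
})

test_that("random property sets are reproducible and span the score range", {
  a <- makePropertySets(100, seed = 4)
  b <- makePropertySets(100, seed = 4)
  expect_equal(vapply(a, drugScore, numeric(1)),
               vapply(b, drugScore, numeric(1)))
  ds <- vapply(a, drugScore, numeric(1))
  expect_lt(min(ds), 0.05 + 0.05)
  expect_gt(max(ds), 0.95 - 0.05)
  expect_true(all(ds > 0 & ds < 1))
})
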