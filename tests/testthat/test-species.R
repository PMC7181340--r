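test_that("energy conversion uses the defining constants and inverts exactly", {
  expect_equal(convertEnergy(1, "hartree", "kcal/mol"), 627.5095)
  expect_equal(convertEnergy(1, "hartree", "eV"), 27.2114)
  expect_equal(convertEnergy(0, "eV", "kcal/mol"), 0)
  expect_equal(convertEnergy(1, "eV", "kcal/mol"), 627.5095 / 27.2114,
               tolerance = 1e-12)
  expect_error(convertEnergy(1, "eV", "joule"), "unknown energy unit")

  units <- c("hartree", "kcal/mol", "eV")
  set.seed(42)
  for (i in 1:20) {
    x <- runif(1, -2000, 2000)
    a <- sample(units, 1); b <- sample(units, 1)
    expect_equal(convertEnergy(convertEnergy(x, a, b), b, a), x,
                 tolerance = 1e-12)
  }
})

test_that("species tables round-trip through CSV field-for-field", {
  s <- tiny_species()
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpeciesTable(s, path)
  back <- readSpeciesTable(path)
  expect_identical(speciesData(back), speciesData(s))
})

test_that("species validity enforces the domain invariants", {
  # radical without a site
  expect_error(
    speciesSet("m", "radical", NA, "gas", -1.0),
    "requires a site label"
  )
  # site on a non-site-resolved form
  expect_error(speciesSet("m", "neutral", "3", "gas", -1.0), "site label")
  # HOMO above LUMO
  expect_error(
    speciesSet("m", "neutral", NA, "gas", -1.0, homo_ev = -2, lumo_ev = -3),
    "HOMO"
  )
  # duplicate key
  expect_error(
    speciesSet("m", c("neutral", "neutral"), NA, "gas", c(-1, -2)),
    "duplicate"
  )
  expect_error(speciesSet("m", "neutral", NA, "gas", Inf), "finite")
  expect_error(speciesSet("m", "weird", NA, "gas", -1.0), "unknown form")
})

test_that("CSV reader reports schema and row-level problems precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,form,site,phase,enthalpy_hartree",
               "m,neutral,,gas,-1.0"), path)
  expect_error(readSpeciesTable(path), "electronic_energy_hartree")

  ok_header <- paste("molecule_id", "form", "site", "phase",
                     "enthalpy_hartree", "electronic_energy_hartree",
                     "homo_ev", "lumo_ev", sep = ",")
  writeLines(c(ok_header, "m,neutral,,gas,not-a-number,,,"), path)
  expect_error(readSpeciesTable(path), "row 1")

  writeLines(c(ok_header,
               "m,neutral,,gas,-1.0,,,",
               "m,neutral,,gas,-1.0,,,"), path)
  expect_error(readSpeciesTable(path), "duplicate")
})

test_that("site labels are normalized: whitespace and Unicode primes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste("molecule_id", "form", "site", "phase",
                     "enthalpy_hartree", "electronic_energy_hartree",
                     "homo_ev", "lumo_ev", sep = ","),
               "m,radical, 3′ ,gas,-1.0,,,",
               "m,radical,4´,gas,-1.1,,,"), path)
  s <- readSpeciesTable(path)
  expect_setequal(speciesData(s)$site, c("3'", "4'"))
})

test_that("gas-phase reference defaults follow the documented convention", {
  r <- referenceEnthalpies()
  expect_equal(r@hAtom, -0.49765 + 0.00236)
  expect_equal(r@proton, 0.00236)
  expect_equal(r@electron, 0.00120)
  # aqueous values have no default
  expect_error(referenceEnthalpies("water"), "aqueous")
  rw <- referenceEnthalpies("water", hAtom = -0.5, proton = -0.42,
                            electron = -0.05)
  expect_s4_class(rw, "ReferenceEnthalpies")
})

test_that("reference enthalpies load from a YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("references:",
               "  gas:   {h_atom: -0.49529, proton: 0.00236, electron: 0.00120}",
               "  water: {h_atom: -0.49768, proton: -0.42131, electron: -0.05}"),
             path)
  refs <- readReferenceConfig(path)
  expect_named(refs, c("gas", "water"))
  expect_equal(refs$water@hAtom, -0.49768)
  expect_equal(refs$gas@phase, "gas")
})
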