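pt_props <- petunidinFixture()$properties

test_that("rule-of-five engine reproduces the published zero-violation verdict", {
  rep <- lipinskiViolations(pt_props)
  expect_equal(rep@violations, 0L)
  expect_true(all(rep@rules$pass))

  bad <- molecularProperties(milogp = 6, mw = 600, nhba = 11L, nhbd = 6L)
  expect_equal(lipinskiViolations(bad)@violations, 4L)

  boundary <- molecularProperties(milogp = 5, mw = 500, nhba = 10L, nhbd = 5L)
  expect_equal(lipinskiViolations(boundary)@violations, 0L)

  expect_error(lipinskiViolations(molecularProperties(mw = 300)), "milogp")
})

test_that("violation count is monotone when any property worsens", {
  set.seed(21)
  for (i in 1:25) {
    p <- molecularProperties(milogp = runif(1, 0, 8), mw = runif(1, 200, 700),
                             nhba = sample(0:14, 1), nhbd = sample(0:8, 1))
    worse <- molecularProperties(milogp = p@milogp + runif(1, 0, 3),
                                 mw = p@mw + runif(1, 0, 200),
                                 nhba = p@nhba + sample(0:3, 1),
                                 nhbd = p@nhbd + sample(0:3, 1))
    expect_gte(lipinskiViolations(worse)@violations,
               lipinskiViolations(p)@violations)
  }
})

test_that("Veber check passes petunidin and applies its two thresholds", {
  expect_equal(veberCheck(pt_props)@violations, 0L)
  expect_equal(veberCheck(molecularProperties(tpsa = 150, nrotb = 11L))@violations, 2L)
  expect_equal(veberCheck(molecularProperties(tpsa = 139.99, nrotb = 10L))@violations, 0L)
})

test_that("bioactivity classification partitions the score line", {
  expect_equal(as.character(bioactivityClass(0.03)), "considerable")
  expect_equal(as.character(bioactivityClass(-0.15)), "moderate")
  expect_equal(as.character(bioactivityClass(-0.51)), "inactive")
  expect_equal(as.character(bioactivityClass(0)), "moderate")
  expect_equal(as.character(bioactivityClass(-0.5)), "moderate")
  # every score maps to exactly one class
  scores <- seq(-1, 1, by = 0.01)
  expect_false(anyNA(bioactivityClass(scores)))
})

test_that("the published bioactivity panel classifies as printed", {
  fx <- petunidinFixture()
  cls <- bioactivityClass(fx$bioactivity)
  considerable <- names(fx$bioactivity)[cls == "considerable"]
  expect_setequal(considerable, c("kinase_inhibitor", "nuclear_receptor_ligand"))
  expect_true(all(cls[!names(fx$bioactivity) %in% considerable] == "moderate"))
})

test_that("sigmoid contributions evaluate the logistic exactly and safely", {
  expect_equal(sigmoidContribution(1.98, 1, -5), 1 / (1 + exp(-3.02)))
  expect_equal(round(sigmoidContribution(1.98, 1, -5), 4), 0.9535)
  expect_equal(round(sigmoidContribution(317.27, 0.012, -6), 4), 0.8996)
  expect_equal(sigmoidContribution(5, 1, -5), 0.5)    # midpoint p = -b/a
  expect_equal(sigmoidContribution(1e6, 1, 0), 0)     # saturates, no overflow
  expect_equal(sigmoidContribution(-1e6, 1, 0), 1)
})

test_that("drug score reproduces the published aggregate and its laws", {
  ds <- drugScore(pt_props)
  expect_equal(ds, 0.804, tolerance = 0.005 / 0.804)
  # with the literal published parameter signs the score collapses
  expect_lt(drugScore(pt_props, literalParams = TRUE), 0.5)

  # toxicity multiplier law
  tox_high <- pt_props
  tox_high@toxicity[] <- "high"
  expect_equal(drugScore(tox_high), ds * 0.6^4, tolerance = 1e-12)

  # neutral point: every property at its logistic midpoint
  neutral <- molecularProperties(clogp = 5, logs = -5, mw = 500,
                                 druglikeness = 0)
  expect_equal(drugScore(neutral), 0.75^4, tolerance = 1e-12)

  expect_error(drugScore(molecularProperties(clogp = 1, logs = -2, mw = 300)),
               "druglikeness")
})

test_that("drug score is monotone in each property and strictly in toxicity", {
  set.seed(31)
  for (p in makePropertySets(20, seed = 31)) {
    ds <- drugScore(p)
    expect_gt(ds, 0); expect_lt(ds, 1)
    heavier <- p; heavier@mw <- p@mw + 100
    expect_lte(drugScore(heavier), ds)
    greasier <- p; greasier@clogp <- p@clogp + 1
    expect_lte(drugScore(greasier), ds)
    more_soluble <- p; more_soluble@logs <- p@logs + 1
    expect_gte(drugScore(more_soluble), ds)
    more_druglike <- p; more_druglike@druglikeness <- p@druglikeness + 1
    expect_gte(drugScore(more_druglike), ds)
    if (any(p@toxicity == "none")) {
      worse <- p
      i <- which(p@toxicity == "none")[1]
      worse@toxicity[i] <- "high"
      expect_lt(drugScore(worse), ds)
    }
  }
})
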