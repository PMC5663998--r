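test_that("neutral mass composes residue, water, alditol and sulfate terms", {
  # empty composition is bare water
  expect_equal(neutralMass(glycanComposition(reduced = FALSE)), 18.01056,
               tolerance = 1e-8)
  # reduction adds exactly two hydrogens
  expect_equal(neutralMass(glycanComposition(hex = 5, hexnac = 2)) -
                 neutralMass(glycanComposition(hex = 5, hexnac = 2,
                                               reduced = FALSE)),
               2.01565, tolerance = 1e-9)
  # sulfate adds 79.95682 per site
  expect_equal(neutralMass(glycanComposition(hex = 3, hexnac = 2,
                                             sulfate = 2)) -
                 neutralMass(glycanComposition(hex = 3, hexnac = 2)),
               2 * 79.95682, tolerance = 1e-9)
  expect_error(glycanComposition(hex = -1), "non-negative")
})

test_that("reduced alditol precursors reproduce the printed anchor m/z", {
  # monosialylated hybrid, printed 945.3 (2-)
  expect_equal(compositionMz(glycanComposition(6, 3, 0, 1), 2), 945.3,
               tolerance = 0.1)
  # disialylated biantennary, printed 1111.4 (2-)
  expect_equal(compositionMz(glycanComposition(5, 4, 0, 2), 2), 1111.4,
               tolerance = 0.1)
  expect_equal(neutralMass(glycanComposition(5, 4, 0, 2)), 2224.80,
               tolerance = 0.01)
})

test_that("m/z model is the deprotonation identity", {
  expect_equal(mzFromMass(18.0106, 1), 17.0033, tolerance = 1e-4)
  expect_equal(mzFromMass(2224.79863, 2), 1111.39, tolerance = 0.005)
  # M = 2*mz2 + 2*p = mz1 + p, to numerical precision
  for (M in c(500, 1236.42, 2224.79863, 3101.2)) {
    mz1 <- mzFromMass(M, 1)
    mz2 <- mzFromMass(M, 2)
    expect_equal(2 * mz2 + 2 * 1.00728, mz1 + 1.00728, tolerance = 1e-9)
  }
  expect_error(mzFromMass(100, 0), "charge")
  expect_error(mzFromMass(100, -1), "charge")
})

test_that("composition strings parse, fold the core suffix, and round-trip", {
  o <- parseComposition("(Neu5Ac)1(Gal)1(GalNAc)1")
  expect_identical(glycanClass(o), "O")
  expect_identical(unname(residueCounts(o)), c(1L, 1L, 0L, 1L))
  n <- parseComposition("(Hex)1(HexNAc)3(dHex)1+(Man)3(GlcNAc)2")
  expect_identical(glycanClass(n), "N")
  expect_identical(unname(residueCounts(n)), c(4L, 5L, 1L, 0L))
  expect_error(parseComposition("(Foo)2(Hex)1"), "unknown class token")

  set.seed(11)
  for (i in 1:100) {
    comp <- randomComposition()
    back <- parseComposition(formatComposition(comp))
    expect_identical(residueCounts(back), residueCounts(comp))
    expect_identical(back@sulfate, comp@sulfate)
  }
})

test_that("topology projection reproduces composition and mass additivity", {
  expect_identical(unname(residueCounts(topologyToComposition(topoCore()))),
                   c(3L, 2L, 0L, 0L))
  # bisected biantennary in the 759.9/913.9 family projects to HexNAc5
  expect_identical(
    unname(residueCounts(topologyToComposition(topoBisected913()))),
    c(4L, 5L, 1L, 0L))
  # composition mass of a random tree equals the sum over its residues
  topos <- list(topoCore(), topoBisected913(), topoLacdiNAc913(),
                topoDisialoBiant())
  clsOf <- c(Man = "Hex", Gal = "Hex", Glc = "Hex", GlcNAc = "HexNAc",
             GalNAc = "HexNAc", Fuc = "dHex", Neu5Ac = "Neu5Ac")
  massOf <- c(Hex = 162.05282, HexNAc = 203.07937, dHex = 146.05791,
              Neu5Ac = 291.09542)
  for (t in topos) {
    comp <- topologyToComposition(t)
    direct <- sum(massOf[clsOf[glycoPGC:::treeResidues(t@root)]]) +
      18.01056 + 2.01565
    expect_equal(neutralMass(comp), direct, tolerance = 1e-9)
  }
})

test_that("merging two fragment compositions across a bond is mass additive", {
  a <- glycanComposition(2, 1, 0, 0, reduced = FALSE, fragment = TRUE)
  b <- glycanComposition(3, 4, 1, 2, reduced = FALSE, fragment = TRUE)
  ab <- glycanComposition(5, 5, 1, 2, reduced = FALSE, fragment = TRUE)
  expect_equal(neutralMass(ab),
               neutralMass(a) + neutralMass(b) - 18.01056,
               tolerance = 1e-9)
})

test_that("N-glycan compositions without the core are rejected", {
  expect_error(glycanComposition(hex = 2, hexnac = 1, glycanClass = "N"),
               "core")
  expect_silent(glycanComposition(hex = 2, hexnac = 1, glycanClass = "N",
                                  fragment = TRUE))
  expect_silent(glycanComposition(hex = 1, hexnac = 1, neu5ac = 1,
                                  glycanClass = "O"))
})
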