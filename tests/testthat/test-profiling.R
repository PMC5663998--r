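test_that("profiles normalize to 100 per class and reject empty samples", {
  areas <- matrix(c(2, 1, 1, 5, 0, 5), nrow = 3,
                  dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  gp <- buildProfile(areas, diagnosis = c("OC", "PC"))
  expect_equal(unname(relAbundance(gp)[, "s1"]), c(50, 25, 25))
  expect_equal(unname(colSums(relAbundance(gp))), c(100, 100))
  # single glycan is 100 %
  one <- buildProfile(matrix(7, 1, 1, dimnames = list("g", "s")), "OC")
  expect_equal(unname(relAbundance(one)[1, 1]), 100)
  bad <- areas; bad[, 2] <- 0
  expect_error(buildProfile(bad, c("OC", "PC")), "s2")
})

test_that("isomer merging conserves the parent glycan fraction", {
  gp <- generateCohort(cohortDesignDiagnosis(4L, 4L), seed = 3)
  merged <- mergeIsomers(gp, by = as.character(
    SummarizedExperiment::rowData(gp)$glycanMass))
  a <- relAbundance(gp)
  m <- relAbundance(merged)
  # 913.9 has a bisecting and a LacdiNAc isomer row
  expect_equal(unname(m["913.9", ]),
               unname(a["bis_913.9a", ] + a["ldn_913.9b", ]))
  expect_equal(unname(colSums(m)), rep(200, ncol(m)))  # N + O classes
})

test_that("the five-type rule table classifies compositions with precedence", {
  expect_identical(classifyGlycanType(glycanComposition(5, 2)),
                   "high_mannose")
  expect_identical(classifyGlycanType(glycanComposition(3, 2, 1)),
                   "paucimannose")
  # Man4 joins the high-mannose family unless fucosylated
  expect_identical(classifyGlycanType(glycanComposition(4, 2)),
                   "high_mannose")
  expect_identical(classifyGlycanType(glycanComposition(4, 2, 1)),
                   "paucimannose")
  expect_identical(classifyGlycanType(glycanComposition(6, 3, 0, 1)),
                   "hybrid")
  expect_identical(classifyGlycanType(glycanComposition(5, 4, 0, 2)),
                   "complex_sialylated")
  expect_identical(classifyGlycanType(glycanComposition(4, 5, 1)),
                   "complex_neutral")
  expect_error(classifyGlycanType(parseComposition("(Neu5Ac)1(Gal)1(GalNAc)1")),
               "N-glycans")
  # topology refinement: HexNAc3 with both arms substituted is not hybrid
  t <- parseGlycanStructure(paste0(
    "Gal(b1-4)GlcNAc(b1-2)Man(a1-6)[Man(a1-3)]",
    "Man(b1-4)GlcNAc(b1-4)GlcNAc-ol"))
  expect_identical(
    classifyGlycanType(topologyToComposition(t), t), "hybrid")
})

test_that("every panel composition receives exactly one glycan type", {
  p <- glycanPanel()
  p <- p[p$glycanClass == "N", ]
  for (i in seq_len(nrow(p))) {
    ty <- classifyGlycanType(parseComposition(p$composition[i],
                                              glycanClass = "N"))
    expect_true(ty %in% c("high_mannose", "hybrid", "complex_neutral",
                          "complex_sialylated", "paucimannose"))
  }
})

test_that("antenna counting requires the complete disaccharide", {
  expect_identical(countAntennae(topoCore()), 0L)
  expect_identical(countAntennae(topoDisialoBiant()), 2L)
  # bisecting GlcNAc and bare GlcNAc stubs do not count
  expect_identical(countAntennae(topoBisected913()), 1L)
  # LacdiNAc antennae count like LacNAc
  expect_identical(countAntennae(topoLacdiNAc913()), 2L)
  tetra <- parseGlycanStructure(paste0(
    "Gal(b1-4)GlcNAc(b1-2)[Gal(b1-4)GlcNAc(b1-6)]Man(a1-6)",
    "[Gal(b1-4)GlcNAc(b1-2)[Gal(b1-4)GlcNAc(b1-4)]Man(a1-3)]",
    "Man(b1-4)GlcNAc(b1-4)GlcNAc-ol"))
  expect_identical(countAntennae(tetra), 4L)
})

test_that("feature summaries aggregate memberships correctly", {
  gp <- generateCohort(cohortDesignDiagnosis(6L, 6L), seed = 8)
  f <- summarizeFeatures(gp)
  types <- as.matrix(f[, c("high_mannose", "hybrid", "complex_neutral",
                           "complex_sialylated", "paucimannose")])
  expect_equal(unname(rowSums(types)), rep(100, nrow(f)))
  degr <- as.matrix(f[, c("monoSialylated", "diSialylated",
                          "triSialylated")])
  expect_equal(unname(rowSums(degr)), rep(100, nrow(f)))
  expect_true(all(f$lacdinacTotal >= 0 & f$lacdinacTotal <= 100))
  expect_true(all(f$alpha26Fraction > 50 & f$alpha26Fraction < 75))

  # a profile holding only LacdiNAc glycans reports lacdinacTotal 100
  areas <- matrix(c(3, 1), 2, 1, dimnames = list(c("a", "b"), "s1"))
  rd <- S4Vectors::DataFrame(glycanClass = rep("N", 2),
                             type = rep("complex_neutral", 2),
                             nSialic = rep(0L, 2), nAntennae = rep(1L, 2),
                             bisecting = rep(FALSE, 2),
                             lacdinac = rep(TRUE, 2),
                             row.names = c("a", "b"))
  pure <- buildProfile(areas, "OC", rowData = rd)
  expect_equal(unname(summarizeFeatures(pure)$lacdinacTotal), 100)

  # unmapped glycans are reported by id
  rd2 <- rd; rd2$type <- NA_character_
  expect_error(summarizeFeatures(buildProfile(areas, "OC", rowData = rd2)),
               "a, b")
})
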