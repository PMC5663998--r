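test_that("antenna fragments reproduce the printed diagnostic m/z values", {
  di <- diagnosticIons()
  expect_equal(unname(di["B_LacdiNAc"]), 405.1, tolerance = 0.1)
  expect_equal(unname(di["F_LacdiNAc"]), 465.1, tolerance = 0.1)
  expect_equal(unname(di["B_sialylLacdiNAc"]), 696.2, tolerance = 0.1)
  expect_equal(unname(di["B_sialylLacNAc"]), 655.2, tolerance = 0.1)

  # the fragment engine emits them from the corresponding topologies
  frL <- generateFragments(topoLacdiNAc913())
  expect_true(any(frL$kind == "B" & abs(frL$mz - 405.15) < 0.01))
  expect_true(any(frL$kind == "F" & abs(frL$mz - 465.17) < 0.01))

  # agalactosylated bisected context: D-221 at printed 508.1
  frB <- generateFragments(topoBisected913())
  expect_equal(frB$mz[frB$kind == "D221"], 508.1, tolerance = 0.1)

  # galactosylated bisected context: D-221 at printed 670.2
  gal <- parseGlycanStructure(paste0(
    "Gal(b1-4)GlcNAc(b1-2)Man(a1-6)[Gal(b1-4)GlcNAc(b1-2)Man(a1-3)]",
    "[GlcNAc(b1-4)]Man(b1-4)GlcNAc(b1-4)GlcNAc-ol"))
  frG <- generateFragments(gal)
  expect_equal(frG$mz[frG$kind == "D221"], 670.2, tolerance = 0.1)

  # sialylated antennae: B ions at printed 696.2 / 655.2
  sialLdn <- parseGlycanStructure(paste0(
    "Neu5Ac(a2-6)GalNAc(b1-4)GlcNAc(b1-2)Man(a1-6)",
    "[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)]",
    "Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc-ol"))
  frS <- generateFragments(sialLdn)
  expect_true(any(frS$kind == "B" & abs(frS$mz - 696.2) <= 0.1))
  expect_true(any(frS$kind == "B" & abs(frS$mz - 655.2) <= 0.1))
})

test_that("B/Y pairs conserve the precursor mass across any single cleavage", {
  for (t in list(topoBisected913(), topoLacdiNAc913(), topoDisialoBiant())) {
    fr <- generateFragments(t, kinds = c("B", "Y"))
    M <- neutralMass(topologyToComposition(t))
    bs <- fr$mz[fr$kind == "B"]
    ys <- fr$mz[fr$kind == "Y"]
    # for every B there is a complementary Y: (B + p) + (Y + p) = M
    for (b in bs) {
      neutralB <- b + 1.00728
      neutralYexp <- M - neutralB
      expect_true(any(abs((ys + 1.00728) - neutralYexp) < 1e-6),
                  label = sprintf("complement of B %.4f in %s", b,
                                  t@notation))
    }
  }
})

test_that("D ions require a 6-arm and D-221 a bisecting GlcNAc", {
  frCore <- generateFragments(topoCore())
  expect_false(any(frCore$kind == "D221"))
  expect_true(any(frCore$kind == "D"))   # bare 6-arm Man context
  frLdn <- generateFragments(topoLacdiNAc913())
  expect_false(any(frLdn$kind == "D221"))
  expect_true(hasBisectingGlcNAc(topoBisected913()))
  expect_false(hasBisectingGlcNAc(topoLacdiNAc913()))
})

test_that("peak matching is nearest-within-tolerance with ambiguity flags", {
  t <- topoLacdiNAc913()
  ions <- generateFragments(t)
  empty <- glycanSpectrum(913.84, 2)
  mm <- matchPeaks(empty, ions)
  expect_true(all(!mm$matched))
  exact <- glycanSpectrum(913.84, 2, mz = ions$mz)
  mm2 <- matchPeaks(exact, ions)
  expect_true(all(mm2$matched))
  # a single peak near two isobaric theoreticals is flagged ambiguous
  two <- data.frame(kind = c("B", "C"), mz = c(400.10, 400.12),
                    residues = "", charge = 1L)
  mm3 <- matchPeaks(glycanSpectrum(500, 1, mz = 400.11), two, tol = 0.3)
  expect_true(all(mm3$ambiguous))
})

test_that("jittered spectra still match at the ion-trap tolerance", {
  t <- topoDisialoBiant()
  ions <- generateFragments(t)
  set.seed(33)
  rates <- replicate(100, {
    sp <- glycanSpectrum(1111.39, 2,
                         mz = ions$mz + rnorm(nrow(ions), 0, 0.05))
    mean(matchPeaks(sp, ions, tol = 0.3)$matched)
  })
  expect_gte(mean(rates), 0.95)
})

test_that("motif classification separates the 913.9 compositional isomers", {
  f1 <- system.file("extdata", "ms2_913.9_isomer1_bisecting.txt",
                    package = "glycoPGC")
  f2 <- system.file("extdata", "ms2_913.9_isomer2_lacdinac.txt",
                    package = "glycoPGC")
  s1 <- readPeakList(f1)
  s2 <- readPeakList(f2)
  cands <- list(topoBisected913(), topoLacdiNAc913())
  r1 <- classifyMotifs(s1, cands)
  r2 <- classifyMotifs(s2, cands)
  expect_true(hasBisectingGlcNAc(S4Vectors::metadata(r1)$candidates[[1]]))
  expect_true(r1$bisecting[1])
  expect_false(r1$lacdinac[1])
  expect_true(hasLacdiNAc(S4Vectors::metadata(r2)$candidates[[1]]))
  expect_true(r2$lacdinac[1])
  expect_false(r2$bisecting[1])
  # deterministic given fixed inputs
  expect_identical(as.data.frame(classifyMotifs(s1, cands)),
                   as.data.frame(r1))
  # candidates inconsistent with the precursor are refused
  expect_error(classifyMotifs(glycanSpectrum(500, 1), cands),
               "precursor")
})

test_that("true topologies are recovered from noisy synthetic spectra", {
  cands <- list(topoBisected913(), topoLacdiNAc913())
  set.seed(91)
  hits <- replicate(200, {
    truth <- sample(1:2, 1)
    sp <- generateSpectrum(cands[[truth]], jitterSd = 0.05,
                           decoyRate = 0.2, seed = sample.int(1e6, 1))
    top <- classifyMotifs(sp, cands)$structure[1]
    top == cands[[truth]]@notation
  })
  expect_gte(mean(hits), 0.9)
})
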