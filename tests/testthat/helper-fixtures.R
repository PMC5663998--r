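## shared topologies and small design constructors used across test files

## 913.9 (2-) compositional isomers: bisected core-fucosylated
## (D-221 context on the agalactosylated 6-arm) and LacdiNAc-type
topoBisected913 <- function() parseGlycanStructure(paste0(
  "GlcNAc(b1-2)Man(a1-6)[Gal(b1-4)GlcNAc(b1-2)Man(a1-3)]",
  "[GlcNAc(b1-4)]Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc-ol"))

topoLacdiNAc913 <- function() parseGlycanStructure(paste0(
  "GalNAc(b1-4)GlcNAc(b1-2)Man(a1-6)[Gal(b1-4)GlcNAc(b1-2)Man(a1-3)]",
  "Man(b1-4)GlcNAc(b1-4)[Fuc(a1-6)]GlcNAc-ol"))

## disialylated biantennary (the most abundant complex N-glycan backbone)
topoDisialoBiant <- function() parseGlycanStructure(paste0(
  "Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-6)",
  "[Neu5Ac(a2-3)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)]",
  "Man(b1-4)GlcNAc(b1-4)GlcNAc-ol"))

topoCore <- function() parseGlycanStructure(
  "Man(a1-6)[Man(a1-3)]Man(b1-4)GlcNAc(b1-4)GlcNAc-ol")

## minimal cohort design: one feature panel with per-group means/SDs
makeTestDesign <- function(meanA, meanB, sd, nA = 14L, nB = 14L,
                           detectA = 1, detectB = 1) {
  k <- length(meanA)
  panel <- data.frame(
    id = sprintf("g%02d", seq_len(k)),
    glycanMass = sprintf("%.1f", 700 + seq_len(k)),
    glycanClass = "N",
    composition = "(Hex)5(HexNAc)4",
    type = "complex_neutral", nSialic = 0L, nAntennae = 2L,
    bisecting = FALSE, lacdinac = FALSE, alpha26 = NA_real_,
    stringsAsFactors = FALSE)
  rownames(panel) <- panel$id
  structure(list(
    panel = panel,
    groups = list(
      A = list(n = nA, mean = meanA, sd = sd,
               detect = rep(detectA, k), diagnosis = "OC", site = "ovary"),
      B = list(n = nB, mean = meanB, sd = sd,
               detect = rep(detectB, k), diagnosis = "PC",
               site = "peritoneum"))
  ), class = "glycoCohortDesign")
}

## random valid composition for round-trip properties
randomComposition <- function() {
  glycanComposition(hex = sample(3:10, 1), hexnac = sample(2:6, 1),
                    dhex = sample(0:3, 1), neu5ac = sample(0:3, 1),
                    sulfate = sample(0:1, 1))
}
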