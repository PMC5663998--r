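## The tissue-cohort preset: a panel of N- and O-glycan structures with
## group-specific mean relative abundances (%), SDs and detection
## frequencies chosen to reproduce the published cohort-level summaries
## for high-grade serous ovarian (OC) vs peritoneal (PC) cancer tissue:
## total LacdiNAc-type N-glycans 2.775 +/- 2.005 % in OC vs 0.1247 +/-
## 1.312 % in PC (the sialylated LacdiNAc species detected in 93% of OC vs
## 22% of PC samples), total sialylation inside the 66.3-68.5 % band,
## bisecting-type structures ~6.85 %, biantennary species ~55 %, branched
## species ~5 %, and alpha2,6 shares of 0.59 (hybrid monosialylated
## isomers) and 0.65 (complex-type isomers). Where only group totals are
## published, the split across member structures is a fixed design choice
## (see the methods vignette).

.panelRow <- function(id, mass, class, comp, type, nSial, nAnt, bis, ldn,
                      a26, mOC, sOC, dOC, mPC, sPC, dPC) {
  data.frame(id = id, glycanMass = mass, glycanClass = class,
             composition = comp, type = type, nSialic = nSial,
             nAntennae = nAnt, bisecting = bis, lacdinac = ldn,
             alpha26 = a26, meanOC = mOC, sdOC = sOC, detOC = dOC,
             meanPC = mPC, sdPC = sPC, detPC = dPC,
             stringsAsFactors = FALSE)
}

#' The serous-cancer tissue glycan panel
#'
#' Per-structure annotation and group-specific generative parameters
#' (mean %, SD %, detection frequency) for the OC/PC cohort preset; see
#' the package vignette for how the panel reproduces the published
#' cohort-level summaries.
#'
#' @return `data.frame`, one row per glycan structure (isomers of one
#'   glycan mass are separate rows, e.g. `"913.9a"`/`"913.9b"`).
#' @export
glycanPanel <- function() {
  r <- .panelRow
  ldnS_OC <- 2.005 / sqrt(5)   # per-species SD so the OC total SD is 2.005
  ldnS_PC <- 1.312 / sqrt(5)
  p <- rbind(
    ## high mannose and paucimannose
    r("hm_Man5",  "779.3",  "N", "(Hex)5(HexNAc)2", "high_mannose", 0L, 0L, FALSE, FALSE, NA, 5.0, 1.50, 1, 5.0, 1.50, 1),
    r("hm_Man6",  "860.3",  "N", "(Hex)6(HexNAc)2", "high_mannose", 0L, 0L, FALSE, FALSE, NA, 3.0, 0.90, 1, 3.0, 0.90, 1),
    r("hm_Man7",  "941.3",  "N", "(Hex)7(HexNAc)2", "high_mannose", 0L, 0L, FALSE, FALSE, NA, 2.0, 0.60, 1, 2.0, 0.60, 1),
    r("hm_Man8",  "1022.4", "N", "(Hex)8(HexNAc)2", "high_mannose", 0L, 0L, FALSE, FALSE, NA, 1.5, 0.45, 1, 1.5, 0.45, 1),
    r("hm_Man9",  "1103.4", "N", "(Hex)9(HexNAc)2", "high_mannose", 0L, 0L, FALSE, FALSE, NA, 1.0, 0.30, 1, 1.0, 0.30, 1),
    r("pm_F",     "618.2",  "N", "(Hex)3(HexNAc)2(dHex)1", "paucimannose", 0L, 0L, FALSE, FALSE, NA, 2.0, 0.60, 1, 2.0, 0.60, 1),
    r("pm_small", "618.7",  "N", "(Hex)3(HexNAc)2", "paucimannose", 0L, 0L, FALSE, FALSE, NA, 1.0, 0.30, 1, 1.0, 0.30, 1),
    ## neutral biantennary backbone species
    r("cn_739.3", "739.3",  "N", "(Hex)3(HexNAc)4(dHex)1", "complex_neutral", 0L, 0L, FALSE, FALSE, NA, 2.5, 0.80, 1, 4.0, 1.20, 1),
    r("cn_812.3", "812.3",  "N", "(Hex)4(HexNAc)4(dHex)1", "complex_neutral", 0L, 1L, FALSE, FALSE, NA, 1.5, 0.45, 1, 1.5, 0.45, 1),
    r("cn_894.3", "894.3",  "N", "(Hex)5(HexNAc)4(dHex)1", "complex_neutral", 0L, 2L, FALSE, FALSE, NA, 3.0, 0.90, 1, 3.0, 0.90, 1),
    ## bisecting-type biantennary
    r("bis_759.9",  "759.9",  "N", "(Hex)3(HexNAc)5(dHex)1", "complex_neutral", 0L, 0L, TRUE, FALSE, NA, 1.30, 0.45, 1, 1.00, 0.35, 1),
    r("bis_840.8",  "840.8",  "N", "(Hex)4(HexNAc)5",        "complex_neutral", 0L, 0L, TRUE, FALSE, NA, 0.85, 0.30, 1, 0.85, 0.30, 1),
    r("bis_913.9a", "913.9",  "N", "(Hex)4(HexNAc)5(dHex)1", "complex_neutral", 0L, 1L, TRUE, FALSE, NA, 1.10, 0.40, 1, 0.80, 0.30, 1),
    r("bis_921.9",  "921.9",  "N", "(Hex)5(HexNAc)5",        "complex_neutral", 0L, 1L, TRUE, FALSE, NA, 0.80, 0.30, 1, 0.80, 0.30, 1),
    r("bis_994.9",  "994.9",  "N", "(Hex)5(HexNAc)5(dHex)1", "complex_neutral", 0L, 2L, TRUE, FALSE, NA, 1.00, 0.40, 1, 2.00, 0.60, 1),
    r("bis_986.5",  "986.5",  "N", "(Hex)5(HexNAc)5(Neu5Ac)1", "complex_sialylated", 1L, 2L, TRUE, FALSE, NA, 0.80, 0.30, 1, 0.80, 0.30, 1),
    r("bis_1286.0", "1286.0", "N", "(Hex)5(HexNAc)5(dHex)1(Neu5Ac)2", "complex_sialylated", 2L, 2L, TRUE, FALSE, NA, 1.00, 0.40, 1, 0.60, 0.25, 1),
    ## hybrid monosialylated isomeric species (alpha2,6 share 0.59)
    r("hyb_783.3", "783.3", "N", "(Hex)6(HexNAc)3(Neu5Ac)1", "hybrid", 1L, 1L, FALSE, FALSE, 0.59, 2.2, 0.70, 1, 2.2, 0.70, 1),
    r("hyb_856.3", "856.3", "N", "(Hex)6(HexNAc)3(dHex)1(Neu5Ac)1", "hybrid", 1L, 1L, FALSE, FALSE, 0.59, 2.8, 0.90, 1, 1.8, 0.70, 1),
    r("hyb_864.3", "864.3", "N", "(Hex)7(HexNAc)3(Neu5Ac)1", "hybrid", 1L, 1L, FALSE, FALSE, 0.59, 1.8, 0.60, 1, 1.8, 0.60, 1),
    r("hyb_937.3", "937.3", "N", "(Hex)7(HexNAc)3(dHex)1(Neu5Ac)1", "hybrid", 1L, 1L, FALSE, FALSE, 0.59, 4.0, 1.20, 1, 2.0, 0.80, 1),
    r("hyb_945.3", "945.3", "N", "(Hex)6(HexNAc)3(Neu5Ac)1", "hybrid", 1L, 1L, FALSE, FALSE, 0.59, 2.6, 0.80, 1, 2.6, 0.80, 1),
    ## complex sialylated biantennary (alpha2,6 share 0.65)
    r("cs_957.8",  "957.8",  "N", "(Hex)5(HexNAc)4(Neu5Ac)1", "complex_sialylated", 1L, 2L, FALSE, FALSE, 0.65, 3.0, 0.90, 1, 3.0, 0.90, 1),
    r("cs_965.9",  "965.9",  "N", "(Hex)5(HexNAc)4(Neu5Ac)1", "complex_sialylated", 1L, 2L, FALSE, FALSE, 0.65, 11.0, 2.80, 1, 11.5, 2.80, 1),
    r("cs_1038.9", "1038.9", "N", "(Hex)5(HexNAc)4(dHex)1(Neu5Ac)1", "complex_sialylated", 1L, 2L, FALSE, FALSE, 0.65, 8.0, 2.00, 1, 10.0, 2.50, 1),
    r("cs_1111.4", "1111.4", "N", "(Hex)5(HexNAc)4(Neu5Ac)2", "complex_sialylated", 2L, 2L, FALSE, FALSE, 0.65, 14.0, 3.50, 1, 14.0, 3.50, 1),
    r("cs_1184.5", "1184.5", "N", "(Hex)5(HexNAc)4(dHex)1(Neu5Ac)2", "complex_sialylated", 2L, 2L, FALSE, FALSE, 0.65, 10.0, 3.00, 1, 10.0, 3.00, 1),
    ## branched tri-/tetra-antennary
    r("br_1294.0", "1294.0", "N", "(Hex)6(HexNAc)5(Neu5Ac)3", "complex_sialylated", 3L, 3L, FALSE, FALSE, NA, 1.5, 0.50, 1, 2.2, 0.70, 1),
    r("br_1148.5", "1148.5", "N", "(Hex)6(HexNAc)5(dHex)1(Neu5Ac)1", "complex_sialylated", 1L, 3L, FALSE, FALSE, NA, 1.2, 0.40, 1, 1.7, 0.55, 1),
    r("br_1221.5", "1221.5", "N", "(Hex)6(HexNAc)5(Neu5Ac)2", "complex_sialylated", 2L, 3L, FALSE, FALSE, NA, 1.0, 0.35, 1, 1.0, 0.35, 1),
    r("br_1440.0", "1440.0", "N", "(Hex)7(HexNAc)6(Neu5Ac)2", "complex_sialylated", 2L, 4L, FALSE, FALSE, NA, 0.8, 0.30, 1, 0.8, 0.30, 1),
    r("br_1550.1", "1550.1", "N", "(Hex)7(HexNAc)6(Neu5Ac)3", "complex_sialylated", 3L, 4L, FALSE, FALSE, NA, 0.6, 0.25, 1, 0.6, 0.25, 1),
    ## LacdiNAc-type structures: group totals 2.775 % (OC) / 0.1247 % (PC)
    r("ldn_913.9b", "913.9",  "N", "(Hex)4(HexNAc)5(dHex)1", "complex_neutral", 0L, 1L, FALSE, TRUE, NA, 0.425, ldnS_OC, 0.90, 0.02494, ldnS_PC, 0.22),
    r("ldn_934.4",  "934.4",  "N", "(Hex)4(HexNAc)6",        "complex_neutral", 0L, 2L, FALSE, TRUE, NA, 0.400, ldnS_OC, 0.90, 0.02494, ldnS_PC, 0.22),
    r("ldn_1059.4", "1059.4", "N", "(Hex)4(HexNAc)5(dHex)1(Neu5Ac)1", "complex_sialylated", 1L, 1L, FALSE, TRUE, NA, 0.500, ldnS_OC, 0.90, 0.02494, ldnS_PC, 0.22),
    r("ldn_1079.9", "1079.9", "N", "(Hex)4(HexNAc)6(Neu5Ac)1", "complex_sialylated", 1L, 2L, FALSE, TRUE, NA, 0.550, ldnS_OC, 0.90, 0.02494, ldnS_PC, 0.22),
    r("ldn_1205.0", "1205.0", "N", "(Hex)5(HexNAc)5(dHex)1(Neu5Ac)2", "complex_sialylated", 2L, 2L, FALSE, TRUE, NA, 0.900, ldnS_OC, 0.93, 0.02494, ldnS_PC, 0.22),
    ## O-glycans (normalized separately)
    r("o_675.3",  "675.3",  "O", "(Hex)1(HexNAc)1(Neu5Ac)1", NA, 1L, NA, FALSE, FALSE, NA, 48.0, 10.0, 1, 48.0, 10.0, 1),
    r("o_966.3",  "966.3",  "O", "(Hex)1(HexNAc)1(Neu5Ac)2", NA, 2L, NA, FALSE, FALSE, NA, 30.0, 8.00, 1, 30.0, 8.00, 1),
    r("o_749.3",  "749.3",  "O", "(Hex)1(HexNAc)2(Neu5Ac)1", NA, 1L, NA, FALSE, FALSE, NA, 6.0, 2.00, 1, 6.0, 2.00, 1),
    r("o_755.3",  "755.3",  "O", "(Hex)2(HexNAc)2(dHex)1",   NA, 0L, NA, FALSE, FALSE, NA, 5.0, 1.50, 1, 5.0, 1.50, 1),
    r("o_1040.5", "1040.5", "O", "(Hex)2(HexNAc)2(Neu5Ac)1", NA, 1L, NA, FALSE, FALSE, NA, 4.0, 1.20, 1, 4.0, 1.20, 1),
    r("o_1331.5", "1331.5", "O", "(Hex)2(HexNAc)2(Neu5Ac)2", NA, 2L, NA, FALSE, FALSE, NA, 3.0, 1.00, 1, 3.0, 1.00, 1),
    r("o_384.2",  "384.2",  "O", "(Hex)1(HexNAc)1",          NA, 0L, NA, FALSE, FALSE, NA, 2.0, 0.60, 1, 2.0, 0.60, 1),
    r("o_587.2",  "587.2",  "O", "(Hex)1(HexNAc)2",          NA, 0L, NA, FALSE, FALSE, NA, 1.5, 0.50, 1, 1.5, 0.50, 1),
    r("o_1128.4", "1128.4", "O", "(Hex)2(HexNAc)2(dHex)1(Neu5Ac)1", NA, 1L, NA, FALSE, FALSE, NA, 0.5, 0.20, 1, 0.5, 0.20, 1)
  )
  rownames(p) <- p$id
  ## the remainder up to 100 % per class sits in the most abundant
  ## non-discriminatory species (Man5 for N, the core-1 base peak for O)
  for (grp in c("OC", "PC")) {
    mcol <- paste0("mean", grp)
    for (cl in c("N", "O")) {
      ix <- p$glycanClass == cl
      rest <- 100 - sum(p[[mcol]][ix])
      sink <- if (cl == "N") "hm_Man5" else "o_675.3"
      p[sink, mcol] <- p[sink, mcol] + rest
    }
  }
  p
}

#' Cohort designs emulating the tissue study's two analyses
#'
#' `cohortDesignDiagnosis()` is the two-group design (OC n = 14, PC
#' n = 14). `cohortDesignSite()` is the three-site design (ovary n = 14,
#' omentum n = 11, peritoneum n = 3); ovary-derived samples follow the OC
#' generative parameters and omentum/peritoneum the PC parameters, with
#' branched N-glycans further elevated in peritoneum-derived tissue.
#'
#' @param nOC,nPC,nOvary,nOmentum,nPeritoneum Group sizes.
#' @return A `glycoCohortDesign` list: `panel` plus per-group `n`, `mean`,
#'   `sd`, `detect` vectors and the group label/metadata mapping.
#' @seealso [generateCohort()]
#' @export
cohortDesignDiagnosis <- function(nOC = 14L, nPC = 14L) {
  p <- glycanPanel()
  structure(list(
    panel = p,
    groups = list(
      OC = list(n = nOC, mean = p$meanOC, sd = p$sdOC, detect = p$detOC,
                diagnosis = "OC", site = "ovary"),
      PC = list(n = nPC, mean = p$meanPC, sd = p$sdPC, detect = p$detPC,
                diagnosis = "PC", site = "peritoneum")
    )
  ), class = "glycoCohortDesign")
}

#' @rdname cohortDesignDiagnosis
#' @export
cohortDesignSite <- function(nOvary = 14L, nOmentum = 11L,
                             nPeritoneum = 3L) {
  p <- glycanPanel()
  pe <- p
  pe[c("br_1294.0", "br_1148.5"), "meanPC"] <- c(3.0, 2.4)
  structure(list(
    panel = p,
    groups = list(
      ovary = list(n = nOvary, mean = p$meanOC, sd = p$sdOC,
                   detect = p$detOC, diagnosis = "OC", site = "ovary"),
      omentum = list(n = nOmentum, mean = p$meanPC, sd = p$sdPC,
                     detect = p$detPC, diagnosis = "PC", site = "omentum"),
      peritoneum = list(n = nPeritoneum, mean = pe$meanPC, sd = pe$sdPC,
                        detect = pe$detPC, diagnosis = "PC",
                        site = "peritoneum")
    )
  ), class = "glycoCohortDesign")
}
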