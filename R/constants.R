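## Monoisotopic residue masses (Da) for the monosaccharide classes searched
## in negative-mode PGC-LC-MS. Residue = free monosaccharide minus water,
## i.e. the mass a unit contributes inside a glycan chain.

#' Monoisotopic mass constants
#'
#' Residue masses of the four monosaccharide classes handled by the mass
#' calculus, plus the small-molecule constants the calculus composes them
#' with. All values are monoisotopic and in Daltons.
#'
#' \describe{
#'   \item{Hex}{hexose residue (Gal/Man/Glc), 162.05282}
#'   \item{HexNAc}{N-acetylhexosamine residue (GlcNAc/GalNAc), 203.07937}
#'   \item{dHex}{deoxyhexose residue (Fuc), 146.05791}
#'   \item{Neu5Ac}{N-acetylneuraminic acid residue, 291.09542}
#' }
#'
#' `GLYCO_WATER` is the terminal water completing a free glycan,
#' `GLYCO_ALDITOL_H2` the two hydrogens gained on borohydride reduction of
#' the reducing end, `GLYCO_PROTON` the monoisotopic charge-carrier mass
#' used for negative-mode deprotonation, `GLYCO_SULFATE` the SO3 adduct
#' mass, and `GLYCO_F_ION_TAIL` the O-CH=CH-O remnant of the 1,3A
#' cross-ring cleavage that defines the F ion.
#'
#' @format Named numeric vector (`RESIDUE_MASS`) and numeric scalars.
#' @keywords internal
#' @name glyco-constants
NULL

RESIDUE_MASS <- c(
  Hex    = 162.05282,
  HexNAc = 203.07937,
  dHex   = 146.05791,
  Neu5Ac = 291.09542
)

GLYCO_WATER      <- 18.01056
GLYCO_ALDITOL_H2 <- 2.01565
GLYCO_PROTON     <- 1.00728
GLYCO_SULFATE    <- 79.95682
GLYCO_F_ION_TAIL <- 59.0133
## HexNAc residue + water: the neutral loss distinguishing D from D-221
GLYCO_D221_LOSS  <- 221.08993

## specific residue identity -> mass class
RESIDUE_CLASS <- c(
  Man = "Hex", Gal = "Hex", Glc = "Hex",
  GlcNAc = "HexNAc", GalNAc = "HexNAc",
  Fuc = "dHex",
  Neu5Ac = "Neu5Ac"
)
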