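#' Default residue-count bounds for composition enumeration
#'
#' Wide enough to cover every glycan mass reported for tissue membrane
#' N-glycomes up to tetra-antennary trisialylated species.
#'
#' @return Named list of `c(min, max)` integer bounds per class.
#' @export
defaultCountBounds <- function() {
  list(Hex = c(0L, 12L), HexNAc = c(0L, 8L), dHex = c(0L, 4L),
       Neu5Ac = c(0L, 4L), sulfate = c(0L, 2L))
}

#' Enumerate candidate monosaccharide compositions for an observed m/z
#'
#' GlycoMod-style search: exhaustively enumerates the bounded integer
#' lattice of (Hex, HexNAc, dHex, Neu5Ac, sulfate) counts whose theoretical
#' neutral mass lies within `tolerance` of the neutral mass implied by the
#' observed m/z and charge. N-glycan mode requires the trimannosyl
#' chitobiose core (Hex >= 3, HexNAc >= 2); O-glycan mode instead requires
#' HexNAc >= 1 (the reducing-end GalNAc-ol).
#'
#' The tolerance is applied on the neutral-mass (deconvoluted) scale, i.e.
#' `|observed neutral - theoretical neutral| <= tolerance`.
#'
#' @param observedMz Observed (deconvoluted) m/z.
#' @param charge Charge magnitude of the observed ion (1-3).
#' @param tolerance Mass tolerance in Da on the neutral-mass scale
#'   (default 0.5, the search tolerance used for ion-trap data).
#' @param glycanClass `"N"` or `"O"`.
#' @param reduced Alditol flag assumed for candidates.
#' @param bounds Per-class count bounds as from [defaultCountBounds()].
#' @return `data.frame` with columns `composition` (canonical string),
#'   `hex`, `hexnac`, `dhex`, `neu5ac`, `sulfate`, `theoreticalMz`, `delta`
#'   (observed - theoretical neutral mass, Da), sorted by `|delta|`
#'   ascending with ties broken by fewer total residues then
#'   lexicographically increasing class counts. Zero rows when nothing
#'   matches.
#' @examples
#' hits <- enumerateCompositions(913.9, charge = 2)
#' head(hits$composition)
#' @export
enumerateCompositions <- function(observedMz, charge = 1L, tolerance = 0.5,
                                  glycanClass = c("N", "O"), reduced = TRUE,
                                  bounds = defaultCountBounds()) {
  glycanClass <- match.arg(glycanClass)
  if (tolerance <= 0) stop("tolerance must be > 0")
  if (is.null(bounds))
    stop("refusing an unbounded composition search; supply count bounds")
  for (b in bounds)
    if (length(b) != 2L || any(b < 0) || b[1] > b[2])
      stop("bounds must be non-negative c(min, max) pairs")
  neutralObs <- observedMz * charge + charge * GLYCO_PROTON
  base <- GLYCO_WATER + if (reduced) GLYCO_ALDITOL_H2 else 0
  lo <- neutralObs - tolerance
  hi <- neutralObs + tolerance

  rows <- vector("list", 64L)
  nrows <- 0L
  bH <- bounds$Hex; bN <- bounds$HexNAc; bD <- bounds$dHex
  bS <- bounds$Neu5Ac; bSu <- bounds$sulfate
  hMin <- if (glycanClass == "N") max(bH[1], 3L) else bH[1]
  nMin <- if (glycanClass == "N") max(bN[1], 2L) else max(bN[1], 1L)
  for (h in hMin:bH[2]) {
    mH <- base + h * RESIDUE_MASS[["Hex"]]
    if (mH > hi) break
    for (nn in nMin:bN[2]) {
      mN <- mH + nn * RESIDUE_MASS[["HexNAc"]]
      if (mN > hi) break
      for (d in bD[1]:bD[2]) {
        mD <- mN + d * RESIDUE_MASS[["dHex"]]
        if (mD > hi) break
        for (s in bS[1]:bS[2]) {
          mS <- mD + s * RESIDUE_MASS[["Neu5Ac"]]
          if (mS > hi) break
          for (su in bSu[1]:bSu[2]) {
            m <- mS + su * GLYCO_SULFATE
            if (m > hi) break
            if (m >= lo) {
              nrows <- nrows + 1L
              if (nrows > length(rows))
                rows <- c(rows, vector("list", length(rows)))
              rows[[nrows]] <- c(h, nn, d, s, su, m)
            }
          }
        }
      }
    }
  }
  if (nrows == 0L)
    return(data.frame(composition = character(), hex = integer(),
                      hexnac = integer(), dhex = integer(),
                      neu5ac = integer(), sulfate = integer(),
                      theoreticalMz = numeric(), delta = numeric()))
  tab <- do.call(rbind, rows[seq_len(nrows)])
  theo <- mzFromMass(tab[, 6], charge)
  out <- data.frame(
    composition = apply(tab, 1L, function(r) {
      formatComposition(glycanComposition(r[1], r[2], r[3], r[4],
                                          sulfate = r[5], reduced = reduced,
                                          glycanClass = glycanClass,
                                          fragment = TRUE))
    }),
    hex = as.integer(tab[, 1]), hexnac = as.integer(tab[, 2]),
    dhex = as.integer(tab[, 3]), neu5ac = as.integer(tab[, 4]),
    sulfate = as.integer(tab[, 5]),
    theoreticalMz = theo,
    delta = neutralObs - tab[, 6]
  )
  o <- order(abs(out$delta),
             out$hex + out$hexnac + out$dhex + out$neu5ac + out$sulfate,
             out$hex, out$hexnac, out$dhex, out$neu5ac, out$sulfate)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
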