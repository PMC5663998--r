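#' Diagnostic ion m/z values used in motif calling
#'
#' Theoretical singly deprotonated negative-mode masses of the antenna
#' fragments that carry the structural evidence in ion-trap MS2 of glycan
#' alditols:
#' \describe{
#'   \item{B_LacdiNAc}{GalNAc-GlcNAc B ion, ~405.15}
#'   \item{F_LacdiNAc}{GalNAc-GlcNAc F ion (1,3A cross-ring, antenna +
#'     59.013), ~465.17}
#'   \item{B_sialylLacdiNAc}{Neu5Ac-GalNAc-GlcNAc B ion, ~696.25}
#'   \item{B_sialylLacNAc}{Neu5Ac-Gal-GlcNAc B ion, ~655.22}
#' }
#'
#' @return Named numeric vector of m/z values.
#' @export
diagnosticIons <- function() {
  hexnac <- RESIDUE_MASS[["HexNAc"]]
  hex <- RESIDUE_MASS[["Hex"]]
  neu <- RESIDUE_MASS[["Neu5Ac"]]
  c(B_LacdiNAc        = 2 * hexnac - GLYCO_PROTON,
    F_LacdiNAc        = 2 * hexnac + GLYCO_F_ION_TAIL,
    B_sialylLacdiNAc  = neu + 2 * hexnac - GLYCO_PROTON,
    B_sialylLacNAc    = neu + hex + hexnac - GLYCO_PROTON)
}

#' Generate theoretical negative-mode fragment ions for a topology
#'
#' Every single glycosidic cleavage yields a B and C ion (non-reducing
#' side) and a Y and Z ion (reducing side, retaining the alditol hydrogens
#' when the structure is reduced). Two double-cleavage ion types carry the
#' diagnostic load on PGC ion-trap data and are emitted when their
#' structural context exists:
#' \itemize{
#'   \item the D ion (6-arm antenna + bisecting GlcNAc if present + the two
#'     branching core mannoses, as a B-type ion), and D-221 (loss of the
#'     bisecting HexNAc + water from D) when a bisecting GlcNAc is present;
#'   \item the F ion (1,3A cross-ring on the branching mannose): antenna
#'     residues + 59.013, one per complete antenna.
#' }
#' Only singly charged fragments are predicted; ions are de-duplicated by
#' (kind, mass).
#'
#' @param topo A [GlycanStructure-class].
#' @param kinds Character subset of `c("B","C","Y","Z","D","D221","F")`.
#' @return `data.frame` with columns `kind`, `mz`, `residues` (composition
#'   string of the retained residues), `charge`.
#' @examples
#' ldn <- parseGlycanStructure("GalNAc(b1-4)GlcNAc(b1-2)Man(a1-6)[Gal(b1-4)GlcNAc(b1-2)Man(a1-3)]Man(b1-4)GlcNAc(b1-4)GlcNAc-ol")
#' fr <- generateFragments(ldn)
#' round(fr$mz[fr$kind == "F"], 2)    # contains 465.17
#' @export
generateFragments <- function(topo,
                              kinds = c("B", "C", "Y", "Z", "D", "D221", "F")) {
  stopifnot(is(topo, "GlycanStructure"))
  kinds <- match.arg(kinds, several.ok = TRUE)
  totalResidueMass <- .subtreeResidueMass(topo@root)
  redH <- if (topo@reduced) GLYCO_ALDITOL_H2 else 0

  rows <- list()
  add <- function(kind, mz, residues) {
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, mz = mz, residues = residues, charge = 1L)
  }
  compString <- function(nodes) {
    cls <- RESIDUE_CLASS[unlist(lapply(nodes, identity))]
    cnt <- table(factor(cls, levels = names(RESIDUE_MASS)))
    formatComposition(glycanComposition(cnt[["Hex"]], cnt[["HexNAc"]],
                                        cnt[["dHex"]], cnt[["Neu5Ac"]],
                                        reduced = FALSE, fragment = TRUE,
                                        glycanClass = topo@glycanClass))
  }

  ## glycosidic single cleavages: walk every non-root node
  .treeWalk(topo@root, function(nd, parent) {
    if (is.null(parent)) return(NULL)
    sub <- .subtreeResidueMass(nd)
    subRes <- treeResidues(nd)
    if (any(c("B", "C") %in% kinds)) {
      b <- sub - GLYCO_PROTON
      if ("B" %in% kinds) add("B", b, compString(subRes))
      if ("C" %in% kinds) add("C", b + GLYCO_WATER, compString(subRes))
    }
    if (any(c("Y", "Z") %in% kinds)) {
      allRes <- treeResidues(topo@root)
      keep <- allRes
      for (r in subRes) keep <- keep[-match(r, keep)]
      y <- (totalResidueMass - sub) + GLYCO_WATER + redH - GLYCO_PROTON
      if ("Y" %in% kinds) add("Y", y, compString(keep))
      if ("Z" %in% kinds) add("Z", y - GLYCO_WATER, compString(keep))
    }
    NULL
  })

  ## D / D-221: 6-arm subtree + beta-Man + bisecting GlcNAc, as B-type ion
  bman <- .findBetaMan(topo)
  if (!is.null(bman) && any(c("D", "D221") %in% kinds)) {
    arm6 <- NULL
    bis <- NULL
    for (ch in bman$children) {
      if (ch$residue == "Man" && !is.null(ch$linkage) && ch$linkage$to == "6")
        arm6 <- ch
      if (ch$residue == "GlcNAc" && !is.null(ch$linkage) &&
          ch$linkage$to == "4")
        bis <- ch
    }
    if (!is.null(arm6)) {
      dres <- c("Man", treeResidues(arm6),
                if (!is.null(bis)) treeResidues(bis))
      dmass <- RESIDUE_MASS[["Hex"]] + .subtreeResidueMass(arm6) +
        (if (!is.null(bis)) .subtreeResidueMass(bis) else 0) - GLYCO_PROTON
      if ("D" %in% kinds) add("D", dmass, compString(dres))
      if ("D221" %in% kinds && !is.null(bis))
        add("D221", dmass - GLYCO_D221_LOSS,
            compString(dres[-match("GlcNAc", dres)]))
    }
  }

  ## F ions: one per complete antenna
  if ("F" %in% kinds) {
    for (ant in .antennaSubtrees(topo))
      add("F", .subtreeResidueMass(ant) + GLYCO_F_ION_TAIL,
          compString(treeResidues(ant)))
  }

  if (length(rows) == 0L)
    return(data.frame(kind = character(), mz = numeric(),
                      residues = character(), charge = integer()))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$kind, round(out$mz, 6))), , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match theoretical fragment ions against spectrum peaks
#'
#' Each theoretical ion is matched to the nearest observed peak within the
#' tolerance. A peak may satisfy several isobaric ions; such matches are
#' flagged ambiguous.
#'
#' @param spec A [GlycanSpectrum-class].
#' @param ions A fragment table as returned by [generateFragments()].
#' @param tol Match tolerance in Da (default 0.3, ion-trap MS2).
#' @return `data.frame`: one row per ion with `kind`, `theoreticalMz`,
#'   `matched`, `peakMz`, `intensity`, `ambiguous`.
#' @export
matchPeaks <- function(spec, ions, tol = 0.3) {
  stopifnot(is(spec, "GlycanSpectrum"), tol > 0)
  pk <- peaks(spec)
  n <- nrow(ions)
  peakIdx <- rep(NA_integer_, n)
  if (nrow(pk) > 0L && n > 0L) {
    for (i in seq_len(n)) {
      d <- abs(pk$mz - ions$mz[i])
      j <- which.min(d)
      if (d[j] <= tol) peakIdx[i] <- j
    }
  }
  out <- data.frame(
    kind = ions$kind,
    theoreticalMz = ions$mz,
    matched = !is.na(peakIdx),
    peakMz = ifelse(is.na(peakIdx), NA_real_, pk$mz[peakIdx]),
    intensity = ifelse(is.na(peakIdx), NA_real_, pk$intensity[peakIdx])
  )
  out$ambiguous <- !is.na(peakIdx) & peakIdx %in%
    peakIdx[duplicated(peakIdx) & !is.na(peakIdx)]
  out
}

## motif evidence read directly off a spectrum
.motifEvidence <- function(spec, tol) {
  di <- diagnosticIons()
  hasPeak <- function(mz)
    nrow(peaks(spec)) > 0L && any(abs(peaks(spec)$mz - mz) <= tol)
  list(
    lacdinacB = hasPeak(di[["B_LacdiNAc"]]),
    lacdinacF = hasPeak(di[["F_LacdiNAc"]]),
    sialylLacdinac = hasPeak(di[["B_sialylLacdiNAc"]]),
    sialylLacnac = hasPeak(di[["B_sialylLacNAc"]])
  )
}

#' Rank candidate topologies against an MS2 spectrum and call motifs
#'
#' For each candidate whose precursor mass is consistent with the spectrum
#' (within `precursorTol` on the neutral-mass scale), theoretical fragments
#' are generated and matched; candidates are ranked by coverage (fraction
#' of predicted ions matched). Diagnostic motif booleans are set only when
#' the corresponding evidence peak is matched within the tolerance:
#' bisecting GlcNAc requires the candidate's D-221 ion, LacdiNAc its B
#' (~405.15) and/or F (~465.17) ion, sialyl-LacdiNAc the B ion ~696.25 and
#' sialyl-LacNAc the B ion ~655.22.
#'
#' @param spec A [GlycanSpectrum-class].
#' @param candidates List of [GlycanStructure-class] candidates.
#' @param tol MS2 match tolerance in Da (default 0.3).
#' @param precursorTol Precursor consistency tolerance in Da on the neutral
#'   mass (default 0.5, the composition-search tolerance).
#' @return A [S4Vectors::DataFrame] ranked by decreasing coverage with
#'   columns `structure` (notation), `coverage`, `nMatched`, `nPredicted`,
#'   `bisecting`, `lacdinac`, `sialylLacdinac`, `sialylLacnac`. The matched
#'   candidate topologies are carried in `metadata()$candidates` in ranked
#'   order.
#' @export
classifyMotifs <- function(spec, candidates, tol = 0.3, precursorTol = 0.5) {
  stopifnot(is(spec, "GlycanSpectrum"))
  if (is(candidates, "GlycanStructure")) candidates <- list(candidates)
  neutralObs <- spec@precursorMz * spec@precursorCharge +
    spec@precursorCharge * GLYCO_PROTON
  keep <- vapply(candidates, function(t)
    abs(neutralMass(topologyToComposition(t)) - neutralObs) <= precursorTol,
    logical(1))
  if (!any(keep))
    stop("no candidate topology within ", precursorTol,
         " Da of the precursor mass")
  candidates <- candidates[keep]
  ev <- .motifEvidence(spec, tol)
  res <- lapply(candidates, function(t) {
    ions <- generateFragments(t)
    mm <- matchPeaks(spec, ions, tol = tol)
    d221 <- mm$kind == "D221"
    list(
      structure = t@notation,
      coverage = if (nrow(mm)) mean(mm$matched) else 0,
      nMatched = sum(mm$matched),
      nPredicted = nrow(mm),
      bisecting = hasBisectingGlcNAc(t) && any(mm$matched[d221]),
      lacdinac = hasLacdiNAc(t) && (ev$lacdinacB || ev$lacdinacF),
      sialylLacdinac = ev$sialylLacdinac,
      sialylLacnac = ev$sialylLacnac
    )
  })
  out <- S4Vectors::DataFrame(
    structure = vapply(res, `[[`, character(1), "structure"),
    coverage = vapply(res, `[[`, numeric(1), "coverage"),
    nMatched = vapply(res, `[[`, integer(1), "nMatched"),
    nPredicted = vapply(res, `[[`, integer(1), "nPredicted"),
    bisecting = vapply(res, `[[`, logical(1), "bisecting"),
    lacdinac = vapply(res, `[[`, logical(1), "lacdinac"),
    sialylLacdinac = vapply(res, `[[`, logical(1), "sialylLacdinac"),
    sialylLacnac = vapply(res, `[[`, logical(1), "sialylLacnac")
  )
  o <- order(-out$coverage, -out$nMatched)
  out <- out[o, , drop = FALSE]
  metadata(out)$candidates <- candidates[o]
  out
}
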