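#' Build relative-abundance profiles from integrated EIC areas
#'
#' Normalizes raw EIC peak areas to relative abundances summing to 100 per
#' glycan class within each sample, the scale on which all downstream
#' statistics operate. N- and O-glycans are normalized separately, as their
#' released pools are measured in separate runs. Structural isomers should
#' enter as separate rows (e.g. `"913.9a"`, `"913.9b"`); [mergeIsomers()]
#' collapses them to glycan-mass level while conserving their summed
#' fraction.
#'
#' @param areas Numeric matrix of areas, glycans x samples (>= 0).
#' @param diagnosis,site Per-sample metadata (see [glycanProfileSet()]).
#' @param rowData Optional per-glycan annotation `DataFrame`.
#' @return A [GlycanProfileSet-class].
#' @export
buildProfile <- function(areas, diagnosis, site = NULL, rowData = NULL) {
  areas <- as.matrix(areas)
  if (any(areas < 0)) stop("EIC areas must be >= 0")
  if (is.null(rowData))
    rowData <- DataFrame(glycanClass = rep("N", nrow(areas)),
                         row.names = rownames(areas))
  rowData <- as(rowData, "DataFrame")
  if (!"glycanClass" %in% names(rowData)) rowData$glycanClass <- "N"
  rel <- areas
  for (cl in unique(rowData$glycanClass)) {
    ix <- rowData$glycanClass == cl
    tot <- colSums(areas[ix, , drop = FALSE])
    bad <- tot <= 0
    if (any(bad))
      stop("sample(s) with zero total ", cl, "-glycan area: ",
           paste(colnames(areas)[bad], collapse = ", "))
    rel[ix, ] <- sweep(areas[ix, , drop = FALSE], 2L, tot / 100, "/")
  }
  glycanProfileSet(rel, diagnosis = diagnosis, site = site,
                   rowData = rowData)
}

#' Merge structural isomer rows into glycan-mass rows
#'
#' Rows sharing the same value of `by` (default: the rowData column
#' `glycanMass`, falling back to row names stripped of a trailing isomer
#' letter) are summed. Normalization is conserved: the merged fraction
#' equals the sum of the isomer fractions.
#'
#' @param x A [GlycanProfileSet-class].
#' @param by Character vector of parent glycan ids, one per row.
#' @return A [GlycanProfileSet-class] at glycan-mass level.
#' @export
mergeIsomers <- function(x, by = NULL) {
  stopifnot(is(x, "GlycanProfileSet"))
  if (is.null(by)) {
    by <- if ("glycanMass" %in% names(rowData(x)))
      as.character(rowData(x)$glycanMass)
    else sub("[a-z]$", "", rownames(x))
  }
  a <- relAbundance(x)
  merged <- rowsum(a, group = by, reorder = FALSE)
  cls <- tapply(rowData(x)$glycanClass, by, function(v) v[1])
  glycanProfileSet(merged, diagnosis = diagnosis(x), site = samplingSite(x),
                   rowData = DataFrame(glycanClass = as.character(
                     cls[rownames(merged)]), row.names = rownames(merged)))
}

#' Classify an N-glycan composition into the five major glycan types
#'
#' Rule table with precedence: paucimannose (HexNAc = 2, truncated mannose
#' arm, no sialic acid, optionally core-fucosylated), then high mannose
#' (HexNAc = 2, Hex 4-9, no fucose; Man4 is grouped with the high-mannose
#' family), then hybrid (HexNAc = 3 with an unsubstituted mannose arm when
#' the topology is known; compositional fallback HexNAc = 3 and Hex >= 4),
#' then complex, which is split into neutral and sialylated by the Neu5Ac
#' count. Every valid N-composition receives exactly one type.
#'
#' @param comp A [GlycanComposition-class] with `glycanClass == "N"`.
#' @param topo Optional [GlycanStructure-class] refining the hybrid rule.
#' @return One of `"paucimannose"`, `"high_mannose"`, `"hybrid"`,
#'   `"complex_neutral"`, `"complex_sialylated"`.
#' @examples
#' classifyGlycanType(glycanComposition(hex = 5, hexnac = 2)) # high mannose
#' @export
classifyGlycanType <- function(comp, topo = NULL) {
  stopifnot(is(comp, "GlycanComposition"))
  if (comp@glycanClass != "N")
    stop("glycan-type classification is defined for N-glycans only")
  cnt <- comp@counts
  hex <- cnt[["Hex"]]; hexnac <- cnt[["HexNAc"]]
  dhex <- cnt[["dHex"]]; neu <- cnt[["Neu5Ac"]]
  if (hexnac == 2L && neu == 0L &&
      (hex <= 3L || (hex == 4L && dhex > 0L)))
    return("paucimannose")
  if (hexnac == 2L && neu == 0L && dhex == 0L && hex >= 4L && hex <= 9L)
    return("high_mannose")
  hybrid <- if (!is.null(topo)) {
    ## a hybrid glycan keeps an unsubstituted (mannosidic) arm
    arms <- .coreArms(topo)
    hexnac == 3L && length(arms) == 2L &&
      any(vapply(arms, function(a) length(.armGlcNAcs(a)) == 0L, logical(1)))
  } else hexnac == 3L && hex >= 4L
  if (hybrid) return("hybrid")
  if (neu > 0L) "complex_sialylated" else "complex_neutral"
}

#' Per-sample structural feature summaries
#'
#' Sums relative abundances over feature memberships: the five glycan-type
#' percentages (summing to 100 over the N-glycan class), sialylation-degree
#' percentages (mono/di/tri, computed over sialylated species only),
#' antennarity percentages (bi/tri/tetra, over the N-glycan total), and the
#' bisecting-GlcNAc and LacdiNAc motif totals. A glycan may contribute to
#' several features (e.g. bisecting and sialylated). The abundance-weighted
#' alpha2,6 fraction is reported when per-structure `alpha26` fractions are
#' annotated.
#'
#' @param x A [GlycanProfileSet-class] whose `rowData` annotates each
#'   N-glycan row with `type` (see [classifyGlycanType()]), `nSialic`,
#'   `nAntennae`, `bisecting` and `lacdinac` (motif structure table from
#'   fragment annotation), optionally `alpha26`.
#' @return `DataFrame`, one row per sample, columns
#'   `high_mannose`, `hybrid`, `complex_neutral`, `complex_sialylated`,
#'   `paucimannose`, `monoSialylated`, `diSialylated`, `triSialylated`,
#'   `biAntennary`, `triAntennary`, `tetraAntennary`, `bisectingTotal`,
#'   `lacdinacTotal`, `alpha26Fraction`.
#' @export
summarizeFeatures <- function(x) {
  stopifnot(is(x, "GlycanProfileSet"))
  rd <- rowData(x)
  nIdx <- rd$glycanClass == "N"
  need <- c("type", "nSialic", "nAntennae", "bisecting", "lacdinac")
  miss <- setdiff(need, names(rd))
  if (length(miss))
    stop("rowData lacks structure-table columns: ",
         paste(miss, collapse = ", "))
  unmapped <- rownames(x)[nIdx][is.na(rd$type[nIdx])]
  if (length(unmapped))
    stop("glycan id(s) with no structure mapping: ",
         paste(unmapped, collapse = ", "))
  a <- relAbundance(x)[nIdx, , drop = FALSE]
  rd <- rd[nIdx, , drop = FALSE]
  sumBy <- function(sel) colSums(a[sel, , drop = FALSE])
  types <- c("high_mannose", "hybrid", "complex_neutral",
             "complex_sialylated", "paucimannose")
  out <- DataFrame(row.names = colnames(x))
  for (tp in types) out[[tp]] <- sumBy(rd$type == tp)
  sial <- rd$nSialic > 0
  sialTot <- sumBy(sial)
  degree <- function(k) {
    v <- 100 * sumBy(rd$nSialic == k) / sialTot
    v[sialTot == 0] <- NA_real_
    v
  }
  out$monoSialylated <- degree(1L)
  out$diSialylated <- degree(2L)
  out$triSialylated <- degree(3L)
  out$biAntennary <- sumBy(!is.na(rd$nAntennae) & rd$nAntennae == 2L)
  out$triAntennary <- sumBy(!is.na(rd$nAntennae) & rd$nAntennae == 3L)
  out$tetraAntennary <- sumBy(!is.na(rd$nAntennae) & rd$nAntennae == 4L)
  out$bisectingTotal <- sumBy(rd$bisecting %in% TRUE)
  out$lacdinacTotal <- sumBy(rd$lacdinac %in% TRUE)
  out$alpha26Fraction <- if ("alpha26" %in% names(rd)) {
    iso <- !is.na(rd$alpha26)
    w <- colSums(a[iso, , drop = FALSE])
    v <- 100 * colSums(a[iso, , drop = FALSE] * rd$alpha26[iso]) / w
    v[w == 0] <- NA_real_
    v
  } else NA_real_
  out
}
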