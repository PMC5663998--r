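#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

## ---------------------------------------------------------------------------
## GlycanComposition
## ---------------------------------------------------------------------------

#' Monosaccharide composition of a glycan
#'
#' Counts per monosaccharide mass class (Hex, HexNAc, dHex, Neu5Ac) plus a
#' sulfate count, a reduced-end (alditol) flag and a glycan class. This is
#' the unit of the mass search: specific identities (Gal vs Man, GalNAc vs
#' GlcNAc) are mass-identical and live only in [GlycanStructure] topologies.
#'
#' N-glycan compositions are validated against the trimannosyl-chitobiose
#' core (Hex >= 3, HexNAc >= 2) unless `fragment = TRUE`, which marks a
#' partial (fragment-side) composition.
#'
#' @slot counts Named integer vector over `c("Hex","HexNAc","dHex","Neu5Ac")`.
#' @slot sulfate Non-negative integer count of sulfate modifications.
#' @slot reduced Logical; `TRUE` for borohydride-reduced alditols.
#' @slot glycanClass `"N"` or `"O"`.
#' @slot fragment Logical; `TRUE` relaxes the N-core constraint.
#'
#' @seealso [glycanComposition()], [parseComposition()], [neutralMass()]
#' @exportClass GlycanComposition
setClass("GlycanComposition",
  representation(
    counts = "integer",
    sulfate = "integer",
    reduced = "logical",
    glycanClass = "character",
    fragment = "logical"
  ),
  prototype(
    counts = c(Hex = 0L, HexNAc = 0L, dHex = 0L, Neu5Ac = 0L),
    sulfate = 0L, reduced = FALSE, glycanClass = "N", fragment = FALSE
  )
)

setValidity("GlycanComposition", function(object) {
  msg <- character()
  if (!identical(names(object@counts), names(RESIDUE_MASS)))
    msg <- c(msg, "counts must be named Hex, HexNAc, dHex, Neu5Ac")
  if (any(is.na(object@counts)) || any(object@counts < 0L))
    msg <- c(msg, "residue counts must be non-negative integers")
  if (length(object@sulfate) != 1L || is.na(object@sulfate) ||
      object@sulfate < 0L)
    msg <- c(msg, "sulfate count must be a single non-negative integer")
  if (!object@glycanClass %in% c("N", "O"))
    msg <- c(msg, "glycanClass must be 'N' or 'O'")
  if (length(msg) == 0L && !object@fragment &&
      object@glycanClass == "N" && sum(object@counts) > 0L &&
      (object@counts[["Hex"]] < 3L || object@counts[["HexNAc"]] < 2L))
    msg <- c(msg,
      "N-glycan composition must contain the Man3GlcNAc2 core (Hex >= 3, HexNAc >= 2)")
  if (length(msg)) msg else TRUE
})

#' Construct a glycan composition
#'
#' @param hex,hexnac,dhex,neu5ac Residue counts per mass class.
#' @param sulfate Sulfate count.
#' @param reduced Alditol (reduced end) flag; released glycans analysed
#'   after borohydride reduction are `reduced = TRUE` (the default).
#' @param glycanClass `"N"` or `"O"`.
#' @param fragment Set `TRUE` for fragment-side compositions, which are not
#'   required to contain the N-glycan core.
#' @return A [GlycanComposition-class] object.
#' @examples
#' glycanComposition(hex = 5, hexnac = 4, neu5ac = 2)   # disialo biantennary
#' @export
glycanComposition <- function(hex = 0, hexnac = 0, dhex = 0, neu5ac = 0,
                              sulfate = 0, reduced = TRUE,
                              glycanClass = c("N", "O"), fragment = FALSE) {
  glycanClass <- match.arg(glycanClass)
  cnt <- c(Hex = hex, HexNAc = hexnac, dHex = dhex, Neu5Ac = neu5ac)
  if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("invalid composition: residue counts must be non-negative integers")
  new("GlycanComposition",
      counts = stats::setNames(as.integer(cnt), names(RESIDUE_MASS)),
      sulfate = as.integer(sulfate), reduced = reduced,
      glycanClass = glycanClass, fragment = fragment)
}

#' @describeIn glycanComposition Residue counts accessor.
#' @param x,object A `GlycanComposition`.
#' @export
residueCounts <- function(x) x@counts

#' @describeIn glycanComposition Reduced-end flag accessor.
#' @export
isReduced <- function(x) x@reduced

#' @describeIn glycanComposition Glycan class (`"N"`/`"O"`) accessor.
#' @export
glycanClass <- function(x) x@glycanClass

setMethod("show", "GlycanComposition", function(object) {
  cat("GlycanComposition (", object@glycanClass, "-glycan",
      if (object@reduced) ", reduced alditol" else "",
      if (object@fragment) ", fragment" else "", ")\n", sep = "")
  cat("  ", formatComposition(object), "\n", sep = "")
  cat("  neutral mass: ", sprintf("%.4f", neutralMass(object)), " Da\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## GlycanStructure
## ---------------------------------------------------------------------------

#' Rooted glycan topology
#'
#' A rooted tree of specific residues (Man, Gal, GlcNAc, GalNAc, Fuc,
#' Neu5Ac) with glycosidic linkages, parsed from condensed IUPAC-like
#' notation. The root is the reducing-end residue (an alditol when
#' `reduced`). Topologies are the unit of fragment prediction and motif
#' logic: bisecting GlcNAc, LacdiNAc antennae and sialyl linkages are all
#' read off the tree.
#'
#' @slot root The root residue node, a nested list with fields `residue`,
#'   `linkage` and `children`.
#' @slot notation The canonical linear notation the structure was built from.
#' @slot reduced Logical alditol flag.
#' @slot glycanClass `"N"` or `"O"`.
#'
#' @seealso [parseGlycanStructure()], [generateFragments()],
#'   [countAntennae()]
#' @exportClass GlycanStructure
setClass("GlycanStructure",
  representation(
    root = "list",
    notation = "character",
    reduced = "logical",
    glycanClass = "character"
  )
)

setValidity("GlycanStructure", function(object) {
  msg <- character()
  if (!object@glycanClass %in% c("N", "O"))
    msg <- c(msg, "glycanClass must be 'N' or 'O'")
  ok <- tryCatch({
    ids <- treeResidues(object@root)
    all(ids %in% names(RESIDUE_CLASS))
  }, error = function(e) FALSE)
  if (!ok) msg <- c(msg, "topology contains unknown residue identities")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GlycanStructure", function(object) {
  comp <- topologyToComposition(object)
  cat("GlycanStructure (", object@glycanClass, "-glycan",
      if (object@reduced) ", reduced" else "", ")\n", sep = "")
  cat("  ", object@notation, "\n", sep = "")
  cat("  composition: ", formatComposition(comp),
      "  [", sprintf("%.4f", neutralMass(comp)), " Da]\n", sep = "")
  if (hasBisectingGlcNAc(object)) cat("  bisecting GlcNAc present\n")
})

## ---------------------------------------------------------------------------
## GlycanSpectrum
## ---------------------------------------------------------------------------

#' An MS2 spectrum of a glycan precursor
#'
#' Precursor m/z and charge plus a fragment peak list, the unit of
#' annotation. Peaks are stored sorted by m/z.
#'
#' @slot precursorMz Precursor m/z (negative mode, deprotonated).
#' @slot precursorCharge Positive integer charge magnitude (1-3).
#' @slot peaks `data.frame` with numeric columns `mz` and `intensity`.
#'
#' @seealso [glycanSpectrum()], [matchPeaks()], [classifyMotifs()]
#' @exportClass GlycanSpectrum
setClass("GlycanSpectrum",
  representation(
    precursorMz = "numeric",
    precursorCharge = "integer",
    peaks = "data.frame"
  )
)

setValidity("GlycanSpectrum", function(object) {
  msg <- character()
  p <- object@peaks
  if (!all(c("mz", "intensity") %in% names(p)))
    msg <- c(msg, "peaks must have columns 'mz' and 'intensity'")
  else {
    if (nrow(p) && any(p$intensity < 0))
      msg <- c(msg, "peak intensities must be >= 0")
    if (nrow(p) > 1L && is.unsorted(p$mz))
      msg <- c(msg, "peaks must be sorted by m/z")
  }
  if (object@precursorCharge < 1L || object@precursorCharge > 3L)
    msg <- c(msg, "precursor charge must be 1, 2 or 3")
  if (length(msg)) msg else TRUE
})

#' Construct an MS2 spectrum
#'
#' @param precursorMz Precursor m/z.
#' @param precursorCharge Charge magnitude (1-3); negative mode is implied.
#' @param mz,intensity Fragment peak vectors (recycled/ordered internally).
#' @return A [GlycanSpectrum-class].
#' @export
glycanSpectrum <- function(precursorMz, precursorCharge = 1L,
                           mz = numeric(), intensity = numeric()) {
  if (length(intensity) == 0L && length(mz) > 0L)
    intensity <- rep(100, length(mz))
  o <- order(mz)
  new("GlycanSpectrum", precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      peaks = data.frame(mz = as.numeric(mz)[o],
                         intensity = as.numeric(intensity)[o]))
}

#' @describeIn glycanSpectrum Peak table accessor.
#' @param x A `GlycanSpectrum`.
#' @export
peaks <- function(x) x@peaks

#' @describeIn glycanSpectrum Precursor m/z accessor.
#' @export
precursorMz <- function(x) x@precursorMz

setMethod("show", "GlycanSpectrum", function(object) {
  cat("GlycanSpectrum: precursor m/z ", sprintf("%.4f", object@precursorMz),
      " [", object@precursorCharge, "-], ", nrow(object@peaks),
      " peaks\n", sep = "")
})

## ---------------------------------------------------------------------------
## GlycanProfileSet
## ---------------------------------------------------------------------------

#' Sample x glycan relative-abundance profiles
#'
#' A [SummarizedExperiment::SummarizedExperiment] with glycan structures as
#' rows and tissue samples as columns. The `"relabund"` assay holds relative
#' abundances in percent, normalized to 100 per glycan class within each
#' sample. `colData` carries the two grouping factors used throughout the
#' statistics layer: `diagnosis` (OC/PC) and `site`
#' (ovary/omentum/peritoneum). `rowData` carries at least `glycanClass` and,
#' when known, composition strings, glycan types and motif flags.
#'
#' @seealso [buildProfile()], [summarizeFeatures()], [differentialTest()]
#' @exportClass GlycanProfileSet
setClass("GlycanProfileSet", contains = "SummarizedExperiment")

setValidity("GlycanProfileSet", function(object) {
  msg <- character()
  if (!"relabund" %in% names(assays(object)))
    msg <- c(msg, "assay 'relabund' is required")
  if (!"glycanClass" %in% names(rowData(object)))
    msg <- c(msg, "rowData column 'glycanClass' is required")
  if (!all(c("diagnosis", "site") %in% names(colData(object))))
    msg <- c(msg, "colData columns 'diagnosis' and 'site' are required")
  if (length(msg) == 0L && ncol(object) > 0L) {
    a <- assay(object, "relabund")
    if (any(a < -1e-9, na.rm = TRUE))
      msg <- c(msg, "relative abundances must be >= 0")
    for (cl in unique(rowData(object)$glycanClass)) {
      s <- colSums(a[rowData(object)$glycanClass == cl, , drop = FALSE])
      if (any(abs(s - 100) > 1e-6))
        msg <- c(msg, sprintf(
          "per-sample %s-glycan abundances must sum to 100", cl))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GlycanProfileSet
#'
#' @param abundance Numeric matrix, glycans x samples, in percent. Each
#'   glycan class must sum to 100 within every sample (use
#'   [buildProfile()] to normalize raw areas).
#' @param diagnosis,site Per-sample grouping factors.
#' @param rowData Optional `DataFrame`/`data.frame` of per-glycan
#'   annotation; a `glycanClass` column is added (default `"N"`) if missing.
#' @return A [GlycanProfileSet-class].
#' @export
glycanProfileSet <- function(abundance, diagnosis, site = NULL,
                             rowData = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(site)) site <- rep(NA_character_, ncol(abundance))
  cd <- DataFrame(diagnosis = as.character(diagnosis),
                  site = as.character(site),
                  row.names = colnames(abundance))
  if (is.null(rowData))
    rowData <- DataFrame(row.names = rownames(abundance))
  rowData <- as(rowData, "DataFrame")
  if (!"glycanClass" %in% names(rowData))
    rowData$glycanClass <- "N"
  se <- SummarizedExperiment(assays = list(relabund = abundance),
                             colData = cd, rowData = rowData)
  new("GlycanProfileSet", se)
}

#' @describeIn glycanProfileSet Relative-abundance matrix accessor
#'   (glycans x samples, percent).
#' @param x A `GlycanProfileSet`.
#' @export
relAbundance <- function(x) assay(x, "relabund")

#' @describeIn glycanProfileSet Diagnosis factor accessor.
#' @export
diagnosis <- function(x) colData(x)$diagnosis

#' @describeIn glycanProfileSet Sampling-site factor accessor.
#' @export
samplingSite <- function(x) colData(x)$site

setMethod("show", "GlycanProfileSet", function(object) {
  callNextMethod()
  d <- table(diagnosis(object), useNA = "no")
  if (length(d))
    cat("diagnosis: ", paste(names(d), d, sep = "=", collapse = ", "), "\n",
        sep = "")
})
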