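#' Neutral monoisotopic mass of a glycan composition
#'
#' Sums residue masses over the composition, adds the terminal water of the
#' free glycan, two hydrogens when the reducing end has been reduced to an
#' alditol, and the sulfate modification mass per sulfate.
#'
#' @param comp A [GlycanComposition-class].
#' @return Monoisotopic neutral mass in Da.
#' @examples
#' neutralMass(glycanComposition())                      # water only, 18.0106
#' neutralMass(glycanComposition(hex = 5, hexnac = 4, neu5ac = 2))
#' @export
neutralMass <- function(comp) {
  stopifnot(is(comp, "GlycanComposition"))
  validObject(comp)
  sum(comp@counts * RESIDUE_MASS) + GLYCO_WATER +
    (if (comp@reduced) GLYCO_ALDITOL_H2 else 0) +
    comp@sulfate * GLYCO_SULFATE
}

#' Negative-mode m/z of a neutral mass
#'
#' Deprotonation model: \eqn{m/z = (M - z \cdot 1.00728)/z} for
#' \eqn{[M-zH]^{z-}} ions, the species observed for underivatized glycan
#' alditols in negative electrospray.
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Charge magnitude, 1-3.
#' @return m/z value(s).
#' @examples
#' mzFromMass(18.0106, 1)            # 17.0033, water minus a proton
#' @export
mzFromMass <- function(mass, charge = 1L) {
  if (any(charge <= 0) || any(charge != round(charge)) || any(charge > 3))
    stop("charge must be a positive integer in 1..3")
  (mass - charge * GLYCO_PROTON) / charge
}

#' Negative-mode m/z of a composition
#'
#' Convenience wrapper: [neutralMass()] followed by [mzFromMass()].
#'
#' @inheritParams neutralMass
#' @inheritParams mzFromMass
#' @return m/z of the \eqn{[M-zH]^{z-}} ion.
#' @export
compositionMz <- function(comp, charge = 1L)
  mzFromMass(neutralMass(comp), charge)

## token -> (class, is core shorthand) lookup for the composition dialect
.COMP_TOKEN <- c(
  Hex = "Hex", HexNAc = "HexNAc", dHex = "dHex", Neu5Ac = "Neu5Ac",
  Man = "Hex", Gal = "Hex", Glc = "Hex",
  GlcNAc = "HexNAc", GalNAc = "HexNAc", Fuc = "dHex",
  NeuAc = "Neu5Ac", S = "sulfate", Sulfate = "sulfate"
)

#' Parse a composition string
#'
#' Reads the `"(Class)count..."` dialect used in glycomics captions, e.g.
#' `"(Hex)1(HexNAc)3(dHex)1+(Man)3(GlcNAc)2"`: specific residue names are
#' folded into their mass classes and a `+(Man)3(GlcNAc)2` suffix (the
#' N-glycan core written separately) is added into the totals.
#'
#' @param text Composition string.
#' @param glycanClass `"N"` or `"O"`; when missing, inferred: compositions
#'   carrying the explicit `+core` suffix or satisfying the N-core counts
#'   parse as `"N"`, others as `"O"`.
#' @param reduced Alditol flag for the resulting composition.
#' @return A [GlycanComposition-class]; round-trips through
#'   [formatComposition()].
#' @examples
#' parseComposition("(Neu5Ac)1(Gal)1(GalNAc)1")          # core 1 O-glycan
#' parseComposition("(Hex)1(HexNAc)3(dHex)1+(Man)3(GlcNAc)2")
#' @export
parseComposition <- function(text, glycanClass = NULL, reduced = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]_]", "", text)
  parts <- strsplit(s, "+", fixed = TRUE)[[1]]
  if (length(parts) > 2L || any(!nzchar(parts)))
    stop("parse error in composition '", text, "': malformed '+core' suffix")
  counts <- c(Hex = 0L, HexNAc = 0L, dHex = 0L, Neu5Ac = 0L)
  sulfate <- 0L
  offset <- 0L
  for (part in parts) {
    pos <- 1L
    while (pos <= nchar(part)) {
      m <- regexpr("^\\(([A-Za-z0-9]+)\\)([0-9]+)", substring(part, pos),
                   perl = TRUE)
      if (m == -1L)
        stop("parse error in composition '", text, "' at offset ",
             offset + pos)
      tok <- sub("^\\(([A-Za-z0-9]+)\\)([0-9]+).*$", "\\1",
                 substring(part, pos))
      n <- as.integer(sub("^\\(([A-Za-z0-9]+)\\)([0-9]+).*$", "\\2",
                          substring(part, pos)))
      cls <- .COMP_TOKEN[tok]
      if (is.na(cls))
        stop("parse error in composition '", text, "': unknown class token '",
             tok, "' at offset ", offset + pos)
      if (cls == "sulfate") sulfate <- sulfate + n
      else counts[cls] <- counts[cls] + n
      pos <- pos + attr(m, "match.length")
    }
    offset <- offset + nchar(part) + 1L
  }
  if (is.null(glycanClass))
    glycanClass <- if (length(parts) == 2L ||
                       (counts[["Hex"]] >= 3L && counts[["HexNAc"]] >= 2L))
      "N" else "O"
  glycanComposition(counts[["Hex"]], counts[["HexNAc"]], counts[["dHex"]],
                    counts[["Neu5Ac"]], sulfate = sulfate, reduced = reduced,
                    glycanClass = glycanClass)
}

#' Serialize a composition to its canonical string
#'
#' Canonical form lists total class counts in fixed order
#' (Hex, HexNAc, dHex, Neu5Ac, S), omitting zero counts; the core is always
#' folded in. `parseComposition(formatComposition(x))` reproduces `x`.
#'
#' @param comp A [GlycanComposition-class].
#' @return Character scalar, e.g. `"(Hex)5(HexNAc)4(Neu5Ac)2"`.
#' @export
formatComposition <- function(comp) {
  stopifnot(is(comp, "GlycanComposition"))
  cnt <- comp@counts
  out <- paste0(
    paste0("(", names(cnt)[cnt > 0L], ")", cnt[cnt > 0L], collapse = ""),
    if (comp@sulfate > 0L) paste0("(S)", comp@sulfate) else ""
  )
  if (!nzchar(out)) "(empty)0" else out
}
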