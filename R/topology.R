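## Condensed IUPAC-like linear notation, e.g.
##   Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-6)[Neu5Ac(a2-3)Gal(b1-4)
##   GlcNAc(b1-2)Man(a1-3)]Man(b1-4)GlcNAc(b1-4)GlcNAc-ol
## The rightmost residue is the reducing end (root); each residue links to
## the next residue on its right; bracketed chains branch onto the residue
## following the bracket. A bisecting GlcNAc is a (b1-4) branch on the
## beta-mannose.

.tokenizeStructure <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  toks <- list()
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    ch <- substring(s, pos, pos)
    if (ch == "[" || ch == "]") {
      toks[[length(toks) + 1L]] <- ch
      pos <- pos + 1L
      next
    }
    rest <- substring(s, pos)
    resAlt <- "(Neu5Ac|GlcNAc|GalNAc|Man|Gal|Glc|Fuc)"
    m <- regexpr(paste0("^", resAlt, "(-ol)?(\\(([ab?])([12])-([1-9?])\\))?"),
                 rest, perl = TRUE)
    if (m == -1L)
      stop("cannot parse structure notation at position ", pos, ": '",
           substring(s, pos, min(n, pos + 15L)), "'")
    frag <- substring(rest, 1L, attr(m, "match.length"))
    res <- sub(paste0("^", resAlt, ".*$"), "\\1", frag, perl = TRUE)
    ol <- grepl("-ol", frag, fixed = TRUE)
    link <- NULL
    lm <- regmatches(frag, regexpr("\\(([ab?])([12])-([1-9?])\\)", frag))
    if (length(lm) == 1L) {
      link <- list(anomeric = sub("^\\(([ab?]).*$", "\\1", lm),
                   from = sub("^\\([ab?]([12]).*$", "\\1", lm),
                   to = sub("^\\([ab?][12]-([1-9?])\\)$", "\\1", lm))
    }
    toks[[length(toks) + 1L]] <- list(residue = res, alditol = ol,
                                      linkage = link)
    pos <- pos + attr(m, "match.length")
  }
  toks
}

## parse token stream of one chain; returns its terminal (rightmost) node
.parseChain <- function(toks, i, stopAt = 0L) {
  pending <- list()
  node <- NULL
  while (i <= length(toks)) {
    tk <- toks[[i]]
    if (identical(tk, "]")) {
      if (stopAt == 0L) stop("unbalanced ']' in structure notation")
      break
    }
    if (identical(tk, "[")) {
      sub <- .parseChain(toks, i + 1L, stopAt = 1L)
      pending[[length(pending) + 1L]] <- sub$node
      i <- sub$i + 1L  # consume ']'
      next
    }
    node <- list(residue = tk$residue, linkage = tk$linkage,
                 alditol = tk$alditol, children = pending)
    pending <- list(node)
    i <- i + 1L
  }
  if (is.null(node)) stop("empty chain in structure notation")
  list(node = node, i = i)
}

#' Parse condensed IUPAC-like glycan notation into a topology
#'
#' @param notation Linear structure string; see
#'   [GlycanStructure-class]. The reducing-end residue is rightmost, with an
#'   optional `-ol` alditol suffix; unknown linkages may be written
#'   `(?1-?)`.
#' @param glycanClass `"N"` or `"O"`; when `NULL`, inferred from the
#'   reducing-end residue (GalNAc root implies `"O"`).
#' @return A [GlycanStructure-class].
#' @examples
#' core <- parseGlycanStructure(
#'   "Man(a1-6)[Man(a1-3)]Man(b1-4)GlcNAc(b1-4)GlcNAc-ol")
#' topologyToComposition(core)   # Hex3 HexNAc2
#' @export
parseGlycanStructure <- function(notation, glycanClass = NULL) {
  toks <- .tokenizeStructure(notation)
  parsed <- .parseChain(toks, 1L)
  if (parsed$i <= length(toks))
    stop("trailing tokens in structure notation")
  root <- parsed$node
  if (!is.null(root$linkage))
    stop("the reducing-end residue must not carry a linkage")
  if (is.null(glycanClass))
    glycanClass <- if (root$residue == "GalNAc") "O" else "N"
  new("GlycanStructure", root = root,
      notation = gsub("[[:space:]]", "", notation),
      reduced = isTRUE(root$alditol), glycanClass = glycanClass)
}

## flat vector of residue identities in a subtree
treeResidues <- function(node) {
  out <- node$residue
  for (ch in node$children) out <- c(out, treeResidues(ch))
  out
}

## apply FUN to every node, collecting results in a list
.treeWalk <- function(node, fun, parent = NULL) {
  out <- list(fun(node, parent))
  for (ch in node$children)
    out <- c(out, .treeWalk(ch, fun, node))
  out
}

#' Project a topology onto its monosaccharide composition
#'
#' Maps each residue identity to its mass class (Man/Gal/Glc to Hex,
#' GlcNAc/GalNAc to HexNAc, Fuc to dHex) and counts; the reduced flag is
#' preserved so composition mass equals topology mass.
#'
#' @param topo A [GlycanStructure-class].
#' @return A [GlycanComposition-class] (validated as `fragment = TRUE` so
#'   partial antenna subtrees project too).
#' @export
topologyToComposition <- function(topo) {
  stopifnot(is(topo, "GlycanStructure"))
  cls <- RESIDUE_CLASS[treeResidues(topo@root)]
  cnt <- table(factor(cls, levels = names(RESIDUE_MASS)))
  glycanComposition(cnt[["Hex"]], cnt[["HexNAc"]], cnt[["dHex"]],
                    cnt[["Neu5Ac"]], reduced = topo@reduced,
                    glycanClass = topo@glycanClass, fragment = TRUE)
}

## mass of a subtree as residue sum (no water)
.subtreeResidueMass <- function(node)
  sum(RESIDUE_MASS[RESIDUE_CLASS[treeResidues(node)]])

## ---------------------------------------------------------------------------
## N-glycan anatomy: core, arms, bisecting GlcNAc, antennae
## ---------------------------------------------------------------------------

## The beta-mannose is the Man whose linkage to its parent is (b1-4); its
## a1-6 / a1-3 Man children carry the arms; a GlcNAc child on C4 bisects.
.findBetaMan <- function(topo) {
  hits <- Filter(Negate(is.null), .treeWalk(topo@root, function(nd, parent) {
    if (nd$residue == "Man" && !is.null(nd$linkage) &&
        nd$linkage$anomeric == "b")
      nd
    else NULL
  }))
  if (length(hits) == 0L) NULL else hits[[1L]]
}

#' Does a topology carry a bisecting GlcNAc?
#'
#' Bisecting GlcNAc is a GlcNAc attached (beta1-4) to the innermost (beta)
#' mannose of the N-glycan core; it gives rise to the diagnostic D-221 ion
#' in negative mode and is excluded from antenna counting.
#'
#' @param topo A [GlycanStructure-class].
#' @return Logical scalar.
#' @export
hasBisectingGlcNAc <- function(topo) {
  bman <- .findBetaMan(topo)
  if (is.null(bman)) return(FALSE)
  any(vapply(bman$children, function(ch)
    ch$residue == "GlcNAc" && !is.null(ch$linkage) &&
      ch$linkage$to == "4", logical(1)))
}

## children of the beta-Man that are core arm mannoses, keyed "3"/"6"
.coreArms <- function(topo) {
  bman <- .findBetaMan(topo)
  if (is.null(bman)) return(list())
  arms <- list()
  for (ch in bman$children)
    if (ch$residue == "Man" && !is.null(ch$linkage) &&
        ch$linkage$to %in% c("3", "6"))
      arms[[ch$linkage$to]] <- ch
  arms
}

## GlcNAc nodes rooted on an arm Man (any depth) that open an antenna;
## includes branch GlcNAcs for tri/tetra-antennary structures
.armGlcNAcs <- function(arm) {
  Filter(Negate(is.null), .treeWalk(arm, function(nd, parent) {
    if (nd$residue == "GlcNAc" && !is.null(parent) &&
        parent$residue == "Man")
      nd
    else NULL
  }))
}

#' Count complete antennae on an N-glycan topology
#'
#' An antenna is counted only when the complete LacNAc (Gal-GlcNAc) or
#' LacdiNAc (GalNAc-GlcNAc) disaccharide is present on a core arm mannose:
#' a bare GlcNAc stub does not count, the bisecting GlcNAc never counts,
#' and capping (sialylation) or fucosylation of an antenna does not change
#' the count.
#'
#' @param topo A [GlycanStructure-class] for an N-glycan.
#' @return Integer antenna count.
#' @export
countAntennae <- function(topo) {
  stopifnot(is(topo, "GlycanStructure"))
  arms <- .coreArms(topo)
  n <- 0L
  for (arm in arms) {
    for (g in .armGlcNAcs(arm)) {
      capped <- any(vapply(g$children, function(ch)
        ch$residue %in% c("Gal", "GalNAc"), logical(1)))
      if (capped) n <- n + 1L
    }
  }
  n
}

## antenna subtrees: each arm GlcNAc with a Gal/GalNAc cap, as full subtree
.antennaSubtrees <- function(topo) {
  out <- list()
  for (arm in .coreArms(topo))
    for (g in .armGlcNAcs(arm))
      if (any(vapply(g$children, function(ch)
        ch$residue %in% c("Gal", "GalNAc"), logical(1))))
        out[[length(out) + 1L]] <- g
  out
}

## does a subtree contain a LacdiNAc unit (GalNAc on GlcNAc)?
.subtreeHasLacdiNAc <- function(node) {
  hits <- .treeWalk(node, function(nd, parent) {
    !is.null(parent) && parent$residue == "GlcNAc" && nd$residue == "GalNAc"
  })
  any(unlist(hits))
}

#' Does a topology carry a LacdiNAc (GalNAcb1-4GlcNAc) antenna?
#'
#' @param topo A [GlycanStructure-class].
#' @return Logical scalar.
#' @export
hasLacdiNAc <- function(topo) .subtreeHasLacdiNAc(topo@root)

## terminal sialic acid linkages present, as character vector of "3"/"6"/"?"
.sialylLinkages <- function(topo) {
  hits <- Filter(Negate(is.null), .treeWalk(topo@root, function(nd, parent) {
    if (nd$residue == "Neu5Ac" && !is.null(nd$linkage)) nd$linkage$to
    else NULL
  }))
  unlist(hits)
}
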