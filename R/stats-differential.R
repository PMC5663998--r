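#' Differential relative abundance between groups
#'
#' Compares each glycan's relative abundance across the grouping factor:
#' two groups use the Wilcoxon rank-sum test (exact when both groups have
#' n <= 25 and the data are untied, normal approximation with continuity
#' correction otherwise), three or more use Kruskal-Wallis. P-values are
#' adjusted across all glycans of each class by the Benjamini-Hochberg
#' false discovery rate. A `test = "t"` option (Welch two-sample /
#' one-way ANOVA) is provided for comparison.
#'
#' @param x A [GlycanProfileSet-class].
#' @param grouping `"diagnosis"` or `"site"` (a colData column).
#' @param test `"rank"` (default) or `"t"`.
#' @return `data.frame` with one row per glycan: `glycan`, `glycanClass`,
#'   per-group `mean_*` and `sd_*`, `p`, `pAdj` (BH within glycan class),
#'   `direction` (group with the larger mean; `NA` for > 2 groups),
#'   `constant` flag (features with zero variance get p = 1).
#' @export
differentialTest <- function(x, grouping = c("diagnosis", "site"),
                             test = c("rank", "t")) {
  stopifnot(is(x, "GlycanProfileSet"))
  grouping <- match.arg(grouping)
  test <- match.arg(test)
  g <- factor(colData(x)[[grouping]])
  g <- droplevels(g[!is.na(g)])
  keep <- !is.na(colData(x)[[grouping]])
  a <- relAbundance(x)[, keep, drop = FALSE]
  g <- factor(colData(x)[[grouping]][keep])
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) < 3L)) stop("need at least 3 samples per group")
  lev <- levels(g)
  res <- lapply(rownames(a), function(id) {
    y <- a[id, ]
    ms <- tapply(y, g, mean)
    ss <- tapply(y, g, stats::sd)
    constant <- stats::sd(y) == 0
    p <- if (constant) 1 else if (nlevels(g) == 2L) {
      y1 <- y[g == lev[1]]; y2 <- y[g == lev[2]]
      if (test == "t")
        stats::t.test(y1, y2)$p.value
      else {
        exact <- length(y1) <= 25L && length(y2) <= 25L &&
          !any(duplicated(y))
        suppressWarnings(stats::wilcox.test(y1, y2, exact = exact,
                                            correct = TRUE)$p.value)
      }
    } else {
      if (test == "t")
        stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
      else
        stats::kruskal.test(y, g)$p.value
    }
    row <- data.frame(glycan = id, p = p, constant = constant,
                      direction = if (nlevels(g) == 2L)
                        lev[which.max(ms)] else NA_character_)
    for (l in lev) {
      row[[paste0("mean_", l)]] <- ms[[l]]
      row[[paste0("sd_", l)]] <- ss[[l]]
    }
    row
  })
  out <- do.call(rbind, res)
  out$glycanClass <- rowData(x)$glycanClass
  out$pAdj <- NA_real_
  for (cl in unique(out$glycanClass)) {
    ix <- out$glycanClass == cl
    out$pAdj[ix] <- stats::p.adjust(out$p[ix], method = "BH")
  }
  out[order(out$p), c("glycan", "glycanClass",
                      grep("^mean_|^sd_", names(out), value = TRUE),
                      "p", "pAdj", "direction", "constant")]
}
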