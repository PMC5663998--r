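#' Read a profile matrix with sample metadata from CSV
#'
#' Expects samples in rows with metadata columns `sample`, `diagnosis`,
#' `site`, and one numeric column per glycan (percent relative abundance),
#' i.e. the transpose-friendly layout written by [writeProfileMatrix()].
#' Rows whose class totals deviate from 100 are renormalized with a
#' warning when `renormalize = TRUE`, otherwise rejected.
#'
#' @param path CSV path.
#' @param glycanClasses Optional named character vector mapping glycan
#'   column names to `"N"`/`"O"`; all `"N"` when omitted.
#' @param renormalize Auto-renormalize rows not summing to 100.
#' @return A [GlycanProfileSet-class].
#' @export
readProfileMatrix <- function(path, glycanClasses = NULL,
                              renormalize = TRUE) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("sample", "diagnosis", "site")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile CSV lacks metadata column(s): ",
         paste(miss, collapse = ", "))
  gcols <- setdiff(names(df), need)
  if (length(gcols) == 0L) stop("no glycan columns found")
  bad <- which(!vapply(df[gcols], is.numeric, logical(1)))
  if (length(bad))
    stop("non-numeric abundance column(s): ",
         paste(gcols[bad], collapse = ", "))
  m <- t(as.matrix(df[gcols]))
  colnames(m) <- df$sample
  cls <- if (is.null(glycanClasses)) stats::setNames(
    rep("N", length(gcols)), gcols) else glycanClasses[gcols]
  for (cl in unique(cls)) {
    ix <- cls == cl
    s <- colSums(m[ix, , drop = FALSE])
    off <- abs(s - 100) > 1e-6
    if (any(off)) {
      if (!renormalize)
        stop("sample(s) not normalized to 100: ",
             paste(df$sample[off], collapse = ", "))
      warning("renormalizing ", sum(off), " sample(s) whose ", cl,
              "-glycan total was not 100")
      m[ix, off] <- sweep(m[ix, off, drop = FALSE], 2L, s[off] / 100, "/")
    }
  }
  glycanProfileSet(m, diagnosis = df$diagnosis, site = df$site,
                   rowData = DataFrame(glycanClass = unname(cls),
                                       row.names = gcols))
}

#' Write a profile matrix with metadata to CSV
#'
#' @param x A [GlycanProfileSet-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeProfileMatrix <- function(x, path) {
  stopifnot(is(x, "GlycanProfileSet"))
  df <- data.frame(sample = colnames(x),
                   diagnosis = diagnosis(x),
                   site = samplingSite(x),
                   t(relAbundance(x)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pre-integrated EIC table
#'
#' CSV with columns `glycan_id`, `rt_min`, `area` (pre-integrated peaks)
#' or `glycan_id`, `rt_min`, `intensity` (raw traces to be integrated with
#' [integratePeaks()]).
#'
#' @param path CSV path.
#' @return `data.frame` split-ready by `glycan_id`, with line numbers of
#'   malformed rows reported on error.
#' @export
readEicTable <- function(path) {
  df <- utils::read.csv(path)
  if (!"glycan_id" %in% names(df) || !"rt_min" %in% names(df) ||
      !any(c("area", "intensity") %in% names(df)))
    stop("EIC CSV needs columns glycan_id, rt_min and area or intensity")
  valcol <- intersect(c("area", "intensity"), names(df))[1]
  bad <- which(!is.finite(df$rt_min) | !is.finite(df[[valcol]]))
  if (length(bad))
    stop("malformed EIC row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  df
}
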