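#' Integrate peaks in an extracted ion chromatogram
#'
#' The trace is smoothed with a centered moving average, split at local
#' minima falling below a fraction of the neighbouring apex, and each
#' segment is integrated by the trapezoid rule. Peaks below `minArea` are
#' dropped. Relative areas are what the profiling layer consumes, so the
#' integration is invariant to uniform intensity scaling.
#'
#' @param rt Retention times (minutes), increasing.
#' @param intensity Signal at each `rt` (>= 0).
#' @param smoothWindow Moving-average window in points (odd; default 5).
#' @param minArea Minimum area for a peak to be reported (default 0).
#' @param valleyFrac Local minima below `valleyFrac * apex` of both
#'   adjacent segments delimit peaks (default 0.1).
#' @return `data.frame` with columns `rt` (apex) and `area`, ordered by
#'   retention time; zero rows for an all-zero trace.
#' @examples
#' rt <- seq(30, 40, by = 0.05)
#' y <- dnorm(rt, 34, 0.3) * 3 + dnorm(rt, 37, 0.3)
#' integratePeaks(rt, y)   # two peaks, areas ~3 and ~1
#' @export
integratePeaks <- function(rt, intensity, smoothWindow = 5L, minArea = 0,
                           valleyFrac = 0.1) {
  stopifnot(length(rt) == length(intensity))
  if (length(rt) < 3L) stop("need at least 3 points in an EIC trace")
  if (is.unsorted(rt)) {
    o <- order(rt)
    rt <- rt[o]; intensity <- intensity[o]
  }
  if (all(intensity <= 0)) return(data.frame(rt = numeric(), area = numeric()))
  w <- max(1L, as.integer(smoothWindow))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- if (w > 1L)
    as.numeric(stats::filter(intensity, rep(1 / w, w), sides = 2)) else
      intensity
  sm[is.na(sm)] <- intensity[is.na(sm)]

  n <- length(sm)
  ## candidate delimiters: interior local minima of the smoothed trace
  isMin <- c(FALSE, sm[2:(n - 1)] <= sm[1:(n - 2)] &
               sm[2:(n - 1)] <= sm[3:n], FALSE)
  cuts <- c(1L, which(isMin), n)
  cuts <- sort(unique(cuts))
  ## merge segments whose shared valley is not deep enough
  repeat {
    if (length(cuts) <= 2L) break
    apex <- vapply(seq_len(length(cuts) - 1L), function(k)
      max(sm[cuts[k]:cuts[k + 1L]]), numeric(1))
    depth <- sm[cuts[2:(length(cuts) - 1L)]]
    shallow <- which(depth > valleyFrac *
                       pmin(apex[-length(apex)], apex[-1]))
    if (length(shallow) == 0L) break
    cuts <- cuts[-(shallow[1] + 1L)]
  }
  segs <- lapply(seq_len(length(cuts) - 1L), function(k)
    cuts[k]:cuts[k + 1L])
  trapz <- function(x, y)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  out <- do.call(rbind, lapply(segs, function(ix) {
    a <- trapz(rt[ix], intensity[ix])
    data.frame(rt = rt[ix][which.max(intensity[ix])], area = a)
  }))
  out <- out[out$area > minArea & out$area > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign sialyl-linkage isomer labels by PGC elution order
#'
#' On porous graphitized carbon, isomers differing only in sialic acid
#' linkage on the same backbone elute in a reproducible order with the
#' alpha2,6-linked forms first: for a disialylated backbone the order is
#' a2,6/a2,6 then a2,6/a2,3 then a2,3/a2,3. Labels from `expected` are
#' applied to peaks in elution order. With fewer peaks than labels the
#' trailing labels are reported absent (and a single unresolved peak is
#' flagged low-confidence); surplus peaks are labelled `"unassigned"`.
#'
#' @param peaks `data.frame` with columns `rt` and `area` (as from
#'   [integratePeaks()]); input order is irrelevant.
#' @param expected Ordered character vector of isomer labels, earliest
#'   eluting first, e.g. `c("a26a26", "a26a23", "a23a23")`.
#' @return `data.frame` with columns `label`, `rt`, `area`, `fraction`
#'   (area fraction over assigned peaks), `lowConfidence`. Absent expected
#'   labels appear with `NA` rt/area and fraction 0.
#' @export
assignSialylIsomers <- function(peaks, expected) {
  if (length(expected) == 0L) stop("expected isomer set must be non-empty")
  peaks <- peaks[order(peaks$rt), , drop = FALSE]
  np <- nrow(peaks)
  ne <- length(expected)
  nAssigned <- min(np, ne)
  lab <- c(expected[seq_len(nAssigned)],
           if (np > ne) rep("unassigned", np - ne),
           if (ne > np) expected[(np + 1L):ne])
  rt <- c(peaks$rt, rep(NA_real_, max(0L, ne - np)))
  area <- c(peaks$area, rep(NA_real_, max(0L, ne - np)))
  assignedArea <- sum(peaks$area[seq_len(nAssigned)])
  frac <- ifelse(is.na(area) | lab == "unassigned", 0,
                 if (assignedArea > 0) area / assignedArea else 0)
  frac[is.na(area)] <- 0
  data.frame(label = lab, rt = rt, area = area, fraction = frac,
             lowConfidence = np == 1L && ne > 1L)
}

#' Abundance-weighted percentage of alpha2,6 sialylation
#'
#' Over a subset of glycans with resolved sialyl-linkage isomers, computes
#' the area fraction carried by alpha2,6-containing isomer labels, weighted
#' by each glycan's profile abundance, as a percentage.
#'
#' @param assignments Named list of isomer assignment tables (as from
#'   [assignSialylIsomers()]), one per glycan.
#' @param weights Optional numeric vector of profile abundances, named like
#'   `assignments`; equal weights when `NULL`.
#' @param isAlpha26 Predicate on labels; the default treats any label
#'   containing `"a26"` (e.g. `"a26a23"`) as alpha2,6-containing.
#' @return Percentage in `[0, 100]`, or `NA` when the total assigned area
#'   is zero (reported as missing).
#' @export
percentAlpha26 <- function(assignments, weights = NULL,
                           isAlpha26 = function(l) grepl("a26", l)) {
  if (length(assignments) == 0L) stop("glycan subset must be non-empty")
  if (is.null(weights)) weights <- rep(1, length(assignments))
  if (!is.null(names(assignments)) && !is.null(names(weights)))
    weights <- weights[names(assignments)]
  num <- 0
  den <- 0
  for (k in seq_along(assignments)) {
    a <- assignments[[k]]
    keep <- !is.na(a$area) & a$label != "unassigned"
    tot <- sum(a$area[keep])
    if (tot <= 0) next
    f26 <- sum(a$area[keep & isAlpha26(a$label)]) / tot
    num <- num + weights[k] * f26
    den <- den + weights[k]
  }
  if (den <= 0) return(NA_real_)
  100 * num / den
}
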