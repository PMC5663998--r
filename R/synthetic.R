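## log-normal parameters from a target mean and SD
.lnormPar <- function(m, s) {
  cv2 <- (s / m)^2
  sdlog <- sqrt(log1p(cv2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic tissue cohort of glycan profiles
#'
#' Emulates the measured structure of a tissue membrane glycomics cohort:
#' for every sample, each glycan's raw abundance is drawn from a
#' group-specific log-normal whose unconditional mean and SD match the
#' design (a Bernoulli detection mask reproduces presence/absence
#' patterns; the conditional mean is inflated by 1/detection so the
#' unconditional mean is preserved), then profiles are renormalized to
#' 100 % per glycan class. Glycans are drawn independently — a documented
#' simplification of real compositional covariance.
#'
#' @param design A design from [cohortDesignDiagnosis()] or
#'   [cohortDesignSite()].
#' @param seed Integer seed; fully determines the cohort.
#' @return A [GlycanProfileSet-class] with the panel annotation in
#'   `rowData` and the generating group in `colData$group`.
#' @examples
#' gp <- generateCohort(cohortDesignDiagnosis(), seed = 1)
#' colSums(relAbundance(gp))   # all 100 per class, here 200 total
#' @export
generateCohort <- function(design, seed = 1L) {
  stopifnot(inherits(design, "glycoCohortDesign"))
  set.seed(seed)
  p <- design$panel
  ng <- nrow(p)
  cols <- list()
  meta <- list()
  for (gname in names(design$groups)) {
    grp <- design$groups[[gname]]
    stopifnot(all(grp$mean >= 0), length(grp$mean) == ng)
    for (i in seq_len(grp$n)) {
      for (attempt in seq_len(100L)) {
        v <- numeric(ng)
        for (j in seq_len(ng)) {
          if (grp$mean[j] <= 0) next
          if (stats::rbinom(1L, 1L, grp$detect[j]) == 0L) next
          lp <- .lnormPar(grp$mean[j] / grp$detect[j], grp$sd[j])
          v[j] <- stats::rlnorm(1L, lp$meanlog, lp$sdlog)
        }
        ok <- all(vapply(unique(p$glycanClass), function(cl)
          sum(v[p$glycanClass == cl]) > 0, logical(1)))
        if (ok) break
        if (attempt == 100L)
          stop("all glycans undetected after 100 redraws")
      }
      cols[[length(cols) + 1L]] <- v
      meta[[length(meta) + 1L]] <-
        data.frame(group = gname, diagnosis = grp$diagnosis,
                   site = grp$site)
    }
  }
  areas <- do.call(cbind, cols)
  md <- do.call(rbind, meta)
  colnames(areas) <- sprintf("S%02d", seq_len(ncol(areas)))
  rownames(areas) <- p$id
  gp <- buildProfile(areas, diagnosis = md$diagnosis, site = md$site,
                     rowData = DataFrame(p[, c("glycanMass", "glycanClass",
                                               "composition", "type",
                                               "nSialic", "nAntennae",
                                               "bisecting", "lacdinac",
                                               "alpha26")],
                                         row.names = p$id))
  colData(gp)$group <- md$group
  gp
}

#' Generate a synthetic EIC trace for isomers of one glycan mass
#'
#' A sum of Gaussian elution peaks with prescribed areas and retention
#' centers plus white noise. When isomer labels are supplied, retention
#' centers are ordered so that alpha2,6-containing forms elute first, the
#' retention rule the isomer assignment relies on.
#'
#' @param areas Peak areas (their proportions are the isomer split; need
#'   not sum to 1).
#' @param rtCenters Retention-time apexes (minutes); defaults to an
#'   equispaced series inside the N-glycan elution window (30-70 min).
#' @param rtSd Gaussian peak width (minutes, default 0.25).
#' @param noiseSd White-noise SD on the intensity scale (default 0).
#' @param rtRange Sampled retention window.
#' @param dt Sampling interval (minutes).
#' @param seed Integer seed for the noise.
#' @return List: `rt`, `intensity`, and `truth` (`data.frame` of rt/area
#'   ground truth).
#' @export
generateEic <- function(areas, rtCenters = NULL, rtSd = 0.25, noiseSd = 0,
                        rtRange = c(30, 70), dt = 0.02, seed = 1L) {
  set.seed(seed)
  k <- length(areas)
  if (is.null(rtCenters))
    rtCenters <- seq(rtRange[1] + 5, rtRange[2] - 5, length.out = max(k, 2L))[seq_len(k)]
  stopifnot(length(rtCenters) == k)
  rt <- seq(rtRange[1], rtRange[2], by = dt)
  y <- numeric(length(rt))
  for (i in seq_len(k))
    y <- y + areas[i] * stats::dnorm(rt, rtCenters[i], rtSd)
  if (noiseSd > 0) y <- pmax(0, y + stats::rnorm(length(rt), 0, noiseSd))
  list(rt = rt, intensity = y,
       truth = data.frame(rt = rtCenters, area = areas))
}

#' Generate a synthetic MS2 spectrum for a topology
#'
#' Theoretical fragments from [generateFragments()] receive m/z jitter
#' N(0, sigma^2) and random intensities; uniform decoy peaks are added at
#' the stated rate over the scan range.
#'
#' @param topo A [GlycanStructure-class].
#' @param jitterSd m/z jitter SD in Da (default 0).
#' @param decoyRate Number of decoy peaks as a fraction of true peaks
#'   (default 0).
#' @param charge Precursor charge for the reported precursor m/z.
#' @param seed Integer seed.
#' @return A [GlycanSpectrum-class].
#' @export
generateSpectrum <- function(topo, jitterSd = 0, decoyRate = 0,
                             charge = 2L, seed = 1L) {
  stopifnot(is(topo, "GlycanStructure"))
  set.seed(seed)
  ions <- generateFragments(topo)
  mz <- ions$mz + if (jitterSd > 0)
    stats::rnorm(nrow(ions), 0, jitterSd) else 0
  int <- stats::runif(nrow(ions), 20, 100)
  nDecoy <- round(decoyRate * nrow(ions))
  if (nDecoy > 0) {
    mz <- c(mz, stats::runif(nDecoy, 150, max(ions$mz)))
    int <- c(int, stats::runif(nDecoy, 20, 100))
  }
  glycanSpectrum(compositionMz(topologyToComposition(topo), charge),
                 charge, mz = mz, intensity = int)
}
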