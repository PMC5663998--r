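#' Reference-gene normalized qPCR expression
#'
#' Normalizes quantification-cycle (Cq) values of target genes against the
#' mean Cq of reference genes per sample (the logarithmic mean of their
#' expression levels), converts to relative expression by 2^-dCq, and
#' rescales each target so the lowest-expressing sample equals 1.
#'
#' @param cq Numeric matrix of Cq values, genes x samples.
#' @param referenceGenes Row names of the (typically three) reference
#'   genes; all must be present with finite Cq in every sample.
#' @return Matrix of relative expression (targets x samples); each row's
#'   minimum is 1.
#' @examples
#' cq <- rbind(GENE = c(24, 23), REF1 = c(20, 20), REF2 = c(21, 21),
#'             REF3 = c(19, 19))
#' normalizeGeneExpression(cq, c("REF1", "REF2", "REF3"))  # GENE: 1, 2
#' @export
normalizeGeneExpression <- function(cq, referenceGenes) {
  cq <- as.matrix(cq)
  miss <- setdiff(referenceGenes, rownames(cq))
  if (length(miss))
    stop("missing reference gene(s): ", paste(miss, collapse = ", "))
  refCq <- colMeans(cq[referenceGenes, , drop = FALSE])
  if (any(!is.finite(refCq)))
    stop("non-finite reference Cq in sample(s): ",
         paste(colnames(cq)[!is.finite(refCq)], collapse = ", "))
  targets <- setdiff(rownames(cq), referenceGenes)
  dcq <- sweep(cq[targets, , drop = FALSE], 2L, refCq)
  expr <- 2^(-dcq)
  sweep(expr, 1L, apply(expr, 1L, min), "/")
}
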