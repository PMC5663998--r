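#' Feature selection by L1-penalized logistic regression
#'
#' Fits a lasso-penalized binomial (two groups) or multinomial (three
#' groups) logistic regression over a log-spaced penalty path with
#' standardized predictors, choosing the penalty by k-fold cross-validated
#' deviance; selected glycans are those with a nonzero coefficient at the
#' chosen penalty. Folds are stratified by group so no fold degenerates to
#' a single class. Fully reproducible under `seed`.
#'
#' @param x A [GlycanProfileSet-class].
#' @param grouping `"diagnosis"` or `"site"`.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed governing fold assignment.
#' @param lambda `"min"` (penalty minimizing CV deviance, default) or
#'   `"1se"`.
#' @param lambdaValue Optional fixed penalty overriding the
#'   cross-validated choice (an arbitrarily large value shrinks every
#'   coefficient to zero).
#' @return `data.frame` with `glycan`, `selected`, `coefficient` (largest
#'   absolute coefficient across classes for multinomial fits).
#' @export
selectFeaturesGlm <- function(x, grouping = c("diagnosis", "site"),
                              folds = 5L, seed = 1L,
                              lambda = c("min", "1se"),
                              lambdaValue = NULL) {
  stopifnot(is(x, "GlycanProfileSet"))
  grouping <- match.arg(grouping)
  lambda <- match.arg(lambda)
  g <- factor(colData(x)[[grouping]])
  if (nlevels(g) < 2L) stop("need at least two groups")
  X <- t(relAbundance(x))
  fam <- if (nlevels(g) == 2L) "binomial" else "multinomial"
  set.seed(seed)
  ## stratified fold ids: cycle folds within each group
  foldid <- integer(length(g))
  for (l in levels(g)) {
    ix <- which(g == l)
    foldid[ix] <- sample(rep_len(seq_len(folds), length(ix)))
  }
  if (any(vapply(split(g, foldid), function(v)
    length(unique(v)) < 2L, logical(1))))
    stop("degenerate single-class cross-validation folds")
  cv <- glmnet::cv.glmnet(X, g, family = fam, alpha = 1,
                          nfolds = folds, foldid = foldid,
                          standardize = TRUE, type.measure = "deviance")
  s <- if (!is.null(lambdaValue)) lambdaValue
  else if (lambda == "min") cv$lambda.min else cv$lambda.1se
  cf <- stats::coef(cv, s = s)
  coefOf <- function(m) {
    v <- as.matrix(m)[-1, 1]   # drop intercept
    v
  }
  co <- if (fam == "binomial") coefOf(cf)
  else {
    mats <- vapply(cf, coefOf, numeric(ncol(X)))
    apply(mats, 1L, function(r) r[which.max(abs(r))])
  }
  data.frame(glycan = colnames(X), selected = co != 0, coefficient = co,
             row.names = NULL)
}

#' Feature selection by random forest permutation importance
#'
#' Grows a forest of classification trees on bootstrap samples with
#' \eqn{\sqrt{p}} candidate features per split and ranks glycans by
#' out-of-bag permutation importance (mean decrease in accuracy). The top-k
#' glycans are reported selected, mirroring the panel size used for
#' glycan-marker reporting. Bit-reproducible under `seed`.
#'
#' @param x A [GlycanProfileSet-class].
#' @param grouping `"diagnosis"` or `"site"`.
#' @param nTrees Number of trees (default 500); fewer than 50 triggers an
#'   instability warning.
#' @param topK Number of glycans reported selected (default 4).
#' @param seed Integer seed.
#' @return `data.frame` with `glycan`, `selected`, `importance`, ordered by
#'   decreasing importance.
#' @export
selectFeaturesRf <- function(x, grouping = c("diagnosis", "site"),
                             nTrees = 500L, topK = 4L, seed = 1L) {
  stopifnot(is(x, "GlycanProfileSet"))
  grouping <- match.arg(grouping)
  if (nTrees < 50L)
    warning("fewer than 50 trees gives unstable permutation importance")
  g <- factor(colData(x)[[grouping]])
  if (nlevels(g) < 2L) stop("need at least two groups")
  X <- t(relAbundance(x))
  colnames(X) <- make.names(colnames(X))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = g, ntree = nTrees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1)[, 1]
  o <- order(-imp)
  data.frame(glycan = rownames(relAbundance(x))[o],
             selected = seq_along(o) <= topK,
             importance = imp[o], row.names = NULL)
}
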