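#' Empirical ROC curve, AUC and Youden operating point
#'
#' Computes the empirical ROC over all score thresholds, the AUC by the
#' trapezoid rule (numerically identical to the Mann-Whitney U statistic
#' divided by n1*n2, counting ties as 1/2), and the operating point
#' maximizing Youden's J = sensitivity + specificity - 1, breaking ties
#' towards higher specificity.
#'
#' @param scores Numeric scores; larger values indicate the positive class.
#' @param labels Logical or two-level factor; `TRUE`/second level =
#'   positive.
#' @return List of class `"glycoRoc"`: `auc`, `sensitivity` and
#'   `specificity` (percent, at the Youden point), `threshold`, and the
#'   full `curve` data.frame (`threshold`, `sensitivity`, `specificity`).
#' @examples
#' rocCurve(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc   # 1
#' @export
rocCurve <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute a ROC curve")
  ## score >= threshold => called positive; thresholds at observed scores
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(scores[labels] >= t) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(scores[!labels] < t) / n0, numeric(1))
  ## AUC as normalized Mann-Whitney U (ties counted half)
  r <- rank(scores)
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  structure(list(
    auc = auc,
    sensitivity = 100 * sens[best],
    specificity = 100 * spec[best],
    threshold = thr[best],
    curve = data.frame(threshold = thr, sensitivity = sens,
                       specificity = spec)
  ), class = "glycoRoc")
}

#' @export
print.glycoRoc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f; Youden point sensitivity %.1f%% / specificity %.1f%% (threshold %.4g)\n",
    x$auc, x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' Combination score for a glycan panel
#'
#' Unpenalized logistic regression of the group on the selected glycans'
#' relative abundances; the fitted linear predictor is the panel score fed
#' to [rocCurve()], as used when reporting a combined AUC for a marker
#' panel.
#'
#' @param x A [GlycanProfileSet-class].
#' @param glycans Row names of the panel glycans.
#' @param grouping `"diagnosis"` or `"site"` (must have two levels).
#' @return List: `scores` (linear predictor per sample), `labels` (logical,
#'   second group level = positive), `roc` (the [rocCurve()] result).
#' @export
panelRoc <- function(x, glycans, grouping = c("diagnosis", "site")) {
  stopifnot(is(x, "GlycanProfileSet"))
  grouping <- match.arg(grouping)
  g <- factor(colData(x)[[grouping]])
  if (nlevels(g) != 2L) stop("panel ROC requires exactly two groups")
  miss <- setdiff(glycans, rownames(x))
  if (length(miss))
    stop("unknown glycan id(s): ", paste(miss, collapse = ", "))
  X <- t(relAbundance(x)[glycans, , drop = FALSE])
  df <- data.frame(y = g == levels(g)[2], X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = "binomial"))
  sc <- stats::predict(fit, type = "link")
  list(scores = sc, labels = df$y, roc = rocCurve(sc, df$y))
}
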