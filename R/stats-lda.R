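#' Linear discriminant analysis with Wilks' lambda
#'
#' Computes the within-group (W) and total (T) scatter matrices of the
#' selected glycan subset, Wilks' lambda = det(W)/det(T), its p-value by
#' Rao's F approximation, and up to two discriminant projections from the
#' eigendecomposition of \eqn{W^{-1} B} (B = between-group scatter),
#' scaled to unit within-group variance. A singular within-group scatter is
#' ridged by `eps` on the diagonal and flagged.
#'
#' @param x A [GlycanProfileSet-class].
#' @param grouping `"diagnosis"` or `"site"`.
#' @param glycans Row names of the feature subset (default: all rows);
#'   requires more samples than features.
#' @param eps Ridge added to a computationally singular W (default 1e-8).
#' @return List of class `"glycoLda"`: `lambda`, `p`, `fStat`, `df`,
#'   `projections` (samples x <= 2 matrix), `groups`, `ridged`.
#' @export
ldaGlycans <- function(x, grouping = c("diagnosis", "site"),
                       glycans = rownames(x), eps = 1e-8) {
  stopifnot(is(x, "GlycanProfileSet"))
  grouping <- match.arg(grouping)
  g <- factor(colData(x)[[grouping]])
  if (nlevels(g) < 2L) stop("need at least two groups")
  X <- t(relAbundance(x)[glycans, , drop = FALSE])
  n <- nrow(X); p <- ncol(X); k <- nlevels(g)
  if (n <= p)
    stop("LDA requires more samples than features (n = ", n, ", p = ", p, ")")
  grand <- colMeans(X)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (l in levels(g)) {
    Xi <- X[g == l, , drop = FALSE]
    mi <- colMeans(Xi)
    Ci <- sweep(Xi, 2L, mi)
    W <- W + crossprod(Ci)
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
  }
  Tm <- W + B
  ridged <- FALSE
  if (rcond(W) < .Machine$double.eps) {
    W <- W + diag(eps, p)
    Tm <- W + B
    ridged <- TRUE
  }
  lambda <- det(W) / det(Tm)
  ## Rao's F approximation for Wilks' lambda
  q <- k - 1
  t1 <- n - 1 - (p + k) / 2
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- t1 * s - p * q / 2 + 1
  lam_s <- lambda^(1 / s)
  fStat <- (1 - lam_s) / lam_s * df2 / df1
  pval <- stats::pf(fStat, df1, df2, lower.tail = FALSE)
  ## discriminant directions: eigenvectors of W^-1 B
  ev <- eigen(solve(W, B))
  nd <- min(2L, k - 1L, p)
  V <- Re(ev$vectors[, seq_len(nd), drop = FALSE])
  ## unit within-group variance scaling
  for (j in seq_len(nd)) {
    wv <- sqrt(drop(t(V[, j]) %*% W %*% V[, j]) / (n - k))
    if (wv > 0) V[, j] <- V[, j] / wv
  }
  proj <- X %*% V
  colnames(proj) <- paste0("LD", seq_len(nd))
  structure(list(lambda = lambda, p = pval, fStat = fStat,
                 df = c(df1 = df1, df2 = df2),
                 projections = proj, groups = g, ridged = ridged),
            class = "glycoLda")
}

#' @export
print.glycoLda <- function(x, ...) {
  cat(sprintf("LDA: Wilks' lambda %.4f, F(%.0f, %.1f) = %.3f, p = %.4g%s\n",
              x$lambda, x$df["df1"], x$df["df2"], x$fStat, x$p,
              if (x$ridged) " (ridged within-scatter)" else ""))
  invisible(x)
}
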