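## small helper: profile set from a features x samples matrix of percents
profileFrom <- function(m, groups, site = NULL) {
  # append a complement row so each sample sums to 100
  comp <- 100 - colSums(m)
  stopifnot(all(comp >= 0))
  mm <- rbind(m, complement = comp)
  glycanProfileSet(mm, diagnosis = groups, site = site)
}

test_that("identical groups yield uniformly non-significant tests", {
  set.seed(1)
  m <- matrix(runif(10 * 12, 1, 5), 10, 12,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  gp <- profileFrom(m, rep(c("OC", "PC"), each = 6))
  # same data in both groups: duplicate columns
  a <- relAbundance(gp)
  a[, 7:12] <- a[, 1:6]
  gp2 <- glycanProfileSet(a, diagnosis = rep(c("OC", "PC"), each = 6))
  d <- differentialTest(gp2)
  expect_true(all(d$p > 0.9))
  expect_true(all(d$pAdj >= d$p - 1e-12))
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.05)
  expect_equal(p.adjust(p, "BH"),
               c(0.005, 0.025, 1 / 30, 0.05, 0.05), tolerance = 1e-9)
  # and the pipeline applies it within glycan class
  set.seed(2)
  m <- matrix(runif(5 * 12, 1, 5), 5, 12,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  gp <- profileFrom(m, rep(c("OC", "PC"), each = 6))
  d <- differentialTest(gp)
  expect_equal(d$pAdj, p.adjust(d$p, "BH"), tolerance = 1e-12)
  expect_true(all(diff(d$pAdj[order(d$p)]) >= -1e-12))
})

test_that("constant features are flagged with p = 1", {
  m <- matrix(3, 2, 12, dimnames = list(c("g1", "g2"), paste0("s", 1:12)))
  m[2, ] <- runif(12, 1, 4)
  gp <- profileFrom(m, rep(c("OC", "PC"), each = 6))
  d <- differentialTest(gp)
  expect_true(d$constant[d$glycan == "g1"])
  expect_equal(d$p[d$glycan == "g1"], 1)
})

test_that("a glycan shifted by two pooled SDs dominates the adjusted p-values", {
  set.seed(42)
  hit <- replicate(200, {
    des <- makeTestDesign(meanA = c(8, rep(4, 9)), meanB = rep(4, 10),
                          sd = rep(2, 10))
    gp <- generateCohort(des, seed = sample.int(1e6, 1))
    d <- differentialTest(gp)
    d$glycan[which.min(d$pAdj)] == "g01"
  })
  expect_gte(mean(hit), 0.95)
})

test_that("lasso selection finds a separating feature and shrinks to zero", {
  set.seed(9)
  found <- replicate(25, {
    m <- matrix(runif(10 * 28, 2, 6), 10, 28,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:28)))
    m[1, ] <- c(runif(14, 1, 2), runif(14, 5, 6))  # perfectly separating
    gp <- profileFrom(m, rep(c("OC", "PC"), each = 14))
    sel <- selectFeaturesGlm(gp, seed = sample.int(1e6, 1))
    sel$selected[sel$glycan == "g1"]
  })
  expect_gte(mean(found), 0.95)
  # infinite penalty: empty selection
  m <- matrix(runif(10 * 28, 2, 6), 10, 28,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:28)))
  gp <- profileFrom(m, rep(c("OC", "PC"), each = 14))
  sel <- selectFeaturesGlm(gp, seed = 1, lambdaValue = 1e6)
  expect_false(any(sel$selected))
  # reproducibility under seed
  expect_identical(selectFeaturesGlm(gp, seed = 7),
                   selectFeaturesGlm(gp, seed = 7))
})

test_that("random-forest importance ranks a planted feature first", {
  set.seed(10)
  top <- replicate(25, {
    des <- makeTestDesign(meanA = c(8, rep(4, 9)), meanB = rep(4, 10),
                          sd = rep(2, 10))
    gp <- generateCohort(des, seed = sample.int(1e6, 1))
    rf <- selectFeaturesRf(gp, seed = sample.int(1e6, 1))
    rf$glycan[1] == "g01"
  })
  expect_gte(mean(top), 0.9)
  # pure noise: importance distribution centered near zero
  m <- matrix(runif(10 * 28, 2, 6), 10, 28,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:28)))
  gp <- profileFrom(m, rep(c("OC", "PC"), each = 14))
  rf <- selectFeaturesRf(gp, seed = 4)
  expect_lt(abs(mean(rf$importance)), 1)
  # bit-reproducible under seed
  expect_identical(selectFeaturesRf(gp, seed = 11),
                   selectFeaturesRf(gp, seed = 11))
  expect_warning(selectFeaturesRf(gp, nTrees = 10L, seed = 1), "unstable")
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  expect_equal(rocCurve(c(1, 2, 3, 4), c(F, F, T, T))$auc, 1)
  set.seed(12)
  for (i in 1:100) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    sc <- c(rnorm(n0), rnorm(n1, sample(c(0, 1), 1)))
    if (i %% 3 == 0) sc <- round(sc)       # force ties
    lab <- c(rep(FALSE, n0), rep(TRUE, n1))
    auc <- rocCurve(sc, lab)$auc
    # brute-force pairwise oracle with half-credit ties
    pairs <- outer(sc[lab], sc[!lab], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(pairs), tolerance = 1e-12)
  }
})

test_that("the Youden operating point reproduces a 13/15, 12/13 confusion", {
  scores <- c(rep(2, 13), rep(0, 2),    # 15 positives, 2 below threshold
              rep(0, 12), 2)            # 13 negatives, 1 above
  labels <- c(rep(TRUE, 15), rep(FALSE, 13))
  r <- rocCurve(scores, labels)
  expect_equal(r$sensitivity, 86.7, tolerance = 0.001)
  expect_equal(r$specificity, 92.3, tolerance = 0.001)
  expect_error(rocCurve(1:5, rep(TRUE, 5)), "both classes")
})

test_that("empirical ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  sc <- rnorm(40)
  lab <- rep(c(FALSE, TRUE), 20)
  sc[lab] <- sc[lab] + 1
  mine <- rocCurve(sc, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("Wilks' lambda matches the determinant-ratio oracle", {
  set.seed(15)
  for (i in 1:20) {
    n <- 24; p <- sample(3:5, 1)
    g <- factor(rep(c("a", "b", "c"), each = 8))
    X <- matrix(rnorm(n * p), n, p)
    X[g == "b", 1] <- X[g == "b", 1] + runif(1, 0, 2)
    m <- t(X); rownames(m) <- paste0("f", 1:p)
    m <- 100 * exp(m) / rep(colSums(exp(m)), each = p)  # valid percentages
    gp <- glycanProfileSet(m, diagnosis = as.character(g),
                           site = as.character(g))
    ## drop one feature: the closed percentages are otherwise collinear
    feats <- paste0("f", seq_len(p - 1))
    res <- ldaGlycans(gp, "site", glycans = feats)
    Y <- t(relAbundance(gp)[feats, , drop = FALSE])
    W <- Reduce(`+`, lapply(levels(g), function(l)
      crossprod(scale(Y[g == l, ], scale = FALSE))))
    Tm <- crossprod(scale(Y, scale = FALSE))
    expect_equal(res$lambda, det(W) / det(Tm), tolerance = 1e-9)
    # cross-check p-value against the MANOVA Wilks test
    fit <- manova(Y ~ g)
    sm <- summary(fit, test = "Wilks")$stats
    expect_equal(res$lambda, sm[1, "Wilks"], tolerance = 1e-6)
    expect_equal(res$p, sm[1, "Pr(>F)"], tolerance = 1e-6)
  }
})

test_that("LDA limits behave: identical means and full separation", {
  set.seed(16)
  m <- matrix(runif(3 * 24, 5, 6), 3, 24,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:24)))
  g <- rep(c("a", "b"), each = 12)
  gp <- profileFrom(m[1:2, ], g)
  r <- ldaGlycans(gp, "diagnosis", glycans = c("f1", "f2"))
  expect_gt(r$lambda, 0.7)
  expect_gt(r$p, 0.05)
  # fully separated one-dimensional groups
  m2 <- rbind(f1 = c(runif(12, 1, 2), runif(12, 50, 51)))
  gp2 <- profileFrom(m2, g)
  r2 <- ldaGlycans(gp2, "diagnosis", glycans = "f1")
  expect_lt(r2$lambda, 0.05)
})

test_that("qPCR normalization follows the reference-gene dCq model", {
  cq <- rbind(GENE = c(24, 23), REF1 = c(20, 20), REF2 = c(21, 21),
              REF3 = c(19, 19))
  colnames(cq) <- c("low", "high")
  e <- normalizeGeneExpression(cq, c("REF1", "REF2", "REF3"))
  expect_equal(unname(e["GENE", ]), c(1, 2))   # one cycle = doubling
  # identical samples are all 1
  same <- rbind(G = c(25, 25, 25), R1 = c(20, 20, 20), R2 = c(21, 21, 21),
                R3 = c(19, 19, 19))
  expect_true(all(normalizeGeneExpression(same, c("R1", "R2", "R3")) == 1))
  expect_error(normalizeGeneExpression(cq, c("REF1", "REFX", "REF3")),
               "REFX")
})

test_that("simulated fold changes are recovered under Cq noise", {
  set.seed(17)
  fold <- c(1, 2, 4, 8)
  est <- replicate(100, {
    cq <- rbind(G = 25 - log2(fold) + rnorm(4, 0, 0.1),
                R1 = 20 + rnorm(4, 0, 0.1),
                R2 = 21 + rnorm(4, 0, 0.1),
                R3 = 19 + rnorm(4, 0, 0.1))
    colnames(cq) <- paste0("s", 1:4)
    normalizeGeneExpression(cq, c("R1", "R2", "R3"))["G", ]
  })
  expect_equal(unname(rowMeans(est)), fold, tolerance = 0.05)
})
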