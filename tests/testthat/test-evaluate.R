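test_that("AUC equals the pair-counting statistic", {
  expect_equal(aucScore(c(1, 1, 0, 0), c(0.8, 0.3, 0.6, 0.1)), 0.75)
  expect_equal(aucScore(c(1, 1, 0), c(0.9, 0.8, 0.1)), 1)
  expect_equal(aucScore(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)  # all tied
  expect_error(aucScore(c(1, 1), c(0.2, 0.3)), "both classes")
  set.seed(41)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    labels <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    expect_equal(aucScore(labels, scores), aucBrute(labels, scores))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(5)
  labels <- sample(0:1, 80, replace = TRUE)
  scores <- runif(80)
  a0 <- aucScore(labels, scores)
  expect_equal(aucScore(labels, exp(3 * scores)), a0)
  expect_equal(aucScore(labels, rank(scores, ties.method = "average")), a0)
})

test_that("ROC curve is a valid step function whose area matches the AUC", {
  set.seed(17)
  labels <- c(1L, 0L, sample(0:1, 48, replace = TRUE))
  scores <- round(runif(50), 2)
  curve <- rocCurve(labels, scores)
  pts <- rocPoints(curve)
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_equal(rocAuc(curve), aucBrute(labels, scores), tolerance = 1e-12)

  sep <- rocCurve(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(any(sep@points$fpr == 0 & sep@points$tpr == 1))
  anti <- rocCurve(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(rocAuc(anti), 0)
})

test_that("operating-point metrics match exhaustive enumeration", {
  labels <- c(rep(0L, 5), rep(1L, 4))
  scores <- c(0.1, 0.2, 0.3, 0.4, 0.9, 0.5, 0.6, 0.7, 0.8)
  curve <- rocCurve(labels, scores)
  s <- sensitivityAtFpr(curve, 0.2)
  expect_equal(s$tpr, 1)
  expect_equal(s$threshold, 0.5)
  expect_equal(sensitivityAtFpr(curve, 0)$tpr, 0)
  expect_equal(sensitivityAtFpr(curve, 1)$tpr, 1)

  labels2 <- c(1L, 1L, 0L, 0L)
  scores2 <- c(0.8, 0.6, 0.1, 0.7)
  curve2 <- rocCurve(labels2, scores2)
  expect_equal(specificityAtTpr(curve2, 0)$specificity, 1)
  sp <- specificityAtTpr(curve2, 0.5)
  expect_equal(sp$specificity, 1)
  expect_equal(sp$threshold, 0.8)
  expect_equal(specificityAtTpr(curve2, 1)$specificity, 0.5)
})

test_that("operating-point metrics are monotone in their constraint", {
  set.seed(23)
  labels <- c(1L, 0L, sample(0:1, 58, replace = TRUE))
  scores <- round(runif(60), 2)
  curve <- rocCurve(labels, scores)
  caps <- seq(0, 1, by = 0.05)
  sens <- vapply(caps, function(cp) sensitivityAtFpr(curve, cp)$tpr,
                 numeric(1))
  spec <- vapply(caps, function(fl) specificityAtTpr(curve, fl)$specificity,
                 numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_true(all(diff(spec) <= 0))
})

test_that("residue pooling follows the positive/negative convention", {
  ds <- TrackDataset(list(makeBindingRecord("D1", 10, 3, "dna_binding"),
                          makeBindingRecord("N1", 8, 0, "non_na_binding"),
                          makeBindingRecord("R1", 9, 2, "rna_binding"),
                          ProteinRecord("U1", "MKWL")))
  pool <- poolResidues(ds, "dna")
  # 3 binding residues; 7 non-binding in D1 plus all 8 of N1; R1/U1 ignored
  expect_equal(sum(pool$labels == 1L), 3)
  expect_equal(sum(pool$labels == 0L), 15)
  expect_error(poolResidues(TrackDataset(), "dna"), "no positive")

  # unknown labels are excluded
  d <- makeBindingRecord("D2", 10, 3)
  lab <- d@labels
  lab$dna_binding[5] <- NA
  d@labels <- lab
  pool2 <- poolResidues(TrackDataset(list(d)), "dna")
  expect_equal(length(pool2$labels), 9)
})

test_that("evalReport computes the metric suite for each source", {
  cfg <- synthConfig(nProteins = 40, lengthRange = c(50, 100), seed = 8)
  ds <- generateDataset(cfg)
  norm <- fitNormalizer(splitRecords(ds, "train"), "dna")
  rep <- evalReport(splitRecords(ds, "test"), "dna", norm = norm)
  expect_equal(rep$method,
               c("disorder_trained", "structure_trained", "min", "max", "avg"))
  metr <- as.matrix(rep[, c("auc", "sens_fpr_0.2", "sens_fpr_0.3",
                            "spec_tpr_0.4", "spec_tpr_0.5")])
  expect_true(all(metr >= 0 & metr <= 1))
  expect_true(all(rep$sens_fpr_0.3 >= rep$sens_fpr_0.2))
})

test_that("normality gate chooses the paired t-test only for normal diffs", {
  set.seed(1)
  gauss <- rnorm(50, mean = 0.05, sd = 0.01)
  g <- nucmeta:::.adGatedTest(gauss)
  expect_identical(g$chosenTest, "t_test")
  expect_lt(g$pValue, 0.05)

  set.seed(1)
  heavy <- c(rnorm(40, 0.02, 0.01), rcauchy(10, 0, 0.5))
  h <- nucmeta:::.adGatedTest(heavy)
  expect_identical(h$chosenTest, "wilcoxon_signed_rank")

  z <- nucmeta:::.adGatedTest(rep(0, 50))
  expect_equal(z$pValue, 1)
  cst <- nucmeta:::.adGatedTest(rep(0.3, 50))  # constant non-zero: signed rank
  expect_identical(cst$chosenTest, "wilcoxon_signed_rank")
  expect_lt(cst$pValue, 0.05)
})

test_that("method comparison is reproducible and degenerate-safe", {
  cfg <- synthConfig(nProteins = 30, lengthRange = c(50, 90), seed = 12)
  ds <- generateDataset(cfg)
  norm <- fitNormalizer(ds, "dna")
  same <- compareMethods(ds, "dna", "avg", "avg", "auc", frac = 0.5,
                         nReps = 10, seed = 4, norm = norm)
  expect_equal(pValue(same), 1)
  expect_false(isSignificant(same))

  s1 <- compareMethods(ds, "dna", "avg", "min", "auc", frac = 0.5,
                       nReps = 10, seed = 4, norm = norm)
  s2 <- compareMethods(ds, "dna", "avg", "min", "auc", frac = 0.5,
                       nReps = 10, seed = 4, norm = norm)
  expect_identical(s1@valuesA, s2@valuesA)
  expect_identical(pValue(s1), pValue(s2))
  expect_identical(chosenTest(s1), chosenTest(s2))
})
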