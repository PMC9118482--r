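test_that("generated records honor class semantics and pass validation", {
  cfg <- synthConfig(seed = 2)
  set.seed(99)
  nn <- generateProtein(cfg, "N1", class = "non_na_binding")
  expect_equal(sum(trackLabels(nn)$dna_binding), 0)
  expect_equal(sum(trackLabels(nn)$rna_binding), 0)
  dna <- generateProtein(cfg, "D1", class = "dna_binding")
  expect_gte(sum(trackLabels(dna)$dna_binding), 1)
  expect_equal(sum(trackLabels(dna)$rna_binding), 0)
  for (rec in list(nn, dna)) expect_length(validateRecord(rec), 0)
})

test_that("noise-free kappa=0 tracks are two-level signals on their role", {
  cfg <- synthConfig(noiseSigma = 0, overlapKappa = 0, seed = 5)
  set.seed(7)
  rec <- generateProtein(cfg, "D1", class = "dna_binding")
  levels <- round(c(cfg$baseProp, cfg$baseProp + cfg$signalMu), 3)
  str_track <- trackPredictions(rec)$dna_structure_trained
  expect_true(all(str_track %in% levels))
  # the high level sits exactly on the structure-detectable binding residues,
  # which with kappa=0 are the binding residues in the structured region
  hi <- str_track == levels[2]
  bind <- trackLabels(rec)$dna_binding == 1L
  dis <- trackLabels(rec)$disorder == 1L
  expect_identical(hi, bind & !dis)
  dis_track <- trackPredictions(rec)$dna_disorder_trained
  expect_identical(dis_track == levels[2], bind & dis)
})

test_that("datasets are reproducible from the seed", {
  cfg <- synthConfig(nProteins = 15, lengthRange = c(40, 80), seed = 42)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(recordIds(d1), recordIds(d2))
  for (i in seq_along(d1)) {
    expect_identical(seqString(d1[[i]]), seqString(d2[[i]]))
    expect_identical(trackLabels(d1[[i]]), trackLabels(d2[[i]]))
    expect_identical(trackPredictions(d1[[i]]), trackPredictions(d2[[i]]))
    expect_identical(recordSplit(d1[[i]]), recordSplit(d2[[i]]))
  }
  d3 <- generateDataset(synthConfig(nProteins = 15,
                                    lengthRange = c(40, 80), seed = 43))
  expect_false(identical(seqString(d1[[1]]), seqString(d3[[1]])))
})

test_that("small datasets with all three classes are rejected", {
  expect_error(generateDataset(synthConfig(nProteins = 6)), "at least 10")
  expect_error(synthConfig(classProbs = c(0.5, 0.4, 0.3)), "sum to 1")
  expect_error(synthConfig(disorderContent = 1.4), "\\[0, 1\\]")
})

test_that("generator recovers its configured parameters at n=300", {
  cfg <- synthConfig(nProteins = 300, seed = 31)
  ds <- generateDataset(cfg)
  recs <- records(ds)

  cls <- vapply(recs, bindingClass, character(1))
  mix <- table(factor(cls, c("dna_binding", "rna_binding",
                             "non_na_binding"))) / length(recs)
  expect_lt(max(abs(as.numeric(mix) - unname(cfg$classProbs))), 0.08)

  dis <- unlist(lapply(recs, function(r) trackLabels(r)$disorder))
  expect_lt(abs(mean(dis) - cfg$disorderContent), 0.05)

  # realized binding prevalence (within binding proteins) within +/- 0.02
  prev <- vapply(c("dna", "rna"), function(task) {
    sub <- recs[cls == paste0(task, "_binding")]
    lab <- unlist(lapply(sub, function(r)
      trackLabels(r)[[paste0(task, "_binding")]]))
    mean(lab)
  }, numeric(1))
  expected <- cfg$bindingPrevalenceStructured * (1 - cfg$disorderContent) +
    cfg$bindingPrevalenceDisordered * cfg$disorderContent
  expect_equal(unname(prev), rep(expected, 2), tolerance = 0.02 / expected)

  # coil bias of predicted SS inside disordered regions
  ssP <- unlist(lapply(recs, function(r) trackPredictions(r)$ss3_pred))
  coilDis <- mean(ssP[dis == 1L] == "C")
  expect_equal(coilDis, cfg$ssPropsDisordered[["C"]], tolerance = 0.05)
})

test_that("class counts stay within 3 sd of the multinomial expectation", {
  n <- 60
  cfg0 <- synthConfig(nProteins = n)
  p <- cfg0$classProbs
  bound <- 3 * sqrt(n * p * (1 - p))
  exceed <- 0L
  for (seed in 1:20) {
    ds <- generateDataset(synthConfig(nProteins = n, seed = seed))
    cls <- vapply(records(ds), bindingClass, character(1))
    counts <- table(factor(cls, c("dna_binding", "rna_binding",
                                  "non_na_binding")))
    exceed <- exceed + sum(abs(counts - n * p) > bound)
  }
  # 60 three-sigma checks: allow the rare boundary exceedance, no more
  expect_lte(exceed, 2L)
})

test_that("consensus gain over the best input decreases with overlap kappa", {
  gain <- vapply(c(0, 0.5, 1), function(kappa) {
    mean(vapply(1:5, function(seed) {
      cfg <- synthConfig(nProteins = 80, lengthRange = c(60, 150),
                         overlapKappa = kappa, noiseSigma = 0.1,
                         seed = 100 + seed)
      ds <- generateDataset(cfg)
      te <- splitRecords(ds, "test")
      norm <- fitNormalizer(splitRecords(ds, "train"), "dna")
      aucOf <- function(src) {
        pool <- poolResidues(te, "dna", src, norm = norm)
        aucScore(pool$labels, pool$scores)
      }
      aucOf("avg") - max(aucOf("disorder_trained"), aucOf("structure_trained"))
    }, numeric(1)))
  }, numeric(1))
  expect_true(gain[1] > gain[2])
  expect_true(gain[2] > gain[3])
  # fully redundant tracks leave no complementarity gain to harvest
  expect_lte(gain[3], 0.01)
})
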