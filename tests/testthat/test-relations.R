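test_that("fractions and compositions follow their definitions", {
  expect_equal(fractionInGroup(c(TRUE, FALSE, FALSE, FALSE),
                               rep(TRUE, 4)), 0.25)
  expect_equal(fractionInGroup(rep(TRUE, 5), c(TRUE, TRUE, FALSE, NA, TRUE)),
               1)
  expect_error(fractionInGroup(c(TRUE, FALSE), c(FALSE, FALSE)), "empty")
  # unknowns excluded from numerator and denominator
  expect_equal(fractionInGroup(c(TRUE, NA, FALSE, TRUE),
                               c(TRUE, TRUE, TRUE, TRUE)), 2 / 3)

  expect_equal(unname(ssComposition(c("H", "H", "E", "C"))),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(ssComposition(rep("C", 6))), c(0, 0, 1))
  expect_error(ssComposition(character(0)), "empty")
  set.seed(2)
  for (i in 1:10) {
    ss <- sample(c("H", "E", "C", NA), 50, replace = TRUE)
    if (all(is.na(ss))) next
    expect_equal(sum(ssComposition(ss)), 1)
  }
})

test_that("percentile summary interpolates linearly between closest ranks", {
  s <- percentileSummary(1:100)
  # independent rank-arithmetic oracle: h = (n-1)p + 1 on the sorted values
  oracle <- vapply(c(0.05, 0.25, 0.5, 0.75, 0.95), function(p) {
    h <- (100 - 1) * p + 1
    lo <- floor(h)
    lo + (h - lo) * ((lo + 1) - lo)  # values are 1..100, x[k] = k
  }, numeric(1))
  expect_equal(unname(s[1:5]), oracle)
  expect_true(all(diff(s[1:5]) >= 0))
  expect_equal(unname(percentileSummary(rep(2.5, 9))[1:5]), rep(2.5, 5))
  expect_equal(unname(percentileSummary(7)[1:5]), rep(7, 5))
  expect_equal(unname(percentileSummary(c(3, NA, 1))["n"]), 2)
  expect_error(percentileSummary(NA_real_), "no values")
})

test_that("relative binding fraction per SS state matches direct counting", {
  rec <- makeBindingRecord("D1", 12, 3)
  lab <- rec@labels
  lab$ss3 <- c(rep("H", 10), "E", "C")
  lab$dna_binding <- c(1L, rep(0L, 9), 0L, 1L)
  rec@labels <- lab
  ds <- TrackDataset(list(rec, makeBindingRecord("N1", 8, 0,
                                                 "non_na_binding")))
  f <- relativeBindingBySs(ds, "dna")
  expect_equal(unname(f), c(0.1, 0, 1))  # 1/10 helix, 0/1 strand, 1/1 coil
  # a state with zero residues is undefined, not zero
  lab$ss3 <- rep("H", 12)
  rec@labels <- lab
  f2 <- relativeBindingBySs(TrackDataset(list(rec)), "dna")
  expect_true(is.na(f2[["E"]]) && is.na(f2[["C"]]))
})

test_that("built-in generator effects are recovered with significance", {
  cfg <- synthConfig(nProteins = 120, lengthRange = c(60, 150), seed = 3)
  ds <- generateDataset(cfg)

  # disordered regions are coil-enriched in the predicted secondary structure
  rel <- relationSuite(ds, "disorder_ss",
                       sources = c("experimental", "predicted"),
                       reps = 50, frac = 0.2, seed = 3)
  st <- relationStats(rel)
  expect_gt(st$disordered[["C"]], st$structured[["C"]])
  tst <- relationTests(rel)$disordered_vs_structured
  expect_true(isSignificant(tst))

  # disordered residues carry more binding than structured ones
  relb <- relationSuite(ds, "disorder_binding",
                        sources = c("experimental", "experimental"),
                        task = "dna", reps = 50, frac = 0.2, seed = 3)
  stb <- relationStats(relb)
  expect_gt(stb$binding, stb$non_binding)
  expect_true(isSignificant(relationTests(relb)$binding_vs_non_binding))

  # binding residues have higher experimental accessibility
  relr <- relationSuite(ds, "binding_rsa",
                        sources = c("experimental", "experimental"),
                        task = "dna", reps = 50, frac = 0.2, seed = 3)
  str_ <- relationStats(relr)
  expect_gt(str_$binding[["p50"]], str_$non_binding[["p50"]])
  expect_true(isSignificant(relationTests(relr)$binding_vs_non_binding))

  # binding is depleted among strand residues: coil > helix > strand
  rels <- relationSuite(ds, "binding_ss",
                        sources = c("experimental", "experimental"),
                        task = "dna", reps = 50, frac = 0.2, seed = 3)
  f <- relationStats(rels)$relative_fraction
  expect_gt(f[["C"]], f[["H"]])
  expect_gt(f[["H"]], f[["E"]])
  expect_true(isSignificant(relationTests(rels)$coil_vs_strand))
})

test_that("experimental and predicted sources agree in direction", {
  cfg <- synthConfig(nProteins = 120, lengthRange = c(60, 150), seed = 13)
  ds <- generateDataset(cfg)
  # SS x RSA: coil is more exposed than helix, helix more than strand,
  # whichever source provides the tracks
  for (src in list(c("experimental", "experimental"),
                   c("predicted", "predicted"))) {
    rel <- relationSuite(ds, "ss_rsa", sources = src, reps = 30,
                         frac = 0.2, seed = 13)
    st <- relationStats(rel)
    expect_gt(st$coil[["p50"]], st$helix[["p50"]])
    expect_gt(st$helix[["p50"]], st$strand[["p50"]])
  }
})

test_that("identical experimental and predicted tracks give identical stats", {
  cfg <- synthConfig(nProteins = 20, lengthRange = c(50, 90),
                     disorderContent = 0, seed = 9)
  ds <- generateDataset(cfg)
  recs <- lapply(records(ds), function(r) {
    p <- r@predictions
    p$ss3_pred <- r@labels$ss3
    p$rsa_pred <- r@labels$rsa
    r@predictions <- p
    r
  })
  ds2 <- TrackDataset(recs)
  re <- relationSuite(ds2, "ss_rsa", sources = c("experimental",
                                                 "experimental"),
                      reps = 20, frac = 0.3, seed = 5)
  rp <- relationSuite(ds2, "ss_rsa", sources = c("predicted", "predicted"),
                      reps = 20, frac = 0.3, seed = 5)
  expect_equal(relationStats(re), relationStats(rp))
  expect_equal(pValue(relationTests(re)$coil_vs_helix),
               pValue(relationTests(rp)$coil_vs_helix))
})

test_that("undefined statistics propagate as NA, never as zero", {
  cfg <- synthConfig(nProteins = 20, lengthRange = c(50, 90), seed = 4)
  ds <- generateDataset(cfg)
  # experimental RSA cannot be measured for disordered residues; the
  # disordered group's summary is NA and the contrast is reported untested
  rel <- relationSuite(ds, "disorder_rsa",
                       sources = c("experimental", "experimental"),
                       reps = 10, frac = 0.3, seed = 4)
  expect_true(all(is.na(relationStats(rel)$disordered)))
  expect_false("disordered_vs_structured" %in% names(relationTests(rel)))
  expect_error(relationSuite(ds, "no_such_pair"), "pair")
})
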