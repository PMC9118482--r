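test_that("track_tsv round trip reproduces the dataset exactly", {
  for (seed in c(1, 7, 23)) {
    cfg <- synthConfig(nProteins = 12, lengthRange = c(40, 80), seed = seed)
    ds <- generateDataset(cfg)
    path <- withr::local_tempfile(fileext = ".tsv")
    writeDataset(ds, path)
    ds2 <- readDataset(path, provenance = ds@provenance)
    expect_equal(recordIds(ds2), recordIds(ds))
    for (i in seq_along(ds)) {
      expect_equal(seqString(ds2[[i]]), seqString(ds[[i]]))
      expect_equal(trackLabels(ds2[[i]]), trackLabels(ds[[i]]))
      expect_equal(trackPredictions(ds2[[i]]), trackPredictions(ds[[i]]))
      expect_equal(bindingClass(ds2[[i]]), bindingClass(ds[[i]]))
      expect_equal(recordSplit(ds2[[i]]), recordSplit(ds[[i]]))
    }
  }
})

test_that("writing the same dataset twice is byte-identical", {
  cfg <- synthConfig(nProteins = 10, lengthRange = c(40, 60), seed = 3)
  ds <- generateDataset(cfg)
  p1 <- withr::local_tempfile()
  p2 <- withr::local_tempfile()
  writeDataset(ds, p1)
  writeDataset(ds, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("empty dataset writes a header-only file", {
  path <- withr::local_tempfile()
  writeDataset(TrackDataset(), path)
  expect_identical(readLines(path), "# nucmeta track_tsv v1")
  expect_length(readDataset(path), 0)
})

test_that("absent tracks round-trip as absent and NA values as NA", {
  rec <- ProteinRecord("P1", "MKLVA",
                       labels = list(disorder = c(0L, 0L, 1L, NA, 0L)),
                       predictions = list(
                         disorder_prop = c(0.1, 0.2, NA, 0.4, 0.5)))
  path <- withr::local_tempfile()
  writeDataset(TrackDataset(list(rec)), path)
  back <- readDataset(path)[[1]]
  expect_named(trackLabels(back), "disorder")  # rsa etc. not zero-filled
  expect_identical(trackLabels(back)$disorder, c(0L, 0L, 1L, NA, 0L))
  expect_equal(trackPredictions(back)$disorder_prop,
               c(0.1, 0.2, NA, 0.4, 0.5))
  # the written NA sentinel appears verbatim
  expect_true(any(grepl("\tNA\t", readLines(path), fixed = TRUE)))
})

test_that("malformed records are rejected with informative errors", {
  path <- withr::local_tempfile()
  writeLines(c("# nucmeta track_tsv v1",
               ">P9\tunlabeled\tsynthetic\tnone",
               "sequence\tM\tK\tL",
               "rsa\t0.100\t0.200"), path)
  expect_error(readDataset(path), "P9")  # track shorter than sequence

  writeLines(c("# nucmeta track_tsv v1",
               ">P9\tunlabeled\tsynthetic\tnone",
               "sequence\tM\tK",
               "ss3\tH\tX"), path)
  expect_error(readDataset(path), "line 4")  # unknown state code

  writeLines(c("# nucmeta track_tsv v1",
               ">P9\tunlabeled\tsynthetic\tnone",
               "sequence\tM\tK",
               "disorder\t1\t2"), path)
  expect_error(readDataset(path), "ternary")
  expect_error(readDataset(withr::local_tempfile()), "no such file")
})

test_that("caid format parses propensity and binary columns", {
  path <- withr::local_tempfile()
  writeLines(c(">P1",
               "1\tM\t0.873\t1",
               "2\tK\t0.544\t1",
               "3\tL\t0.102\t0",
               "4\tV\t0.001\t0",
               "5\tA\tNA\tNA"), path)
  ds <- readDataset(path, format = "caid")
  rec <- ds[[1]]
  expect_identical(seqString(rec), "MKLVA")
  expect_equal(trackPredictions(rec)$disorder_prop,
               c(0.873, 0.544, 0.102, 0.001, NA))
  expect_identical(trackLabels(rec)$disorder, c(1L, 1L, 0L, 0L, NA))
  # caid round trip through the writer
  out <- withr::local_tempfile()
  writeDataset(ds, out, format = "caid")
  back <- readDataset(out, format = "caid")
  expect_equal(trackPredictions(back[[1]]), trackPredictions(rec))
  expect_identical(trackLabels(back[[1]]), trackLabels(rec))
})

test_that("fasta reader returns sequence-only records", {
  path <- withr::local_tempfile()
  writeLines(c(">P1 some description", "MKLV", "AAWY", ">P2", "GGH"), path)
  ds <- readFasta(path)
  expect_identical(recordIds(ds), c("P1", "P2"))
  expect_identical(seqString(ds[[1]]), "MKLVAAWY")
  expect_identical(seqString(ds[[2]]), "GGH")
})

test_that("record validation reports violations without throwing", {
  rec <- makeBindingRecord("OK1")
  expect_identical(validateRecord(rec), character(0))

  bad <- ProteinRecord("B1", "MKLVAGHW",
                       labels = list(rsa = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6,
                                             1.3, 0.8)))
  v <- validateRecord(bad)
  expect_length(v, 1)
  expect_match(v, "rsa")
  expect_match(v, "residue 7")

  bad2 <- ProteinRecord("B2", "MKLV", bindingClass = "non_na_binding",
                        labels = list(dna_binding = c(0L, 1L, 0L, 0L)))
  expect_match(validateRecord(bad2), "non_na_binding")

  bad3 <- ProteinRecord("B3", "MKLV",
                        labels = list(disorder = c(1L, 0L, 0L, 0L),
                                      ss3 = c("H", "H", "E", "C"),
                                      rsa = c(NA, 0.2, 0.3, 0.4)))
  expect_match(validateRecord(bad3), "disordered residue 1")

  bad4 <- ProteinRecord("B4", "MKLV", bindingClass = "dna_binding",
                        labels = list(dna_binding = rep(0L, 4)))
  expect_match(validateRecord(bad4), "dna_binding")
})

test_that("dataset containers subset and index by id", {
  ds <- makeSmallDataset()
  expect_length(ds, 4)
  expect_identical(recordIds(ds[c(1, 3)]), c("D1", "N1"))
  expect_identical(ds[["N2"]]@id, "N2")
  expect_error(ds[["missing"]], "no record")
  expect_error(TrackDataset(list(makeBindingRecord("X"),
                                 makeBindingRecord("X"))), "duplicate")
})
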