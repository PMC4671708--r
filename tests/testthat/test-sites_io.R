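test_that("position schemes map labels to the documented offsets", {
  don <- positionScheme("donor")
  acc <- positionScheme("acceptor")
  expect_equal(offsetOf(don, "-1"), 9L)
  expect_equal(offsetOf(don, "+3"), 12L)
  expect_equal(offsetOf(don, "-10"), 0L)
  expect_equal(offsetOf(don, "+20"), 29L)
  expect_equal(offsetOf(don, c("+1", "+2")), c(10L, 11L))
  expect_equal(offsetOf(acc, "-3"), 17L)
  expect_equal(offsetOf(acc, "-20"), 0L)
  expect_equal(offsetOf(acc, c("-2", "-1")), c(18L, 19L))
  expect_equal(offsetOf(acc, "+1"), 20L)
  expect_error(offsetOf(don, "+21"), "unknown position")
  # invariant positions never sit in the analysis window
  expect_false(any(don@invariant %in% don@window))
  expect_false(any(acc@invariant %in% acc@window))
})

test_that("loader keeps valid records and excludes bad ones with reasons", {
  tmp <- tempfile(fileext = ".tsv")
  good <- donorSeq()
  badDi <- good
  substr(badDi, 11, 12) <- "GA"
  withN <- good
  substr(withN, 3, 3) <- "N"
  writeSiteTSV(tmp, c("a", "b", "c", "d"),
               human = c(good, badDi, good, withN),
               mouse = c(good, good, good, good),
               dog = c(good, good, substr(good, 1, 29), good))
  ds <- readSpliceSites(tmp, "donor")
  expect_s4_class(ds, "SpliceSiteSet")
  expect_equal(length(ds), 2L)               # b: bad dinucleotide, c: short
  expect_setequal(siteIds(ds), c("a", "d"))  # N is retained
  expect_equal(nrow(exclusions(ds)), 2L)
  expect_match(exclusions(ds)$reason[exclusions(ds)$id == "b"],
               "non-canonical GT")
  expect_match(exclusions(ds)$reason[exclusions(ds)$id == "c"],
               "not 30 nt")
})

test_that("empty files give empty datasets; missing columns error", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(paste(c("id", "hg19_chr_num", "hg19_chr_chain", "hg19_coord",
                     "age", "human_seq", "mouse_seq", "dog_seq"),
                   collapse = "\t"), tmp)
  ds <- readSpliceSites(tmp, "donor")
  expect_equal(length(ds), 0L)
  bad <- tempfile(fileext = ".tsv")
  writeLines("id\thuman_seq\tmouse_seq", bad)
  expect_error(readSpliceSites(bad, "donor"), "missing required column")
})

test_that("write + reload round-trips the records", {
  ds <- tinyDonorSet(5, ages = c(0.1, 0.9, 1.0, 2.5, 0.3))
  ds <- setNt(ds, "mouse", "-2", 2, "C")
  tmp <- tempfile(fileext = ".tsv")
  writeSpliceSites(ds, tmp)
  expect_true(file.exists(paste0(tmp, ".provenance.json")))
  back <- readSpliceSites(tmp, "donor")
  expect_equal(siteIds(back), siteIds(ds))
  expect_equal(as.character(siteSeqs(back, "human")),
               as.character(siteSeqs(ds, "human")))
  expect_equal(as.character(siteSeqs(back, "mouse")),
               as.character(siteSeqs(ds, "mouse")))
  expect_equal(as.character(siteSeqs(back, "dog")),
               as.character(siteSeqs(ds, "dog")))
  expect_equal(siteAges(back), siteAges(ds))
})

test_that("flipped sequence orientation is auto-detected and normalized", {
  std <- donorSeq(exon = "ACGTACGTAA")
  flipped <- paste0(substr(std, 13, 30), substr(std, 11, 12),
                    substr(std, 1, 10))
  tmp <- tempfile(fileext = ".tsv")
  writeSiteTSV(tmp, c("x", "y"), human = rep(flipped, 2),
               mouse = rep(flipped, 2), dog = rep(flipped, 2))
  ds <- readSpliceSites(tmp, "donor")
  expect_equal(length(ds), 2L)
  expect_equal(ds@provenance$orientation, "flipped")
  expect_equal(as.character(siteSeqs(ds, "human")[1]), std)
})

test_that("canonical dinucleotide holds in all three species after load", {
  ds <- generateTriples(defaultGeneratorSpec("acceptor", n = 50, seed = 2))
  tmp <- tempfile(fileext = ".tsv")
  writeSpliceSites(ds, tmp)
  back <- readSpliceSites(tmp, "acceptor")
  for (g in c("human", "mouse", "dog")) {
    s <- as.character(siteSeqs(back, g))
    expect_true(all(substr(s, 19, 20) == "AG"))
  }
})

test_that("age split is exhaustive, boundary goes old, negatives error", {
  ds <- tinyDonorSet(6, ages = c(0, 0.99, 1.0, 3.2, NA, 0.5))
  sp <- splitByAge(ds)
  expect_equal(length(sp$young) + length(sp$old), 5L)
  expect_equal(sp$nMissingAge, 1L)
  expect_true("s03" %in% siteIds(sp$old))    # age exactly 1.0 is old
  expect_setequal(c(siteIds(sp$young), siteIds(sp$old)),
                  setdiff(siteIds(ds), "s05"))
  expect_length(intersect(siteIds(sp$young), siteIds(sp$old)), 0L)
  allZero <- tinyDonorSet(3, ages = rep(0, 3))
  expect_equal(length(splitByAge(allZero)$young), 3L)
  neg <- tinyDonorSet(2, ages = c(0.5, -0.1))
  expect_error(splitByAge(neg), "negative")
  # custom threshold
  sp2 <- splitByAge(ds, thresholdKs = 0.75)
  expect_true("s02" %in% siteIds(sp2$old))
})
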