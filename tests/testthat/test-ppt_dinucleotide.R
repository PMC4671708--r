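acceptorSet <- function(introns, exon = "GCCGCCGCCG") {
  SpliceSiteSet(sprintf("a%03d", seq_along(introns)),
                human = paste0(introns, "AG", exon),
                mouse = paste0(introns, "AG", exon),
                dog = paste0(introns, "AG", exon),
                ssType = "acceptor")
}

PPT <- paste0("-", 12:7)

test_that("all-T regions give TT ratio 1 and undefined others", {
  ds <- acceptorSet(rep(paste(rep("T", 18), collapse = ""), 3))
  tab <- dinucleotideObsExp(ds, PPT)
  tt <- tab[tab$dinucleotide == "TT", ]
  expect_equal(tt$ratio, 1)
  expect_equal(tt$observedCount, 3 * 5)    # 5 overlapping pairs per site
  expect_true(all(is.nan(tab$ratio[tab$dinucleotide != "TT"])))
})

test_that("i.i.d. sequences have all ratios near 1 at large n", {
  set.seed(50)
  intr <- vapply(1:4000, function(i)
    paste(sample(NUC4, 18, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)),
          collapse = ""), "")
  ds <- acceptorSet(intr)
  tab <- dinucleotideObsExp(ds, PPT)
  expect_true(all(abs(tab$ratio - 1) < 0.12))
})

test_that("pair counts pool all overlapping pairs minus skipped Ns", {
  set.seed(51)
  intr <- vapply(1:30, function(i)
    paste(sample(c(NUC4, "N"), 18, replace = TRUE,
                 prob = c(rep(0.23, 4), 0.08)), collapse = ""), "")
  ds <- acceptorSet(intr)
  tab <- dinucleotideObsExp(ds, PPT)
  # brute-force count of non-N adjacent pairs in the region
  off <- offsetOf(positionScheme("acceptor"), PPT) + 1L
  s <- substr(as.character(siteSeqs(ds, "human")), off[1], off[length(off)])
  nPairs <- 0
  for (x in s) for (j in 1:5) {
    pair <- substr(x, j, j + 1)
    if (!grepl("N", pair)) nPairs <- nPairs + 1
  }
  expect_equal(sum(tab$observedCount), nPairs)
})

test_that("Markov fit matches hand tallies and flags empty rows", {
  ds <- acceptorSet(rep(paste0("TTTTTTTT", "TCTCTC", "TTTT"), 2))
  mk <- fitMarkovRegion(ds, PPT)   # region = TCTCTC
  expect_equal(mk@transition["T", "C"], 1)
  expect_equal(mk@transition["C", "T"], 1)
  expect_equal(unname(mk@initial), c(0, 0, 0, 1))
  expect_true(all(mk@flagged[c("A", "G")]))
  expect_equal(unname(mk@transition["A", ]), rep(0.25, 4))

  # 4-sequence fixture vs hand tally
  ds4 <- acceptorSet(c(paste0("TTTTTTTT", "TTCTCC", "TTTT"),
                       paste0("TTTTTTTT", "CTTTGC", "TTTT"),
                       paste0("TTTTTTTT", "TCCTTT", "TTTT"),
                       paste0("TTTTTTTT", "GTTCTT", "TTTT")))
  mk4 <- fitMarkovRegion(ds4, PPT)
  # hand tally of pairs starting with T across the 4 regions:
  # TTCTCC: TT,TC,CT,TC,CC ; CTTTGC: CT,TT,TT,TG,GC ;
  # TCCTTT: TC,CC,CT,TT,TT ; GTTCTT: GT,TT,TC,CT,TT
  # from T: TT x7, TC x4, TG x1  (12 total)
  expect_equal(unname(mk4@transition["T", ]),
               c(0, 4, 1, 7) / 12, tolerance = 1e-12)
  # initial = first-position frequencies: T,C,T,G
  expect_equal(unname(mk4@initial), c(0, 1, 1, 2) / 4)
})

test_that("artificial PPT keeps flanks and honors a degenerate chain", {
  set.seed(53)
  intr <- vapply(1:20, function(i)
    paste(sample(NUC4, 18, replace = TRUE), collapse = ""), "")
  ds <- acceptorSet(intr)
  allT <- matrix(rep(c(0, 0, 0, 1), each = 4), 4, 4,
                 dimnames = list(NUC4, NUC4))
  degen <- new("MarkovRegionModel", initial = c(0, 0, 0, 1),
               transition = allT, region = PPT,
               flagged = rep(FALSE, 4))
  art <- generateArtificialPPT(ds, PPT, degen, genome = "human", seed = 2)
  off <- offsetOf(positionScheme("acceptor"), PPT) + 1L
  s <- as.character(siteSeqs(art, "human"))
  expect_true(all(substr(s, off[1], off[6]) == "TTTTTT"))
  # flanks untouched, other genomes untouched
  expect_equal(substr(s, 1, off[1] - 1),
               substr(as.character(siteSeqs(ds, "human")), 1, off[1] - 1))
  expect_equal(substr(s, off[6] + 1, 30),
               substr(as.character(siteSeqs(ds, "human")), off[6] + 1, 30))
  expect_equal(as.character(siteSeqs(art, "mouse")),
               as.character(siteSeqs(ds, "mouse")))
})

test_that("Markov regeneration preserves pairs but breaks lag-2 structure", {
  # source with strong lag-2 periodicity: alternating TC repeated
  set.seed(54)
  base <- c("TCTCTC", "CTCTCT")
  intr <- vapply(1:3000, function(i)
    paste0("TTTTTTTT", sample(base, 1), "TTTT"), "")
  ds <- acceptorSet(intr)
  mk <- fitMarkovRegion(ds, PPT)
  art <- generateArtificialPPT(ds, PPT, mk, genome = "human", seed = 8)
  tabArt <- dinucleotideObsExp(art, PPT)
  tabReal <- dinucleotideObsExp(ds, PPT)
  # adjacent-pair (dinucleotide) content is preserved within sampling error
  for (dn in c("TC", "CT")) {
    expect_equal(tabArt$observedFreq[tabArt$dinucleotide == dn],
                 tabReal$observedFreq[tabReal$dinucleotide == dn],
                 tolerance = 0.05)
  }
  # mononucleotide content preserved too
  mkArt <- fitMarkovRegion(art, PPT)
  expect_equal(unname(mkArt@initial), unname(mk@initial), tolerance = 0.05)
})

test_that("run lengths count maximal tandem dinucleotide repeats", {
  expect_equal(unname(runLengthCounts("ACACAC", "AC")), c(0, 0, 1))
  expect_length(runLengthCounts("TTTT", "AC"), 0)
  expect_equal(unname(runLengthCounts(c("TTACACTT", "ACAC"), "AC")),
               c(0, 2))
  # fixture vs an exhaustive scan oracle
  set.seed(55)
  seqs <- vapply(1:200, function(i)
    paste(sample(NUC4, 30, replace = TRUE), collapse = ""), "")
  for (dn in c("TC", "CT", "AG")) {
    got <- runLengthCounts(seqs, dn)
    # oracle: slide over every start offset, count maximal repeats
    oracle <- integer(0)
    for (s in seqs) {
      j <- 1
      while (j <= nchar(s) - 1) {
        k <- 0
        while (j + 2 * k + 1 <= nchar(s) &&
               substr(s, j + 2 * k, j + 2 * k + 1) == dn) k <- k + 1
        if (k > 0) {
          if (k > length(oracle)) oracle <- c(oracle, integer(k - length(oracle)))
          oracle[k] <- oracle[k] + 1L
          j <- j + 2 * k
        } else j <- j + 1
      }
    }
    expect_equal(unname(got), oracle)
  }
})
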